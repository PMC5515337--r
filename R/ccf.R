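#' Tumor cell fraction of a mutation
#'
#' Deterministic cancer-cell-fraction estimate from the standard identity
#'
#' `ccf = vaf * (purity * local_cn + 2 * (1 - purity)) / (purity * multiplicity)`
#'
#' i.e. the observed variant allele fraction rescaled by the expected
#' allele dilution given tumor purity, the local total copy number in
#' tumor cells, the normal-cell copy number (2), and the number of mutant
#' copies per tumor cell. The raw value is returned unclamped; values above
#' 1 indicate noise or a misspecified multiplicity and are clamped by the
#' callers that need a fraction.
#'
#' @param vaf variant allele fraction in `[0, 1]`.
#' @param purity tumor cell content in `(0, 1]`.
#' @param local_cn local total copy number in tumor cells (non-negative
#'   integer).
#' @param multiplicity mutant copies per tumor cell (integer in
#'   `[1, max(local_cn, 1)]`).
#' @return numeric vector of (unclamped) tumor cell fractions.
#' @export
#' @examples
#' estimate_ccf(0.25, 0.5, 2, 1)      # 1: heterozygous clonal at 50% purity
#' estimate_ccf(0.1, 0.4, 3, 1)       # 0.6
estimate_ccf <- function(vaf, purity, local_cn, multiplicity = 1) {
  if (any(purity <= 0))
    stop("purity must be > 0 (a sample with no tumor cells carries no",
         " information about tumor cell fractions)", call. = FALSE)
  if (any(purity > 1)) stop("purity must be <= 1", call. = FALSE)
  if (any(local_cn < 0)) stop("local_cn must be non-negative", call. = FALSE)
  if (any(multiplicity < 1) || any(multiplicity > pmax(local_cn, 1)))
    stop("multiplicity must lie in [1, max(local_cn, 1)]", call. = FALSE)
  vaf * (purity * local_cn + 2 * (1 - purity)) / (purity * multiplicity)
}

#' Most plausible mutant-copy multiplicity
#'
#' With purity and local copy number fixed, the expected VAF is
#' proportional to the multiplicity; the estimator rounds the implied
#' multiplicity at `ccf = 1` and clamps it into `[1, max(local_cn, 1)]`.
#' Equivalent to choosing the integer multiplicity whose implied CCF is
#' closest to 1 for sub-unit spacing.
#'
#' @inheritParams estimate_ccf
#' @return integer vector of multiplicities.
#' @export
#' @examples
#' estimate_multiplicity(0.5, 1, 2)   # 1
#' estimate_multiplicity(0.9, 1, 2)   # 2
estimate_multiplicity <- function(vaf, purity, local_cn) {
  if (any(purity <= 0) || any(purity > 1))
    stop("purity must be in (0, 1]", call. = FALSE)
  m <- round(vaf * (purity * local_cn + 2 * (1 - purity)) / purity)
  as.integer(pmin(pmax(m, 1), pmax(local_cn, 1)))
}

#' Estimate tumor cell fraction and classify clonality
#'
#' Computes the VAF from read counts, an exact binomial (Clopper-Pearson)
#' confidence interval on it, propagates point estimate and interval
#' through the CCF identity (same multiplier applied to both endpoints),
#' clamps the fraction scale to `[0, 1]`, and labels the mutation *clonal*
#' when the interval's upper bound reaches `clonal_threshold`: a mutation
#' is called clonal unless its data exclude presence in (essentially) all
#' tumor cells.
#'
#' @param alt_count mutant read count(s).
#' @param depth total depth(s) (> 0).
#' @param purity tumor cell content in `(0, 1]` (recycled).
#' @param local_cn local total copy number (recycled; default 2).
#' @param multiplicity mutant copies per tumor cell; `NULL` (default) to
#'   estimate via [estimate_multiplicity()].
#' @param clonal_threshold CCF upper-bound threshold for the clonal call
#'   (default 0.9).
#' @param conf_level confidence level of the binomial interval
#'   (default 0.95).
#' @return a `fel_ccf` data.frame with columns `alt_count`, `depth`, `vaf`,
#'   `purity`, `local_cn`, `multiplicity`, `ccf` (raw), `ccf_clamped`,
#'   `ci_low`, `ci_high` (clamped), `label`.
#' @export
#' @examples
#' classify_clonality(200, 400, purity = 1)   # ccf 1, clonal
#' classify_clonality(10, 400, purity = 1)    # ccf 0.05, subclonal
classify_clonality <- function(alt_count, depth, purity, local_cn = 2,
                               multiplicity = NULL, clonal_threshold = 0.9,
                               conf_level = 0.95) {
  n <- max(length(alt_count), length(depth), length(purity),
           length(local_cn))
  alt_count <- rep_len(alt_count, n); depth <- rep_len(depth, n)
  purity <- rep_len(purity, n); local_cn <- rep_len(local_cn, n)
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  if (any(alt_count > depth))
    stop("alt_count must not exceed depth", call. = FALSE)
  vaf <- alt_count / depth
  if (is.null(multiplicity))
    multiplicity <- estimate_multiplicity(vaf, purity, local_cn)
  multiplicity <- rep_len(multiplicity, n)
  mult_factor <- (purity * local_cn + 2 * (1 - purity)) /
    (purity * multiplicity)
  ccf <- vaf * mult_factor
  ci <- t(vapply(seq_len(n), function(i)
    stats::binom.test(alt_count[i], depth[i],
                      conf.level = conf_level)$conf.int,
    numeric(2)))
  ci_low <- pmin(pmax(ci[, 1] * mult_factor, 0), 1)
  ci_high <- pmin(pmax(ci[, 2] * mult_factor, 0), 1)
  out <- data.frame(
    alt_count = alt_count, depth = depth, vaf = vaf, purity = purity,
    local_cn = local_cn, multiplicity = multiplicity,
    ccf = ccf, ccf_clamped = pmin(pmax(ccf, 0), 1),
    ci_low = ci_low, ci_high = ci_high,
    label = ifelse(ci_high >= clonal_threshold, "clonal", "subclonal"),
    stringsAsFactors = FALSE)
  class(out) <- c("fel_ccf", "data.frame")
  attr(out, "clonal_threshold") <- clonal_threshold
  attr(out, "conf_level") <- conf_level
  out
}

#' Per-mutation CCF table for a set of lesions
#'
#' Joins a mutation table to per-lesion purities and (optionally) segment
#' profiles -- the local copy number of each mutation is taken from the
#' overlapping segment; mutations outside any segment get local CN 2 with
#' a warning -- then runs [classify_clonality()] per mutation.
#'
#' @param mutations a `fel_mutations` table.
#' @param purity named numeric vector (`lesion_id -> purity`) or data.frame
#'   with columns `lesion_id`, `purity`.
#' @param profiles optional named list of `fel_segments` keyed by lesion id.
#' @inheritParams classify_clonality
#' @return a `fel_ccf` data.frame with `lesion_id`, `gene`, `key` columns
#'   prepended.
#' @export
ccf_table <- function(mutations, purity, profiles = NULL,
                      clonal_threshold = 0.9, conf_level = 0.95) {
  if (is.data.frame(purity))
    purity <- stats::setNames(purity$purity, purity$lesion_id)
  missing_p <- setdiff(unique(mutations$lesion_id), names(purity))
  if (length(missing_p) > 0)
    stop("no purity provided for lesion(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  pur <- unname(purity[mutations$lesion_id])
  cn <- rep(2L, nrow(mutations))
  if (!is.null(profiles)) {
    for (lid in intersect(unique(mutations$lesion_id), names(profiles))) {
      i <- which(mutations$lesion_id == lid & !is.na(mutations$pos))
      if (length(i) == 0) next
      hit <- .local_cn_at(profiles[[lid]], mutations$chrom[i],
                          mutations$pos[i])
      if (anyNA(hit))
        warning("mutation(s) in ", lid, " fall outside all segments; ",
                "assuming local CN 2", call. = FALSE)
      cn[i][!is.na(hit)] <- hit[!is.na(hit)]
    }
  }
  est <- classify_clonality(mutations$alt_count, mutations$depth, pur,
                            local_cn = cn,
                            clonal_threshold = clonal_threshold,
                            conf_level = conf_level)
  out <- cbind(data.frame(lesion_id = mutations$lesion_id,
                          gene = mutations$gene, key = mutations$key,
                          stringsAsFactors = FALSE),
               as.data.frame(est))
  class(out) <- c("fel_ccf", "data.frame")
  attr(out, "clonal_threshold") <- clonal_threshold
  attr(out, "conf_level") <- conf_level
  out
}

#' @export
print.fel_ccf <- function(x, ...) {
  cat("<fel_ccf> ", nrow(x), " mutation(s); ",
      sum(x$label == "clonal"), " clonal / ",
      sum(x$label == "subclonal"), " subclonal (threshold ",
      attr(x, "clonal_threshold") %||% "unknown", ")\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}
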