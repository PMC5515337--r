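#' Probability that two unrelated lesions share an identical hotspot
#'
#' Recurrent hotspot mutations (the *MED12* exon-2 codon-44 changes in
#' fibroepithelial lesions) can be shared by two lesions that never had a
#' common ancestor. If a fraction `f_m` of unrelated lesions carry the
#' exact nucleotide change `m`, the probability that two independently
#' arising lesions both carry it is `f_m^2`. Frequencies are computed from
#' the raw cohort counts, never from rounded percentages: 14/177 gives
#' `(14/177)^2 = 0.00626`, which reports as 0.006 at three decimals.
#'
#' @param key mutation key(s), e.g. `"MED12:c.131G>T"` (see
#'   [mutation_key()]). Keys absent from the table have frequency 0 and
#'   therefore probability 0.
#' @param freq a `fel_freq` reference table (see [frequency_table()],
#'   [fel_cohort_freq()]).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
#' @examples
#' ca <- fel_cohort_freq("cohort_A")
#' round(chance_sharing_probability("MED12:c.131G>T", ca), 3)  # 0.006
#' round(chance_sharing_probability("MED12:c.131G>A", ca), 3)  # 0.027
chance_sharing_probability <- function(key, freq) {
  mutation_frequency(freq, key)^2
}

#' Shared-hotspot evidence for one lesion pair
#'
#' Intersects the mutation keys of two lesions and combines the per-mutation
#' chance-sharing probabilities of the shared ones by product (independence
#' across distinct mutations). Shared mutations absent from the frequency
#' table are listed but assigned probability 1 -- they carry no evidential
#' weight rather than a fabricated frequency. An empty intersection gives a
#' combined probability of 1 (no evidence of relatedness).
#'
#' @param lesion_a,lesion_b `fel_mutations` tables (or data.frames with a
#'   `key` column), one lesion each.
#' @param freq a `fel_freq` reference table.
#' @param alpha significance level for the relatedness call (default 0.05).
#' @return a `fel_evidence` object: list with `lesion_pair`,
#'   `shared_mutations`, `per_mutation_probability`, `combined_probability`,
#'   `significant`, `alpha`.
#' @export
#' @examples
#' muts <- read_mutation_table(system.file("extdata", "five_lesion",
#'   "mutations_synthetic.tsv", package = "felclone"))
#' by_lesion <- split(muts, muts$lesion_id)
#' pair_evidence(by_lesion$FA2, by_lesion$BenignPT, fel_cohort_freq("cohort_A"))
pair_evidence <- function(lesion_a, lesion_b, freq, alpha = 0.05) {
  stopifnot(inherits(freq, "fel_freq"))
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must be a probability in (0, 1)", call. = FALSE)
  key_a <- if (is.data.frame(lesion_a)) unique(lesion_a$key)
           else unique(as.character(lesion_a))
  key_b <- if (is.data.frame(lesion_b)) unique(lesion_b$key)
           else unique(as.character(lesion_b))
  id_a <- if (is.data.frame(lesion_a) && nrow(lesion_a) > 0)
    lesion_a$lesion_id[1] else "lesion_a"
  id_b <- if (is.data.frame(lesion_b) && nrow(lesion_b) > 0)
    lesion_b$lesion_id[1] else "lesion_b"
  shared <- sort(intersect(key_a, key_b))
  known <- shared %in% names(freq$counts)
  per_p <- stats::setNames(rep(1, length(shared)), shared)
  per_p[known] <- chance_sharing_probability(shared[known], freq)
  combined <- if (length(per_p) == 0) 1 else prod(per_p)
  structure(
    list(lesion_pair = c(id_a, id_b), shared_mutations = shared,
         shared_in_table = stats::setNames(known, shared),
         per_mutation_probability = per_p,
         combined_probability = combined,
         significant = combined < alpha, alpha = alpha,
         cohort_label = freq$cohort_label),
    class = "fel_evidence")
}

#' Pairwise shared-hotspot relatedness over all lesions of one patient
#'
#' Evaluates [pair_evidence()] for every unordered pair of lesions and
#' returns a per-pair summary table.
#'
#' @param lesions a `fel_mutations` table covering >= 2 lesions, or a named
#'   list of per-lesion `fel_mutations` tables.
#' @param freq a `fel_freq` reference table.
#' @param alpha significance level (default 0.05).
#' @param bonferroni if `TRUE`, divide `alpha` by the number of pairs
#'   before calling significance (off by default; per-pair probabilities
#'   are reported either way).
#' @return a `fel_graph` data.frame with one row per unordered pair:
#'   `lesion_a`, `lesion_b`, `n_shared`, `shared_keys`, `combined_p`,
#'   `significant`; the full `fel_evidence` objects are in
#'   `attr(, "evidence")`.
#' @export
#' @examples
#' muts <- read_mutation_table(system.file("extdata", "five_lesion",
#'   "mutations_synthetic.tsv", package = "felclone"))
#' relatedness_graph(muts, fel_cohort_freq("cohort_A"))
relatedness_graph <- function(lesions, freq, alpha = 0.05,
                              bonferroni = FALSE) {
  if (is.data.frame(lesions)) {
    by_lesion <- split(lesions, lesions$lesion_id)
  } else {
    by_lesion <- lesions
    if (is.null(names(by_lesion)) || anyDuplicated(names(by_lesion)))
      stop("lesions must have unique lesion ids", call. = FALSE)
  }
  ids <- names(by_lesion)
  if (length(ids) < 2)
    stop("need at least two lesions", call. = FALSE)
  pairs <- utils::combn(ids, 2)
  alpha_eff <- if (bonferroni) alpha / ncol(pairs) else alpha
  ev <- lapply(seq_len(ncol(pairs)), function(j)
    pair_evidence(by_lesion[[pairs[1, j]]], by_lesion[[pairs[2, j]]],
                  freq, alpha = alpha_eff))
  out <- data.frame(
    lesion_a = pairs[1, ], lesion_b = pairs[2, ],
    n_shared = vapply(ev, function(e) length(e$shared_mutations), integer(1)),
    shared_keys = vapply(ev, function(e)
      paste(e$shared_mutations, collapse = ";"), character(1)),
    combined_p = vapply(ev, function(e) e$combined_probability, numeric(1)),
    significant = vapply(ev, function(e) e$significant, logical(1)),
    stringsAsFactors = FALSE)
  structure(out, evidence = ev, alpha = alpha_eff,
            cohort_label = freq$cohort_label,
            class = c("fel_graph", "data.frame"))
}

#' @export
print.fel_evidence <- function(x, ...) {
  cat("<fel_evidence> ", x$lesion_pair[1], " vs ", x$lesion_pair[2], "\n",
      sep = "")
  if (length(x$shared_mutations) == 0) {
    cat("  no shared mutations; combined probability 1\n")
  } else {
    for (k in x$shared_mutations)
      cat(sprintf("  shared %-22s p = %s\n", k,
                  if (x$shared_in_table[[k]])
                    format(round(x$per_mutation_probability[[k]], 3))
                  else "1 (not in frequency table)"))
    cat(sprintf("  combined probability %.4g (%s at alpha = %g)\n",
                x$combined_probability,
                if (x$significant) "significant" else "not significant",
                x$alpha))
  }
  invisible(x)
}

#' @export
print.fel_graph <- function(x, ...) {
  cat("<fel_graph> ", nrow(x), " lesion pair(s), ",
      sum(x$significant), " significant at alpha = ", attr(x, "alpha"),
      " (frequencies: ", attr(x, "cohort_label"), ")\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}
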