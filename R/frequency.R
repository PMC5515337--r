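#' Reference cohort mutation-frequency table
#'
#' Holds, for a reference cohort of unrelated lesions, how many carried each
#' exact hotspot mutation. Frequencies `f_m = count/n_total` feed the
#' chance-sharing probability `f_m^2` (see [chance_sharing_probability()]).
#'
#' @param entries data.frame with columns `gene`, `cdna_change`, `count`
#'   and optionally `protein_change`.
#' @param n_total cohort size (positive integer).
#' @param cohort_label short label for provenance in reports.
#' @return a `fel_freq` object: list with `cohort_label`, `n_total`,
#'   `counts` (named integer vector keyed by mutation key) and `meta`.
#' @export
#' @examples
#' frequency_table(
#'   data.frame(gene = "MED12", cdna_change = "c.131G>T", count = 14),
#'   n_total = 177, cohort_label = "example")
frequency_table <- function(entries, n_total, cohort_label = "cohort") {
  n_total <- .as_count(n_total, "n_total")
  if (length(n_total) != 1 || n_total <= 0)
    stop("n_total must be a single positive integer", call. = FALSE)
  req <- c("gene", "cdna_change", "count")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  counts <- .as_count(entries$count, "count")
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  bad <- which(counts > n_total)
  if (length(bad) > 0)
    stop("count exceeds cohort size for ", entries$gene[bad[1]], " ",
         entries$cdna_change[bad[1]], ": ", counts[bad[1]], " > ", n_total,
         call. = FALSE)
  keys <- mutation_key(entries$gene, entries$cdna_change)
  if (anyDuplicated(keys))
    stop("duplicate mutation key in frequency table: ",
         keys[duplicated(keys)][1], call. = FALSE)
  structure(
    list(cohort_label = as.character(cohort_label), n_total = n_total,
         counts = stats::setNames(counts, keys),
         meta = as.data.frame(entries, stringsAsFactors = FALSE)),
    class = "fel_freq")
}

#' Read a mutation-frequency table from delimited text
#'
#' Expects a comma-delimited file with columns `gene`, `cdna_change`,
#' `count`, `n_total` (and optionally `protein_change`); `n_total` must be
#' constant across rows.
#'
#' @param path path to the CSV file.
#' @param cohort_label label for the cohort; defaults to the file name.
#' @return a `fel_freq` object.
#' @export
read_frequency_table <- function(path, cohort_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"n_total" %in% names(df))
    stop("frequency table ", path, " is missing required column(s): n_total",
         call. = FALSE)
  n_tot <- unique(.as_count(df$n_total, "n_total"))
  if (length(n_tot) != 1)
    stop("n_total must be constant within one frequency table: ", path,
         call. = FALSE)
  if (is.null(cohort_label))
    cohort_label <- sub("\\.[^.]*$", "", basename(path))
  frequency_table(df[setdiff(names(df), "n_total")], n_tot, cohort_label)
}

#' Packaged MED12 exon-2 hotspot frequency tables
#'
#' Two pooled reference cohorts of unrelated fibroepithelial lesions,
#' bundled as package fixtures:
#' * `"cohort_A"`: 98 FAs + 79 PTs (n = 177), Gly44Val (`c.131G>T`) in
#'   14/177 and Gly44Asp (`c.131G>A`) in 29/177;
#' * `"cohort_B"`: 100 FAs + 76 PTs (n = 176), Gly44Val in 13/176 and
#'   Gly44Asp in 37/176.
#'
#' @param cohort `"cohort_A"` or `"cohort_B"`.
#' @return a `fel_freq` object.
#' @export
#' @examples
#' fel_cohort_freq("cohort_A")
fel_cohort_freq <- function(cohort = c("cohort_A", "cohort_B")) {
  cohort <- match.arg(cohort)
  file <- switch(cohort, cohort_A = "med12_cohort_A.csv",
                 cohort_B = "med12_cohort_B.csv")
  path <- system.file("extdata", file, package = "felclone", mustWork = TRUE)
  read_frequency_table(path, cohort_label = cohort)
}

#' Population frequency of a mutation in a reference cohort
#'
#' @param freq a `fel_freq` object.
#' @param key mutation key(s) (see [mutation_key()]); keys absent from the
#'   table have frequency 0.
#' @return numeric vector of frequencies in `[0, 1]`.
#' @export
mutation_frequency <- function(freq, key) {
  stopifnot(inherits(freq, "fel_freq"))
  counts <- freq$counts[key]
  counts[is.na(counts)] <- 0L
  unname(counts) / freq$n_total
}

#' @export
print.fel_freq <- function(x, ...) {
  cat("<fel_freq> ", x$cohort_label, " (n = ", x$n_total, ")\n", sep = "")
  f <- x$counts / x$n_total
  for (k in names(x$counts))
    cat(sprintf("  %-22s %4d/%d  f = %.4f\n", k, x$counts[[k]], x$n_total,
                f[[k]]))
  invisible(x)
}
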