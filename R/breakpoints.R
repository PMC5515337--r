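#' Extract filtered DNA breakpoints from a segment profile
#'
#' A breakpoint is the boundary between two adjacent same-chromosome
#' segments with differing total copy number; its position is recorded as
#' the end of the left segment. Chromosome starts and ends are telomeric by
#' definition and never produce breakpoints (a whole-chromosome loss
#' yields none). Boundaries falling inside an exclusion region
#' (telomeric/centromeric windows, see [exclusion_windows()]) are removed.
#'
#' @param profile a `fel_segments` object.
#' @param excl optional `fel_regions` exclusion set.
#' @return data.frame with columns `chrom`, `pos`, `left_cn`, `right_cn`
#'   (class `fel_breakpoints`).
#' @export
#' @examples
#' p <- segment_profile(
#'   data.frame(chrom = "chr16", start = c(1, 10e6), end = c(10e6 - 1, 90e6),
#'              total_cn = c(2L, 1L)),
#'   "FA3", "hg19")
#' extract_breakpoints(p)
extract_breakpoints <- function(profile, excl = NULL) {
  stopifnot(inherits(profile, "fel_segments"))
  n <- nrow(profile)
  bp <- data.frame(chrom = character(0), pos = integer(0),
                   left_cn = integer(0), right_cn = integer(0),
                   stringsAsFactors = FALSE)
  if (n > 1) {
    i <- which(profile$chrom[-n] == profile$chrom[-1] &
               profile$total_cn[-n] != profile$total_cn[-1])
    bp <- data.frame(chrom = profile$chrom[i], pos = profile$end[i],
                     left_cn = profile$total_cn[i],
                     right_cn = profile$total_cn[i + 1],
                     stringsAsFactors = FALSE)
  }
  if (!is.null(excl) && nrow(bp) > 0)
    bp <- bp[!.in_regions(excl, bp$chrom, bp$pos), , drop = FALSE]
  rownames(bp) <- NULL
  structure(bp, lesion_id = attr(profile, "lesion_id"),
            class = c("fel_breakpoints", "data.frame"))
}

# maximum one-to-one matching between two breakpoint sets.
# Edges connect same-chromosome breakpoints within `tolerance` bp.
# A greedy pass in ascending-distance order (ties: lower coordinate in a,
# then in b) seeds the matching; augmenting paths then enlarge it to a true
# maximum, keeping the result deterministic. Returns 2-column matrix of
# (row in a, row in b).
.match_pairs <- function(a, b, tolerance) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0)
    return(matrix(integer(0), ncol = 2))
  edges <- do.call(rbind, lapply(seq_len(na), function(i) {
    j <- which(b$chrom == a$chrom[i] & abs(b$pos - a$pos[i]) <= tolerance)
    if (length(j) == 0) return(NULL)
    cbind(i = i, j = j, d = abs(b$pos[j] - a$pos[i]))
  }))
  if (is.null(edges)) return(matrix(integer(0), ncol = 2))
  edges <- edges[order(edges[, "d"], a$pos[edges[, "i"]],
                       b$pos[edges[, "j"]]), , drop = FALSE]
  match_a <- integer(na); match_b <- integer(nb)   # 0 = unmatched
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, "i"]; j <- edges[k, "j"]
    if (match_a[i] == 0 && match_b[j] == 0) {
      match_a[i] <- j; match_b[j] <- i
    }
  }
  adj <- split(edges[, "j"], factor(edges[, "i"], levels = seq_len(na)))
  augment <- function(i, visited) {
    for (j in adj[[i]]) {
      if (visited[j]) next
      visited[j] <- TRUE
      if (match_b[j] == 0) {
        match_b[j] <<- i; match_a[i] <<- j
        return(TRUE)
      }
      # tentative reassignment of j's current partner
      old <- match_b[j]
      match_b[j] <<- i; match_a[i] <<- j; match_a[old] <<- 0L
      if (augment(old, visited)) return(TRUE)
      match_b[j] <<- old; match_a[old] <<- j; match_a[i] <<- 0L
    }
    FALSE
  }
  for (i in seq_len(na))
    if (match_a[i] == 0) augment(i, logical(nb))
  i <- which(match_a > 0)
  cbind(i = i, j = match_a[i])
}

#' Count matched breakpoints between two lesions
#'
#' Size of a maximum one-to-one matching in which two breakpoints may pair
#' only if they lie on the same chromosome within `tolerance` base pairs.
#' The matching is deterministic (ascending-distance greedy seed completed
#' by augmenting paths) and exact: property tests confirm equality with an
#' exhaustive maximum-matching oracle.
#'
#' @param a,b `fel_breakpoints` data.frames (see [extract_breakpoints()]).
#' @param tolerance maximum positional difference in base pairs
#'   (default 1 Mb, the bin-level resolution of targeted-panel copy-number
#'   segmentation).
#' @return integer matched count.
#' @export
match_breakpoints <- function(a, b, tolerance = 1e6) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  nrow(.match_pairs(a, b, tolerance))
}

#' Partial identity score between two breakpoint sets
#'
#' Dice-style overlap of the filtered breakpoint sets of two lesions:
#' `2 * matched / (n_a + n_b)` (0 when both sets are empty), where
#' `matched` is the maximum one-to-one matching of [match_breakpoints()].
#' The score is symmetric and bounded in `[0, 1]`; identical sets score 1,
#' disjoint sets 0. An optional rarity-weighted variant replaces counts by
#' sums of per-breakpoint weights: `(sum of w_a + w_b over matched pairs) /
#' (sum of all weights)`, so that matches at rarely broken loci count for
#' more.
#'
#' @param a,b `fel_breakpoints` data.frames.
#' @param tolerance matching tolerance in base pairs (default 1 Mb).
#' @param weights optional function taking a breakpoint data.frame and
#'   returning one non-negative weight per row (rarity weights).
#' @return a `fel_identity` object: list with `lesion_pair`,
#'   `matched_breakpoints`, `n_a`, `n_b`, `score`, `weighted`.
#' @export
#' @examples
#' a <- data.frame(chrom = "chr4", pos = 44e6, left_cn = 1L, right_cn = 2L)
#' b <- data.frame(chrom = "chr4", pos = 44.2e6, left_cn = 1L, right_cn = 2L)
#' partial_identity_score(a, b)$score   # 1: single mutual match
partial_identity_score <- function(a, b, tolerance = 1e6, weights = NULL) {
  pairs <- .match_pairs(a, b, tolerance)
  n_a <- nrow(a); n_b <- nrow(b)
  m <- nrow(pairs)
  if (is.null(weights)) {
    score <- if (n_a + n_b > 0) 2 * m / (n_a + n_b) else 0
  } else {
    w_a <- weights(a); w_b <- weights(b)
    if (any(w_a < 0) || any(w_b < 0))
      stop("weights must be non-negative", call. = FALSE)
    tot <- sum(w_a) + sum(w_b)
    score <- if (tot > 0)
      sum(w_a[pairs[, 1]]) + sum(w_b[pairs[, 2]]) else 0
    if (tot > 0) score <- score / tot
  }
  structure(
    list(lesion_pair = c(attr(a, "lesion_id") %||% "a",
                         attr(b, "lesion_id") %||% "b"),
         matched_breakpoints = m, n_a = n_a, n_b = n_b,
         score = score, weighted = !is.null(weights),
         tolerance = tolerance),
    class = "fel_identity")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Calibrate a relatedness cutoff from unrelated-pair scores
#'
#' Lesions from different patients are unrelated by construction; their
#' partial identity scores form an empirical null. The cutoff above which
#' a pair is called clonally related is either the upper limit of the
#' normal-approximation 95% interval of the null score distribution
#' (`mean + z * sd`, `z = qnorm((1 + level)/2)`; method `"normal_ci"`,
#' default) or the empirical `(1 + level)/2` quantile (`"percentile"`).
#'
#' @param unrelated_scores numeric vector of null scores (>= 3 for
#'   `normal_ci`, >= 20 for `percentile`).
#' @param method `"normal_ci"` or `"percentile"`.
#' @param level interval level (default 0.95).
#' @return a `fel_null` object: list with `unrelated_scores`, `mean`, `sd`,
#'   `cutoff`, `method`, `level`.
#' @export
#' @examples
#' calibrate_cutoff(c(0, 0, 0, 0.04))$cutoff   # 0.01 + 1.96 * 0.02
calibrate_cutoff <- function(unrelated_scores,
                             method = c("normal_ci", "percentile"),
                             level = 0.95) {
  method <- match.arg(method)
  n_min <- if (method == "normal_ci") 3L else 20L
  if (length(unrelated_scores) < n_min)
    stop("calibration with method '", method, "' requires at least ", n_min,
         " unrelated scores (got ", length(unrelated_scores), ")",
         call. = FALSE)
  m <- mean(unrelated_scores)
  s <- stats::sd(unrelated_scores)
  cutoff <- switch(method,
    normal_ci = m + stats::qnorm((1 + level) / 2) * s,
    percentile = unname(stats::quantile(unrelated_scores,
                                        probs = (1 + level) / 2)))
  structure(list(unrelated_scores = unrelated_scores, mean = m, sd = s,
                 cutoff = cutoff, method = method, level = level),
            class = "fel_null")
}

#' Breakpoint-based clonal relatedness of one lesion pair
#'
#' Extracts filtered breakpoints for the two lesions and a reference set of
#' profiles from *other* patients, scores every cross-patient pair
#' (lesion-vs-reference and reference-vs-reference) to form the null,
#' calibrates the cutoff, and calls the pair related when its score
#' strictly exceeds it. A pair in which either lesion has no filtered
#' breakpoints (a flat copy-number profile) is non-informative: its score
#' is 0 and the verdict `FALSE`, flagged so that downstream interpretation
#' does not mistake absence of evidence for evidence of independence.
#'
#' @param a,b `fel_segments` profiles of the two lesions under test.
#' @param reference_profiles list of `fel_segments` from other patients
#'   (unrelated by construction). If empty, no cutoff can be calibrated:
#'   the result carries `status = "no_reference"` and an `NA` verdict.
#' @param excl optional `fel_regions` exclusion set.
#' @param tolerance matching tolerance in bp (default 1 Mb).
#' @param method,level cutoff calibration, see [calibrate_cutoff()].
#' @return a `fel_relatedness` object: list with `identity`
#'   (`fel_identity`), `null` (`fel_null` or `NULL`), `verdict` (logical or
#'   `NA`), `non_informative`, `status`.
#' @export
pair_relatedness <- function(a, b, reference_profiles, excl = NULL,
                             tolerance = 1e6,
                             method = c("normal_ci", "percentile"),
                             level = 0.95) {
  method <- match.arg(method)
  bp_a <- extract_breakpoints(a, excl)
  bp_b <- extract_breakpoints(b, excl)
  identity <- partial_identity_score(bp_a, bp_b, tolerance)
  non_informative <- nrow(bp_a) == 0 || nrow(bp_b) == 0
  if (length(reference_profiles) == 0) {
    return(structure(list(identity = identity, null = NULL, verdict = NA,
                          non_informative = non_informative,
                          status = "no_reference"),
                     class = "fel_relatedness"))
  }
  bp_ref <- lapply(reference_profiles, extract_breakpoints, excl = excl)
  null_scores <- c(
    vapply(bp_ref, function(r)
      partial_identity_score(bp_a, r, tolerance)$score, numeric(1)),
    vapply(bp_ref, function(r)
      partial_identity_score(bp_b, r, tolerance)$score, numeric(1)))
  if (length(bp_ref) > 1) {
    ref_pairs <- utils::combn(length(bp_ref), 2)
    null_scores <- c(null_scores, vapply(seq_len(ncol(ref_pairs)),
      function(k) partial_identity_score(bp_ref[[ref_pairs[1, k]]],
                                         bp_ref[[ref_pairs[2, k]]],
                                         tolerance)$score, numeric(1)))
  }
  null <- calibrate_cutoff(null_scores, method = method, level = level)
  verdict <- !non_informative && identity$score > null$cutoff
  structure(list(identity = identity, null = null, verdict = verdict,
                 non_informative = non_informative, status = "ok"),
            class = "fel_relatedness")
}

#' @export
print.fel_identity <- function(x, ...) {
  cat(sprintf(
    "<fel_identity> %s vs %s: %d matched of %d + %d breakpoints, score %.4f%s\n",
    x$lesion_pair[1], x$lesion_pair[2], x$matched_breakpoints, x$n_a, x$n_b,
    x$score, if (x$weighted) " (rarity-weighted)" else ""))
  invisible(x)
}

#' @export
print.fel_null <- function(x, ...) {
  cat(sprintf(
    "<fel_null> %d unrelated scores: mean %.4f, sd %.4f; %s cutoff %.4f (level %g)\n",
    length(x$unrelated_scores), x$mean, x$sd, x$method, x$cutoff, x$level))
  invisible(x)
}

#' @export
print.fel_relatedness <- function(x, ...) {
  print(x$identity)
  if (!is.null(x$null)) print(x$null)
  cat("  verdict: ",
      if (is.na(x$verdict)) "undefined (no reference profiles)"
      else if (x$non_informative) "not related (non-informative: flat profile)"
      else if (x$verdict) "clonally related" else "not related", "\n",
      sep = "")
  invisible(x)
}

#' Histogram of the null score distribution with the calibrated cutoff
#'
#' @param x a `fel_null` object.
#' @param observed optional observed pair score to mark.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.fel_null <- function(x, observed = NULL, ...) {
  graphics::hist(x$unrelated_scores, breaks = 30,
                 main = "Unrelated-pair partial identity scores",
                 xlab = "score", ...)
  graphics::abline(v = x$cutoff, lty = 2)
  if (!is.null(observed)) graphics::abline(v = observed, lwd = 2)
  invisible(x)
}
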