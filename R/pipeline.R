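# shared identity-score analysis for a set of study lesions against a
# reference panel: one null (study-vs-reference and reference-vs-reference
# cross-patient scores), one cutoff, one score per study pair
.identity_analysis <- function(profiles, reference_profiles, excl,
                               tolerance, method, level) {
  bp <- lapply(profiles, extract_breakpoints, excl = excl)
  bp_ref <- lapply(reference_profiles, extract_breakpoints, excl = excl)
  null_scores <- unlist(lapply(bp, function(x)
    vapply(bp_ref, function(r)
      partial_identity_score(x, r, tolerance)$score, numeric(1))),
    use.names = FALSE)
  if (length(bp_ref) > 1) {
    ref_pairs <- utils::combn(length(bp_ref), 2)
    null_scores <- c(null_scores, vapply(seq_len(ncol(ref_pairs)),
      function(k) partial_identity_score(bp_ref[[ref_pairs[1, k]]],
                                         bp_ref[[ref_pairs[2, k]]],
                                         tolerance)$score, numeric(1)))
  }
  null <- calibrate_cutoff(null_scores, method = method, level = level)
  ids <- names(profiles)
  pairs <- utils::combn(ids, 2)
  per_pair <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- partial_identity_score(bp[[a]], bp[[b]], tolerance)
    data.frame(lesion_a = a, lesion_b = b,
               matched_breakpoints = res$matched_breakpoints,
               n_a = res$n_a, n_b = res$n_b, score = res$score,
               cna_non_informative = res$n_a == 0 || res$n_b == 0,
               identity_related = res$n_a > 0 && res$n_b > 0 &&
                 res$score > null$cutoff,
               stringsAsFactors = FALSE)
  }))
  list(null = null, per_pair = per_pair)
}

# the pipeline's verdict rule, pure in its inputs (unit-testable):
# related if either evidence line is positive; non_informative only when a
# pair offers no usable evidence at all (no mutation data on one side and a
# flat/absent copy-number comparison); unrelated otherwise
.pair_verdict <- function(hotspot_significant, identity_related,
                          cna_non_informative, has_mutation_data) {
  if (isTRUE(hotspot_significant) || isTRUE(identity_related)) {
    verdict <- "related"
  } else if (!has_mutation_data && isTRUE(cna_non_informative)) {
    verdict <- "non_informative"
  } else {
    verdict <- "unrelated"
  }
  notes <- character(0)
  if (isTRUE(hotspot_significant)) notes <- c(notes, "hotspot")
  if (isTRUE(identity_related)) notes <- c(notes, "identity")
  if (isTRUE(hotspot_significant) && isTRUE(identity_related))
    notes <- c(notes, "concordant")
  if (isTRUE(cna_non_informative)) notes <- c(notes, "cna_non_informative")
  list(verdict = verdict, notes = paste(notes, collapse = ";"))
}

#' Run the full clonal-relatedness pipeline for one patient
#'
#' Orchestrates the three analysis stages -- shared-hotspot test, CCF
#' clonality labels, breakpoint partial-identity score with null-calibrated
#' cutoff -- into one per-pair relatedness report. A pair is called
#' *related* when either evidence line is positive (the hotspot test alone
#' suffices; concordant positives are annotated), *non_informative* when
#' neither mutation data nor an informative copy-number comparison exists
#' for it, and *unrelated* otherwise.
#'
#' The configuration (YAML file or equivalent list; relative paths are
#' resolved against the config file's directory) understands:
#' \describe{
#'   \item{genome_build}{required; no default.}
#'   \item{mutations}{path to a minimal mutation TSV
#'     ([read_mutation_table()]).}
#'   \item{frequency_table}{path to a frequency CSV, or one of the bundled
#'     cohort labels `"cohort_A"`/`"cohort_B"`.}
#'   \item{segments, purity, reference_segments}{optional SEG / purity-TSV
#'     paths; `reference_sim: {n, seed}` simulates a reference panel
#'     instead of reading one.}
#'   \item{exclusion_bed}{optional BED of telomere/centromere windows;
#'     when absent, default 3 Mb windows are generated from the bundled
#'     hg19 tables.}
#'   \item{alpha, clonal_threshold, tolerance, cutoff_method,
#'     cutoff_level}{thresholds, with the defaults 0.05, 0.9, 1e6,
#'     `"normal_ci"`, 0.95.}
#' }
#'
#' @param config path to a YAML config file, or a named list.
#' @param outdir output directory; overrides `config$outdir`. `NULL` to
#'   skip writing and just return results.
#' @return (invisibly) a list with `relatedness` (per-pair report
#'   data.frame), `ccf` (per-mutation `fel_ccf` or `NULL`), `graph`
#'   (`fel_graph`), `identity_null` (`fel_null` or `NULL`), and `paths` of
#'   any files written (`relatedness.tsv`, `relatedness.json`, `ccf.tsv`,
#'   `run_log.txt`). Reports are deterministic given identical config and
#'   inputs.
#' @export
#' @examples
#' cfg <- system.file("extdata", "five_lesion", "config.yaml",
#'                    package = "felclone")
#' res <- run_pipeline(cfg, outdir = tempfile("felclone_report_"))
#' res$relatedness[, c("lesion_a", "lesion_b", "verdict")]
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    if (!file.exists(config_path))
      stop("config file not found: ", config_path, call. = FALSE)
    cfg <- yaml::read_yaml(config_path)
    base <- dirname(normalizePath(config_path))
  } else {
    config_path <- NULL
    cfg <- config
    base <- getwd()
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  if (is.null(cfg$genome_build))
    stop("config must name genome_build (no default)", call. = FALSE)
  alpha <- cfg$alpha %||% 0.05
  clonal_threshold <- cfg$clonal_threshold %||% 0.9
  tolerance <- cfg$tolerance %||% 1e6
  cutoff_method <- cfg$cutoff_method %||% "normal_ci"
  cutoff_level <- cfg$cutoff_level %||% 0.95

  if (is.null(cfg$mutations)) stop("config must name mutations", call. = FALSE)
  mutations <- read_mutation_table(resolve(cfg$mutations))
  freq <- if (is.null(cfg$frequency_table)) {
    fel_cohort_freq("cohort_A")
  } else if (cfg$frequency_table %in% c("cohort_A", "cohort_B")) {
    fel_cohort_freq(cfg$frequency_table)
  } else read_frequency_table(resolve(cfg$frequency_table))

  profiles <- if (!is.null(cfg$segments))
    read_seg(resolve(cfg$segments), genome_build = cfg$genome_build,
             seg_value = cfg$seg_value %||% "integer_cn") else NULL
  purity <- if (!is.null(cfg$purity)) {
    p <- utils::read.delim(resolve(cfg$purity), stringsAsFactors = FALSE)
    stats::setNames(p$purity, p$lesion_id)
  } else NULL
  refs <- if (!is.null(cfg$reference_segments)) {
    read_seg(resolve(cfg$reference_segments),
             genome_build = cfg$genome_build,
             seg_value = cfg$seg_value %||% "integer_cn")
  } else if (!is.null(cfg$reference_sim)) {
    simulate_reference_cohort(
      sim_config(seed = cfg$reference_sim$seed),
      n_profiles = cfg$reference_sim$n %||% 22L)
  } else NULL
  excl <- if (!is.null(cfg$exclusion_bed)) {
    read_exclusion_bed(resolve(cfg$exclusion_bed))
  } else exclusion_windows()

  # lesion universe: anything named by mutations, segments or purity
  lesion_ids <- unique(c(mutations$lesion_id, names(profiles),
                         names(purity)))
  if (length(lesion_ids) < 2)
    stop("need at least two lesions to assess relatedness", call. = FALSE)
  if (nrow(mutations) == 0)
    warning("mutation table is empty: all pairs will lack hotspot evidence",
            call. = FALSE)
  by_lesion <- lapply(stats::setNames(lesion_ids, lesion_ids), function(id) {
    m <- mutations[mutations$lesion_id == id, , drop = FALSE]
    if (nrow(m) == 0) m$lesion_id <- character(0)
    m
  })
  graph <- relatedness_graph(by_lesion, freq, alpha = alpha)

  ccf <- if (!is.null(purity) && nrow(mutations) > 0)
    ccf_table(mutations, purity, profiles,
              clonal_threshold = clonal_threshold) else NULL

  identity <- if (!is.null(profiles) && !is.null(refs) && length(refs) > 0) {
    keep <- profiles[intersect(lesion_ids, names(profiles))]
    if (length(keep) >= 2)
      .identity_analysis(keep, refs, excl, tolerance, cutoff_method,
                         cutoff_level) else NULL
  } else NULL

  report <- graph[, c("lesion_a", "lesion_b", "n_shared", "shared_keys",
                      "combined_p", "significant")]
  names(report)[names(report) == "significant"] <- "hotspot_significant"
  if (!is.null(identity)) {
    report <- merge(report, identity$per_pair,
                    by = c("lesion_a", "lesion_b"), all.x = TRUE,
                    sort = FALSE)
    report$cutoff <- identity$null$cutoff
  } else {
    report$matched_breakpoints <- NA_integer_
    report$n_a <- NA_integer_; report$n_b <- NA_integer_
    report$score <- NA_real_; report$cna_non_informative <- NA
    report$identity_related <- NA; report$cutoff <- NA_real_
  }
  has_mut <- vapply(by_lesion, nrow, integer(1)) > 0
  vn <- lapply(seq_len(nrow(report)), function(j)
    .pair_verdict(report$hotspot_significant[j],
                  isTRUE(report$identity_related[j]),
                  report$cna_non_informative[j],
                  has_mut[[report$lesion_a[j]]] &&
                    has_mut[[report$lesion_b[j]]]))
  report$verdict <- vapply(vn, `[[`, character(1), "verdict")
  report$notes <- vapply(vn, `[[`, character(1), "notes")

  paths <- character(0)
  if (is.null(outdir)) outdir <- cfg$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(relatedness_tsv = file.path(outdir, "relatedness.tsv"),
               relatedness_json = file.path(outdir, "relatedness.json"),
               run_log = file.path(outdir, "run_log.txt"))
    utils::write.table(report, paths[["relatedness_tsv"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, paths[["relatedness_json"]],
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(ccf)) {
      paths <- c(paths, ccf_tsv = file.path(outdir, "ccf.tsv"))
      utils::write.table(as.data.frame(ccf), paths[["ccf_tsv"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    log_lines <- c(
      paste0("felclone version: ", utils::packageVersion("felclone")),
      paste0("config: ", if (is.null(config_path)) "<in-memory list>"
             else paste0(basename(config_path), " md5=",
                         unname(tools::md5sum(config_path)))),
      paste0("genome_build: ", cfg$genome_build),
      paste0("frequency_table: ", freq$cohort_label,
             " (n=", freq$n_total, ")"),
      paste0("alpha: ", alpha, "; clonal_threshold: ", clonal_threshold,
             "; tolerance: ", tolerance, "; cutoff: ", cutoff_method,
             " level ", cutoff_level),
      paste0("lesions: ", paste(lesion_ids, collapse = ", ")),
      paste0("reference profiles: ",
             if (is.null(refs)) 0L else length(refs)),
      paste0("verdicts: ",
             paste(sprintf("%s-%s=%s", report$lesion_a, report$lesion_b,
                           report$verdict), collapse = "; ")))
    writeLines(log_lines, paths[["run_log"]])
  }
  invisible(list(relatedness = report, ccf = ccf, graph = graph,
                 identity_null = if (is.null(identity)) NULL
                 else identity$null,
                 paths = paths))
}
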