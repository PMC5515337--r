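#' Configuration for the synthetic multi-lesion cohort generator
#'
#' The generator emulates the study design the analysis assumes: a patient
#' with several synchronous lesions, some of which descend from a common
#' clone. Related lesions share a founder hotspot mutation (drawn from a
#' reference spectrum) and a fixed number of copy-number breakpoints
#' (jittered between the two lesions); every lesion additionally carries
#' private mutations and private breakpoints. Read counts follow binomial
#' sampling of the purity-diluted expected allele fraction.
#'
#' Defaults mirror the study conditions: five lesions of which two pairs
#' are clonally related, founder hotspots drawn from the `cohort_A` MED12
#' spectrum, mean sequencing depth 1000x (high-depth targeted panel), three
#' shared non-telomeric/non-centromeric breakpoints per related pair, and
#' copy-number-quiet genomes (on average one private filtered breakpoint
#' per lesion; fibroadenomas and benign phyllodes tumors are frequently
#' flat).
#'
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @param n_patients number of patients for [simulate_cohort()].
#' @param lesions_per_patient lesions per patient (>= 2).
#' @param related_pair_fraction fraction of the `floor(lesions/2)` possible
#'   disjoint pairs that are clonally related (1 = the study topology: two
#'   related pairs plus one independent lesion when there are five lesions).
#' @param hotspot_spectrum a `fel_freq` table the founder and independent
#'   hotspots are drawn from.
#' @param background_mutation_rate mean private (passenger/driver) mutation
#'   count per lesion (Poisson).
#' @param purity_range uniform range for per-lesion tumor cell content.
#' @param mean_depth mean sequencing depth (Poisson).
#' @param breakpoints_per_lesion mean private filtered breakpoint count per
#'   lesion (Poisson).
#' @param shared_breakpoint_count breakpoints shared by a related pair.
#' @param tolerance_jitter maximum absolute positional jitter (bp) applied
#'   independently to each lesion's copy of a shared breakpoint; keep below
#'   the matching tolerance so shared breakpoints stay matchable.
#' @param clonal_fraction probability that a private mutation is clonal;
#'   otherwise its CCF is uniform on `subclonal_ccf_range`.
#' @param subclonal_ccf_range CCF range of subclonal private mutations.
#' @param genome data.frame `chrom`, `length` (default: bundled hg19).
#' @param centromeres data.frame `chrom`, `pos` (default: bundled hg19).
#' @return a validated `fel_sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' sim <- simulate_patient(cfg)
#' sim$truth
sim_config <- function(seed = NULL, n_patients = 1L,
                       lesions_per_patient = 5L,
                       related_pair_fraction = 1,
                       hotspot_spectrum = fel_cohort_freq("cohort_A"),
                       background_mutation_rate = 2,
                       purity_range = c(0.3, 0.7),
                       mean_depth = 1000,
                       breakpoints_per_lesion = 1,
                       shared_breakpoint_count = 3L,
                       tolerance_jitter = 2e5,
                       clonal_fraction = 0.7,
                       subclonal_ccf_range = c(0.2, 0.6),
                       genome = fel_genome(),
                       centromeres = fel_centromeres()) {
  stopifnot(inherits(hotspot_spectrum, "fel_freq"))
  if (lesions_per_patient < 2)
    stop("lesions_per_patient must be >= 2", call. = FALSE)
  probs <- c(related_pair_fraction, purity_range, clonal_fraction,
             subclonal_ccf_range)
  if (any(probs < 0) || any(probs > 1))
    stop("fractions and purities must lie in [0, 1]", call. = FALSE)
  if (any(genome$length <= 0))
    stop("degenerate genome: zero-length chromosome ",
         genome$chrom[genome$length <= 0][1], call. = FALSE)
  if (background_mutation_rate < 0 || breakpoints_per_lesion < 0 ||
      mean_depth <= 0 || tolerance_jitter < 0 || shared_breakpoint_count < 0)
    stop("rates, depth and jitter must be non-negative", call. = FALSE)
  structure(list(
    seed = seed, n_patients = as.integer(n_patients),
    lesions_per_patient = as.integer(lesions_per_patient),
    related_pair_fraction = related_pair_fraction,
    hotspot_spectrum = hotspot_spectrum,
    background_mutation_rate = background_mutation_rate,
    purity_range = purity_range, mean_depth = mean_depth,
    breakpoints_per_lesion = breakpoints_per_lesion,
    shared_breakpoint_count = as.integer(shared_breakpoint_count),
    tolerance_jitter = tolerance_jitter,
    clonal_fraction = clonal_fraction,
    subclonal_ccf_range = subclonal_ccf_range,
    genome = genome, centromeres = centromeres),
    class = "fel_sim_config")
}

# expected VAF of a mutation with given CCF under purity dilution
.expected_vaf <- function(ccf, purity, local_cn = 2, multiplicity = 1) {
  ccf * purity * multiplicity / (purity * local_cn + 2 * (1 - purity))
}

# sample n genomic positions outside the exclusion regions
.sample_positions <- function(n, genome, excl) {
  out <- data.frame(chrom = character(0), pos = numeric(0))
  while (nrow(out) < n) {
    k <- max(n - nrow(out), 1) * 2L
    ci <- sample.int(nrow(genome), k, replace = TRUE,
                     prob = genome$length)
    pos <- floor(stats::runif(k, 1, genome$length[ci])) + 0
    keep <- !.in_regions(excl, genome$chrom[ci], pos)
    out <- rbind(out, data.frame(chrom = genome$chrom[ci][keep],
                                 pos = pos[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

# jitter shared breakpoint positions, resampling jitter that would land in
# an exclusion window (so shared breakpoints survive filtering by design)
.jitter_positions <- function(bp, jitter, genome, excl) {
  if (jitter == 0 || nrow(bp) == 0) return(bp)
  len <- stats::setNames(genome$length, genome$chrom)
  for (i in seq_len(nrow(bp))) {
    for (try in 1:50) {
      p <- bp$pos[i] + round(stats::runif(1, -jitter, jitter))
      p <- min(max(p, 2), len[[bp$chrom[i]]] - 1)
      if (!.in_regions(excl, bp$chrom[i], p)) { bp$pos[i] <- p; break }
    }
  }
  bp
}

# build a full-coverage segment profile whose internal copy-number
# transitions sit exactly at the given breakpoint positions
.profile_from_breakpoints <- function(bp, lesion_id, genome,
                                      genome_build = "hg19") {
  seg <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
    chrom <- genome$chrom[ci]; len <- genome$length[ci]
    pos <- sort(unique(bp$pos[bp$chrom == chrom]))
    pos <- pos[pos >= 1 & pos < len]
    if (length(pos) == 0)
      return(data.frame(chrom = chrom, start = 1, end = len, total_cn = 2L))
    alt_cn <- if (stats::runif(1) < 0.5) 1L else 3L
    bounds <- c(0, pos, len)
    data.frame(chrom = chrom, start = bounds[-length(bounds)] + 1,
               end = bounds[-1],
               total_cn = rep_len(c(2L, alt_cn), length(bounds) - 1))
  }))
  segment_profile(seg, lesion_id, genome_build)
}

# presence matrix of spectrum hotspots across n independent lesions
.draw_hotspots <- function(n, freq) {
  f <- freq$counts / freq$n_total
  m <- matrix(stats::runif(n * length(f)) < rep(f, each = n), nrow = n,
              dimnames = list(NULL, names(freq$counts)))
  m
}

# hotspot key -> synthetic genomic annotation (MED12-exon-2-style mapping)
.hotspot_annotation <- function(keys, freq) {
  meta <- freq$meta
  meta_keys <- mutation_key(meta$gene, meta$cdna_change)
  i <- match(keys, meta_keys)
  gene <- meta$gene[i]
  cdna <- meta$cdna_change[i]
  parsed <- regmatches(cdna, regexec("c\\.(-?[0-9]+)([ACGT])>([ACGT])", cdna))
  num <- vapply(parsed, function(p) as.integer(p[2]), integer(1))
  data.frame(
    gene = gene, cdna_change = cdna,
    protein_change = if ("protein_change" %in% names(meta))
      meta$protein_change[i] else NA_character_,
    chrom = "chrX", pos = 70339099L + num,
    ref_allele = vapply(parsed, `[`, character(1), 3),
    alt_allele = vapply(parsed, `[`, character(1), 4),
    stringsAsFactors = FALSE)
}

.private_genes <- c("FGFR2", "KDM6A", "KMT2D", "SETD2", "CCND2", "TERT")

# one lesion's read counts for a set of mutations
.sim_reads <- function(n, ccf, purity, mean_depth) {
  depth <- pmax(stats::rpois(n, mean_depth), 1L)
  vaf <- .expected_vaf(ccf, purity)
  alt <- stats::rbinom(n, depth, vaf)
  list(alt = alt, depth = depth)
}

.simulate_patient_impl <- function(config, patient_id) {
  L <- config$lesions_per_patient
  lesion_ids <- paste0(patient_id, "_L", seq_len(L))
  n_rel <- round(config$related_pair_fraction * (L %/% 2))
  clone_of <- integer(L)
  if (n_rel > 0)
    for (k in seq_len(n_rel)) clone_of[c(2 * k - 1, 2 * k)] <- k
  purity <- stats::runif(L, config$purity_range[1], config$purity_range[2])
  names(purity) <- lesion_ids
  excl <- exclusion_windows(config$genome, config$centromeres)

  # --- copy-number profiles ---
  shared_bp <- lapply(seq_len(max(n_rel, 0)), function(k)
    .sample_positions(config$shared_breakpoint_count, config$genome, excl))
  profiles <- stats::setNames(vector("list", L), lesion_ids)
  for (i in seq_len(L)) {
    bp <- .sample_positions(stats::rpois(1, config$breakpoints_per_lesion),
                            config$genome, excl)
    if (clone_of[i] > 0)
      bp <- rbind(.jitter_positions(shared_bp[[clone_of[i]]],
                                    config$tolerance_jitter,
                                    config$genome, excl), bp)
    profiles[[i]] <- .profile_from_breakpoints(bp, lesion_ids[i],
                                               config$genome)
  }

  # --- mutations ---
  # Each clone carries exactly one founder hotspot drawn at the population
  # spectrum: the tabulated variants with probability count/n_total each,
  # otherwise a distinct untabulated variant (the remainder of the
  # spectrum, e.g. the many MED12 exon-2 changes a two-entry table does
  # not list). Drawing founders at population frequency -- not uniformly
  # over the tabulated entries -- is what makes the chance that two
  # independent clones share a tabulated hotspot equal f_m^2, the quantity
  # the chance-sharing test assumes.
  spectrum <- config$hotspot_spectrum
  other_mass <- spectrum$n_total - sum(spectrum$counts)
  founder_key <- if (n_rel > 0)
    sample(c(names(spectrum$counts), ".other"), n_rel, replace = TRUE,
           prob = c(spectrum$counts, other_mass)) else character(0)
  founder_ann <- function(k) {
    key <- founder_key[k]
    if (key != ".other") return(.hotspot_annotation(key, spectrum))
    # untabulated founder: unique synthetic variant per clone
    data.frame(gene = spectrum$meta$gene[1],
               cdna_change = sprintf("c.%dG>A", 400L + k),
               protein_change = NA_character_, chrom = "chrX",
               pos = 70339099L + 400L + k, ref_allele = "G",
               alt_allele = "A", stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(L)) {
    ann <- if (clone_of[i] > 0) {
      founder_ann(clone_of[i])
    } else {
      keys <- names(spectrum$counts)[.draw_hotspots(1, spectrum)[1, ]]
      if (length(keys) > 0) .hotspot_annotation(keys, spectrum) else NULL
    }
    if (!is.null(ann) && nrow(ann) > 0) {
      keys <- mutation_key(ann$gene, ann$cdna_change)
      reads <- .sim_reads(length(keys), ccf = 1, purity = purity[i],
                          mean_depth = config$mean_depth)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(lesion_id = lesion_ids[i], stringsAsFactors = FALSE),
        ann, alt_count = reads$alt, depth = reads$depth,
        is_promoter = FALSE)
    }
    n_bg <- stats::rpois(1, config$background_mutation_rate)
    if (n_bg > 0) {
      # private mutations sit in copy-neutral regions of this lesion
      loc <- .sample_positions(4 * n_bg + 8, config$genome, excl)
      cn_ok <- .local_cn_at(profiles[[i]], loc$chrom, loc$pos) == 2L
      loc <- loc[which(cn_ok), , drop = FALSE][seq_len(min(n_bg, sum(cn_ok))),
                                               , drop = FALSE]
      if (nrow(loc) > 0) {
        gene <- sample(.private_genes, nrow(loc), replace = TRUE)
        ccf <- ifelse(stats::runif(nrow(loc)) < config$clonal_fraction, 1,
                      stats::runif(nrow(loc), config$subclonal_ccf_range[1],
                                   config$subclonal_ccf_range[2]))
        ref <- sample(c("A", "C", "G", "T"), nrow(loc), replace = TRUE)
        alt <- vapply(ref, function(r)
          sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
        reads <- .sim_reads(nrow(loc), ccf, purity[i], config$mean_depth)
        rows[[length(rows) + 1]] <- data.frame(
          lesion_id = lesion_ids[i], gene = gene,
          cdna_change = NA_character_, protein_change = NA_character_,
          chrom = loc$chrom, pos = loc$pos, ref_allele = ref,
          alt_allele = unname(alt), alt_count = reads$alt,
          depth = reads$depth, is_promoter = gene == "TERT",
          stringsAsFactors = FALSE)
      }
    }
  }
  mutations <- mutation_calls(do.call(rbind, rows))

  pairs <- utils::combn(L, 2)
  truth <- data.frame(
    lesion_a = lesion_ids[pairs[1, ]], lesion_b = lesion_ids[pairs[2, ]],
    related = clone_of[pairs[1, ]] > 0 &
      clone_of[pairs[1, ]] == clone_of[pairs[2, ]],
    stringsAsFactors = FALSE)

  structure(list(patient_id = patient_id, mutations = mutations,
                 profiles = profiles, purity = purity, truth = truth),
            class = "fel_patient_sim")
}

#' Simulate one multi-lesion patient
#'
#' Generates per-lesion mutation tables (with binomial read counts), full
#' segment profiles, per-lesion purities and ground-truth pair labels under
#' the given configuration. With `config$seed` set, output is reproducible
#' byte for byte.
#'
#' @param config a `fel_sim_config` (see [sim_config()]).
#' @param patient_id identifier prefixed to lesion ids.
#' @return a `fel_patient_sim` list: `mutations` (`fel_mutations`),
#'   `profiles` (named list of `fel_segments`), `purity` (named vector),
#'   `truth` (pair table with logical `related`).
#' @export
simulate_patient <- function(config, patient_id = "P1") {
  stopifnot(inherits(config, "fel_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  .simulate_patient_impl(config, patient_id)
}

#' Simulate a cohort of unrelated reference profiles
#'
#' Stands in for a reference panel of lesions from distinct patients (all
#' cross-pair truth labels "unrelated"): independent copy-number profiles
#' with private breakpoints only, suitable for null calibration with
#' [calibrate_cutoff()] / [pair_relatedness()].
#'
#' @param config a `fel_sim_config`; `breakpoints_per_lesion` controls the
#'   per-profile breakpoint count.
#' @param n_profiles number of reference profiles (default 22).
#' @return named list of `fel_segments`.
#' @export
simulate_reference_cohort <- function(config, n_profiles = 22L) {
  stopifnot(inherits(config, "fel_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  excl <- exclusion_windows(config$genome, config$centromeres)
  ids <- sprintf("REF%02d", seq_len(n_profiles))
  stats::setNames(lapply(ids, function(id) {
    bp <- .sample_positions(stats::rpois(1, config$breakpoints_per_lesion),
                            config$genome, excl)
    .profile_from_breakpoints(bp, id, config$genome)
  }), ids)
}

#' Simulate a multi-patient cohort
#'
#' @param config a `fel_sim_config`; `n_patients` patients are generated
#'   from one seeded random stream.
#' @return a `fel_cohort_sim` list: `patients` (list of
#'   `fel_patient_sim`) and `truth` (combined pair table with a
#'   `patient_id` column).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "fel_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  patients <- lapply(seq_len(config$n_patients), function(i)
    .simulate_patient_impl(config, sprintf("P%03d", i)))
  truth <- do.call(rbind, lapply(patients, function(p)
    cbind(patient_id = p$patient_id, p$truth)))
  rownames(truth) <- NULL
  structure(list(patients = patients, truth = truth),
            class = "fel_cohort_sim")
}

#' Write a simulated patient (or cohort) to disk
#'
#' Writes `mutations.tsv` (the minimal mutation-table format of
#' [read_mutation_table()]), `segments.seg`, `purity.tsv` and `truth.tsv`;
#' for a cohort, one subdirectory per patient. Identical seeds and configs
#' produce byte-identical files.
#'
#' @param sim a `fel_patient_sim` or `fel_cohort_sim`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(sim, "fel_cohort_sim")) {
    for (p in sim$patients)
      write_simulation(p, file.path(outdir, p$patient_id))
    return(invisible(outdir))
  }
  stopifnot(inherits(sim, "fel_patient_sim"))
  cols <- c("lesion_id", "gene", "protein_change", "cdna_change", "chrom",
            "pos", "ref_allele", "alt_allele", "alt_count", "depth",
            "is_promoter")
  utils::write.table(as.data.frame(sim$mutations)[, cols],
                     file.path(outdir, "mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_seg(sim$profiles, file.path(outdir, "segments.seg"))
  utils::write.table(
    data.frame(lesion_id = names(sim$purity), purity = unname(sim$purity)),
    file.path(outdir, "purity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.fel_patient_sim <- function(x, ...) {
  cat("<fel_patient_sim> ", x$patient_id, ": ",
      length(x$profiles), " lesions, ", nrow(x$mutations), " mutations, ",
      sum(x$truth$related), " related pair(s) of ", nrow(x$truth), "\n",
      sep = "")
  invisible(x)
}
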