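# independent oracles and small builders shared across tests

# exhaustive maximum one-to-one matching between breakpoint sets
# (branch-and-bound enumeration; independent of the package's algorithm)
brute_force_matching <- function(a, b, tolerance) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(0L)
  compat <- matrix(FALSE, na, nb)
  for (i in seq_len(na))
    compat[i, ] <- a$chrom[i] == b$chrom & abs(a$pos[i] - b$pos) <= tolerance
  best <- 0L
  rec <- function(i, used_b, count) {
    if (count + (na - i + 1L) <= best) return(invisible())
    if (i > na) { best <<- max(best, count); return(invisible()) }
    for (j in which(compat[i, ] & !used_b)) {
      used_b[j] <- TRUE
      rec(i + 1L, used_b, count + 1L)
      used_b[j] <- FALSE
    }
    rec(i + 1L, used_b, count)
  }
  rec(1L, logical(nb), 0L)
  best
}

# breakpoint table builder
bp_set <- function(chrom, pos, lesion_id = "x") {
  structure(data.frame(chrom = chrom, pos = pos,
                       left_cn = rep(2L, length(pos)),
                       right_cn = rep(1L, length(pos)),
                       stringsAsFactors = FALSE),
            lesion_id = lesion_id,
            class = c("fel_breakpoints", "data.frame"))
}

# random breakpoint instance on a couple of chromosomes, scaled so that
# chance matches are common enough to exercise the matcher
random_bp <- function(n, chroms = c("chr1", "chr2"), max_pos = 50) {
  bp_set(sample(chroms, n, replace = TRUE),
         sample.int(max_pos, n, replace = TRUE) * 1e5)
}

# minimal single-lesion mutation table
lesion_muts <- function(lesion_id, keys) {
  gene <- sub(":.*", "", keys)
  cdna <- sub("^[^:]+:", "", keys)
  mutation_calls(data.frame(
    lesion_id = lesion_id, gene = gene, cdna_change = cdna,
    alt_count = 100L, depth = 400L, stringsAsFactors = FALSE))
}

five_lesion_path <- function(file) {
  system.file("extdata", "five_lesion", file, package = "felclone",
              mustWork = TRUE)
}
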