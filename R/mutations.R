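#' Canonical identity key of a somatic mutation
#'
#' Mutations are identified by `gene:cdna_change` (e.g. `"MED12:c.131G>T"`),
#' the resolution at which hotspot sharing is assessed: Gly44Val
#' (`c.131G>T`) and Gly44Asp (`c.131G>A`) hit the same codon but are
#' distinct events. When the cDNA annotation is absent the key falls back
#' to genomic coordinates `chrom:pos:ref:alt`.
#'
#' @param gene gene symbol (character).
#' @param cdna_change cDNA-level change, HGVS-like (character; `NA`, `""`
#'   or `"."` count as absent).
#' @param chrom,pos,ref_allele,alt_allele fallback genomic identity.
#' @return character vector of mutation keys.
#' @export
#' @examples
#' mutation_key("MED12", "c.131G>T")
#' mutation_key("MED12", NA, "chrX", 70339230, "G", "T")
mutation_key <- function(gene, cdna_change, chrom = NA, pos = NA,
                         ref_allele = NA, alt_allele = NA) {
  has_cdna <- !is.na(cdna_change) & nzchar(cdna_change) & cdna_change != "."
  ifelse(has_cdna,
         paste0(gene, ":", cdna_change),
         paste(chrom, pos, ref_allele, alt_allele, sep = ":"))
}

#' Build a validated table of somatic mutation calls
#'
#' The central mutation container: one row per mutation per lesion, with
#' read support. Validation enforces `alt_count <= depth`, `depth > 0`,
#' `pos >= 1`, and uniqueness of `(lesion_id, key)`. A `vaf` column
#' (`alt_count/depth`) and the identity `key` (see [mutation_key()]) are
#' derived.
#'
#' @param df data.frame with required columns `lesion_id`, `gene`,
#'   `cdna_change`, `alt_count`, `depth`; optional `protein_change`,
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `is_promoter`.
#' @return a `fel_mutations` data.frame.
#' @export
mutation_calls <- function(df) {
  req <- c("lesion_id", "gene", "cdna_change", "alt_count", "depth")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  opt <- c(protein_change = NA_character_, chrom = NA_character_,
           pos = NA_integer_, ref_allele = NA_character_,
           alt_allele = NA_character_)
  for (nm in names(opt))
    if (!nm %in% names(df)) df[[nm]] <- rep(opt[[nm]], nrow(df))
  if (!"is_promoter" %in% names(df))
    df$is_promoter <- rep(FALSE, nrow(df))

  df$lesion_id <- as.character(df$lesion_id)
  df$gene <- as.character(df$gene)
  df$cdna_change <- as.character(df$cdna_change)
  df$alt_count <- .as_count(df$alt_count, "alt_count")
  df$depth <- .as_count(df$depth, "depth")
  df$pos <- .as_count(df$pos, "pos", allow_na = TRUE)
  df$is_promoter <- as.logical(df$is_promoter)

  if (any(df$depth <= 0))
    stop("depth must be positive (row ", which(df$depth <= 0)[1], ")",
         call. = FALSE)
  bad <- which(df$alt_count > df$depth)
  if (length(bad) > 0)
    stop("alt_count exceeds depth (row ", bad[1], ": ",
         df$alt_count[bad[1]], " > ", df$depth[bad[1]], ")", call. = FALSE)
  if (any(!is.na(df$pos) & df$pos < 1))
    stop("pos must be >= 1", call. = FALSE)

  df$vaf <- df$alt_count / df$depth
  df$key <- mutation_key(df$gene, df$cdna_change, df$chrom, df$pos,
                         df$ref_allele, df$alt_allele)
  dup <- duplicated(df[, c("lesion_id", "key")])
  if (any(dup))
    stop("duplicate mutation within a lesion: ", df$lesion_id[dup][1], " ",
         df$key[dup][1], call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("fel_mutations", "data.frame")
  df
}

# integer coercion with informative failure; `line` offsets row -> file line
.as_count <- function(x, col, allow_na = FALSE, line_offset = 0L) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(allow_na & (is.na(x) | x %in% c("", "."))))
  if (length(bad) == 0)
    bad <- which(!is.na(v) & v %% 1 != 0)
  if (length(bad) > 0) {
    where <- if (line_offset > 0) paste0("line ", bad[1] + line_offset)
             else paste0("row ", bad[1])
    stop("non-integer value in column '", col, "' at ", where, ": '",
         x[bad[1]], "'", call. = FALSE)
  }
  as.integer(v)
}

#' Read a minimal MAF-like mutation table (TSV)
#'
#' Expects a tab-delimited file with a header naming at least `lesion_id`,
#' `gene`, `cdna_change`, `alt_count` and `depth` (the documented minimal
#' mutation-table header; extra columns are kept). Rows with
#' `alt_count > depth` or non-integer read counts are rejected with the
#' offending file line.
#'
#' @param path path to the tab-delimited table.
#' @return a `fel_mutations` data.frame (see [mutation_calls()]).
#' @export
#' @examples
#' tsv <- system.file("extdata", "five_lesion", "mutations_synthetic.tsv",
#'                    package = "felclone")
#' muts <- read_mutation_table(tsv)
#' table(muts$lesion_id)
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  req <- c("lesion_id", "gene", "cdna_change", "alt_count", "depth")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("mutation table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  # validate counts with file line numbers (header = line 1)
  df$alt_count <- .as_count(df$alt_count, "alt_count", line_offset = 1L)
  df$depth <- .as_count(df$depth, "depth", line_offset = 1L)
  bad <- which(df$alt_count > df$depth)
  if (length(bad) > 0)
    stop("alt_count exceeds depth at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  mutation_calls(df)
}

#' Read somatic mutations from a VCF (minimal subset)
#'
#' Reads `CHROM`/`POS`/`REF`/`ALT` plus per-sample `AD` (allelic depths,
#' `ref,alt`) and `DP` from a VCF 4.x file. Each VCF sample column becomes a
#' lesion; records where a sample has no alternate reads are skipped for
#' that sample. Gene and cDNA annotation are not parsed from a plain VCF,
#' so mutation keys fall back to `chrom:pos:ref:alt`.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return a `fel_mutations` data.frame.
#' @export
read_mutation_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ad)) stop("VCF has no AD FORMAT field: ", path, call. = FALSE)
  out <- list()
  for (s in colnames(ad)) {
    alt_n <- suppressWarnings(
      as.integer(vapply(strsplit(ad[, s], ","), function(x)
        if (length(x) >= 2) x[2] else NA_character_, character(1))))
    ref_n <- suppressWarnings(
      as.integer(vapply(strsplit(ad[, s], ","), `[`, character(1), 1)))
    depth <- if (!is.null(dp)) as.integer(dp[, s]) else ref_n + alt_n
    depth[is.na(depth)] <- (ref_n + alt_n)[is.na(depth)]
    keep <- !is.na(alt_n) & alt_n > 0 & !is.na(depth) & depth > 0
    if (!any(keep)) next
    out[[s]] <- data.frame(
      lesion_id = s,
      gene = NA_character_, cdna_change = NA_character_,
      chrom = fix$CHROM[keep],
      pos = as.integer(fix$POS[keep]),
      ref_allele = fix$REF[keep], alt_allele = fix$ALT[keep],
      alt_count = alt_n[keep], depth = depth[keep],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    stop("no usable sample records in VCF: ", path, call. = FALSE)
  mutation_calls(do.call(rbind, out))
}

#' @export
print.fel_mutations <- function(x, ...) {
  cat("<fel_mutations> ", nrow(x), " mutation call(s) across ",
      length(unique(x$lesion_id)), " lesion(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)[
    , c("lesion_id", "gene", "protein_change", "cdna_change",
        "alt_count", "depth", "vaf")], 10), digits = 3)
  if (nrow(x) > 10) cat("... and ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}
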