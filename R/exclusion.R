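#' Read genomic exclusion regions from a BED file
#'
#' Exclusion regions mark telomeric and centromeric windows whose apparent
#' copy-number transitions are unreliable; breakpoints falling inside them
#' are discarded before identity scoring. BED intervals are 0-based
#' half-open on disk and are converted to the package's internal 1-based
#' inclusive convention on read.
#'
#' @param path path to a BED file (>= 3 columns).
#' @return a `fel_regions` data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_exclusion_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  exclusion_regions(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # already 1-based after import
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Write exclusion regions to a BED file
#'
#' @param regions a `fel_regions` data.frame (1-based inclusive).
#' @param path output path; coordinates are converted to BED's 0-based
#'   half-open convention.
#' @return `path`, invisibly.
#' @export
write_exclusion_bed <- function(regions, path) {
  stopifnot(inherits(regions, "fel_regions"))
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a set of exclusion regions
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive, `end >= start`).
#' @return a `fel_regions` data.frame.
#' @export
exclusion_regions <- function(df) {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- data.frame(chrom = as.character(df$chrom),
                    start = .as_count(df$start, "start"),
                    end = .as_count(df$end, "end"),
                    stringsAsFactors = FALSE)
  if (any(out$end < out$start))
    stop("exclusion interval with end < start", call. = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fel_regions", "data.frame")
  out
}

#' Generate telomere/centromere exclusion windows
#'
#' Builds fixed-width exclusion windows: `telomere_width` bases at each
#' chromosome end and `centromere_width` bases on each side of every
#' centromere midpoint. Window sizes default to 3 Mb, the scale at which
#' targeted-panel copy-number calls near telomeres and centromeres stop
#' being trustworthy.
#'
#' @param genome data.frame with columns `chrom`, `length`; defaults to the
#'   bundled hg19 table (22 autosomes + X).
#' @param centromeres data.frame with columns `chrom`, `pos` (centromere
#'   midpoints); defaults to the bundled hg19 table.
#' @param telomere_width,centromere_width window half-widths in base pairs.
#' @return a `fel_regions` data.frame.
#' @export
#' @examples
#' excl <- exclusion_windows()
#' head(excl)
exclusion_windows <- function(genome = fel_genome(),
                              centromeres = fel_centromeres(),
                              telomere_width = 3e6,
                              centromere_width = 3e6) {
  tel <- rbind(
    data.frame(chrom = genome$chrom, start = 1,
               end = pmin(telomere_width, genome$length)),
    data.frame(chrom = genome$chrom,
               start = pmax(1, genome$length - telomere_width + 1),
               end = genome$length))
  cen <- merge(centromeres, genome, by = "chrom")
  cen <- data.frame(chrom = cen$chrom,
                    start = pmax(1, cen$pos - centromere_width),
                    end = pmin(cen$length, cen$pos + centromere_width))
  exclusion_regions(rbind(tel, cen))
}

#' Bundled hg19 chromosome lengths (22 autosomes + X)
#' @return data.frame with columns `chrom`, `length`.
#' @export
fel_genome <- function() {
  path <- system.file("extdata", "genome_hg19.tsv", package = "felclone",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled hg19 centromere midpoints
#' @return data.frame with columns `chrom`, `pos`.
#' @export
fel_centromeres <- function() {
  path <- system.file("extdata", "centromeres_hg19.tsv", package = "felclone",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# TRUE for positions falling inside any exclusion interval
.in_regions <- function(regions, chrom, pos) {
  if (is.null(regions) || nrow(regions) == 0)
    return(rep(FALSE, length(chrom)))
  vapply(seq_along(chrom), function(i)
    any(regions$chrom == chrom[i] & regions$start <= pos[i] &
        regions$end >= pos[i]), logical(1))
}
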