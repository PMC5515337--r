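#' Build a validated per-lesion copy-number segment profile
#'
#' Segments are 1-based inclusive intervals with integer total copy number.
#' The constructor sorts by `(chrom, start)`, rejects overlapping segments,
#' and merges contiguous same-chromosome runs with equal copy number (so a
#' profile's internal boundaries are exactly its copy-number transitions).
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `total_cn`.
#' @param lesion_id sample identifier.
#' @param genome_build genome build label (required; segment coordinates
#'   are meaningless without it).
#' @return a `fel_segments` data.frame with attributes `lesion_id` and
#'   `genome_build`.
#' @export
#' @examples
#' segment_profile(
#'   data.frame(chrom = "chr16", start = c(1, 10e6), end = c(10e6 - 1, 90e6),
#'              total_cn = c(2L, 1L)),
#'   lesion_id = "FA3", genome_build = "hg19")
segment_profile <- function(segments, lesion_id, genome_build) {
  req <- c("chrom", "start", "end", "total_cn")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (missing(genome_build) || is.null(genome_build) || !nzchar(genome_build))
    stop("genome_build is required for a segment profile", call. = FALSE)
  seg <- data.frame(chrom = as.character(segments$chrom),
                    start = .as_count(segments$start, "start"),
                    end = .as_count(segments$end, "end"),
                    total_cn = .as_count(segments$total_cn, "total_cn"),
                    stringsAsFactors = FALSE)
  if (any(seg$total_cn < 0))
    stop("total_cn must be non-negative", call. = FALSE)
  bad <- which(seg$end < seg$start)
  if (length(bad) > 0)
    stop("segment end < start (", seg$chrom[bad[1]], ":", seg$start[bad[1]],
         "-", seg$end[bad[1]], ")", call. = FALSE)
  seg <- seg[order(seg$chrom, seg$start, seg$end), , drop = FALSE]
  # overlap check within chromosome
  same <- which(seg$chrom[-1] == seg$chrom[-nrow(seg)])
  ovl <- same[seg$start[same + 1] <= seg$end[same]]
  if (length(ovl) > 0) {
    i <- ovl[1]
    stop("overlapping segments in ", lesion_id, ": ",
         seg$chrom[i], ":", seg$start[i], "-", seg$end[i], " and ",
         seg$chrom[i + 1], ":", seg$start[i + 1], "-", seg$end[i + 1],
         call. = FALSE)
  }
  # merge contiguous equal-CN runs
  if (nrow(seg) > 1) {
    keep_open <- c(TRUE, !(seg$chrom[-1] == seg$chrom[-nrow(seg)] &
                           seg$total_cn[-1] == seg$total_cn[-nrow(seg)] &
                           seg$start[-1] == seg$end[-nrow(seg)] + 1L))
    run <- cumsum(keep_open)
    seg <- do.call(rbind, lapply(split(seg, run), function(g)
      data.frame(chrom = g$chrom[1], start = g$start[1],
                 end = g$end[nrow(g)], total_cn = g$total_cn[1],
                 stringsAsFactors = FALSE)))
    seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  }
  rownames(seg) <- NULL
  structure(seg, lesion_id = as.character(lesion_id),
            genome_build = as.character(genome_build),
            class = c("fel_segments", "data.frame"))
}

#' Read copy-number segment profiles from a SEG file
#'
#' SEG is the standard tab-delimited exchange format for segmented
#' copy-number data, with header `ID chrom loc.start loc.end seg.mean`
#' (column-name matching is case-insensitive and tolerant of the common
#' `sample`/`chromosome`/`start`/`end`/`value` spellings). The value column
#' is interpreted either as integer total copy number (default) or as a
#' log2 ratio mapped to `round(2 * 2^value)`.
#'
#' @param path path to the SEG file.
#' @param genome_build genome build of the coordinates (required, no
#'   default).
#' @param seg_value `"integer_cn"` (default) or `"log2_ratio"`.
#' @return named list of `fel_segments` profiles, one per sample ID.
#' @export
#' @examples
#' seg <- system.file("extdata", "five_lesion", "segments_synthetic.seg",
#'                    package = "felclone")
#' profiles <- read_seg(seg, genome_build = "hg19")
#' names(profiles)
read_seg <- function(path, genome_build,
                     seg_value = c("integer_cn", "log2_ratio")) {
  seg_value <- match.arg(seg_value)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  nm <- tolower(gsub("[^a-z0-9]+", ".", tolower(names(df))))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)
    if (length(i) == 0)
      stop("SEG file ", path, " is missing a ", what, " column", call. = FALSE)
    i[1]
  }
  id_c <- pick(c("id", "sample", "sample.id", "sampleid"), "sample ID")
  ch_c <- pick(c("chrom", "chromosome", "chr"), "chromosome")
  st_c <- pick(c("loc.start", "start"), "start")
  en_c <- pick(c("loc.end", "end"), "end")
  va_c <- pick(c("seg.mean", "value", "cn", "total.cn"), "value")
  val <- as.numeric(df[[va_c]])
  cn <- if (seg_value == "log2_ratio") as.integer(round(2 * 2^val))
        else {
          if (any(abs(val - round(val)) > 1e-8))
            stop("SEG value column is not integer copy number; use seg_value",
                 " = \"log2_ratio\" for log2-ratio files: ", path,
                 call. = FALSE)
          as.integer(round(val))
        }
  ids <- as.character(df[[id_c]])
  out <- lapply(split(seq_len(nrow(df)), ids), function(i)
    segment_profile(data.frame(chrom = as.character(df[[ch_c]][i]),
                               start = df[[st_c]][i], end = df[[en_c]][i],
                               total_cn = cn[i], stringsAsFactors = FALSE),
                    lesion_id = ids[i[1]], genome_build = genome_build))
  out[unique(ids)]
}

#' Write segment profiles to a SEG file
#'
#' Inverse of [read_seg()] (integer copy-number dialect); round-tripping a
#' profile through write/read preserves all fields.
#'
#' @param profiles a `fel_segments` object or (named) list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "fel_segments")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(ID = attr(p, "lesion_id"), chrom = p$chrom,
               loc.start = p$start, loc.end = p$end, seg.mean = p$total_cn,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.fel_segments <- function(x, ...) {
  cat("<fel_segments> ", attr(x, "lesion_id"), " (", attr(x, "genome_build"),
      "): ", nrow(x), " segment(s) on ", length(unique(x$chrom)),
      " chromosome(s)\n", sep = "")
  altered <- sum(x$total_cn != 2L)
  cat("  segments with total CN != 2: ", altered, "\n", sep = "")
  invisible(x)
}

# total copy number of a profile at given positions (2 when uncovered)
.local_cn_at <- function(profile, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    hit <- profile$chrom == chrom[i] & profile$start <= pos[i] &
      profile$end >= pos[i]
    if (any(hit)) profile$total_cn[which(hit)[1]] else NA_integer_
  }, integer(1))
}
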