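test_that("mutation tables map rows to calls and derive VAF and keys", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("lesion_id\tgene\tprotein_change\tcdna_change\talt_count\tdepth",
               "MalignantPT\tMED12\tGly44Asp\tc.131G>A\t120\t400"), tsv)
  m <- read_mutation_table(tsv)
  expect_s3_class(m, "fel_mutations")
  expect_equal(nrow(m), 1L)
  expect_equal(m$vaf, 0.30)
  expect_equal(m$key, "MED12:c.131G>A")
})

test_that("mutation table validation rejects malformed input precisely", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("lesion_id\tgene\talt_count\tdepth", "A\tMED12\t10\t5"), tsv)
  expect_error(read_mutation_table(tsv), "cdna_change")

  writeLines(c("lesion_id\tgene\tcdna_change\talt_count\tdepth",
               "A\tMED12\tc.131G>T\t10\t5"), tsv)
  expect_error(read_mutation_table(tsv), "alt_count exceeds depth at line 2")

  writeLines(c("lesion_id\tgene\tcdna_change\talt_count\tdepth",
               "A\tMED12\tc.131G>T\t10\t400",
               "A\tTERT\tc.-124C>T\tten\t400"), tsv)
  expect_error(read_mutation_table(tsv), "line 3")

  expect_error(
    mutation_calls(data.frame(lesion_id = "A", gene = "MED12",
                              cdna_change = "c.131G>T", alt_count = 1,
                              depth = 0)),
    "depth")
})

test_that("mutation table reading is order-independent", {
  path <- five_lesion_path("mutations_synthetic.tsv")
  m <- read_mutation_table(path)
  lines <- readLines(path)
  set.seed(11)
  shuf <- tempfile(fileext = ".tsv")
  writeLines(c(lines[1], sample(lines[-1])), shuf)
  m2 <- read_mutation_table(shuf)
  key_pairs <- function(x) sort(paste(x$lesion_id, x$key))
  expect_equal(key_pairs(m2), key_pairs(m))
})

test_that("the five-lesion fixture carries the expected mutation repertoire", {
  m <- read_mutation_table(five_lesion_path("mutations_synthetic.tsv"))
  expect_equal(length(unique(m$lesion_id)), 5L)
  expect_equal(nrow(m), 12L)                    # lesion-level records
  expect_equal(length(unique(m$key)), 10L)      # distinct mutations
  # sharing pattern: Gly44Val in FA2 + benign PT, Gly44Asp in FA3 +
  # malignant PT, Gly44Cys private to FA1
  expect_setequal(m$lesion_id[m$key == "MED12:c.131G>T"],
                  c("FA2", "BenignPT"))
  expect_setequal(m$lesion_id[m$key == "MED12:c.131G>A"],
                  c("FA3", "MalignantPT"))
  expect_equal(m$lesion_id[m$key == "MED12:c.130G>T"], "FA1")
  expect_setequal(m$gene[m$lesion_id == "FA2"],
                  c("MED12", "FGFR2", "KDM6A", "KMT2D"))
  expect_true(all(c("TERT", "SETD2") %in% m$gene[m$lesion_id == "MalignantPT"]))
  expect_equal(sum(m$gene == "SETD2"), 2L)
  expect_true(m$is_promoter[m$gene == "TERT"])
})

test_that("SEG reading sorts, merges equal-CN neighbours and finds boundaries", {
  seg <- tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr16\t1\t10000000\t2",
               "S1\tchr16\t10000001\t90000000\t1"), seg)
  p <- read_seg(seg, genome_build = "hg19")$S1
  bp <- extract_breakpoints(p)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$pos, 10000000L)
  expect_equal(bp$left_cn, 2L)
  expect_equal(bp$right_cn, 1L)

  # contiguous equal-CN segments merge into one; no breakpoint
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr1\t1\t100\t2",
               "S1\tchr1\t101\t200\t2"), seg)
  p <- read_seg(seg, genome_build = "hg19")$S1
  expect_equal(nrow(p), 1L)
  expect_equal(p$end, 200L)
  expect_equal(nrow(extract_breakpoints(p)), 0L)

  # unsorted input is equivalent to sorted input
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr2\t500\t900\t3",
               "S1\tchr1\t101\t200\t1",
               "S1\tchr1\t1\t100\t2"), seg)
  p_unsorted <- read_seg(seg, genome_build = "hg19")$S1
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr1\t1\t100\t2",
               "S1\tchr1\t101\t200\t1",
               "S1\tchr2\t500\t900\t3"), seg)
  p_sorted <- read_seg(seg, genome_build = "hg19")$S1
  expect_identical(as.data.frame(p_unsorted), as.data.frame(p_sorted))
})

test_that("SEG validation and dialects behave as documented", {
  seg <- tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr1\t1\t100\t2",
               "S1\tchr1\t50\t200\t1"), seg)
  expect_error(read_seg(seg, genome_build = "hg19"), "overlapping")

  # log2-ratio dialect: CN = round(2 * 2^value)
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tseg.mean",
               "S1\tchr1\t1\t100\t0",
               "S1\tchr1\t101\t200\t-1",
               "S1\tchr1\t201\t300\t0.585"), seg)
  p <- read_seg(seg, genome_build = "hg19", seg_value = "log2_ratio")$S1
  expect_equal(p$total_cn, c(2L, 1L, 3L))

  expect_error(read_seg(seg, genome_build = "hg19"), "log2")
  expect_error(read_seg(tempfile(), genome_build = "hg19"), "not found")
})

test_that("segment profiles round-trip through SEG bit-exactly", {
  profiles <- read_seg(five_lesion_path("segments_synthetic.seg"),
                       genome_build = "hg19")
  out <- tempfile(fileext = ".seg")
  write_seg(profiles, out)
  back <- read_seg(out, genome_build = "hg19")
  expect_identical(names(back), names(profiles))
  for (id in names(profiles)) {
    expect_identical(as.data.frame(back[[id]]), as.data.frame(profiles[[id]]))
    expect_identical(attr(back[[id]], "lesion_id"), id)
  }
})

test_that("frequency tables validate counts and reproduce cohort fixtures", {
  ca <- fel_cohort_freq("cohort_A")
  expect_equal(ca$n_total, 177L)
  expect_equal(mutation_frequency(ca, "MED12:c.131G>T"), 14 / 177)
  expect_equal(mutation_frequency(ca, "MED12:c.131G>A"), 29 / 177)
  cb <- fel_cohort_freq("cohort_B")
  expect_equal(cb$n_total, 176L)
  expect_equal(mutation_frequency(cb, "MED12:c.131G>T"), 13 / 176)
  expect_equal(mutation_frequency(cb, "MED12:c.131G>A"), 37 / 176)
  # all frequencies live in [0, 1]
  for (ft in list(ca, cb))
    expect_true(all(ft$counts / ft$n_total >= 0 &
                    ft$counts / ft$n_total <= 1))

  expect_error(
    frequency_table(data.frame(gene = "MED12", cdna_change = "c.131G>T",
                               count = 200), n_total = 177),
    "exceeds cohort size")

  empty <- frequency_table(
    data.frame(gene = character(0), cdna_change = character(0),
               count = integer(0)), n_total = 10)
  expect_equal(mutation_frequency(empty, "MED12:c.131G>T"), 0)
})

test_that("exclusion windows convert cleanly between BED and internal coordinates", {
  excl <- exclusion_windows(telomere_width = 3e6, centromere_width = 3e6)
  expect_s3_class(excl, "fel_regions")
  expect_true(all(excl$end >= excl$start))
  # 2 telomeric + 1 centromeric window per chromosome
  expect_equal(nrow(excl), 3L * nrow(fel_genome()))
  bed <- tempfile(fileext = ".bed")
  write_exclusion_bed(excl, bed)
  back <- read_exclusion_bed(bed)
  expect_equal(as.data.frame(back)[order(back$chrom, back$start), ],
               as.data.frame(excl)[order(excl$chrom, excl$start), ],
               ignore_attr = TRUE)
  expect_error(exclusion_regions(data.frame(chrom = "chr1", start = 10,
                                            end = 5)),
               "end < start")
})

test_that("the VCF subset reader recovers per-sample read support", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tFA2\tBenignPT",
    paste0("chrX\t70339230\t.\tG\tT\t.\tPASS\t.\tGT:AD:DP\t",
           "0/1:865,135:1000\t0/1:840,210:1050"),
    paste0("chr5\t1295228\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP\t",
           "0/0:950,0:950\t0/1:660,290:950")), con = vcf)
  m <- read_mutation_vcf(vcf)
  expect_s3_class(m, "fel_mutations")
  # FA2 carries only the chrX variant; BenignPT both
  expect_equal(sum(m$lesion_id == "FA2"), 1L)
  expect_equal(sum(m$lesion_id == "BenignPT"), 2L)
  fa2 <- m[m$lesion_id == "FA2", ]
  expect_equal(fa2$alt_count, 135L)
  expect_equal(fa2$depth, 1000L)
  expect_equal(fa2$key, "chrX:70339230:G:T")
})
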