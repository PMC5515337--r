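test_that("breakpoint extraction respects telomere/centromere filtering", {
  p <- segment_profile(
    data.frame(chrom = "chr16", start = c(1, 10e6 + 1),
               end = c(10e6, 90e6), total_cn = c(2L, 1L)),
    "L1", "hg19")
  expect_equal(extract_breakpoints(p)$pos, 10e6)

  # exclusion interval covering the boundary removes it
  excl <- exclusion_regions(data.frame(chrom = "chr16", start = 9e6,
                                       end = 11e6))
  expect_equal(nrow(extract_breakpoints(p, excl)), 0L)

  # whole-chromosome loss: chromosome ends are telomeric by definition
  flat_loss <- segment_profile(
    data.frame(chrom = "chr16", start = 1, end = 90354753, total_cn = 1L),
    "L1", "hg19")
  expect_equal(nrow(extract_breakpoints(flat_loss)), 0L)

  # equal-CN boundaries are not breakpoints even across a gap
  gap <- segment_profile(
    data.frame(chrom = "chr1", start = c(1, 2e6), end = c(1e6, 3e6),
               total_cn = c(2L, 2L)), "L1", "hg19")
  expect_equal(nrow(extract_breakpoints(gap)), 0L)
})

test_that("breakpoint matching obeys the distance threshold", {
  a <- bp_set("chr1", c(1e7, 2e7, 3e7))
  expect_equal(match_breakpoints(a, a, tolerance = 0), 3L)

  one <- bp_set("chr1", 10.0e6)
  other <- bp_set("chr1", 10.4e6)
  expect_equal(match_breakpoints(one, other, tolerance = 5e5), 1L)
  expect_equal(match_breakpoints(one, other, tolerance = 1e5), 0L)
  # chromosomes never cross-match
  expect_equal(match_breakpoints(bp_set("chr1", 1e7), bp_set("chr2", 1e7),
                                 tolerance = 1e6), 0L)
  expect_error(match_breakpoints(one, other, tolerance = -1), "tolerance")
})

test_that("matching finds a true maximum even where nearest-first pairing fails", {
  # nearest-first greedy alone would pair (6,5) and strand both 0 and 11
  a <- bp_set("chr1", c(0, 6) + 1e6)
  b <- bp_set("chr1", c(5, 11) + 1e6)
  expect_equal(match_breakpoints(a, b, tolerance = 5), 2L)
})

test_that("matching equals the exhaustive maximum-matching oracle", {
  set.seed(505)
  for (rep in 1:200) {
    a <- random_bp(sample(0:8, 1))
    b <- random_bp(sample(0:8, 1))
    tol <- sample(c(0, 1e5, 2e5, 5e5), 1)
    expect_identical(match_breakpoints(a, b, tol),
                     brute_force_matching(a, b, tol))
  }
})

test_that("partial identity score matches its closed form and bounds", {
  a <- bp_set("chr1", seq(10e6, 100e6, by = 10e6))           # 10 breakpoints
  b_match <- bp_set("chr1", c(10.1e6, 20.2e6, 30.3e6))
  b_priv <- bp_set("chr2", seq(5e6, 50e6, by = 5e6))         # 10 private
  b <- bp_set(c(b_match$chrom, b_priv$chrom), c(b_match$pos, b_priv$pos))
  res <- partial_identity_score(a, b, tolerance = 1e6)
  expect_equal(res$matched_breakpoints, 3L)
  expect_equal(res$n_a, 10L)
  expect_equal(res$n_b, 13L)
  expect_equal(res$score, 2 * 3 / 23)

  # identical and disjoint sets
  expect_equal(partial_identity_score(a, a)$score, 1)
  expect_equal(partial_identity_score(a, b_priv)$score, 0)
  # both empty
  e <- bp_set(character(0), numeric(0))
  expect_equal(partial_identity_score(e, e)$score, 0)
})

test_that("identity score is symmetric, bounded, and monotone", {
  set.seed(909)
  for (rep in 1:50) {
    a <- random_bp(sample(0:10, 1))
    b <- random_bp(sample(0:10, 1))
    ab <- partial_identity_score(a, b, tolerance = 2e5)
    ba <- partial_identity_score(b, a, tolerance = 2e5)
    expect_equal(ab$score, ba$score)
    expect_gte(ab$score, 0)
    expect_lte(ab$score, 1)
  }
  # adding a matched pair (far from everything) never decreases the score;
  # adding a private breakpoint to one side never increases it
  a <- bp_set("chr1", c(10e6, 30e6))
  b <- bp_set("chr1", c(10.2e6, 70e6))
  base <- partial_identity_score(a, b)$score
  a_plus <- bp_set(c(a$chrom, "chr5"), c(a$pos, 50e6))
  b_plus <- bp_set(c(b$chrom, "chr5"), c(b$pos, 50.1e6))
  expect_gte(partial_identity_score(a_plus, b_plus)$score, base)
  a_priv <- bp_set(c(a$chrom, "chr9"), c(a$pos, 90e6))
  expect_lte(partial_identity_score(a_priv, b)$score, base)
})

test_that("rarity weighting reweights matched and total breakpoints", {
  a <- bp_set("chr1", c(10e6, 30e6))
  b <- bp_set("chr1", c(10.1e6, 80e6))
  w <- function(bp) ifelse(bp$pos < 20e6, 3, 1)   # the matched pair is rare
  res <- partial_identity_score(a, b, weights = w)
  expect_true(res$weighted)
  expect_equal(res$score, (3 + 3) / (3 + 1 + 3 + 1))
  unw <- partial_identity_score(a, b)
  expect_equal(unw$score, 0.5)
  expect_error(partial_identity_score(a, b, weights = function(bp)
    rep(-1, nrow(bp))), "non-negative")
})

test_that("cutoff calibration matches hand-computed forms", {
  expect_equal(calibrate_cutoff(rep(0.02, 5))$cutoff, 0.02)  # sd 0
  scores <- c(0, 0, 0, 0.04)
  cal <- calibrate_cutoff(scores)
  expect_equal(cal$mean, 0.01)
  expect_equal(cal$sd, 0.02)
  expect_equal(cal$cutoff, 0.01 + qnorm(0.975) * 0.02)
  expect_gte(cal$cutoff, cal$mean)

  expect_error(calibrate_cutoff(c(0, 0.1)), "at least 3")
  expect_error(calibrate_cutoff(runif(10), method = "percentile"),
               "at least 20")
  set.seed(3)
  s <- runif(50)
  pc <- calibrate_cutoff(s, method = "percentile", level = 0.95)
  expect_equal(pc$cutoff, unname(quantile(s, 0.975)))
  expect_true(pc$cutoff >= min(s) && pc$cutoff <= max(s))
})

test_that("pair relatedness calls shared-breakpoint profiles and flags flat ones", {
  prof <- read_seg(five_lesion_path("segments_synthetic.seg"),
                   genome_build = "hg19")
  excl <- exclusion_windows()
  cfg <- sim_config(seed = 11)
  refs <- simulate_reference_cohort(cfg, n_profiles = 22)

  res <- pair_relatedness(prof$FA3, prof$MalignantPT, refs, excl = excl)
  expect_equal(res$identity$matched_breakpoints, 3L)
  expect_equal(res$identity$score, 0.6)
  expect_true(res$verdict)
  expect_false(res$non_informative)

  # a profile against itself scores 1
  self <- pair_relatedness(prof$FA3, prof$FA3, refs, excl = excl)
  expect_equal(self$identity$score, 1)
  expect_true(self$verdict)

  # the flat benign-PT profile is non-informative, never related
  flat <- pair_relatedness(prof$BenignPT, prof$MalignantPT, refs,
                           excl = excl)
  expect_equal(flat$identity$score, 0)
  expect_false(flat$verdict)
  expect_true(flat$non_informative)

  # no reference profiles: cutoff unavailable, verdict undefined
  none <- pair_relatedness(prof$FA3, prof$MalignantPT, list(), excl = excl)
  expect_identical(none$status, "no_reference")
  expect_true(is.na(none$verdict))
})
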