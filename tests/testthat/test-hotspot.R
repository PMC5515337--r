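ca <- fel_cohort_freq("cohort_A")
cb <- fel_cohort_freq("cohort_B")

test_that("chance-sharing probability is the squared raw-count frequency", {
  expect_equal(chance_sharing_probability("MED12:c.131G>T", ca), (14 / 177)^2)
  expect_equal(chance_sharing_probability("MED12:c.131G>A", ca), (29 / 177)^2)
  expect_equal(chance_sharing_probability("MED12:c.131G>A", cb), (37 / 176)^2)
  # absent mutations share with probability 0
  expect_equal(chance_sharing_probability("TP53:c.743G>A", ca), 0)
  # monotone in count at fixed cohort size
  p_seq <- vapply(1:177, function(k)
    chance_sharing_probability("MED12:c.1A>T", frequency_table(
      data.frame(gene = "MED12", cdna_change = "c.1A>T", count = k),
      n_total = 177)), numeric(1))
  expect_true(all(diff(p_seq) > 0))
})

test_that("squared frequency matches the empirical two-lesion sharing rate", {
  # Monte-Carlo oracle: carrier status of two independently drawn lesions
  f <- 29 / 177
  set.seed(4242)
  n <- 1e6
  both <- mean(rbinom(n, 1, f) & rbinom(n, 1, f))
  se <- sqrt(f^2 * (1 - f^2) / n)
  expect_lt(abs(both - f^2), 3 * se)
})

test_that("pair evidence intersects lesions and multiplies probabilities", {
  muts <- read_mutation_table(five_lesion_path("mutations_synthetic.tsv"))
  by_lesion <- split(muts, muts$lesion_id)

  ev <- pair_evidence(by_lesion$FA2, by_lesion$BenignPT, ca)
  expect_equal(ev$shared_mutations, "MED12:c.131G>T")
  expect_equal(ev$combined_probability, (14 / 177)^2)
  expect_true(ev$significant)

  # distinct hotspots imply no shared evidence
  ev0 <- pair_evidence(by_lesion$FA3, by_lesion$FA1, ca)
  expect_equal(length(ev0$shared_mutations), 0L)
  expect_equal(ev0$combined_probability, 1)
  expect_false(ev0$significant)

  # lesion vs itself with k mutations of known frequency: product f^(2k)
  les <- lesion_muts("L1", c("MED12:c.131G>T", "MED12:c.131G>A"))
  ev_self <- pair_evidence(les, les, ca)
  manual <- prod(vapply(ev_self$shared_mutations, function(k)
    mutation_frequency(ca, k)^2, numeric(1)))   # brute-force product
  expect_equal(ev_self$combined_probability, manual)
  expect_equal(manual, (14 / 177)^2 * (29 / 177)^2)
})

test_that("pair evidence is symmetric and monotone in shared mutations", {
  a <- lesion_muts("A", c("MED12:c.131G>T", "FGFR2:c.755C>G"))
  b <- lesion_muts("B", c("MED12:c.131G>T", "MED12:c.131G>A"))
  ab <- pair_evidence(a, b, ca)
  ba <- pair_evidence(b, a, ca)
  expect_equal(ab$shared_mutations, ba$shared_mutations)
  expect_equal(ab$per_mutation_probability, ba$per_mutation_probability)
  expect_equal(ab$combined_probability, ba$combined_probability)
  expect_equal(ab$significant, ba$significant)

  # adding one more shared mutation can only shrink the combined probability
  b2 <- lesion_muts("B", "MED12:c.131G>T")
  one <- pair_evidence(a, b2, ca)
  b3 <- lesion_muts("B", c("MED12:c.131G>T", "FGFR2:c.755C>G"))
  two <- pair_evidence(a, b3, ca)
  expect_lte(two$combined_probability, one$combined_probability)
  # combined never exceeds the smallest per-mutation probability
  expect_lte(ab$combined_probability, min(ab$per_mutation_probability))
})

test_that("shared mutations without population frequency carry no weight", {
  a <- lesion_muts("A", c("MED12:c.131G>T", "FGFR2:c.755C>G"))
  b <- lesion_muts("B", c("MED12:c.131G>T", "FGFR2:c.755C>G"))
  ev <- pair_evidence(a, b, ca)
  expect_setequal(ev$shared_mutations,
                  c("MED12:c.131G>T", "FGFR2:c.755C>G"))
  expect_equal(ev$per_mutation_probability[["FGFR2:c.755C>G"]], 1)
  expect_equal(ev$combined_probability, (14 / 177)^2)
})

test_that("the relatedness graph covers all unordered pairs", {
  muts <- read_mutation_table(five_lesion_path("mutations_synthetic.tsv"))
  g <- relatedness_graph(muts, ca, alpha = 0.05)
  expect_equal(nrow(g), choose(5, 2))
  expect_equal(sum(g$significant), 2L)
  sig <- g[g$significant, ]
  pairs <- paste(pmin(sig$lesion_a, sig$lesion_b),
                 pmax(sig$lesion_a, sig$lesion_b))
  expect_setequal(pairs, c("BenignPT FA2", "FA3 MalignantPT"))

  # n lesions -> n(n-1)/2 evidence records
  for (n in c(2, 4, 6)) {
    lesions <- stats::setNames(
      lapply(seq_len(n), function(i) lesion_muts(paste0("L", i),
                                                 "MED12:c.131G>T")),
      paste0("L", seq_len(n)))
    expect_equal(nrow(relatedness_graph(lesions, ca)), n * (n - 1) / 2)
  }

  # two lesions without mutations: one pair, no evidence
  empty <- lesion_muts("Z", "MED12:c.131G>T")[0, ]
  g0 <- relatedness_graph(list(L1 = empty, L2 = empty), ca)
  expect_equal(nrow(g0), 1L)
  expect_false(g0$significant)

  expect_error(relatedness_graph(list(L1 = empty, L1 = empty), ca),
               "unique")
  expect_error(pair_evidence(empty, empty, ca, alpha = 1.5), "alpha")
})

test_that("Bonferroni option tightens the per-pair level", {
  lesions <- stats::setNames(
    lapply(1:5, function(i) lesion_muts(paste0("L", i), "MED12:c.131G>A")),
    paste0("L", 1:5))
  plain <- relatedness_graph(lesions, ca, alpha = 0.05)
  bonf <- relatedness_graph(lesions, ca, alpha = 0.05, bonferroni = TRUE)
  # (29/177)^2 = 0.0268 < 0.05 but > 0.05/10 = 0.005
  expect_true(all(plain$significant))
  expect_false(any(bonf$significant))
})
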