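test_that("RPKM formula and invariances", {
  expect_equal(compute_rpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_rpkm(0, 1158, 45e6), 0)
  # the 1158-nt transcript at 45M reads: direct formula evaluation
  expect_equal(compute_rpkm(231, 1158, 45e6), 231 * 1e9 / (1158 * 45e6))
  expect_equal(compute_rpkm(231, 1158, 45e6), 4.43293, tolerance = 1e-5)
  # scaling counts and library depth together leaves RPKM unchanged
  withr::local_seed(3)
  cts <- sample(1:1e4, 50)
  lens <- sample(200:3000, 50)
  expect_equal(compute_rpkm(cts * 7, lens, 3e6 * 7), compute_rpkm(cts, lens, 3e6))
  expect_error(compute_rpkm(10, 0, 1e6), "length")
  expect_error(compute_rpkm(10, 100, 0), "library")
})

make_rpkm_long <- function(values) {
  # values: list(transcript_id = c(m_br, f_br, m_es, f_es))
  purrr::map_dfr(names(values), function(id) {
    tibble::tibble(
      transcript_id = id,
      sample = c("m_br", "f_br", "m_es", "f_es"),
      tissue = c("brain", "brain", "eyestalk", "eyestalk"),
      sex = c("M", "F", "M", "F"),
      rpkm = values[[id]]
    )
  })
}

test_that("tissue contrast: null identity, a strong contrast, and group sizes", {
  flat <- make_rpkm_long(list(t1 = c(10, 10, 10, 10)))
  res <- tissue_contrast(flat)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  chh <- make_rpkm_long(list(chh_b1 = c(0.12, 0.46, 309.12, 450.84)))
  res2 <- tissue_contrast(chh)
  expect_lt(res2$p_value, 0.05)
  expect_true(res2$significant)
  expect_equal(res2$brain_mean, 0.29)
  expect_equal(res2$eyestalk_mean, 379.98)

  one_per_group <- tibble::tibble(
    transcript_id = "t", sample = c("s1", "s2"),
    tissue = c("brain", "eyestalk"), sex = c("M", "M"), rpkm = c(1, 2))
  expect_error(tissue_contrast(one_per_group), ">= 2 values")
})

test_that("a non-significant printed row agrees with the exact permutation test", {
  dh <- c(78.61, 70.11, 66.36, 61.51)
  res <- tissue_contrast(make_rpkm_long(list(dh = dh)))
  p_perm <- oracle_permutation_p(dh[1:2], dh[3:4])
  expect_gt(res$p_value, 0.05)
  expect_gt(p_perm, 0.05)
  # both routes agree on the ordering of evidence strength vs the CHH row
  chh <- tissue_contrast(make_rpkm_long(list(chh = c(0.12, 0.46, 309.12, 450.84))))
  expect_lt(chh$p_value, res$p_value)
})

test_that("printed tissue means are reproduced from the per-sex values", {
  t3 <- load_study_tables("table3")
  expect_equal((t3$m_br + t3$f_br) / 2, t3$br_mean, tolerance = 0.011)
  expect_equal((t3$m_es + t3$f_es) / 2, t3$es_mean, tolerance = 0.011)
  # and summarize_expression reconstructs the published report layout
  long <- make_rpkm_long(list(rpch = c(12.84, 15.22, 48.32, 52.63)))
  rep_ <- summarize_expression(long)
  expect_equal(rep_$br_mean, 14.03)
  expect_equal(rep_$es_mean, 50.475)
  expect_true(rep_$significant)
  expect_false(rep_$untestable)
})

test_that("zero-variance and untestable rows are reported, not dropped", {
  zero <- make_rpkm_long(list(t0 = c(0, 0, 0, 0)))
  rep0 <- summarize_expression(zero)
  expect_equal(rep0$br_mean, 0)
  expect_false(rep0$significant)

  split_means <- make_rpkm_long(list(tz = c(1, 1, 2, 2)))
  expect_equal(tissue_contrast(split_means)$p_value, 0)

  single <- tibble::tibble(transcript_id = "t", sample = c("s1", "s2"),
                           tissue = c("brain", "eyestalk"), sex = c("M", "F"),
                           rpkm = c(3, 4))
  rep1 <- summarize_expression(single)
  expect_true(rep1$untestable)
  expect_true(is.na(rep1$p_value))
})

test_that("rpkm_table joins counts, lengths and libraries", {
  counts <- tibble::tibble(transcript_id = c("a", "b"),
                           m_br = c(100L, 0L), f_br = c(120L, 0L),
                           m_es = c(10L, 5L), f_es = c(12L, 6L))
  lengths <- tibble::tibble(transcript_id = c("a", "b"), length_nt = c(1000L, 500L))
  samples <- tibble::tibble(sample = c("m_br", "f_br", "m_es", "f_es"),
                            tissue = c("brain", "brain", "eyestalk", "eyestalk"),
                            sex = c("M", "F", "M", "F"),
                            lib_size = rep(1e6, 4))
  long <- rpkm_table(counts, lengths, samples)
  expect_equal(nrow(long), 8L)
  expect_equal(long$rpkm[long$transcript_id == "a" & long$sample == "m_br"], 100)
  bad <- samples; bad$lib_size <- c(50, 1e6, 1e6, 1e6)
  expect_error(rpkm_table(counts, lengths, bad), "library size")
})

test_that("simulated counts are reproducible and power the known contrasts", {
  tx <- tibble::tibble(
    transcript_id = c("null1", "null2", "up"),
    length_nt = c(1000L, 1500L, 1000L),
    brain_mean = c(500, 800, 5),
    eyestalk_fold = c(1, 1, 1000)
  )
  sim1 <- simulate_counts(tx, depth = 450e3, seed = 99)
  sim2 <- simulate_counts(tx, depth = 450e3, seed = 99)
  expect_identical(sim1$counts, sim2$counts)
  expect_false(identical(sim1$counts,
                         simulate_counts(tx, depth = 450e3, seed = 100)$counts))
  long <- rpkm_table(sim1$counts, sim1$lengths, sim1$samples)
  res <- tissue_contrast(long)
  # the simulated 1000x contrast is recovered in the tissue means
  up <- res[res$transcript_id == "up", ]
  expect_gt(up$eyestalk_mean, 100 * max(up$brain_mean, 0.01))
  # and is detected on the variance-stabilised scale
  res_log <- tissue_contrast(long, log2_transform = TRUE)
  expect_true(res_log$significant[res_log$transcript_id == "up"])
  zero <- simulate_counts(
    tibble::tibble(transcript_id = "z", length_nt = 500L,
                   brain_mean = 0, eyestalk_fold = 1), seed = 1)
  expect_true(all(unlist(zero$counts[, -1]) == 0))
  expect_error(simulate_counts(tx, dispersion = 0), "positive")
})
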