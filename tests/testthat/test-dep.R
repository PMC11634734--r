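test_that("preprocess drops contaminants and log2-transforms once", {
  m <- matrix(2^seq(8, 12, length.out = 40), 10, 4)
  m[3, 2] <- NA
  lfq <- toy_lfq(m, rep(c("a", "b"), each = 2), scale = "linear",
                 contaminant = c(TRUE, TRUE, rep(FALSE, 8)))
  out <- preprocess_lfq(lfq)
  expect_equal(nrow(out$intensities), 8)
  expect_equal(out$scale, "log2")
  expect_error(preprocess_lfq(out), "already log2")
  lfq2 <- toy_lfq(matrix(1024, 2, 4), rep("a", 4), scale = "linear")
  expect_equal(unique(as.vector(preprocess_lfq(lfq2)$intensities)), 10)
  # missing entries stay missing (row 3 becomes row 1 after the drop)
  expect_true(is.na(out$intensities[1, 2]))
})

test_that("valid-value filter is per-group with an inclusive boundary", {
  m <- matrix(20, 3, 11)
  # protein 1: 3/5 valid in group a (0.6, boundary), 0/6 in b -> kept
  m[1, c(4, 5, 6:11)] <- NA
  # protein 2: 2/5 and 3/6 valid -> dropped
  m[2, c(3, 4, 5, 9, 10, 11)] <- NA
  lfq <- toy_lfq(m, rep(c("a", "b"), c(5, 6)))
  kept <- filter_valid(lfq, 0.6)
  expect_equal(rownames(kept$intensities),
               rownames(lfq$intensities)[c(1, 3)])
  expect_error(filter_valid(lfq, 0), "min_frac")
  expect_error(filter_valid(lfq, 1.2), "min_frac")
})

test_that("lowering the filter threshold never drops a kept protein", {
  set.seed(13)
  m <- matrix(rnorm(300, 25), 30, 10)
  m[sample(300, 120)] <- NA
  lfq <- toy_lfq(m, rep(c("a", "b"), each = 5))
  kept_ids <- function(f) rownames(filter_valid(lfq, f)$intensities)
  fracs <- c(0.9, 0.7, 0.5, 0.3)
  for (i in seq_len(length(fracs) - 1)) {
    expect_true(all(kept_ids(fracs[i]) %in% kept_ids(fracs[i + 1])))
  }
})

test_that("imputation draws from the downshifted Gaussian per column", {
  set.seed(31)
  m <- matrix(rnorm(3000 * 4, 25, 2), 3000, 4)
  miss <- matrix(runif(3000 * 4) < 0.3, 3000, 4)
  m_na <- m
  m_na[miss] <- NA
  lfq <- toy_lfq(m_na, rep("a", 4))
  out <- impute_lfq(lfq, width = 0.3, downshift = 1.8, seed = 5)
  expect_false(any(is.na(out$intensities)))
  # observed entries untouched
  expect_identical(out$intensities[!miss], m[!miss])
  for (s in 1:4) {
    obs <- m[!miss[, s], s]
    imp <- out$intensities[miss[, s], s]
    expect_equal(mean(imp), mean(obs) - 1.8 * sd(obs), tolerance = 0.08)
    expect_equal(sd(imp), 0.3 * sd(obs), tolerance = 0.03)
  }
  # determinism and the no-missing identity
  out2 <- impute_lfq(lfq, seed = 5)
  expect_identical(out$intensities, out2$intensities)
  full <- toy_lfq(m, rep("a", 4))
  expect_identical(impute_lfq(full)$intensities, full$intensities)
  thin <- toy_lfq(matrix(c(20, NA, NA, 21, 22, 23), 3, 2), rep("a", 2))
  expect_error(impute_lfq(thin), "fewer than 2 observed")
})

test_that("Welch contrast matches the closed form and t.test", {
  lfq <- toy_lfq(matrix(c(1, 2, 3, 2, 3, 4), 1, 6), rep(c("a", "b"), each = 3))
  # single-protein contrast: z is undefined (sd of one d), so check t/df/p
  tab <- suppressWarnings(welch_contrast(lfq, "a", "b"))
  expect_equal(tab$t, -1.224745, tolerance = 1e-6)
  expect_equal(tab$df, 4)
  expect_equal(tab$p, 0.2878641, tolerance = 1e-6)
  set.seed(17)
  for (i in 1:100) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- matrix(rnorm(n1 + n2, 20, 2), 1)
    lfq_i <- toy_lfq(x, rep(c("a", "b"), c(n1, n2)))
    got <- suppressWarnings(welch_contrast(lfq_i, "a", "b"))
    ref <- t.test(x[1, 1:n1], x[1, n1 + 1:n2])
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$d_log2, unname(diff(rev(ref$estimate))),
                 tolerance = 1e-10)
  }
})

test_that("contrast z-scores standardize the difference distribution", {
  d_true <- c(1, -1, 0, 2, -2)
  set.seed(2)
  m <- cbind(matrix(rep(d_true, 3), 5, 3), matrix(0, 5, 3)) +
    matrix(rnorm(30, 0, 1e-8), 5, 6)
  lfq <- toy_lfq(m, rep(c("a", "b"), each = 3))
  tab <- welch_contrast(lfq, "a", "b")
  expect_equal(mean(tab$z), 0, tolerance = 1e-8)
  expect_equal(sd(tab$z), 1, tolerance = 1e-8)
  expect_equal(tab$z[4], (tab$d_log2[4] - mean(tab$d_log2)) / sd(tab$d_log2))
  expect_equal(tab$z[4], 1.264911, tolerance = 1e-3)
  # identical groups: d = 0, p = 1
  ident <- toy_lfq(matrix(rep(c(5, 6, 7), 2), 1), rep(c("a", "b"), each = 3))
  got <- suppressWarnings(welch_contrast(ident, "a", "b"))
  expect_equal(got$d_log2, 0)
  expect_equal(got$p, 1)
})

test_that("DEP calls apply the combined p and z rule", {
  tab <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4"),
    d_log2 = c(2, 0.5, -2, 1), t = 0, df = 4,
    p = c(0.01, 0.01, 0.01, 0.5),
    z = c(1.5, 0.5, -1.5, 2), significant = NA
  )
  calls <- call_deps(tab, alpha = 0.05, z_cut = 1)
  expect_equal(calls$up, "p1")
  expect_equal(calls$down, "p3")
})

test_that("under the null the p stage is calibrated and z tightens calls", {
  sim <- simulate_lfq(lfq_sim_spec(
    n_proteins = 4000, groups = c(a = 6, b = 6), dep_frac = 0,
    target_missing_rate = 0, seed = 23))
  lfq <- preprocess_lfq(sim$lfq)
  tab <- welch_contrast(lfq, "a", "b")
  frac_p <- mean(tab$p < 0.05)
  expect_lt(abs(frac_p - 0.05), 0.012)
  # with heterogeneous protein variances, low-variance proteins reach
  # p < alpha at small |d| and are removed by the z cutoff
  set.seed(24)
  scl <- runif(4000, 0.2, 3)
  het <- lfq
  het$intensities <- 25 + (het$intensities - 25) * scl
  tab_h <- welch_contrast(het, "a", "b")
  calls <- call_deps(tab_h, 0.05, 1)
  expect_lt(length(calls$up) + length(calls$down), sum(tab_h$p < 0.05))
})

test_that("planted log2 effects of 1+ are detected with high power", {
  sim <- simulate_lfq(lfq_sim_spec(
    n_proteins = 2000, groups = c(young_wt = 6, aged_wt = 6, aged_ko = 6),
    dep_frac = 0.1, effect_log2 = c(1, 2), target_missing_rate = 0,
    seed = 29))
  lfq <- preprocess_lfq(sim$lfq)
  tab <- welch_contrast(lfq, "aged_wt", "young_wt")
  dep_ids <- sim$truth$effects$protein_id[sim$truth$effects$is_dep]
  power <- mean(tab$significant[match(dep_ids, tab$protein_id)])
  expect_gte(power, 0.8)
})

test_that("set overlap partitions exactly", {
  ov <- overlap_sets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov, list(only_a = "a", only_b = "d", both = c("b", "c")))
  expect_equal(overlap_sets(c("x"), c("y"))$both, character(0))
  ident <- overlap_sets(c("a", "b"), c("a", "b"))
  expect_equal(ident$both, c("a", "b"))
  expect_length(ident$only_a, 0)
})

test_that("reversal membership follows the sign and significance rule", {
  mk <- function(d, p, z) tibble::tibble(
    protein_id = paste0("p", seq_along(d)), d_log2 = d, t = 0, df = 4,
    p = p, z = z, significant = p < 0.05 & abs(z) > 1)
  t_age <- mk(c(1, 0.8, 1.2), c(0.01, 0.01, 0.01), c(1.2, 1.5, 1.4))
  t_ko <- mk(c(-0.8, 0.9, -1.1), c(0.02, 0.02, 0.2), c(-1.1, 1.3, -1.2))
  rev <- reversal_signature(t_age, t_ko)
  expect_equal(rev$protein_id, "p1") # p2 same sign, p3 ko not significant
  expect_equal(rev$pattern, "up_age_down_ko")
  expect_error(reversal_signature(t_age, t_ko[1:2, ]), "universe")
})

test_that("planted reversal proteins are recovered through the pipeline", {
  sim <- simulate_lfq(lfq_sim_spec(n_proteins = 2000, seed = 1))
  imp <- sim$lfq |> preprocess_lfq() |> filter_valid() |> impute_lfq(seed = 101)
  t_age <- welch_contrast(imp, "aged_wt", "young_wt")
  t_ko <- welch_contrast(imp, "aged_ko", "aged_wt")
  rev <- reversal_signature(t_age, t_ko)
  # every reported member satisfies the rule exactly
  expect_true(all(rev$p_age < 0.05 & abs(rev$z_age) > 1))
  expect_true(all(rev$p_ko < 0.05 & abs(rev$z_ko) > 1))
  expect_true(all(sign(rev$d_age) == -sign(rev$d_ko)))
  planted <- sim$truth$effects$protein_id[sim$truth$effects$is_reversal]
  expect_gt(length(intersect(rev$protein_id, planted)), 0)
})

test_that("the CV summary reports per-group medians on the linear scale", {
  m <- matrix(c(8, 10, 12, 8, 10, 12), 1)
  lfq <- toy_lfq(m, rep(c("a", "b"), each = 3), scale = "linear")
  cv <- cv_summary(lfq)
  expect_equal(cv$median_cv_pct, c(20, 20))
  dup <- toy_lfq(rbind(rep(50, 3), rep(60, 3)), rep("a", 3),
                 scale = "linear")
  expect_equal(cv_summary(dup)$median_cv_pct, 0)
  logd <- toy_lfq(matrix(20, 2, 4), rep("a", 4), scale = "log2")
  expect_error(cv_summary(logd), "linear-scale")
})
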