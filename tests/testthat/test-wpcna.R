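test_that("signed adjacency maps correlation through ((1+r)/2)^beta", {
  x1 <- c(1, 2, 3, 4, 5, 6)
  x <- rbind(a = x1, b = 2 * x1 + 3, c = -x1,
             d = rep(c(1, -1), 3) * c(1, 1, -1, -1, 1, 1))
  # rows a,b perfectly correlated; a,c anti-correlated
  adj <- signed_adjacency(x, beta = 7)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 0)
  expect_true(all(adj >= 0 & adj <= 1))
  # orthogonal pair: r = 0 -> 0.5^7
  y <- rbind(p = c(1, -1, 1, -1), q = c(1, 1, -1, -1))
  expect_equal(signed_adjacency(y, beta = 7)["p", "q"], 0.5^7)
  bad <- rbind(u = c(1, 1, 1, 1), v = c(1, 2, 3, 4))
  expect_error(signed_adjacency(bad), "zero-variance")
  expect_error(signed_adjacency(matrix(NA_real_, 2, 4)), "missing")
})

test_that("TOM matches the brute-force triple loop and its bounds", {
  # three identical profiles: all adjacencies 1, TOM 1
  x <- matrix(rep(c(1, 4, 2, 5, 3), 3), 3, 5, byrow = TRUE)
  x <- x + matrix(0, 3, 5)
  tom1 <- tom_similarity(signed_adjacency(x, beta = 7))
  expect_equal(unname(tom1), matrix(1, 3, 3))
  set.seed(19)
  for (i in 1:5) {
    n <- sample(5:10, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, tom_bruteforce(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
  ns <- matrix(runif(16), 4)
  diag(ns) <- 1
  expect_error(tom_similarity(ns), "symmetric")
})

test_that("an isolated pair without shared neighbors has TOM zero", {
  a <- diag(4)
  a[1, 2] <- a[2, 1] <- 0 # no direct link, no shared neighbors
  a[3, 4] <- a[4, 3] <- 0.5
  expect_equal(tom_similarity(a)[1, 2], 0)
})

test_that("a perfectly correlated block forms exactly one module", {
  set.seed(41)
  base <- rnorm(40)
  block <- t(sapply(1:30, function(i) 2 * base + i)) # identical profiles
  noise <- matrix(rnorm(40 * 40), 40, 40)
  x <- rbind(block, noise)
  rownames(x) <- sprintf("P%03d", 1:70)
  fit <- run_wpcna(x, min_module_size = 20)
  g <- glance(fit)
  expect_equal(g$n_modules, 1)
  mod <- fit$assignment$module
  expect_equal(sum(mod == "ME01"), 30)
  expect_true(all(mod[1:30] == "ME01"))
})

test_that("planted modules are recovered with high agreement", {
  skip_if_not_installed("mclust")
  sim <- simulate_lfq(lfq_sim_spec(
    n_proteins = 500, groups = c(all = 24), dep_frac = 0, n_modules = 3,
    module_size = 50, module_cor = 0.8, target_missing_rate = 0, seed = 7))
  fit <- run_wpcna(sim$truth$log2_complete)
  expect_equal(glance(fit)$n_modules, 3)
  ari <- mclust::adjustedRandIndex(fit$assignment$module,
                                   sim$truth$modules$module)
  expect_gte(ari, 0.9)
})

test_that("pure noise leaves proteins unassigned", {
  n_mod <- vapply(1:20, function(s) {
    sim <- simulate_lfq(lfq_sim_spec(
      n_proteins = 300, groups = c(all = 24), dep_frac = 0, n_modules = 0,
      target_missing_rate = 0, seed = 50 + s))
    glance(run_wpcna(sim$truth$log2_complete))$n_modules
  }, numeric(1))
  expect_gte(mean(n_mod == 0), 0.8)
})

test_that("module eigengenes summarize and orient correctly", {
  set.seed(43)
  base <- rnorm(10)
  x <- rbind(t(sapply(1:5, function(i) i + 3 * base)),
             matrix(rnorm(30), 3, 10))
  rownames(x) <- paste0("P", 1:8)
  asn <- tibble::tibble(protein_id = rownames(x),
                        module = c(rep("ME01", 5), rep("ME00", 3)))
  me <- module_eigengenes(x, asn)
  expect_equal(colnames(me$eigengenes), "ME01")  # ME00 excluded
  expect_equal(unname(me$var_explained["ME01"]), 1, tolerance = 1e-10)
  expect_equal(abs(cor(me$eigengenes[, 1], base)), 1, tolerance = 1e-10)
  expect_gt(cor(me$eigengenes[, 1], base) * sign(3), 0) # positive orientation
  expect_equal(sum(me$eigengenes[, 1]^2), 1)            # unit norm
  # two anti-correlated proteins still span one component
  x2 <- rbind(a = base, b = -2 * base)
  asn2 <- tibble::tibble(protein_id = c("a", "b"), module = "ME01")
  me2 <- module_eigengenes(x2, asn2)
  expect_equal(unname(me2$var_explained["ME01"]), 1, tolerance = 1e-10)
  # permuting proteins within the module leaves the eigengene unchanged
  perm <- sample(rownames(x)[1:5])
  asn3 <- asn
  me3 <- module_eigengenes(x[c(perm, rownames(x)[6:8]), ], asn)
  expect_equal(me3$eigengenes, me$eigengenes, tolerance = 1e-10)
})

test_that("eigengene-similar modules merge below the cut height", {
  set.seed(47)
  f <- rnorm(20)
  g <- 0.5 * scale(f)[, 1] + sqrt(0.75) * scale(rnorm(20))[, 1]
  mk_block <- function(fac, n, sd) {
    t(sapply(1:n, function(i) fac + rnorm(20, 0, sd)))
  }
  # blocks 1 and 2 share a factor (ME cor ~ 1, merge); block 3's factor
  # correlates only ~0.5 with it (dissimilarity ~0.5 > 0.25, stays)
  x <- rbind(mk_block(f, 25, 0.3), mk_block(f, 25, 0.3),
             mk_block(3 * g, 25, 0.3))
  rownames(x) <- paste0("P", 1:75)
  asn <- tibble::tibble(
    protein_id = rownames(x),
    module = rep(c("ME01", "ME02", "ME03"), each = 25))
  merged <- merge_modules(x, asn, merge_cut_height = 0.25)
  expect_equal(length(setdiff(unique(merged$module), "ME00")), 2)
  # the two same-factor blocks end up together, the third stays apart
  expect_equal(length(unique(merged$module[1:50])), 1)
  expect_false(merged$module[60] %in% merged$module[1:50])
})

test_that("module-trait correlation reproduces the t-based p-value", {
  set.seed(53)
  x <- matrix(rnorm(30 * 24), 30, 24)
  rownames(x) <- paste0("P", 1:30)
  colnames(x) <- paste0("S", 1:24)
  asn <- tibble::tibble(protein_id = rownames(x), module = "ME01")
  me <- module_eigengenes(x, asn)
  u <- me$eigengenes[, 1]
  # trait engineered to have sample correlation exactly 0.6 with the ME
  v <- rnorm(24)
  v <- residuals(lm(v ~ u))
  trait <- 0.6 * scale(u)[, 1] + sqrt(1 - 0.36) * scale(v)[, 1]
  traits <- tibble::tibble(sample_id = colnames(x),
                           exact = trait, same = u,
                           ortho = scale(v)[, 1], flat = 1)
  expect_warning(tc <- module_trait_correlation(me, traits), "zero-variance")
  expect_equal(tc$r["ME01", "same"], 1, tolerance = 1e-10)
  expect_equal(tc$r["ME01", "ortho"], 0, tolerance = 1e-10)
  expect_equal(tc$r["ME01", "exact"], 0.6, tolerance = 1e-10)
  expect_equal(tc$p["ME01", "exact"], 0.00191, tolerance = 1e-2)
  expect_true(is.na(tc$r["ME01", "flat"]))
})

test_that("hypergeometric enrichment matches enumeration and BH", {
  bg <- paste0("g", 1:10)
  sets <- list(s1 = bg[1:5], s2 = bg[6:10])
  mod <- bg[c(1:4)]
  tab <- enrich_hypergeometric(mod, sets, bg)
  expect_equal(tab$p[tab$set == "s1"], 5 / 210, tolerance = 1e-12)
  expect_equal(tab$p[tab$set == "s2"], 1)          # overlap 0: P(X >= 0) = 1
  expect_equal(tab$ratio[tab$set == "s1"], 1)
  set.seed(59)
  for (i in 1:20) {
    nbg <- sample(8:10, 1)
    bgx <- paste0("g", seq_len(nbg))
    sz <- sample(2:6, 1)
    setx <- sample(bgx, sz)
    modx <- sample(bgx, sample(2:5, 1))
    p_pkg <- enrich_hypergeometric(modx, list(s = setx), bgx)$p
    k <- length(intersect(setx, modx))
    expect_equal(p_pkg, hyper_enumeration(k, sz, nbg, length(modx)),
                 tolerance = 1e-12)
  }
  # BH step-up on three sets
  ps <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(ps, "BH"), c(0.03, 0.03, 0.03))
  expect_error(enrich_hypergeometric(character(0), sets, bg), "empty")
  expect_error(enrich_hypergeometric(c("zz"), sets, bg), "background")
})

test_that("simulated traits hit their target correlations", {
  sim <- simulate_lfq(lfq_sim_spec(
    n_proteins = 300, groups = c(all = 24), dep_frac = 0, n_modules = 3,
    module_size = 40, module_cor = 0.8, target_missing_rate = 0, seed = 7))
  tt <- simulate_trait_table(sim$truth, tibble::tibble(
    name = c("tied", "free", "geno"),
    module = c(1, NA, NA), target_r = c(0.9, 0, 0),
    type = c("continuous", "continuous", "binary")), seed = 3)
  f1 <- sim$truth$factors[, 1]
  expect_lt(abs(cor(tt$tied, f1) - 0.9), 0.15)
  expect_lt(abs(cor(tt$free, f1)), 0.3)
  expect_true(all(tt$geno %in% c(0, 1)))
  expect_error(simulate_trait_table(sim$truth, tibble::tibble(
    name = "bad", module = 9, target_r = 0.5)), "unknown module")
})

test_that("a trait tied to a planted module tops that module's correlations", {
  sim <- simulate_lfq(lfq_sim_spec(
    n_proteins = 500, groups = c(all = 24), dep_frac = 0, n_modules = 3,
    module_size = 50, module_cor = 0.8, target_missing_rate = 0, seed = 7))
  tt <- simulate_trait_table(sim$truth, tibble::tibble(
    name = c("tied", "free"), module = c(1, NA), target_r = c(0.9, 0)),
    seed = 11)
  fit <- run_wpcna(sim$truth$log2_complete, traits = tt)
  # the detected module holding most of planted module 1
  truth_mod <- sim$truth$modules$module
  hit <- names(which.max(table(fit$assignment$module[truth_mod == 1])))
  tc <- tidy(fit$trait_corr)
  best_trait <- tc$trait[tc$module == hit][which.max(abs(tc$r[tc$module == hit]))]
  expect_equal(best_trait, "tied")
  best_mod <- tc$module[tc$trait == "tied"][which.max(abs(tc$r[tc$trait == "tied"]))]
  expect_equal(best_mod, hit)
})

test_that("GMT files round-trip and agree with an independent reader", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c("first", "second"))
  back <- read_gmt(path)
  expect_equal(back[["alpha"]], sets$alpha)
  expect_equal(back[["beta"]], sets$beta)
  skip_if_not_installed("fgsea")
  ref <- fgsea::gmtPathways(path)
  expect_equal(ref[["alpha"]], sets$alpha)
  expect_equal(ref[["beta"]], sets$beta)
})
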