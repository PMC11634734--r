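# fixtures are built in code: square-wave activity records, toy LFQ
# matrices, and small schedules used across the test files

# a noise-free LD record: active (constant `level`) through the dark phase
square_record <- function(n_days = 6, level = 12, bin_minutes = 5,
                          lights_on = 6, lights_off = 18) {
  bpd <- 1440 %/% bin_minutes
  clock <- (seq_len(bpd) - 1) * bin_minutes / 60
  dark <- clock >= lights_off | clock < lights_on
  counts <- matrix(rep(ifelse(dark, level, 0), n_days),
                   nrow = n_days, byrow = TRUE)
  activity_record(counts, bin_minutes, tibble::tibble(
    day = seq_len(n_days), phase = "LD",
    lights_on_h = lights_on, lights_off_h = lights_off, stress = FALSE
  ))
}

# minimal lfq_matrix from a plain matrix with one or two groups
toy_lfq <- function(m, groups, scale = "log2", contaminant = NULL) {
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  ann <- tibble::tibble(sample_id = colnames(m), group = groups)
  lfq_matrix(m, ann, scale = scale, contaminant = contaminant)
}

# brute-force TOM by the triple loop, literal formula
tom_bruteforce <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  k <- rowSums(a) - 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# literal IS / IV formulas, written independently of the implementation
is_literal <- function(x, p = 24) {
  n <- length(x)
  xb <- mean(x)
  xh <- tapply(x, rep(seq_len(p), times = n / p), mean)
  n * sum((xh - xb)^2) / (p * sum((x - xb)^2))
}

iv_literal <- function(x) {
  n <- length(x)
  n * sum(diff(x)^2) / ((n - 1) * sum((x - mean(x))^2))
}

# Spearman rho via explicit average ranks
spearman_literal <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# upper-tail hypergeometric p by complete enumeration over the overlap count
hyper_enumeration <- function(k, set_size, bg_size, module_size) {
  kk <- seq(k, min(set_size, module_size))
  sum(choose(set_size, kk) * choose(bg_size - set_size, module_size - kk)) /
    choose(bg_size, module_size)
}
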