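#' Preprocess an LFQ matrix: drop contaminants, log2-transform
#'
#' The first stage of the differential-expression pipeline: removes rows
#' flagged as contaminants and log2-transforms the remaining linear
#' intensities. Missing entries stay missing. Applying it to an already
#' log2-scale matrix is an error (double-transform guard).
#'
#' @param lfq A linear-scale [lfq_matrix()].
#' @return A log2-scale [lfq_matrix()] without contaminant rows.
#' @export
preprocess_lfq <- function(lfq) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  if (lfq$scale != "linear") {
    abort("matrix is already log2-transformed")
  }
  keep <- !lfq$contaminant
  lfq_matrix(log2(lfq$intensities[keep, , drop = FALSE]), lfq$annotations,
             scale = "log2", contaminant = rep(FALSE, sum(keep)))
}

#' Filter proteins on valid values per group
#'
#' Keeps a protein iff the fraction of observed (non-missing) values
#' reaches `min_frac` in at least one annotation group. The boundary is
#' inclusive: a protein observed in exactly 60% of one group's samples
#' passes the default filter.
#'
#' @param lfq A log2-scale [lfq_matrix()].
#' @param min_frac Required valid fraction, in (0, 1\].
#' @return The filtered [lfq_matrix()].
#' @export
filter_valid <- function(lfq, min_frac = 0.6) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  if (lfq$scale != "log2") abort("filter on the log2-scale matrix")
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1) {
    abort("`min_frac` must be in (0, 1]")
  }
  gcols <- group_columns(lfq)
  fracs <- vapply(gcols, function(cols) {
    rowMeans(!is.na(lfq$intensities[, cols, drop = FALSE]))
  }, numeric(nrow(lfq$intensities)))
  keep <- apply(as.matrix(fracs), 1, max) >= min_frac
  lfq_matrix(lfq$intensities[keep, , drop = FALSE], lfq$annotations,
             scale = "log2", contaminant = lfq$contaminant[keep])
}

#' Impute missing values from a downshifted Gaussian
#'
#' Replaces each missing entry with a draw from a normal distribution whose
#' mean sits `downshift` observed standard deviations below the observed
#' mean and whose SD is `width` times the observed SD — the standard
#' left-censored (MNAR) imputation for label-free proteomics. By default
#' the observed mean and SD are those of the entry's sample column
#' (`per_column = TRUE`, the Perseus convention); a whole-matrix mode is
#' available. Observed entries are never altered.
#'
#' @param lfq A filtered log2-scale [lfq_matrix()].
#' @param width Imputed SD as a fraction of the observed SD (default 0.3).
#' @param downshift Gap between observed and imputed means, in observed
#'   SDs (default 1.8).
#' @param seed Integer seed for the draws (`NULL` = current RNG stream).
#' @param per_column Use column-wise moments (default) or whole-matrix.
#' @return A complete [lfq_matrix()] (no missing values).
#' @export
impute_lfq <- function(lfq, width = 0.3, downshift = 1.8, seed = NULL,
                       per_column = TRUE) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  if (lfq$scale != "log2") abort("impute on the log2-scale matrix")
  x <- lfq$intensities
  miss <- is.na(x)
  if (!any(miss)) return(lfq)
  with_seed(seed, {
    if (per_column) {
      for (s in seq_len(ncol(x))) {
        obs <- x[!miss[, s], s]
        if (length(obs) < 2) {
          abort(sprintf("column %s has fewer than 2 observed values",
                        colnames(x)[s]))
        }
        mu <- mean(obs); sg <- sd(obs)
        k <- sum(miss[, s])
        if (k > 0) {
          x[miss[, s], s] <- rnorm(k, mu - downshift * sg, width * sg)
        }
      }
    } else {
      obs <- x[!miss]
      if (length(obs) < 2) abort("fewer than 2 observed values in matrix")
      mu <- mean(obs); sg <- sd(obs)
      x[miss] <- rnorm(sum(miss), mu - downshift * sg, width * sg)
    }
  })
  out <- lfq_matrix(x, lfq$annotations, scale = "log2",
                    contaminant = lfq$contaminant)
  attr(out, "imputed") <- miss
  out
}

#' Welch's t contrast over all proteins
#'
#' For each protein, the mean log2 difference `d` between two groups
#' (numerator minus denominator), Welch's t statistic with
#' Welch–Satterthwaite degrees of freedom, the two-sided p-value, and the
#' contrast-wide standardized difference `z = (d - mean(d)) / sd(d)`. The
#' significance flag requires both `p < alpha` and `|z| > z_cut`, the
#' combined cutoff drawn as threshold lines on a volcano plot.
#'
#' @param lfq A complete (imputed) log2-scale [lfq_matrix()].
#' @param numerator,denominator Group labels to contrast.
#' @param name Contrast name (default `"numerator_vs_denominator"`).
#' @param alpha,z_cut Significance cutoffs stored with the table.
#' @return A tibble of class `dep_table` with columns `protein_id`,
#'   `d_log2`, `t`, `df`, `p`, `z`, `significant`.
#' @export
welch_contrast <- function(lfq, numerator, denominator, name = NULL,
                           alpha = 0.05, z_cut = 1) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  if (lfq$scale != "log2") abort("contrast the log2-scale matrix")
  x <- lfq$intensities
  if (any(is.na(x))) abort("matrix has missing values: impute first")
  groups <- lfq$annotations$group
  for (g in c(numerator, denominator)) {
    if (sum(groups == g) < 2) {
      abort(sprintf("group '%s' needs at least 2 samples", g))
    }
  }
  x1 <- x[, groups == numerator, drop = FALSE]
  x2 <- x[, groups == denominator, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  d <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, Inf * sign(d)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * pt(-abs(tstat), df)
  z <- (d - mean(d)) / sd(d)
  out <- tibble(
    protein_id = rownames(x),
    d_log2 = unname(d), t = unname(tstat), df = unname(df),
    p = unname(p), z = unname(z),
    significant = unname(p < alpha & abs(z) > z_cut)
  )
  class(out) <- c("dep_table", class(out))
  attr(out, "contrast") <- name %||% paste(numerator, "vs", denominator,
                                           sep = "_")
  attr(out, "alpha") <- alpha
  attr(out, "z_cut") <- z_cut
  out
}

#' Call differentially expressed proteins from a contrast table
#'
#' Applies the combined cutoff: up-regulated proteins have `p < alpha` and
#' `z > z_cut`; down-regulated have `p < alpha` and `z < -z_cut`. An
#' optional Benjamini–Hochberg mode applies the same cutoffs to BH-adjusted
#' p-values instead (off by default; the standard workflow uses raw p plus
#' the z cutoff).
#'
#' @param dep A `dep_table` from [welch_contrast()].
#' @param alpha P-value cutoff.
#' @param z_cut Standardized-difference cutoff (use 0 to disable).
#' @param adjust Apply BH adjustment before thresholding.
#' @return Named list with character vectors `up` and `down`.
#' @export
call_deps <- function(dep, alpha = 0.05, z_cut = 1, adjust = FALSE) {
  p <- if (adjust) p.adjust(dep$p, method = "BH") else dep$p
  list(
    up = dep$protein_id[p < alpha & dep$z > z_cut],
    down = dep$protein_id[p < alpha & dep$z < -z_cut]
  )
}

#' Partition two protein sets into exclusive and shared members
#'
#' @param set_a,set_b Character vectors of protein IDs.
#' @return Named list `only_a`, `only_b`, `both`.
#' @export
overlap_sets <- function(set_a, set_b) {
  list(
    only_a = setdiff(set_a, set_b),
    only_b = setdiff(set_b, set_a),
    both = intersect(set_a, set_b)
  )
}

#' Reversal signature: opposite aging and knockout responses
#'
#' Filters for proteins significant in both the aging contrast (aged WT vs
#' young WT) and the knockout contrast (aged KO vs aged WT) whose log2
#' differences have opposite signs — proteins whose aging change the
#' knockout pushes back toward the young level.
#'
#' @param dep_age,dep_ko `dep_table`s over the same protein universe.
#' @param alpha,z_cut Significance cutoffs applied to both contrasts.
#' @return Tibble with one row per member: `protein_id`, `d_age`, `p_age`,
#'   `z_age`, `d_ko`, `p_ko`, `z_ko`, `pattern` (`"up_age_down_ko"` or
#'   `"down_age_up_ko"`).
#' @export
reversal_signature <- function(dep_age, dep_ko, alpha = 0.05, z_cut = 1) {
  if (!setequal(dep_age$protein_id, dep_ko$protein_id)) {
    abort("contrast tables must cover the same protein universe")
  }
  merged <- left_join(
    dplyr::select(as_tibble(dep_age), "protein_id",
                  d_age = "d_log2", p_age = "p", z_age = "z"),
    dplyr::select(as_tibble(dep_ko), "protein_id",
                  d_ko = "d_log2", p_ko = "p", z_ko = "z"),
    by = "protein_id"
  )
  sig <- merged$p_age < alpha & abs(merged$z_age) > z_cut &
    merged$p_ko < alpha & abs(merged$z_ko) > z_cut &
    sign(merged$d_age) == -sign(merged$d_ko) & merged$d_age != 0
  out <- merged[sig, ]
  out$pattern <- ifelse(out$d_age > 0, "up_age_down_ko", "down_age_up_ko")
  out
}

#' Per-group median coefficient of variation
#'
#' Quality-control summary on the linear-scale matrix: for every protein
#' and group, `CV% = 100 * sd / mean` over observed values (proteins with
#' fewer than two observed values in a group contribute nothing to that
#' group); the per-group median CV is reported.
#'
#' @param lfq A linear-scale [lfq_matrix()].
#' @return Tibble with columns `group`, `median_cv_pct`, `n_proteins`.
#' @export
cv_summary <- function(lfq) {
  stopifnot(inherits(lfq, "lfq_matrix"))
  if (lfq$scale != "linear") {
    abort("CV is computed on linear-scale intensities")
  }
  gcols <- group_columns(lfq)
  rows <- imap(gcols, function(cols, g) {
    sub <- lfq$intensities[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    cv <- rep(NA_real_, nrow(sub))
    ok <- n_obs >= 2
    if (!any(ok)) {
      abort(sprintf("group '%s' has no protein with 2+ observed values", g))
    }
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, sd, na.rm = TRUE)
    cv[ok] <- 100 * s[ok] / m[ok]
    tibble(group = g, median_cv_pct = median(cv, na.rm = TRUE),
           n_proteins = sum(ok))
  })
  bind_rows(rows)
}
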