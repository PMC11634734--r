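#' Two-factor ANOVA with interaction
#'
#' Fits `outcome ~ factor_a * factor_b` and reports F tests for both main
#' effects and the interaction. Type II sums of squares are the default
#' (identical to Type I/III in balanced designs); Type III with sum
#' contrasts is available for parity with SPSS-style output.
#'
#' @param data Data frame of per-animal measurements.
#' @param outcome Name of the numeric outcome column.
#' @param factor_a,factor_b Names of the two factor columns (defaults
#'   `"genotype"` and `"sex"`).
#' @param ss_type 2 (default) or 3.
#' @return Tibble with columns `term`, `sumsq`, `df`, `statistic`,
#'   `p_value`.
#' @export
two_way_anova <- function(data, outcome, factor_a = "genotype",
                          factor_b = "sex", ss_type = 2) {
  data <- as.data.frame(data)
  for (v in c(outcome, factor_a, factor_b)) {
    if (!v %in% names(data)) abort(sprintf("column '%s' not found", v))
  }
  data[[factor_a]] <- factor(data[[factor_a]])
  data[[factor_b]] <- factor(data[[factor_b]])
  cells <- table(data[[factor_a]], data[[factor_b]])
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)[1, ]
    abort(sprintf("cell %s:%s has fewer than 2 observations",
                  rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  fml <- stats::reformulate(sprintf("%s * %s", factor_a, factor_b),
                            response = outcome)
  if (ss_type == 3) {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    fit <- lm(fml, data = data)
    tab <- car::Anova(fit, type = 3)
    tab <- tab[!rownames(tab) %in% "(Intercept)", ]
  } else {
    fit <- lm(fml, data = data)
    tab <- car::Anova(fit, type = 2)
  }
  tibble(
    term = rownames(tab),
    sumsq = tab[["Sum Sq"]],
    df = tab[["Df"]],
    statistic = tab[["F value"]],
    p_value = tab[["Pr(>F)"]]
  )
}

#' Tukey honestly-significant-difference post hoc comparisons
#'
#' Pairwise group comparisons with studentized-range adjusted p-values,
#' after a one-way fit on the grouping column.
#'
#' @param data Data frame.
#' @param outcome Numeric outcome column name.
#' @param grouping Factor column name.
#' @return Tibble with `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(data, outcome, grouping) {
  data <- as.data.frame(data)
  data[[grouping]] <- factor(data[[grouping]])
  sizes <- table(data[[grouping]])
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(sprintf("group '%s' has fewer than 2 observations",
                  names(sizes)[which(sizes < 2)[1]]))
  }
  fml <- stats::reformulate(grouping, response = outcome)
  tk <- TukeyHSD(aov(fml, data = data))[[grouping]]
  tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
}

#' Repeated-measures phase effect
#'
#' One-way repeated-measures ANOVA for a within-animal phase factor (e.g.
#' DD baseline vs DD stress), fit as `metric ~ phase + Error(animal)`.
#' With exactly two phases the F statistic equals the square of the paired
#' t statistic.
#'
#' @param data Data frame with one row per animal x phase.
#' @param metric Numeric outcome column name.
#' @param phase Phase column name (default `"phase"`).
#' @param id Animal identifier column name (default `"animal_id"`).
#' @return One-row tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
rm_stress_effect <- function(data, metric, phase = "phase",
                             id = "animal_id") {
  data <- as.data.frame(data)
  data[[phase]] <- factor(data[[phase]])
  data[[id]] <- factor(data[[id]])
  counts <- table(data[[id]], data[[phase]])
  if (any(counts != 1)) {
    abort("each animal must have exactly one value per phase (paired design)")
  }
  fml <- stats::as.formula(sprintf("%s ~ %s + Error(%s)", metric, phase, id))
  fit <- aov(fml, data = data)
  within <- summary(fit)[["Error: Within"]][[1]]
  row <- within[trimws(rownames(within)) == phase, ]
  f_val <- row[["F value"]]
  p_val <- row[["Pr(>F)"]]
  if (row[["Sum Sq"]] < 1e-12) { # no phase effect at all (identical phases)
    f_val <- 0
    p_val <- 1
  }
  tibble(
    statistic = f_val,
    df1 = row[["Df"]],
    df2 = within[trimws(rownames(within)) == "Residuals", "Df"],
    p_value = p_val
  )
}

#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlations among numeric marker columns with
#' average-rank tie handling and two-sided p-values from the t
#' approximation `t = rho * sqrt(n - 2) / sqrt(1 - rho^2)`. Constant
#' markers give `NA` entries with a warning.
#'
#' @param data Data frame, one row per animal.
#' @param markers Character vector of marker columns (default: all numeric
#'   columns).
#' @return Object of class `cor_matrix`: list with matrices `rho`, `p` and
#'   `n`. [tidy()] gives a long tibble of pairs.
#' @export
spearman_matrix <- function(data, markers = NULL) {
  data <- as.data.frame(data)
  markers <- markers %||%
    names(data)[vapply(data, is.numeric, logical(1))]
  if (length(markers) < 2) abort("need at least 2 markers")
  m <- as.matrix(data[markers])
  if (nrow(m) < 4) abort("need at least 4 animals")
  const <- apply(m, 2, function(v) var(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warn(paste0("constant markers reported as NA: ",
                paste(markers[const], collapse = ", ")))
  }
  rho <- suppressWarnings(cor(m, method = "spearman",
                              use = "pairwise.complete.obs"))
  rho[const, ] <- NA
  rho[, const] <- NA
  n <- nrow(m)
  tstat <- rho * sqrt(n - 2) / sqrt(pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  diag(p) <- NA
  structure(list(rho = rho, p = p, n = n), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("<cor_matrix> %d markers, n = %d\n", nrow(x$rho), x$n))
  print(round(x$rho, 3))
  invisible(x)
}

#' @rdname spearman_matrix
#' @param x A `cor_matrix`.
#' @param ... Unused.
#' @export
tidy.cor_matrix <- function(x, ...) {
  nm <- colnames(x$rho)
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(
    marker_a = nm[pairs[, 1]],
    marker_b = nm[pairs[, 2]],
    rho = x$rho[pairs],
    p = x$p[pairs]
  )
}
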