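#' Signed soft-thresholded adjacency
#'
#' Pairwise protein co-expression adjacency for a signed network:
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta`, so perfectly anti-correlated
#' proteins get adjacency 0 and perfectly correlated proteins 1. The
#' diagonal is 1.
#'
#' @param x Complete log2 matrix, proteins in rows, samples in columns, or
#'   an imputed [lfq_matrix()].
#' @param beta Soft-threshold power (default 7).
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return Symmetric adjacency matrix with entries in \[0, 1\].
#' @export
signed_adjacency <- function(x, beta = 7, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(x, "lfq_matrix")) {
    if (x$scale != "log2") abort("network analysis needs the log2 matrix")
    x <- x$intensities
  }
  if (any(is.na(x))) abort("matrix has missing values: impute first")
  if (ncol(x) < 3) abort("need at least 3 samples")
  if (beta < 1) abort("`beta` must be >= 1")
  v <- row_vars(x)
  if (any(v == 0)) {
    abort(paste0("zero-variance proteins: ",
                 paste(head(rownames(x)[v == 0], 5), collapse = ", ")))
  }
  r <- cor(t(x), method = method)
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix (TOM)
#'
#' Neighborhood-sharing similarity on an adjacency matrix:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and connectivity `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. For adjacency in \[0, 1\] with unit diagonal the TOM is
#' symmetric with entries in \[0, 1\]; module detection clusters on the
#' dissimilarity `1 - TOM`.
#'
#' @param adj Symmetric adjacency matrix with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) {
    abort("adjacency must be symmetric")
  }
  if (any(abs(diag(adj) - 1) > 1e-10)) {
    abort("adjacency must have unit diagonal")
  }
  # sum_{u != i,j} a_iu a_uj = (A^2)_ij - a_ii a_ij - a_ij a_jj
  l <- adj %*% adj - 2 * adj
  k <- rowSums(adj) - 1
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

module_labels <- function(cluster, min_module_size) {
  sizes <- table(cluster)
  small <- names(sizes)[sizes < min_module_size]
  cluster[as.character(cluster) %in% small] <- 0L
  kept <- sort(table(cluster[cluster != 0]), decreasing = TRUE)
  relabel <- setNames(seq_along(names(kept)), names(kept))
  out <- ifelse(cluster == 0, "ME00",
                sprintf("ME%02d", relabel[as.character(cluster)]))
  unname(out)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' `1 - TOM`; initial branches come from a static cut of the dendrogram at
#' a fraction of its tallest merge height; branches smaller than
#' `min_module_size` are left unassigned. Branch membership is then
#' cleaned by module membership (kME): a protein whose correlation with
#' its module's eigengene falls below `kme_min` is released to `ME00` —
#' this removes proteins that attach to a branch through chance
#' correlation, which otherwise contaminate modules at moderate sample
#' sizes. Modules are labeled `ME01`, `ME02`, ... in decreasing size
#' order with `ME00` reserved for unassigned proteins.
#'
#' @param tom TOM similarity matrix from [tom_similarity()].
#' @param min_module_size Smallest retained module (default 20).
#' @param cut_frac Static cut height as a fraction of the tallest merge
#'   (default 0.92); ignored when `cut_height` is given.
#' @param cut_height Absolute dissimilarity cut height (optional).
#' @param x Expression matrix (proteins x samples) used for the kME
#'   cleanup; when `NULL` the cleanup is skipped.
#' @param kme_min Minimum |module membership| retained (default 0.5).
#' @return Tibble of class `module_assignment` with columns `protein_id`,
#'   `module`; attributes `cut_height` and `sizes`.
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_frac = 0.92,
                           cut_height = NULL, x = NULL, kme_min = 0.5) {
  n <- nrow(tom)
  ids <- rownames(tom) %||% sprintf("P%05d", seq_len(n))
  if (n < min_module_size || n < 2) {
    out <- tibble(protein_id = ids, module = rep("ME00", n))
    class(out) <- c("module_assignment", class(out))
    return(out)
  }
  h <- hclust(as.dist(1 - tom), method = "average")
  cut_height <- cut_height %||% (cut_frac * max(h$height))
  cl <- cutree(h, h = cut_height)
  lab <- module_labels(cl, min_module_size)
  if (!is.null(x) && any(lab != "ME00")) {
    lab <- prune_by_kme(x, ids, lab, kme_min, min_module_size)
  }
  out <- tibble(protein_id = ids, module = lab)
  class(out) <- c("module_assignment", class(out))
  attr(out, "cut_height") <- cut_height
  attr(out, "sizes") <- sort(table(lab[lab != "ME00"]), decreasing = TRUE)
  out
}

# release proteins whose module membership (cor with the module eigengene)
# is below kme_min, then re-apply the size floor and renumber by size
prune_by_kme <- function(x, ids, lab, kme_min, min_module_size) {
  asn <- tibble(protein_id = ids, module = lab)
  me <- module_eigengenes(x, asn)
  for (m in colnames(me$eigengenes)) {
    rows <- which(lab == m)
    kme <- as.vector(cor(t(x[ids[rows], , drop = FALSE]),
                         me$eigengenes[, m]))
    lab[rows[abs(kme) < kme_min]] <- "ME00"
  }
  sizes <- table(lab[lab != "ME00"])
  lab[lab %in% names(sizes)[sizes < min_module_size]] <- "ME00"
  kept <- sort(table(lab[lab != "ME00"]), decreasing = TRUE)
  relabel <- setNames(sprintf("ME%02d", seq_along(names(kept))), names(kept))
  ifelse(lab == "ME00", "ME00", unname(relabel[lab]))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' proteins' standardized expression, expressed in sample space: a
#' unit-norm per-sample summary vector, sign-oriented to correlate
#' positively with the module's mean standardized expression. The
#' fraction of variance it explains is reported. `ME00` (unassigned) is
#' excluded; a single-protein module's eigengene is that protein's
#' standardized profile.
#'
#' @param x Complete log2 matrix (proteins x samples) or [lfq_matrix()].
#' @param assignment A `module_assignment` from [detect_modules()].
#' @return Object of class `module_eigengenes`: list with `eigengenes`
#'   (samples x modules matrix), `var_explained` (named vector) and
#'   `sample_ids`. [tidy()] gives a long tibble.
#' @export
module_eigengenes <- function(x, assignment) {
  if (inherits(x, "lfq_matrix")) x <- x$intensities
  if (any(is.na(x))) abort("matrix has missing values: impute first")
  mods <- sort(setdiff(unique(assignment$module), "ME00"))
  if (!length(mods)) abort("no assigned modules")
  me <- matrix(NA_real_, ncol(x), length(mods),
               dimnames = list(colnames(x), mods))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    rows <- assignment$protein_id[assignment$module == m]
    sub <- x[rows, , drop = FALSE]
    z <- t(scale(t(sub))) # standardize each protein across samples
    s <- svd(t(z))        # samples x proteins
    u1 <- s$u[, 1]
    # orient positively with the mean standardized profile; a perfectly
    # balanced module (mean profile ~ 0) falls back to the first protein
    mp <- rowMeans(t(z))
    if (sd(mp) < 1e-12) mp <- z[1, ]
    if (cor(u1, mp) < 0) u1 <- -u1
    me[, m] <- u1
    ve[m] <- s$d[1]^2 / sum(s$d^2)
  }
  structure(list(eigengenes = me, var_explained = ve,
                 sample_ids = colnames(x)),
            class = "module_eigengenes")
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat(sprintf("<module_eigengenes> %d modules x %d samples\n",
              ncol(x$eigengenes), nrow(x$eigengenes)))
  print(round(x$var_explained, 3))
  invisible(x)
}

#' @rdname module_eigengenes
#' @param ... Unused.
#' @export
tidy.module_eigengenes <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$eigengenes), times = ncol(x$eigengenes)),
    module = rep(colnames(x$eigengenes), each = nrow(x$eigengenes)),
    eigengene = as.vector(x$eigengenes)
  )
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the pair of modules whose eigengene dissimilarity
#' `1 - cor(ME_a, ME_b)` is smallest, while it is below
#' `merge_cut_height`, recomputing eigengenes after each merge. Labels are
#' renumbered by decreasing size at the end.
#'
#' @param x Complete log2 matrix or [lfq_matrix()].
#' @param assignment A `module_assignment`.
#' @param merge_cut_height Dissimilarity threshold below which modules
#'   merge (default 0.25, i.e. eigengene correlation above 0.75).
#' @return Updated `module_assignment`.
#' @export
merge_modules <- function(x, assignment, merge_cut_height = 0.25) {
  if (inherits(x, "lfq_matrix")) x <- x$intensities
  if (merge_cut_height <= 0 || merge_cut_height >= 1) {
    abort("`merge_cut_height` must be in (0, 1)")
  }
  lab <- assignment$module
  repeat {
    mods <- setdiff(unique(lab), "ME00")
    if (length(mods) < 2) break
    me <- module_eigengenes(x, tibble(protein_id = assignment$protein_id,
                                      module = lab))
    cm <- cor(me$eigengenes)
    diss <- 1 - cm
    diag(diss) <- Inf
    mi <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    if (diss[mi[1], mi[2]] >= merge_cut_height) break
    a <- colnames(cm)[mi[1]]; b <- colnames(cm)[mi[2]]
    lab[lab == b] <- a
  }
  # renumber by decreasing size
  kept <- sort(table(lab[lab != "ME00"]), decreasing = TRUE)
  relabel <- setNames(sprintf("ME%02d", seq_along(names(kept))), names(kept))
  lab <- ifelse(lab == "ME00", "ME00", relabel[lab])
  out <- tibble(protein_id = assignment$protein_id, module = unname(lab))
  class(out) <- c("module_assignment", class(out))
  attr(out, "sizes") <- sort(table(lab[lab != "ME00"]), decreasing = TRUE)
  out
}

#' Module–trait correlation
#'
#' Pearson correlation between each module eigengene and each numeric
#' trait, with the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Zero-variance traits give `NA` with a warning.
#'
#' @param me A `module_eigengenes` object.
#' @param traits Tibble with `sample_id` and numeric trait columns, aligned
#'   with the eigengene samples.
#' @return Object of class `module_trait_corr`: list with matrices `r` and
#'   `p` (modules x traits) and `n`. [tidy()] gives a long tibble;
#'   [autoplot()] draws the correlation heatmap.
#' @export
module_trait_correlation <- function(me, traits) {
  stopifnot(inherits(me, "module_eigengenes"))
  traits <- as_tibble(traits)
  if (!"sample_id" %in% names(traits)) abort("traits need a sample_id column")
  if (!setequal(traits$sample_id, me$sample_ids)) {
    abort("trait samples must match eigengene samples")
  }
  traits <- traits[match(me$sample_ids, traits$sample_id), ]
  tm <- as.matrix(traits[setdiff(names(traits), "sample_id")])
  storage.mode(tm) <- "double"
  const <- apply(tm, 2, function(v) var(v) == 0)
  if (any(const)) {
    warn(paste0("zero-variance traits reported as NA: ",
                paste(colnames(tm)[const], collapse = ", ")))
  }
  n <- nrow(tm)
  r <- suppressWarnings(cor(me$eigengenes, tm))
  r[, const] <- NA
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  structure(list(r = r, p = p, n = n), class = "module_trait_corr")
}

#' @export
print.module_trait_corr <- function(x, ...) {
  cat(sprintf("<module_trait_corr> %d modules x %d traits (n = %d)\n",
              nrow(x$r), ncol(x$r), x$n))
  invisible(x)
}

#' @rdname module_trait_correlation
#' @param x A `module_trait_corr`.
#' @param ... Unused.
#' @export
tidy.module_trait_corr <- function(x, ...) {
  tibble(
    module = rep(rownames(x$r), times = ncol(x$r)),
    trait = rep(colnames(x$r), each = nrow(x$r)),
    r = as.vector(x$r),
    p = as.vector(x$p)
  )
}

#' Hypergeometric gene-set enrichment for one module
#'
#' Upper-tail hypergeometric test of the overlap between a module's
#' proteins and each gene set, against a stated background universe, with
#' Benjamini–Hochberg adjustment across sets.
#'
#' @param module_proteins Character vector (nonempty).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector containing all tested proteins
#'   (must be a superset of the module).
#' @return Tibble with columns `set`, `set_size`, `overlap`, `ratio`
#'   (overlap / module size), `p`, `p_adj`, sorted by `p`.
#' @export
enrich_hypergeometric <- function(module_proteins, gene_sets, background) {
  if (!length(module_proteins)) abort("empty module")
  if (!length(gene_sets)) abort("no gene sets supplied")
  if (!all(module_proteins %in% background)) {
    abort("background must contain every module protein")
  }
  bg <- unique(background)
  mod <- unique(module_proteins)
  nn <- length(bg)
  n_mod <- length(mod)
  rows <- imap(gene_sets, function(members, nm) {
    in_bg <- intersect(unique(members), bg)
    k <- length(intersect(in_bg, mod))
    kk <- length(in_bg)
    p <- phyper(k - 1, kk, nn - kk, n_mod, lower.tail = FALSE)
    tibble(set = nm, set_size = kk, overlap = k, ratio = k / n_mod, p = p)
  })
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  arrange(out, .data$p)
}

#' Run the full weighted correlation network analysis
#'
#' Convenience wrapper chaining [signed_adjacency()], [tom_similarity()],
#' [detect_modules()], [merge_modules()], [module_eigengenes()] and, when
#' traits are supplied, [module_trait_correlation()].
#'
#' @param x Complete log2 matrix (proteins x samples) or imputed
#'   [lfq_matrix()].
#' @param traits Optional trait tibble (see [module_trait_correlation()]).
#' @param beta Soft-threshold power.
#' @param min_module_size Minimum module size.
#' @param merge_cut_height Eigengene merge threshold.
#' @param cut_frac Static dendrogram cut as a fraction of the tallest
#'   merge height.
#' @param kme_min Module-membership cleanup threshold (see
#'   [detect_modules()]).
#' @param method Correlation type for the adjacency.
#' @return Object of class `wpcna_fit`: list with `assignment`,
#'   `eigengenes`, `trait_corr` (or NULL) and the parameters. [glance()]
#'   summarises module count and sizes.
#' @export
run_wpcna <- function(x, traits = NULL, beta = 7, min_module_size = 20,
                      merge_cut_height = 0.25, cut_frac = 0.92,
                      kme_min = 0.5, method = "pearson") {
  if (inherits(x, "lfq_matrix")) {
    if (x$scale != "log2") abort("network analysis needs the log2 matrix")
    x <- x$intensities
  }
  adj <- signed_adjacency(x, beta = beta, method = method)
  tom <- tom_similarity(adj)
  assignment <- detect_modules(tom, min_module_size = min_module_size,
                               cut_frac = cut_frac, x = x,
                               kme_min = kme_min)
  if (length(setdiff(unique(assignment$module), "ME00")) >= 2) {
    assignment <- merge_modules(x, assignment,
                                merge_cut_height = merge_cut_height)
  }
  me <- NULL
  tc <- NULL
  if (length(setdiff(unique(assignment$module), "ME00"))) {
    me <- module_eigengenes(x, assignment)
    if (!is.null(traits)) tc <- module_trait_correlation(me, traits)
  }
  structure(
    list(assignment = assignment, eigengenes = me, trait_corr = tc,
         params = list(beta = beta, min_module_size = min_module_size,
                       merge_cut_height = merge_cut_height,
                       cut_frac = cut_frac, kme_min = kme_min,
                       method = method)),
    class = "wpcna_fit"
  )
}

#' @export
print.wpcna_fit <- function(x, ...) {
  sizes <- table(x$assignment$module)
  cat(sprintf("<wpcna_fit> %d proteins, %d modules (+ %d unassigned)\n",
              nrow(x$assignment),
              length(setdiff(names(sizes), "ME00")),
              if ("ME00" %in% names(sizes)) sizes[["ME00"]] else 0L))
  invisible(x)
}

#' @rdname run_wpcna
#' @param ... Unused.
#' @export
glance.wpcna_fit <- function(x, ...) {
  sizes <- table(x$assignment$module)
  assigned <- sizes[setdiff(names(sizes), "ME00")]
  tibble(
    n_modules = length(assigned),
    n_unassigned = if ("ME00" %in% names(sizes)) as.integer(sizes[["ME00"]])
      else 0L,
    min_size = if (length(assigned)) min(assigned) else NA_integer_,
    max_size = if (length(assigned)) max(assigned) else NA_integer_,
    beta = x$params$beta
  )
}
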