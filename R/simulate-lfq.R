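#' Specification for a simulated LFQ experiment
#'
#' Parameters of the LFQ generator. On the log2 scale every protein has a
#' baseline abundance drawn from `N(base_log2_mean, base_log2_sd^2)`. A
#' fraction `dep_frac` of proteins carries a planted aging effect (aged
#' groups shifted by a log2 fold change of random sign with magnitude drawn
#' uniformly from `effect_log2`); of those, `reversal_frac` also carry a
#' knockout effect of the opposite sign (aged-KO shifted back toward the
#' young level), emulating a "young-like" reversal signature. Co-expression
#' modules are planted as blocks of proteins sharing a latent per-sample
#' factor scaled so the expected within-module pairwise correlation equals
#' `module_cor`. Missingness is left-censored: the probability that an
#' entry is missing is a decreasing logistic function of its true log2
#' intensity, `plogis(missing_steepness * (missing_midpoint_log2 - x))`,
#' which reduces to intensity-independent 50% missingness at steepness 0.
#'
#' @param n_proteins Number of proteins.
#' @param groups Named integer vector of samples per group, in design order
#'   (default `c(young_wt = 5, aged_wt = 6, aged_ko = 6)`).
#' @param base_log2_mean,base_log2_sd Baseline log2 abundance distribution.
#' @param dep_frac Fraction of proteins with a planted aging effect.
#' @param effect_log2 Length-2 range of planted |log2 fold change|.
#' @param reversal_frac Fraction of planted DEPs with an opposing KO effect.
#' @param n_modules,module_size,module_cor Planted co-expression structure.
#' @param missing_steepness,missing_midpoint_log2 Logistic censoring
#'   parameters; an `NA` midpoint is calibrated at generation time so the
#'   overall expected missing fraction equals `target_missing_rate`.
#' @param target_missing_rate Overall missing fraction used to calibrate an
#'   `NA` midpoint (default 0.2, typical protein-group-level missingness).
#' @param noise_sd Residual within-group log2 noise SD. The default 0.18
#'   corresponds to a ~12.5% coefficient of variation on the linear scale,
#'   the quantitative precision typical of deep DIA label-free data.
#' @param seed Integer seed.
#' @return A list of class `lfq_sim_spec`.
#' @export
lfq_sim_spec <- function(n_proteins = 2000,
                         groups = c(young_wt = 5, aged_wt = 6, aged_ko = 6),
                         base_log2_mean = 25, base_log2_sd = 2,
                         dep_frac = 0.1, effect_log2 = c(1, 2),
                         reversal_frac = 0.1,
                         n_modules = 0, module_size = 50, module_cor = 0.8,
                         missing_steepness = 0.8,
                         missing_midpoint_log2 = NA,
                         target_missing_rate = 0.2,
                         noise_sd = 0.18, seed = 1L) {
  stopifnot(n_proteins > 0, all(groups > 0), length(groups) >= 1)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named vector of group sizes")
  }
  assert_scalar_number(dep_frac, "dep_frac", 0, 1)
  assert_scalar_number(reversal_frac, "reversal_frac", 0, 1)
  if (n_modules > 0) {
    assert_scalar_number(module_cor, "module_cor", 0, 1)
    if (module_cor <= 0 || module_cor >= 1) {
      abort("`module_cor` must be in (0, 1)")
    }
    if (n_modules * module_size > n_proteins) {
      abort("planted modules need more proteins than `n_proteins`")
    }
  }
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(missing_steepness, "missing_steepness", 0)
  structure(
    list(n_proteins = as.integer(n_proteins), groups = groups,
         base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
         dep_frac = dep_frac, effect_log2 = effect_log2,
         reversal_frac = reversal_frac, n_modules = as.integer(n_modules),
         module_size = as.integer(module_size), module_cor = module_cor,
         missing_steepness = missing_steepness,
         missing_midpoint_log2 = missing_midpoint_log2,
         target_missing_rate = target_missing_rate,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "lfq_sim_spec"
  )
}

#' Simulate an LFQ experiment with known ground truth
#'
#' Generates a linear-scale [lfq_matrix()] under the model described in
#' [lfq_sim_spec()] together with its ground truth: per-protein planted
#' effects for the aging (aged-WT vs young-WT) and knockout (aged-KO vs
#' aged-WT) contrasts, module membership, latent module factors, and the
#' missingness indicator.
#'
#' The aging effect shifts all aged samples relative to young wild type;
#' the knockout effect additionally shifts aged-KO samples relative to aged
#' wild type. Group labels `young_wt`, `aged_wt`, `aged_ko` activate these
#' effects; with other labels no effects are planted unless `dep_frac = 0`.
#'
#' @param spec An [lfq_sim_spec()].
#' @return List with elements `lfq` (an [lfq_matrix()], linear scale, NA for
#'   censored entries) and `truth`: a list with `effects` (tibble:
#'   `protein_id`, `effect_age`, `effect_ko`, `is_dep`, `is_reversal`),
#'   `modules` (tibble: `protein_id`, `module` with 0 = none), `factors`
#'   (samples x modules matrix of latent factors), `log2_complete` (the
#'   uncensored log2 matrix) and `missing` (logical matrix).
#' @export
simulate_lfq <- function(spec) {
  stopifnot(inherits(spec, "lfq_sim_spec"))
  np <- spec$n_proteins
  ns <- sum(spec$groups)
  grp <- rep(names(spec$groups), times = spec$groups)
  sample_ids <- sprintf("%s_%02d", grp, unlist(lapply(spec$groups, seq_len)))
  protein_ids <- sprintf("P%05d", seq_len(np))

  with_seed(spec$seed, {
    mu <- rnorm(np, spec$base_log2_mean, spec$base_log2_sd)

    n_dep <- round(spec$dep_frac * np)
    effect_age <- numeric(np)
    effect_ko <- numeric(np)
    dep_idx <- if (n_dep > 0) sample.int(np, n_dep) else integer(0)
    if (n_dep > 0) {
      mag <- runif(n_dep, spec$effect_log2[1], spec$effect_log2[2])
      sgn <- sample(c(-1, 1), n_dep, replace = TRUE)
      effect_age[dep_idx] <- sgn * mag
      n_rev <- round(spec$reversal_frac * n_dep)
      rev_idx <- if (n_rev > 0) dep_idx[seq_len(n_rev)] else integer(0)
      if (n_rev > 0) {
        effect_ko[rev_idx] <- -sign(effect_age[rev_idx]) *
          runif(n_rev, spec$effect_log2[1], spec$effect_log2[2])
      }
    } else {
      rev_idx <- integer(0)
    }

    module <- integer(np)
    factors <- NULL
    if (spec$n_modules > 0) {
      pool <- setdiff(seq_len(np), dep_idx)
      need <- spec$n_modules * spec$module_size
      if (length(pool) < need) {
        abort("not enough non-DEP proteins to plant the requested modules")
      }
      # plant modules among the most abundant eligible proteins: a module
      # whose members sit at the censoring limit is unrecoverable by any
      # method once its values are mostly imputed, which would defeat the
      # generator's purpose of providing a recoverable ground truth
      pool <- pool[order(mu[pool], decreasing = TRUE)]
      members <- sample(pool[seq_len(min(length(pool), 2 * need))], need)
      module[members] <- rep(seq_len(spec$n_modules),
                             each = spec$module_size)
      factors <- matrix(rnorm(ns * spec$n_modules), ns, spec$n_modules,
                        dimnames = list(sample_ids,
                                        paste0("factor_", seq_len(spec$n_modules))))
    }

    aged <- grp %in% c("aged_wt", "aged_ko")
    ko <- grp == "aged_ko"
    x <- matrix(mu, np, ns) +
      outer(effect_age, as.numeric(aged)) +
      outer(effect_ko, as.numeric(ko)) +
      matrix(rnorm(np * ns, 0, spec$noise_sd), np, ns)
    if (spec$n_modules > 0) {
      # loading chosen so cor within a module = v / (v + noise_sd^2) = module_cor
      lambda <- sqrt(spec$module_cor / (1 - spec$module_cor)) * spec$noise_sd
      in_mod <- module > 0
      x[in_mod, ] <- x[in_mod, ] + lambda * t(factors[, module[in_mod],
                                                      drop = FALSE])
    }
    dimnames(x) <- list(protein_ids, sample_ids)

    midpoint <- spec$missing_midpoint_log2
    if (is.na(midpoint)) {
      # solve for the midpoint giving the target overall missing fraction
      if (spec$missing_steepness == 0) {
        midpoint <- 0 # steepness 0: flat 50% regardless of midpoint
      } else if (spec$target_missing_rate == 0) {
        midpoint <- -Inf # no censoring
      } else {
        rate_at <- function(m) {
          mean(stats::plogis(spec$missing_steepness * (m - x)))
        }
        midpoint <- stats::uniroot(
          function(m) rate_at(m) - spec$target_missing_rate,
          lower = min(x) - 20, upper = max(x) + 20
        )$root
      }
    }
    p_miss <- stats::plogis(spec$missing_steepness * (midpoint - x))
    miss <- matrix(runif(np * ns) < p_miss, np, ns,
                   dimnames = dimnames(x))

    linear <- 2^x
    linear[miss] <- NA

    ann <- tibble(sample_id = sample_ids, group = grp)
    list(
      lfq = lfq_matrix(linear, ann, scale = "linear"),
      truth = list(
        effects = tibble(
          protein_id = protein_ids,
          effect_age = effect_age,
          effect_ko = effect_ko,
          is_dep = seq_len(np) %in% dep_idx,
          is_reversal = seq_len(np) %in% rev_idx
        ),
        modules = tibble(protein_id = protein_ids, module = module),
        factors = factors,
        log2_complete = x,
        missing = miss,
        missing_midpoint_log2 = midpoint
      )
    )
  })
}

#' Simulate a sample-trait table tied to planted module factors
#'
#' Builds per-sample numeric traits whose correlation with a named latent
#' module factor approximates a target, plus binary encodings. A continuous
#' trait tied to module `m` at target correlation `r` is generated as
#' `r*f_m + sqrt(1 - r^2)*noise`; a binary tied trait thresholds that
#' latent variable at 0 (its observed correlation is attenuated relative to
#' the target). Traits with `module = NA` are independent noise (or fair
#' coin flips when binary).
#'
#' @param truth Ground-truth list from [simulate_lfq()] (needs `factors`).
#' @param trait_specs Tibble/data frame with columns `name`, `module`
#'   (integer or NA), `target_r`, and optionally `type` (`"continuous"`
#'   default, or `"binary"`).
#' @param seed Integer seed.
#' @return Tibble with `sample_id` and one numeric column per trait.
#' @export
simulate_trait_table <- function(truth, trait_specs, seed = 1L) {
  trait_specs <- as_tibble(trait_specs)
  if (!all(c("name", "module", "target_r") %in% names(trait_specs))) {
    abort("`trait_specs` needs columns name, module, target_r")
  }
  if (!"type" %in% names(trait_specs)) trait_specs$type <- "continuous"
  f <- truth$factors
  tied <- trait_specs$module[!is.na(trait_specs$module)]
  if (length(tied) && (is.null(f) || any(tied > ncol(f)) || any(tied < 1))) {
    abort("trait references an unknown module factor")
  }
  ns <- if (!is.null(f)) nrow(f) else nrow(truth$missing) * 0 +
    ncol(truth$log2_complete)
  sample_ids <- if (!is.null(f)) rownames(f) else colnames(truth$log2_complete)
  with_seed(seed, {
    cols <- lapply(seq_len(nrow(trait_specs)), function(i) {
      m <- trait_specs$module[i]
      r <- trait_specs$target_r[i]
      latent <- if (is.na(m)) {
        rnorm(ns)
      } else {
        r * as.vector(scale(f[, m])) + sqrt(max(0, 1 - r^2)) * rnorm(ns)
      }
      if (trait_specs$type[i] == "binary") {
        as.integer(latent > 0)
      } else {
        latent
      }
    })
    names(cols) <- trait_specs$name
    bind_cols(tibble(sample_id = sample_ids), as_tibble(cols))
  })
}

#' Binary trait encodings from sample annotations
#'
#' Expands the categorical annotation columns of an LFQ matrix into 0/1
#' indicator traits (one per level, reference level dropped), the encoding
#' used when correlating module eigengenes with genotype/sex/age.
#'
#' @param lfq An [lfq_matrix()].
#' @param columns Annotation columns to encode (default all except
#'   `sample_id`).
#' @return Tibble with `sample_id` and one 0/1 column per non-reference
#'   level, named `column_level`.
#' @export
encode_annotations <- function(lfq, columns = NULL) {
  ann <- lfq$annotations
  columns <- columns %||% setdiff(names(ann), "sample_id")
  out <- tibble(sample_id = ann$sample_id)
  for (cl in columns) {
    lev <- unique(ann[[cl]])
    for (l in lev[-1]) {
      out[[paste(cl, l, sep = "_")]] <- as.integer(ann[[cl]] == l)
    }
  }
  out
}
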