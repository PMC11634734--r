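---
title: "circaprot: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circaprot: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaprot)
```

circaprot re-implements, as a reusable and tested pipeline, the
computational analysis of an aged-mouse phenotyping study: circadian
wheel-running rhythmometry, label-free proteomics differential
expression with left-censored imputation and a reversal-signature
filter, weighted protein correlation network analysis with module–trait
correlation, and the accompanying group statistics. This vignette is the
package's account of the underlying models, the parameters that matter,
and the choices made where the design was genuinely open.

## The synthetic study

Raw per-animal behavior and the original mass-spectrometry output are
not redistributable, so the package ships generators whose defaults
define the study conditions and whose ground truth makes every stage
verifiable by parameter recovery.

### Wheel-running records

`simulate_activity()` generates binned counts (5-min bins by default)
under an ordered schedule of phases mirroring a standard protocol: 9
light/dark (LD) days with lights on 06:00–18:00, a 7-h phase advance
with 9 days to re-entrain, 9 days of constant darkness (DD), and 9
further DD days after an acute stress event. The model is a two-state
skeleton plus noise:

* each circadian cycle has an **active window** covering `active_frac`
  (default 0.5) of the cycle, anchored at the cycle's onset;
* under LD the onset is locked to dark onset; during the phase advance it
  moves toward the advanced dark onset at `reentrain_rate_h_per_day`
  (default 1 h/day); in DD it drifts by `tau_h − 24` per day; after the
  stress day the period changes by `delta_tau_h` — stress is modeled
  *only* as a period change, because the other stress phenotypes
  (amplitude, fragmentation) are exercised by their own parameters;
* inside the active window a two-state (bout/rest) Markov chain flips
  with per-bin probability `fragmentation`, giving direct control over
  the intradaily variability statistic downstream. The chain is
  symmetric, so a fragmented window spends about half its bins in rest
  bouts;
* counts are Poisson with rate `rate_active` (default 15 counts/bin
  during bouts) or `rate_rest` (default 0.2); light masks activity: on
  lighted days, bins in the light get `rate_rest` regardless of
  circadian state.

The default rates are free parameters, not fitted values — wheel-running
reports rarely publish per-animal rates — and each record carries its true
per-day onset and period in an attribute for recovery tests. What the
generator deliberately does not emulate: mechanistic clock-gene
dynamics, ultradian rhythms within bouts, aftereffects of entrainment,
or gradual (rather than stepwise) period change after stress. Passing
tests therefore show that the analysis recovers the parameters of this
class of rhythm, not that it is robust to every pathology of real
actigraphy.

### LFQ matrices

`simulate_lfq()` builds a proteins × samples intensity matrix on the
log2 scale and exponentiates: baseline abundances are
`N(base_log2_mean = 25, base_log2_sd = 2)`; within-group noise is
`N(0, noise_sd²)` with `noise_sd = 0.18`, chosen so that the linear-scale
coefficient of variation is ≈ 12.5%, the quantitative precision typical
of deep DIA label-free data. A fraction `dep_frac = 0.1` of proteins
carries an aging effect (aged groups shifted by a log2 fold change of
random sign, magnitude uniform on `effect_log2 = c(1, 2)`); of those,
`reversal_frac = 0.1` also carry an opposing knockout effect, emulating
a young-like reversal. Co-expression modules are planted as blocks
sharing a latent per-sample factor with loading chosen so the expected
within-module pairwise correlation equals `module_cor`. Module members
are drawn from the most abundant eligible proteins: a "module" planted
at the censoring limit would be unrecoverable by any method once its
values are imputed, defeating the generator's purpose of providing a
recoverable truth.

Missingness is left-censored (MNAR): an entry is missing with
probability `plogis(steepness × (midpoint − x))` on the log2 scale
(`steepness = 0.8` per log2 unit). When the midpoint is not given it is
calibrated at generation time so the overall expected missing fraction
equals `target_missing_rate` (default 0.2). At steepness 0 the model
degenerates to intensity-independent 50% missingness, which the tests
use as the "flat" limit case.

`simulate_trait_table()` produces per-sample traits tied to a named
module factor at a target correlation (`r·f + sqrt(1 − r²)·noise`);
binary traits threshold the latent variable at zero and are therefore
attenuated relative to the target, which is documented rather than
corrected. `encode_annotations()` expands categorical annotations to 0/1
indicators, the coding used for module–trait heatmaps.

## Actigraphy

**Chi-square periodogram.** For a trial period of `P` bins the series is
folded into `P` phase classes and
`Qp = Σ_h n_h (M_h − M̄)² / (SS_tot/N)` is referred to χ²(P−1). Two
numerical choices matter. First, the default folds *all* bins (class
sizes `n_h` differ by at most one); the classical variant that truncates
to complete periods (`truncate = TRUE`) discards up to a full cycle and
measurably widens the peak on 6-day records — with full folding the
package recovers τ ∈ {23.5, 24.0, 24.7} within one 5-min bin on 6-day
simulated records across seeds, which the truncated variant does not.
Second, the significance line is Bonferroni-corrected across the ~97
trial periods of the default 20–28 h scan; at a raw per-period α of
0.05, essentially every pure-noise record would show some "significant"
period. The search grid is one bin wide (5 min), covering the murine
free-running range at native resolution. Amplitude is defined as the
peak `Qp` excess over its significance line; commercial actigraphy
software reports an "amplitude" variable without a published definition,
so the package states its own.

**Onset detection.** An onset opens a 1-h window with ≥ 75% of bins at
or above threshold, preceded by 4 quiet hours (< 25% active bins). Three
hardening choices, all exposed as parameters: the threshold defaults to
*half* the median of nonzero bin counts (at the median itself, Poisson
noise leaves ~half of genuinely active bins "inactive" and the window
criterion essentially never fires); interior rest gaps up to 0.5 h
flanked by activity are closed first (fragmented records otherwise
delay and jitter the onset; closing cannot extend an active run outward,
so clean records are unchanged); and the onset bin itself must be
active (otherwise every onset shifts early by up to a quarter hour).
Successive onsets at least 16 h apart are chained, and the day index
advances by the rounded cycle count, so drifting onsets unwrap correctly
and missing days are tolerated.

**Periods from onsets.** The onset-regression period is `24 + slope` of
unwrapped onset time on day index. Both period estimators are computed
and reported separately by `circadian_metrics()`; published methods
sections often conflate the two, so no attempt is made to privilege
either.

**IS, IV, RA.** Computed on hourly bins (p = 24), matching their
hourly-means definitions. IS is 1 exactly when all days are identical
and has expectation ≈ 1/n_days for unstructured noise; IV has
expectation `2n/(n−1)` for iid noise and can exceed 2 for strictly
alternating series — the conventional 0–2 range describes typical data,
not a bound. RA uses the standard M10/L5 definition on 10 and 5
*consecutive hours* of the circular mean profile; a days-based phrasing
of M10/L5 occasionally seen in methods text is treated as an erratum
for hours.

**Re-entrainment.** Days until the onset is within `tol_h` (default
0.5 h) of the pre-advance level minus the advance, sustained for
`sustain_days` (default 2) consecutive observed days. The pre-advance
level is the *median* onset by default — robust to the occasional
late-detected onset on fragmented records — with the mean available.
Both defaults are judgement calls and are exposed in the
configuration.

## Differential expression

The stage order is fixed and guarded by the matrix's scale flag:
contaminant removal and log2 transform (`preprocess_lfq()`, which
refuses an already-log2 matrix), the 60%-valid-in-at-least-one-group
filter with an inclusive boundary (exactly 60% passes), imputation, then
contrasts. Imputation replaces each missing entry with a draw from
`N(μ_s − 1.8 σ_s, (0.3 σ_s)²)` using the entry's sample-column observed
moments (the column-wise convention; a whole-matrix mode is available)
and never alters observed entries. Welch's *t* uses the
Welch–Satterthwaite degrees of freedom; `z` standardizes the log2
differences across all tested proteins within the contrast, and the
">1" cutoff is read as a magnitude cutoff (`|z| > 1`), matching its use
as symmetric volcano-plot threshold lines. No multiple-testing
correction is applied in the main call — raw p plus the z cutoff is the
rule this workflow follows — with a Benjamini–Hochberg option off by
default.

Two behaviors of this pipeline are worth stating because the test suite
documents them quantitatively. First, downshifted imputation *attenuates
and destabilizes* effects for proteins censored in both compared groups
(their group means collapse to the same downshifted distribution) and
*inflates within-group variance* for partially censored proteins; power
against planted 1–2 log2-unit effects is therefore high on complete
data but distinctly lower under 20% MNAR. Second, the aging and
knockout contrasts share the aged-WT group, so their noise is
negatively correlated by construction; occasional non-planted proteins
satisfy the reversal rule through this shared-group artifact, which a
real study would face equally. The reversal-recovery contract is
therefore stated as a mean recall across replicate simulations, and the
membership rule itself is checked exactly.

Welch's test at n = 6 + 6 is slightly conservative (empirical type-I
error below the nominal 5%), a known property of the estimated-df
approximation; the acceptance script averages replicate null
simulations to report the rate stably.

## Network analysis

The adjacency is signed, `((1 + cor)/2)^β` with β = 7, Pearson by
default and Spearman switchable. TOM follows the standard formula with
unit diagonal; a brute-force triple-loop oracle pins the implementation
to 1e-12 in the tests. Module detection clusters `1 − TOM` with average
linkage and applies a *static* cut — a deliberate simplification of the
hybrid dynamic tree cut, preserving the testable contract
(planted-module recovery) — at a fraction of the tallest merge height
(default 0.92). A merge-height *quantile* parameterization degenerates
here: merge heights concentrate near the dendrogram top, so a 0.99
quantile cuts above the noise merges and returns one giant cluster.
After the cut, branches below `min_module_size = 20` are released, and
membership is cleaned by kME: proteins whose correlation with their
module eigengene is below `kme_min = 0.5` go to `ME00`. Without this
cleanup, noise proteins with chance factor correlations (|r| ≈ 0.3–0.4
at 24 samples) attach to branches and cap recovery at ARI ≈ 0.85;
with it the planted-module test recovers ARI ≥ 0.9. Labels `ME01…`
are ordered by decreasing size; `ME00` is reserved for unassigned.

Eigengenes are the first left-singular vector of the standardized
module submatrix (unit norm), sign-oriented to correlate positively with
the module's mean standardized profile; a perfectly balanced module
(mean profile zero) orients against its first protein as the tie-break.
Merging joins the closest eigengene pair while dissimilarity
`1 − cor < 0.25`, recomputing eigengenes each step, which makes the
result independent of label order. Module–trait correlation is Pearson
with `t = r√(n−2)/√(1−r²)`; zero-variance traits give NA with a
warning. Enrichment is upper-tail hypergeometric per gene set with BH
adjustment across sets within a module (the adjustment scope is a
choice fixed here).

The end-to-end pipeline runs the network stage with Spearman adjacency:
imputed entries sit ~1.8 column-SDs below the observed distribution and
behave as extreme outliers under Pearson correlation. `run_wpcna()`
itself keeps Pearson as its default, matching the WGCNA convention.

## Group statistics

Two-way ANOVA uses Type II sums of squares by default (identical to
Type I/III in balanced designs) with Type III under sum contrasts
available for SPSS parity; the multivariate (MANOVA) gate of
SPSS-style workflows is replaced by univariate ANOVAs per outcome, since
only univariate F values are reported downstream and the gate adds no
testable output. Tukey HSD comes from the studentized range; the
repeated-measures stress effect is `metric ~ phase + Error(animal)`,
which reduces exactly to the squared paired t for two phases (asserted
in the tests); Spearman p-values use the t approximation with
average-rank ties. No outlier removal is performed by default.

## Pipeline, seeds and problem sizes

`run_pipeline()` sequences the four arms from one configuration with
explicit defaults (α 0.05, z cutoff 1, width 0.3, downshift 1.8, β 7,
minimum module size 20, merge cut 0.25) and derives per-stage seeds from
the global seed through a fixed affine map, so stages can be rerun in
isolation. Every number in the JSON summary is recomputable from the
stage TSVs. The demo configuration simulates 12 knockout and 12
wild-type animals per sex and a 3-group × 5–6-sample LFQ design with
planted modules and reversals.

The test suite and acceptance script run at desk scale by choice:
2,000–5,000-protein matrices, 6–9-day records, 10–20 replicate
simulations where a rate or a recall is being estimated. These sizes
estimate each contract's quantity with comfortable margin relative to
its tolerance while keeping the whole suite in the tens of seconds.

## Known limitations

* The activity model's entrainment is instantaneous at lights-off and
  its re-entrainment linear; transients, masking rebound and
  aftereffects are not modeled.
* MNAR imputation attenuates true effects for doubly censored proteins;
  recall of planted reversals is bounded well below 1 under realistic
  censoring, and module recovery on imputed matrices is partial —
  released-to-ME00 members, not misassignment, dominate the loss.
* The static-cut module detector is not the hybrid dynamic tree cut; on
  real data with nested or close modules the published module count
  would not be reproduced, and no claim is made that it should be.
* Hypergeometric enrichment takes user-supplied GMT collections; no
  ontology is bundled or fetched.
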