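---
title: "Methods: integrative urine biosensing for aggressive prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative urine biosensing for aggressive prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uroscent` implements a four-armed analysis of urine-based detection of
high-grade (Gleason 9) prostate cancer: scoring of double-blind canine
scent-detection trials, GC-MS volatilome statistics, urinary 16S
microbiota processing, and a neural-network emulator of canine
diagnoses trained on total-ion chromatograms. A synthetic-data
generator reproduces the statistical structure each arm assumes, so the
whole pipeline can be exercised and validated end to end without access
to patient samples. This vignette records the models, the parameters
that matter, and the numerical choices made where the design was
genuinely open.

## Canine trial scoring

A carousel trial presents one cancer sample among three biopsy-negative
controls per set. The dog sniffs pots in order; indicating the target
ends the set as a true positive, falsely indicating a control replaces
that control with a blank and re-tasks the dog, and a second false call
ends the set. `score_dog()` tallies set-level outcomes: a true positive
is a set whose final pass indicated the target, every control
indication counts one false positive, and 3 controls are presented per
set unless a record carries explicit count overrides (some published
tallies are recorded counts that cannot be re-derived mechanically from
the per-run table, so the JSON schema accepts
`overrides: {false_positives, controls_presented}`).

Chance statistics use two elementary null models: the probability of
picking the one target out of `n` pots `k` times in a row,
`(1/n)^k`, and the binomial tail probability of at most `m` missed sets
out of `k` when each set is a random yes/no decision. For the latter
the per-set null success probability defaults to 1/2 (a yes/no
decision), which reproduces the printed tail probability 0.035 for at
most one miss in eight balanced-reward sets; it is a configurable
argument, not a constant.

## GC-MS volatilome statistics

Compounds observed in fewer than 3% of samples are removed
(`prevalence_filter()`, ceiling rule on the count). Each surviving
compound is screened with the two-sided Wilcoxon rank-sum test
(`rank_sum_test()`), chosen because zero inflation rules out parametric
location tests; zeros are treated as true zeros, never as missing. The
test uses exact enumeration for combined samples of 10 or fewer without
ties and the continuity- and tie-corrected normal approximation
otherwise. At these sample sizes the exact null distribution is
discrete; no normal approximation can track it better than about 0.09
uniformly, which is the bound the property tests assert. Screening
keeps compounds at a deliberately liberal p < 0.2 for model building
and flags p < 0.05 separately for display; no multiplicity correction
is applied by default (a Benjamini-Hochberg option exists).

The sparse model is a two-stage procedure: sure-independence screening
ranks compounds by the absolute coefficient of a univariate logistic
fit on the standardized `log1p` abundance and keeps at most
`n / log(n)`; then a SCAD-penalized logistic regression is solved by
local-linear-approximation (LLA) iterations, each a weighted lasso with
penalty factors equal to the SCAD derivative at the current
coefficients (SCAD `a = 3.7`; MCP and plain lasso are options). The
first LLA pass over a whole tuning-parameter grid is one lasso path
fit, after which each grid point gets its reweighted refinements. The
tuning parameter is chosen by stratified k-fold cross-validated
deviance (10 folds by default); the deviance minimizer is the default
rule, with the one-standard-error rule available for users preferring
sparser fits.

The final model on the selected panel is a Firth bias-reduced logistic
fit: Newton iterations on the Jeffreys-penalized likelihood
`l(b) + 0.5 log det I(b)` with hat-value-adjusted scores, step-halving
that accepts a step only if it improves the penalized likelihood or
shrinks the penalized score (the score criterion prevents oscillation
on the likelihood plateau near boundary solutions), convergence at a
penalized-score norm below 1e-8, and a ridge-stabilized fallback for
singular information. Firth estimates stay finite under the (near-)
complete separation that small VOC panels routinely produce; the
intercept-only fit has the closed form `logit((s + 1/2)/(n + 1))`,
verified exhaustively in the tests.

Out-of-sample performance is assessed by jackknife (leave-one-out)
prediction in which *everything* — prevalence filter, rank-sum screen,
SIS ranking, penalized selection, cross-validated tuning, and the Firth
refit — is repeated without the held-out sample. This guards against
the over-optimism that in-sample variable selection induces. Two
details matter for honesty of the resulting ROC:

- Each held-out score is centered on its training fold's class
  prevalence. Without this, folds with no informative features predict
  the training prevalence, which moves opposite to the held-out label
  (leaving out a case lowers the training case fraction) and drives the
  null AUC toward 0 — an artifact, not a property of the data.
- Even centered, leave-one-out with repeated selection can run mildly
  *pessimistic* under the null (features chosen without the held-out
  sample tend to rank it on the wrong side), and a single null AUC at
  n = 60 has sampling SD near 0.1. The calibration tests therefore
  check equivalence of the mean with chance within a 0.1 margin rather
  than exact per-run equality — the method never errs on the
  optimistic side, which is the direction the jackknife exists to
  control.

## Urinary microbiota processing

Contaminant removal runs in three phases, and the removed set is their
union (plus the indicator species themselves):

1. **Negative-control abundance.** A species is flagged when its mean
   relative abundance across the blank extraction controls is at least
   `ratio_threshold` (default 1) times its mean relative abundance
   across true samples *and* it appears in at least
   `min_control_prevalence` controls (default 2). The literature this
   rule descends from states no closed formula, so both knobs are
   exposed and per-species evidence is recorded for audit.
2. **Indicator correlation.** Any non-indicator species whose Spearman
   correlation (mid-ranks, computed on relative abundances across true
   samples only — reagent covariation is an effect across real
   specimens, so blanks are excluded) with any of the 10 indicator
   contaminant species strictly exceeds 0.30 is flagged. Constant
   species have undefined correlation and are never flagged.
3. **Genus blacklist.** Exact genus-token membership in a list of
   common reagent-contaminant genera. The packaged default list is a
   stand-in following the well-known kit-contaminant genera; studies
   should supply their own.

Rarefaction draws exactly 2,700 reads per sample without replacement
(via `vegan::rrarefy`); samples below depth are dropped and reported,
never resampled with replacement. Beta diversity uses Bray-Curtis
(`vegan::vegdist`) and unweighted UniFrac (`picante::unifrac`,
presence/absence branch fractions; unrooted trees are midpoint-rooted
with a warning), with principal coordinates via `ape::pcoa` (Gower
double-centering; negative eigenvalues reported, their axes omitted).
Differential abundance reuses the same rank-sum test on relative
abundances, reporting mean percent abundance over the species-positive
samples per group. The whole-profile view is hierarchical clustering of
Euclidean distances on log-transformed relative abundances
(pseudocount 1e-6) of the top 25 species, summarized by the mean
silhouette width of the cancer/control labels: values near zero mean
the full community profile does not separate the groups even when
individual species do — the qualitative pattern this pipeline is
designed to exhibit.

## Neural emulator of canine diagnoses

Chromatograms are cut to the 10-14 min retention-time window — 205
points on the default grid (spacing 4/205 min) — and normalized to
[0, 1] by the single global minimum and maximum of the training matrix
(not per-feature), stored for identical application at inference. The
classifier is a fully connected 205-32-2 sigmoid MLP whose outputs
represent canine-indicated positive and negative alerts (it emulates
the dog's calls, not biopsy truth), trained by online backpropagation:
learning rate 0.1, momentum 0.03, Fisher-Yates reshuffling of exemplar
order every epoch, targets encoded at 0.1/0.9 (the scale margin, which
keeps sigmoid targets reachable), stopping at a root-mean-square output
error of 0.15. The 32-unit hidden layer is deliberately small — the aim
is interpretability, not benchmark accuracy. Weights initialize
uniformly in [-0.5, 0.5] from the seed; training halts with a
diagnostic if the RMS rises for 10 consecutive epochs.

**Skeletonization** works backward from a chosen output node, keeping
the `keep_per_layer` largest-magnitude weights into it and, for each
retained hidden node, the largest incoming weights in turn. An input's
saliency is the maximum over retained paths of the product of absolute
weights; its sign of influence is the product of weight signs on that
path. The pruning criterion is |weight|; with no pruning the ranking
provably equals the exhaustive all-paths computation, which the tests
assert.

**Auto-associative filtering** trains a 205-32-205 bottleneck MLP to
reconstruct canine-negative-indicated spectra only. Applied to a new
spectrum it returns the nearest negative-like spectrum it knows, and
the residual (input minus reconstruction) exposes anomalies: excess
peaks where the input holds features no negative spectrum has, and
depletion troughs where an expected negative feature is missing. The
anomaly threshold is per grid point: 1.25 times the training set's
absolute-residual envelope at that retention time, with a 3-point
minimum region width. Residuals concentrate at imperfectly memorized
peak apexes and are heavy-tailed, so any single global multiple of a
location-free scale (a median, say) either alarms on in-distribution
peak misfit or misses depletions; the local envelope sits just above
everything the training set can produce at each point while remaining
far below genuinely novel features. The concordance report then
cross-tabulates retention-time regions flagged by skeletonization, by
the difference spectra, or by both.

## The synthetic-data generator

The generator's defaults emulate the study conditions: 12 cancer and 38
biopsy-negative urine samples with six blank extraction controls; dogs
at 71.4% per-presentation sensitivity and 76.2% specificity; 1,157
compounds with 7 differential; 150 species with 30 reagent
contaminants tracked by 10 indicators; rarefiable library sizes around
30,000 reads. Choices the sources leave open, decided once:

- **VOC zeros by detection-limit censoring.** Each compound's latent
  abundance is log-normal (sdlog 1); values below the compound's
  `zero_inflation` quantile of the baseline distribution are recorded
  as zero. Undisturbed compounds are zero with exactly the nominal
  rate, while differential compounds shift their zero rate together
  with their mean — the behaviour of real peaks near the limit of
  detection. An independent Bernoulli zero layer was rejected because
  it decouples presence from abundance and makes the planted signal
  unrecoverable by any classifier, contradicting what the generator
  must emulate.
- **Differential effect size** is a log-mean shift of 2 (alternating
  elevated/reduced in cancer), a calibration choice, not an estimate
  of any real effect.
- **Chromatograms** are a constant baseline (50 units) plus Gaussian
  peaks (sigma 0.03 min) with per-peak log-normal amplitude variation
  at sdlog 0.25 (~25% CV, between-subject scale) and additive Gaussian
  noise with SD 10 (signal-to-noise roughly 40-160 on major peaks).
  The planted case-specific signals sit at the retention times the
  downstream extraction must recover: excesses at 13.177 and
  13.563 min, depletions (control-only peaks) at 12.698, 10.561,
  10.899 and 11.473 min. Amplitude variation much above 25% CV makes a
  low-amplitude control indistinguishable from a depleted case, which
  would defeat depletion recovery by construction rather than by
  method failure.
- **Taxa counts** are negative-binomial around a log-normal community
  profile; a latent per-sample reagent factor (lognormal, sdlog 1)
  drives all contaminants jointly, so contaminants correlate with the
  indicators across true samples and dominate the low-biomass blanks,
  where biological species appear only as sparse Poisson noise.
  True-sample totals are topped up to the rarefaction depth so no true
  sample drops by construction (dropped-sample behaviour is tested with
  explicitly shallow samples).
- **Trial simulation** draws one Bernoulli per pot presentation;
  blanks are never indicated. With re-runs after no-indication passes,
  the set-level detection rate exceeds the per-presentation
  sensitivity, so parameter recovery is assessed on the
  per-presentation ground-truth log the simulator returns.

What the generator does *not* emulate: retention-time drift and peak
shape changes, co-eluting compounds, batch effects in either assay,
taxonomic misassignment, dogs' learning dynamics across reward-scheme
changes, and any real association between the three assays beyond the
shared cohort labels. Passing tests on this generator demonstrate that
each method recovers the structure it assumes; they are not evidence
about real urine.

## Problem sizes and numerical settings

Test and acceptance experiments use sizes chosen to exercise the
methods well inside a routine laptop budget: jackknife calibration runs
20 null data sets of n = 60 with a 12-point tuning grid and 5-fold
inner cross-validation; the planted-signal jackknife uses the full
study-sized design (50 samples, 1,157 compounds); neural-network
planted-peak recovery uses 10 seeds of 60 chromatograms each. Key
numerical settings: Firth convergence at penalized-score norm 1e-8
(iteration cap 200); LLA refinements capped at 2 after the lasso-path
initialization with coefficient-change tolerance 1e-6; rank-sum
exactness cutoff at combined n = 10; anomaly regions need 3 consecutive
points beyond the local threshold; all generators and fold assignments
are pure functions of an integer seed.
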