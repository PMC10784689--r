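---
title: "Measuring a shared intuitive-physics ability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring a shared intuitive-physics ability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physbattery)
```

physbattery analyzes trial-level task batteries designed to measure stable
individual differences in intuitive physics — people's capacity to predict
physical outcomes (which way a tower topples, where a hidden puck reappears,
which ball is heavier) from brief perceptual input. The central scientific
questions it addresses are psychometric: do such tasks measure anything
stable about a person (reliability)? Is there a single ability common to
scenarios as different as judging tower stability and inferring mass from a
collision (a general factor)? And is that ability distinct from neighboring
faculties such as spatial reasoning and working memory (residualization)?

This vignette explains each model and procedure, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Data model

The unit of observation is one subject's binary correctness on one trial of
one task, in long format (`subject_id`, `task_id`, `trial_id`, `correct`,
`missing`). Missingness is a separate boolean, never `NA` smuggled into
`correct`, so files round-trip unambiguously. Accuracy is the proportion
correct over *non-missing* trials; a subject with no observed trials in a
task gets an undefined (`NaN`) cell that propagates as pairwise deletion
into every downstream correlation, rather than a silent zero. Each task
carries a chance level (0.5 for all two-alternative tasks in the reference
battery), which anchors the exclusion rules.

Exclusion rules mirror standard online-battery quality control: subjects
below chance on two or more tasks are removed entirely (bot/effort filter;
strictly-below by default, configurable because "below chance" could
arguably include exact chance); subjects failing working-memory catch
criteria (symmetry accuracy under 85%, or zero recalled spans) are removed
entirely; subjects giving one identical response across all trials are
removed; and a subject missing more than 25% of one task's trials is
dropped from *that task only*, keeping their data everywhere else. The
per-task rule runs first so that the subject-level rules always see the
retained data, which makes `apply_exclusions()` idempotent.

## Split-half reliability

A task is reliable when subjects' accuracy on one random half of its trials
correlates, across subjects, with their accuracy on the other half. One
split draws a balanced partition of every task's trials (the same joint
split serves all tasks in an iteration, which the combined measure and the
factor validation require); accuracies are correlated and Fisher-z
transformed, `z = atanh(r)`, the variance-stabilizing scale on which
correlations can be averaged and compared linearly. Because a random split
can be unrepresentative, the procedure is iterated (10,000 times in the
reference analyses; tests and examples use smaller counts, stated where
used) and the mean z reported, with the 2.5th/97.5th percentiles of the
iterated distribution as the interval. The combined battery measure
averages the per-task half accuracies across tasks before correlating.

Since each half contains only half the trials, this estimates the
reliability of a *half-length* test; no Spearman–Brown correction is
applied in the reported values (it is used only internally when comparing
recovered factor loadings to generative ones, where full-length reliability
is the right attenuation scale).

At `|r| = 1` — which legitimately happens on small deterministic fixtures —
r is clamped to ±(1 − 1e−12) before `atanh` and the result flagged, so
infinities never propagate silently.

**Permutation null.** Significance comes from re-running split iterations
with the subject correspondence between halves shuffled, collecting the
resulting z values as the null distribution, and locating the observed mean
z in it with the add-one estimator `p = (1 + #{null ≥ obs})/(1 + n_perm)`,
one-sided because positive association is the hypothesis. A calibration
caveat discovered while testing: comparing a *mean over splits* against
*single-split* null draws makes the test conservative under a global null
(the mean has smaller sampling variance than any single draw), so its
type-I rate at α = 0.05 sits near 1–2% rather than 5% on batteries with no
subject-level signal. The construction is kept because it is the field's
standard form and errs in the safe direction; the obvious "statistic-matched"
alternative (permuting once and averaging over the same splits) turns out to
over-reject, because the identity pairing carries variance from the
complementary-half coupling (a subject's two half accuracies are
anticorrelated given their fixed trial total) that no pairing permutation
can reproduce.

Degenerate iterations — a half with zero variance across subjects — are
flagged and excluded from the mean with counts reported; a run where more
than half the iterations degenerate errors instead of returning a number.

## Between-task correlations and difference tests

Pairwise task correlations use the full accuracy table with pairwise
deletion, and 95% intervals from resampling subjects with replacement
(percentile form; BCa is out of scope). The resampling unit for these
off-diagonal cells is the subject; within-task (diagonal) entries belong to
the split-half machinery. The difference between two dependent correlations
is tested by bootstrapping subjects, recomputing both correlations per
replicate, and taking the two-tailed add-one p on the Δz distribution;
degenerate replicates are redrawn with a 10% cap.

## Single-factor model and cross-validated validation

A one-factor model on the task-accuracy correlation matrix asks whether one
latent ability can account for the shared variance among tasks. Extraction
is iterated principal-axis factoring: starting communalities are squared
multiple correlations, the reduced matrix is eigendecomposed, the first
factor retained, and communalities updated to convergence (tolerance 1e−6).
Two numerical choices matter:

- **Iteration cap 50.** When the data contain no common variance the
  one-factor model is unidentified — any single-variable communality
  reproduces the off-diagonals equally well — and the communality update
  drifts upward indefinitely (the top eigenvalue of the reduced matrix
  always exceeds the largest communality). Long iteration runs therefore
  manufacture a spurious single-task factor out of noise. A modest cap,
  the convention among mature factor-analysis implementations, keeps the
  minimal solution; genuine factor structures converge in well under 50
  iterations. Non-convergence is reported and warned, never hidden.
- **Heywood clamping.** Communalities above 1, which small-sample runs
  occasionally produce, are clamped to 0.9999 and flagged.

Maximum-likelihood extraction (`method = "ml"`, via `stats::factanal`) is
available as an alternative and serves as an independent cross-check in the
test suite. Factor scores use the regression (Thurstone) method — needed
because the validation step requires subject-level scores — and the sign is
oriented so the loading sum is nonnegative. Whether accuracies are
standardized before fitting is moot: the model is fit to a correlation
matrix.

**Validation on left-out halves.** Per iteration, the factor is fit to the
half-A accuracies and its scores are correlated with each task's half-B
accuracy. The per-task mean z measures how much of each task's individual
variation the common factor captures in *independent* data. The
`ratio_to_reliability` statistic divides the factor R² (`tanh(mean z)²`) by
the task's own split-half R², computed with the identical split-seed
stream so split noise cancels: a ratio near 1 means the factor captures
essentially all the variance the task's own noise ceiling allows; a ratio
near 0 exposes a reliable but task-specific component.

The ratio mixes two ingredients, which matters when interpreting it. The
factor score is far less noisy than any single half (it averages all
tasks), so its validation correlation is attenuated by one noisy half
only, while the split-half correlation is attenuated by two. For a battery
with equal loadings λ and half-noise-to-stable-variance ratio ν per task,
the expected ratio grows with ν: a long, highly reliable task (small ν)
shows a ratio well below 1 whenever task-specific stable variance exists,
while a short noisy task can show a ratio at or above 1 even though the
factor misses its specific variance. Ratios are therefore comparable
*across* tasks of similar length, and against 1 only for tasks whose
stable variance is essentially all shared or whose trial noise is
substantial.

An interpretive caveat verified in the tests: because validation targets
tasks that are included in the factor fit, *any* data-driven weighting of
individually reliable tasks predicts their own left-out halves. A battery
of reliable but mutually uncorrelated tasks therefore still yields positive
validation z — the permutation test correctly detects stable aligned
subject variance, not the existence of a common factor per se. The ratio
against each task's reliability ceiling, and the between-task correlations,
carry that discriminating information. The permutation p is calibrated when
no stable individual differences of any kind exist.

## Covariate residualization

To ask whether battery performance is *just* spatial ability or working
memory in disguise, each half's combined score is regressed (OLS, intercept
always included, covariates standardized internally so results are
invariant to affine rescaling) on the covariate scores, and the two
residual vectors are correlated across subjects. Reliable residual
correlation means the battery carries stable variance the covariates cannot
explain. The permutation null shuffles the split-half alignment as in the
reliability engine. A cross-measure variant (`residualized_correlation()`)
partials the same covariates out of two different score vectors — e.g. a
compressed battery score and a novel task — and correlates the residuals.

A limitation verified by simulation: residualization is *linear*. When a
covariate measures a latent exactly but the battery expresses that latent
nonlinearly (accuracy is a guessing-floor logistic of ability, so it always
does to some degree), OLS removes only the linear component and the stable
curvature survives into the residuals. With hundreds of trials the binomial
noise is small enough that this leaves a modest but clearly reliable
residual correlation (mean z ≈ 0.1 in the ceiling simulation of the test
suite) even though the covariate carries *all* of the latent information.
Reliable residual variance is therefore evidence that the covariates do not
linearly explain the battery — a weaker statement than full independence.

## Battery compression (short-form construction)

The compressed battery selects `k` trials per task (default 10) by pure
random search: each draw is scored by correlating subjects' mean accuracy
on the drawn trials with their full-battery score, and the best draw after
`n_iter` iterations wins (ties broken by first-seen order; the running
argmax is nondecreasing by construction and asserted in tests). Choices
made where the procedure was open:

- **Full-battery score**: mean of per-task means by default (each task
  weighted equally, consistent with the combined reliability measure);
  a grand mean over trials (tasks weighted by length) is a flag away.
- **Part-whole overlap**: the subset's trials are contained in the full
  battery, so even signal-free data yield a positive subset-to-total
  correlation. The default reproduces that (documented, and demonstrated
  on null batteries in the tests); `exclude_selected = TRUE` scores the
  full battery on unselected trials only for an overlap-free diagnostic.
- **Cross-validation**: the selection correlation is an optimum over many
  draws and overfits accordingly, so subjects are split once (default
  50% holdout) into a training set used for selection and a validation
  set on which the winner is re-scored. `holdout_fraction = 0` reproduces
  selection and evaluation on the same subjects; both numbers are
  reported, neither conflated with the other.

An exhaustive mode enumerates every candidate subset on small instances and
is checked against brute-force enumeration in the tests.

## The synthetic battery generator

Because the analyses are validated by parameter recovery rather than on any
particular human dataset, the generator produces trial-level batteries with
exactly the latent structure the analyses assume. Per trial,

P(correct) = c_t + (1 − c_t) · logistic(a_t (λ_t θ_i + √(1 − λ_t²) s_it − b_j)),

the standard guessing-floor (3PL-style) form with a logistic link (probit
would differ negligibly; logistic keeps closed-form checks easy): θ is the
shared ability, s_it task-specific ability (both unit normal), b_j item
difficulties, a_t discrimination, c_t the two-alternative chance floor. A
separate spatial latent correlates ρ with θ (Cholesky mixing) and drives
covariate scores `loading_on_general·θ + loading_on_spatial·spatial +
noise`, standardized.

Defaults, chosen once as a realistic mid-range battery: the five-task
roster with 48/64/240/40/58 trials and c = 0.5 throughout; λ = 0.6 for all
tasks (between-task accuracy correlations around 0.2–0.35, the range
typical of individual-differences batteries); a = 1.5 and σ_b = 1, which
place accuracies roughly between 0.55 and 0.95 — near chance for the
weakest subjects, near ceiling for the strongest; ρ = 0.4; missingness
completely at random at 2% (video-load failures are plausibly ignorable;
informative missingness is out of scope). The three default covariates
(mental rotation, working memory, face memory analogues) load 0.30/0.50,
0.25/0.35, 0.15/0.10 on the general/spatial latents with noise SDs 0.70,
0.80, 0.95. No empirical item-difficulty spread is asserted anywhere;
σ_b is exposed in the config.

Seeding is counter-based: every component (latents, each task's
difficulties and responses, each covariate, the missingness mask) draws
under its own subseed derived from the master seed, so adding a sixth task
cannot perturb the first five tasks' data — a property the tests assert
byte-for-byte.

Design-enumeration helpers reproduce the factorial structure of each task's
stimulus set (6 block counts × 8 towers = 48; 30 ordered weight pairs × 2
filmings × 4 presentations = 240; 14 objects × 4 angles × 4 materials =
224; and so on), and the ramp-style generator balances positive/negative
ground truth 50/50 with the outcome unconfounded with any factorial cell.

What the generator deliberately does **not** emulate: response times,
learning or fatigue across trials, informative missingness, item-level
misfit (e.g. the mass-judgment bias that gives collision tasks a reliable
task-specific component in real data is representable only abstractly, as
a low λ with high reliability), and any dependence between trials beyond
the latent abilities. Passing parameter-recovery tests therefore shows the
estimators are correct under the stated model, not that real batteries
satisfy that model.

## Problem sizes and determinism

Reference analyses iterate 10,000 times; the package's tests and the
bundled acceptance script use 15–200 iterations per engine and batteries of
50–500 subjects, sizes at which every property they assert is already
stable. All engines take explicit integer seeds (no wall-clock seeding),
derive per-iteration subseeds from them, and restore global RNG state on
exit; identical configs produce byte-identical reports, which the pipeline
tests verify.

## Known limitations

- The split-half permutation test is conservative under a global null (see
  above); its p-values are trustworthy evidence *for* reliability, not a
  calibrated type-I instrument at exactly α.
- With five observed variables a one-factor solution is near the edge of
  identifiability; small batteries produce occasional Heywood cases and
  non-convergence, which are flagged rather than repaired silently.
- The factor-validation z inherits a part-whole structure (tasks validate
  against their own left-out halves); interpret it jointly with
  `ratio_to_reliability` and the between-task correlations.
- Residualization is plain OLS on observed covariate scores; measurement
  error in covariates leaves attenuation-shaped residual confounding,
  nonlinear latent-to-score mappings leave reliable curvature in the
  residuals (see above), and no SEM/latent-variable correction is
  attempted.
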