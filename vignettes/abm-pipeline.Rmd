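---
title: "Methods: the dot-probe ABM analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dot-probe ABM analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmprobe)
```

## The task and the quantity of interest

A dot-probe trial presents a vertically arranged pair of faces of the same
person — one neutral, one disgusted — for 500 ms after a 500 ms fixation
cross, then replaces one face with a probe letter (E or F) that the
participant identifies as fast as possible. When the probe appears at the
threat face's location the trial is *congruent*; at the neutral location,
*incongruent*. The attentional bias index is

$$\mathrm{bias} = \overline{RT}_{\text{incongruent}} - \overline{RT}_{\text{congruent}},$$

in milliseconds: positive values mean attention was drawn to the threat
face (probes there were answered faster). Training schedules either mirror
the measurement task (mock) or apply the modification contingency — the
probe always replaces the neutral face — intended to push attention away
from threat. Neutral–neutral filler pairs (20% of trials by default)
conceal the contingency and carry no congruency.

`generate_measurement_schedule()` and `generate_training_schedule()`
enforce counterbalancing *exactly* within each block — equal congruent and
incongruent counts, threat position balanced top/bottom within each
congruency, probe letters balanced across the block, filler probe sides
balanced — and then shuffle trial order under the caller's seed. Exact
rather than stochastic balance was an open choice; we chose exactness
because it makes the validator (`validate_schedule()`) a crisp structural
contract and never costs anything statistically. Counts that cannot balance
(scored trials not divisible by 4 for balanced variants, or by 2 under the
contingency) raise an error naming the violated constraint rather than
silently approximating.

## Cleaning and exclusion

Measurement-phase responses are cleaned in three ordered stages
(`filter_trials()`): (1) error trials are dropped; (2) responses faster
than 200 ms or slower than 2000 ms are dropped (strict bounds); (3) within
each trial type separately, responses more than 2 sample standard
deviations from that type's mean — computed on the survivors of stages 1–2
— are dropped in a single pass. The stage order and the single pass are
deliberate: a per-person mean and SD are only meaningful once impossible
responses are out, and iterating the trim would make the retained set
depend on a fixed-point process the rule never describes. The SD uses the
n − 1 denominator. Discard fractions are reported against the *input*
count of each type, and a participant loses analysability when any of the
four (assessment × type) fractions strictly exceeds 20% — "more than" is
read as a strict inequality, so exactly 20% survives.

Filler trials never enter per-type statistics or the bias index; training
trials are never cleaned or analysed. A trial type left with fewer than two
in-bounds survivors skips the SD stage with a warning record instead of
producing an undefined trim.

## Reliability

`splithalf_bias_reliability()` estimates internal consistency of the bias
index by random split-halves: per split, each participant's retained
congruent trials are partitioned into two near-equal halves, likewise the
incongruent trials (stratifying by type is required — otherwise a half may
lack one type and have no bias index); the Pearson correlation of the two
half-indices across participants is Spearman–Brown corrected,
$r' = 2r/(1+r)$, and the mean over 5000 splits is reported. Correcting
each split and then averaging is the default (the common permutation
split-half practice); `order = "average-first"` gives the other reading.
Odd trial counts assign the surplus trial to a random half per split.
Negative split correlations are corrected as-is — the formula is defined on
(−1, 1] — because truncation at zero would bias the average upward exactly
when reliability is genuinely poor, the situation this estimator exists to
reveal. The splitting core is vectorised (one ranking pass per participant
across all splits), so 5000 splits over ~100 participants run in seconds.

`cronbach_alpha()` implements the standard closed form
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$ with sample
variances, dropping and reporting incomplete rows.

## Reliable and clinically significant change

`jt_params()` turns a baseline sample and a reliability estimate into the
Jacobson–Truax constants: $SE_M = SD\sqrt{1-r}$,
$S_{diff} = \sqrt{2\,SE_M^2}$, the reliable-change threshold
$1.96\,S_{diff}$, and (criterion A) the recovery cutoff
$\text{mean} - 1.96\,SD$ for instruments where lower is better. Two
boundary conventions follow the wording of the definitions: reliable change
is *inclusive* at the threshold ("at least 1.96 times"), while the cutoff
comparison is *strict* ("lower than"). The cutoff is rounded to the
instrument's integer scale for classification by default — matching how
such cutoffs are reported and applied — with the raw value retained and a
flag (`use_rounded_cutoff = FALSE`) for the unrounded convention, since
which of the two an analyst intends is genuinely ambiguous.

The five categories — recovered, non-reliably recovered, improved,
unchanged, deteriorated — partition the (baseline, follow-up) plane;
`classify_cohort()` applies them at every available follow-up against
baseline, skipping missing timepoints. For the bias index only the
reliable-change half of the machinery applies (there is no meaningful
clinical cutoff for a difference-of-means RT score), via `rci_classify()`.
Change is always follow-up minus baseline, and improvement is negative for
both the anxiety total and the bias index.

## Inference

`rm_anova_bias()` performs the 2 (pre/post, within) × 4 (group, between)
mixed-design ANOVA through base `aov()` with a participant error stratum;
the module owns the completeness filtering (complete pre/post pairs,
exclusions honoured) and flags numerically degenerate strata (zero residual
variation) instead of reporting a meaningless F.

`fit_lmm_set()` fits a ladder of linear mixed-effects models for the
longitudinal questionnaire total via `nlme::lme`: from intercept-only to
the full three-way interaction of time (coded 0, 1, 2, 3 for the four
assessments — equal steps, not calendar spacing), training condition
(mock = 0, active = 1) and stimulus dimensionality (2D = 0, 3D = 1), each
with a random intercept and random time slope per participant. Estimation
is maximum likelihood, not REML, so AIC ordering and likelihood-ratio tests
across fixed-effect structures are valid. Fixed-effect t tests use the
containment degrees of freedom (within-participant terms against
$N_{obs}-N_{subj}-p_{within}$, between terms against $N_{subj}-p_{between}-1$).
Participants with missing follow-ups contribute their available rows;
nothing is imputed. The exact intermediate rungs of the ladder are an open
design point; the default set (`default_lmm_ladder()`) spans every additive
and interactive combination of the three factors and is replaceable by any
named list of formulas. Convergence failures are recorded per model without
aborting the set. `nlminb` is tried first and `optim` as a fallback.

## The synthetic cohort

`simulate_cohort()` generates a complete four-arm study: blocked allocation
(blocks of 4, 8 or 12 session slots, each containing the four groups
equally often), a 100-trial pre measurement, two 190-trial training blocks
per the group's variant, a 100-trial post measurement, and questionnaire
records at four timepoints.

Reaction times are ex-Gaussian — Gaussian($\mu \pm \delta/2$, $\sigma$)
plus an exponential tail $\tau$ — the standard generative model for RT
data; the congruency shift of $\pm\delta/2$ makes the *expected* bias index
equal the participant's true effect $\delta$. Contaminants exercise every
cleaning rule: fast guesses Uniform(50, 200) ms, attentional lapses
Uniform(2000, 4000) ms, and a per-trial error probability. Default
population values ($\mu$ = 450 ± 50, $\sigma$ = 50 ± 10, $\tau$ = 100 ± 25 ms,
$\delta$ = 0 ± 10 ms, 4% errors, 2% guesses, 2% lapses) are ordinary
values for speeded two-choice tasks; the reference trial reports no
trial-level distributions, so these are free configuration, not estimates
of that study.

Questionnaire totals follow a linear trajectory (baseline 69.7 ± 19.3
points, slope −5.9 ± 4 points per assessment, residual SD 8), rounded and
clipped to the 0–144 scale; the 48 item ratings (0–3) are generated by
randomized allocation of the total, so items sum to the total exactly —
sufficient for Cronbach's alpha, which is the only consumer of item-level
data. Dropout is missing-completely-at-random with probabilities 0.06
(1-week) and 0.11 (3-months). An optional `first_trial_loss` flag emulates
a recording fault that leaves four 99-trial pre assessments, proving the
pipeline tolerant of short assessments.

What the generator does *not* emulate: practice and fatigue drifts within a
session, sequential trial dependencies, stimulus-identity effects,
non-linear symptom trajectories, and informative dropout. Passing tests
therefore certify the pipeline's arithmetic and its statistical calibration
under a well-behaved generative model, not robustness to those
real-data features.

Because the totals are clipped at the scale floor, steep negative
trajectories from low baselines are attenuated; the fitted mean time slope
on a simulated cohort therefore sits slightly above the generating mean
slope. This is a property of the bounded scale, not an estimator defect,
and disappears when intercepts sit far from the bounds.

## Randomness and numerics

All randomness descends from one seed: `derive_seeds()` draws per-stage
sub-seeds, so changing, say, the number of reliability splits leaves the
cohort unchanged. Seeded helpers restore the caller's RNG state. Two
numerical floors matter: the ANOVA flags residual mean squares below
$10^{-12}$ of the data scale as degenerate, and exactly-zero residual
variance is outside what a mixed model can fit — the noiseless limit is
exercised with residual noise at $10^{-6}$ and recovers the generating
slope to five decimals.

Test problem sizes are chosen to keep the full suite fast while preserving
the statistical meaning of each check: structural tests use 8–16
participant cohorts; calibration checks use 500 replicates of 40–96
participant designs; parameter-recovery checks use 200 replicates near the
reference study's scale (~50–100 participants), where maximum-likelihood
variance-component bias is negligible.

## Limitations

The split-half estimate is a property of a particular assessment length
and cleaning outcome; it is not test–retest reliability. Criterion-A
recovery uses only the dysfunctional-sample cutoff (criterion A); the
normative-population cutoffs require data this pipeline does not model.
Group-level baseline summaries recombined with `pooled_moments()` carry the
rounding of the published table — constants rebuilt from them (notably the
bias-index $S_{diff}$) agree with values computed from raw data only to
that rounding.
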