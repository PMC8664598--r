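---
title: "Methods: attention-disengagement scoring, questionnaire domains, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-disengagement scoring, questionnaire domains, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Signaled night awakening — a nighttime awakening the infant signals (for
example by crying) and that requires parental assistance — is one of the
most common sleep concerns in infancy. `overlapgaze` implements the
computational pipeline used to ask whether frequent signaled night
awakening is associated with two aspects of early social development:

1. **Social information processing**, measured as attention disengagement
   from emotional faces in the Overlap task at 8 and 24 months of age; and
2. **Socio-emotional behavior**, measured by the parent-rated BITSEA
   questionnaire at 24 months.

Children are grouped by parent-reported awakening counts: the *waking*
group (three or more signaled awakenings per night) and the *nonwaking*
group (at most one); children with exactly two awakenings are excluded so
that the groups are distinct.

Because infant gaze and questionnaire data cannot be redistributed, the
package pairs the analysis code with a first-class synthetic cohort
generator whose defaults encode the study conditions, so every stage can be
exercised and tested end to end.

# The Overlap task and the dwell-time index

Each trial shows a central face (happy, fearful, neutral with eyes open, or
neutral with eyes closed) alone for 1000 ms; a lateral distractor then
appears for 3000 ms while the face stays visible. Across a session there
are 24 trials, 6 per condition, in a randomized order constrained so that
no emotion repeats more than 4 times in a row and the distractor side
repeats at most 3 times. The face subtends 15.8° × 11.4°, the distractor
15.8° × 4.0°, and the two are separated by 13.6°.

The disengagement latency $x_i$ of trial $i$ is the last time point at
which gaze is inside the central face region before a saccade that lands in
the distractor region, measured from distractor onset. Latencies are
converted to the **normalized dwell-time index**

$$\text{index}(x) \;=\; 1 - \frac{1000 - x}{840}
  \;=\; \frac{x - 160}{840}, \qquad x \in [160, 1000],$$

so the shortest acceptable latency (160 ms) scores 0 and a trial without a
saccade by the 1000-ms window end ("timeout") scores 1. The condition
score is the mean index over the $n$ scorable trials of that condition.
Timeout trials count as scorable with index 1 — the formula folds the
absence of a saccade into the top of the scale — and they therefore also
count toward the inclusion rule (at least 2 scorable trials in every
condition), which the index definition makes the natural reading.

## Validity rules by age

Two measurement instruments are modeled as two *age modes*:

* **`infant8`** — manual frame-by-frame video coding at 25 fps. Sample
  times are floored to the 40-ms frame grid before scoring
  (`frame_quantize()`), the anticipatory threshold is 160 ms, and trials
  with excessive movement are rejected. "Excessive movement" has no
  published quantitative definition; the package implements it as a
  configurable ceiling (default 2) on the number of central-region exits
  before distractor onset and flags this as a package convention.
* **`toddler24`** — automated coding of 300-Hz eye-tracking coordinates.
  The anticipatory threshold is 150 ms; runs of missing samples up to
  200 ms are linearly interpolated while longer gaps reject the trial;
  a trial also requires at least 70% of the pre-disengagement time on the
  face, and a saccade that occurs inside a stretch of missing data is
  rejected.

Both modes reject trials without central fixation at trial start or at
distractor onset, and saccades that do not land in the distractor region
("wrong direction"; landing must register within 200 ms of leaving the
face, a directedness convention made explicit here).

Latencies in [150, 160) ms are admissible at 24 months but fall below the
160-ms floor of the printed normalization; the package keeps the printed
constants (160/840) and clamps the index at 0 rather than rescaling the
normalization to the 150-ms floor, which is the literal reading of the
published formula.

# BITSEA domain scoring

The BITSEA has 42 items rated 0/1/2, of which 31 measure socio-emotional
problems and 11 measure competence. The analysis domains are
internalizing, externalizing, dysregulation, and competence, scored as
plain item sums; `dysregulation_no_sleep` removes the two sleep items
("Wakes up at night and needs help to fall asleep again", "Has trouble
falling asleep or staying asleep") to protect the group comparison from
circularity with the awakening-based grouping.

The licensed item-to-domain map is proprietary, so the packaged default
(`inst/extdata/bitsea_items_synthetic.tsv`) is a synthetic mapping that
honors every structural constraint (42 items, 31/11 split, 11 competence
items, both sleep items verbatim, domain sizes 8/6/8/11 plus 9 unassigned
problem items); holders of the instrument can point `load_instrument()` at
their own file. Missing responses default to complete-domain scoring, with
optional person-mean imputation when at most 25% of a domain's items are
missing — explicit and conservative, and switchable.

# The statistical layer

* **Linear mixed model** of the longitudinal dwell indices with
  group (between), age and emotion (within) and all interactions as fixed
  effects and a child-level random intercept, which uses all incomplete
  longitudinal data. F tests use the Satterthwaite approximation (hence
  fractional denominator degrees of freedom). Candidate covariance
  structures — compound symmetry, AR(1) over age within child × condition,
  and heterogeneous residual variance by emotion — are compared by AIC and
  the selected structure is always reported; the published analysis names
  the criterion but not the winner, so the comparison is reported rather
  than hard-coded. Bonferroni-corrected pairwise condition contrasts are
  computed within each group, with Cohen's d defined as the contrast
  estimate over the square root of the summed random-intercept and
  residual variances (a stated convention; the source analysis does not
  define d for model contrasts).
* **t-tests** for the BITSEA domains: pooled-variance by default with
  $d = (M_1-M_2)/s_p$, switching to Welch with Satterthwaite df when a
  median-centered Levene pretest rejects at .05 (matching the fractional
  df that published analyses of unequal-variance domains show). A
  summary-statistics interface allows re-analysis of published tables.
* **Pearson 2×2 chi-square** without continuity correction,
  $X^2 = n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d))$: this convention reproduces
  the published co-sleeping (20.376) and falling-asleep-alone (16.454)
  statistics exactly from the printed counts, which pins it down. The
  three-category breastfeeding covariate is dichotomized as exclusively
  breastfed vs any formula (the published df = 1 implies some
  dichotomization; the split used is not stated, so the most common one is
  chosen).
* **Pearson correlations** between condition dwell indices at each age and
  the BITSEA domains, pairwise complete, with unadjusted two-sided p
  values (the exploratory table is explicitly unadjusted).

# The synthetic cohort generator

`simulate_cohort()` draws, per child $j$, a standardized gaze intercept
$z_j$ and, per trial in condition $c$, a latent index

$$s = m_{g,c} + \sigma_{\text{subject}} z_j + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma_{\text{trial}}^2),$$

emitted as a timeout when $s \ge 1$, clamped to the anticipatory floor
(latency 160 ms, index 0) when $s < 0$, and otherwise as a saccade with
latency $160 + 840s$. The location $m_{g,c}$ is calibrated by monotone
root finding (`calibrate_censored_mean()`, tolerance well below $10^{-6}$)
so that the **post-censoring** mean equals the documented condition mean
$\mu_{g,c}$ — the defaults are the published group × emotion pattern
(waking: fearful .611, happy .550, neutral-open .541, neutral-closed .505;
nonwaking: fearful .646, happy .602, neutral-open .510, neutral-closed
.551), held constant over age because the source analysis found no
interactions involving age (an optional `age_trend` parameter exists for
sensitivity work). Default variances are $\sigma_{\text{subject}} = 0.10$
between children and $\sigma_{\text{trial}} = 0.25$ within condition —
values chosen once as realistic for infant disengagement data and frozen.

Unscorable trials are injected at rate 0.10 by violating one validity rule
chosen uniformly (late initial fixation, wrong-direction saccade,
anticipatory latency, and at 24 months a >200-ms gap), which yields the
reported ≈5.4 scorable trials of 6 per condition at 8 months; an extra 3%
of 24-month trials carry long gaps. Group sizes default to 77/69,
retention at 24 months to 0.83, and awakening counts are truncated-Poisson
draws (conditioned on ≥3 or ≤1) whose conditional means match the
published 3.8 and 0.9.

**Observation grids.** Emitted latencies are snapped to the observation
grid of the age — the 40-ms video frame at 8 months, the 300-Hz sample
period (10/3 ms) at 24 months — by rounding, and the snapped value is what
the ground truth records. Manual video coding cannot resolve gaze shifts
below the frame duration, so frame-aligned ground truth is the honest
description of what that instrument measures; rounding (rather than
flooring) keeps the snap mean-zero so the calibrated condition means are
unaffected. A consequence verified in the tests is that scoring the
emitted streams recovers the ground-truth latencies *exactly*, on both
paths.

**BITSEA item model.** Each domain has a latent trait per child (shared
child factor loading 0.3 across domains — a stated convention, since
within-child domain correlations are not published), shifted between
groups, and items are graded-threshold discretizations of the latent with
a domain loading. A two-class item model (a few frequently endorsed
"common" items plus rare items) is calibrated at simulation time by
numerical optimization so that the nonwaking-group domain sum matches the
published mean and SD *and* the discretized-scale Cronbach's alpha matches
the published reliability (.515–.660); a homogeneous item model cannot do
all three for sparse scales like internalizing (mean 1.05, SD 0.99,
α = .515), which is why the two-class structure exists. The latent group
shift is then solved so the standardized domain difference equals the
published effect sizes (d = 0.72 dysregulation, −0.48 competence, 0.38
internalizing, 0.19 externalizing). The competence latent additionally
correlates 0.337 with the child's gaze intercept, reproducing the
published 8-month happy-dwell × competence association at the latent
level. Covariate frequencies (breastfeeding, co-sleeping, falling asleep
alone, healthcare center) follow the published group-wise counts; maternal
depressive and anxiety scores are emitted as opaque plausible numeric
columns only.

## What the generator does and does not emulate

The generator reproduces the AOI-level structure of the task — fixations
at region centers, clean transitions, missing-data runs, and rule-specific
violations — but not oculomotor kinematics (saccade velocity profiles,
smooth pursuit, drift), calibration error, or heterogeneous per-child data
quality. Passing round-trip tests therefore show that the scoring rules
and index algebra are implemented correctly and that the statistical layer
recovers the generative structure; they do not validate robustness to the
messiness of real infant eye-tracking, which should be assessed on real
data. Real published F and p values are fitted to unavailable human data
and are not reproduction targets; the recomputable quantities are the
analytic worked examples (index endpoints, chi-squares, the
summary-statistics t-test) and the generator round-trips.

# Numerical choices and degenerate inputs

* AOI membership uses closed rectangles with ties resolved as "inside" the
  central region; the 13.6° face–distractor distance is read as
  nearest-edge separation (center-to-center is a config switch, since the
  published description does not disambiguate). Distractor sides are
  balanced 12/12 (counts not published; balance is the natural default).
* The schedule sampler is rejection sampling over random permutations
  (cap 10,000) with a deterministic interleaved-order repair; an
  infeasible spec (for example a single condition with a run cap below its
  trial count) raises an error.
* Trial windows are closed on the right at distractor onset + 1000 ms,
  because the index treats 1000 ms as the last measured time point.
* An all-identical dwell table is a degenerate-fit error; a noiseless
  cell-constant table (zero residual variance, where a mixed model cannot
  estimate its variance components) falls back to a fixed-effects
  least-squares decomposition that reports the cell means exactly and
  F = 0 for effects with zero sum of squares.
* Cronbach's alpha is undefined (signaled) for zero total variance;
  correlations are undefined (NA, flagged) for constant columns or fewer
  than 3 complete pairs.

# Problem sizes used by the tests and acceptance script

The packaged test suite exercises the simulator round-trip at 150 children
and the property suites at 200 null replicates (mixed-model type-I error),
2000 replicates (t-test power vs the noncentral-t closed form), 1000
random trials (scorer vs brute-force oracle), and 400–600 children
(latent-correlation recovery) — sizes chosen to give clear statistical
verdicts at desk scale. `scripts/acceptance.R` re-runs the round-trip at
the full 500 children with the study's group proportions. All stochastic
checks state their tolerance as a multiple of the relevant Monte-Carlo
standard error, fixed before the fact.

# Known limitations

* The synthetic instrument map is structurally faithful but not the
  licensed BITSEA; real item-level analyses require the licensed mapping.
* The "excessive movement" rejection rule and the saccade-directedness
  landing window are explicit package conventions where the published
  description is qualitative.
* The generator's BITSEA effects operate at the domain-sum level; the
  sleep items receive the same group shift as the rest of dysregulation,
  so the sleep-removed variant's published summaries are approximated
  rather than separately calibrated.
* The mixed model reports Satterthwaite F tests from the random-intercept
  fit; the AIC comparison covers a small, stated candidate set of
  covariance structures rather than an exhaustive one.
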