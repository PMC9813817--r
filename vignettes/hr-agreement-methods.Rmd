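---
title: "Validating a wearable heart-rate monitor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a wearable heart-rate monitor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hragree` answers a concrete validation question: when a wrist-worn
photoplethysmography (PPG) monitor and a reference electrocardiogram (ECG)
record the same person's heart rate through a stress protocol, how accurate
is the wearable, and can the two devices be used interchangeably? The
package implements the full repeated-measures analysis — accuracy indices,
a mixed-effects phase ANOVA, and a family of agreement metrics derived from
mixed-model variance components — together with a synthetic study generator
so that every estimator can be exercised against known ground truth.

## The study design being analysed

The canonical input is a Trier Social Stress Test (TSST): five protocol
blocks per subject — 5 min relaxation, 3 min anticipatory stress, a 5 min
oral (speech) task, 5 min mental arithmetic, and a closing 5 min
relaxation. Both relaxation blocks are relabelled to a single `relaxation`
phase before analysis (`label_and_merge()`), so the analysis phases are
relaxation, anticipation, oral and arithmetic. Heart rate rises from
relaxation through anticipation and arithmetic to the oral task.

Data arrive as long-format per-device bpm series plus a phase schedule.
`pair_epochs()` aligns the devices on half-open windows
`[k * epoch_s, (k+1) * epoch_s)`, averaging each device within a window and
keeping windows where both devices supply at least half of their expected
sample count. The default epoch is 5 s — the wearable's reporting
granularity, coarser than the beat-level ECG. Differences are oriented
test minus reference throughout, so a wearable that under-reads yields a
negative bias. Timestamps are protocol-relative seconds; no clock-drift or
cross-correlation alignment is attempted.

## Phase ANOVA

For a single device the phase effect is tested with the REML fit

```
bpm ~ phase + (1 | subject) + (1 | subject:phase)
```

(`fit_phase_model()`), i.e. phases fixed, subjects and the subject-by-phase
interaction random. `omnibus_test()` reports the Type III F-statistic with
Satterthwaite denominator degrees of freedom and partial
$\eta^2 = F \, df_1 / (F \, df_1 + df_2)$, with a 90% CI obtained by
inverting the noncentral-F CDF in the noncentrality parameter and mapping
$\lambda / (\lambda + df_1 + df_2 + 1)$ (90% is the usual reporting level
for variance-explained effect sizes, whose sampling distribution is
one-sided). `pairwise_contrasts()` returns all six phase differences with
Tukey-adjusted p-values on Satterthwaite degrees of freedom. We use
Satterthwaite for the contrasts as well as the omnibus test, rather than
switching to Kenward–Roger post hoc: at these balanced design sizes the two
are nearly indistinguishable, and a single df method keeps the pipeline's
behaviour easy to reason about. This is a deliberate, documented choice.

## Accuracy

`accuracy_by_phase()` reports, per phase and pooled,
$\mathrm{MAE} = \overline{|d|}$ and
$\mathrm{MAPE} = \overline{|d| / \mathrm{ref}} \times 100$, judged against
a clinically acceptable difference (CAD) of 10 bpm and a 10% MAPE
threshold. Overall rows pool epochs rather than averaging phase summaries;
with unequal phase durations the two conventions differ, and pooling
answers the question "how wrong is a randomly chosen reading". MAE
confidence intervals use the subject-level bootstrap described below —
epoch-level resampling would ignore the strong within-subject correlation
and understate the interval width.

## Agreement metrics

All agreement metrics derive from two REML fits on the paired epochs.

**Difference model** (`fit_difference_model()`):

```
diff ~ 1 + (1 | subject) + (1 | subject:phase)
```

gives the bias $\mu_d$ (fixed intercept) and difference-scale variance
components whose sum is $\mathrm{Var}(D)$. From these:

* limits of agreement: $\mu_d \pm z_{(1+\ell)/2} \sqrt{\mathrm{Var}(D)}$
  (`loa_mixed()`);
* mean squared deviation: $\mathrm{MSD} = \mu_d^2 + \mathrm{Var}(D)$
  (`msd()`), the expected squared disagreement for one subject at one
  moment;
* coverage probability:
  $\mathrm{CP} = \Phi\!\big(\tfrac{\mathrm{CAD} - \mu_d}{\sigma}\big) -
   \Phi\!\big(\tfrac{-\mathrm{CAD} - \mu_d}{\sigma}\big)$ with
  $\sigma^2 = \mathrm{MSD} - \mu_d^2$ (`coverage_probability()`); a zero
  $\sigma$ degenerates to the indicator $|\mu_d| \le \mathrm{CAD}$;
* total deviation index:
  $\mathrm{TDI}(p) = z_{(1+p)/2}\sqrt{\mathrm{MSD}}$
  (`total_deviation_index()`), the normal-approximation boundary containing
  $p \cdot 100\%$ of absolute differences. The exact noncentral-$\chi^2$
  inversion is out of scope; at the bias-to-spread ratios seen in this
  setting the approximation error is well under 1% (the test suite checks
  it against a $10^6$-draw simulation).

**Stacked model** (`ccc_vc()`): both devices' readings in one frame,

```
bpm ~ device + phase + (1 | subject) + (1 | subject:phase) +
      (1 | subject:device) + (1 | subject:phase:epoch)
```

The shared epoch-level term captures the genuine moment-to-moment heart-rate
fluctuation that both devices track together; following the longitudinal
variance-components CCC convention it counts as agreement, so

$$\mathrm{CCC} = \frac{\sigma^2_{s} + \sigma^2_{sp} + \sigma^2_{st}}
  {\sigma^2_{s} + \sigma^2_{sp} + \sigma^2_{st} + \sigma^2_{sd} +
   \sigma^2_{\beta} + \sigma^2_{e}},$$

with $\sigma^2_\beta = (\beta_{test} - \beta_{ref})^2 / 2$ the systematic
device shift. Without the epoch term the shared wander would be booked as
residual disagreement and two identical devices could never reach CCC = 1.
On balanced two-device data with no temporal structure the estimator
reduces to Lin's moment CCC (tested to within 2%). Interpretation bands:
&lt;0.90 poor, 0.90–0.95 moderate, 0.95–0.99 substantial, &gt;0.99 perfect.

The stacked residual $\sigma^2_e$ is the within-device replication
variance. It feeds

* the repeatability coefficient
  $\mathrm{RC} = 1.96\sqrt{2\sigma^2_e}$
  (`repeatability_coefficient()`), and
* the coefficient of individual agreement
  $\mathrm{CIA} = 2\sigma^2_e / \mathrm{MSD}$ (`cia()`), replication
  disagreement relative to between-device disagreement, with CIA = 1
  meaning switching devices adds nothing beyond replication error and
  values below ~0.8 conventionally read as poor interchangeability. The
  formula is fixed by internal consistency: for two devices that differ
  only by independent replication noise, $\mathrm{MSD} = 2\sigma^2_e$
  exactly, so CIA = 1. Both devices are assumed to share the replication
  variance (the pooled stacked-model residual); device-specific residual
  variances are not modelled.

Per-phase reports (`agreement_by_phase()`) refit both models within each
phase (dropping the phase terms). The difference model's LoA pool all
variance components while MSD uses the same pool, so the two are mutually
consistent here by construction; analyses that estimate them from different
models can print an LoA half-width inconsistent with their MSD, which is
worth checking when comparing published tables.

## Cluster bootstrap

All confidence intervals come from a seeded subject-level bootstrap
(`cluster_bootstrap()`): subjects are resampled with replacement, every
epoch of a drawn subject is kept, and duplicates are relabelled as distinct
clusters so the mixed models see the right design. Intervals are BCa
(`bca_interval()`): bias correction $z_0$ from the fraction of replicates
below the point estimate (ties counted half), acceleration from the
skewness of leave-one-subject-out jackknife values, endpoints taken as
order statistics with no extrapolation. With $z_0 = a = 0$ the interval is
exactly the percentile interval. The reporting default is B = 5000
replicates; the test suite uses a few hundred to keep runtimes short, which
only widens the Monte-Carlo wobble of the interval endpoints, not their
location. A statistic may fail on the occasional degenerate replicate;
more than 1% failures aborts with a census rather than silently reporting
a biased interval.

## The synthetic study generator

`generate_study()` draws latent trajectories

$$\mathrm{hr}_{spt} = \mu_p + a_s + g_{sp} + w_{spt}, \qquad
  a_s \sim N(0, \sigma^2_{subject}),\;
  g_{sp} \sim N(0, \sigma^2_{interaction}),$$

with $w$ a stationary AR(1) wander on the 5 s grid, and observes them
through two configurable device models. Defaults: 34 subjects, phase means
72/80/86/90 bpm (relaxation/anticipation/arithmetic/oral — only their
ordering is empirically constrained; the values are chosen as typical
adult HR under these tasks), and variance components 116.57, 14.47 and
29.72 bpm².

Two notes on those numbers. First, the 116.57 component is sometimes
labelled "within-subject" in validation reports; in the model structure it
can only be the between-subject intercept variance, and the generator
treats it that way. Second, the AR(1) autocorrelation defaults to 0.3:
an iid-residual REML fit to autocorrelated data books the variance of the
correlated cell means into the interaction component
(inflation $\approx \sigma^2_w \bar{c}$, with $\bar{c}$ the mean pairwise
correlation within a cell). At $\rho = 0.3$ this bias is ~6% of the
interaction component and ~1% of the residual — comfortably inside the
15% parameter-recovery tolerance the package holds itself to — whereas at
$\rho = 0.9$ it would be ~55% and the generator would contradict the very
model the analysis fits. Positive-but-modest serial correlation also acts
as a deliberate misspecification stressor: the fitted models never include
an AR term.

The device model (`device_error_model()`) composes a constant calibration
bias, a proportional under-read above a knee (default 90 bpm — the pattern
wrist PPG shows at high heart rates), white noise, a reporting lag, epoch
dropout, integer quantization, a per-subject calibration offset (wear
position and anatomy), and optional phase-specific effects: an extra
per-subject bias and a noise multiplier for a named phase. Dropout draws
come from a stream keyed by subject but not device, so identical device
models lose identical epochs. Per-subject RNG streams are derived with a
multiplicative mix from the master seed, so enlarging a study never
perturbs the subjects already generated.

`tsst_study_config()` packages the default scenario: an ECG with 1.5 bpm
noise, and a wearable with slope −0.30 above 90 bpm, 5 bpm noise, a 3 bpm
per-subject offset SD, 2% dropout, integer output, and an
anticipation-specific effect (mean −6 bpm, SD 7 bpm across subjects, noise
× 1.5). The anticipation term is what a purely HR-driven error model cannot
produce: anticipation has only the second-lowest mean HR, yet it is the
phase where wrist devices do worst in practice — subjects gesture and
fidget while preparing a speech, and individual differences in anticipatory
stress are large. With it, the scenario reproduces the qualitative pattern
the analysis should detect: relaxation best and anticipation worst on every
agreement metric, and the largest MAE in anticipation.

What the generator does *not* emulate: beat-to-beat variability
(RR intervals), waveform-level artefacts, clock drift between devices,
non-normal error distributions, and motion-correlated dropout. Passing
tests therefore demonstrate that the estimators recover the truth under
the stated Gaussian mixed-model world, not that any particular wearable
behaves like this.

## Numerical choices and degenerate inputs

* Exactly constant differences short-circuit the difference model
  (`lmer` cannot fit a zero-residual model): bias = the constant, all
  components 0. Identically, an all-zero diff column short-circuits
  CCC = 1 with $\sigma^2_e = 0$, and `cia(0, 0)` is defined as 1.
* Variance components are REML estimates with lme4's non-negativity
  bounds; singular fits are reported with a warning, never dropped.
* `coverage_probability()` tolerates `msd < bias^2` only to numerical
  slack (`1e-9`); a genuinely smaller MSD is an input error.
* BCa quantile indices subtract `1e-9` before `ceiling()` so that exact
  quantile levels (e.g. 0.05 × B integer) do not flip an order statistic
  on floating-point noise.
* Bootstrap replicates that fail (singular resamples) are dropped up to a
  1% budget, then the run aborts with a failure census.
* Problem sizes in the test suite were chosen to exercise asymptotic
  claims at the smallest scale where they are expected to hold: parameter
  recovery at 200 subjects (~10% relative SE on a subject-level variance
  component against a 15% band), law-of-large-numbers checks at 2000
  subjects, oracle equivalence at $10^6$ draws, type-I error at 1000
  null fits, bootstrap coverage at 500 datasets × 400 replicates.

## Known limitations

* TDI uses the normal approximation, slightly anti-conservative for large
  bias-to-spread ratios.
* The epoch-pairing resolution is a convention; analyses of real data
  whose pairing policy differs will not reproduce epoch-sensitive indices
  (MAE) exactly.
* CCC confidence intervals bootstrap the whole stacked model and are the
  most expensive part of a report; per-phase CIs multiply that cost by
  the number of phases.
* The phase ANOVA fits epoch-level data; published analyses that
  aggregate to subject-phase means first will show larger denominator
  degrees of freedom differences than Satterthwaite-vs-KR alone explains.
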