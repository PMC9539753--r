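---
title: "Dissociating attention from motor confounds in the 5CSRTT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating attention from motor confounds in the 5CSRTT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fivechoice)
```

## The problem

The five-choice serial reaction time task (5CSRTT) measures sustained
attention and impulsivity in rodents: a brief light cue appears in one of
five apertures, and the animal must poke the cued aperture within the
stimulus duration (SD) plus a 4 s limited hold. Trials end in one of four
outcomes: **correct**, **incorrect** (poke in a dark aperture),
**omission** (no poke inside the window), or **premature** (poke during the
5 s intertrial interval before the cue). Omissions are the conventional
readout of attentional lapses — but they are also produced by anything that
keeps the animal away from the aperture wall, most notably *still eating
the previous reward*. In mouse lines with motor impairment (the package's
presets mirror a *Ube3a* maternal-deletion model of Angelman syndrome,
where mice eat pellets several seconds more slowly than wild-type
littermates), slow eating inflates omissions and masquerades as an
attention deficit.

The package implements the analysis that untangles this: conditioning the
omission rate on the outcome of the *previous* trial.

- **OAC** (omissions after correct): omissions among trials whose
  predecessor was correct. A reward was just delivered, so eating can spill
  into the current trial; OAC is *confounded* by eating speed.
- **OAIO** (omissions after incorrect/omission): the same fraction among
  trials with no preceding reward. Eating cannot explain an omission here,
  so OAIO isolates the attentional component.
- **Extended OAIO** additionally drops trials whose predecessor is an
  omission that itself follows a correct trial: a very long eating bout can
  outlast one entire trial and still occupy the animal two trials after the
  reward.

The first trial of a session (no predecessor) and trials following a
premature response belong to no denominator. A flag
(`include_premature_predecessor`) exposes the broader "after any
non-correct trial" reading; the default follows the narrower
incorrect-or-omission definition. Metrics are always computed within a
session and aggregated per mouse — the mouse is the unit of analysis, and
sessions are never chained across days.

## The generative agent

Because no raw cohort data are distributed, the package includes a
stochastic agent that plays every protocol stage and emits timestamped
event logs, letting every analysis path be exercised end to end. Its
parameters (`agent_params()`) are:

| parameter | meaning | default |
|---|---|---|
| `lapse_base` | lapse probability at the 16 s reference SD | 0.05 |
| `lapse_sd_slope` | added lapse per halving of the SD | 0.05 |
| `accuracy_given_response` | P(cued aperture chosen \| response) | 0.85 |
| `latency_mu`, `latency_sigma` | log-normal response latency (s) | log(1), 0.35 |
| `premature_hazard` | ITI poke hazard (events/s) | 0.01 |
| `magazine_latency_mean` | reward delivery to head entry (s) | 2 |
| `eating_mean`, `eating_shape` | Gamma eating duration (s) | 10.4, 10 |
| `activity` | habituation locomotion score | 50 |
| `aperture_bias` | 5 weights for non-cued aperture choice | uniform |

A cued trial unfolds by an ordered mechanism:

1. During the ITI a premature poke occurs with probability
   $1 - e^{-h \cdot \mathrm{ITI}}$.
2. At stimulus onset, if residual eating time from the previous reward
   exceeds the whole response window (SD + limited hold), the trial is an
   omission regardless of attention. **This is the confound, built in
   mechanistically**: the ITI clock starts at reward *retrieval* while
   eating continues concurrently, so eating time beyond the 5 s ITI
   intrudes into the next stimulus window. Occupancy is all-or-none;
   partial attention while eating is not modeled.
3. Otherwise the agent lapses with probability
   $\mathrm{lapse}(SD) = \mathrm{clamp}(\mathrm{base} + \mathrm{slope}
   \cdot \log_2(16/SD),\, 0,\, 1)$. The $\log_2$ link anchored at 16 s was
   chosen because the staircase SDs are near-geometric; any monotone link
   supports the qualitative properties.
4. Otherwise a log-normal latency is drawn; outrunning the window is an
   omission, else the poke is correct with probability
   `accuracy_given_response` (incorrect pokes choose a dark aperture by
   `aperture_bias`).
5. A correct poke delivers a pellet; the magazine is entered after a
   Gamma(shape 2) latency; eating lasts a Gamma(`eating_shape`) duration.

Premature responses do not restart the trial (at most one premature
outcome per trial), matching per-trial outcome bookkeeping. Eating bouts
are allowed to run concurrently with subsequent trials; in the event
stream, `EAT_END` annotations are matched to open bouts first-in-first-out,
which pins down the per-session total and mean eating time exactly even
when bouts interleave (individual bout boundaries can swap when one bout
outlasts the next — an ambiguity inherent to any interleaved log).

Default and preset values: the eating means (10.4 s control, 15.6 s
mutant-like) and the cohort age structure (~P70–P160; the mutant-like
group younger on average, as Mendelian sampling happened to produce) are
the study conditions the presets emulate; group sizes default to 14
control / 16 mutant-like. The premature hazard is essentially
unconstrained by the source analyses and its default (0.01/s, about 5% of
ITIs) is a conventional mild-impulsivity figure. Between-mouse variation
is modeled as mean-preserving log-normal jitter (CV 0.15) on eating time,
latency scale, lapse rate and activity, so cross-mouse regressions
(eating vs OAC; activity vs omissions) have realistic spread. Each mouse
runs on a deterministic substream of the master seed, so changing the
cohort size does not reshuffle existing mice.

## The staged protocol

`default_protocol()` encodes the full staged design: two magazine sessions
(pellets at pseudorandom 4/8/16/32 s intervals, 50 pellets or 25 min);
operant acquisition (five lit apertures, any poke rewarded, 60 trials or
25 min, advance after >25 trials on two consecutive sessions);
visuospatial discrimination (one lit aperture, 5 s ITI, advance after
>25 trials *and* >50% accuracy on two consecutive sessions); 5CSRTT
training (SD staircase 16, 8, 4, 2, 1.5, 1 s; advance on a single session
with <30% omissions, >60% accuracy and >50 trials, or forcibly after 10
sessions at the same SD); and two test days (variable SD 1/0.5/0.2 s,
30 min; variable ITI 5/7.5/12.5 s at SD 1 s, 45 min; 100-trial caps).

All criterion comparisons are strict, exactly as printed — ties fail. The
forced-advance counter counts sessions at the current SD *including* the
evaluated session and resets on every advance, the simplest reading of
"after 10 sessions at the same SD"; hence a deterministic perfect agent
finishes training in exactly 6 sessions and an agent that never meets
criteria in exactly 60. Criteria are evaluated at session end only (the
protocol does not adjudicate mid-session timeouts). Habituation is a
stage with no trials whose only output is a scalar activity score — video
tracking is an input to the analysis, not part of it. Magazine "priming"
(pellets placed in apertures) affects hardware, not analysis, and is not
modeled.

## Event-log dialect

Sessions serialize to plain CSV: `#`-prefixed header lines (mouse id,
group, age, stage, SD, ITI, date, protocol hash), a `time_s,event,arg`
column header, then one row per event with times in seconds from session
start at millisecond precision. `EAT_END` is a first-class event so that
video-annotated real data flow through the same path as simulation; a
missing eat-end yields an absent eating time, never zero. Logs round-trip
losslessly, parse identically with LF or CRLF endings, and validation
errors cite line numbers. The protocol hash fingerprints every
configuration field, so a log is tied to the exact protocol that produced
it.

## Statistics

The battery mirrors the standard analysis surface for this design:
Student's t by default (pooled variance, matching df = 28 reporting for
14 + 16 mice; Welch by flag), two-way repeated-measures ANOVA with the
subject nested in group (between effect tested against subject-within-group
error; within and interaction against the subject-by-level error;
uncorrected degrees of freedom, no sphericity adjustment), Bonferroni
post-hoc group contrasts per within level (p multiplied by the number of
levels, clipped at 1), ordinary least-squares regression, and a fixed
age-covariate adjustment (`value ~ group + age`). The supplementary-style
random-effects (lmer) analyses are deliberately approximated by this
fixed-covariate model; random slopes are out of scope.

Numerical conventions: the ANOVA refuses unbalanced or incomplete designs
rather than imputing (silent imputation would corrupt the calibration
properties); zero-sum-of-squares effects report F = 0, p = 1, and a
positive effect over a zero error term reports F = Inf, p = 0; accuracy
with no responded trials is undefined (`NA`, flagged) and excluded from
group means; with a single within level the ANOVA collapses to the
two-sample t (F = t²).

## What the simulation does and does not show

The generator reproduces the *logic* of the empirical dissociation with
eating speed as the only manipulated parameter: two groups with identical
lapse parameters and eating means of 15 s vs 10 s (5 s ITI) separate
strongly in OAC while OAIO stays at chance in the large majority of
replicate cohorts. The leakage that remains in OAIO is itself
informative: a Gamma-tailed eating bout occasionally outlasts an entire
omission trial, contaminating the trial after it — precisely the chain the
extended OAIO definition removes, and with `oaio_ext` the null is retained
almost completely. Conversely, steepening one group's `lapse_sd_slope`
produces a genotype-by-SD interaction in OAIO concentrated at short SDs —
an attention effect that emerges as demand rises.

Passing these properties shows the pipeline computes what it claims on
data whose generating process is known. It does *not* validate the agent
as a model of mouse behavior: there is no learning (acquisition and
discrimination are passed as soon as sampling allows, with no
session-over-session improvement), no within-session fatigue or satiety,
no licking microstructure or circadian modulation, and response latencies
are stationary. Aperture preference is uniform by default, so the
perseveration analyses run but show no built-in group contrast. Real
response latencies of animals that eat slowly might also shift in ways the
agent does not capture (the agent responds at its drawn latency even while
finishing a pellet).

## Problem sizes

The shipped analyses use the full preset cohort (30 mice) through the
complete protocol for the descriptive tables; 40–100 independent replicate
cohorts (one training session per SD per mouse) for the dissociation
rates; 5,000 trials per SD for lapse recovery (recovered within ±0.05 of
truth, typically ±0.02); and 500 synthetic replicates for the null
calibration of the ANOVA p-value. These sizes give stable rates while
keeping a full run in the order of minutes on one core.
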