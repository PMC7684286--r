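---
title: "Models and methods: pitch reinforcement by visual substitution"
author: "pitchsubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pitch reinforcement by visual substitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchsubs)
```

## The paradigm

In closed-loop operant pitch conditioning, the pitch (fundamental frequency)
of one targeted song syllable is measured on every rendition, and a brief
binary stimulus — switching the chamber light off (LO) for a few hundred
milliseconds — is delivered whenever pitch crosses a threshold. Every
morning the threshold resets to the previous day's median pitch, so if a
bird does not move its pitch distribution the expected stimulus contingency
is 50% each day. The interesting phenomenon is a *valence inversion*: deaf
birds, for whom the light is the only feedback their song produces, shift
pitch *toward* the stimulus zone (the stimulus acts as an appetitive
reinforcer), whereas hearing birds shift *away* from it (aversive). This
package implements both halves of the analysis of such experiments: the
behavioral statistics applied to per-rendition pitch tables, and a
reinforcement-learning model — a SARSA agent with an intrinsic
*manipulation bonus* — that reproduces the inversion.

## Behavioral statistics

**Daily summaries and d′.** All effects are expressed as standardized daily
pitch changes
$$ d'_{i,j} = \frac{\bar p_j - \bar p_i}{\sqrt{\tfrac12(\sigma_i^2 + \sigma_j^2)}}, $$
with day means $\bar p$ and day variances $\sigma^2$ computed from the
curated renditions of one bird ( `daily_summaries()`, `dprime()` ). We use
the sample ($n-1$) variance throughout. The measure is antisymmetric in its
days and invariant to rescaling pitch by a positive constant, which the test
suite checks as properties.

**Paradigm criteria.** Reinforcement starts only after stable singing,
$|d'_{i-4,i}| < 0.5$ over the last five baseline days (strict inequality:
the boundary value keeps the bird in baseline), and ends when the cumulative
shift against the last baseline day exceeds $2.5$ d′ or when the pitch
stabilizes again ( `paradigm_criteria()` ).

**Direction and magnitude.** The global direction of a bird's response is
$\delta = \mathrm{sign}(d'_{b,l})$ between the last baseline and last
stimulus day; the aligned magnitude $\bar a' = \delta \langle
d'_{i-1,i}\rangle$ makes responses comparable between birds that shifted up
and down. The degenerate case $d'_{b,l} = 0$ (measure zero under any
continuous model) is mapped to $\delta = +1$ with a warning.

**Mixed models.** Population effects are estimated with linear mixed-effect
models fitted by maximum likelihood through `lme4` (ML rather than REML so
that nested model variants are comparable; the package's robustness variant
collapses two fixed effects into one). The daily-change model is
$$ d'^{\,j}_{i-1,i} = b\,\vartheta_i + a\,\theta_i + d\,\varphi_i + r_j, $$
with indicator $\vartheta$ for baseline days, $\theta$ for post-baseline
days in control birds, signed $\varphi \in \{+1,-1\}$ for stimulus days in
treated birds (positive toward the stimulus zone) and a Gaussian random
intercept $r_j$ per bird. Inference uses the residual degrees-of-freedom
convention, $\mathrm{df} = n_\mathrm{obs} - n_\mathrm{fixed}$. The
singing-rate model regresses last-three-day relative singing rates on
deafness, stimulus exposure and their interaction. Changes that straddle the
baseline/stimulus boundary carry all-zero indicators and only inform the
random intercept. Per-bird responses are tested against time-matched control
windows with pooled-variance t-tests at $\alpha = 0.05$, deliberately
uncorrected for multiple comparisons, and the robustness of population
comparisons to the arbitrary treated–control assignment is quantified by
re-running the test over 1000 random feasibility-constrained pairings,
scarcity-first ( `random_pairings()` ).

**Binomial direction argument.** The probability that $k$ of $n$ birds drift
the same way under a fair-coin null depends on the tail convention, so
`binomial_direction_prob()` exposes it as an argument (`one_sided`,
`two_sided`, `point`) rather than asserting any bound; for $k=9, n=10$ the
one-sided tail is $11/1024 \approx 1.07\%$ and the two-sided tail twice
that.

## The synthetic cohort generator

`simulate_bird()` / `simulate_cohort()` generate per-rendition tables with
the statistical structure the analysis assumes, for all five groups (deaf
substituted *subs*, deaf control *unsubs*, hearing *LO*, hearing control
*noLO*, and *subs-rand* with random 50% delivery). Within a day, pitches are
i.i.d. Gaussian with constant standard deviation; the reinforcement response
moves only the day mean, because all reported statistics are day-level. The
stimulus flag is produced by the actual closed-loop controller: each
stimulus-day morning the threshold becomes yesterday's median, and a
rendition triggers strictly beyond the threshold on the bird's target side.
A useful consequence — not an input — is that a bird shifting its mean by
$s$ d′ per day shows a daily contingency of about $\Phi(s)$; at the default
response of $0.19$ d′/day this is $\approx 57\%$.

Defaults mirror the study conditions the analysis is designed for: responses
of $+0.19$ (deaf substituted) and $-0.08$ (hearing) d′/day signed toward the
stimulus zone, zero spontaneous drift in controls, six baseline and eleven
stimulus days, 150 renditions per day (the analysis' inclusion rule requires
more than 100), baseline coefficient of variation about 1% (7.5 Hz at
750 Hz), and multiplicative singing-rate trends that land the last-three-day
relative rates near +25% (subs), −34% (unsubs), −9% (LO) and +8% (noLO).
Per-bird seeds derive from the cohort master seed plus the bird's position,
so extending a design never perturbs existing birds.

The generator deliberately omits several features of real data: within-day
pitch autocorrelation and circadian trends, non-Gaussian pitch tails,
song-bout structure, detector misdetections (hence no curation step), and
between-bird heterogeneity of the response magnitude (the mixed model's
random intercept is therefore estimated near zero on synthetic cohorts).
Passing tests on this generator show that the pipeline recovers what it
assumes — they do not validate the Gaussian day model itself, which the
recorded data must justify.

## Acoustic features

The acoustic module reproduces the standard songbird measures on numeric
waveforms: Harmonic Product Spectrum pitch in a 512-sample (16 ms at
32 kHz) Hamming window, using $H = 5$ harmonics by default (exposed in
`spectrogram_config()`); the log-power spectrogram with a 128-sample hop, an
offset of 0.1 added to linear power before the natural log, and the lowest
10 bins (cutoff 625 Hz) removed; per-frame Wiener entropy (log ratio of
geometric to arithmetic mean power — 0 for flat spectra, strongly negative
for tonal ones) summarized by its mean (noisiness) and variance
(complexity); and the spectrogram bias–variance decomposition across two
days (Euclidean distance of day-mean spectrograms; mean pixel-wise variance
within a day) after cropping all renditions to the shortest duration.
Whether linear power is normalized before the fixed 0.1 offset is left as a
config toggle (`normalize`), since the offset is only meaningful relative
to the signal scale. Fixtures are synthetic harmonic stacks
(`harmonic_stack()`), including missing-fundamental stacks that exercise
the defining property of the HPS estimator.

## The agent model

**World.** `syllable_world()` builds a three-note syllable; each note offers
six action variants, each variant has a home sensory state (18 states in
all) and emits one of the three adjacent states with probabilities
$(0.25, 0.5, 0.25)$; at the edges the out-of-range neighbour's mass folds
inward so that every row keeps exactly three nonzero entries. States 13–16
trigger light-off, overlapping the territory of notes 2 and 3; the exact
emission weights are a config parameter because only the structure, not the
numbers, matters for the sign results. Deaf agents observe only the binary
light channel; hearing agents observe the emitted sensory state. The
sensory situation without singing is a distinguished *silence* observation
with the light on, which pins the no-action light-off probability to zero.

**Rewards.** Each action's reward is $R = E + M + r\,\mathbb 1\{\mathrm{LO}\}$:

* $M = D_{KL}(\hat\vartheta_0 \| \hat\vartheta_j)$, the *manipulation
  bonus* — the divergence between the sensory distribution without acting
  and the one following action $j$. For deaf agents this reduces exactly to
  the Shannon surprise of light-on, $-\log\hat\vartheta_j(\mathrm{on})$.
* $E$, an *exploration bonus*: the Bayesian expected information gain about
  the action's outcome distribution from one more observation (closed-form
  Dirichlet expression in `exploration_bonus()`); positive, monotonically
  decreasing in experience, vanishing asymptotically.
* $r \le 0$, the extrinsic punishment, delivered only on light-off events.

**Sensory estimator.** The agent estimates $\hat\vartheta_j$ by shrinking
the empirical outcome frequencies toward the no-action baseline:
$\hat\vartheta_j = (1-\lambda) f_j + \lambda \hat\vartheta_0$, equal to
$\hat\vartheta_0$ before the first observation, with $\lambda = 0.005$.
This choice has three consequences we consider essential to the model's
logic. First, an action carries no estimated impact before any evidence
($M(0) = 0$). Second, impact is bounded at $-\log\lambda \approx 5.3$ nats
and depends on the observed outcome *frequencies*, not on how often the
action happens to have been tried — under a count-based (add-one) estimate,
$-\log\hat\vartheta_j$ grows like the logarithm of the visit count, so the
first-visited action snowballs regardless of its actual effect and the
hearing model's premise that "no action is singled out" fails. Third, under
random 50% delivery every action's estimate converges to
$(\tfrac12,\tfrac12)$ and the achievable impact saturates at
$-\log(\tfrac12 + \tfrac\lambda 2) \approx \log 2$, strictly below what a
contingent action can reach. The generic add-one estimator remains
available as `estimate_theta()`.

**Exploration prior.** The exploration bonus uses a Perks prior (total
pseudocount mass 1 spread over the alphabet) rather than add-one: with a
per-symbol pseudocount of 1, the total prior mass scales with the alphabet,
handing the hearing agent (19 symbols) an exploration drive roughly eight
times stronger and slower-decaying than the deaf agent's (2 symbols) — a
modality asymmetry that is an artifact of the encoding, not part of the
model. Both the prior and $\lambda$ are exposed in `agent_config()`.

**Learning.** Tabular SARSA over (note, variant) with learning rate
$\alpha = 0.1$, within-syllable discount $\gamma = 0.9$ (episodes are
independent syllables) and $\varepsilon$-greedy action selection with
$\varepsilon = 0.1$ and uniform tie-breaks; Q initializes at zero. Some
exploration is necessary for the bonuses to be estimated at all; the sign
results are not sensitive to $\varepsilon$ in the 0.05–0.2 range.
"Converged" behavior (contingency, motivation index, prediction-error
summaries) is read from the last 20% of trials. The motivation index is the
visit-weighted mean Q over that window, so unvisited state-actions do not
dilute it.

## Simulation protocols and what they show

`sweep_reinforcement()` runs 20 agents per cell over eight log-spaced
reinforcement magnitudes from $-0.01$ to $-2$ nats per light-off, 2000
trials per agent, for deaf, hearing and ablated-deaf ($M$ forced to zero in
the reward while everything else, including the random stream, is shared)
cohorts, plus light-never-off control cohorts for the motivation baselines.
On this grid the deaf model exceeds the critical 50% contingency at every
cell while the ablated model never does, and the deaf motivation index sits
far above its control while the hearing index sits below its control —
jointly, `plausible_region()` reports the contiguous sub-interval where all
orderings hold (about $-2$ to $-0.045$ under the defaults).

One boundary behavior is worth stating precisely: at the two smallest
magnitudes ($|r| \le 0.02$) the hearing cohort's contingency sits near the
world's base rate (about 0.65) rather than below one half, because at that
horizon the exploration bonus still dominates a punishment tilt of order
$10^{-2}$ nats and keeps the policy near uniform; averaged across the grid
the hearing contingency is about 42%, and every cell with
$|r| \gtrsim 0.045$ lies below 50%. The avoidance claim is therefore a
statement about non-negligible punishments (or, equivalently, about longer
horizons).

`subs_rand_run()` wires the world to deliver light-off on a fair coin per
syllable: the measured per-action impact converges to $\log 2$ (within
0.01 at 10,000 trials) and the contingency to one half — the model's
account of why uncontrollable delivery is less motivating than contingent
delivery. `rpe_summary()` reads the prediction errors of converged punished
agents at note 2, restricted by default to trials whose chosen action can
trigger light-off (the analogue of analyzing targeted renditions): hit
trials carry negative and escape trials positive mean errors, the
dopaminergic sign pattern.

Problem sizes used by the test suite and the acceptance script — 20 agents
per cell, 2000 trials (10,000 for the random-delivery bound), 100 recovery
replicates per effect size, 250,000 episodes for the fixed-policy
dynamic-programming comparison — were chosen so each check resolves its
quantity well inside its tolerance on a single CPU.

## Numerical and degenerate-input conventions

Even-count medians average the two central order statistics. Threshold
comparisons are strict (equality never triggers). A day without data carries
the previous threshold forward, mirroring recording crashes. d′ is undefined
(error) when both day variances vanish; consecutive-day d′ is reported as
`NA` in that case. KL divergence raises on support violations unless
infinity is explicitly allowed. SARSA's terminal note bootstraps from zero.
All stochastic entry points take explicit seeds, and cohort/sweep seeds
derive per bird/agent from a master seed plus a counter so results are
bit-reproducible and extensible.

## Limitations

The agent model is a deliberately minimal touchstone: no eligibility
traces, no function approximation, no within-day threshold dynamics, and a
discrete 18-state sensory space whose emission weights are structural
assumptions. The behavioral generator's day-level Gaussian model cannot
test curation, detector errors, or within-day dynamics. The exploration
bonus is one reasonable formalization of "information gain"; the package's
claims about it are confined to the qualitative contract (positive,
decreasing, vanishing) that the downstream results rely on.
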