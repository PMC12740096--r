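---
title: "Quantifying stable cognitive traits in the nine-arm radial maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stable cognitive traits in the nine-arm radial maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazetraits)
```

# The measurement problem

A longitudinal cognitive study follows the same animals across their adult
life — here, mice tested at 4, 8, 12 and 18 months, each test being a
16-day session in a nine-arm radial maze plus object-recognition/location
tests and an open field. The scientific question is individual-level, not
group-level: is an animal's cognitive performance a stable trait, so that
measuring it early predicts it late? Answering that requires (i) scalar
per-session performance metrics, (ii) a way to put metrics from different
scales on a common footing and combine them, (iii) regression machinery
for cross-age stability, and (iv) a chance-level reference for the maze
behaviour. `mazetraits` implements all four, plus a generator of synthetic
cohorts with known ground truth so that the whole pipeline can be
validated by parameter recovery.

# Maze metrics

A trial ends after 10 minutes or after nine arm entries, whichever comes
first; revisits count toward the nine. We read the termination rule this
way because daily error counts of about three are only possible if
revisits consume entries. All session metrics are means over the observed
days of a per-day quantity; a missing day reduces the divisor rather than
contributing a zero.

**Decision-making time** is `T/(n+1)` per day. The printed form of this
definition is ambiguous about where the session average enters; dividing
each day's trial time by its entry count (plus one) and averaging
reproduces the magnitude of reported cohort means (tens of seconds),
whereas a single division of one trial time by `16(n+1)` would not. The
`+1` makes a zero-entry day score its full trial duration rather than
diverge.

**Unique-sequence decomposition** parses the day's entry list greedily,
left to right: the current segment grows while each new entry is new *to
the segment*; an entry already in the segment closes it, and that entry
opens the next segment. Three consequences worth stating explicitly,
because they are easy to get wrong: segments partition the entry list; the
entry that triggers an error belongs to the *next* segment, never to two
segments at once; and the trailing segment counts even if no error ever
closes it — an error-free full trial contributes a single segment of
length nine. The **unique-sequence score** is `sum_i i * f_i^2` with `f_i`
counted *within each trial* and the score averaged over days; per-trial
counting reproduces the single-digit score scale reported for real
cohorts, whereas pooling counts across a session would inflate the squared
terms roughly 16-fold.

One property of the score as defined deserves a caveat: it is not
monotone in performance. Any partition of nine entries into segments of
*distinct* lengths scores exactly 9, while repeated segment lengths
inflate the square (e.g. lengths 3+3+3 score 27). A fragmented,
chance-level trial can therefore out-score a perfect one. We implement the
formula as printed and treat its inter-age correlation — which is
indifferent to the direction of the mapping — as the primary stability
readout.

**Errors** are entries minus distinct arms entered — equivalently, every
return to an arm already visited that day. Note that segment boundaries
are a subset of errors: a return to an arm from an *earlier* segment is an
error that closes nothing.

**Exploration ratio** divides the number of distinct non-centre regions
entered (of 27: arms, bridges, outer-centre sectors) by 27; the
inner-centre is excluded because animals are introduced there.
**Learning rate** is the negated OLS slope of daily errors on day number,
so improvement is positive. **Cumulative arm time**, **velocity** and the
four object-preference ratios (OR1/OR15/OL1/OL15, chance = 0.5) complete
the eleven registered metrics. Open-field measures (arena speed,
outer-zone occupancy) are computed but kept out of the cognitive metric
universe: that task assays anxiety, not cognition. A preference ratio with
zero exploration of both objects is undefined and propagates as a flagged
`NA` — excluded from Z-tables with a warning rather than silently scored
as 0, since a near-zero-exploration animal is a documented outlier case,
not a maximally biased one.

# Standardisation, combination, stability

Z-scores are computed per age and per metric with the *population*
standard deviation (the definition carries no n−1 qualifier; a
`sd_type = "sample"` switch exists and is recorded in the output, since
the choice rescales every Z by a constant). Decision time and errors are
sign-inverted after standardisation so a higher Z always means better.
Composites use Stouffer's method `sum(Z_i)/sqrt(k)`, with `k` the number
of metrics actually available per mouse. Its printed form in the source
material is typographically garbled; the text names Stouffer's method
explicitly, which fixes the formula.

Cross-age stability is a linear fit of the late composite on the early
one. The fitting objective is squared error with an optional L2 penalty
`lambda` on the slope — the natural reading of "regularisation against
over-fitting" for a two-parameter model whose printed loss function is
also garbled. The default is `lambda = 0`, never silently nonzero, and at
zero the estimates equal ordinary least squares to machine precision
(tested against `lm()` and the closed-form normal equations).
Significance is always reported from the F test of the *unpenalised* fit,
which is how fit significance is conventionally quoted for these
regressions; `R^2 = r^2` holds exactly for the simple fit. A constant
response leaves `r` undefined (`NA`, flagged) with slope zero; a constant
predictor is an error.

**Per-mouse lifespan trends** regress per-*day* metric values on age —
up to 64 observations per mouse across the four ages. We fit on days, not
on the four block means, because reported per-mouse p-values in the 1e-4
range are only attainable with ~60 degrees of freedom. With the
generator's noise model (below) the day-level residuals are exchangeable
within mouse, so these per-day fits are well specified.

**Decliner detection** flags a mouse when at least `m` of the five maze
metrics (USS, errors, decision time, arm time, exploration ratio) show a
significant trend in that metric's adverse direction; `m = 3` by default,
p-values raw (the consensus rule is the guard against isolated false
positives), with a Bonferroni option for familywise control across the
five metrics.

**Combination search** scores every non-empty subset of the eleven
metrics (2047) by the mean R² of its Stouffer composite across age
comparisons. Which age pairs enter the mean is not pinned down by the
design, so the default compares the first age against each later one
(4→8, 4→12, 4→18) — prediction *from* the first age point is the framing
of the whole analysis — and the pairs are configurable. Ties are broken
lexicographically so the ranking is deterministic.

**Resampling robustness** draws random mouse subsets of every size from 1
to n (n draws per size — 441 resampled datasets for the 21-mouse case,
matching the published count), refits each, and summarises the variance of
r by degrees of freedom. The exact published resampling scheme is not
described; this sizes-times-draws convention is a documented default, not
a claim about the original procedure. Draws of fewer than three mice
cannot support a fit and are excluded from the variance curve. The
signature of a stable trait is a variance that is low and flat above ~10
degrees of freedom and explodes below ~5.

# The null model

Chance-level behaviour is an agent that starts on a uniformly chosen arm
and then draws arms iid-uniformly — *including* the arm it is on — for
nine entries, 16 trials per agent. Two alternative kernels are available:
no-immediate-repeat, and an arbitrary offset-weight kernel over −4..+4
circular steps. Applying the same decomposition code path as for real
data (no duplicated parsing logic) gives the chance distribution of
unique-sequence lengths.

Whether the published chance-level mode of two requires same-arm
re-entries to be allowed was left open; the implementation answers it
empirically: the uniform-iid kernel yields a pooled-length distribution
with mode 2, while forbidding immediate repeats shifts the mode to 3. So
re-entries must be allowed, which is also consistent with re-entries being
scored as offset-0 moves in the adjacent-arm analysis.

Because the exact pooled distribution has nearly tied mass at lengths 2
and 3 (0.2436 vs 0.2312), the sample mode of a single 928-trial cohort
equals 2 only ~80% of the time. The package therefore ships the exact
distribution (`null_length_distribution()`, a linear dynamic program over
the parse state) alongside the simulator, and the tests assert the mode on
the exact distribution and on simulations pooled over seeds, with each
individual seed checked for consistency against the exact distribution by
chi-squared. A closed-form pmf for the *first* segment length
(`analytic_first_segment_pmf()`, mode 3 for nine arms) is included as an
independent oracle that also distinguishes first-segment from
pooled-segment statistics.

# The synthetic cohort generator

The generator is the package's stand-in for the unreleased tracking data,
and its defaults are the study conditions: 22 mice, ages 4/8/12/18
months, 16 trials per age, inter-age correlation 0.7 for maze metrics,
0.3 for speed, 0.0 for object preference; weight rising 0.35 g/month from
~22 g, open-field speed falling 0.26 cm/s/month from 12.71 cm/s,
outer-zone occupancy rising 0.0067/month from 0.729; an optional
attrition schedule (58/46/31/22) and an optional planted decliner.

**Latent structure.** Each mouse carries time-invariant latents — revisit
avoidance (cognitive ability), decision tempo, and arm dwell — and the
inter-age decorrelation of the maze metrics is carried entirely by
day-level sampling noise, calibrated so that 16-day session means
correlate at the planted rho between *any* two ages. This is a
test-retest-reliability reading of trait stability and is the design the
whole study argues for: the trait itself does not wobble, measurements
do. A per-step autoregressive latent was rejected because it cannot
simultaneously give the adjacent-age and the 4-vs-18-month correlation
the same planted value — under AR(1) the three-step correlation would be
rho³ ≈ 0.34, not 0.7 — and because genuine age-level wobble would make
the per-day trend regressions anticonservative. Speed and object
preference, whose instability is the point, use compound-symmetric
age-level latents giving exactly their class rho.

**Mechanics.** Arm sequences are drawn from an offset-biased kernel with
its mass on the ±2 adjacent arms (the empirically preferred move),
modulated by an ability-dependent penalty on re-entering any arm already
visited that day — ability acts on error propensity, never on speed,
because the study's dissociation (maze metrics predictive, speed not)
must emerge from the construction. Inter-entry intervals and dwell times
are lognormal with mouse-level medians set by the tempo and dwell latents;
a trial truncates at 600 s, so slow days also have fewer entries, fewer
error opportunities and shorter sequences, as in the real task.
Outer-centre visits, bridge-only visits, open-field occupancy
(logit-normal outer fraction), object bouts and strictly increasing
weight series fill out the dataset. All randomness flows from one
mandatory seed through named substreams per mouse, age and stage, so
adding a mouse never perturbs another mouse's data, and regeneration is
byte-identical. With `noise_sd = 0` the per-age substreams are replayed
identically, so a fully stable specification (rho = 1) reproduces each
mouse's data exactly at every age — a useful degenerate check.

**Calibration.** The couplings and day-noise scales were fixed once, by
simulation at large n (2000 mice), to meet the construction targets: the
4-vs-18-month correlation of the session-mean unique-sequence score
equals the planted 0.7 (the calibration anchor), daily errors ≈ 3,
decision time ≈ 60–65 s, arm time ≈ 95 s, exploration ratio ≈ 0.77, and
entry counts ≈ 8 of 9. The couplings are deliberately kept in the
near-linear range of the revisit-penalty curve: a steeper, more saturated
mapping reproduced the same reliability but inflated the cohort-to-cohort
spread of the correlation estimate well beyond its Fisher sampling
theory. Two realized correlations sit above their class target — errors
(~0.85) and exploration ratio (~0.75) — because both are mechanically
cleaner readouts of the same latent than the USS; they are reported here
for honesty and are not used as recovery anchors.

**Planted decliner.** A decliner loses `drift` latent s.d. per age point
from onset on all three maze latents. The default drift of 1.0 was chosen
by power analysis to emulate a frank decliner — per-day trend t-statistics
around 4, the scale implied by per-mouse p-values near 1e-4 with
correlations of 0.4–0.6 — and makes decision time, arm time and
exploration ratio reliably significant while errors fire less often (the
slowing cancels part of the error-count rise) and the USS, non-monotone as
noted above, rarely does. The m-of-5 consensus is what identifies the
animal.

# What passing tests do and do not show

The generator emulates event-log structure, metric scales, age effects
and trait stability — not spatial trajectories, odour cues, oestrous or
housing covariates, video-tracking artefacts, or real attrition dynamics.
Recovery of the planted correlation and decliner therefore validates the
*pipeline* (metrics, standardisation, fits, search, detection), not any
claim about real mice. The published real-data correlations cannot be
reproduced without the unreleased data; what the tests reproduce is the
qualitative design: stable maze metrics predictive across ages, speed and
object preference not, and chance-level arm choice chaining only two
unique arms.

Problem sizes used by the test suite and the acceptance script: 200
replicate cohorts of 22 mice at two ages for correlation recovery (mean
bias and 95% Fisher-interval coverage), 200 four-age cohorts for decliner
recovery, 20 seeds of 58 × 16 null trials for the modal length, 1e5
trials for the first-segment chi-squared, and eight cohorts for the
cross-class dissociation. These sizes put Monte-Carlo error comfortably
below the decision thresholds they feed.

# Numerical choices and degenerate inputs

Population (not sample) sd in Z-scores, recorded in output metadata;
ridge penalty default 0; F-test always on the unpenalised fit; mode ties
in histograms broken toward the smaller length and reported alongside;
lexicographic tie-break in the subset ranking; constant responses flagged
`NA` rather than erroring mid-cohort; zero-exploration preference ratios
flagged `NA`; trials with zero entries score their full duration as
decision time and zero elsewhere. Table writers emit 17 significant
digits so write → read is the identity on doubles, and every output file
header records the package version, the RNG seed and a config
fingerprint.

The package exposes its functionality as ordinary R functions (the
modelling core as a classed fit object with the usual `print`, `summary`,
`coef`, `predict`, `residuals` and `plot` methods); an analysis of this
kind is driven from R scripts rather than a shell, so no command-line
wrapper is shipped.
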