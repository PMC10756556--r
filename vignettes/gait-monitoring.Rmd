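---
title: "Monitoring limb recovery from vertical ground reaction forces"
author: "gaitrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring limb recovery from vertical ground reaction forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6.5,
                      fig.height = 4)
library(gaitrec)
```

## The monitoring problem

After orthopedic surgery on a weight-bearing limb — here the model system is a
critical-size metatarsal defect in adult sheep, replaced by a bioceramic
scaffold under external fixation — the clinically pressing question is whether
the limb is *functionally* recovering, week by week, without relying on
radiographs whose signal lags the mechanical state of the healing tissue. A
single-axis force platform embedded in a walkway offers a cheap, continuous
answer: each time a foot lands on the plate it records the vertical ground
reaction force (GRF) of that stance phase at 50 Hz. Lameness is visible
immediately: the operated limb's stance is shorter, its force curve flatter
and single-humped, and the other three limbs compensate.

`gaitrec` implements the full analysis chain for such longitudinal recordings:

1. **Stance segmentation** — find the stance phases in a raw force trace and
   apply inclusion filters (`detect_stance_phases()`,
   `apply_inclusion_filters()`).
2. **Gait parameters** — peak and stance-average GRF, contact time, and two
   impulse variants, all normalized by body weight
   (`compute_parameters()`, `aggregate_daily()`).
3. **Inter-limb asymmetry** — the classical symmetry index between operated
   and contralateral limbs (`asymmetry_index()`, `asymmetry_series()`).
4. **Longitudinal statistics** — linear trend fits, a limb-by-parameter
   R² matrix, and recovery time/rate estimators (`ols_fit()`,
   `correlation_matrix()`, `fit_recovery()`).
5. **Synthetic cohorts** — a seeded generator that emulates the statistical
   structure such studies produce (`simulate_cohort()`), so the pipeline can
   be validated end to end against known ground truth.

## Stance segmentation

The detection rule follows the physical definition: a stance runs from the
time-point at which a force increase is first recorded until the force
returns to zero. Because real platforms have a noise floor, "zero" is an
onset threshold (default 5 N, roughly 1 %BW of a 55 kg sheep and far below
even an acutely lame limb's peak of ~60 N and up). A phase is the maximal run
of samples strictly above the threshold *plus one bounding baseline sample on
each side* — those two samples are the onset and return-to-baseline
time-points themselves. Two consequences make this convention attractive on
a uniform grid:

* the contact time `(end_index - start_index) / fs` of a noise-free synthetic
  stance equals its nominal duration exactly, and
* the trapezoidal time-average over the phase reproduces the continuous
  stance-average force (a 42 %BW half-sine gives 26.74 %BW, the analytic
  `42·2/π`), rather than the upward-biased average over supra-threshold
  samples only.

Samples exactly at the threshold close a phase; runs touching either end of
the recording are flagged `edge_truncated` and excluded. The study protocol
also discarded stances walked above or below amble speed (2–4 km/h) by eye; a
single platform cannot measure speed, so a contact-time window (default
0.15–1.20 s) stands in for that criterion, and a minimal peak force (default
20 N) gates out transient blips. These defaults are deliberate
approximations; both are `seg_config()` parameters.

## Gait parameters and the impulse ambiguity

Per phase, with `A` the trapezoidal integral of force over the stance and
`BW·g` the body weight in newtons (`g` = 9.81 m/s²):

| quantity        | definition            | healthy hind reference |
|-----------------|-----------------------|------------------------|
| `grf_peak_pct`  | `max(F)/(BW·g)·100`   | 42 %BW                 |
| `grf_mean_pct`  | `A/(t_c·BW·g)·100`    | 28 %BW                 |
| `t_c`           | stance duration       | 0.58 s (hind), 0.52 s (fore) |
| `imp_rel_pct`   | `A/(t_c·BW·g)·100`    | ≈ stance-average       |
| `imp_abs_pct_s` | `A/(BW·g)·100`        | %BW·s                  |

Normalizing the impulse by contact time (to decouple gait speed) makes it
*identical* to the stance-average force — an identity the test suite asserts
rather than hides. Since published force-platform work is not consistent
about which impulse it reports, both variants are always computed;
`asymmetry_series()` defaults to the non-normalized variant (whose asymmetry
behaves very differently from the GRF asymmetries, as severe early lameness
shortens contact *and* flattens the curve simultaneously) and trajectory
summaries default to the normalized one. The daily average over a session's
valid phases (7–10 per limb in the study protocol) is the unit of analysis;
all phases weigh equally.

## The asymmetry index

For daily means $X_I$ (ipsilateral = operated side) and $X_C$
(contralateral),

$$\mathrm{Asymmetry}(\%) = 100\cdot\frac{|X_I - X_C|}{0.5\,(X_I + X_C)}.$$

The pair-mean denominator gives the index its two useful anchors: 0 for
perfect symmetry and 200 when exactly one limb bears nothing; it is symmetric
in its arguments and scale-invariant. Asymmetries are computed per animal and
day and then summarized, not the other way round; days missing one limb are
skipped with a note, and zero-denominator days are emitted as flagged rows.

## Longitudinal statistics

Trend fits are ordinary least squares (`stats::lm` under the hood), reported
with R² and the two-sided slope p-value ($t$, $n-2$ df). Following
force-platform convention, R² ≥ 0.49 is labelled *strong* and ≥ 0.81 *very
strong*, with significance at p < 0.01; a constant response is a legal null
fit (slope 0, R² 0, p 1). The limb-by-parameter matrix regresses every pair
of (limb, parameter) daily-mean series, matched by animal and day and pooled
across animals (each animal-day a replicate — a `per_animal` mode is provided
for sensitivity); day post-surgery enters as a pseudo-variable, and since the
R² of a simple regression is direction-free the matrix is symmetric with unit
diagonal. No multiple-testing correction is applied by default, matching the
raw-p convention of the field; a Bonferroni switch exists.

Two recovery estimators summarize a daily-mean series:

* `recovery_time()` — the first measurement day inside a ±5 % band around the
  control reference *that stays inside on every later day*. The persistence
  clause keeps single lucky days from counting. Note the structural bias of
  any banded criterion: a parameter rising linearly to control at day
  $T$ enters the 5 % band roughly $0.05\,v_{ctrl}/\text{slope}$ days earlier
  (about 17 days for the default peak-GRF trajectory), so with weekly
  sessions the estimator typically reports 147 for a day-160 normalization.
* `recovery_rate()` — the OLS slope over a day window, converted to calendar
  months of 30.44 days.

`fit_recovery()` wraps both into a classed model object (pooling per-animal
daily means into a per-day cohort series) with `print`, `summary`, `coef`,
`predict` and `plot` methods.

## The synthetic gait generator

The generator exists so that every operation above can be tested against
ground truth, and its defaults *are* the study conditions: 8 operated + 3
control animals, body weight ~ N(57.9, 9.62²) kg truncated at 30 kg, weekly
sessions on days 7–210 (the first post-surgical week is latency), 7–10
phases per limb and session, and 5 % multiplicative lognormal noise (mean
one) on each phase's peak force and contact time.

**Waveform family.** The stance curve is modelled as
$$F(t) \propto \sin^p(\pi t/t_c)\,\bigl[1 - d\,\sin^2(\pi t/t_c)\bigr]\,
\bigl[1 + (a-1)\,t/t_c\bigr],$$
rescaled so the sampled maximum equals the requested peak exactly. This is
the smallest family that reproduces the observed morphologies with
controllable mean/peak ratio: $d=0,p=1$ is a half-sine; $d > 1/3$ gives the
healthy hindlimb's double-peaked M-shape with a mid-stance valley; $p > 1$
narrows the hump into the "punctual contact" single maximum of an acutely
lame limb. The mean/peak force ratio of the family is **not monotone** in
$d$: it rises from $2/\pi \approx 0.637$ at $d=0$ to ≈ 0.780 at $d=0.5$,
then falls towards 0.551 as $d \to 1$. `solve_dip_depth()` therefore solves
the calibration on one monotone branch — `flat` (shallow, single-hump side)
or `deep` (pronounced M-shape, the branch used for healthy limbs, where the
28/42 control ratio gives $d \approx 0.84$).

**Trajectories.** Each limb's parameters follow piecewise-linear recovery
trajectories (`trajectory_params()`): the operated hind peak GRF runs 23 →
42 %BW over days 7 → 160 (a 19 %BW gain, ~3.8 %BW/month), its contact time
0.28 → 0.58 s by day 200, and its shape sharpness relaxes from $p=2$
(stance-average exactly half the peak, 11.5 %BW at day 7) to $p=1$ by day
160, after which the healthy M-template applies — the single-hump-to-M
transition is modelled as abrupt at the force-normalization day, since the
study observed that the M-shape was still absent in the medium term while the
scalar parameters had normalized; a longer-lasting flat shape can be
configured. The contralateral hind starts elevated (peak +17.59 %BW,
stance-average 38 %BW, contact +0.05 s), the forelimbs start +11.2 (IF) and
+21.7 (CF) %BW above the fore control peak at the control mean/peak ratio;
all force elevations decay linearly to control by day 160, contact times by
day 200. The fore control *peak* (59 %BW) is a package calibration choice:
the study prints the fore stance-average control (45 %BW) but not its peak,
and 59 both keeps the printed early-elevation arithmetic plausible (~70–81
%BW initial fore peaks) and puts the 45/59 ratio inside the waveform
family's attainable range.

**Heterogeneity and noise.** Between-animal variation multiplies each
animal's *deviation from control* by a mean-one lognormal factor (CV 5 %),
so the cohort-mean trajectories stay at the printed values; per-step noise
multiplies peak and contact time independently. Gaps between phases are
0.3–0.6 s of exact zeros. Everything is a pure function of `(config, seed)`.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: multi-limb double contacts on one plate,
baseline drift and sensor noise inside a stance, within-stance shape
variability beyond the three shape parameters, speed-dependent waveform
changes (speed enters only through contact time), interrupted walks, and
animals refusing sessions. Segmentation robustness to those failure modes is
exactly what the inclusion filters and the human-supervisor annotations of a
real protocol are for.

## Numerical choices and degenerate inputs

* Trapezoidal integration on the uniform grid (error $O(\Delta t^2)$,
  negligible at 50 Hz); sampling rate inferred as `1/median(diff(time))`
  with a 1 % uniformity tolerance.
* The dip-depth root search runs `uniroot` on a monotone branch with the
  ratio evaluated on an 800-interval grid (ratio accurate to ~1e-5);
  unreachable targets raise a domain error naming the attainable interval.
* A contact spanning fewer than 8 samples is a resolution error, not a
  silent short phase.
* Ties at the onset threshold close a phase (strictly-above opens), so a
  plateau at the gate level never extends a stance.
* `aggregate_daily()` reports sd = 0 with a caution for single-phase groups;
  empty inputs yield empty frames, not errors; both-limbs-zero asymmetry
  days are flagged `NA` rows.
* Simulation sizes in the tests are scaled to what the checks need (e.g. 3
  control animals × 10 sessions × 8 phases for the control grand means, 1000
  phases for the noise-CV law-of-large-numbers check).

## A worked example

```{r example}
cfg <- cohort_config(n_operated = 1, n_control = 1,
                     session_days = seq(7, 210, 14),
                     phases_min = 8, phases_max = 8)
cohort <- simulate_cohort(cfg, seed = 42)
analysis <- analyze_cohort(cohort, quiet = TRUE)
analysis

asym <- asymmetry_series(analysis$daily, "impulse", quiet = TRUE)
head(asym[asym$pair == "hind" & asym$animal_id == "OP01", ])

fit <- fit_recovery(analysis$daily, limb = "IH", parameter = "grf_peak_pct",
                    animals = "OP01", window = c(7, 160))
summary(fit)
plot(fit)
```

## Known limitations

* The amble-speed inclusion criterion is proxied by contact-time bounds; a
  real deployment should carry external discard annotations in the manifest.
* Recordings are single-axis; shear components and center-of-pressure are out
  of scope.
* The recovery-time estimator is banded and session-quantized: its value is
  resolved only to the session interval and is structurally earlier than the
  full-normalization day (see above).
* The correlation matrix pools animals as replicates by default; with few
  animals and long series this mixes within- and between-animal variation —
  use the `per_animal` mode to check robustness.
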