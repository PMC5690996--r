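---
title: "Off-line correction of rotational setup errors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Off-line correction of rotational setup errors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setupcorr)
```

## The problem

In fractionated radiotherapy the patient is repositioned every day, and the
actual position deviates from the planned one by a six-degrees-of-freedom
(6DoF) *setup error*: translations $t_x, t_y, t_z$ (mm) and rotations
pitch/roll/yaw (degrees, about the IEC 61217 x/y/z machine axes). Modern
cone-beam CT (CBCT) imaging measures this error, and robotic couches can
correct all six components — but daily ("online") imaging of every fraction
carries a heavy workload and extra imaging dose. Off-line protocols image
only a few fractions and correct the dominant, *systematic* part of the
error from those measurements.

Rotations matter because targets sit off-axis: a point at distance $r$ from
the isocenter moves by the chord $2r\sin(\theta/2)$ under a rotation
$\theta$, so a 2° error displaces tissue 50 mm off-axis by about 1.7 mm —
comparable to the 2 mm CTV-to-PTV margins used for intracranial treatments.

## Error model and terminology

For patient $p$ at fraction $f$, each axis is modelled as

$$ e_{pf} = S_p + a_p f + \varepsilon_{pf}, \qquad
   S_p \sim \mathcal N(\mu^*, \Sigma^{*2}),\;
   a_p \sim \mathcal N(0, \tau^2),\;
   \varepsilon_{pf} \sim \mathcal N(0, \sigma^{*2}). $$

The population decomposition follows the standard systematic/random
convention:

* $S_p$ (per-patient systematic error) — mean of the patient's errors over
  all fractions;
* $\mu$ — mean of $S_p$ over patients;
* $\Sigma$ — sample SD (denominator $n-1$) of $S_p$ over patients;
* $\sigma$ — RMS over patients of the per-patient sample SDs.

The pooling rule for $\sigma$ (RMS of per-patient SDs, $n-1$ within and
across patients) is the common van-Herk-style convention; where the
underlying clinical report does not spell out its pooling rule we fix this
one throughout and document it here. Systematic errors drive margins roughly
four times harder than random errors, which is why the protocols target
$\Sigma$.

## The protocols

All protocols measure the *raw post-setup* error at imaged fractions and
treat the three rotations (and three translations) as independent per-axis
scalars; a correction $C$ is the value *added* to the raw error, so residual
$=$ error $+$ correction and a perfect correction is the negated error.

* **none** — no imaging; the residual is the raw error.
* **online** — daily imaging; each fraction is corrected on the couch before
  treatment. The residual is drawn from a zero-mean noise model (default SD
  0.2° / 0.2 mm, the positioning accuracy of clinical 6DoF couches, which is
  also consistent with clinically observed post-correction spreads of
  0.2–0.3°).
* **NAL** — image the first 3 fractions; from fraction 4 onward apply the
  fixed correction $C = -\bar e_{1:3}$ per axis.
* **eNAL** — NAL, plus weekly follow-up images at fractions $8, 13, 18,
  \dots$ After each follow-up $f_k$ all measurements so far are fitted by
  least squares, $e_i \approx S_k + a_k f_i$, and the refreshed correction
  $C_k = -(S_k + a_k f_k)$ applies from fraction $f_k + 1$ until the next
  update. For 30 fractions this needs 8 CBCTs.
* **eNAL++** — the eNAL schedule and fit, but every *imaged* fraction
  (including the first three) is corrected online on the day. For 30
  fractions: 8 online-corrected and 22 off-line-corrected fractions, with
  the same workload as eNAL.

Three ordering choices deserve explanation because the protocol definitions
leave them open:

1. **First eNAL correction.** The initial eNAL correction is the NAL mean of
   the first three fractions, not a 3-point least-squares fit: the running
   fit starts at the first weekly follow-up ($f_k = 8$). A 3-point line fit
   over fractions 1–3 would extrapolate day-to-day noise with a large-variance
   slope; the mean is the stable estimator, and it is how eNAL is defined in
   the off-line-correction literature.
2. **Effect of a measurement on its own fraction.** A follow-up measurement
   refreshes the correction for *later* fractions only — off-line, the image
   analyzed after fraction $f_k$ cannot reposition the patient at $f_k$. For
   eNAL++ this ordering is moot: the measured fraction itself is corrected
   online.
3. **Degenerate fits.** With fewer than two points (or coincident fraction
   indices) the slope is forced to 0 and the intercept to the mean. The
   default schedules never hit this; it guards nonstandard configurations.

**Couch limits.** Commanded rotational corrections are clipped per axis to
±3° (the rotational travel of clinical 6DoF couch tops); translations are
not clipped, since only rotational limits are stated for the hardware this
models. Clipping applies to the total commanded off-line correction, not to
the online-residual noise draw (the latter *is* the post-correction
measurement, not a couch command).

## Rotation geometry and the additive treatment

`rotation_matrix()` composes the three rotations about fixed axes as
$R = R_z(\mathrm{yaw})\,R_y(\mathrm{roll})\,R_x(\mathrm{pitch})$, and
`displacement_at_point()` returns $Rp - p + t$. The chord form is exact; at
one decimal the 2°/50 mm case prints 1.7 mm whether computed as chord or arc
length.

Protocol arithmetic, by contrast, treats rotations as per-axis additive
scalars. Within one axis this is exact (rotations about a common axis
commute and their angles add). Across axes the additive picture carries a
second-order error that scales as $r\theta^2$: about 0.4–0.6 mm at 100 mm
when *all three* angles sit at the observed 3.2° maximum simultaneously, and
below 0.02 mm once angles are at the ≤0.7° scale of post-correction
residuals. Since every statistic and every correction in the protocols is
per-axis, and since composition order is likewise a second-order effect, the
additive treatment is admissible for the analysis; the fixed composition
order above is used only when converting a 6DoF error into a spatial
displacement. An early design draft asserted a 0.02 mm cross-axis bound at
3.2°; direct computation shows that bound belongs to the ~0.7° regime, and
the tests assert the verified bounds instead.

## The synthetic cohort generator

No per-fraction clinical dataset is distributable, so the generator stands
in for a cohort like the one that motivated the protocols: ~19 intracranial
(meningioma) patients treated in 28–30 fractions under mask fixation, with
CBCT-measured rotational errors. Defaults state that world:

| parameter | default | basis |
|---|---|---|
| `n_patients` | 19 | single-centre cohort size |
| `n_fractions` | 30 | 28–30 fraction schedules; follow-ups at 8,13,… apply unchanged to 28 |
| `mu_star` | 0 | no population bias after laser setup |
| `Sigma_star` (rot) | 0.9/0.8/0.8° | clinically reported post-setup $\Sigma$ (pitch/roll/yaw) |
| `sigma_star` (rot) | 0.4° | not reported clinically; chosen so post-setup scatter is consistent with the reported $\Sigma$ and the ~3.2° extremes (a config field, not a constant) |
| `tau` | 0 | no time trend unless studied explicitly |
| `max_abs_deg` | 3.2° | largest rotation observed clinically |
| `online_sd` | 0.2 | couch accuracy 0.2 mm / 0.2° |
| `Sigma_star`/`sigma_star` (trans) | 2 / 1 mm | plumbing only; no quantitative claim |

Rotational per-fraction errors beyond `max_abs_deg` are **resampled** (the
daily noise term is redrawn) rather than clipped, so no probability mass
piles at ±3.2°. At the defaults the bound sits >3 total SDs out and distorts
recovered moments by well under 1%; if a pathological configuration makes
the bound unreachable (systematic value beyond it with zero noise), values
are clamped after 1000 rounds with a warning. Normality of the clinical
error distribution is an assumption — the family is isolated in one internal
function (`simulate_course`) so it can be substituted.

What a green test does **not** establish: the generator draws independent
Gaussian axes with a shared within-patient SD, no intrafraction drift
between imaging and treatment, and no patient counter-movement after couch
rotation. Clinical residuals at online fractions come from post-treatment
CBCTs ~15 min later and may include drift the 0.2 noise term only summarizes.
Also, clinical online statistics are typically computed from ~8 re-imaged
fractions per patient, whereas this package decomposes *all* simulated
fractions; masking to the imaged subset reproduces the clinical subsampling
if needed.

## Numerical choices

* Sample ($n-1$) SDs everywhere; $\sigma$ as RMS of per-patient SDs.
* All fractions enter the decomposition, including the uncorrected fractions
  1–3 of NAL/eNAL.
* Least squares via the closed-form normal equations on centred data (exact
  for the ≤9-point fits involved); tests check it against `lm()` to 1e-10.
* Degrees at every interface; radians only inside trigonometry.
* Fractions are 1-based and contiguous.
* All randomness flows from explicit integer seeds (`withr::with_seed`), so
  populations, residuals, and output files are bit-reproducible; generation
  never perturbs the ambient RNG stream.
* CSV output uses fixed 10-decimal formatting (no locale-dependent
  separators); round-trips agree to better than 1e-9.

## Worked example

```{r example}
cfg <- simulation_config(n_patients = 19, n_fractions = 30, seed = 42)
population <- simulate_population(cfg)
decompose_population(population)

tab <- compare_protocols(population, online_sd = 0.2, seed = 43)
subset(tab, axis == "pitch",
       select = c(policy, mu, Sigma, sigma, mean_n_cbct, reduction_pct))
```

The comparison reproduces the characteristic accuracy-versus-workload
picture: `none` keeps the full systematic spread; NAL removes most of it
with 3 CBCTs; eNAL and eNAL++ approach the online protocol's residual
$\Sigma$ at under a third of its workload; and eNAL++ additionally trims the
random error because its imaged fractions are corrected online. NAL and eNAL
slightly *inflate* $\sigma$ — the applied correction carries estimation
noise — which is expected and resolvable only at population scale.

## Known limitations

* Rotations are corrected as independent axes; true 6DoF kinematics of a
  particular couch (pivot location, travel coupling) are out of scope.
* The online-residual model is white noise; it does not model intrafraction
  drift or counter-movement.
* Translational defaults are placeholders to exercise the 6DoF plumbing.
* Clinical match-file dialects vary; only the documented CSV schema is
  parsed, with a `column_map` hook for renamed headers.
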