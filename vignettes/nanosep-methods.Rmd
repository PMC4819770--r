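---
title: "Measuring nanometer separations between two-color FISH foci: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nanometer separations between two-color FISH foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosep)
library(tibble)
```

`nanosep` measures distances between two-color RNA-FISH transcription
foci far below the diffraction limit, using nothing more exotic than a
widefield fluorescence image. This vignette is the package's account of
the models it assumes, the parameters that matter, and the places where
the design was genuinely open — and what the synthetic validation does
and does not show about real data.

## The image model

A fluorophore cluster much smaller than the diffraction limit images as
an Airy pattern, well approximated by a 2D Gaussian of standard
deviation

$$ s = 0.21\,\lambda / \mathrm{NA}, $$

about 94 nm for 650-nm emission through a 1.45-NA objective. A camera
pixel integrates that profile over its area, so the expected counts in
pixel $(i, j)$ are

$$ \mu_{ij} = G\,\Big[ b + N \int_{\text{pixel}} \mathcal{N}_2(x_0, y_0, s)\Big], $$

with $N$ the expected photons in the spot, $b$ the uniform background in
photons/pixel, and $G$ the camera gain. The generator draws Poisson shot
noise on photons, multiplies by gain, adds Gaussian read noise, and
rounds to non-negative integer counts. Two consequences worth noting:

* **Pixel integration, not point sampling.** Both the generator and the
  fitters evaluate the Gaussian as an error-function difference over
  each pixel. A point-sampled fitting model applied to integrated data
  recovers positions (by symmetry) but inflates the fitted width by
  roughly $a^2/12$ in variance — with 200-nm pixels and $s \approx 94$
  nm that is a ~17% width bias, which would silently corrupt the
  precision formula. Using the integrated model everywhere removes this
  bias and makes the generator-fitter pair an exact oracle.
* **Integer counts.** Rounding the noiseless expected image loses the
  sub-half-count tail mass, about 1–2 counts of a 1000-photon spot
  (<0.2%); photon-conservation checks use a 0.5% band for this reason.

Coordinates: 0-based pixel indices, with the center of pixel $(i, j)$ at
$((j + 0.5)a, (i + 0.5)a)$ nm, x along columns, y along rows. All
positions are reported in nm.

## Localization

Three estimators share one contract (`localize_spots()` returns the same
table for each):

* **Least squares (`fit_gaussian_lsq`)** — the default. An elliptical
  Gaussian $z_0 + A\exp\{-[((x-x_0)/s_x)^2 + ((y-y_0)/s_y)^2]/2\}$ is
  fitted by a Levenberg–Marquardt loop with an analytic Jacobian. The
  two widths adjust independently: lateral symmetry is a safe initial
  assumption but never true in practice. Initialization follows the
  standard rules — brightest pixel for $A$ (ties broken to the first in
  row-major order, so fits are deterministic), its center for
  $(x_0, y_0)$, the theoretical width for $s_x = s_y$, the perimeter
  mean for $z_0$. Convergence is declared when the relative change in
  the residual sum of squares between successive iterations falls below
  0.01% (`tol = 1e-4`); a parameter-step criterion is available via
  `converge_on = "params"`. Iteration counts are recorded; at moderate
  SNR the median is about 6.
* **Centroid (`localize_centroid`)** — background-subtracted,
  negative-clipped intensity centroid. Cheap, accurate for bright spots,
  and degrades rapidly with noise because fluctuations in the ROI tails
  carry large lever arms. It also carries a small pixelation bias (up to
  ~0.8 nm at $s/a \approx 0.47$) for emitters away from pixel centers,
  which is why the exact three-estimator agreement oracle is evaluated
  at a pixel center.
* **Maximum likelihood (`fit_gaussian_mle`)** — maximizes the Poisson
  likelihood of the gain-corrected counts under the same integrated
  model (read noise is ignored in the likelihood). It is the most
  accurate at low photon counts and the slowest. Its convergence
  tolerance is relative change of the negative log-likelihood; the
  default is tighter (`1e-8`) than the least-squares 0.01% because the
  log-likelihood is orders of magnitude larger than its curvature near
  the optimum, so a 0.01% band would stop materially short of the
  maximum.

The model equation has no rotation term; a rotated-Gaussian mode
(`rotated = TRUE`, point-sampled, numerical Jacobian) exists for
elongated foci but is off by default.

**Precision.** The per-axis uncertainty of a fitted center is

$$ \sigma = \sqrt{ \frac{s^2}{N} + \frac{a^2}{12N}
   + \frac{8\pi s^4 b^2}{a^2 N^2} }, $$

with $s = \sqrt{s_x s_y}$ for asymmetric fits. $N$ is estimated as the
background-subtracted total intensity before gain (the model-based
volume $2\pi A s_x s_y / a^2 G$ is reported as a cross-check); $b$ is
estimated as the standard deviation of the perimeter-pixel photon
values, which for Poisson background approaches $\sqrt{b_{\text{true}}}$
— the quantity the formula's third term wants. Monte-Carlo calibration
in the test suite confirms the least-squares per-axis RMSE stays within
$[0.8, 1.5]\times$ this prediction across $N$ from 500 to 20000 and $b$
from 0 to 20; unweighted least squares sits 20–30% above the bound at
low $N$, which is expected (the formula is a lower-bound-style estimate
and least squares is not efficient under Poisson noise).

## Spot QC

A candidate focus passes QC if it is bright, contrasted and
Gaussian-like:

* `snr` = (peak − perimeter mean) / perimeter mean ≥ 3 — the excess
  brightness over background. A peak at 4× background has `snr = 3`.
* `local_contrast` = (peak − perimeter mean) / perimeter SD ≥ 5. A spot
  over a perfectly flat non-zero perimeter is infinitely contrasted and
  passes; a completely flat ROI has undefined contrast and fails. The
  literature does not define "local contrast" numerically; this
  definition and its threshold are package choices, configurable and
  echoed into output tables.
* `gaussian_likeness` = Pearson correlation between the ROI and its
  best-fit Gaussian ≥ 0.7 (also a package choice).

Candidate detection (`find_candidate_foci`) automates what is often a
manual step: local maxima above median + 5 MAD, non-maximum suppression
at $2s$ spacing, then per-candidate QC, ordered brightest-first. Manual
selection is still supported — any table of click coordinates can be
passed to `localize_spots()` or `cmd_measure()` directly.

## Channel registration

Residual chromatic aberration displaces one channel relative to the
other by tens of nanometers — larger than the distances being measured.
The correction is built from multispectral beads visible in both
channels:

1. `match_fiducials()` pairs bead localizations by mutual nearest
   neighbors after removing the median displacement; at least 12
   surviving pairs are required.
2. `build_lwm_transform()` fits the displacement field (A minus B) in
   two stages. A global order-2 polynomial, fitted unpenalized to all
   control pairs, captures translation, rotation and smooth low-order
   aberration with minimal variance. On its residuals, one local
   quadratic per control point is fitted to the `k = 12` nearest pairs
   (Gaussian distance weights scaled to the k-th-neighbor radius), with
   a mild ridge penalty (`ridge = 1`, in the local fit's normalized
   coordinates) on the non-constant terms. The correction at a query
   point is the global map plus the weighted mean of the local maps
   under a compact cubic kernel that fades each map out at the edge of
   its own neighborhood.
3. By default the field is evaluated on an 8-pixel grid and bilinearly
   interpolated (`evaluation = "direct"` computes it exactly, for
   validation).
4. `residual_error()` measures the residual misalignment `r` as the RMS
   corrected-B-to-A distance over held-out pairs that took no part in
   the fit. `r` is mandatory downstream.

Why the two-stage, ridge-stabilized form: a plain quadratic on 12 noisy
points has six parameters and amplifies bead localization noise by
roughly 30–50% at held-out positions. Because the physical displacement
field is smooth and small, shrinking the local fits toward the global
map removes most of that variance at the cost of a bias that is zero for
translations, and under 2 nm for noiseless smooth warps of 50-nm
amplitude at realistic bead densities. With the stabilized fits, the
held-out residual tracks the closed-form noise floor — the
root-sum-square of the two per-channel radial localization errors — to
within a few percent. The weight kernel, grid pitch and ridge strength
are documented choices, not published values, and all are configurable.

Note one convention carefully: the precision formula's $\sigma$ is
per-axis, while the noise floor of `r` combines *radial* RMS errors
(each $\sqrt{2}\sigma$ per channel for isotropic noise). A "15-nm
per-peak precision" therefore corresponds to a ~30-nm bead-pair residual
floor, and the package treats `r` as the empirical holdout RMS, whatever
its decomposition.

`apply_transform()` flags queries outside the convex hull of the control
beads as extrapolations. Transforms are serialized as a TSV of control
pairs plus a small header and rebuilt deterministically on read. One
model should be built per acquisition day and passed explicitly to the
measurement command.

## Separation analysis

Registered two-color foci are paired by mutual nearest neighbors within
a 200-nm gate (the diffraction limit — two targets on the same allele
appear as one overlapping spot; the gate is configurable and should be
widened when genuinely larger separations are expected). Each pair
yields

$$ d = \lVert \mathbf{p}_A - \mathbf{p}_B \rVert, \qquad
   u = \sqrt{\sigma_A^2 + \sigma_B^2 + r^2}, $$

and the record is flagged significant only when $d > u$. Missing
$\sigma$ or $r$ is an error, not a default: uncertainty is part of the
measurement.

Separations are binned into half-open 30-nm bins and summarized by a
least-squares Gaussian fit to the bin counts, with amplitudes rescaled
so the analytic areas $A\,\mathrm{sd}\sqrt{2\pi}$ of compared
distributions are equal. Two caveats are deliberate fidelity choices
rather than oversights. First, distances are magnitudes, so near zero
true separation their distribution is Rayleigh-like, not Gaussian; the
Gaussian summary is the field's convention and is kept as the primary
output (fitting the raw separations rather than binned counts, or
reporting the empirical mean, are the fallbacks when the histogram is
degenerate — fewer than 3 nonzero bins). Second, all distances are 2D
projections; unknown z-offsets appear as error in the measured
separations and are not modeled.

`chance_colocalization()` quantifies the null argument for why an
overlapping red/green pair implies same-allele origin: with ~200-nm
spots in a ~100-µm² nucleus and a couple of foci per channel, random
overlap occurs in well under 1% of nuclei.

## The synthetic generator as a validation instrument

The generator emulates: diffraction-limited spots with the correct
pixel-integrated profile; Poisson shot noise; uniform background; camera
gain and Gaussian read noise; smooth inter-channel warps (translation +
rotation + quadratic terms, bounded displacement); isolated bead fields
and nucleus scenes with exact ground truth. Defaults mirror the
acquisition the package targets: 200-nm pixels, 1.45 NA, 594/647-nm
channels, background around 10 photons/pixel, and — for FISH foci — a
faint-probe budget of ~150 photons, chosen so the per-peak localization
precision lands in the ~10–15-nm class reported for intronic probe sets
(published protocols do not state camera gains or photon budgets, so
these are package choices, made once).

It does **not** emulate: non-uniform (structured) backgrounds beyond
what QC rejects, autofluorescent debris, fluorophore blinking or
bleaching, channel bleed-through, focus drift, a real Airy profile, or
3D structure. Passing the synthetic suite therefore demonstrates that
the estimators, the registration and the uncertainty propagation are
correct and calibrated *under the stated image model*; it does not
certify performance on pathological real-world backgrounds, which is
what the QC gate and the per-record uncertainty are there to police.

Validation study sizes (chosen to characterize the estimators while
keeping the suite quick to run): 500-spot batches per condition for
convergence and precision calibration across a 12-condition grid;
1000 paired spots for the estimator-accuracy ordering; 300 pairs for the
colocalization control; 40–200 fiducials for registration recovery; and
four 80-pair groups at true separations 0, 68, 150 and 300 nm — rendered
faint, registered through an equally faint bead field so the residual
`r` sits on the same scale as the per-peak precision, exactly the regime
in which a ~30-nm combined uncertainty arises — for the end-to-end
recovery property (fitted histogram means strictly ordered and within
the combined uncertainty of truth).

## Probe-design constraints

The helper screens intronic oligo candidates against the constraints
that make a probe set behave like a point source and hybridize evenly:
50-mer windows within ±5 points of 55% GC (the tolerance is a package
choice; published guidance says only "roughly the same"); five modified
(amino-dT) positions per oligo spaced more than 8 bases apart
(implemented as gap ≥ 9, maximizing the minimum gap, ties leftmost); no
20-mer shared exactly with a background sequence set on either strand;
and a five-probe set spanning at most 600 nt (warning above 400 nt),
chosen by an exact minimal-span sweep. Everything here is exact string
matching — no melting-temperature or secondary-structure modeling — and
each screen is tested against a brute-force oracle.

## Known limitations

* 2D only; axial offsets inflate measured separations.
* The precision formula is an approximation; at very low photon counts
  the least-squares RMSE exceeds it by design of the estimator, and the
  package reports the formula value, not an empirical bootstrap.
* The LWM ridge introduces a small bias for strongly non-smooth warps;
  set `ridge = 0` (and accept the variance) if the aberration field is
  known to have sharp structure.
* Gaussian histogram summaries are biased upward near zero separation;
  compare like with like (the colocalization control is summarized the
  same way).
* The probe uniqueness screen is exact-match only; it will not flag
  near-matches that hybridize detectably.
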