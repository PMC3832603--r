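---
title: "Camera OECF characterisation and linearisation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera OECF characterisation and linearisation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oecflin)
```

## The measurement model

A camera pixel integrates scene radiance into photoelectrons and maps
them through a nonlinear gain to a digital level. `oecflin` separates
the two stages.

**Forward exposure.** The photoelectron-generating photon amount at a
pixel follows the standard camera equation

$$ n \;=\; \frac{\pi\,A_d\,t_{int}}{4\,f_\#^2\,(1+m)^2}
   \int L(\lambda)\,S(\lambda)\,T(\lambda)\,d\lambda $$

with $L$ the spectral radiance incident on the lens (photon-flux units,
µmol m⁻² s⁻¹ nm⁻¹ sr⁻¹), $S$ the dimensionless spectral sensitivity,
$T$ the combined lens/filter transmittance, $A_d$ the effective
detector area (m²), $t_{int}$ the integration time (s), $f_\#$ the
relative aperture and $m$ the optical magnification.
`exposure_integral()` evaluates this with trapezoidal integration after
linear interpolation onto the common wavelength overlap, restricted to
the support of $S$. The prefactor is the standard form from the imaging
literature; on 1–5 nm grids higher-order quadrature changes the result
by well under the 0.1% grid-refinement tolerance the tests enforce.
Energy radiance converts to photon flux per wavelength as
$v(\lambda)\,\lambda/(h c N_A)\cdot 10^6$ (CODATA constants); spectra
are binned by per-bin arithmetic means so per-nm units are preserved.

**Gain (OECF).** The opto-electronic conversion function maps exposure
$E$ to digital level $p$. Two fitted representations are provided.

## Biexponential route

$$ f(E) = a - b\,e^{-cE} - d\,e^{-gE}, \qquad a = b + d $$

The constraint enforces $f(0)=0$; $a$ is the notional limiting output
approached at large exposure. $b, d$ are amplitudes in pixel-intensity
levels (bounded by the bit-depth ceiling), $c, g$ rates in inverse
photon-amount units. The model captures the two empirical regimes of
consumer-camera gain — steep response at low light, compression towards
saturation — with only four free parameters, and covers the whole
curve, so no minimum-response cut-off is needed.

*Fitting* (`fit_biexp()`) is bounded least squares (`nls`, port
algorithm; `optim`/L-BFGS-B fallback) under a multi-start grid: rate
starts log-spaced over two decades from `1/E_span`, the faster rate
assigned to $c$; amplitude starts split the maximum response evenly.
Two-exponential models are initialisation-sensitive, hence the grid;
the exponentials are exchangeable, so fits are reported under the
tie-break $c \ge g$. 95% CI half-widths are $1.96\,\mathrm{SE}$ from
the Gauss–Newton covariance; the normal matrix is inverted through an
SVD pseudoinverse so the rate-degenerate case $c \approx g$ (a single
exponential) still yields a fit and finite intervals. The working
maximum `e_max` is *derived* from the fit by solving $f(E) = g_{max}$
rather than imposed as a second constraint.

*Inversion* (`invert_biexp()`) brackets the root geometrically, solves
with `uniroot` (tolerance $10^{-12}$ of the bracket) and polishes with
Newton steps, giving $|f(f^{-1}(p)) - p| \le 10^{-9} a$ and round-trip
errors at machine precision. Responses at or above the asymptote have
no solution and raise an error.

## Cubic Bézier route

On normalised axes the OECF is fitted by
$B(t) = \sum_i \binom{3}{i}(1-t)^{3-i} t^i P_i$, $t \in [0,1]$.
$P_0$ and $P_3$ are pinned to the minimum and maximum data points (four
free scalars remain, the same count as the biexponential). Each data
point receives a chord-length parameter value and the interior control
points solve a linear least-squares problem on the Bernstein design.

**Parameter correction.** One correction pass (the default) refines the
interior control points and the per-point parameter values *jointly* by
damped Gauss–Newton with an analytic Jacobian, endpoints and
$t_1 = 0, t_n = 1$ held fixed. The classical alternation — project
points onto the curve, refit linearly, repeat — was implemented first
and found to stall: the geometric residual barely identifies the
parameterisation (a reparameterised cubic traces nearly the same
points), so alternation creeps at ~$10^{-3}$ per pass. The joint update
removes that degeneracy and recovers exact generating curves to
machine precision in one pass; step halving guards noisy data. Passes
are configurable (`correction_passes = 0` gives the plain chord-length
fit).

**Normalisation protocol.** Responses divide by $2^{bit} - 1$ (255 for
8-bit), exposures by `e_max`, the exposure producing the working
maximum $g_{max}$. Note the axes use different anchors: normalised
responses top out near $g_{max}/255 \approx 0.96$, which is why the
packaged calibrations' top control points sit at 0.94–0.96, not 1.
$g_{max}$ defaults to 250 of 255 — just below saturation, avoiding
clipped levels whose distribution breaks the gain model. Below
`p_min` (packaged values: 31 and 37 levels for the two cameras)
responses follow a different distribution; `filter_p_min()` removes
them (boundary retained) before single-segment Bézier fitting.
`fit_bezier_segments()` covers the full curve including the low region
with C⁰-continuous segments, at the cost of LUT values that cluster
per segment instead of covering the curve uniformly.

**LUT inversion.** `build_lut()` evaluates the curve at 256 uniformly
spaced $t$ values and stores the samples axes-swapped, i.e. as ordered
(response, exposure) pairs; `lut_lookup()` interpolates linearly
between bracketing entries. Monotonicity of $y(t)$ is required (the
table is otherwise not a function) and of $x(t)$ *validated, not
imposed*: a non-monotone fit carries a warning flag but remains usable
for analysis. The packaged red and green calibrations are themselves
slightly non-monotone in $x$ under their verbatim published
coordinates — the warning is expected there. LUT round-trip error is
bounded by half the node spacing and shrinks as the table grows; the
tests check 256 against 4096 entries.

## Uncertainty propagation

**Monte-Carlo bounds** (`sample_coefficients()`, `mc_linear_bounds()`).
Each coefficient is drawn independently from a Gaussian centred on its
fitted value with SD = CI half-width / 1.96 (the normal 95% quantile;
the source intervals are reported as symmetric 95% bounds). Under the
$a = b + d$ constraint, $a$ is recomputed per draw rather than sampled.
Draws violating positivity are redrawn and counted. For each of 256
response levels spanning $[0, g_{max}]$ (biexponential) or the curve's
response range (Bézier) every draw is inverted and the mean/SD of the
recovered exposure recorded. Biexponential inversion inside the
simulation uses a vectorised monotone-grid start plus Newton steps —
numerically identical to `invert_biexp()` at the tested tolerances but
hundreds of times faster than per-level root finding.

Draws whose asymptote falls below the top requested level cannot be
inverted there and are dropped with a warning above 5%. With the
packaged red-channel intervals roughly a third of draws are dropped:
$a = b + d \sim N(260, \approx 24^2)$ sits close to $g_{max} = 250$.
That is a property of the published intervals, not of the
implementation; the SD-versus-level curve (`sd_curve()`) still shows
the expected behaviour — near-zero SD at low levels (the constraint
pins $f(0) = 0$ regardless of the draw), roughly linear growth
mid-range, and a sharp rise to the maximum at $g_{max}$, which is the
practical argument for keeping the working range below saturation.
For the Bézier route both uncertainty axes are reported: the SD of the
recovered exposure at fixed response, and the SD of the curve's
response at fixed $t$.

**Bootstrap control-point intervals** (`bootstrap_bezier()`). The curve
is refitted on `n_boot` subsets of `subset_size` points (default
1000 × 32, drawn without replacement from the measurement set) and 95%
half-widths taken as 1.96 × SD across replicates. A design choice was
open here: with fully random subsets the subset extremes — which pin
$P_0$/$P_3$ — wander along the curve, so even noiseless data on an
exact Bézier produce scattered replicate fits (a sub-arc of a cubic
Bézier is a *different* cubic Bézier). The default therefore anchors
every subset to the full data's two extreme points
(`anchor = "global"`), restoring the identity "noiseless exact data ⇒
zero-width intervals" and making the intervals measure curve-sampling
spread; the fully random variant remains available as
`anchor = "subset"`. With-replacement resampling is a flag.

## Synthetic data: the stated world

`simulate_oecf()` emulates the measurement protocol: an exposure ladder
(by default the neutral-density set OD {0, 0.1, 0.2, 0.3, 0.5, 0.7,
1.0, 1.2, 1.5} — four physical filters, their stacked combinations and
the open beam — based at the exposure giving $g_{max}$), the true
biexponential gain, additive Gaussian read noise in intensity levels
(default SD 1), clamping and 8-bit quantisation; 96 points total,
spread round-robin over the ladder. Noise is Gaussian rather than
Poisson because the characterisation pipeline treats uncertainty as
normal throughout; a shot-noise-dominated sensor would need the
per-photoelectron variant. The generator does *not* emulate
fixed-pattern noise, vignetting, chromatic effects or demosaicing
artefacts, so a green round-trip test establishes correctness of the
inversion chain, not robustness to structured sensor error.
`simulate_image()` renders ground-truth exposure maps with a dark
offset and matching dark frame for the image pipeline.

Default truth parameters are the packaged published coefficients, so
synthetic fixtures stay anchored to a real camera. Parameter-recovery
experiments (96 points, noise SD 1, 200 seeded replicates) must recover
each coefficient with median relative error ≤ 10%; the acceptance
suite runs exactly that.

## Image pipeline

`linearize_image()` chains dark subtraction (clipped at zero — negative
differences have no physical meaning for intensity levels), response
normalisation, per-pixel inversion and rescaling by `e_max`. Both
methods invert through a precomputed $2^{bit}$-entry table, exact at
integer levels, so cost is one lookup per pixel regardless of method.
Pixels at or above $g_{max}$ are flagged saturated and assigned the top
exposure; pixels below the Bézier `p_min` are flagged and assigned the
lowest linearisable exposure. The 50×50 ROI sampler anchors its window
top-left at `floor(dim/2) − 25`, a deterministic "image centre" within
one pixel. Output units are either µmol-equivalents (× `e_max`) or the
normalised [0, 1] exposure scale. TIFF I/O is a minimal baseline
(uncompressed greyscale, 8/16-bit, little-endian) reader/writer — the
formats this package itself produces — not a general TIFF library.

## Method comparison

`sse()` is the plain sum of squared errors between measured and
recovered exposures. `wilcoxon_signed_rank()` drops zero differences
(Wilcoxon's original treatment; the dropped count is reported), ranks
with midranks, uses $W = \min(W^+, W^-)$ and reports two-sided
p-values: exact via convolution over doubled ranks (integers even with
midranks) for $n \le 12$ in auto mode, else the tie-corrected normal
approximation with continuity correction. The exact path is validated
against brute-force enumeration of all $2^n$ sign assignments in the
tests.

## Numerical choices, in one place

- Solver tolerances: `nls` default port tolerances with 200 iterations;
  inversion bracket tolerance $10^{-12}$, Newton polish to
  $\sim 10^{-15}$ relative.
- Biexponential bounds: all coefficients in $(0, \infty)$, amplitudes
  additionally $\le 2^{bit}$.
- Tie-breaks: $c \ge g$ (exchangeable exponentials); `p_min` boundary
  responses retained; even-dimension ROI anchored at centre − 25.
- Degenerate inputs: $c = g$ handled by pseudoinverse covariance;
  collinear Bézier data reproduce the straight chord; zero-width CIs
  propagate to exactly zero SD bounds.
- Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; equal seeds give bit-identical results.

## Known limitations

- The published coefficient tables carry a unit inconsistency (rates
  printed per mol, exposures per µmol; the printed `e_max` values are
  not reproduced by solving $f(E) = g_{max}$ with the printed
  coefficients under either reading). Fixtures store the printed values
  verbatim and carry `e_max` as a separate anchor rather than silently
  "fixing" either number.
- Published Bézier x-coordinates are non-monotone for two channels;
  curves are flagged, not repaired.
- No RAW demosaicing, colour-space handling, flat-field/vignetting
  correction or spectroradiometer drivers: the pipeline consumes
  post-conversion greyscale-per-channel TIFFs.
- Coefficient draws in the Monte-Carlo are independent (no fit
  covariance), matching how the source intervals are reported; with
  strongly correlated fit parameters this overstates the bounds.
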