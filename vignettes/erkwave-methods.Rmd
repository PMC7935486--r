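---
title: "Mechanochemical ERK waves and tissue-flow quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanochemical ERK waves and tissue-flow quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erkwave)
```

This vignette documents the scientific content of `erkwave`: the
mechanochemical cell-chain model, the image-quantification pipeline, the
synthetic-data generators used to validate both, and the numerical and
design choices made where more than one construction was defensible.

## The 1D mechanochemical cell chain

The growing cochlear-duct epithelium is idealised as `N` cells in a line,
each a linear spring of constant $k$ and rest length $L$, joined at
junctions $x_1 < x_2 < \dots < x_{N+1}$ that move against a viscous
substrate friction $\eta_c$. Cell $j$ spans junctions $j$ and $j+1$ and
carries strain $\varepsilon_j = (x_{j+1}-x_j)/L - 1$, ERK activity $E_j$,
and contractile force $F_j$ applied at its rear junction (the cell
contracts at its rear to move forward):

$$\eta_c \dot x_i = k(\varepsilon_i - \varepsilon_{i-1}) + F_i, \qquad
  \eta_E \dot E_j = \tanh(\alpha\,\varepsilon_j) - E_j, \qquad
  \eta_F \dot F_j = \lambda E_j - F_j.$$

Stretching activates ERK (saturating, sensitivity $\alpha$, timescale
$\eta_E$); ERK drives contraction (amplitude $\lambda$, timescale
$\eta_F$); contraction of one cell stretches its basal neighbour. This
closed loop propagates activity from the apex toward the base — a
retrograde wave — while every junction is pulled apically, producing the
opposing cell flow.

### Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `eta_c` | junction friction | 40 | nN·min/µm |
| `k` | spring constant | 20 | nN |
| `L` | rest cell length | 5 | µm |
| `F_tip` | tip self-propulsion | 6 | nN |
| `alpha` | strain sensitivity | 3 | — |
| `eta_E` | ERK timescale | 30 | min |
| `eta_F` | force timescale | 10 | min |
| `lam` | force amplitude | 9 | nN |
| `N` | cells | 1000 | — |
| `dt` | Euler step | 0.01 | min |
| `w`, `v` | imposed wave half-wavelength / speed (uncoupled) | 84, 0.42 | µm, µm/min |

The integrator is plain forward Euler with all derivatives evaluated on
the incoming state; `dt` must stay below both relaxation timescales, and
any violation of the junction ordering aborts the run with the failure
time (this is how the anti-diffusive `elastic = "printed"` orientation,
kept for reference, announces itself).

### Two genuinely open constructions, and how they were fixed

**Elastic-term orientation.** Writing the elastic force on junction $i$ as
the tension difference of its two adjacent springs,
$k(\varepsilon_i - \varepsilon_{i-1})$, yields a diffusive, stable chain
whose linearisation has a travelling-wave instability with the correct
(retrograde) propagation direction. The index-reversed variant
$k(\varepsilon_i - \varepsilon_{i+1})$ is anti-diffusive and blows up
within simulated minutes; it is retained behind `elastic = "printed"`
purely so the instability is demonstrable.

**Moving boundary.** The model statement fixes junction $1$ and calls
junction $N+1$ "the moving boundary" driven by $F_{tip}$. A literal force
balance at a free end ($\eta_c\dot x_{N+1} = -k\varepsilon_N + F_{tip}$)
lets the last spring equilibrate against the tip force, after which the
near-tip oscillator dies and no sustained wave train survives. A
*kinematic* moving boundary — the tip junction advancing at its
free-motion speed $F_{tip}/\eta_c$ — keeps the tip region permanently
strained and acts as a pacemaker that emits waves with an emergent period
of roughly 400 min, the period implied by the measured 168-µm wavelength
at 0.42 µm/min. The kinematic form is therefore the default
(`tip = "kinematic"`), with the force balance available as
`tip = "force"`.

### The lag analysis protocol

`model_lag()` cross-correlates, per cell, the extension-shrinkage rate
$d\varepsilon_j/dt$ against the ERK activity rate $dE_j/dt$ (central
differences on a 1-min recording grid) and reports the median per-cell
peak lag. Negative lag means the strain rate leads. Defaults:

* duration 6000 min, transient discard 2000 min. The wave train needs
  ~2000 min to establish; afterwards the near-tip zone is quasi-steady
  for several full periods.
* analysis cells at $0.84N$–$0.90N$: the established wave train adjacent
  to the generation zone, where oscillations are near-sinusoidal. Deeper
  into the chain the oscillation saturates ($|\varepsilon|$ of order 1,
  $\tanh$ fully engaged) and waveform asymmetry drags the raw peak of the
  cross-correlation toward smaller magnitudes; the linear phase delay
  $\arctan(\omega\eta_E)/\omega \approx 28$ min at the emergent period is
  the mechanistically meaningful quantity and is what the near-tip zone
  reports.
* `xcorr_lag()` z-scores both series and normalises so that the identity
  pair peaks at exactly 1; ties at the peak break toward the smaller
  absolute lag. Its curve agrees with `stats::ccf` to 10 decimal places
  (a test asserts this), but the implementation is independent.

With these defaults the coupled regime gives a lag of $-27$ min and the
uncoupled regime $-3$ min; both are invariant under halving `dt`. In the
uncoupled regime the force still lags the imposed wave by
$\sim\arctan(\omega\eta_F)/\omega$, but strain responds to the force
*gradient* almost instantaneously, which is why the residual lag is only
a couple of minutes.

## The quantification pipeline

**FRET ratio.** Each channel is median-filtered (3×3) per frame, then
background-subtracted, then divided (FRET/CFP). Background defaults to
the mean of the darkest 1% of pixels per frame and channel — robust and
parameter-free on real movies — but can be a fixed pair of values or a
user region. Synthetic movies generated by this package contain no
background pedestal, so their analysis passes `background = c(0, 0)`;
with "auto" the texture floor itself would be subtracted and dim-pixel
ratios would destabilise. Pixels whose subtracted CFP is not positive get
`NA` ratios.

**PIV.** 40-px interrogation windows with 50% overlap; per window the
displacement is the peak of the zero-padded, overlap-normalised
cross-correlation (6 FFTs per window), refined per axis by a 3-point
Gaussian fit (parabolic fallback where logs are undefined), with
displacements capped at a quarter window. Textureless windows are flagged
invalid and later replaced by the neighbourhood median in
`median_filter_field()`. On band-limited textures integer shifts are
recovered to ~0.03 px and half-pixel shifts well within 0.2 px.

**Projection and strain rate.** The apex–base line is an ordered polyline
starting at the apex; window centers within one grid spacing are assigned
to their nearest point on it, and elongation speed is reported positive
toward the apex. The extension-shrinkage rate divides speed differences
of adjacent on-line windows by their arc separation and smooths with a
5-sample moving average (MATLAB-style shrinking window at the ends); the
unsmoothed rate telescopes exactly to the end-to-end speed difference.
Note one orientation subtlety: with speed positive toward the apex and
arc length growing away from it, this quantity is the negative of the
velocity divergence; the synthetic generator defines its ground-truth lag
in terms of exactly this pipeline quantity, so recovered lags compare
directly.

**Windowed ERK series.** Otsu's threshold on the CFP window isolates the
cytoplasmic region; activity is the mean ratio over that mask, `NA` for
empty masks with isolated gaps linearly interpolated; the rate is the
central-difference time derivative.

**Kymograph and wave speed.** Activity is sampled every half PIV spacing
along the line, averaged over a 20-px perpendicular band (bilinear
interpolation). `wave_speed()` estimates the dominant spatial wavelength
from the mean column spectrum, smooths each column over about a sixth of
it, thins maxima to half-wavelength separation, links them across frames
by nearest-to-predicted-position (the prediction extrapolates each
ridge's recent drift), drops maxima within a quarter wavelength of the
domain edges (partially visible crests pin there and flatten fits), fits
position against time per ridge with parabolic sub-sample refinement, and
averages per-ridge speeds weighted by ridge length, discarding ridges
shorter than half the longest. On 400 µm × 960 min phantoms with
amplitude-to-noise 6, speeds from 0.1 to 1.0 µm/min are recovered within
5%; a static stripe yields speed 0 (a vertical ridge, slope 0).

**Curvature and thickness.** Traced layers are interpolated with natural
cubic splines — parametric in chord length by default, since the coiled
duct is not the graph of a function; the graph form $y = S(x)$ with its
per-interval coefficient formula
$\kappa_i(x) = (6a(x-x_i)+2b)\,/\,(1+(3a(x-x_i)^2+2b(x-x_i)+c)^2)^{3/2}$
is retained for formula-level verification. Closed curves (first point
repeated) automatically switch to periodic end conditions, which removes
the end-flattening bias of natural ends; on evenly-sampled circles the
curvature is then exact to numerical precision, and the open-curve bias
stays confined to the end intervals. Curvature sign is positive where the
curve bends around the declared lumen point, independent of tracing
direction. The midline of a layer joins midpoints of the two contours
matched by normalized arc length (equivalent to the skeleton for
layer-like contours, and deterministic); thickness is the length of the
midline-normal chord clipped by the contours, falling back (flagged) to
nearest-vertex distances where a normal shoots past an open contour end.
`local_edge_curvature()` samples four points at 19-µm arc spacing
bracketing the reference two-a-side, fits the exact cubic interpolant,
and averages the curvature at the two central knots — for a cubic, knot
evaluations are markedly more accurate than mid-interval ones (1% vs 3%
error on a 50-µm circle), and their mean is a second-order estimate at
the reference.

**EdU mapping.** Stacks split at the middle z (middle slice to the floor
for odd counts); projections are max, sum, or duct-masked mean with
per-pixel denominators. Duct masks come from Otsu thresholding plus
closing (3-px disc), hole filling, and largest-component selection. The
partition places 21 equal-arc marks on the medial and lateral curves,
joins corresponding marks by chords, divides each chord into 10, and
forms 20×10 regions whose outer edges follow the duct curves; pixels are
assigned to the first containing region in index order, so the tiling is
exact (on a rectangular duct: 200 congruent rectangles). Region means are
normalized by 255. Cell density divides a counting domain into five equal
mediolateral sections and reports cells per µm².

## Synthetic data: what it emulates, and what it does not

`make_wave_movie()` builds a band-limited random texture (CFP), advects
it with a uniform apex-ward drift plus a small travelling oscillation,
and modulates FRET with a retrograde intensity wave; the oscillation's
phase is set so the pipeline's extension-shrinkage rate leads the ERK
rate by the requested lag. Defaults mirror the study conditions: 0.625
µm/px (a 40-px window is 25 µm, 4–5 cell diameters), 12-min frames, flow
0.24 µm/min toward the apex, wave 0.42 µm/min toward the base, wavelength
168 µm, deformation-to-ERK lag 24 min. Advection is sub-pixel sampling of
a static texture, so the true displacement is known exactly for PIV
validation. Geometric phantoms (circles, annuli, Archimedean spirals,
rectangular and annular-sector ducts, gradient volumes, Poisson point
fields) carry closed-form ground truth. Everything is bit-deterministic
under a fixed seed, and generators restore the caller's RNG state.

What the generator does *not* emulate: photon statistics (noise is
additive Gaussian on intensity), cell-scale texture evolution (the
texture is rigid under advection, only translated), out-of-plane motion,
photobleaching, and the curved 3D geometry of the real duct. Passing
tests therefore demonstrate correctness of the measurement operators
under controlled conditions, not robustness to every imaging artifact of
real FRET movies.

## Problem sizes used by the test-suite and validation runs

The model validation runs the full reference chain (N = 1000, dt = 0.01
min, 6000 simulated minutes); convergence and reproducibility properties
use a 300-cell chain over 3000 min, and qualitative properties
(boundedness, retrogradicity, equilibrium) 50–120 cells. Pipeline
validation uses 512×64-px movies of 30–48 frames, 80×80-sample kymograph
phantoms, and 200×60-px duct masks. These sizes keep every wave feature
several samples wide and several periods long, which is what the
estimators assume.

## Known limitations

* The coupled chain's late-time dynamics coarsen slowly (wave periods
  lengthen over tens of thousands of minutes); the lag protocol
  deliberately measures the established-but-not-yet-coarsened regime that
  the model's kymographs display.
* `wave_speed()` assumes a dominant wavelength; kymographs with several
  superimposed wavetrains of very different scales will be smoothed at
  the dominant one only.
* The midline construction assumes roughly parallel contours; strongly
  non-parallel tracings (branching layers) would need a true medial-axis
  method.
* PIV displacement is capped at a quarter window per frame pair; faster
  flows need a larger window or shorter frame interval.
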