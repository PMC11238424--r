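---
title: "Quantifying the glass transition of dense motile bacteria from image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the glass transition of dense motile bacteria from image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactglass)
```

## The system and the measurement problem

A quasi-two-dimensional population of motile, rod-shaped bacteria (E. coli:
width about 1 um, length 2-6 um) confined in a shallow circular well keeps
growing and dividing while it swims.  As the area fraction $\phi$ — the
fraction of the field of view covered by cells — rises toward dense packing,
the population's motion slows dramatically and eventually arrests without any
onset of positional or orientational order: a glass transition driven by
density, with activity instead of temperature.  Because the constituents are
rods, two families of degrees of freedom can arrest separately: the
orientations (nematic angles, defined modulo $\pi$) and the translations.
The arrest happens in two steps — an *orientation glass*, where the angle
field freezes while cells still rattle and occasionally escape their cages,
followed by a *complete glass* where translations arrest too.

Everything in this package works directly on time-lapse phase-contrast image
stacks (cells dark on a bright background), so no cell segmentation is
needed for the headline observables.  Per-cell analyses (tracking, velocity
correlations) are provided separately.

## Image-based observables

**Pre-processing.**  Frames are divided pixel-wise by a Gaussian-weighted
local mean (`correct_illumination()`; window default
$2\lfloor\min(H,W)/16\rfloor+1$ px, Gaussian $\sigma$ = window/4, symmetric
padding), which removes illumination gradients and normalizes intensities to
a local background of 1.  Analyses are restricted to a rectangular region of
interest away from the well perimeter (`crop_roi()`).

**Area fraction.**  `estimate_area_fraction()` clusters the pooled intensity
histogram with 3-class fuzzy c-means ($m=2$, tolerance $10^{-5}$, centers
initialized at the 0.1/0.5/0.9 quantiles, hence deterministic) and counts
pixels below a threshold placed midway between the *darkest and brightest*
class centers.  This "extremes" rule is a deliberate design choice: on
synthetic movies with known coverage it matches the true covered fraction to
better than 0.005 across densities and noise realizations, because the two
extreme centers are pinned by the dominant dark (cell) and bright
(background) modes, whereas the middle center — and therefore any rule built
on it — is bistable on nearly bimodal histograms.  Both alternative rules
(`"mid_high"`, `"low_mid"`) remain available.  $\phi$ is reported as the
mean over the frames of a group and its error as the standard deviation.

**Differential variance analysis.**  The elementary object is the intensity
difference $\Delta I(\vec r, t, \Delta t) = I(\vec r, t+\Delta t) -
I(\vec r, t)$.  Its variance over pixels and reference times,
$V(\Delta t)$, saturates at $V(\infty) = 2\,\mathrm{Var}(I)$ (pooled over
all pixels and frames of the group) when the scene has fully decorrelated,
giving the overlap function

$$Q(\Delta t) = 1 - V(\Delta t)/V(\infty),$$

an image-space proxy for the fraction of material that has not moved,
behaving like a self-intermediate scattering function.  All admissible
(sliding, overlapping) reference times are used; their statistical
dependence is accepted, as is standard.  Retaining the instantaneous
overlaps $Q(t, \Delta t)$ gives the dynamic susceptibility

$$\chi_4^Q(\Delta t) = \phi\left[\langle Q(t,\Delta t)^2\rangle_t -
\langle Q(t,\Delta t)\rangle_t^2\right],$$

the standard measure of dynamic heterogeneity; its peak grows and moves to
longer lags as the transition is approached.  The prefactor is the group's
*measured* $\phi$.  Lags are laid out pseudo-logarithmically
(`lag_frames()`), capped at half the group length, because relaxation
spans decades in $\Delta t$.

**Orientation field.**  `orientation_field()` computes a per-pixel nematic
angle $\theta(\vec r, t) \in [-\pi/2, \pi/2)$ from the structure tensor: the
Gaussian-smoothed outer product of intensity gradients, with the orientation
given by $\tfrac12\,\mathrm{atan2}\!\left(2\langle\Delta_x\Delta_y\rangle,\,
\langle\Delta_x^2\rangle - \langle\Delta_y^2\rangle\right)$ rotated by
$\pi/2$ so that the returned angle is the structure (rod-axis) direction.
Two scales enter, and keeping them distinct is essential: gradients are
computed with Gaussian-derivative filters at `deriv_sigma_px` (default 1 px)
while the tensor is pooled over a window `sigma_px` (default 6 px, about one
cell width at the reference pixel size of 0.1724 um/px).  A single shared
scale of 6 px would low-pass the image *before* differentiation and
suppress the micron-scale lateral packing signal by
$e^{-\sigma^2 k^2/2}\sim10^{-3}$; on stripe patterns and rendered rod
lattices the resulting field is essentially noise (about 30 degrees median
error), while the split-scale estimator reads test patterns exactly and
tracks per-rod ground truth within 5 degrees median on rendered movies at
moderate density.  Flat regions (tensor trace below $10^{-6}\times$ the
frame intensity variance) are masked (`NA`), never assigned an angle.
Angles follow the physical convention: measured from $+x$, counterclockwise
with $y$ pointing up; image rows grow downward and the gradient sign is
flipped accordingly.

The orientational correlator and susceptibility mirror the translational
pair:

$$C_\theta(\Delta t) = \langle\cos 2[\theta(\vec r, t+\Delta t) -
\theta(\vec r, t)]\rangle_{\vec r, t}, \qquad
\chi_4^\theta(\Delta t) = \phi\,\mathrm{Var}_t\,C_\theta(t, \Delta t).$$

The $\cos 2(\cdot)$ respects the nematic symmetry automatically; masked
pixels are excluded pairwise.  All angle differences anywhere in the
package go through `nematic_diff()`, which wraps into $[-\pi/2, \pi/2)$.

**Microdomains.**  Dense rod populations organize into microdomains of
nearly common orientation.  `orientation_gradient_sq()` computes
$|\nabla\theta|^2$ (central differences of `nematic_diff`, one-sided at the
image edge, in (rad/um)$^2$); pixels at or above a threshold — default
$10^{-2}$ (rad/um)$^2$ applied to the *squared* gradient, the
dimensionally consistent reading, with the exponent exposed as a knob —
are boundaries, and the rest is partitioned into 4-connected components
(4-connectivity avoids diagonal leakage through 1 px boundaries; components
under 4 px are quantization debris and dropped).  Domain areas are
exponentially distributed, $P(A)\propto e^{-A/A_0}$; `fit_domain_areas()`
estimates $A_0$ by the left-truncated maximum-likelihood estimator
$\hat A_0 = \overline{A - A_{\min}}$ (binning-free, with a well-defined
normal-approximation confidence interval) rather than histogram regression.
Tallies with and without border-touching domains are both available via the
`touches_border` flag, since either convention is defensible.

**Static structure factor.**  `static_structure_factor()` averages the
squared modulus of the 2D FFT of mean-subtracted frames, normalized by the
pixel count, and bins it into annuli one frequency step wide (DC excluded);
the frame mean is removed because the raw transform is otherwise dominated
by the $q=0$ peak.  No window function is applied by default (a Hann option
exists).  The overall normalization is arbitrary in the same sense the
plotted quantity is; Parseval consistency is enforced by test.

## Relaxation times and their divergence laws

`fit_stretched_exponential()` fits $a\,e^{-(\Delta t/\tau)^\beta}$ by
Levenberg-Marquardt with a deterministic multi-start over
$\beta\in\{0.5,1,1.5\}$, $\tau$ and $\beta$ on the log scale, $a\in(0,1.5]$,
$\beta\le 2$; 95% intervals come from the linearized covariance.  A curve
that never decays below $a/e$ inside the window cannot pin $\tau$ from
above: by default this errors, and with `accept_extrapolated = TRUE` the
fit is flagged `censored` and treated as a lower bound.  Censored groups
are excluded from the divergence-law fits — near the transition the
relaxation time exceeds any practical observation window, and pretending
otherwise would bias the laws.

Two standard divergence laws are fitted to $\tau(\phi)$, both by
Levenberg-Marquardt on $\log\tau$ (uniform weights in $\log\tau$, since
$\tau$ spans decades; this also makes the fits exactly invariant under
$\tau \to a\tau$):

* the mode-coupling (MCT) power law $\tau\sim(\phi_c-\phi)^{-\gamma}$,
  with $\phi_c$ a free nonlinear parameter constrained to
  $(\max\phi, 1]$;
* the Vogel-Fulcher-Tammann law, committed here as
  $\tau \sim A\exp[c\,\phi/(\phi_{VFT}-\phi)]$, with the variant
  $A\exp[c/(\phi_{VFT}-\phi)]$ behind `variant = "simple"` because the
  literature writes both forms.

`compare_channels()` propagates the two channels' $\phi_c$ standard errors
into a confidence interval on $\phi_c^\theta - \phi_c^Q$ and reports
whether the orientational channel vitrifies first at the 95% level.

For context, `mct_thermal_gamma_min()` solves the thermal MCT exponent
relations $\lambda = \Gamma(1-a)^2/\Gamma(1-2a) =
\Gamma(1+b)^2/\Gamma(1+2b)$, $\gamma = 1/(2a) + 1/(2b)$: $\gamma(\lambda)$
increases on $\lambda\in[1/2,1)$, and at $\lambda = 1/2$ (where $b=1$
exactly) it attains its minimum $\gamma_{\min}\approx 1.765$.  A measured
$\gamma$ below this bound is impossible for a thermal glass former and is
therefore a signature of athermal (active) dynamics.

## Per-cell kinematics

`segment_cells()` is a deliberately classical segmenter (fuzzy-c-means
threshold on the darkest class, morphological opening, distance-transform
watershed, second-moment ellipses); it is adequate for dilute-to-moderate
scenes and validation work, not a replacement for learned segmentation in
fully jammed images.  `link_tracks()` solves each frame-to-frame
correspondence *exactly* — a Hungarian assignment on the standard augmented
cost matrix with birth/death cost `max_disp_um^2` — rather than greedily;
detections are canonically ordered first, so the result is invariant under
permutation of the input and ties resolve deterministically.  Mothers are
not joined to daughters: a division ends a track, keeping per-cell
displacement statistics clean.  On top of tracks sit
`displacement_orientation_histogram()` (motion is strongly concentrated
along the body axis), `velocity_correlation()` (equal-time
$\langle\vec v_i\cdot\vec v_j\rangle$ binned in pair distance, standard
errors treating pairs as independent; default velocity lag 2 frames
$\approx 0.053$ s, bins 0.5 um), and a descriptive cage-escape flag
(window displacement > 2 cell widths in 2 s).

## The synthetic-data generator

`simulate_rods()` is a first-class module, not a test fixture: overdamped
Langevin dynamics of 2D spherocylinders that self-propel along their body
axis (signed speed; nematic angle representative in $[-\pi/2,\pi/2)$ with
the polarity carried by the sign, flipped consistently on wrap), repel
harmonically through the closest-point overlap of their axis segments
(the contact force also exerts the torque of its lever arm, which is what
builds nematic microdomains), elongate exponentially, and divide
symmetrically at a set length into daughters with fresh identities,
resampled speeds, and a small (0.05 rad) orientation kick.  Integration is
explicit Euler-Maruyama; the step is snapped to an integer divisor of the
frame interval so simulated time is exact, and a non-finite state aborts
with a message naming the step to reduce.  A harmonic wall confines rod
centers; the invariant $|\vec r| \le R$ is additionally enforced exactly.

`render_frames()` rasterizes dark spherocylinders on a bright background at
the reference optical scales (pixel 0.1724 um; blur $\sigma$ =
0.258 um / 2.355, reading the optical resolution as a FWHM; additive
Gaussian noise, seeded), and `ground_truth()` returns the per-pixel angle
truth, exact coverage, and true track table against which the analysis
chain is validated.

Deliberate defaults, chosen once at values realistic for this organism and
geometry: well radius 35.6 um; rod width 1 um; initial lengths
U(2.5, 4.5) um with division at 5 um (so lengths roam roughly 2.5-5 um,
matching the observed 2-6 um range without attempting its exact
distribution); speed scale 2 um/s with lognormal spread 0.2;
$D_t = 0.01\ \mu m^2/s$, $D_r = 0.05\ \mathrm{rad}^2/s$; repulsion
stiffness 100 (mobility units), mobility 1, rotational mobility
$12\mu/L^2$ (slender-rod scaling); growth rate $3.5\times10^{-4}$/s
(about a 33 min doubling); dt = 1 ms; frame interval 0.0263 s.

One optional behavior, `wall_reversal`, flips a rod's run when it pushes
outward at the wall.  Without it, *non-interacting* swimmers in a closed
well accumulate at the boundary and the bulk drains, so no statistically
stationary movie exists; with it (boundary run reversal is documented
E. coli behavior under confinement) the density stays uniform.  It is off
by default and switched on where a stationary non-interacting reference
movie is needed.

**What the generator does and does not emulate.**  It produces dense
nematic microdomains, motion along the body axis, growth/division, and a
density-controllable slowdown — the statistical structure the analysis
assumes.  It does not model run-and-tumble chemotaxis, hydrodynamic
interactions, 3D buckling, or phase-contrast halo optics, and seeded
configurations above the random-sequential-addition limit contain residual
overlaps.  Passing tests on rendered movies therefore validate the
*analysis machinery* against known truth; they do not certify biological
realism of the dynamics.

## Validation design and problem sizes

The test suite validates every operation against an independent oracle:
exhaustive double loops for $Q$, $\chi_4$, $C_\theta$ and a naive
$O(N^4)$ DFT for $S(q)$ on toy stacks; textbook fuzzy c-means; brute-force
enumeration of all partial matchings for the tracker; closed forms
(rigid translation, rigid rotation, stripe patterns) elsewhere.  Problem
sizes are deliberately modest so the whole suite runs in about a minute:
validation movies are 60-200 frames at 64-190 px, wells of radius
7-16 um with tens of rods.  Two larger end-to-end checks are part of the
suite's design:

* an imposed-slowdown series (`mct_movie_series()`): eight fixed-density
  phantom-rod movies (interactions off, wall reversal on; 200 frames at
  64 x 64 px) whose per-level speeds follow
  $v(\phi)\propto(\phi_c-\phi)^{\gamma}$ with generating parameters
  $\phi_c = 0.882$, $\gamma = 1.6$ — experimentally realistic values for
  dense E. coli — so the movie decorrelation time ($\propto 1/v$) follows
  the matching MCT law.  Interactions are disabled in this series because
  crowding would superpose its own slowdown on the imposed law.  The full
  chain (overlap function, stretched-exponential fits, MCT fit) recovers
  $\phi_c$ with its 95% interval covering the generating value across
  seeds;
* a stationarity check of $S(q)$ between disjoint halves of a well-mixed
  movie, compared per annulus in relative terms after discarding the
  mixing transient and the sparsest annuli, whose scatter is dominated by
  the finite number of Fourier modes.

## Known limitations

* The structure-tensor field degrades gracefully but measurably in scenes
  with heavy unphysical overlaps (phantom seeds above jamming); accuracy
  statements are made at moderate density against generator truth.
* The classical segmenter cannot split truly flush parallel rod pairs whose
  separating gap is far below the optical resolution — that information is
  not in the image; the watershed handles blur-bridged pairs.
* Censored (non-relaxing) groups contribute no $\tau$; with few relaxing
  groups the nonlinear $\phi_c$ is weakly constrained and its interval wide.
* The area-fraction threshold rules are calibrated against rendered optics;
  strongly different imaging modalities may prefer a different rule — all
  three are exposed.

## A compact end-to-end example

```{r example, eval = FALSE}
# simulate and render a fluid-phase movie
p <- sim_params(area_fraction = 0.45, well_radius = 7, speed = 1.5,
                wall_reversal = TRUE, growth_rate = 0,
                duration = 60 * 0.0263, seed = 21)
stack <- render_frames(simulate_rods(p), optics_params(dim_px = c(88, 88)),
                       seed = 71)
stack <- crop_roi(stack, list(x = 25, y = 25, w = 40, h = 40))

res <- run_analysis(stack, analysis_config(group_size = 30))
print(res)

q <- res$groups[[1]]$q_curve
plot(q$lags, q$values, log = "x", xlab = "lag (s)", ylab = "Q")
```
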