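---
title: "Methods: lamellar diffraction analysis and its forward model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lamellar diffraction analysis and its forward model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellar)
```

## The model

An oriented multilayer of membranes with repeat distance $d$ diffracts at
$q_h = 2\pi h / d$. The measured quantity per reflection is the integrated
Bragg intensity $I_h$; the reconstruction target is the periodic,
centrosymmetric neutron scattering length density (NSLD) profile

$$\rho(z) \;=\; \frac{2}{d}\sum_{h=1}^{n} V_h\, |F_h|\,
  \cos\!\left(\frac{2\pi h z}{d}\right),$$

band-limited to the $n$ observed orders, with amplitudes
$|F_h| = \sqrt{I_h\, C_\mathrm{abs}\, C_\mathrm{Lor}\, C_\mathrm{flux}}$
and signs $V_h$ (the centrosymmetric phase problem). Key assumptions:

* the stack is centrosymmetric and well oriented, so a cosine-only series
  suffices (`structure_factors_from_profile()` refuses profiles that are
  not even within tolerance);
* intensities are Poisson counts; all uncertainties propagate from
  $\sqrt{N}$ counting errors;
* the sample is a thin film in reflection, giving the correction
  geometry below.

### Intensity corrections

* **Absorption** $C_\mathrm{abs} = \alpha/(1 - e^{-\alpha})$ with
  $\alpha = 2\mu t/\sin\theta$: the in-plane path grows at grazing
  incidence. The variant $\alpha = 2\mu t \sin\theta$ is exposed
  (`geometry = "times_sin"`) because the source text for this correction
  is typographically ambiguous; the reflection geometry is the default.
* **Lorentz** $C_\mathrm{Lor} = \sin 2\theta$.
* **Flux** $C_\mathrm{flux} = 1/\mathrm{erf}\!\big(L\sin\theta/(\sqrt8\,
  \delta)\big)$: a Gaussian beam of width $2\delta$ overfills a sample of
  length $L$ at small angles. The denominator convention
  ($\sqrt8\,\delta$ vs $8\delta$) is a config option
  (`flux_denominator`), default `sqrt8`.

All three tend to 1 in their physical limits ($\mu t \to 0$,
$\theta = 45^\circ$, $L\sin\theta \gg \delta$), which the tests assert.

### d-spacing

Peak positions are converted to $q_h = 4\pi\sin\theta_h/\lambda$
($\lambda$ default 4.487 Å) and fitted by weighted least squares
$q_h = s\,h + b$; then $d = 2\pi/s$ and $\sigma_d = 2\pi\sigma_s/s^2$.
The intercept is free — it absorbs a zero-angle misalignment and is
flagged when significant. A literature formula of the form
$d = \lambda/\Delta q$ is dimensionally inconsistent when $q$ is in
Å$^{-1}$; the $q$-space fit used here is self-consistent with the
single-peak rule $d = 2\pi/q_1$ that applies when only one order is
observed, and the two agree to machine precision on exact input.

### Phase assignment

All $2^n$ sign vectors are enumerated ($n \le 4$ in practice, so 16
hypotheses). The global sign is fixed by requiring $\rho(0) \le 0$ (the
midplane of a lipid stack at 8% D2O is occupied by low-density aliphatic
ends). Two constraints follow the physics of these films:

1. $\rho(0)$ is the minimum of the central region $|z| \le d/8$;
2. the profile's global maxima lie in the polar-head window
   $|z|/(d/2) \in [0.5, 0.95]$ (configurable).

Hypotheses passing both are ranked by the **density at the centre of the
water gap** $z = \pm d/2$, lowest first. At the 8% D2O "null water"
contrast the gap scatters essentially nothing, so a correct sign set
leaves it empty. This ranking has a useful exactness property: for a
truth of the family $[-, -, +, -]$, flipping any single sign $V_h$
($h \ge 2$) changes the gap value by $-2 V_h |F_h| (-1)^h > 0$, i.e.
*every* wrong vector in the $\rho(0)\le 0$ branch has a strictly higher
gap density, independent of the amplitude magnitudes. Ranking by the
depth of the central minimum alone cannot work — the all-negative vector
maximises the central depth *by construction* whatever the data — which
is why the gap criterion is the ranking key; the central depth is still
reported per hypothesis. With fewer than 3 orders the search refuses:
two orders cannot resolve the headgroup region and would produce a
misleading profile.

### Metrics

* `bilayer_thickness()`: $d_b$ = twice the position of the head peak
  (largest local maximum at $z > 0$), refined by parabolic interpolation
  through the three surrounding grid points.
* `water_thickness()`: $d_w = d - d_b$, exact.
* `trough_depth()`: $\max\{\rho\ \mathrm{over}\ |z| \le d/8\} - \rho(0)$,
  counted only when the profile has a shoulder (an interior local
  maximum besides the head peak); a profile that rises monotonically
  from the midplane (e.g. a single-order $-\cos$) has no trough.
* `hump_metric()`: largest local maximum strictly between $d/8$ and the
  head peak, with amplitude measured above the chord joining
  $\rho(d/8)$ and $\rho(z_\mathrm{head})$.
* `component_decomposition()`: see below.

## The forward simulator

`fixture_preset()` encodes four sample archetypes of archaeal-lipid
films as sums of mirrored Gaussian components (headgroup pair, CH2 pair,
CH3 singlet at $z=0$, water at the gap edge):

| label | orders | headgroup amp. | CH2 (hump) | CH3 (trough) |
|-------|--------|----------------|------------|--------------|
| D     | 3 (95% RH) / 2 (80% RH) | 0.2 | — | $-0.25$, $\sigma$ 5 Å |
| T     | 4 | 1.0 (reference) | $+0.38$ at $\pm 11$ Å | — |
| DT11  | 4 | 0.6 | $+0.15$ | $-0.10$ |
| DT21  | 4 | 0.47 | $+0.11$ | $-0.16$ |

Lamellar periods and head-to-head distances per (label, temperature,
humidity) come from a packaged table of the study conditions this
generator emulates (periods 47–56 Å, $d_b$ 36–44 Å, 60–90 °C, 80/95% RH);
intermediate conditions interpolate linearly — a fixture behaviour, not a
physical claim. The water amplitude scales with the D2O fraction and
vanishes at 8% ("null water"); headgroup amplitude softens slightly with
temperature. NSLD amplitudes are arbitrary units throughout (no absolute
scale is ever needed; the tetraether headgroup amplitude 1.0 is the
reference).

The component geometry was chosen, once, under four simultaneous
requirements verified numerically over the whole condition grid: (i) the
implied structure-factor signs form the $[-,-,+,(-)]$ pattern expected of
phased data from such films; (ii) the true vector passes both phase
constraints and tops the gap-density ranking at every condition; (iii)
the diether-richer mixture has the deeper midplane trough; (iv) the
weakest rendered order stays detectable (the tetraether third order
carries $\sim 6\times 10^{-4}$ of the first-order intensity — this sets
the peak-detection default `min_prominence = 2e-4`). Requirement (i) is
why the CH2 pair sits at $\pm 11$ Å rather than exactly $\pm 10$: at
$\pm 10$ the third-order moment of the tetraether mix turns negative.

Rendering: Gaussian peaks of fixed $2\theta$ width (default
$\sigma = 0.15^\circ$; the instrumental line shape is not otherwise
specified) with areas $I_h \times$ `counts_scale`, a linear background,
and optional Poisson noise under an explicit seed. 2D $\Omega$-maps add a
Gaussian mosaic ridge per order (weights normalised per column so ROI
integration reproduces the 1D pattern exactly) over the scan range
$-1^\circ$ to $13^\circ$ in $0.05^\circ$ steps. Instrument defaults
($\mu t = 0.1$, $L = 50$ mm, $\delta = 1$ mm, background 20 counts/bin,
`counts_scale` $10^5$) are realistic for a cold-neutron membrane
diffractometer; only the wavelength and the scan range are fixed by the
emulated setup.

### What a green test does and does not establish

The generator produces idealised data: exactly Gaussian peaks on an
exactly linear background, exact Poisson statistics, no detector
artefacts, no mosaic asymmetry, no sample misalignment, and components
drawn from the same Gaussian family the decomposition assumes. Parameter
recovery on these fixtures validates the *algebra and statistics* of the
chain — corrections, fitting, error propagation, phase logic, Fourier
synthesis — not its robustness to real-world systematics (peak-shape
misfit, background curvature, calibration drift).

### The band limit and $d_b$

A 3–4-order truncated cosine series cannot place its head maximum
arbitrarily: the fourth-order ridge attracts it toward $3d/8$. An
exhaustive scan over sign-family amplitude patterns shows head positions
at $0.77$–$0.80\,d$ (the regime of these films) are only reachable when
the higher orders are weak, i.e. when trough and hump are absent from
the reconstruction. Consequently the pipeline's band-limited $d_b$ sits
$0.8$–$2.3$ Å below the generator's head-to-head distance, a truncation
bias that is a property of the method, not a bug; real measurements at
the same band limit carry it too. The package therefore treats the
$\pm 0.5$ Å figure quoted for $d_b$ as what it is — a counting-noise
resolution: across seeded Poisson replicates the recovered $d_b$ scatters
about the noise-free value with median error far below 0.5 Å (the
acceptance suite measures $\sim 0.01$ Å at `counts_scale` $10^5$). The
analytic (non-band-limited) preset profiles do carry the tabulated
$d_b$ exactly, and `bilayer_thickness(build_profile(preset))` returns
it.

For the same reason the reconstruction's hump shoulder appears near
$d/6$ regardless of where the generating CH2 pair sits; the hump-position
check is therefore made on the analytic profile, where the metric
recovers the generator's CH2 centre.

## Component decomposition

With only 3–4 cosine moments, a three-moiety Gaussian model with free
centres and widths is under-determined — we verified that a model
*without* any CH3 term reproduces every fixture's moments to numerical
zero, so no data-driven criterion can apportion density between CH3 and
the other moieties. The decomposition is therefore a *reconstruction
under declared priors*: widths fixed at 2.6 / 3.0 / 3.5 Å (headgroup /
CH2 / CH3), CH2 centre fixed at $\pm 11$ Å, headgroup centre searched
within $d_b/2 \pm 2$ Å (fixed at $d_b/2$ when only 3 orders exist), and
the three amplitudes solved by linear least squares with sign
constraints (headgroup $\ge 0$; CH3 $\le 0$, aliphatic density being
negative at 8% D2O). A relative residual above 20% flags the result
unreliable. When a 100% D2O profile is available the water curve is the
amplitude-aligned contrast difference (`water_profile_by_contrast()`),
aligned on the chain region $|z| \le 0.3\,d$ where water tails are
negligible; otherwise water is taken as $\approx 0$ per the 8% contrast.

## Numerical choices

* **Grids**: profiles live on $z_j = -d/2 + j\,d/N$, $N = 512$ by
  default (>60-fold oversampling of a 4-order band limit; $N$ even so
  $z = 0$ is a grid point). Cosine moments use the rectangle rule on
  this grid — spectrally accurate for smooth periodic integrands and
  *exactly* unitary against `synthesize_profile()` (discrete
  orthogonality; the round trip is tested at $10^{-10}$).
* **Peak fitting**: simultaneous Gaussians + shared linear background,
  weighted by $1/\sigma^2$, BFGS with a Nelder–Mead fallback; parameter
  covariance from the Gauss–Newton $J^\top W J$; reduced $\chi^2$
  recorded so misfit is visible. Candidates closer than one estimated
  width are merged before fitting; a fitted area that comes out
  non-positive drops its peak with a warning.
* **Order indexing**: peaks are indexed on the best arithmetic
  progression in $q$ (candidate spacings from all $q_i/m$; most inliers
  within 10% wins, larger spacing breaking ties so the fundamental is
  preferred); off-progression peaks are flagged non-lamellar and
  excluded from the d-spacing fit but kept in the set.
* **Detection**: running-median background, 5-point smoothing,
  plateau-tolerant local maxima, classic prominence with strict-ascent
  terrain (so exact ties in smoothed integer counts do not erase a
  peak), threshold `max(min_prominence * strongest, 5 * median(sigma))`.
* **Degenerate inputs**: empty candidate lists, all-zero profiles,
  single-order profiles, 2-order refusals and corrupted grid rows all
  have defined, tested behaviour; batch analysis
  (`analyze_condition_grid()`) never aborts on a single failed row.
* **Seeding**: every stochastic operation takes an explicit integer
  seed, restores the caller's RNG state, and records the seed in the
  output metadata; identical config + seed gives byte-identical files.

## Known limitations

* No refinement of wavelength or zero-angle offset from the data; no
  per-pixel detector corrections or absolute NSLD units (arbitrary
  scale).
* The truncation bias of $d_b$ (above) is inherent at 3–4 orders.
* The decomposition's moiety attribution is only as good as its priors;
  with real data whose component widths differ from the priors the
  amplitudes shift accordingly (the relative-residual flag does not
  catch this, since the basis can still fit the few moments).
* Mosaic spread is modelled as a symmetric Gaussian in $\Omega$ only; no
  3D scattering geometry beyond the specular plane.
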