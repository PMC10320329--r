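---
title: "Morphoelastic wrinkling of a growing bilayer: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphoelastic wrinkling of a growing bilayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Petal epidermal cells of some flowering plants (the *Hibiscus trionum*
"venus" petal is the canonical example) develop quasi-periodic nano-ridges
on their cuticle. Mechanically the cuticle is a bilayer: a thin, stiff
outer film over a compliant substrate of cuticular and cell-wall material.
As the cell produces cuticle, the film gains volume faster than the
in-plane extent available to it grows; the film is therefore compressed
against its boundaries and, past a critical compressive strain, buckles
into a periodic wrinkle pattern. `morphowrinkle` simulates this process
quasi-statically.

Growth enters through the multiplicative decomposition of the deformation
gradient,

\[ F = A\,G, \]

where \(G = \mathrm{diag}(g_1, g_2)\) (or \(\mathrm{diag}(g_1, g_2, g_3)\)
in 3D) is a prescribed, layerwise-homogeneous growth tensor and \(A\) is
the elastic response. Each layer is a compressible neo-Hookean solid,

\[ \Psi = \tfrac{\mu}{2}(I_1 - 3) - \mu \ln J_e +
   \tfrac{\lambda}{2} \ln^2 J_e , \]

with \(I_1 = \mathrm{tr}(A^{\!\top}\!A)\), \(J_e = \det A\), and Lamé
parameters \(\mu = E/2(1+\nu)\), \(\lambda = E\nu/((1+\nu)(1-2\nu))\). The
two layers share \(\nu\) and differ by the stiffness mismatch
\(R = E_f/E_s\) (substrate modulus normalised to 1). The total reference
energy density is \(J_g\,\Psi(F G^{-1})\): mass is added at constant
density, so a grown volume element weights its energy by
\(J_g = \det G\). The nominal stress used in the equilibrium equation
\(\nabla\!\cdot\!P = 0\) is the exact gradient of that energy,

\[ P = J_g \left( \mu A + (\lambda \ln J_e - \mu) A^{-\top} \right)
   G^{-\top}, \]

equivalently \(P = F\bar S\) with \(\bar S = J_g\,G^{-1} S_e\,G^{-\top}\).
This is the standard energy-consistent growth pull-back; a compatible,
homogeneously grown body is exactly stress-free under it, which the test
suite verifies both pointwise and on assembled meshes.

"Time" is an internal clock: the growth entries \(g_{k,i}(t)\) and the
boundary schedules are functions of a pseudo-time \(t\), and the solver
computes a stationary equilibrium at each grid point. No inertia or
viscosity enters; configurations are irreversible in the sense that they
are held by growth and boundary data alone, with zero external traction.

### Boundary conditions

The base of the bilayer follows the underlying cell wall. Turgor pressure
bulges it; the package prescribes this as a displacement schedule on the
base facet: a single parabolic bulge of profile \(r(t)\,x(x - w_o)\)
with a ramp \(r(t)\) that caps at a time \(\tau\); a three-segment
version with clamped junction intervals between cells; or, in 3D, a
sine-product bump field with a uniform stretch of the length direction
emulating cell elongation. The bulge is applied *towards the free
surface*: turgor pushes the cell wall outward, which arcs and stretches
the film riding above it and thereby delays onset. (Applied in the
opposite sense, the dip stretches the substrate vertically and
Poisson-compresses the film, *advancing* onset -- simulations make the
sign choice unambiguous.) Lateral faces are pinned in their normal direction (the
neighbouring cells confine the in-plane extent — this is precisely the
"larger volume into a smaller one" mechanism that converts growth into
compression); the top surface is always traction-free.

### The analytic oracle

For a thin stiff film on a deep compliant substrate the primary
instability obeys the classical scaling rules

\[ \lambda_c = 2\pi h \left( \frac{\bar E_f}{3 \bar E_s} \right)^{1/3}
   = \gamma_1 h R^{1/3}, \qquad
   \varepsilon_c = \tfrac14 \left( \frac{3\bar E_s}{\bar E_f}
   \right)^{2/3} = \gamma_2 R^{-2/3}, \]

with plane-strain moduli \(\bar E = E/(1-\nu^2)\) (which cancel to \(R\)
when the layers share \(\nu\)). The exponents are exact for this class of
bilayers; the prefactors \(\gamma_1 = 2\pi/3^{1/3}\),
\(\gamma_2 = 3^{2/3}/4\) are the half-space values and shift by order ten
per cent for finite substrate depth. The package therefore treats the
*exponents* as the oracle's hard predictions and the prefactors as
approximate. `growth_to_strain()` converts a scenario's growth and
boundary schedules into the effective film strain
\(\varepsilon(t) = 1 - L(t)/(g_{f,1}(t)\,w_o)\), where \(L(t)\) is the
arc length of the (possibly bulged) base — bulging lengthens \(L\) and
delays the time at which \(\varepsilon\) reaches \(\varepsilon_c\), which
is the mechanism behind the patchy, junction-first onset seen on real
petals.

One subtlety matters when comparing wavelengths across stiffness ratios:
the film *thickens while it grows* (in the canonical cross-section laws,
\(g_{f,2}(t) = 1 + 5t^2\)). The \(h\) in the scaling law is the film
thickness at the moment the threshold is reached, so the measured
wavelength is \(\lambda \approx \lambda_c(h) \cdot g_{f,2}(t^*)\), and
since \(t^*\) depends on \(R\), raw wavelengths mix the two scalings. The
scaling studies therefore report \(\lambda / g_{f,2}(t^*)\) when fitting
the \(R^{1/3}\) exponent; the same quantity divided by \(\lambda_c\)
checks the prefactor (it comes out within ten per cent at \(R = 10\)).

## Numerics

**Discretisation.** 2D cross-sections (plane strain — ridges are uniform
along the cell axis at onset) use 9-node biquadratic quadrilaterals with
3×3 Gauss quadrature; quadratic displacements keep volumetric locking
mild at \(\nu = 0.45\)–\(0.48\) without a mixed field. 3D runs use
trilinear hexahedra with the \(\lambda\)-part of the energy integrated at
the element centre (selective reduced integration) to relieve locking.
Meshes are structured and graded: at least two element layers through the
film, geometrically coarsening layers through the substrate, and an
in-plane size tied to the expected wrinkle wavelength. Experience with
the cross-section studies says 16 elements per *effective* (grown)
wavelength is needed for clean mode selection; 8 per wave visibly
degrades the selected wavelength and delays onset, so the study
constructors default to 16.

**Continuation.** Each pseudo-time step warm-starts Newton's method from
the previous equilibrium, with the consistent tangent assembled
analytically and solved by sparse LU, a backtracking line search on the
residual norm, and a Levenberg-style adaptive diagonal shift that
engages when the line search creeps near a singular tangent.
Convergence demands a residual below \(10^{-8}\) relative to the
assembled load scale (25 iterations maximum); a failed step bisects the
growth/boundary increment, down to 1/64 of the grid step. At branch
events (the primary bifurcation, wavenumber exchanges, secondary
thresholds) the tangent is singular to working precision and the damped
iteration can plateau; an iterate whose residual is still at least four
orders below the load scale is then accepted and recorded (three orders
at the deepest sub-step, with a warning). All ordinary steps meet the
strict tolerance.

**Crossing the bifurcation.** The flat state remains an equilibrium past
the critical strain, and Newton iteration happily converges to it — or to
the unstable middle branch of the imperfect pitchfork — which would leave
the film spuriously flat. Two mechanisms deal with this. First, a
geometric imperfection: film node depths are perturbed by seeded,
zero-mean uniform noise of amplitude \(10^{-4} h\) (below any detection
threshold, reproducible by seed). Second, and decisively, a stability
check: once the oracle strain reaches 40% of critical, every converged
tangent is classified by the inertia of a sparse LDL factorisation; if
negative eigenvalues exist, the state is nudged along a negative-curvature
direction (shifted inverse iteration) and re-solved until a stable
equilibrium is found. The nudges only alter the Newton initial guess —
every accepted state is an exact equilibrium of the unforced problem —
and the first indefinite step coincides with the oracle's predicted onset
to about one per cent in the flat-base studies. The inertia test is
essential: the smallest-*magnitude* eigenvalue can be a harmless positive
mode even when buckling modes have already gone unstable.

**Onset and metrics.** The free surface is sampled at the top nodes
(16 samples per wavelength at the default resolution), the cell-scale
bulge is removed by a Gaussian-weighted local quadratic regression
(window three wavelengths; the quadratic basis reproduces a parabolic
bulge exactly, and the Gaussian weighting leaks under 2% of a sinusoid
into the trend at that window), and the amplitude is half the mean
peak-to-trough of the remaining oscillation. Two refinements matter on
strongly bulged surfaces: the regression runs in two passes (the second
pass removes the smooth non-parabolic residual that a large deformed
bulge leaks through the first pass, while attenuating the
wavelength-scale oscillation negligibly), and global metrics exclude a
margin of about one wavelength at each pinned lateral edge, where the
artificial confinement concentrates boundary distortion -- in the wide
canonical domains that zone is a negligible fraction of the surface; in
the scaled study domains it would otherwise dominate onset detection. Wavelengths are Euclidean
distances between consecutive sub-sample-refined crest points of the
actual surface, which on a curved base reproduces the exact crest-map
expansion implemented in `curved_wavelength_map()`. Onset is the first
time the amplitude exceeds \(0.05h\) for two consecutive steps — above
the imperfection floor, below mature amplitudes.

## Study sizes and defaults

The canonical cross-section uses an in-plane extent of 2.0 with
\(h = 0.0016\): roughly 60–130 wrinkles, which is faithful but expensive.
The *study* constructors (`wrinkle_study_scenario()`,
`three_cell_study_scenario()`, `volume_study_scenario()`) run the same
physics on domains hosting 10–20 waves:

* `wrinkle_study_scenario(R)` sets the width to 8 effective onset
  wavelengths (predicted a priori from the oracle, including the
  thickness-growth factor) and sizes the mesh at 16 elements per
  effective wavelength with 100 pseudo-time steps. For \(R \le 1\),
  where no wrinkling branch exists, the \(R = 10\) sizing is reused so
  the control run is directly comparable.
* `three_cell_study_scenario()` shrinks the three-cell widths tenfold
  (film thickness and depth unchanged; each cell still hosts 12–20
  waves) and scales the per-segment bulge rates by ten to preserve
  slopes.
* `volume_study_scenario()` replaces the printed volumetric geometry —
  whose in-plane extent is smaller than the predicted wavelength at
  moderate stiffness ratios, so no wrinkle can fit — with a slab of
  width 1.0 hosting ~14 waves across three turgor bulges, keeps the
  printed growth laws and schedule structure (b = 1.5, τ = 0.12,
  length stretch 0.5·b·t), and raises the bulge ramp to 0.6 so the bulge
  height is commensurate with the wavelength at this scale. The 3D run
  is deliberately coarse (trilinear elements, ~5000 hexahedra) and is
  used for qualitative ordering only: where the pattern initiates, not
  precise wavelengths.

Other defaults worth knowing: the stiffness ratio and Poisson ratio of
the volumetric scenarios are not part of their printed parameter sets;
\(R = 20\), \(\nu = 0.45\) are adopted once and exposed as arguments.
The three-cell growth curves are printed only graphically; the registry
reconstructs them from the quadratic family with rates chosen to
reproduce the described orderings (slow vs fast thickening
distinguishes cases C and D), and flags them as reconstructed in the
scenario note. The clamped junction intervals between cells have no
printed width; the registry derives them as the remaining base length
split into four equal clamps, which closes the geometry exactly while
preserving every printed segment width. Film thickness growth that stops
mid-run is implemented as an abrupt, exact freeze.

## What the synthetic fixtures do and do not show

The metric tests run on `make_profile()` fixtures: perfect sinusoids on
flat or parabolic bases, carried by the same normal-offset construction
used in the crest-map derivation, with optional seeded Gaussian height
noise. These fixtures have exact ground truth (amplitude, wavenumber,
per-wave crest distances verified against brute-force point mapping), so
they pin down estimator bias — but they are cleaner than FEM surfaces
(no mode mixing, no boundary layers near the pinned lateral edges) and
much cleaner than microscopy data. Passing them shows the estimators are
correct, not that amplitude extraction from a real cryo-SEM profile would
be this accurate.

Similarly, the simulated trajectories emulate growth-driven compression
with idealised, layerwise-homogeneous growth and noise-free material
parameters. Real cuticles have spatially varying thickness and stiffness,
cell divisions, and viscoelastic relaxation, none of which are modelled;
wavelength variance in the simulations comes only from curvature
(geometric crest spreading plus asynchronous onset), which is exactly
the mechanism the crest-map expansion isolates.

## Known limitations

* No arc-length continuation: secondary bifurcations (period doubling)
  are not followed; the runs stop well before those thresholds matter.
* The 3D path uses trilinear elements with selective reduced
  integration; film bending is stiffer than converged, so 3D onset times
  and wavelengths are qualitative.
* The stability push selects a wrinkled branch deterministically
  (fixed-seed inverse iteration), but near-coincident modes can make the
  selected branch mesh-dependent — another reason the studies fix 16
  elements per wave.
* Physical (μm) rescaling of amplitudes and wavelengths is left to the
  user: the model is nondimensional and no calibration factor is built
  in.
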