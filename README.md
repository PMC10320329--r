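# morphowrinkle

Quasi-static morphoelastic simulation of wrinkling in growing
film/substrate bilayers — the mechanics behind the quasi-periodic
nano-ridges that develop on the cuticle of petal epidermal cells (and on
many other growing layered surfaces).

Petal cuticles are mechanical bilayers: a thin, stiff outer film on a
compliant substrate of cuticular and cell-wall material. As the cell
synthesises cuticle, the film gains volume faster than the in-plane
extent available to it; confined by its neighbours, it is compressed and,
past a critical strain, buckles into a periodic wrinkle pattern. This
package is for researchers in plant biomechanics and pattern formation
who want to simulate that process, quantify the resulting pattern, and
test it against the classical film-on-substrate scaling laws.

## The model

Growth enters through the multiplicative decomposition of the
deformation gradient,

    F = A G,     G = diag(g_1, g_2[, g_3]),

with G a prescribed, layerwise-homogeneous growth tensor (internal
pseudo-time clocks the growth laws) and A the elastic response. Both
layers are compressible neo-Hookean,

    Psi = mu/2 (I_1 - 3) - mu ln J_e + lambda/2 ln^2 J_e,

sharing a Poisson ratio nu and differing by the stiffness mismatch
R = E_f/E_s. Equilibria of div P = 0 (P the nominal stress, the exact
gradient of the total energy J_g Psi(F G^-1)) are computed by a
finite-element Newton continuation: biquadratic quadrilaterals in 2D
plane strain, trilinear hexahedra with selective reduced integration in
3D, analytic consistent tangents, sparse direct solves, inertia-based
stability classification with branch pushes through the wrinkling
bifurcation. Turgor pressure of the underlying cell is prescribed as a
bulged base displacement schedule (single cell, multi-cell with clamped
junctions, or 3D bump fields with cell-elongation stretch).

The analytic onset oracle provides the classical scaling rules

    lambda_c = 2 pi h (R/3)^(1/3),      eps_c = (1/4) (3/R)^(2/3),

(critical wavelength and strain for a thin stiff film on a deep
substrate, plane-strain moduli, shared nu), against which the
finite-element results are checked: the exponents 1/3 and -2/3 are the
oracle's hard predictions, the prefactors are approximate.

## Worked example

The scaled single-cell cross-section study at stiffness mismatch R = 10
(a domain hosting eight expected wavelengths; film thickness h = 0.0016,
ratio h/H_o = 0.008, nu = 0.45; the film grows in-plane as 1 + t^2/2 and
thickens as 1 + 5 t^2; flat base):

```r
library(morphowrinkle)

scn <- wrinkle_study_scenario(R = 10)
sim <- run_quasistatic(scn, stop_after_onset = 6)
sim
#> wrinkle simulation <study_flat_R10>: 57 states, t in [0, 0.56]
#>   onset t* = 0.5
#>   final: amplitude 0.001957, mean wavelength 0.03396 (predicted 0.03396)
```

What the numbers mean: the oracle predicts onset when the effective film
strain `1 - 1/g_f1(t)` reaches `eps_c = 0.112`, i.e. at t = 0.502; the
simulation detects onset (amplitude above 5% of the film thickness,
sustained) at t* = 0.5. The mean wavelength just after onset, 0.034, is
the critical wavelength of the film *at its grown thickness*:
`lambda_c x g_f2(t*) = 0.0151 x 2.25 = 0.0340` -- the oracle prediction
to three digits. The amplitude keeps growing with further film expansion
while the wavelength stays put:

```r
critical_strain(10, 0.45)
#> [1] 0.1120351
predict_onset_time(scn)
#> [1] 0.5023359
critical_wavelength(0.0016, 10, 0.45)
#> [1] 0.01501733
```

Scenario registry: `list_scenarios()` names the canonical parameter
sets (single-cell cross-sections with flat or turgor-bulged bases,
three-cell bases with clamped junctions, volumetric single-cell and
three-cell runs); `describe_scenario(get_scenario("three_cell_B"))`
prints every parameter plus the oracle predictions;
`write_scenario()` / `read_scenario()` round-trip scenarios through JSON
configs. A thin command-line front end lives in `inst/cli/morphowrinkle`
(`run`, `list-scenarios`, `describe`, `predict`, `sweep`).

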