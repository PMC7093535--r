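---
title: "Electric double layers, screening factors and dose-response analysis for deformed-graphene FET biosensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electric double layers, screening factors and dose-response analysis for deformed-graphene FET biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crumplefet)
```

## The problem

A graphene field-effect transistor detects adsorbed nucleic acids through
their charge: unscreened charge near the channel gates it and moves the
Dirac point (the gate voltage of minimal drain current). The fundamental
limit is Debye screening — in physiological electrolyte the screening length
is below 1 nm, so counter-ions neutralize most of an adsorbed molecule's
charge before the channel feels it. Nanoscale deformation ("crumpling") of
the graphene changes this: concave valleys and narrow folds exclude hydrated
ions, so DNA adsorbed there stays electrostatically exposed, and sharply
bent, base-decorated regions can open a bandgap that amplifies the current
response. `crumplefet` implements the computational chain behind this
picture: a synthetic electrolyte/DNA configuration generator standing in for
molecular dynamics, concentration profiling, the ionic screening-factor
statistic, electrostatic potentials and a capacitance proxy, the
Dirac-shift carrier model with a bandgap-mobility hot-spot extension,
transfer-curve Dirac extraction, and Sips dose-response fitting with
limit-of-detection estimation.

## The stated world of the synthetic generator

No force-field simulation is in scope, so every downstream stage is
exercised on configurations drawn from an explicit, documented mean-field
world. Ion positions are sampled by rejection from a Boltzmann density

$$c_\pm(\mathbf r) = c_\text{bulk}\,
  \exp\!\left(\mp \frac{e\,\psi(\mathbf r)}{k_B T}\right),\qquad
  \psi = \psi_0 e^{-d/\lambda_D} + \sum_i
  \frac{q_i\,e^{-s_i/\lambda_D}}{4\pi\varepsilon_0\varepsilon_r s_i},$$

where $d$ is the distance from the sheet, $s_i$ the distance to the $i$-th
DNA backbone charge, $\lambda_D$ the Debye length of the bath, and
$\psi_0 = \sigma\lambda_D/(\varepsilon_0\varepsilon_r)$ the linearized
(Grahame) surface potential. The second term makes counter-ions condense
around the backbone wherever it is reachable — the feature that
differentiates flat from concave adsorption.

Steric rules carry the confinement physics that mean-field electrostatics
alone cannot:

* **Hard cores.** Ion centres keep at least `ion_radius` (0.15 nm, a bare
  ion radius) from the sheet and at least the DNA `exclusion_radius`
  (0.5 nm, the effective backbone radius) from every charge site.
* **Hydration-shell confinement.** A hydrated ion sitting against a concave
  wall loses more of its first hydration shell than against a flat wall at
  the same distance. The generator probes, on a fixed direction set, the
  fraction of a shell of radius `hydration_shell` (0.35 nm, the first
  water shell of Na+) truncated by the solid, and applies a Boltzmann
  penalty of `confinement_kT` (20 kT) per unit of truncation *in excess of
  the flat-wall baseline*. Flat sheets are exactly unaffected — which keeps
  the closed-form Gouy–Chapman oracle valid — while valleys are depleted,
  reproducing the valley/crest contrast seen in concentration maps of
  crumpled sheets. The 20 kT scale is a conservative fraction of an alkali
  ion's full first-shell hydration free energy (of order 100 kT).
* **The interstice rule.** A hydrated ion cannot occupy a slit narrower
  than its hydration diameter: points simultaneously within
  `hydration_shell` of the sheet *and* of the DNA surface are inaccessible.
  On a flat sheet this blocks a strip under the chain; in a concave valley
  the wrapped wall turns essentially the whole DNA-occupied groove into
  such an interstice. This is the mechanism that displaces the screening
  onset outward and raises the unscreened DNA charge in concave systems.

Global electroneutrality is enforced per frame by the Na+/Cl− split: total
ion charge + DNA charge + $\sigma A$ vanishes to within one elementary
charge (the residual is the rounding of $\sigma A/e$).

Choices the sources leave open, fixed here once:

* **Surface charge density** $\sigma = -0.01$ C/m² by default. This
  corresponds to a carrier density of $\sim 6\times10^{16}$ m⁻², typical of
  liquid-gated graphene near its Dirac point; it also places the 22 e of an
  adsorbed 22-mer and the sheet's own countercharge ($\sigma A \approx
  10$ e over a simulation-box footprint) on comparable footing, which is the
  regime in which DNA screening structure is visible in the screening
  factor at all. An early prototype used $-0.05$ C/m² ($3\times10^{17}$
  m⁻², implausibly heavily doped); it buried the DNA structure under the
  surface's own counter-ion layer.
* **DNA charge model**: one −1 e site per base, 22 sites for the 22-mer
  probe `AACCACACAACCTACTACCTCA`, at 0.7 nm rise per base (extended
  adsorbed ssDNA) and a 0.35 nm stand-off (a π-stacking gap). The paper-scale
  box edges (12.5 nm) are shorter than the 15.4 nm track, so the track wraps
  through the periodic y boundary.
* **Sinusoid box**: two exact corrugation periods (10.82 × 12.5 × 10 nm)
  rather than the quoted 11.10 nm edge, so the surface is strictly periodic
  in the box; the 3% footprint difference is immaterial to every statistic
  computed here.
* **Trench**: a half-cylinder groove of radius 1.225 nm carved below the
  plane, the stated-diameter stand-in for a narrow fold modelled
  atomistically with a carbon nanotube. The groove spans the box in y;
  `trench_length` caps the DNA track length.

What this world does *not* emulate: explicit water (and hence the water
contribution to the net charge entering the measured potential),
ion–ion correlations, nonlinear Poisson–Boltzmann saturation, DNA
flexibility and sequence-dependent adsorption, and instrument drift. A
green directional test (concave vs flat, crumpled vs flat) therefore
establishes that the package's statistics respond to confinement geometry
in the direction the physical argument predicts — not that the magnitudes
match molecular dynamics, which are typically far larger.

## Profiles and the screening factor

`bin_concentration()` histograms a species in the distance-from-surface
coordinate; bin molarity is $c_b = n_b/(N_A V_b)$ with the shell volume
$V_b$ exact for flat sheets and Monte-Carlo estimated (10⁶ points, fixed
internal seed, cached per geometry) for curved ones, so profiles are
deterministic and counts are conserved exactly. The default grid (0.05 nm
bins to 5 nm) resolves the sub-nanometre double layer. Distances for
sampling and binning use a memoised bilinear lookup accurate to ~10⁻³ nm;
the public `surface_distance()` is exact to 10⁻⁶ nm (coarse scan plus
golden-section refinement) and is what the brute-force oracle tests.

The screening factor is the cumulative net ionic charge normalized by the
surface charge magnitude,

$$SF(z) = \frac{\int_0^z F\,([\mathrm{Na^+}] - [\mathrm{Cl^-}])\,dz'}{|\sigma|},$$

integrated per bin in SI units (mol/m³ × C/mol × m; piecewise-constant
profiles integrate exactly). $SF(0)=0$; 1 means full neutralization of the
surface charge; the reported curve is deliberately *not* clamped — with
adsorbed DNA it exceeds 1 at large $z$, and for an electroneutral frame its
far-boundary value is $(|\sigma|A + |Q_\text{DNA}|)/(|\sigma|A)$, which the
tests assert as a conservation check. On a linearized Gouy–Chapman profile
$SF(z) = 1 - e^{-z/\lambda_D}$ exactly, the closed-form oracle used
throughout.

The screening onset is the first crossing of a threshold (default 0.05,
linearly interpolated; the threshold is exposed because the sources mark
onset with an unquantified arrow). The unscreened DNA charge weights each
backbone charge by $1 - \min(SF(d), 1)$ at its distance — the clamp lives
only inside this weighting — and is clamped to the physical range
$[0, Q_\text{DNA}]$. The weighting scheme itself is this package's
construction; only the proportionality of the Dirac shift to unscreened
charge is inherited from the sources.

## Potential and capacitance

`potential_profile()` integrates the one-dimensional Poisson equation twice
over a laboratory-z net charge profile,
$V(z) = -\iint_{z_0}^{z} q(z')/(A\varepsilon_0\varepsilon_r)\,dz'\,dz'$,
with $V(z_0) = V'(z_0) = 0$ and the slab charge treated as a sheet at the
bin midpoint (this makes the parallel-plate case exact, which the tests
require to 0.1%). With explicit solvent in $q$ the permittivity is the
vacuum one; for implicit-solvent charge profiles pass
`relative_permittivity = 78.5`.

The capacitance proxy is $C_\text{eff} = |\sigma| / |V_\text{surface} -
V_\text{bulk}|$ with the bulk plateau taken as the mean over the last 10%
of the grid, flagged when the mean tail slope exceeds 10% of the peak slope
(the tolerance accommodates the statistical ripple of frame-averaged
profiles while still catching an uncompensated far field). For a linearized
Gouy–Chapman layer this reduces to $\varepsilon_0\varepsilon_r/\lambda_D$
within discretization error. Because the whole construction is
one-dimensional in z, a corrugated sheet — whose own charge and
counter-ions spread over the corrugation amplitude in z, with valleys
additionally depleted — shows a larger drop and hence a lower capacitance
than a flat sheet at matched σ, the direction the device measurements show
(they report roughly threefold; this world gives ~1.2–1.3×, a direction-only
statement).

## The Dirac chain and the hot-spot reconstruction

The carrier model is $\Delta V_D = e\,\Delta n / C_T$ with
$\Delta n = \alpha N_\text{DNA}^\text{unscreened}$; the coupling α is a
free parameter in (0, 1] because the sources state only proportionality.
Mobility in gapped graphene follows $\mu \propto E_g^{-3/2}$.

The hot-spot model is a declared reconstruction (versioned
`"hotspot-mixture-1"` and echoed into every result): a fraction $f$ of the
channel area has the hot-spot gap, carriers there respond inversely to
mobility, so

$$\Delta V(f) = f\,\frac{e\,n_\text{hotspot}}{C_T}
  \left(\frac{E_g^\text{hot}}{E_g^\text{bg}}\right)^{3/2},$$

inverted for the minimal $f$ by bisection to 10⁻⁶ relative tolerance. The
inverse relation between carrier response and mobility is an assumption
stated by the reconstruction, not derived; the published "~10⁻⁷% of the
area" figure rests on supplementary algebra not reproduced here, so
matching it is a stretch goal, not an asserted result. The default gap
values (0.4224 eV background, 1.7641 eV with an adsorbed adenine) are
consumed as inputs from electronic-structure calculations, never computed.

## Transfer curves and dose-response

Dirac extraction smooths with a centred moving average (window 5), takes
the grid argmin, and refines with a local parabola over ±0.1 V; the vertex
is kept only if it stays inside the fit window, ties resolve to the
smallest voltage (flagged), and an edge minimum is an error. The refined
argmin was chosen over derivative-zero methods for robustness on the coarse
(10 mV) experimental sweeps; the estimator is exactly
translation-equivariant and invariant to rescaling the current. Replicates
aggregate as mean ± SD, matching the experimental convention.

`fit_sips()` fits the Sips (Langmuir–Freundlich) isotherm
$|\Delta V|(C) = \Delta V_\max (KC)^a / (1 + (KC)^a)$ by nonlinear least
squares in the parameterization $(\Delta V_\max, \log_{10} K, a)$ with
$a \in (0, 2]$, multi-start over a grid of affinities and heterogeneities.
The default objective is **unweighted**: the shift readout has additive,
concentration-independent noise (millivolts on a voltage measurement), for
which unweighted least squares is the maximum-likelihood fit and the
reported standard errors are calibrated — the package's coverage test (±2
SE containing the truth in ≥ 90 of 100 seeded tables) depends on this.
Relative-residual weighting is available as an option for data whose error
grows with signal.

The LOD rule formalizes "overlapped with the standard deviation of negative
controls": the LOD is the lowest tested concentration whose mean absolute
shift exceeds $\overline{|NC|} + k\,\mathrm{sd}(|NC|)$ (default $k = 3$)
*and* whose higher concentrations all pass too. The persistence clause
prevents a single-point false positive from setting the LOD — the same
reasoning that discounts an isolated few-mV reading at the lowest dose.
Molecule counts are $\mathrm{round}(C \cdot V \cdot N_A)$, with the
unrounded value and a 2-significant-figure "approximately" view retained
(600 zM and 20 aM in 50 µL give 18 and ~600 molecules).

## Numerical choices

* Integration is per-bin (piecewise-constant) for profiles and trapezoidal
  (midpoint-sheet) for potentials; at the default 0.05 nm grids all
  closed-form oracles are met within 0.5%.
* Curved-bin volumes and the distance/penalty lookup tables use fixed
  internal seeds and caches, so identical inputs give bit-identical
  outputs regardless of call order; the global RNG stream is saved and
  restored around them.
* Rejection sampling uses a per-species upper bound assembled from the
  surface contact value and a deterministic probe of contact spheres
  around every DNA site, with a 25% safety margin.
* Degenerate inputs are first-class: empty frames give zero profiles,
  zero-volume bins are flagged `NA`, a screening factor that never reaches
  its threshold returns `NA` with a message, and σ = 0 is an explicit
  normalization error.

## Known limitations

* Directional claims (concave vs flat, crumpled vs flat) are reproduced
  with margins far smaller than molecular dynamics shows, because the
  mean-field world lacks explicit water and ion correlations; the
  seeded ensembles in the tests are sized so the systematic direction
  clears the sampling noise.
* The trench geometry supports distance computation, generation and
  1-D profiles, but not 2-D maps.
* The hot-spot mixture is one defensible reconstruction among several; its
  absolute area fractions should not be quoted as the published figure.
* Sips fits on data spanning twelve decades can pin the heterogeneity
  exponent at its bound for pathological tables; the fit flags this rather
  than failing.
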