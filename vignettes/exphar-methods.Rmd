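---
title: "Adjustable-overlap stockholder partitioning and toy Hirshfeld atom refinement: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{exphar methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The partition

A stockholder partition assigns atom $A$ the share
$w_A(\mathbf r) = \rho^\circ_A(\mathbf r)^n / \sum_B \rho^\circ_B(\mathbf r)^n$
of the total electron density, where $\rho^\circ_A$ are spherically
averaged isolated-atom densities placed at the nuclei and $n \ge 1$ is
the overlap exponent. The exponent applies to the isolated-atom densities
only, never to the total density; $n = 1$ runs through the same code path
and reproduces the classic Hirshfeld weights bitwise. Completeness
($\sum_A w_A \rho = \rho$ pointwise) holds identically for every $n$
because the weights sum to one wherever the promolecule is nonzero.

Two numerical conventions:

* **Large exponents.** Weights are formed on the log scale relative to
  the per-point maximum, so $n = 64$ and beyond neither overflow nor
  underflow.
* **Far field.** Where the promolecule falls below `zero_threshold`
  (default $10^{-30}$ e/bohr³) the $0^n/0^n$ ratio is replaced by
  nearest-site assignment. The affected region carries no appreciable
  density, so integrals are unchanged to well beyond the quoted
  tolerances, and the weights are never NaN.

**Isolated-atom densities.** The shipped default is a single-ζ Slater 1s
form, $\rho(r) = N_e (\zeta^3/\pi) e^{-2\zeta r}$ (atomic units), which
is analytic, normalizes exactly, and has a closed-form Fourier transform
used as the oracle for the numerical engine. The partition algebra never
looks inside the density objects, so any non-negative normalized radial
profile can be plugged in; the single-ζ family is a default, not a
commitment. Per-element exponents live in a packaged plain-text table
(`inst/extdata/slater_zeta.txt`) and can be overridden per call.

The per-element defaults deserve a word. A single-ζ shell must stand in
for a whole atom. For hydrogen the hydrogenic ζ = 1 is exact. For the
heavy toy elements we deliberately choose *compact, core-like* exponents
(ζ = 3.2–4.0 bohr⁻¹): real first-row atoms keep their core density away
from bond midpoints, so at an X–H bond midpoint the isolated-atom
densities of X and H are of comparable magnitude and hydrogen's
stockholder share of the bond region is a realistic 0.3–0.4. A diffuse
single shell holding all of Z electrons would instead swamp the hydrogen
everywhere and push its stockholder share toward zero — the wrong regime
for everything this package studies. Valence-like exponents for bond
orbitals are a separate table (`slater_valence_zeta.txt`).

**Overlap coefficient.** Interatomic density overlap is quantified by a
definition-pluggable coefficient with two shipped options: the default
*min* overlap $o_{AB} = \int \min(\rho_A/N_A,\; \rho_B/N_B)\,d^3r$ of the
population-normalized atomic densities, and a Carbo-style *product*
overlap $\int\rho_A\rho_B / (\int\rho_A^2 \int\rho_B^2)^{1/2}$. Both are
symmetric, lie in $[0,1]$, decay with separation and are non-increasing
in $n$ on the toy systems; neither is claimed to equal any particular
published table's convention, which is why both are shipped and the
definition is an explicit argument. Integrals are averaged over the two
atom-centred grid estimates, which makes $o_{AB} = o_{BA}$ exact.

## 2. Quadrature

Atom-centred integration uses a spherical × radial product grid.

* **Spherical grids** are requested by the nominal size of the classical
  octahedral rules (590, 5810, …) and realized as Gauss–Legendre ×
  uniform-azimuth product grids generated in code with the same
  polynomial exactness degree (590 → degree 41, 5810 → degree 131). We
  generate rather than embed node tables: the generator is a few lines,
  exact by construction (Gauss–Legendre handles the polar polynomials,
  the uniform azimuth handles the trigonometric ones), testable against
  moment identities, and keeps the package free of hundreds of kilobytes
  of tabulated nodes. The exactness properties the named sizes promise —
  unit vectors, weights summing to 1, annihilation of spherical
  harmonics up to the rule's degree — are asserted in the test suite.
* **Radial grids** use the Mura–Knowles log-cubed map
  $r_i = -\alpha\,\ln(1 - (i/(m+1))^3)$ with chain-rule weights,
  $m = 75$ and $\alpha = 5$ bohr by default for every element (the same
  grid for all atoms). $\alpha$ is exposed because no published value is
  attached to the 75-point rule we mirror; 5 bohr puts half the nodes
  inside ~2 bohr, which suits exponentially decaying atomic densities,
  and the defaults recover every shipped density's electron count to
  $10^{-6}$.
* **No fuzzy-cell multi-centre scheme.** Every integrand we integrate is
  dominated by one centre (an atomic density, a weight–density product,
  a form-factor integrand). Diffuse two-centre products — the toy bond
  densities, the overlap coefficients — converge more slowly on a single
  centre; where symmetry matters we average the two atom-centred
  estimates, and the tests use midpoint-centred grids for total-density
  normalization. The accuracy consequence is visible in the test suite:
  the completeness identity for the sharp-cored heteronuclear toy is
  checked at $2\times10^{-3}$ against a molecule-centred reference grid,
  versus $10^{-5}$ for the mild-cusp symmetric diatomic.

## 3. Form factors and the cached engine

The aspherical form factor is the Fourier transform of the partitioned
atomic density about its own nucleus (*atom-local phase convention*);
the lattice phase $e^{2\pi i \mathbf h\cdot\mathbf x_A}$ is applied by
the structure-factor engine. This matches `.tsc` usage, where tables are
per-atom and position-free.

The expensive part of a table build is $\cos/\sin(2\pi\,\mathbf
h\cdot\mathbf u)$ over (grid offset, reflection) pairs. Those phases
depend only on the grid and the reflection list — not on site positions,
the exponent, or ADPs — so `form_factor_engine()` computes them once and
every subsequent table for any geometry or exponent costs two real
matrix–vector products per site. This is what makes the refinement
macro-cycle (which regenerates tables at each new geometry) and the
full experiment grid affordable.

The `.tsc` dialect is minimal: `TITLE:`, `SYMM: expanded`,
`SCATTERERS:`, `DATA:` and one line per reflection of `h k l` plus
`re,im` pairs; the reader ignores unknown header keys.

## 4. The refinement engine

Least squares on $F^2$ (HKLF-4 style) with SHELX-type weights
$w = 1/(\sigma^2 + (aP)^2 + bP)$. The default $P$ convention is the
*literal* $P = 2F_c^2 + \max(F_o^2, 0)$; the conventional SHELXL $P/3$
is a switch (`p_convention = "standard"`). The literal form is the
default for fidelity to the formula as printed in the refinement
literature this engine mirrors; the probable missing /3 is acknowledged
here, and both conventions are tested. Weight parameters $a, b$ are
user-fixed per run — no automatic weight optimization, since unstable
weighting schemes are exactly the confounder one wants excluded when
comparing refinements across exponents.

Gauss–Newton with central finite-difference derivatives (two step sizes
agree to $10^{-5}$ relative in the tests) and backtracking step damping;
the damping matters only when the model is deliberately wrong (the bias
experiment), where an undamped step can diverge. Standard uncertainties
come from the goof-scaled inverse normal matrix — the usual convention,
flagged here because an unscaled variant exists. Refined parameters are
the overall scale, selected fractional coordinates and selected
Cartesian $U$ components; occupancies are fixed; ADPs are handled in the
Cartesian convention internally and converted to/from the CIF
reciprocal-basis convention at the file boundary.

**Outer loop and convergence.** Form-factor tables are regenerated from
the current geometry at the start of each macro-cycle. Convergence is
declared when, immediately after a regeneration, the first
least-squares cycle already satisfies max |shift/su| < 0.1. On
noise-free data the goof — and with it every su — tends to zero, making
shift/su pure round-off noise; shifts below crystallographic
significance ($10^{-5}$ in fractional coordinates and Å², $10^{-5}$
relative on the scale) therefore also count as at rest. Freeing all
positions in P1 leaves the floating origin undetermined; the engine
reports the rank-deficient coordinates by name rather than silently
pseudo-inverting.

## 5. ADP similarity statistics

* `msd_corr` has two paths that agree to $10^{-6}$: direction-space
  quadrature on the degree-131 grid, and the closed form obtained from
  the isotropic fourth-moment identity
  $\langle n_i n_j n_k n_l\rangle = (\delta_{ij}\delta_{kl} +
  \delta_{ik}\delta_{jl} + \delta_{il}\delta_{jk})/15$, which gives
  $\mathrm{cov} \propto \mathrm{tr}(U_1U_2) -
  \mathrm{tr}(U_1)\mathrm{tr}(U_2)/3$. The index is undefined for
  isotropic tensors (relative eigenvalue spread below $10^{-9}$); the
  implementation returns `NA` with a warning rather than a number, and
  set-level summaries skip such atoms and report how many were skipped.
* `gaussian_overlap` evaluates $\eta = \tfrac12\int|p_1-p_2|$ exactly up
  to 1D numerics: in the frame diagonalizing $U_1^{-1/2}U_2U_1^{-1/2}$
  the region where one Gaussian exceeds the other is a level set of a
  quadratic form in normal variables, whose probability is computed by
  Imhof characteristic-function inversion (`stats::integrate` on a
  smooth, algebraically decaying integrand). Tests check a dense 1D
  radial oracle ($10^{-6}$) and a $10^6$-sample Monte Carlo oracle.
  The percent form is $\eta_r = 100\,\eta$ — the percentage of
  probability mass by which the displacement PDFs differ. The factor is
  isolated in one place; any alternative rescaling (for instance against
  a maximal-difference normalizer) can be swapped in without touching
  callers, and no table-level $\eta_r$ value from the literature is
  asserted anywhere.
* `merritt_cc` uses the closed Gaussian form; $S_{12} = 100(1-\mathrm{CC})$
  is definitional and exact.
* `fit_isotropic_scale` defaults to full-tensor Frobenius least squares
  $q = \sum\mathrm{tr}(U_\mathrm{ref}U_\mathrm{tgt}) /
  \sum\mathrm{tr}(U_\mathrm{tgt}^2)$; a $U_\mathrm{eq}$-ratio estimator
  is provided as an alternative because more elaborate published
  rescaling schemes exist that this package does not reproduce.

## 6. The synthetic laboratory

`make_structure()` builds P1 toy crystals: a heavy pseudo-atom X (Z = 7)
bonded to hydrogen at 1.0 Å in a ~4.3–4.7 Å box, with seeded jitter in
the bond orientation and ADP magnitudes only — identical (template,
seed) pairs are bitwise identical. ADP magnitudes are physically
motivated for an organic crystal near 100 K: H has $U_\mathrm{eq}
\approx 0.03$ Å², prolate transverse to the bond (libration), and the
heavy atom displaces about a third of that (mass effect).

`simulate_intensities()` enumerates all Friedel-unique P1 reflections to
`d_min` and evaluates the package's own forward model. Noise is
multiplicative Gaussian on $F^2$, seeded; quadrature contributes no
randomness. The *sigma model* deserves emphasis: the default
`"counting"` model assigns $\sigma = \mathrm{rel}\,(F^2 + 0.05\max F^2)$
with rel = max(noise, 2%) — a relative error on strong reflections with
a background-dominated floor for weak ones, the shape counting
statistics produce. Since $\sigma$ sets the least-squares weights, this
choice is not cosmetic: a constant $\sigma$ gives weak high-angle
reflections the same absolute weight as the strongest data, and under a
deliberately bias-injected model that drives the refinement into
unphysical minima. The plain multiplicative model remains available.

**The neighbour-bias experiment.** For each condition (q_fix, n, d_min)
the experiment simulates noise-free data from the truth structure, fixes
the heavy atom's ADP at q_fix × truth (position fixed too — it anchors
the P1 origin), refines the scale and the hydrogen's position and ADP
with the exponent-n partition, and records the hydrogen ADP against
truth: MSD_corr, the $U_\mathrm{eq}$ ratio, and the *bond-direction MSD
excess* (refined minus truth, along the X–H bond — positive means the
ellipsoid inflated along the bond).

Two design points:

* **Truth and model share one density family, including a bond.** The
  default total density is the `"bonding"` model: each X–H pair shares a
  two-electron LCAO σ orbital built from valence exponents, with one
  electron contributed by each partner. Truth simulation and refinement
  use the same family, so the unbiased control (q_fix = 1) recovers
  truth exactly at every exponent and the experiment isolates the
  neighbour-bias mechanism, not density-model error. The plain
  promolecule total is *not* a usable default here: partitioned with
  n = 1 it returns each atom's own isolated spherical density — no
  interatomic sharing whatsoever — so the overlap-mediated coupling
  under study would be absent by construction.
* **What the experiment shows.** At the low-resolution condition
  (d_min = 0.8 Å) the under-scaled neighbour inflates the refined H
  ellipsoid along the bond, and the inflation decreases monotonically as
  the exponent reduces the interatomic overlap; the hydrogen
  $U_\mathrm{eq}$ likewise decreases with n. At high resolution
  (d_min = 0.5 Å) the injected inconsistency is concentrated at angles
  where hydrogen scattering is negligible; the biased least-squares
  problem develops multiple local minima and Gauss–Newton lands on
  different branches for different exponents, so no monotone trend is
  asserted there — the per-condition records are still reported. A
  deliberately misfit model also keeps drifting slightly as tables chase
  geometry, so the biased refinements may finish without the formal
  shift/su flag; the recorded metrics are the converged-to-tolerance
  endpoints of the damped iteration.

**What the toy does not emulate.** Quantum-chemical densities (the toy
is analytic single-ζ + one σ bond), crystal-field effects, space-group
symmetry beyond P1, absorption/extinction, Poisson counting noise,
anharmonicity, and multi-atom error compensation (only one atom is free,
so the injected error has exactly one place to leak). Passing tests
therefore demonstrate the partition algebra, the integration engine, the
statistics, and the qualitative overlap-bias mechanism — not agreement
with any particular measured crystal.

## 7. Problem sizes

The test and acceptance runs use the diatomic template: 367 reflections
at d_min = 0.8 Å and 2094 at 0.5 Å in the ~91 Å³ cell; 590-order angular
× 75-point radial grids (44 250 points) for form factors; the
degree-131 grid for MSD_corr quadrature; a 2 × 6 × 2 experiment grid
(q_fix × exponent × resolution). The full grid completes in a few
minutes on one CPU thanks to the cached phase engine.

## 8. Known limitations

* Single-ζ 1s densities have no shell structure; the compact-core
  default for heavy elements is a modelling stance (see §1), not a fit
  to atomic structure factors.
* The overlap coefficient's literature convention is ambiguous; two
  definitions are shipped and named, and only ordering claims are made.
* η_r is 100·η; alternative rescalings exist and are deliberately not
  guessed.
* The refinement su values use the goof-scaled covariance; unscaled su
  differ by the goof factor.
* Atom-centred quadrature of diffuse two-centre products is the least
  accurate integral in the package (§2); tolerances in the tests state
  the achieved accuracy explicitly.
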