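---
title: "Charge-transfer complex analysis with ctclab"
author: "ctclab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-transfer complex analysis with ctclab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctclab)
```

# Scope

`ctclab` implements the desk-side analysis chain of a donor–acceptor
charge-transfer (CT) complex study. A CT complex forms when an electron-rich
drug molecule (the donor) binds an electron-poor quinone (the acceptor),
producing a new visible absorption band. From UV–Vis measurements of that
band the package determines the binding stoichiometry, the association
constant $K_c$ and the standard Gibbs energy of complexation, and validates
the derived spectrophotometric assay ICH-style. On the computational side it
consumes QTAIM bond-critical-point descriptors (classifying the hydrogen
bonds that hold the complex together), performs counterpoise (BSSE)
interaction-energy arithmetic, and maps non-covalent interactions with a
wavefunction-free promolecular NCI/RDG engine.

Quantum-chemical computation itself (DFT optimisation, TD-DFT excitations,
wavefunction topology searches) is out of scope: descriptor tables and
excited-state lists are consumed as inputs, and electron densities are
approximated promolecularly.

# Binding equilibria and stoichiometry

The core model is the 1:1 association $D + A \rightleftharpoons DA$ with
constant $K_c$ (L/mol). `solve_equilibrium_1to1()` returns the exact complex
concentration — the physical root of
$c^2 - (d_0 + a_0 + 1/K_c)\,c + d_0 a_0 = 0$ — evaluated in the
cancellation-safe form $c = 2 d_0 a_0 / (b + \sqrt{b^2 - 4 d_0 a_0})$.
General $mD + nA$ equilibria are solved numerically by bisection
(`solve_equilibrium_mn()`); both routes are cross-checked against each other
in the test suite.

Three classical analyses sit on top:

* **Job's continuous variation** (`job_analysis()`): at fixed total
  concentration, the absorbance maximum versus donor mole fraction $x$ falls
  at $x = m/(m+n)$ for a $D_mA_n$ complex. The maximum is located by a local
  quadratic fit through the top five points rather than a raw argmax — on
  noiseless data the two coincide, while under noise the fit is markedly more
  stable. The fitted $x_{max}$ is snapped to the nearest ratio among
  1:1, 1:2, 2:1, 1:3, 3:1; anything farther than 0.06 in mole fraction is
  reported `indeterminate` rather than forced.
* **Molar-ratio titration** (`molar_ratio_breakpoint()`): two unconstrained
  line segments are fitted over every admissible split (≥ 3 points each;
  series are at most dozens of points, so exhaustive search is cheap) and
  the intersection abscissa of the best split is the stoichiometric break.
* **Benesi–Hildebrand** (`benesi_hildebrand_fit()`): ordinary least squares
  of $[D]/A$ on $1/[A]$, valid when the acceptor is in large excess; the
  intercept gives $1/\varepsilon_c$ and the intercept/slope ratio gives
  $K_c$. The regression is unweighted by default, matching the plain
  straight-line treatment customary for these plots; an inverse-variance
  weighting is available behind a flag. A nonpositive slope or intercept
  marks the result degenerate instead of erroring, so batch pipelines can
  carry the flag forward.

Thermodynamics follows as
$\Delta G^0 = -2.303\,R\,T\,\log_{10} K_c$ with $R = 8.314$ J mol⁻¹ K⁻¹,
reported in kcal/mol via the thermochemical calorie (4184 J). The default
temperature is 298 K (25 °C with the integer-offset Kelvin convention);
using 298.15 K would change $\Delta G^0$ by under 0.01 kcal/mol, below
reporting precision. The gas constant is taken in J mol⁻¹ K⁻¹ even though
source tables sometimes print "kJ": only the J-based value reproduces
published $\Delta G^0$ magnitudes of order −15 kcal/mol.

# Assay validation

`fit_calibration()` is ordinary least squares of absorbance on concentration
with residual-variance standard errors. Detection limits follow the ICH
convention with $\sigma$ = the standard deviation of the intercept:
$LOD = 3.3\,\sigma/S$ and $LOQ = 10\,\sigma/S$. This choice of $\sigma$ is
deliberate — it is the only reading that reproduces published LOD/LOQ pairs
exactly from their tabulated slope and intercept uncertainty. Precision uses
the sample (n−1) standard deviation throughout: `rsd_percent()` for
replicate RSDs (intra-assay as the mean of per-day RSDs, inter-assay across
day means) and `recovery_percent()` for accuracy. Report rendering rounds
LOD/LOQ to 4 decimals and RSD to 3; full precision is kept on the objects.

# QTAIM descriptor algebra

A bond critical point (BCP) carries the density $\rho$, its Laplacian
$\nabla^2\rho$, the Lagrangian kinetic energy $G$, and the potential energy
density $V$ (all a.u.). Everything else is derived: $H = G + V$, $K = -H$,
the $|V|/G$ ratio, and the interaction-energy estimate $E_{int} = V/2$
(627.5095 kcal/mol per hartree). `classify_hbond()` applies the Rozas
scheme — weak ($\nabla^2\rho > 0$, $H > 0$), moderate ($\nabla^2\rho > 0$,
$H < 0$), strong (both negative) — plus the $|V|/G$ regime (closed-shell
< 1 ≤ intermediate < 2 ≤ shared) and a Popelier-range flag for
$\rho \in [0.002, 0.040]$ a.u. (the range is configurable; it is a standard
window, not a universal constant). The classification is total: $H = 0$
falls in the nonnegative-$H$ (weak) branch and $\nabla^2\rho = 0$ is classed
by the sign of $H$, both carrying a boundary flag, because the published
criteria use strict inequalities and exact zeros must still classify
deterministically.

`check_virial_consistency()` applies the local virial relation
$\tfrac14\nabla^2\rho = 2G + V$ with a default 2% tolerance (about 2 units
in the last digit of a 3-significant-figure table). Published rows
occasionally violate it — typically a typographical Laplacian — and the
package's policy is to *flag, never repair*: the bundled descriptor table
for the linagliptin complexes contains one such row (BCP 126), which the
report marks inconsistent while all other rows pass comfortably.

Counterpoise arithmetic (`bsse_correct()`) adds the BSSE to the raw
supermolecular interaction energy. BSSE magnitudes are conventionally
tabulated in hartree next to kcal/mol energies; the default therefore
converts at 627.5095 kcal/mol per hartree, with `bsse_units = "kcal"`
available when the correction is already converted. This unit inference is
the only one under which the bundled raw/corrected pairs reconcile
(e.g. −75.32 + 0.00338 × 627.5095 = −73.20).

# Spectra

Wavelength–energy conversion uses $hc = 1239.84$ eV·nm, which reproduces
tabulated band-gap pairs at two-decimal rounding (487.5 nm → 2.54 eV,
514.0 nm → 2.41 eV). `simulate_uv_spectrum()` convolves an excited-state
list into a spectrum as a sum of Gaussians *in energy space*, centred at
each transition energy, with amplitude equal to the oscillator strength
(arbitrary units — no absolute molar absorptivities are implied) and a
common FWHM defaulting to 0.333 eV, the customary broadening for TD-DFT
stick spectra. `find_lambda_max()` breaks exact ties toward the longer
wavelength because the CT band is the red-most feature of interest. No
baseline correction or smoothing is ever applied implicitly;
Savitzky–Golay smoothing exists as an explicit preprocessing step.

# The promolecular NCI/RDG engine

The NCI index maps non-covalent interactions through two scalar fields: the
reduced density gradient
$$s(\mathbf r) = \frac{|\nabla\rho|}{2\,(3\pi^2)^{1/3}\,\rho^{4/3}}$$
and the density signed by the middle Hessian eigenvalue,
$\mathrm{sign}(\lambda_2)\,\rho$. Low-$s$, low-$\rho$ regions are
non-covalent contacts; $\lambda_2 < 0$ marks attraction (hydrogen bonds),
$\lambda_2 > 0$ repulsion (steric crowding).

The density is **promolecular**: a sum of unrelaxed spherical atomic
densities, the standard desk-scale stand-in where converged wavefunctions
are unavailable. Each atom (H, C, N, O, Cl) is a sum of single-zeta
Slater-type shells with Slater's-rules exponents,
$\rho_{shell}(r) = occ \cdot N^2 r^{2n-2} e^{-2\zeta r}/4\pi$, a closed form
whose gradient and Hessian are accumulated analytically — no numerical
differentiation anywhere in the engine (finite differences appear only as
the *test oracle*, agreeing to better than $10^{-5}$ relative). Hessian
eigenvalues come from the closed-form trigonometric solution for symmetric
3×3 matrices, vectorised over the grid and checked against LAPACK in the
tests. Promolecular densities exaggerate absolute density values near
nuclei and ignore charge relaxation, so the engine is qualitative: it
reproduces the presence, sign and location of NCI features, not exact
isovalues from self-consistent densities.

Numerical choices: default grid spacing 0.1 bohr with a 2 Å margin box;
a density floor of $10^{-10}$ a.u. before the $\rho^{4/3}$ division
(floored points are excluded from scatter output); coordinates enter in Å
and all internal math and cube output are in bohr (1 Å = 1.8897259886
bohr); a $\lambda_2$ whose magnitude is below $10^{-12}$ of the extreme
eigenvalues is treated as exactly zero so the sign convention is
deterministic.

One design point deserves emphasis. In a promolecular density the midpoint
between *any* two atoms — bonded or not, at any separation — is a saddle
with two negative tangential curvatures, i.e. $\lambda_2 < 0$; truly
positive $\lambda_2$ needs ring- or cage-like surroundings. Consequently
the intramolecular H···H saddle inside each water monomer of the test dimer
produces a permanent negative-signed, low-RDG feature that would mask the
*intermolecular* hydrogen-bond signature. `nci_scatter()` therefore offers
the standard intermolecular filter: with a fragment partition on the
geometry, grid points where one fragment contributes more than 95% of the
density are dropped. With it, the hydrogen-bond trough (low RDG at
$\mathrm{sign}(\lambda_2)\rho \in [-0.05, -0.01]$ a.u.) is present for a
water dimer at 1.9 Å H···O separation and vanishes at 4.0 Å, as it must —
the decision is carried by the density-magnitude window, not by a sign
flip.

# Synthetic data and what the tests show

Every analysis stage has a generator with known ground truth
(`gen_titration()`, `gen_job_series()`, `gen_calibration()`,
`gen_assay_replicates()`, `gen_hbond_dimer()`), all pure functions of their
specification and seed (the RNG state of the caller is saved and restored).
Defaults mirror the study conditions: titrations with donor 3 µM against
acceptor 1–4 µM, Job series at total 1×10⁻⁴ M with 11 mole fractions,
calibration designs spanning the published linear ranges. Noise is
multiplicative on absorbance by default, since photometric noise scales
with signal at these absorbances; an additive option exists.

Two caveats frame what passing tests demonstrate. First, the published
titration design (donor 3 µM, acceptor 1–4 µM) violates the acceptor-excess
assumption of the Benesi–Hildebrand linearisation; the generator can
reproduce that design, but parameter-recovery claims use an excess-acceptor
design (donor 1 µM, acceptor 100–1000 µM), where the recovered $K_c$ has
median relative error below 5% noiseless and below 15% at 1% noise over 20
seeds and $K_c \in \{10^3, 10^4, 10^5\}$. Published $K_c$ magnitudes of
$10^{10}$–$10^{12}$ L/mol cannot be re-derived without the raw absorbances,
so only $\Delta G^0(K_c)$ is reproduced. Second, the generators emulate
idealised instruments: no drift, stray light or temperature dependence, and
the toy dimer geometries are rigid standard monomers — so NCI results
validate the engine's mathematics, not any particular optimised complex
geometry.

Problem sizes used by the shipped checks: Job analysis at 11 points,
recovery at 3 × 2 × 20 simulated titrations of 8 points, and NCI grids at
0.1 bohr spacing over a water-dimer box (roughly 10⁶ points), all
comfortably desk-scale.

# Pipeline and provenance

`run_pipeline()` dispatches the stages (`simulate`, `job`, `titrate`, `bh`,
`thermo`, `validate`, `qtaim`, `nci`) over the CSV/XYZ interfaces and wraps
every result with the exact configuration used plus an MD5 digest of each
input file, so re-running with identical inputs and seed yields identical
result JSON. A thin `Rscript` wrapper (`inst/cli/ctclab`) exposes the same
stages from a shell; the R functions remain the primary interface.

# Known limitations

* No multi-wavelength global fitting, 2:1 Benesi–Hildebrand variants, or
  van't Hoff temperature series (single-temperature design).
* The promolecular engine supports H, C, N, O, Cl and is qualitative by
  construction; no wavefunction file readers, no critical-point search, no
  isosurface rendering (cube files delegate that to standard viewers).
* Validation covers linearity, LOD/LOQ, precision and recovery; no
  robustness designs or specificity scoring.
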