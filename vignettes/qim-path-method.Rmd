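---
title: "Tunneling splittings from the imaginary-mode reaction path"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tunneling splittings from the imaginary-mode reaction path}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qimpath)
```

## The model

A symmetric double well supports pairs of nearly degenerate levels whose
gap — the tunneling splitting — is set by the barrier the light atom moves
through. `qimpath` computes these splittings from a one-dimensional cut of
the full potential-energy surface: the rectilinear path along the
imaginary-frequency normal mode of the transition state.

The procedure is, in order:

1. **Normal-mode analysis at the saddle point.** The Cartesian Hessian is
   mass-weighted (masses in electron-mass units, so all quantities are in
   Hartree atomic units and the mass-weighted coordinate carries its own
   mass of 1), rigid translations and rotations are projected out by
   representing the Hessian in the orthogonal complement of an explicit
   translation/rotation basis, and the result is diagonalised. A valid
   transition state has exactly one imaginary mode; anything else is a hard
   error, not a warning.
2. **Path relaxation.** For each value of the path coordinate
   $Q_\mathrm{im}$, the energy is minimized over the coefficients of the
   remaining saddle-point modes. The march starts at the saddle point,
   proceeds in increments of 0.05 mass-weighted a.u., warm-starts each
   point from its inward neighbour (keeping the relaxation on one valley
   branch), and continues past the minima until the energy has risen a
   configurable amount above the lowest point found.
3. **Bound states.** The tabulated profile is interpolated with a cubic
   spline and the 1d Schrödinger equation
   $[-\tfrac12 \partial^2/\partial Q_\mathrm{im}^2 + V(Q_\mathrm{im})]\psi_n
   = E_n\psi_n$ is solved with a sinc (uniform-grid) discrete variable
   representation, whose kinetic matrix is known in closed form and whose
   potential matrix is diagonal. Splittings are the gaps of consecutive
   level pairs below the barrier.

The kinetic-energy operator is exact for a rectilinear path; what is
neglected is the vibrational-angular-momentum (Coriolis) coupling of the
Watson Hamiltonian, which is small for H-atom transfer in molecules of this
size, and any zero-point motion of the orthogonal modes (no vibrationally
adiabatic correction is applied — adding one is known to degrade
H-transfer splittings). The main physical limitation is the fixed,
straight path: corner-cutting tunneling paths cannot be represented, so
splittings far below about 1 cm⁻¹ are outside the method's reliable range.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `step` (path increment) | 0.05 | mass-weighted a.u. | a few hundred points suffice for a good spline; the default is deliberately dense because each relaxation is cheap |
| `energy_cap_cm1` (stop rule) | max(4·barrier, 5000) | cm⁻¹ above the minimum | how far the repulsive walls are followed; see below |
| `gtol` (reduced gradient) | 1e-8 | hartree per a.u. | Newton convergence in the orthogonal subspace |
| `n_points` (1d DVR grid) | 501 | — | verified by an automatic doubling check (default: lowest 8 levels must move < 0.01 cm⁻¹) |
| `effective_mass` | 1 | mass-weighting mass | 2 emulates H→D transfer on a fixed profile |
| `imag_tol` | 10 | cm⁻¹ | eigenvalues below −(10 cm⁻¹)² count as imaginary, avoiding noise misclassification |

**Wall height and DVR convergence.** The default stop rule follows the
walls to max(4·barrier, 5000 cm⁻¹) above the minimum, which is ample for
the ground pair. The doubling check is stricter than that: states
approaching the wall top feel the truncation of the grid (the eigenfunction
is forced to zero against a finite potential, which degrades the otherwise
spectral convergence of the sinc basis), so converged 8-state tables want
walls of order 10–20·10³ cm⁻¹. The cap is a plain argument; the acceptance
computations use 9000 cm⁻¹ for the model profiles, whose splittings are
then stable to well under 0.01 cm⁻¹ under grid doubling.

**Energy references.** Profiles are stored relative to the transition
state (with the absolute energy recorded); level tables are reported
relative to the potential minimum, located by refining the spline below
grid resolution — the minimum *on* the grid wobbles by
O(step² × curvature) between grids, which would contaminate comparisons at
the 0.1 cm⁻¹ level.

## Mass convention

Mass weighting uses electron masses (true atomic units), not amu. The
choice rescales $Q_\mathrm{im}$ — wells of an H-transfer system then sit
at tens of a.u. — but cancels exactly in every energy: with amu weighting
both the coordinate and the effective mass rescale, leaving the spectrum
unchanged. The convention is fixed once so that profiles, splittings and
file formats are mutually consistent.

## The closed-form relaxed path and its parametrisation

The coupled model potentials expose
$V_\mathrm{rel}(Q_0) = V_\mathrm{dw}(Q_0) - \sum_i (c_i Q_0^2 + b_i Q_0)^2
/ (2\omega_i^2)$, the relaxation at *frozen* $Q_0$. When all bilinear
couplings $b_i$ vanish the saddle-point Hessian is diagonal, the imaginary
mode is exactly the $Q_0$ axis, and this closed form *is* the pipeline's
$V(Q_\mathrm{im})$ — the configuration used for the end-to-end exactness
check (agreement at every grid point to better than 1e-10 hartree). With
$b_i \ne 0$ the imaginary mode mixes into the bath and freezing
$Q_\mathrm{im}$ is not freezing $Q_0$; the closed form then describes a
different (equally well-defined) parametrisation of the relaxed valley.
`make_mode_set()` lets a caller relax along an explicit axis when that is
the quantity wanted.

The same geometry explains the IRC-projection guarantee: projecting the
relaxed-path geometries themselves onto $\vec q_\mathrm{im}$ recovers the
profile identically, and for symmetric-coupling models the analytic curved
valley projects onto the exact profile too. A true steepest-descent path
is a *different* curve — its points are not constrained minima of the
hyperplanes — so projecting an external IRC reproduces the relaxed profile
only approximately (they agree at the saddle point and the minima), which
is precisely the approximation the projection workflow accepts in exchange
for not needing a global surface. The projected segment also ends at the
minimum; the repulsive walls must come from the harmonic extension.

## Zero-order levels: the divider treatment

The two-level analysis of an asymmetric well needs per-well levels with
tunneling suppressed. Both wells are split at the barrier-top abscissa.
Two treatments are implemented:

* **plateau** (default): beyond the divider the potential is held at the
  barrier-top value, so the zero-order state decays under a flat barrier;
* **hard**: an infinite wall at the divider (the DVR domain is truncated
  there).

The hard wall compresses the well and pushes its level up by a few percent
of the well spacing; because the barrier-top abscissa shifts toward the
raised well under a tilt, the bias is *differential* and inflates the
apparent detuning $d$, to the point of violating the two-level lower bound
$\Delta \ge 2|d|$ at large detuning. The plateau form tracks the two-level
decomposition of the full spectrum to a few tenths of a percent across a
resonance scan and preserves the bound, so it is the default; the hard
wall is kept as an option, and shifting the divider by a few percent of
the well width moves plateau zero-order levels by far less than the
detunings being resolved.

## What the model potentials emulate — and what they do not

The fixtures stand in for full-dimensional molecular surfaces:

* `quartic_double_well` is the generic symmetric double well; its outer
  wall is strongly anharmonic over the zero-point amplitude.
* `gaussian_double_well` (harmonic base + Gaussian barrier) has an outer
  wall that tends to its harmonic asymptote — much closer to molecular
  H-transfer wells, which are near-harmonic over the relevant amplitudes.
  The presets use this form; their barrier heights (1400 and 1172 cm⁻¹),
  well positions (±36, ±40 a.u.) and bath frequencies (400–1800 cm⁻¹)
  are chosen so splittings land in the 1–100 cm⁻¹ regime of intramolecular
  H transfer, and the well-shape parameter is chosen so that replacing the
  true walls by the relaxed-harmonic extension changes the ground
  splitting by a few percent, the behaviour reported for real systems.
  They are synthetic: no preset is a fit to any molecule.
* `oho_chain_pes` is a three-particle donor–H–acceptor chain whose
  potential is symmetric under swapping the ends. A purely harmonic bath
  attached to a double well in a *linear* combination of coordinates
  produces an exactly symmetric relaxed profile for any masses (the
  constrained quadratic minimisation preserves the parity); the chain
  therefore carries a cubic symmetric coupling $g\,u^2(y_1-y_3)$, through
  which unequal end masses (¹⁶O vs ¹⁸O) break the mass-weighted
  reflection and make the two wells differ in shape at equal depth — the
  isotope-induced zero-point asymmetry scenario, where the observed
  splitting roughly doubles while the inferred tunneling coupling stays at
  the symmetric half-splitting.

What passing tests on these fixtures do *not* show: performance on real
Born–Oppenheimer surfaces (no molecular PES is bundled), methyl-rotor or
other internal-rotation complications (the Watson-Hamiltonian picture
cannot describe them), corner-cutting dynamics, and vibrational-angular-
momentum effects. The paper-scale benchmark splittings for real molecules
require machine-learned surfaces that are out of scope here.

## Numerical choices

* **Constrained minimiser**: Newton in the reduced subspace with an
  eigenvalue-shift safeguard and a step-norm cap (2 a.u.); a step is only
  accepted downhill, and the shift is inflated on rejection. Convergence
  is declared at reduced-gradient ∞-norm < 1e-8; 200 iterations is a hard
  failure, reported with the last gradient norm. At the saddle point the
  orthogonal Hessian block is positive definite, so the first point
  converges immediately and continuation keeps later points on branch.
* **Mirroring**: for a declared-symmetric system only the positive half is
  computed; the claim is verified by relaxing a few negative points and
  comparing to 1e-8 hartree, so a silently asymmetric potential is an
  error, not a wrong answer.
* **Spline**: `stats::splinefun(method = "fmm")`, which reproduces
  polynomials through cubic order globally (a natural spline would not,
  at the ends); evaluation outside the tabulated range is an error rather
  than extrapolated wall fabrication.
* **Sign conventions / tie-breaks**: every eigenvector is flipped so its
  largest-magnitude component is positive — physics is sign-invariant but
  paths become reproducible. 2d assignments count wavefunction sign
  changes on the slice through the maximum marginal density; if the
  neighbouring slices disagree the state is flagged ambiguous instead of
  guessed.
* **Degenerate inputs**: non-symmetric Hessians, mode sets with zero or
  two imaginary modes, domains not containing the potential minimum,
  dividers outside the domain, tilts large enough to erase a well, and
  product bases above the memory guard all raise errors with the offending
  quantity in the message. A single-well potential passed to the
  splitting pairing warns and pairs nothing.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on the analytic
fixtures: paths of a few thousand 7-dimensional relaxations, 1d DVR grids
of 301–801 points, 2d product bases up to 64×64, and resonance scans over
nine tilt values. These sizes keep every check exact at the stated
tolerances while the whole suite completes in a few minutes on one core.

## Known limitations

* Only M ≤ 2 relaxed coordinates are implemented (the API reserves the
  general multi-mode form).
* The 2d solver is a dense direct-product diagonalisation with a basis
  guard; iterative eigensolvers are out of scope.
* Rotational structure, VAM corrections and curvilinear (internal
  coordinate) modes are not treated.
* The harmonic-oscillator exactness check at its canonical settings
  (513 points, domain ±60) is limited by domain truncation of the n = 7
  state at about 1e-8 hartree; widening the domain to ±65 removes the
  effect entirely (the suite documents both).
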