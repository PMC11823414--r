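---
title: "Approximate Hamiltonians from a linear vibronic coupling model and electron spin dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate Hamiltonians from a linear vibronic coupling model and electron spin dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcspin)
```

## The problem

The electron spin dynamics of an anisotropic lanthanide complex in solution
are driven almost entirely by the time-varying ligand field: as the molecule
and its solvent shell move, the crystal-field part of the molecular
Hamiltonian fluctuates on the femtosecond scale, and these fluctuations
modulate the spin states.  Simulating this requires the molecular (or spin)
Hamiltonian at every step of a molecular dynamics (MD) trajectory.  Doing so
with a multiconfigurational electronic-structure calculation at each step is
accurate but extremely expensive; the linear vibronic coupling (LVC) model
offers a cheap approximation: parametrize the Hamiltonian once at a
reference ("anchor") geometry and extrapolate linearly to nearby geometries.

This package implements that workflow end to end, together with the
diagnostics needed to decide *how often* the LVC model must be
re-parametrized: a truncation-error metric, a density-matrix similarity
metric, reparametrization schedulers (fixed interval, bisection, and an
RMSD-threshold adaptive rule), and a seeded synthetic data generator with a
quadratic ground-truth model so the full machinery is testable without any
electronic-structure software.

## The model

The molecular Hamiltonian is split as
$\hat H = \hat H^{\mathrm{MCH}} + \hat H^{\mathrm{SOC}}$,
where the molecular Coulomb Hamiltonian (MCH) contains only spin-free
operators and the spin–orbit coupling (SOC) term couples spin and orbital
degrees of freedom.  In the eigenbasis of the MCH at the anchor geometry
$\mathbf R = \mathbf 0$, the MCH matrix at a displaced geometry
$\Delta\mathbf R$ is expanded to first order:

- diagonal entries $E_m + \boldsymbol\kappa^{(m)}\cdot\Delta\mathbf R$,
  with $\boldsymbol\kappa^{(m)}$ the state gradients;
- off-diagonal entries
  $\boldsymbol\lambda^{(mn)}\cdot\Delta\mathbf R$, with
  $\boldsymbol\lambda^{(mn)}$ the nonadiabatic coupling (NAC) vectors.

`evaluate_mch()` builds this matrix; `diagonalize()` yields the displaced
eigenstates.  The SOC term is taken in the atomic mean-field (AMFI) form
$\hat H^{\mathrm{SOC}} = \hat{\mathbf V}\cdot\hat{\mathbf S}$: three spatial
operator components $V_{x,y,z}$ dotted with the spin operator.  The spatial
components are transported into the displaced eigenbasis with the same
unitary that diagonalizes the MCH (the AMFI matrices themselves are treated
as geometry-independent), and the full matrix is assembled over a single
spin multiplicity by the Wigner–Eckart structure
$H^{\mathrm{SOC}} = \sum_\alpha V_\alpha \otimes S_\alpha$
(`assemble_soc()`).  `lvc_hamiltonian()` chains these steps; at the anchor
geometry it reproduces the reference Hamiltonian exactly, which is both a
mathematical identity of a Taylor expansion at its expansion point and the
package's most basic correctness check.

### Basis conventions

The product basis is spin-free-state–major with $M_S$ descending within each
state.  Since no universal convention exists, this one is fixed and used
everywhere.  Degenerate eigenvectors are made reproducible by phase-fixing
(largest-magnitude component real-positive) and ordering degenerate columns
by their first significant component.

### Comparison basis

The SOC assembly is basis-covariant:
$(U^\dagger V U)\otimes S = (U\otimes 1)^\dagger (V\otimes S)(U\otimes 1)$.
The total LVC Hamiltonian can therefore be written either in the displaced
MCH eigenbasis (as a state-interaction calculation would report it) or in
the anchor's own product basis (`basis = "reference"`).  The two are
unitarily equivalent, but only the reference representation is continuous
in $\Delta\mathbf R$: comparing two Hamiltonians each expressed in its own
adiabatic basis produces order-one artifacts whenever an avoided crossing
reorders eigenstates between the two models, because the matrix elements get
permuted even though the operators are close.  All error metrics and the
propagated Hamiltonian series therefore use one common reference basis
(`hamiltonian_series()` transports each anchor's matrices through the stored
unitary connecting it to the base anchor).  This mirrors standard practice
of comparing spin Hamiltonians in a fixed angular-momentum basis.

## The spin Hamiltonian and Stevens projection

Within one LS term the electronic states are described by the effective
Hamiltonian
$$\hat H = \lambda\,\hat{\mathbf L}\cdot\hat{\mathbf S}
 + \sum_{k\in\{2,4,6\}}\sum_{q=-k}^{k}\theta_k B_k^q\,\hat O_k^q ,$$
in the $|L\,S\,M_L\,M_S\rangle$ basis ($M_L$-major, descending).  The
$\hat O_k^q$ are the 27 extended Stevens operators (cosine combinations for
$q>0$, sine for $q<0$), built from ladder operators and the standard
$J_z$-polynomials (`stevens_operators()`); $\theta_k$ are the
operator-equivalent factors, available as the tabulated
$f^9$ (Dy$^{3+}$) constants
$\alpha=-2/315$, $\beta=-8/135135$, $\gamma=4/3864861$ or as unit factors
for toys (`stevens_theta()`).  The operator set
$\{\hat{\mathbf L}\cdot\hat{\mathbf S}\}\cup\{\theta_k\hat O_k^q\otimes 1\}$
is mutually orthogonal under the trace inner product, so the least-squares
projection of any Hermitian matrix onto it reduces to ratios of traces
(`project_spin_parameters()`); the Frobenius norm of the part of the matrix
outside the operator span is reported as a residual diagnostic.  For
matrices built by `build_spin_hamiltonian()` the projection round-trips to
machine precision; for half-integer spin and real parameters every
eigenvalue is doubly degenerate (Kramers pairs), which the tests verify on
random parameter sets.

Mapping ab initio spin–orbit eigenstates onto $|L\,S\,M_L\,M_S\rangle$
labels is deliberately out of scope: the synthetic systems carry explicit
labels, and the general angular-momentum-matching problem is left to the
parametrization producer.

## Spin dynamics

The density matrix is column-stacked into a vector, and the Liouville–von
Neumann equation becomes
$\mathrm d|\rho\rangle/\mathrm dt = -\mathrm i\,G\,|\rho\rangle$ with
$G = 1\otimes H - H^{\mathsf T}\otimes 1$ (`build_liouvillian()`; the
convention is pinned by a commutator oracle test).  With a
piecewise-constant Hamiltonian series at $\delta t = 1$ fs spacing, each
step applies $\exp(-\mathrm i\,G\,\delta t)$ by a Taylor
matrix-exponential-times-vector algorithm (`expm_times_vector()`):

- the step is divided into equal substeps, their number the infinity norm
  of the (dimensionless) exponent $-\mathrm i\,G\,\delta t$ rounded up,
  which guarantees monotone convergence of the series;
- within a substep, terms are added until the next term changes no element
  by more than `taylor_cutoff` (default $10^{-14}$);
- exceeding `max_taylor_terms` (default 200) signals a pathological
  norm/cutoff combination instead of silently looping.

`propagate()` rotates the whole series into the eigenbasis of the $t=0$
Hamiltonian, starts from a thermal state (Boltzmann populations over the
initial eigenvalues at 300 K by default, off-diagonals zero) and logs trace,
purity, substep and term counts per step.  Internally the generator is
applied through the commutator $H\rho-\rho H$ on the reshaped matrix rather
than by materializing the $d^2\times d^2$ superoperator — the algebra is
identical (the substep count uses the exact superoperator infinity norm
derived from $H$), but the cost per step drops from $O(d^4)$ to two $d\times
d$ matrix products.  The dynamics are entirely unitary: trace and purity
conservation over long runs, including across reparametrization
discontinuities, are acceptance-tested at $10^{-10}$ and $10^{-8}$.

Femtoseconds are converted to atomic time units
(1 a.u. = 0.02418884254 fs) before exponentiation; energies are in hartree
throughout, coordinates in bohr internally and angstrom on disk
(1 Å = 1.8897261246 bohr).

## Error, similarity and scheduling diagnostics

The truncation error of an approximate Hamiltonian is the relative Frobenius
deviation
$\lVert H^{\mathrm{LVC}}-H^{\mathrm{ref}}\rVert_F/\lVert H^{\mathrm{ref}}\rVert_F$
(`hamiltonian_error()`), normalized by the reference matrix.  The metric is
gauge-sensitive to a global energy shift; an option removes the mean
diagonal from both matrices first, but the default keeps the raw gauge.
Term-wise attribution (`term_errors()`) builds SOC-only and
crystal-field-only Hamiltonians from two parameter sets and reports each
error separately.

Two propagated trajectories are compared by the normalized inner product of
their vectorised density matrices (`similarity()`).  The real part is the
default — it is sign-sensitive and decays from 1 as the approximate
trajectory dephases from the reference — with the modulus available as an
option.

Schedulers decide which anchor serves each frame.  Fixed and bisection
schedules assign every frame to its temporally nearest anchor (an LVC model
predicts backward as well as forward), with ties resolved toward the
*earlier* anchor.  The adaptive scheduler walks the trajectory and counts
each first passage of the Kabsch RMSD (relative to the current reference
geometry) through the threshold as a crossing: at odd crossings only the
RMSD reference moves, at even crossings a new anchor is created — the
every-other-crossing rule, which exploits the forward/backward symmetry.
The crossing test uses `rmsd >= threshold` with a $10^{-9}$ relative
tolerance so that exactly-on-threshold constructions are not lost to
floating-point noise.  Under this rule, on a trajectory whose RMSD grows
monotonically between crossings, no frame is ever further than twice the
threshold from its serving anchor.

RMSD itself is computed after centroid removal and an optimal proper
rotation (Kabsch, reflections excluded), without mass weighting, over all
sites including solvent point charges by default — a site mask restricts it
to a subset (e.g. solute-only) since conventions differ on whether solvent
enters the RMSD.  Point charges that crossed a periodic boundary are first
translated to the adjacent image that minimizes their displacement from the
reference (`unwrap_to_reference()`, orthorhombic boxes only).

## The synthetic study system

Because no reference parametrizations are distributed, the package generates
its own study conditions (`generate_parametrization()`,
`ground_truth_model()`, `generate_trajectory()`), all deterministic from a
seed:

- **States and spin.** Default 18 spin-free states with $S=5/2$ (product
  dimension 108), emulating the sextet manifold of an $f^9$ ion; the
  pipeline diagnostics use a 12-state variant for speed.
- **Energies.** Spread over 0.01 hartree (≈2200 cm$^{-1}$), with level
  spacings jittered within 0.4–1.6× the mean.  Bounded spacings matter:
  accidental quasi-degeneracies make the truncation error at an avoided
  crossing scale like $a^2/\mathrm{gap}(a)$ instead of $a^2$, destroying the
  quadratic-order scaling that a Taylor-truncation analysis predicts and
  that the acceptance suite checks.
- **Couplings.** Gradients and NACs are zero-mean Gaussians with standard
  deviations 0.03 and 0.015 $E_h a_0^{-1}$, the magnitude regime of a
  geometry-sensitive lanthanide complex; SOC matrices are random Hermitian
  with 0.001 hartree elements.
- **Ground truth.** A quadratic model adds sparse second-order couplings
  (six random Cartesian pairs per matrix element, sd 0.05 $E_h a_0^{-2}$),
  so the linear model has a nonzero, geometry-correlated truncation error,
  while evaluation stays cheap.  With these defaults a single anchor
  reaches a maximum error of roughly 4–6 % over a 100-frame window —
  fluctuating in the regime reported for real parametrization studies —
  and 10-frame reparametrization keeps it well below 1 %.
- **Trajectories.** Superpositions of sinusoidal per-site modes (default
  amplitudes 0.06/0.04 Å, periods 450/700 fs) plus optional jitter; frame 0
  equals the reference, and a negative time offset produces frames
  bracketing the anchor for forward/backward error studies.  Because each
  mode displacement is odd in time, the constructed $\pm t$ errors are
  near-symmetric by design.
- **Re-parametrization.** `lvc_reparametrize()` produces the anchor an
  explicit calculation at a displaced geometry would give for the quadratic
  truth: the exact first-order expansion about the new geometry, expressed
  in the truth's eigenbasis there, with the SOC components transported by
  the same unitary.

What the synthetic system does *not* emulate: real vibrational spectra and
anharmonicity, temperature-dependent mode occupations, solvent exchange,
state-dependent SOC geometry dependence, and any quantitative property of a
specific complex.  Passing tests demonstrate the correctness of the
machinery and the qualitative error/similarity/scheduling phenomenology, not
predictions for a particular molecule.

The magic-angle toy (`point_charge_b20()`) evaluates the leading
point-charge crystal-field parameter
$B_2^0 \propto \sum_i q_i (3\cos^2\theta_i-1)/(2r_i^3)$ (proportionality
constant 1 in atomic units, no radial or shielding factors) and exhibits the
sign change at $\theta = \arccos(1/\sqrt3) \approx 54.74^\circ$ that makes
near-magic-angle coordination geometries so sensitive.

## Problem sizes and runtimes

The test and acceptance workloads are sized for a single CPU: the
conservation run uses 1000 steps at $d=12$; the propagator oracle 200 random
generators at $d\le 8$; Stevens round-trips 100 sets at dimension 66; the
pipeline diagnostics a 12-state, 100-frame system with fixed schedules of
100/40/20/10 frames.  These sizes were chosen so the full suite completes in
a few minutes while every qualitative contrast (error growth, schedule
ordering, similarity decay, RMSD correlation) is comfortably resolved.

## Known limitations

- Single spin multiplicity only; multi-multiplicity Wigner–Eckart blocks
  are not implemented.
- Orthorhombic periodic boxes only; no triclinic cells.
- XYZ is the only trajectory format.
- Unitary dynamics only — no dissipation, no external field; the density
  matrix formalism is retained anyway so a Lindblad extension would slot in.
- The Stevens projection requires the Hamiltonian already expressed in (or
  labeled onto) the $|L\,S\,M_L\,M_S\rangle$ basis.
- LVC anchors are linear models; quadratic vibronic coupling appears only in
  the synthetic ground truth, not as a usable model class.

## A short example

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(seed = 1, n_states = 12,
                                    n_frames = 100, interval = 10))
print(run)
head(run$error_trace)
```
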