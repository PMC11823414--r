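# lvcspin

Approximate molecular and spin Hamiltonians along a molecular dynamics
trajectory from a linear vibronic coupling (LVC) model, and electron spin
dynamics simulations driven by them.

## The problem

The spin dynamics of anisotropic lanthanide complexes in solution — for
example the Dy(III) PARASHIFT-type imaging agents — are driven by the
femtosecond-scale fluctuation of the ligand field as the complex and its
solvent shell move.  Simulating them requires the molecular Hamiltonian at
every MD time step, which is prohibitively expensive at the
multiconfigurational level of theory.  The LVC model parametrizes the
Hamiltonian once, at an anchor geometry, from the state energies *E*<sub>m</sub>,
state gradients **κ**<sup>(m)</sup> and nonadiabatic couplings
**λ**<sup>(mn)</sup>, and extrapolates linearly:

- MCH matrix at displacement ΔR: diagonal *E*<sub>m</sub> + **κ**<sup>(m)</sup>·ΔR,
  off-diagonal **λ**<sup>(mn)</sup>·ΔR;
- spin–orbit coupling: H<sup>SOC</sup> = Σ<sub>α</sub> V<sub>α</sub> ⊗ S<sub>α</sub>,
  with the spatial AMFI components V<sub>α</sub> transported into the
  displaced eigenbasis.

The package provides, for this workflow:

- **lvc_core** — Hamiltonian reconstruction (`evaluate_mch`, `diagonalize`,
  `assemble_soc`, `lvc_hamiltonian`) with a JSON parametrization container;
- **spin projection** — extended Stevens operators, the effective spin
  Hamiltonian λ **L**·**S** + Σ θ<sub>k</sub> B<sub>k</sub><sup>q</sup> O<sub>k</sub><sup>q</sup>,
  and its trace-orthogonal projection from any Hermitian matrix;
- **geometry** — XYZ trajectories, Kabsch RMSD, periodic-image unwrapping;
- **propagation** — vectorised Liouville–von Neumann dynamics with the
  Taylor matrix-exponential-times-vector algorithm (infinity-norm substep
  rule) and thermal initialization;
- **metrics** — relative Frobenius truncation error, term-wise error
  decomposition, density-matrix similarity;
- **schedulers** — fixed-interval, bisection, and RMSD-threshold adaptive
  reparametrization (the every-other-crossing rule);
- **synthetic data** — seeded parametrization generators, a quadratic
  ground-truth model standing in for per-step reference calculations, and
  harmonic trajectories, so everything runs offline.

## Worked example

A seeded synthetic system (12 sextet spin-free states, 100 frames at 1 fs)
propagated with a single anchor versus re-parametrization every 10 fs:

```r
library(lvcspin)

run10 <- run_pipeline(pipeline_config(seed = 1, n_states = 12,
                                      n_frames = 100, interval = 10))
print(run10)
#> LVC pipeline run [config 5aa02e1f]
#>   12 states, S = 2.5, 100 frames, schedule fixed (10 anchors)
#>   max error      : 0.0005 (0.05%)
#>   final similarity: 0.999999

run1 <- run_pipeline(pipeline_config(seed = 1, n_states = 12,
                                     n_frames = 100, interval = 1000))
print(run1)
#> LVC pipeline run [config 6ac02b6f]
#>   12 states, S = 2.5, 100 frames, schedule fixed (1 anchors)
#>   max error      : 0.0594 (5.94%)
#>   final similarity: 0.903755
```

Reading: with a single anchor the truncation error saturates near 6 % over
100 fs and the propagated density matrix visibly dephases from the
ground-truth trajectory (similarity 0.904); re-parametrizing every 10 fs
keeps the error below 0.1 % and the dynamics essentially exact
(similarity 0.999999).  The `run$error_trace`, `run$similarity` and
`run$log` data frames hold the per-frame error/RMSD traces, the similarity
trace and the trace/purity conservation log.

Spin-parameter projection works on any Hermitian matrix in the
|L S M\_L M\_S⟩ basis and round-trips exactly on matrices built from
parameters:

```r
p  <- spin_params(lambda = 1.2e-3, B = c(k2q0 = 2e-4, k4q3 = -5e-5),
                  theta = "dy3+")
pr <- project_spin_parameters(build_spin_hamiltonian(p),
                              angular_basis(5, 5/2), theta = "dy3+")
pr$lambda                       # 0.0012
attr(pr, "residual_norm")       # ~2.5e-18 hartree
```

A thin command-line wrapper over these functions is installed at
`inst/scripts/lvc-tool.R` (subcommands `synth`, `rmsd`, `schedule`,
`project`, `run`).

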