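## Seed-deterministic generators: synthetic LVC parametrizations, a
## quadratic ground-truth Hamiltonian model (so the linear model has a
## nonzero, geometry-correlated truncation error), harmonic test
## trajectories, and a point-charge crystal-field toy.

#' Default synthetic scales
#'
#' The study conditions of the synthetic system: a spin-free energy window
#' of 0.01 hartree (~2200 cm^-1, a lanthanide LS-term crystal-field span),
#' gradient and NAC scales of a few 10^-2 hartree/bohr (the magnitude
#' regime of a geometry-sensitive Dy(III) complex), an SOC operator scale
#' an order below the energy window, and quadratic couplings sized so that
#' single-anchor truncation errors span roughly 0-10% over a 100-frame,
#' ~0.1 A-amplitude trajectory.
#'
#' @return named numeric vector of scales (atomic units)
#' @export
lvc_synth_scales <- function() {
  c(energy_window = 0.01,     # hartree; span of the spin-free energies
    kappa = 0.03,             # hartree/bohr; per-component gradient sd
    nac = 0.015,              # hartree/bohr; per-component NAC sd
    soc = 0.001,              # hartree; SOC operator element sd
    quadratic = 0.05)         # hartree/bohr^2; quadratic coupling sd
}

#' Generate a synthetic LVC reference parametrization
#'
#' Emulates the output of a multiconfigurational parametrization for an
#' n-state, spin-S system: ascending energies in a stated window, zero-mean
#' Gaussian gradients and NAC vectors, random Hermitian SOC component
#' matrices, and a random compact reference geometry.  Fully deterministic
#' given the seed.
#'
#' @param n_states number of spin-free states (default 18, a Dy(III)
#'   sextet-manifold preset; total product dimension 108)
#' @param spin_S spin quantum number (default 5/2)
#' @param n_sites number of sites (atoms + point charges)
#' @param scales named vector as [lvc_synth_scales()]
#' @param seed integer seed
#' @param anchor_time anchor time (fs)
#' @param n_charges how many of the sites are solvent point charges
#' @return an [lvc_param()]
#' @export
generate_parametrization <- function(n_states = 18L, spin_S = 5/2,
                                     n_sites = 8L,
                                     scales = lvc_synth_scales(),
                                     seed = 1L, anchor_time = 0,
                                     n_charges = max(0L, n_sites - 4L)) {
  if (n_states < 1L) .stopf("n_states must be >= 1")
  if (any(scales < 0) || !all(is.finite(scales)))
    .stopf("scales must be finite and nonnegative")
  for (nm in names(lvc_synth_scales()))
    if (is.na(scales[nm])) .stopf("scales is missing '%s'", nm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ncart <- 3L * n_sites
  ## compact pseudo-molecular geometry, ~2-4 bohr from the origin
  geometry <- matrix(stats::rnorm(ncart, sd = 2.5), n_sites, 3)
  site_flags <- c(rep("atom", n_sites - n_charges), rep("charge", n_charges))
  ## jittered but bounded level spacings: gaps within 0.4-1.6 of the mean,
  ## so the spectrum has no accidental quasi-degeneracies
  if (n_states > 1L) {
    g <- 0.4 + 1.2 * stats::runif(n_states - 1L)
    energies <- c(0, cumsum(g))
    energies <- energies / max(energies) * scales[["energy_window"]]
  } else energies <- 0
  gradients <- matrix(stats::rnorm(n_states * ncart, sd = scales[["kappa"]]),
                      n_states, ncart)
  nacs <- array(0, dim = c(n_states, n_states, ncart))
  if (n_states > 1L) {
    for (m in seq_len(n_states - 1L)) {
      for (k in (m + 1L):n_states) {
        v <- stats::rnorm(ncart, sd = scales[["nac"]])
        nacs[m, k, ] <- v
        nacs[k, m, ] <- v
      }
    }
  }
  soc <- lapply(c(x = "x", y = "y", z = "z"), function(a) {
    M <- matrix(complex(real = stats::rnorm(n_states^2, sd = scales[["soc"]]),
                        imaginary = stats::rnorm(n_states^2, sd = scales[["soc"]])),
                n_states, n_states)
    .hermitize(M)
  })
  lvc_param(anchor_time = anchor_time, geometry = geometry,
            site_flags = site_flags, energies = energies,
            gradients = gradients, nacs = nacs, soc = soc, spin_S = spin_S)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Quadratic ground-truth Hamiltonian model
#'
#' Augments a reference parametrization with sparse symmetric quadratic
#' couplings Q^(mn) so that the "true" Hamiltonian carries the second-order
#' terms the linear model truncates.  Stands in for an explicit
#' electronic-structure calculation at each displaced geometry.  Coupled
#' coordinate pairs are restricted to a small random subset (`n_modes`
#' Cartesian pairs per matrix element) to keep evaluation cheap.
#'
#' @param base an [lvc_param()]
#' @param quad_scale sd of the quadratic coefficients (hartree/bohr^2)
#' @param n_modes number of coupled Cartesian coordinate pairs per element
#' @param seed integer seed
#' @return object of class `ground_truth`: list with `base` and sparse
#'   coupling table `quad` (data.frame m, n, i, j, coef)
#' @export
ground_truth_model <- function(base, quad_scale = lvc_synth_scales()[["quadratic"]],
                               n_modes = 6L, seed = 1L) {
  stopifnot(inherits(base, "lvc_param"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 7L)
  n <- n_states(base)
  nc <- n_cart(base)
  rows <- list()
  for (m in seq_len(n)) {
    for (k in m:n) {
      ii <- sample.int(nc, n_modes, replace = TRUE)
      jj <- sample.int(nc, n_modes, replace = TRUE)
      cf <- stats::rnorm(n_modes, sd = quad_scale)
      rows[[length(rows) + 1L]] <- data.frame(m = m, n = k, i = ii, j = jj,
                                              coef = cf)
    }
  }
  structure(list(base = base, quad = do.call(rbind, rows)),
            class = "ground_truth")
}

#' Evaluate the ground-truth Hamiltonian at a displacement
#'
#' The linear MCH expansion plus the quadratic terms
#' (1/2) sum coef * dR_i * dR_j per matrix element (applied symmetrically),
#' followed by the same diagonalize / SOC-transform / Wigner-Eckart
#' assembly as the linear model.  With zero quadratic couplings this equals
#' [lvc_hamiltonian()] for every displacement.
#'
#' @param model a [ground_truth_model()]
#' @param disp displacement vector (bohr), length 3N
#' @param basis `"displaced"` (eigenbasis of the ground-truth MCH at the
#'   displacement) or `"reference"` (the base-anchor product basis); see
#'   [lvc_hamiltonian()]
#' @return `ham_matrix`
#' @export
ground_truth_hamiltonian <- function(model, disp,
                                     basis = c("displaced", "reference")) {
  basis <- match.arg(basis)
  stopifnot(inherits(model, "ground_truth"))
  base <- model$base
  Hmch <- ground_truth_mch(model, disp)
  mult <- 2 * base$spin_S + 1
  if (basis == "reference") {
    return(ham_matrix(kronecker(Hmch, diag(mult)) +
                        .as_mat(assemble_soc(base$soc, base$spin_S))))
  }
  eig <- diagonalize(ham_matrix(Hmch))
  Vt <- lapply(base$soc, transform_operator, transform = eig$vectors)
  Hsoc <- assemble_soc(Vt, base$spin_S)
  ham_matrix(kronecker(diag(eig$values), diag(mult)) + .as_mat(Hsoc))
}

#' Ground-truth MCH matrix at a displacement (base-anchor eigenbasis)
#'
#' The linear expansion plus the quadratic terms, before any SOC assembly.
#'
#' @inheritParams ground_truth_hamiltonian
#' @return real symmetric n_states x n_states matrix (hartree)
#' @export
ground_truth_mch <- function(model, disp) {
  stopifnot(inherits(model, "ground_truth"))
  Hmch <- Re(.as_mat(evaluate_mch(model$base, disp)))
  q <- model$quad
  dv <- as.numeric(disp)
  add <- 0.5 * q$coef * dv[q$i] * dv[q$j]
  for (r in seq_len(nrow(q))) {
    Hmch[q$m[r], q$n[r]] <- Hmch[q$m[r], q$n[r]] + add[r]
    if (q$m[r] != q$n[r])
      Hmch[q$n[r], q$m[r]] <- Hmch[q$n[r], q$m[r]] + add[r]
  }
  Hmch
}

#' Generate a harmonic synthetic trajectory
#'
#' Superposes sinusoidal per-site displacement modes (zero at frame 0, so
#' the first frame equals the reference) plus optional seeded Gaussian
#' jitter.  Mode directions are random unit vectors per site, fixed by the
#' seed.  Emulates thermal motion whose RMSD from the starting geometry
#' grows over the window when the periods exceed it.
#'
#' @param ref reference [traj_frame()] (angstrom)
#' @param n_frames number of frames (>= 2)
#' @param dt frame spacing (fs, default 1)
#' @param mode_amplitudes per-mode amplitudes (angstrom)
#' @param mode_periods per-mode periods (fs)
#' @param jitter sd of per-coordinate Gaussian noise (angstrom)
#' @param seed integer seed
#' @param t_offset time of the first frame relative to the reference (fs);
#'   a negative offset yields frames bracketing the reference, which sits
#'   at t = 0 where every mode displacement vanishes
#' @return list of [traj_frame()]
#' @export
generate_trajectory <- function(ref, n_frames = 100L, dt = 1,
                                mode_amplitudes = c(0.06, 0.04),
                                mode_periods = c(450, 700),
                                jitter = 0, seed = 1L, t_offset = 0) {
  stopifnot(inherits(ref, "traj_frame"))
  if (n_frames < 2L) .stopf("n_frames must be >= 2")
  if (any(mode_periods <= 0)) .stopf("mode periods must be positive")
  stopifnot(length(mode_amplitudes) == length(mode_periods))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 13L)
  n <- nrow(ref$coordinates)
  dirs <- lapply(seq_along(mode_periods), function(k) {
    d <- matrix(stats::rnorm(3L * n), n, 3)
    d / sqrt(rowSums(d^2))
  })
  lapply(seq_len(n_frames), function(f) {
    t <- t_offset + (f - 1L) * dt
    xyz <- ref$coordinates
    for (k in seq_along(mode_periods)) {
      xyz <- xyz + dirs[[k]] * mode_amplitudes[k] *
        sin(2 * pi * t / mode_periods[k])
    }
    if (jitter > 0 && t != 0)
      xyz <- xyz + matrix(stats::rnorm(3L * n, sd = jitter), n, 3)
    traj_frame(ref$time + t, xyz, ref$symbols, site_flags = ref$site_flags)
  })
}

#' Synthetic stream whose Kabsch RMSD grows linearly in time
#'
#' An isotropically breathing geometry: coordinates of a centered reference
#' with unit root-mean-square radius are scaled by (1 + rate * t), so the
#' Kabsch RMSD between the frames at t1 and t2 is exactly
#' rate * |t1 - t2| (angstrom).  Used to exercise the adaptive scheduler
#' against the every-other-crossing rule.
#'
#' @param n_frames number of frames
#' @param rate RMSD growth rate (angstrom per fs)
#' @param dt frame spacing (fs)
#' @param n_sites number of sites (>= 4 recommended)
#' @return list of [traj_frame()]
#' @export
linear_rmsd_stream <- function(n_frames = 120L, rate = 0.01, dt = 1,
                               n_sites = 4L) {
  ## centered tetrahedral-ish geometry normalized to unit rms radius
  base <- matrix(c(1, 1, 1,
                   1, -1, -1,
                   -1, 1, -1,
                   -1, -1, 1), 4, 3, byrow = TRUE)
  if (n_sites > 4L)
    base <- rbind(base, 1.5 * base[rep_len(seq_len(4), n_sites - 4L), ])
  base <- sweep(base, 2, colMeans(base))
  base <- base / sqrt(mean(rowSums(base^2)))
  lapply(seq_len(n_frames), function(f) {
    t <- (f - 1L) * dt
    traj_frame(t, base * (1 + rate * t), rep("X", nrow(base)))
  })
}

#' Leading point-charge crystal-field parameter B_2^0
#'
#' The second-order axial crystal-field parameter of a set of point charges
#' in simple electrostatic crystal-field theory:
#' B_2^0 = C * sum_i q_i (3 cos^2(theta_i) - 1) / (2 r_i^3), with the
#' proportionality constant C = 1 in atomic units (charge e, distance bohr,
#' energy hartree; radial expectation values and shielding are not
#' included).  Changes sign across the magic angle
#' theta = acos(1/sqrt(3)) ~ 54.7356 degrees.
#'
#' @param charges data.frame with columns `q` (charge, e), `r` (distance,
#'   bohr, > 0) and `theta` (polar angle, degrees)
#' @return B_2^0 (hartree)
#' @export
point_charge_b20 <- function(charges) {
  stopifnot(all(c("q", "r", "theta") %in% names(charges)))
  if (any(charges$r <= 0)) .stopf("charge distances must be positive")
  th <- charges$theta * pi / 180
  sum(charges$q * (3 * cos(th)^2 - 1) / (2 * charges$r^3))
}
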