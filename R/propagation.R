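#' Vectorised density matrix state
#'
#' Column-stacked density matrix rho as a complex vector of length d^2,
#' tagged with its basis and time.  Validation checks Hermiticity, unit
#' trace, and (optionally) positivity of the reshaped matrix.
#'
#' @param vector complex vector of length d^2 (column-stacked rho)
#' @param basis_tag basis the state is expressed in
#' @param time state time (fs)
#' @param validate check the density-matrix invariants
#' @return object of class `density_state`
#' @export
density_state <- function(vector, basis_tag = "initial-spin-eigenbasis",
                          time = 0, validate = TRUE) {
  d <- sqrt(length(vector))
  if (abs(d - round(d)) > 1e-9) .stopf("state length %d is not a perfect square",
                                       length(vector))
  d <- as.integer(round(d))
  st <- structure(list(vector = as.complex(vector), dim = d,
                       basis_tag = basis_tag, time = as.numeric(time)),
                  class = "density_state")
  if (validate) {
    rho <- state_matrix(st)
    .check_hermitian(rho, tol = 1e-8, what = "density matrix")
    if (abs(Re(sum(diag(rho))) - 1) > 1e-8)
      .stopf("density matrix trace %.12g != 1", Re(sum(diag(rho))))
    ev <- eigen(.hermitize(rho), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      .stopf("density matrix has negative eigenvalue %.3e", min(ev))
  }
  st
}

#' @export
print.density_state <- function(x, ...) {
  rho <- state_matrix(x)
  cat(sprintf("Density state: d = %d, t = %g fs, Tr = %.10g, purity = %.10g\n",
              x$dim, x$time, Re(sum(diag(rho))),
              Re(sum(diag(rho %*% rho)))))
  invisible(x)
}

#' Reshape a density state back to its d x d matrix
#'
#' @param state a [density_state()]
#' @return complex d x d matrix
#' @export
state_matrix <- function(state) {
  matrix(state$vector, state$dim, state$dim)
}

#' Population of a basis state
#'
#' Real part of the corresponding diagonal element of the reshaped density
#' matrix.
#'
#' @param state a [density_state()]
#' @param index basis-state index (1-based)
#' @return population in [0, 1]
#' @export
population <- function(state, index) {
  if (index < 1L || index > state$dim) .stopf("population index out of range")
  Re(state$vector[(index - 1L) * state$dim + index])
}

#' Propagator configuration
#'
#' @param dt time step between Hamiltonians (fs); the trajectory spacing
#' @param taylor_cutoff convergence cutoff: Taylor terms are added until the
#'   next term changes no element by more than this
#' @param temperature initial thermal-state temperature (kelvin)
#' @param max_taylor_terms safety bound per substep
#' @return object of class `propagator_config`
#' @export
propagator_config <- function(dt = 1, taylor_cutoff = 1e-14,
                              temperature = 300, max_taylor_terms = 200L) {
  if (dt <= 0) .stopf("dt must be positive")
  if (taylor_cutoff <= 0) .stopf("taylor_cutoff must be positive")
  structure(list(dt = dt, taylor_cutoff = taylor_cutoff,
                 temperature = temperature,
                 max_taylor_terms = as.integer(max_taylor_terms)),
            class = "propagator_config")
}

#' Liouvillian superoperator of a Hamiltonian
#'
#' Column-stacking generator G = 1 (x) H - H^T (x) 1, so that
#' d|rho>/dt = -i G |rho> reproduces the commutator -i [H, rho].  All
#' eigenvalues of G are real (differences of H's eigenvalues).
#'
#' @param H Hermitian matrix (hartree)
#' @return complex d^2 x d^2 matrix
#' @export
build_liouvillian <- function(H) {
  M <- .as_mat(H)
  .check_hermitian(M, tol = 1e-10, what = "Hamiltonian")
  d <- nrow(M)
  id <- diag(d)
  kronecker(id, M) - kronecker(t(M), id)
}

## exact infinity norm of -i G dt without forming G:
## row (i,j) of G holds H[i,k] (k != i), -H[j,l] (l != j) and H[i,i]-H[j,j]
.liouvillian_inf_norm <- function(H, dt_au) {
  aH <- abs(H)
  rs <- rowSums(aH) - abs(diag(H))      # sum_{k != i} |H_ik|
  d <- nrow(H)
  best <- 0
  for (i in seq_len(d)) {
    v <- rs[i] + rs + abs(diag(H)[i] - diag(H))
    best <- max(best, max(v))
  }
  best * dt_au
}

## shared Taylor stepper: w <- exp(-i * dt_au * A) v where A is given through
## its action `apply_A(v)`; substeps per the infinity-norm rule on -i A dt.
.taylor_exp_action <- function(apply_A, v, dt_au, inf_norm, cfg) {
  n_sub <- max(1L, as.integer(ceiling(inf_norm - 1e-12)))
  h <- dt_au / n_sub
  taylor_max <- 0L
  for (s in seq_len(n_sub)) {
    term <- v
    acc <- v
    k <- 0L
    repeat {
      k <- k + 1L
      if (k > cfg$max_taylor_terms)
        .stopf(paste0("Taylor expansion did not converge within %d terms ",
                      "(substep norm %.3g, cutoff %.3g)"),
               cfg$max_taylor_terms, inf_norm / n_sub, cfg$taylor_cutoff)
      term <- (-1i * h / k) * apply_A(term)
      acc <- acc + term
      if (max(abs(term)) <= cfg$taylor_cutoff) break
    }
    taylor_max <- max(taylor_max, k)
    v <- acc
  }
  attr(v, "substeps") <- n_sub
  attr(v, "taylor_terms") <- taylor_max
  v
}

#' Matrix-exponential-times-vector by scaled Taylor expansion
#'
#' Computes exp(-i G dt) v without diagonalizing G.  The step is divided
#' into equal substeps, their number the infinity norm of the exponent
#' -i G dt rounded up to the next whole number (which guarantees monotonic
#' convergence of the series); within each substep Taylor terms are added
#' until the next term changes no element by more than `cfg$taylor_cutoff`.
#'
#' @param G complex generator matrix (e.g. from [build_liouvillian()])
#' @param v complex vector
#' @param dt_au time step in atomic time units
#' @param cfg a [propagator_config()]
#' @return the propagated vector, with attributes `"substeps"` and
#'   `"taylor_terms"`
#' @export
expm_times_vector <- function(G, v, dt_au, cfg = propagator_config()) {
  G <- as.matrix(G)
  if (ncol(G) != length(v)) .stopf("generator/vector dimension mismatch")
  inf_norm <- max(rowSums(abs(G))) * abs(dt_au)
  .taylor_exp_action(function(x) G %*% x, as.complex(v), dt_au, inf_norm, cfg)
}

#' Thermal (Boltzmann) initial state
#'
#' Diagonal density matrix in the eigenbasis of H0 with populations
#' p_i proportional to exp(-E_i / kB T) and all off-diagonal elements zero.
#' Expressed in the same basis as H0 (not rotated): rho = U diag(p) U^H.
#'
#' @param H0 Hermitian initial Hamiltonian (hartree)
#' @param temperature kelvin (> 0)
#' @param in_eigenbasis if TRUE, return the state in the eigenbasis of H0
#'   (a diagonal density matrix) rather than in H0's own basis
#' @return a [density_state()]
#' @export
thermal_state <- function(H0, temperature = 300, in_eigenbasis = FALSE) {
  if (temperature <= 0) .stopf("temperature must be positive")
  eig <- diagonalize(H0)
  beta <- 1 / (lvc_constants[["kB_hartree"]] * temperature)
  w <- exp(-(eig$values - min(eig$values)) * beta)
  p <- w / sum(w)
  if (in_eigenbasis) {
    rho <- diag(p) + 0i
    tag <- "initial-spin-eigenbasis"
  } else {
    U <- eig$vectors
    rho <- U %*% (p * Conj(t(U)))
    tag <- ham_basis(H0)
  }
  density_state(as.complex(rho), basis_tag = tag, time = 0)
}

#' Propagate through a piecewise-constant Hamiltonian series
#'
#' Rotates every Hamiltonian into the eigenbasis of the first one (the
#' t = 0 spin Hamiltonian), starts from the thermal state of that
#' Hamiltonian, and advances the vectorised density matrix one dt step per
#' series element with the Taylor exponential action.  The evolution is
#' entirely unitary; trace and purity drift are logged per step.
#'
#' @param H_series list of Hermitian matrices (same order and basis),
#'   the Hamiltonian at t = 0, dt, 2 dt, ...; element k drives the step
#'   from (k-1) dt to k dt
#' @param cfg a [propagator_config()]
#' @param rho0 optional initial [density_state()] in the t = 0 eigenbasis,
#'   overriding the thermal state
#' @return object of class `spin_dynamics`: list with `states` (list of
#'   [density_state()], including t = 0), `log` (data.frame time, trace,
#'   purity, substeps, taylor_terms) and `transform` (the t = 0 eigenbasis
#'   unitary)
#' @export
propagate <- function(H_series, cfg = propagator_config(), rho0 = NULL) {
  stopifnot(length(H_series) >= 1L)
  d <- nrow(.as_mat(H_series[[1]]))
  tags <- unique(vapply(H_series, function(h)
    attr(h, "basis_tag") %||% "unspecified", ""))
  if (length(tags) != 1L)
    .stopf("Hamiltonian series mixes basis tags: %s", paste(tags, collapse = ", "))
  dims <- vapply(H_series, function(h) nrow(.as_mat(h)), 1L)
  if (any(dims != d)) .stopf("Hamiltonian series mixes dimensions")
  eig0 <- diagonalize(H_series[[1]])
  U0 <- eig0$vectors
  rot <- lapply(H_series, function(h) transform_operator(h, U0))
  if (is.null(rho0)) {
    beta <- 1 / (lvc_constants[["kB_hartree"]] * cfg$temperature)
    w <- exp(-(eig0$values - min(eig0$values)) * beta)
    rho <- diag(w / sum(w)) + 0i
  } else {
    stopifnot(inherits(rho0, "density_state"), rho0$dim == d)
    rho <- state_matrix(rho0)
  }
  dt_au <- .fs_to_au(cfg$dt)
  n_steps <- length(H_series)
  states <- vector("list", n_steps + 1L)
  states[[1]] <- density_state(as.complex(rho),
                               basis_tag = "initial-spin-eigenbasis",
                               time = 0, validate = FALSE)
  log <- data.frame(time = numeric(n_steps + 1L), trace = NA_real_,
                    purity = NA_real_, substeps = NA_integer_,
                    taylor_terms = NA_integer_)
  log$time[1] <- 0
  log$trace[1] <- Re(sum(diag(rho)))
  log$purity[1] <- Re(sum(diag(rho %*% rho)))
  v <- as.complex(rho)
  for (k in seq_len(n_steps)) {
    Hk <- rot[[k]]
    inf_norm <- .liouvillian_inf_norm(Hk, dt_au)
    apply_G <- function(x) {
      m <- matrix(x, d, d)
      as.complex(Hk %*% m - m %*% Hk)
    }
    v <- .taylor_exp_action(apply_G, v, dt_au, inf_norm, cfg)
    t_k <- k * cfg$dt
    states[[k + 1L]] <- density_state(v, basis_tag = "initial-spin-eigenbasis",
                                      time = t_k, validate = FALSE)
    m <- matrix(v, d, d)
    log$time[k + 1L] <- t_k
    log$trace[k + 1L] <- Re(sum(diag(m)))
    log$purity[k + 1L] <- Re(sum(diag(m %*% m)))
    log$substeps[k + 1L] <- attr(v, "substeps")
    log$taylor_terms[k + 1L] <- attr(v, "taylor_terms")
  }
  structure(list(states = states, log = log, transform = U0),
            class = "spin_dynamics")
}

#' @export
print.spin_dynamics <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("Spin dynamics: %d states over %g fs (d = %d)\n",
              n, x$states[[n]]$time, x$states[[1]]$dim))
  cat(sprintf("  max |Tr rho - 1| : %.3e\n", max(abs(x$log$trace - 1))))
  cat(sprintf("  purity drift     : %.3e\n",
              max(abs(x$log$purity - x$log$purity[1]))))
  invisible(x)
}

#' Population trace of one basis state over a dynamics run
#'
#' @param dyn a `spin_dynamics` result
#' @param index basis-state index in the t = 0 eigenbasis (ascending energy)
#' @return data.frame with columns `time` and `population`
#' @export
population_trace <- function(dyn, index) {
  data.frame(
    time = vapply(dyn$states, `[[`, 0, "time"),
    population = vapply(dyn$states, population, 0, index = index))
}
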