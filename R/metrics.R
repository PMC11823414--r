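#' Relative Frobenius-norm error between two Hamiltonians
#'
#' ||H_approx - H_ref||_F / ||H_ref||_F, the truncation-error measure used
#' throughout the package (a dimensionless fraction; multiply by 100 for
#' percent).  Optionally both matrices have their mean diagonal (a global
#' energy shift, Tr H / d) removed first; the default keeps the raw gauge.
#'
#' @param H_approx,H_ref Hermitian matrices of equal order (hartree)
#' @param remove_shift subtract Tr(H)/d * 1 from both before comparing
#' @return nonnegative error fraction
#' @export
hamiltonian_error <- function(H_approx, H_ref, remove_shift = FALSE) {
  A <- .as_mat(H_approx)
  B <- .as_mat(H_ref)
  if (!all(dim(A) == dim(B))) .stopf("Hamiltonian dimensions differ")
  ta <- attr(H_approx, "basis_tag")
  tb <- attr(H_ref, "basis_tag")
  if (!is.null(ta) && !is.null(tb) && !identical(ta, tb))
    .stopf("Hamiltonian basis tags differ: '%s' vs '%s'", ta, tb)
  if (remove_shift) {
    d <- nrow(A)
    A <- A - diag(Re(sum(diag(A))) / d, d)
    B <- B - diag(Re(sum(diag(B))) / d, d)
  }
  nb <- .fnorm(B)
  if (nb == 0) .stopf("reference Hamiltonian has zero norm; error undefined")
  .fnorm(A - B) / nb
}

#' Term-wise error decomposition of two spin-parameter sets
#'
#' Builds SOC-only, crystal-field-only and full spin Hamiltonians from each
#' parameter set and reports the relative Frobenius error of each pair —
#' the decomposition that attributes the truncation error to the SOC and
#' crystal-field terms separately.
#'
#' @param p_approx,p_ref [spin_params()] with identical L, S, theta
#' @return named numeric vector `c(soc_error=, cf_error=, total_error=)`
#' @export
term_errors <- function(p_approx, p_ref) {
  stopifnot(inherits(p_approx, "spin_params"), inherits(p_ref, "spin_params"))
  if (p_approx$L != p_ref$L || p_approx$S != p_ref$S ||
      any(p_approx$theta != p_ref$theta))
    .stopf("parameter sets differ in L, S or theta")
  ca <- component_hamiltonians(p_approx)
  cr <- component_hamiltonians(p_ref)
  err <- function(A, B) {
    if (.fnorm(.as_mat(B)) == 0 && .fnorm(.as_mat(A)) == 0) return(0)
    hamiltonian_error(A, B)
  }
  c(soc_error = err(ca$soc_only, cr$soc_only),
    cf_error = err(ca$cf_only, cr$cf_only),
    total_error = hamiltonian_error(build_spin_hamiltonian(p_approx),
                                    build_spin_hamiltonian(p_ref)))
}

#' Similarity of two vectorised density matrices
#'
#' Normalized complex inner product of the vectorised states:
#' Re <rho_a | rho_b> / (||rho_a|| ||rho_b||) (the default), or its modulus
#' with `method = "modulus"`.  Equals 1 for identical states and decays as
#' an approximately propagated trajectory diverges from a reference one,
#' sensitive to the phase of off-diagonal elements as well as their
#' magnitude.
#'
#' @param rho_a,rho_b [density_state()] objects of equal dimension
#' @param method `"real"` (signed, default) or `"modulus"`
#' @return similarity in [-1, 1]
#' @export
similarity <- function(rho_a, rho_b, method = c("real", "modulus")) {
  method <- match.arg(method)
  stopifnot(inherits(rho_a, "density_state"), inherits(rho_b, "density_state"))
  if (rho_a$dim != rho_b$dim) .stopf("density states differ in dimension")
  va <- rho_a$vector
  vb <- rho_b$vector
  na <- sqrt(Re(sum(Conj(va) * va)))
  nb <- sqrt(Re(sum(Conj(vb) * vb)))
  if (na == 0 || nb == 0) .stopf("zero-norm density state")
  ip <- sum(Conj(va) * vb) / (na * nb)
  if (method == "real") Re(ip) else Mod(ip)
}

#' Similarity trace between two dynamics runs
#'
#' @param dyn_a,dyn_b `spin_dynamics` results over the same time grid
#' @param method passed to [similarity()]
#' @return data.frame with columns `time` and `similarity`
#' @export
similarity_trace <- function(dyn_a, dyn_b, method = "real") {
  na <- length(dyn_a$states)
  stopifnot(length(dyn_b$states) == na)
  data.frame(
    time = vapply(dyn_a$states, `[[`, 0, "time"),
    similarity = mapply(function(a, b) similarity(a, b, method = method),
                        dyn_a$states, dyn_b$states))
}

#' Truncation error as a function of separation from the anchor
#'
#' Evaluates the LVC Hamiltonian and a ground-truth Hamiltonian at every
#' frame and reports the relative Frobenius error against the relative time
#' (frame time minus anchor time), for frames before and after the anchor.
#'
#' Both Hamiltonians are expressed in the anchor's reference product basis
#' (see [lvc_hamiltonian()]); the `truth` callback must return its
#' Hamiltonian in that same basis.
#'
#' @param anchor an [lvc_param()]
#' @param truth a function(displacement) returning the ground-truth
#'   Hamiltonian at that displacement in the anchor reference basis (e.g. a
#'   partially applied [ground_truth_hamiltonian()] with
#'   `basis = "reference"`)
#' @param frames list of [traj_frame()] bracketing the anchor time
#' @param box optional [periodic_box()] for unwrapping
#' @return object of class `error_trace`: data.frame with columns `time`
#'   (fs), `relative_time` (fs), `error` (fraction) and attribute
#'   `"anchor_time"`
#' @export
error_vs_separation <- function(anchor, truth, frames, box = NULL) {
  times <- vapply(frames, `[[`, 0, "time")
  if (anchor$anchor_time < min(times) || anchor$anchor_time > max(times))
    .stopf("anchor time %g fs outside the frame range [%g, %g]",
           anchor$anchor_time, min(times), max(times))
  err <- vapply(frames, function(f) {
    disp <- frame_displacement(f, anchor, box = box)
    hamiltonian_error(lvc_hamiltonian(anchor, disp, basis = "reference"),
                      truth(disp))
  }, 0)
  out <- data.frame(time = times, relative_time = times - anchor$anchor_time,
                    error = err)
  attr(out, "anchor_time") <- anchor$anchor_time
  class(out) <- c("error_trace", class(out))
  out
}

#' Average an error trace over positive and negative relative time
#'
#' Pairs each forward separation with the matching backward separation and
#' averages the two errors, the presentation used when the behaviour before
#' and after the anchor is (near-)symmetric.
#'
#' @param trace an [error_vs_separation()] result
#' @return data.frame with columns `separation` (fs, >= 0) and `error`
#' @export
fold_error_trace <- function(trace) {
  sep <- abs(trace$relative_time)
  agg <- stats::aggregate(trace$error, by = list(separation = sep), FUN = mean)
  names(agg)[2] <- "error"
  agg[order(agg$separation), , drop = FALSE]
}

#' Spearman rank correlation between truncation error and Kabsch RMSD
#'
#' @param errors per-frame error fractions
#' @param rmsds per-frame RMSD values (angstrom)
#' @return Spearman correlation coefficient
#' @export
error_rmsd_correlation <- function(errors, rmsds) {
  stopifnot(length(errors) == length(rmsds))
  stats::cor(errors, rmsds, method = "spearman")
}
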