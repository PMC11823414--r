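#' Construct an LVC reference parametrization
#'
#' One anchor of a linear vibronic coupling model: the spin-free state
#' energies, state gradients and nonadiabatic-coupling (NAC) vectors of the
#' molecular Coulomb Hamiltonian (MCH) at the reference geometry, plus the
#' three spatial components of the mean-field spin-orbit operator in the
#' reference MCH eigenbasis.  All quantities in atomic units (hartree, bohr).
#'
#' @param anchor_time time of the anchor geometry along the trajectory (fs)
#' @param geometry N x 3 matrix of site coordinates (bohr); rows are sites
#'   (atoms or solvent point charges)
#' @param site_flags character vector, "atom" or "charge", length N
#' @param energies spin-free state energies E_m (hartree), length n_states;
#'   must be nondecreasing
#' @param gradients n_states x 3N matrix; row m is the gradient kappa^(m)
#'   (hartree/bohr)
#' @param nacs n_states x n_states x 3N array; slice `[m, n, ]` is the
#'   coupling vector lambda^(mn) (hartree/bohr).  Only m < n slots are
#'   consulted; the matrix element is used symmetrically.
#' @param soc list of three complex Hermitian n_states x n_states matrices
#'   named `x`, `y`, `z`: the spatial SOC-operator components V_alpha in the
#'   reference eigenbasis (hartree)
#' @param spin_S total spin quantum number of the multiplicity considered
#'   (half-integer; 5/2 for a Dy(III) sextet manifold)
#' @return object of class `lvc_param`
#' @export
lvc_param <- function(anchor_time, geometry, site_flags, energies, gradients,
                      nacs, soc, spin_S) {
  geometry <- as.matrix(geometry)
  if (ncol(geometry) != 3L) .stopf("geometry must be an N x 3 matrix")
  n_sites <- nrow(geometry)
  ncart <- 3L * n_sites
  n <- length(energies)
  if (n < 1L) .stopf("at least one spin-free state is required")
  if (is.unsorted(energies)) .stopf("reference energies must be nondecreasing")
  site_flags <- rep_len(as.character(site_flags), n_sites)
  if (!all(site_flags %in% c("atom", "charge")))
    .stopf("site_flags must be 'atom' or 'charge'")
  gradients <- as.matrix(gradients)
  if (!identical(dim(gradients), c(n, ncart)))
    .stopf("gradients must be %d x %d (states x 3N), got %d x %d",
           n, ncart, nrow(gradients), ncol(gradients))
  if (!identical(dim(nacs), c(n, n, ncart)))
    .stopf("nacs must be %d x %d x %d", n, n, ncart)
  if (!is.list(soc) || !all(c("x", "y", "z") %in% names(soc)))
    .stopf("soc must be a list with components x, y, z")
  for (a in c("x", "y", "z")) {
    soc[[a]] <- as.matrix(soc[[a]]) + 0i
    if (!identical(dim(soc[[a]]), c(n, n)))
      .stopf("soc$%s must be %d x %d", a, n, n)
    .check_hermitian(soc[[a]], tol = 1e-10, what = sprintf("soc$%s", a))
  }
  spin_S <- .check_half_integer(spin_S, "spin_S")
  if (!all(is.finite(gradients)) || !all(is.finite(nacs)))
    .stopf("gradients/nacs contain non-finite values")
  structure(
    list(anchor_time = as.numeric(anchor_time), geometry = geometry,
         site_flags = site_flags, energies = as.numeric(energies),
         gradients = gradients, nacs = nacs,
         soc = soc[c("x", "y", "z")], spin_S = spin_S),
    class = "lvc_param")
}

#' @export
print.lvc_param <- function(x, ...) {
  cat(sprintf("LVC reference parametrization\n"))
  cat(sprintf("  anchor time : %g fs\n", x$anchor_time))
  cat(sprintf("  sites       : %d (%d atoms, %d point charges)\n",
              nrow(x$geometry), sum(x$site_flags == "atom"),
              sum(x$site_flags == "charge")))
  cat(sprintf("  states      : %d spin-free, S = %s  (product dim %d)\n",
              length(x$energies), format(x$spin_S),
              length(x$energies) * (2 * x$spin_S + 1)))
  cat(sprintf("  energy span : %.6g hartree\n",
              diff(range(x$energies))))
  invisible(x)
}

n_states <- function(param) length(param$energies)
n_cart <- function(param) 3L * nrow(param$geometry)

#' Hamiltonian matrix container
#'
#' A complex Hermitian matrix tagged with the basis it is expressed in.
#'
#' @param matrix complex square matrix (hartree)
#' @param basis_tag one of "mch-eigenbasis-product", "term-basis",
#'   "so-eigenbasis", "initial-spin-eigenbasis"
#' @param tol relative Frobenius tolerance for the Hermiticity check
#' @return object of class `ham_matrix` (the matrix with attributes)
#' @export
ham_matrix <- function(matrix, basis_tag = "mch-eigenbasis-product",
                       tol = 1e-12) {
  basis_tag <- match.arg(basis_tag,
                         c("mch-eigenbasis-product", "term-basis",
                           "so-eigenbasis", "initial-spin-eigenbasis"))
  m <- as.matrix(matrix) + 0i
  .check_hermitian(m, tol = tol, what = "Hamiltonian")
  structure(m, basis_tag = basis_tag, class = c("ham_matrix", class(m)))
}

#' @export
print.ham_matrix <- function(x, ...) {
  cat(sprintf("Hamiltonian matrix: %d x %d, basis '%s', ||H||_F = %.6g hartree\n",
              nrow(x), ncol(x), attr(x, "basis_tag"), .fnorm(unclass(x))))
  invisible(x)
}

ham_basis <- function(H) attr(H, "basis_tag") %||% "mch-eigenbasis-product"

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_mat <- function(H) {
  m <- unclass(H)
  attr(m, "basis_tag") <- NULL
  m
}

#' Linear MCH Hamiltonian at a displaced geometry
#'
#' First-order expansion of the molecular Coulomb Hamiltonian about the
#' anchor geometry: diagonal entries E_m + kappa^(m) . dR, off-diagonal
#' entries lambda^(mn) . dR, in the reference MCH eigenbasis.
#'
#' @param param an [lvc_param()]
#' @param disp displacement vector dR of length 3N (bohr), ordered as the
#'   anchor geometry rows flattened row-wise (x1 y1 z1 x2 ...)
#' @return `ham_matrix` of order n_states
#' @export
evaluate_mch <- function(param, disp) {
  stopifnot(inherits(param, "lvc_param"))
  disp <- as.numeric(disp)
  if (length(disp) != n_cart(param))
    .stopf("displacement length %d does not match 3N = %d",
           length(disp), n_cart(param))
  if (!all(is.finite(disp))) .stopf("displacement contains non-finite values")
  n <- n_states(param)
  H <- matrix(0, n, n)
  diag(H) <- param$energies + as.numeric(param$gradients %*% disp)
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      for (k in (m + 1L):n) {
        v <- sum(param$nacs[m, k, ] * disp)
        H[m, k] <- v
        H[k, m] <- v
      }
    }
  }
  if (!all(is.finite(H))) .stopf("non-finite MCH matrix element")
  ham_matrix(H)
}

#' Diagonalize a Hermitian Hamiltonian deterministically
#'
#' Eigenvalues ascending.  The unitary is made reproducible by fixing each
#' eigenvector's phase so its largest-magnitude component is real-positive;
#' within a degenerate cluster columns are ordered by the index of their
#' first significant component.
#'
#' @param H Hermitian matrix (`ham_matrix` or plain complex matrix)
#' @param tol Hermiticity tolerance (relative Frobenius)
#' @return list with `values` (real, ascending) and `vectors` (unitary U
#'   with U^H H U diagonal)
#' @export
diagonalize <- function(H, tol = 1e-10) {
  M <- .as_mat(H)
  .check_hermitian(M, tol = tol, what = "Hamiltonian")
  e <- eigen(.hermitize(M), symmetric = TRUE)
  idx <- order(e$values)
  val <- e$values[idx]
  vec <- e$vectors[, idx, drop = FALSE]
  ## deterministic gauge
  d <- length(val)
  scale <- max(abs(val), 1)
  i <- 1L
  while (i <= d) {
    j <- i
    while (j < d && (val[j + 1L] - val[i]) <= 1e-12 * scale) j <- j + 1L
    if (j > i) {
      block <- vec[, i:j, drop = FALSE]
      ## order degenerate columns by first significant component index
      first_sig <- apply(abs(block) > 1e-8, 2, function(z) which(z)[1])
      block <- block[, order(first_sig), drop = FALSE]
      vec[, i:j] <- block
    }
    i <- j + 1L
  }
  for (k in seq_len(d)) {
    col <- vec[, k]
    p <- which.max(abs(col))
    ph <- col[p] / abs(col[p])
    vec[, k] <- col / ph
  }
  list(values = val, vectors = vec)
}

#' Similarity-transform an operator
#'
#' Returns U^H O U — the matrix of the operator O in the basis whose columns
#' (in the old basis) are the columns of U.  Preserves Hermiticity, trace
#' and spectrum when U is unitary.
#'
#' @param O complex matrix
#' @param transform unitary matrix U
#' @return complex matrix of the same order
#' @export
transform_operator <- function(O, transform) {
  O <- .as_mat(O)
  U <- as.matrix(transform)
  if (!all(dim(O) == dim(U))) .stopf("operator/transform dimension mismatch")
  Conj(t(U)) %*% O %*% U
}

#' Assemble the spin-orbit Hamiltonian from spatial SOC components
#'
#' Wigner-Eckart reassembly within a single spin multiplicity:
#' H_SOC = sum_alpha V_alpha (x) S_alpha, in the product basis ordered
#' spin-free-state-major (state index varies slowest; within each state the
#' spin projection runs M_S = S, S-1, ..., -S).
#'
#' @param V list of three complex Hermitian n x n matrices named x, y, z
#'   (the spatial SOC components in the current spin-free eigenbasis)
#' @param spin_S spin quantum number (half-integer)
#' @param basis_tag basis tag for the result
#' @return `ham_matrix` of order n (2S+1)
#' @export
assemble_soc <- function(V, spin_S, basis_tag = "mch-eigenbasis-product") {
  stopifnot(is.list(V), all(c("x", "y", "z") %in% names(V)))
  S <- spin_matrices(spin_S)
  n <- nrow(as.matrix(V$x))
  d <- n * (2 * .check_half_integer(spin_S) + 1)
  H <- matrix(0 + 0i, d, d)
  for (a in c("x", "y", "z")) {
    Va <- as.matrix(V[[a]]) + 0i
    .check_hermitian(Va, tol = 1e-10, what = sprintf("V_%s", a))
    H <- H + kronecker(Va, S[[a]])
  }
  ham_matrix(H, basis_tag = basis_tag)
}

#' Full LVC molecular Hamiltonian at a displaced geometry
#'
#' The pipeline of the linear vibronic coupling model: evaluate the linear
#' MCH at the displacement, diagonalize it, carry the spatial SOC components
#' into the displaced eigenbasis with the same unitary, reassemble the SOC
#' term, and add the diagonal MCH energies in the product basis.  At zero
#' displacement this reproduces the anchor Hamiltonian exactly.
#'
#' Because the SOC assembly is basis-covariant
#' ((U^H V U) (x) S = (U (x) 1)^H (V (x) S) (U (x) 1)), the same total
#' Hamiltonian can equivalently be expressed in the anchor's own product
#' basis without diagonalizing, as H_MCH(dR) (x) 1 + sum V_alpha (x)
#' S_alpha; `basis = "reference"` selects that representation, which is the
#' one to use when Hamiltonians from different geometries (or models) are
#' compared or propagated as a series, since it is continuous in dR and
#' free of eigenstate-ordering ambiguities at avoided crossings.
#'
#' @inheritParams evaluate_mch
#' @param basis `"displaced"` (eigenbasis of the displaced MCH, as a
#'   state-interaction calculation would report it) or `"reference"` (the
#'   anchor product basis)
#' @param keep_transform if TRUE (displaced basis only), attach the MCH
#'   eigenvector unitary and eigenvalues as attributes `"transform"` and
#'   `"mch_values"`
#' @return `ham_matrix` of order n_states (2S+1)
#' @export
lvc_hamiltonian <- function(param, disp, basis = c("displaced", "reference"),
                            keep_transform = FALSE) {
  basis <- match.arg(basis)
  Hmch <- evaluate_mch(param, disp)
  mult <- 2 * param$spin_S + 1
  if (basis == "reference") {
    H <- kronecker(.as_mat(Hmch), diag(mult)) +
      .as_mat(assemble_soc(param$soc, param$spin_S))
    return(ham_matrix(H))
  }
  eig <- diagonalize(Hmch)
  Vt <- lapply(param$soc, transform_operator, transform = eig$vectors)
  Hsoc <- assemble_soc(Vt, param$spin_S)
  H <- kronecker(diag(eig$values), diag(mult)) + .as_mat(Hsoc)
  out <- ham_matrix(H)
  if (keep_transform) {
    attr(out, "transform") <- eig$vectors
    attr(out, "mch_values") <- eig$values
  }
  out
}

#' Reference (anchor) total Hamiltonian of a parametrization
#'
#' The molecular Hamiltonian at the anchor geometry itself:
#' diag(E) (x) 1 + sum_alpha V_alpha (x) S_alpha.
#'
#' @param param an [lvc_param()]
#' @return `ham_matrix`
#' @export
anchor_hamiltonian <- function(param) {
  lvc_hamiltonian(param, rep(0, n_cart(param)))
}
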