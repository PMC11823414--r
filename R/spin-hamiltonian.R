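#' Angular momentum product basis |L S M_L M_S>
#'
#' Basis bookkeeping for an LS term: dimension (2L+1)(2S+1), ordered
#' M_L-major (descending M_L, then descending M_S within each M_L).
#'
#' @param L orbital angular momentum (nonnegative integer)
#' @param S spin (half-integer)
#' @return object of class `lvc_basis`: list with `L`, `S`, `dim`, and the
#'   per-basis-state `M_L`, `M_S` labels
#' @export
angular_basis <- function(L, S) {
  if (abs(L - round(L)) > 1e-9 || L < 0) .stopf("L must be a nonnegative integer")
  S <- .check_half_integer(S, "S")
  L <- round(L)
  mL <- seq(L, -L)
  mS <- seq(S, -S)
  structure(
    list(L = L, S = S, dim = length(mL) * length(mS),
         M_L = rep(mL, each = length(mS)), M_S = rep(mS, times = length(mL))),
    class = "lvc_basis")
}

#' @export
print.lvc_basis <- function(x, ...) {
  cat(sprintf("|L S M_L M_S> basis: L = %d, S = %s, dim = %d (M_L-major, descending)\n",
              x$L, format(x$S), x$dim))
  invisible(x)
}

#' The L.S spin-orbit operator in the product basis
#'
#' @param basis an [angular_basis()]
#' @return complex Hermitian matrix sum_alpha L_alpha (x) S_alpha
#' @export
ls_operator <- function(basis) {
  Lm <- angular_momentum_matrices(basis$L)
  Sm <- spin_matrices(basis$S)
  kronecker(Lm$x, Sm$x) + kronecker(Lm$y, Sm$y) + kronecker(Lm$z, Sm$z)
}

#' Spin Hamiltonian parameter set
#'
#' The SOC parameter lambda plus the 27 crystal-field parameters B_k^q of
#' the Stevens expansion, with the operator-equivalent factors theta_k.
#'
#' @param lambda SOC parameter (hartree)
#' @param B named numeric vector of 27 crystal-field parameters (hartree);
#'   names `"k<k>q<q>"` as produced by [stevens_operators()].  Missing names
#'   default to 0.
#' @param theta named vector `c(k2=, k4=, k6=)` of operator-equivalent
#'   factors, or a preset name for [stevens_theta()]
#' @param L,S quantum numbers of the carrier term (default the 6H term:
#'   L = 5, S = 5/2)
#' @return object of class `spin_params`
#' @export
spin_params <- function(lambda = 0, B = numeric(), theta = "unit",
                        L = 5, S = 5/2) {
  if (is.character(theta)) theta <- stevens_theta(theta)
  if (!all(c("k2", "k4", "k6") %in% names(theta)) || any(theta == 0))
    .stopf("theta must provide nonzero k2, k4, k6 factors")
  slots <- unlist(lapply(c(2L, 4L, 6L),
                         function(k) sprintf("k%dq%d", k, seq(-k, k))))
  full <- stats::setNames(numeric(length(slots)), slots)
  if (length(B)) {
    bad <- setdiff(names(B), slots)
    if (length(bad)) .stopf("unknown CFP slot(s): %s", paste(bad, collapse = ", "))
    full[names(B)] <- B
  }
  structure(list(lambda = as.numeric(lambda), B = full,
                 theta = theta[c("k2", "k4", "k6")],
                 L = round(L), S = .check_half_integer(S, "S")),
            class = "spin_params")
}

#' @export
print.spin_params <- function(x, ...) {
  cat(sprintf("Spin Hamiltonian parameters (L = %d, S = %s)\n", x$L, format(x$S)))
  cat(sprintf("  lambda   : %.8g hartree\n", x$lambda))
  nz <- x$B[x$B != 0]
  cat(sprintf("  CFPs     : %d of 27 nonzero", length(nz)))
  if (length(nz)) cat(sprintf(", |B| in [%.3g, %.3g] hartree",
                              min(abs(nz)), max(abs(nz))))
  cat("\n")
  cat(sprintf("  theta_k  : %.6g %.6g %.6g\n",
              x$theta[["k2"]], x$theta[["k4"]], x$theta[["k6"]]))
  invisible(x)
}

#' Build the spin Hamiltonian from its parameters
#'
#' H = lambda L.S + sum_{k,q} theta_k B_k^q (O_k^q (x) 1_S) in the
#' |L S M_L M_S> basis.
#'
#' @param p a [spin_params()]
#' @return `ham_matrix` with basis tag `"term-basis"`
#' @export
build_spin_hamiltonian <- function(p) {
  stopifnot(inherits(p, "spin_params"))
  basis <- angular_basis(p$L, p$S)
  H <- p$lambda * ls_operator(basis)
  ops <- suppressWarnings(stevens_operators(p$L))
  id_s <- diag(2 * p$S + 1)
  for (nm in names(ops)) {
    b <- p$B[[nm]]
    if (b != 0) {
      k <- as.integer(substr(nm, 2, 2))
      H <- H + p$theta[[paste0("k", k)]] * b * kronecker(ops[[nm]], id_s)
    }
  }
  ham_matrix(H, basis_tag = "term-basis")
}

#' SOC-only and crystal-field-only component Hamiltonians
#'
#' Splits the spin Hamiltonian into its two physical terms; their sum equals
#' [build_spin_hamiltonian()] exactly.
#'
#' @param p a [spin_params()]
#' @return list with `soc_only` and `cf_only` `ham_matrix` objects
#' @export
component_hamiltonians <- function(p) {
  stopifnot(inherits(p, "spin_params"))
  p_soc <- spin_params(lambda = p$lambda, theta = p$theta, L = p$L, S = p$S)
  p_cf <- spin_params(lambda = 0, B = p$B, theta = p$theta, L = p$L, S = p$S)
  list(soc_only = build_spin_hamiltonian(p_soc),
       cf_only = build_spin_hamiltonian(p_cf))
}

#' Project spin Hamiltonian parameters from a Hermitian matrix
#'
#' Trace-orthogonal least-squares decomposition of a Hamiltonian in the
#' |L S M_L M_S> basis onto the operator set {L.S} U {theta_k O_k^q (x) 1}.
#' Because the set is mutually orthogonal under Tr(A^H B), each coefficient
#' is a ratio of traces: lambda = Tr(H L.S) / Tr((L.S)^2) and analogously
#' per B_k^q.  Round-trips [build_spin_hamiltonian()] exactly; for a matrix
#' not in the operator span the Frobenius norm of the residual is attached
#' as a diagnostic.
#'
#' @param H Hermitian matrix of order (2L+1)(2S+1)
#' @param basis an [angular_basis()]
#' @param theta operator-equivalent factors (named vector or preset name)
#' @return a [spin_params()] with attribute `"residual_norm"` (hartree) and
#'   `"residual_relative"` (fraction of ||H||_F; NA for H = 0)
#' @export
project_spin_parameters <- function(H, basis, theta = "unit") {
  stopifnot(inherits(basis, "lvc_basis"))
  M <- .as_mat(H)
  if (nrow(M) != basis$dim)
    .stopf("Hamiltonian order %d does not match basis dimension %d",
           nrow(M), basis$dim)
  .check_hermitian(M, tol = 1e-10, what = "Hamiltonian")
  if (is.character(theta)) theta <- stevens_theta(theta)
  LS <- ls_operator(basis)
  tr_inner <- function(A, B) sum(Conj(A) * B)    # Tr(A^H B)
  lambda <- Re(tr_inner(LS, M)) / Re(tr_inner(LS, LS))
  resid <- M - lambda * LS
  ops <- suppressWarnings(stevens_operators(basis$L))
  id_s <- diag(2 * basis$S + 1)
  B <- stats::setNames(numeric(length(ops)), names(ops))
  for (nm in names(ops)) {
    O <- kronecker(ops[[nm]], id_s)
    g <- Re(tr_inner(O, O))
    if (g < 1e-14) next                          # vanishing operator (small L)
    k <- as.integer(substr(nm, 2, 2))
    coef <- Re(tr_inner(O, M)) / g
    B[[nm]] <- coef / theta[[paste0("k", k)]]
    resid <- resid - coef * O
  }
  out <- spin_params(lambda = lambda, B = B, theta = theta,
                     L = basis$L, S = basis$S)
  rn <- .fnorm(resid)
  attr(out, "residual_norm") <- rn
  nh <- .fnorm(M)
  attr(out, "residual_relative") <- if (nh > 0) rn / nh else NA_real_
  out
}

#' Lande-interval spin-orbit multiplet energies
#'
#' Closed-form spectrum of lambda L.S: for each J from |L-S| to L+S the
#' energy lambda [J(J+1) - L(L+1) - S(S+1)] / 2, (2J+1)-fold degenerate.
#'
#' @param lambda SOC parameter (hartree)
#' @param L,S quantum numbers
#' @return numeric vector of (2L+1)(2S+1) energies, ascending
#' @export
lande_levels <- function(lambda, L, S) {
  J <- seq(abs(L - S), L + S)
  e <- lambda * (J * (J + 1) - L * (L + 1) - S * (S + 1)) / 2
  sort(rep(e, times = 2 * J + 1))
}

#' Read/write a crystal-field parameter table
#'
#' Plain-text key-value table with columns k, q, value (hartree); lambda is
#' stored as the pseudo-row `k = 0, q = 0`.
#'
#' @param p a [spin_params()]
#' @param path file path
#' @return for the writer, `path` invisibly; for the reader, a
#'   [spin_params()]
#' @export
write_parameter_table <- function(p, path) {
  stopifnot(inherits(p, "spin_params"))
  kk <- as.integer(substr(names(p$B), 2, 2))
  qq <- as.integer(sub("^k[0-9]q", "", names(p$B)))
  df <- data.frame(k = c(0L, kk), q = c(0L, qq),
                   value = c(p$lambda, unname(p$B)))
  utils::write.table(format(df, digits = 17, scientific = TRUE),
                     path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @param theta,L,S passed to [spin_params()] on read
#' @export
read_parameter_table <- function(path, theta = "unit", L = 5, S = 5/2) {
  df <- utils::read.table(path, header = TRUE)
  if (!all(c("k", "q", "value") %in% names(df)))
    .stopf("parameter table must have columns k, q, value")
  lam <- df$value[df$k == 0]
  cf <- df[df$k != 0, ]
  B <- stats::setNames(cf$value, sprintf("k%dq%d", cf$k, cf$q))
  spin_params(lambda = if (length(lam)) lam[[1]] else 0, B = B,
              theta = theta, L = L, S = S)
}
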