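## Extended Stevens operators O_k^q, k in {2,4,6}, q in [-k, k], following
## the extended Stevens convention: cosine (q > 0) and sine (q < 0) tesseral
## combinations of ladder operators, symmetrized with the standard
## polynomials F_{k,|q|}(J_z, X) where X = J(J+1).

## F_{k,q}(z) polynomial applied elementwise to the diagonal J_z values
.stevens_poly <- function(k, q, z, X) {
  key <- sprintf("%d.%d", k, q)
  switch(key,
    "2.0" = 3 * z^2 - X,
    "2.1" = z,
    "2.2" = rep(1, length(z)),
    "4.0" = 35 * z^4 - (30 * X - 25) * z^2 + 3 * X^2 - 6 * X,
    "4.1" = 7 * z^3 - (3 * X + 1) * z,
    "4.2" = 7 * z^2 - X - 5,
    "4.3" = z,
    "4.4" = rep(1, length(z)),
    "6.0" = 231 * z^6 - (315 * X - 735) * z^4 +
            (105 * X^2 - 525 * X + 294) * z^2 -
            5 * X^3 + 40 * X^2 - 60 * X,
    "6.1" = 33 * z^5 - (30 * X - 15) * z^3 + (5 * X^2 - 10 * X + 12) * z,
    "6.2" = 33 * z^4 - (18 * X + 123) * z^2 + X^2 + 10 * X + 102,
    "6.3" = 11 * z^3 - (3 * X + 59) * z,
    "6.4" = 11 * z^2 - X - 38,
    "6.5" = z,
    "6.6" = rep(1, length(z)),
    .stopf("no Stevens polynomial for k = %d, q = %d", k, q)
  )
}

.matrix_power <- function(M, p) {
  out <- diag(nrow(M)) + 0i
  for (i in seq_len(p)) out <- out %*% M
  out
}

#' A single extended Stevens operator
#'
#' O_k^q acting in the (2j+1)-dimensional |j, m> space (descending m).
#' For q > 0 the cosine combination (J+^q + J-^q)/2 is used, for q < 0 the
#' sine combination (J+^q - J-^q)/(2i); either is symmetrized with the
#' standard polynomial in J_z: O = (P F(Jz) + F(Jz) P) / 2.  For q = 0 the
#' operator is the polynomial itself.
#'
#' @param k rank (2, 4 or 6)
#' @param q component, -k <= q <= k
#' @param j angular momentum quantum number of the carrier space
#' @return complex Hermitian (2j+1) x (2j+1) matrix
#' @export
stevens_operator <- function(k, q, j) {
  if (!k %in% c(2L, 4L, 6L)) .stopf("k must be 2, 4 or 6, got %s", format(k))
  if (abs(q) > k) .stopf("|q| must be <= k")
  j <- .check_half_integer(j, "j")
  J <- angular_momentum_matrices(j)
  X <- j * (j + 1)
  z <- J$m
  Fz <- diag(.stevens_poly(k, abs(q), z, X)) + 0i
  if (q == 0) return(Fz)
  Jp <- J$x + 1i * J$y
  Jm <- J$x - 1i * J$y
  Pp <- .matrix_power(Jp, abs(q))
  Pm <- .matrix_power(Jm, abs(q))
  P <- if (q > 0) (Pp + Pm) / 2 else (Pp - Pm) / (2i)
  (P %*% Fz + Fz %*% P) / 2
}

#' The full table of 27 extended Stevens operators
#'
#' All O_k^q for k in {2, 4, 6}, q in [-k, k], in the (2L+1)-dimensional
#' orbital space.  The operators are Hermitian, traceless, and mutually
#' orthogonal under the trace inner product Tr(A^H B).  For L < 3 the k = 6
#' (and for L < 2 the k = 4) operators vanish identically; they are returned
#' as zero matrices with a warning flag.
#'
#' @param L orbital angular momentum quantum number (nonnegative integer)
#' @return named list of 27 matrices, names `"k<k>q<q>"` (e.g. `"k2q-1"`),
#'   with attribute `"zero_ranks"` listing ranks k whose operators vanish
#'   for this L
#' @export
stevens_operators <- function(L) {
  if (abs(L - round(L)) > 1e-9 || L < 0) .stopf("L must be a nonnegative integer")
  L <- round(L)
  ops <- list()
  zero_ranks <- integer()
  for (k in c(2L, 4L, 6L)) {
    rank_zero <- TRUE
    for (q in seq(-k, k)) {
      O <- stevens_operator(k, q, L)
      if (max(abs(O)) > 1e-12) rank_zero <- FALSE
      ops[[sprintf("k%dq%d", k, q)]] <- O
    }
    if (rank_zero) zero_ranks <- c(zero_ranks, k)
  }
  if (length(zero_ranks))
    warning(sprintf("Stevens operators of rank %s vanish identically for L = %d",
                    paste(zero_ranks, collapse = ", "), L), call. = FALSE)
  attr(ops, "zero_ranks") <- zero_ranks
  ops
}

#' Operator-equivalent (Stevens) factors
#'
#' Configuration constants theta_k multiplying the crystal-field terms.  The
#' `"dy3+"` preset carries the standard tabulated factors for Dy(III), f^9:
#' alpha = -2/315, beta = -8/135135, gamma = 4/3864861.  The `"unit"` preset
#' (theta_k = 1) is intended for synthetic toy systems.
#'
#' @param config `"dy3+"` or `"unit"`
#' @return named numeric vector `c(k2 = ..., k4 = ..., k6 = ...)`
#' @export
stevens_theta <- function(config = c("dy3+", "unit")) {
  config <- match.arg(config)
  switch(config,
    "dy3+" = c(k2 = -2 / 315, k4 = -8 / 135135, k6 = 4 / 3864861),
    "unit" = c(k2 = 1, k4 = 1, k6 = 1)
  )
}
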