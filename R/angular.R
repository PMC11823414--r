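#' Angular momentum matrices for arbitrary half-integer j
#'
#' Builds the standard matrix representations of J_x, J_y, J_z in the
#' |j, m> basis ordered by descending m (m = j, j-1, ..., -j), from the
#' ladder-operator matrix elements <m+1|J+|m> = sqrt(j(j+1) - m(m+1)).
#' Units of hbar = 1.
#'
#' @param j total angular momentum quantum number (half-integer, >= 0)
#' @return list with complex matrices `x`, `y`, `z` of order 2j+1,
#'   plus `j` and the `m` values (descending)
#' @examples
#' J <- angular_momentum_matrices(1/2)
#' Re(diag(J$z))          # 0.5 -0.5
#' @export
angular_momentum_matrices <- function(j) {
  j <- .check_half_integer(j, "j")
  m <- seq(j, -j)                     # descending
  d <- length(m)
  Jz <- diag(m, d, d) + 0i
  Jp <- matrix(0 + 0i, d, d)
  ## row index = m+1 state, col index = m state; with descending ordering the
  ## raising operator populates the superdiagonal
  if (d > 1) {
    lower_m <- m[-1]                  # states being raised
    amp <- sqrt(j * (j + 1) - lower_m * (lower_m + 1))
    Jp[cbind(seq_len(d - 1), seq_len(d - 1) + 1L)] <- amp
  }
  Jm <- Conj(t(Jp))
  list(
    x = (Jp + Jm) / 2,
    y = (Jp - Jm) / (2i),
    z = Jz,
    j = j,
    m = m
  )
}

#' Spin matrices (alias for angular momentum matrices)
#'
#' @param S spin quantum number (half-integer)
#' @return as [angular_momentum_matrices()]
#' @export
spin_matrices <- function(S) angular_momentum_matrices(S)
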