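#' Physical constants and unit conversions
#'
#' All internal arithmetic is in Hartree atomic units (hartree, bohr,
#' atomic time units); trajectory files on disk are in angstrom and
#' femtoseconds and are converted on read/write.
#'
#' @format A named numeric vector with elements
#' \describe{
#'   \item{bohr_per_angstrom}{1 Angstrom = 1.8897261246 bohr}
#'   \item{fs_per_au_time}{1 atomic time unit = 0.02418884254 fs}
#'   \item{kB_hartree}{Boltzmann constant, 3.166811563e-6 hartree/K}
#' }
#' @export
lvc_constants <- c(
  bohr_per_angstrom = 1.8897261246,
  fs_per_au_time    = 0.02418884254,
  kB_hartree        = 3.166811563e-6
)

.bohr <- function() lvc_constants[["bohr_per_angstrom"]]
.fs_to_au <- function(t_fs) t_fs / lvc_constants[["fs_per_au_time"]]

## shared input check helpers -------------------------------------------------

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_half_integer <- function(j, what = "j") {
  if (length(j) != 1L || !is.finite(j) || j < 0 ||
      abs(2 * j - round(2 * j)) > 1e-9)
    .stopf("%s must be a nonnegative half-integer, got %s", what, format(j))
  round(2 * j) / 2
}

## Frobenius norm safe for complex matrices (base::norm coerces to real)
.fnorm <- function(M) sqrt(sum(Mod(M)^2))

.check_hermitian <- function(M, tol = 1e-10, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    .stopf("%s must be a square matrix", what)
  nrm <- .fnorm(M)
  dev <- .fnorm(M - Conj(t(M)))
  if (dev > tol * max(nrm, 1))
    .stopf("%s is not Hermitian (relative deviation %.3e)", what, dev / max(nrm, 1))
  invisible(M)
}

.hermitize <- function(M) (M + Conj(t(M))) / 2
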