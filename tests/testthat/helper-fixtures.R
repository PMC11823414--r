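# shared fixture builders: every fixture is generated in code at test time

hermitian_random <- function(d, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(complex(real = rnorm(d * d, sd = sd),
                      imaginary = rnorm(d * d, sd = sd)), d, d)
  (M + Conj(t(M))) / 2
}

# two-state, one-site toy with a single NAC component along x
two_state_toy <- function(e = c(0, 0.01), nac_x = 0.005, soc_scale = 0) {
  nacs <- array(0, c(2, 2, 3))
  nacs[1, 2, 1] <- nac_x
  nacs[2, 1, 1] <- nac_x
  soc <- if (soc_scale > 0) {
    lapply(list(x = 1, y = 2, z = 3),
           function(i) hermitian_random(2, sd = soc_scale, seed = 100 + i))
  } else {
    z <- matrix(0, 2, 2)
    list(x = z, y = z, z = z)
  }
  lvc_param(0, matrix(0, 1, 3), "atom", e, matrix(0, 2, 3), nacs, soc, 1/2)
}

frob <- function(M) sqrt(sum(Mod(M)^2))

# plain matrix from a ham_matrix (drops class and basis tag)
mat <- function(H) {
  m <- unclass(H)
  attr(m, "basis_tag") <- NULL
  m
}

random_spin_params <- function(seed, L = 5, S = 5/2, theta = "unit",
                               lambda_sd = 1e-3, b_sd = 1e-4) {
  set.seed(seed)
  nm <- unlist(lapply(c(2L, 4L, 6L), function(k) sprintf("k%dq%d", k, seq(-k, k))))
  spin_params(lambda = rnorm(1, sd = lambda_sd),
              B = setNames(rnorm(27, sd = b_sd), nm),
              theta = theta, L = L, S = S)
}

# uniform random density matrix (mixed, valid)
random_density <- function(d, seed) {
  set.seed(seed)
  A <- matrix(complex(real = rnorm(d * d), imaginary = rnorm(d * d)), d, d)
  rho <- A %*% Conj(t(A))
  rho <- rho / Re(sum(diag(rho)))
  density_state(as.complex(rho), time = 0)
}
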