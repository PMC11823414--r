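au_per_fs <- 1 / lvcspin::lvc_constants[["fs_per_au_time"]]

test_that("the Liouvillian reproduces the commutator under column stacking", {
  for (seed in 1:5) {
    H <- hermitian_random(4, sd = 1e-3, seed = seed)
    G <- build_liouvillian(H)
    rho <- state_matrix(random_density(4, seed + 50))
    lhs <- G %*% as.complex(rho)
    rhs <- as.complex(H %*% rho - rho %*% H)
    expect_equal(as.complex(lhs), rhs, tolerance = 1e-12)
  }
  expect_equal(max(Mod(build_liouvillian(matrix(0, 3, 3)))), 0)
})

test_that("the Liouvillian of a diagonal Hamiltonian holds the level differences", {
  G <- build_liouvillian(diag(c(0.2, 0.5)))
  expect_equal(sort(Re(diag(G))), sort(c(0, 0.2 - 0.5, 0.5 - 0.2, 0)))
  expect_equal(max(Mod(G - diag(diag(G)))), 0)
})

test_that("expm_times_vector matches the spectral-decomposition oracle", {
  cfg <- propagator_config()
  for (seed in 1:20) {
    d <- sample(2:4, 1)
    H <- hermitian_random(d, sd = 2e-3, seed = seed)
    G <- build_liouvillian(H)
    set.seed(seed + 500)
    v <- complex(real = rnorm(d^2), imaginary = rnorm(d^2))
    dt <- runif(1, 10, 60)       # atomic time units
    e <- eigen(G)
    ref <- e$vectors %*% (exp(-1i * e$values * dt) * solve(e$vectors, v))
    out <- expm_times_vector(G, v, dt, cfg)
    expect_lt(max(Mod(as.complex(out) - as.complex(ref))), 1e-10)
  }
})

test_that("the substep count follows the infinity-norm rule and G = 0 is the identity", {
  cfg <- propagator_config()
  v <- c(1 + 0i, 0i, 0i, 0i)
  out <- expm_times_vector(matrix(0, 4, 4), v, 100, cfg)
  expect_equal(as.complex(out), v)
  expect_equal(attr(out, "substeps"), 1L)
  G <- diag(c(1, 2, 3, 4)) + 0i
  out2 <- expm_times_vector(G, v, 2.5, cfg)
  expect_equal(attr(out2, "substeps"), as.integer(ceiling(4 * 2.5)))
})

test_that("Taylor non-convergence within the term bound is reported", {
  cfg <- propagator_config(max_taylor_terms = 2L)
  G <- diag(c(0.9, 0.9)) + 0i
  expect_error(expm_times_vector(G, c(1 + 0i, 0i), 1, cfg), "did not converge")
})

test_that("two-level populations follow the Rabi closed form", {
  a <- 3e-4
  H <- matrix(c(0, a, a, 0), 2, 2)
  G <- build_liouvillian(H)
  cfg <- propagator_config()
  v <- as.complex(matrix(c(1, 0, 0, 0), 2, 2))
  period_fs <- pi / a / au_per_fs
  n_steps <- ceiling(10 * period_fs)
  worst <- 0
  for (k in seq_len(min(n_steps, 300))) {
    v <- expm_times_vector(G, v, au_per_fs * n_steps / min(n_steps, 300), cfg)
    t_au <- au_per_fs * n_steps / min(n_steps, 300) * k
    worst <- max(worst, abs(Re(v[1]) - cos(a * t_au)^2))
  }
  expect_lt(worst, 1e-8)
})

test_that("thermal states obey the Boltzmann closed forms", {
  kT <- lvcspin::lvc_constants[["kB_hartree"]] * 300
  # two degenerate levels -> 1/2, 1/2
  th <- thermal_state(ham_matrix(diag(c(0.001, 0.001))), 300,
                      in_eigenbasis = TRUE)
  expect_equal(population(th, 1), 0.5, tolerance = 1e-12)
  # gap >> kT -> ground state
  th2 <- thermal_state(ham_matrix(diag(c(0, 100 * kT))), 300,
                       in_eigenbasis = TRUE)
  expect_equal(population(th2, 1), 1, tolerance = 1e-6)
  # gap = kT ln 2 -> 2:1
  th3 <- thermal_state(ham_matrix(diag(c(0, kT * log(2)))), 300,
                       in_eigenbasis = TRUE)
  expect_equal(population(th3, 1), 2/3, tolerance = 1e-12)
  expect_equal(population(th3, 2), 1/3, tolerance = 1e-12)
  expect_error(thermal_state(ham_matrix(diag(2)), -5), "positive")
})

test_that("a stationary thermal state stays constant under its own Hamiltonian", {
  H <- ham_matrix(hermitian_random(5, sd = 1e-3, seed = 3))
  dyn <- propagate(rep(list(H), 20), propagator_config())
  pops <- vapply(dyn$states, population, 0, index = 2)
  expect_lt(max(abs(pops - pops[1])), 1e-12)
})

test_that("trace, purity and segment energy are conserved across a discontinuous series", {
  set.seed(8)
  Hs <- c(rep(list(ham_matrix(hermitian_random(6, sd = 5e-4, seed = 81))), 25),
          rep(list(ham_matrix(hermitian_random(6, sd = 5e-4, seed = 82))), 25))
  dyn <- propagate(Hs, propagator_config())
  expect_lt(max(abs(dyn$log$trace - 1)), 1e-10)
  expect_lt(max(abs(dyn$log$purity - dyn$log$purity[1])), 1e-8)
  # energy constant within each constant-H segment
  U0 <- dyn$transform
  H1r <- transform_operator(unclass(Hs[[1]]), U0)
  en <- vapply(dyn$states[1:26], function(s)
    Re(sum(diag(H1r %*% state_matrix(s)))), 0)
  expect_lt(max(abs(en - en[1])), 1e-9)
})

test_that("one dt step equals two dt/2 steps under the same Hamiltonian", {
  H <- ham_matrix(hermitian_random(5, sd = 1e-3, seed = 12))
  d1 <- propagate(list(H), propagator_config(dt = 1))
  d2 <- propagate(list(H, H), propagator_config(dt = 0.5))
  expect_lt(max(Mod(d1$states[[2]]$vector - d2$states[[3]]$vector)), 1e-9)
})

test_that("population accessor validates its index and sums to the trace", {
  st <- random_density(4, 77)
  expect_error(population(st, 9), "out of range")
  expect_equal(sum(vapply(1:4, population, 0, state = st)), 1,
               tolerance = 1e-12)
  # pure state
  v <- numeric(16); v[6] <- 1   # |2><2| in column stacking
  expect_equal(population(density_state(v), 2), 1)
})

test_that("a basis-tag mismatch in the series is rejected", {
  H1 <- ham_matrix(hermitian_random(3, sd = 1e-3, seed = 1))
  H2 <- ham_matrix(hermitian_random(3, sd = 1e-3, seed = 2),
                   basis_tag = "term-basis")
  expect_error(propagate(list(H1, H2)), "basis tags")
})

test_that("density_state validation catches broken invariants", {
  expect_error(density_state(c(1, 0, 0)), "perfect square")
  expect_error(density_state(as.complex(diag(c(0.7, 0.7)))), "trace")
  bad <- diag(c(1.5, -0.5)) + 0i
  expect_error(density_state(as.complex(bad)), "negative eigenvalue")
})
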