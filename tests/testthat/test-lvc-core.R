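test_that("zero displacement reproduces the reference energies exactly", {
  p <- generate_parametrization(n_states = 5, spin_S = 1/2, n_sites = 4, seed = 1)
  H <- evaluate_mch(p, rep(0, 12))
  expect_equal(Re(diag(unclass(H))), p$energies, tolerance = 0)
  off <- unclass(H); diag(off) <- 0
  expect_equal(max(Mod(off)), 0)
})

test_that("two-state toy matches the closed-form 2x2 eigenvalues", {
  toy <- two_state_toy(e = c(0, 0.01), nac_x = 0.005)
  H <- evaluate_mch(toy, c(1, 0, 0))    # lambda . dR = 0.005
  expect_equal(Re(mat(H)), matrix(c(0, 0.005, 0.005, 0.01), 2, 2))
  ev <- diagonalize(H)$values
  expect_equal(ev, 0.005 + c(-1, 1) * sqrt(2 * 0.005^2), tolerance = 1e-12)
})

test_that("a single-state system reduces to a gradient energy shift", {
  p <- lvc_param(0, matrix(0, 1, 3), "atom", 0.1,
                 matrix(c(0.002, 0, 0), 1, 3), array(0, c(1, 1, 3)),
                 list(x = matrix(0, 1, 1), y = matrix(0, 1, 1),
                      z = matrix(0, 1, 1)), 1/2)
  H <- evaluate_mch(p, c(1, 0, 0))
  expect_equal(Re(mat(H)), matrix(0.102))
})

test_that("evaluate_mch is linear in the displacement about the anchor", {
  p <- generate_parametrization(n_states = 6, spin_S = 1/2, n_sites = 4, seed = 3)
  E0 <- diag(p$energies)
  set.seed(11)
  d1 <- rnorm(12, sd = 0.1); d2 <- rnorm(12, sd = 0.1)
  a <- 0.7; b <- -1.3
  lhs <- unclass(evaluate_mch(p, a * d1 + b * d2)) - E0
  rhs <- a * (unclass(evaluate_mch(p, d1)) - E0) +
    b * (unclass(evaluate_mch(p, d2)) - E0)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("evaluate_mch rejects mismatched displacement lengths", {
  p <- generate_parametrization(n_states = 3, spin_S = 1/2, n_sites = 4, seed = 1)
  expect_error(evaluate_mch(p, rep(0, 5)), "does not match 3N")
  expect_error(evaluate_mch(p, c(rep(0, 11), NaN)), "non-finite")
})

test_that("diagonalize round-trips random Hermitian matrices", {
  for (seed in 1:5) {
    H <- hermitian_random(10, seed = seed)
    e <- diagonalize(H)
    expect_false(is.unsorted(e$values))
    U <- e$vectors
    expect_lt(frob(Conj(t(U)) %*% U - diag(10)), 1e-12 * 10)
    expect_lt(frob(U %*% diag(e$values) %*% Conj(t(U)) - H), 1e-12 * frob(H) * 100)
  }
})

test_that("diagonalize of a diagonal matrix sorts the diagonal", {
  H <- diag(c(3, 1, 2)) + 0i
  e <- diagonalize(H)
  expect_equal(e$values, c(1, 2, 3))
  expect_equal(Mod(e$vectors), diag(3)[, c(2, 3, 1)], tolerance = 1e-14)
})

test_that("diagonalize rejects non-Hermitian input", {
  M <- matrix(c(0, 1, 0, 0), 2, 2) + 0i
  expect_error(diagonalize(M), "not Hermitian")
})

test_that("transform_operator preserves trace, norm and spectrum under a unitary", {
  set.seed(21)
  O <- hermitian_random(6, seed = 21)
  U <- diagonalize(hermitian_random(6, seed = 22))$vectors
  Ot <- transform_operator(O, U)
  expect_equal(sum(diag(Ot)), sum(diag(O)), tolerance = 1e-12)
  expect_equal(frob(Ot), frob(O), tolerance = 1e-12)
  expect_equal(diagonalize(Ot)$values, diagonalize(O)$values, tolerance = 1e-10)
  expect_equal(transform_operator(O, diag(6) + 0i), O)
  expect_equal(transform_operator(diag(6) + 0i, U), diag(6) + 0i,
               tolerance = 1e-12)
})

test_that("assemble_soc matches the element-wise Wigner-Eckart brute force", {
  n <- 2; S <- 1/2
  V <- list(x = hermitian_random(n, seed = 31), y = hermitian_random(n, seed = 32),
            z = hermitian_random(n, seed = 33))
  H <- mat(assemble_soc(V, S))
  Sm <- spin_matrices(S)
  mult <- 2L
  # explicit double loop over (state, M_S) pairs, state-major ordering
  brute <- matrix(0 + 0i, n * mult, n * mult)
  for (m in 1:n) for (a in 1:mult) for (k in 1:n) for (b in 1:mult) {
    row <- (m - 1L) * mult + a; col <- (k - 1L) * mult + b
    for (al in c("x", "y", "z"))
      brute[row, col] <- brute[row, col] + V[[al]][m, k] * Sm[[al]][a, b]
  }
  expect_equal(H, brute, tolerance = 1e-14)
})

test_that("assemble_soc trivial cases: zero V and 1-state S_z", {
  z <- matrix(0, 2, 2)
  expect_equal(max(Mod(unclass(assemble_soc(list(x = z, y = z, z = z), 1/2)))), 0)
  v <- 0.3
  H <- assemble_soc(list(x = matrix(0, 1, 1), y = matrix(0, 1, 1),
                         z = matrix(v, 1, 1)), 1/2)
  expect_equal(Re(diag(unclass(H))), c(v / 2, -v / 2))
})

test_that("lvc_hamiltonian is exact at the anchor geometry", {
  p <- generate_parametrization(n_states = 6, spin_S = 5/2, n_sites = 5, seed = 7)
  H0 <- anchor_hamiltonian(p)
  expect_equal(hamiltonian_error(lvc_hamiltonian(p, rep(0, 15)), H0), 0)
  expect_equal(hamiltonian_error(lvc_hamiltonian(p, rep(0, 15), basis = "reference"),
                                 H0), 0)
})

test_that("constant model: zero gradients and NACs give a displacement-independent Hamiltonian", {
  p <- generate_parametrization(n_states = 4, spin_S = 1/2, n_sites = 3, seed = 5,
                                scales = c(energy_window = 0.01, kappa = 0,
                                           nac = 0, soc = 0.001, quadratic = 0))
  H0 <- lvc_hamiltonian(p, rep(0, 9))
  set.seed(55)
  H1 <- lvc_hamiltonian(p, rnorm(9))
  expect_equal(unclass(H1), unclass(H0), tolerance = 1e-12)
})

test_that("every returned Hamiltonian is Hermitian and SOC norm is transform-invariant", {
  p <- generate_parametrization(n_states = 5, spin_S = 3/2, n_sites = 4, seed = 9)
  soc_norm0 <- frob(unclass(assemble_soc(p$soc, p$spin_S)))
  set.seed(77)
  for (i in 1:5) {
    d <- rnorm(12, sd = 0.2)
    H <- unclass(lvc_hamiltonian(p, d))
    expect_lt(frob(H - Conj(t(H))), 1e-12 * frob(H))
    eig <- diagonalize(evaluate_mch(p, d))
    Vt <- lapply(p$soc, transform_operator, transform = eig$vectors)
    expect_equal(frob(unclass(assemble_soc(Vt, p$spin_S))), soc_norm0,
                 tolerance = 1e-10)
  }
})

test_that("displaced and reference representations are unitarily equivalent", {
  p <- generate_parametrization(n_states = 4, spin_S = 1, n_sites = 3, seed = 13)
  set.seed(14)
  d <- rnorm(9, sd = 0.1)
  Ha <- lvc_hamiltonian(p, d)
  Hr <- lvc_hamiltonian(p, d, basis = "reference")
  expect_equal(diagonalize(Ha)$values, diagonalize(Hr)$values, tolerance = 1e-10)
})

test_that("parametrization container round-trips bit-faithfully and rejects bad files", {
  p <- generate_parametrization(n_states = 5, spin_S = 1/2, n_sites = 4, seed = 9)
  tf <- withr::local_tempfile(fileext = ".json")
  write_parametrization(p, tf)
  p2 <- read_parametrization(tf)
  expect_identical(p$energies, p2$energies)
  expect_identical(p$gradients, p2$gradients)
  expect_identical(p$nacs, p2$nacs)
  expect_identical(p$soc, p2$soc)
  expect_identical(p$geometry, p2$geometry)
  expect_identical(p$spin_S, p2$spin_S)

  obj <- jsonlite::read_json(tf)
  obj$gradients <- obj$gradients[1:2]
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, tf2, auto_unbox = TRUE, digits = I(17))
  expect_error(read_parametrization(tf2), "'gradients'")
  obj$gradients <- NULL
  jsonlite::write_json(obj, tf2, auto_unbox = TRUE, digits = I(17))
  expect_error(read_parametrization(tf2), "missing field 'gradients'")
})
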