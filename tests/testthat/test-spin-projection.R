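test_that("angular momentum matrices satisfy the ladder and Casimir identities", {
  for (j in c(1/2, 1, 3/2, 5/2, 5)) {
    J <- angular_momentum_matrices(j)
    d <- 2 * j + 1
    # commutator [Jx, Jy] = i Jz
    comm <- J$x %*% J$y - J$y %*% J$x
    expect_lt(frob(comm - 1i * J$z), 1e-12 * d)
    # Casimir
    J2 <- J$x %*% J$x + J$y %*% J$y + J$z %*% J$z
    expect_equal(J2, diag(d) * j * (j + 1) + 0i, tolerance = 1e-12)
    expect_equal(Re(diag(J$z)), seq(j, -j))
  }
  # j = 1 ladder element 1/sqrt(2)
  J1 <- angular_momentum_matrices(1)
  expect_equal(Re(J1$x[1, 2]), 1 / sqrt(2), tolerance = 1e-14)
  expect_error(angular_momentum_matrices(0.3), "half-integer")
})

test_that("O_2^0 for L=1 is diag(1, -2, 1) and all operators are traceless Hermitian", {
  expect_equal(Re(diag(stevens_operator(2, 0, 1))), c(1, -2, 1))
  ops <- stevens_operators(5)
  expect_length(ops, 27)
  for (O in ops) {
    expect_lt(Mod(sum(diag(O))), 1e-12 * max(Mod(O), 1))
    expect_lt(frob(O - Conj(t(O))), 1e-12 * max(frob(O), 1))
  }
})

test_that("known Stevens matrix elements match the literature table (J = 2, O_4^0)", {
  # diagonal of O_4^0 for J = 2: 12, -48, 72, -48, 12
  expect_equal(Re(diag(stevens_operator(4, 0, 2))), c(12, -48, 72, -48, 12))
  # O_2^2 = (J+^2 + J-^2)/2: <m|O|m+-2> = sqrt-product ladder amplitudes
  O22 <- stevens_operator(2, 2, 1)
  expect_equal(Re(O22[1, 3]), 1, tolerance = 1e-14)  # j=1: sqrt(2)*sqrt(2)/2
})

test_that("the 27 Stevens operators are mutually trace-orthogonal for L = 5", {
  ops <- stevens_operators(5)
  G <- vapply(ops, function(A) vapply(ops, function(B)
    Re(sum(Conj(A) * B)), 0), numeric(27))
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-10 * min(diag(G)))
  expect_gt(min(diag(G)), 0)
})

test_that("rank-k operators vanish for small L with a warning flag", {
  expect_warning(ops <- stevens_operators(1), "rank 4, 6")
  expect_equal(attr(ops, "zero_ranks"), c(4L, 6L))
  expect_equal(max(Mod(ops[["k6q0"]])), 0)
})

test_that("L.S-only spin Hamiltonian reproduces the Lande interval rule", {
  for (lambda in c(2e-3, -1.5e-3)) {
    p <- spin_params(lambda = lambda, L = 5, S = 5/2)
    ev <- diagonalize(build_spin_hamiltonian(p))$values
    expect_equal(ev, lande_levels(lambda, 5, 5/2), tolerance = 1e-10)
  }
})

test_that("a pure B_2^0 Hamiltonian is diagonal in M_L", {
  th <- stevens_theta("unit")
  b <- 3e-4
  p <- spin_params(lambda = 0, B = c(k2q0 = b), theta = th, L = 5, S = 5/2)
  H <- unclass(build_spin_hamiltonian(p))
  expect_lt(max(Mod(H - diag(diag(H)))), 1e-14)
  basis <- angular_basis(5, 5/2)
  expect_equal(Re(diag(H)), b * (3 * basis$M_L^2 - 5 * 6), tolerance = 1e-12)
})

test_that("zero parameters give the zero matrix and a zero projection", {
  p <- spin_params(lambda = 0, L = 5, S = 5/2)
  H <- build_spin_hamiltonian(p)
  expect_equal(max(Mod(unclass(H))), 0)
  pr <- project_spin_parameters(H, angular_basis(5, 5/2))
  expect_equal(pr$lambda, 0)
  expect_equal(max(abs(pr$B)), 0)
})

test_that("projection round-trips random parameter sets to 1e-10 relative", {
  basis <- angular_basis(5, 5/2)
  for (seed in 1:10) {
    p <- random_spin_params(seed, theta = "dy3+")
    H <- build_spin_hamiltonian(p)
    pr <- project_spin_parameters(H, basis, theta = "dy3+")
    expect_equal(pr$lambda, p$lambda, tolerance = 1e-10)
    expect_equal(pr$B, p$B, tolerance = 1e-10)
    expect_lt(attr(pr, "residual_norm"), 1e-12 * max(frob(unclass(H)), 1))
  }
})

test_that("projection ignores perturbations orthogonal to the operator span", {
  basis <- angular_basis(5, 5/2)
  p <- random_spin_params(42)
  H <- unclass(build_spin_hamiltonian(p))
  # Gram-Schmidt residual of a random Hermitian direction against the span
  set.seed(43)
  P <- hermitian_random(basis$dim, sd = 1e-4)
  span <- c(list(ls = ls_operator(basis)),
            lapply(suppressWarnings(stevens_operators(5)),
                   function(O) kronecker(O, diag(6))))
  for (Oi in span) P <- P - Oi * sum(Conj(Oi) * P) / sum(Conj(Oi) * Oi)
  pr <- project_spin_parameters(ham_matrix(H + P, basis_tag = "term-basis"),
                                basis)
  expect_equal(pr$lambda, p$lambda, tolerance = 1e-9)
  expect_equal(pr$B, p$B, tolerance = 1e-8)
  expect_equal(attr(pr, "residual_norm"), frob(P), tolerance = 1e-8)
})

test_that("component Hamiltonians add to the full one and isolate the terms", {
  p <- random_spin_params(7, theta = "dy3+")
  comp <- component_hamiltonians(p)
  expect_equal(unclass(comp$soc_only) + unclass(comp$cf_only),
               unclass(build_spin_hamiltonian(p)), tolerance = 1e-14)
  p_nob <- spin_params(lambda = p$lambda, theta = p$theta, L = p$L, S = p$S)
  expect_equal(max(Mod(unclass(component_hamiltonians(p_nob)$cf_only))), 0)
})

test_that("J_z symmetry holds exactly when all q != 0 CFPs vanish, and breaks otherwise", {
  basis <- angular_basis(5, 5/2)
  Jz_tot <- kronecker(diag(basis$M_L[seq(1, basis$dim, 6)]), diag(6)) +
    kronecker(diag(11), diag(seq(5/2, -5/2)))
  axial <- spin_params(lambda = 1e-3,
                       B = c(k2q0 = 2e-4, k4q0 = -1e-5, k6q0 = 3e-6),
                       L = 5, S = 5/2)
  H <- unclass(build_spin_hamiltonian(axial))
  expect_lt(frob(H %*% Jz_tot - Jz_tot %*% H), 1e-12)
  tilted <- spin_params(lambda = 1e-3, B = c(k2q0 = 2e-4, k2q2 = 1e-4),
                        L = 5, S = 5/2)
  Ht <- unclass(build_spin_hamiltonian(tilted))
  expect_gt(frob(Ht %*% Jz_tot - Jz_tot %*% Ht), 1e-6)
})

test_that("Kramers degeneracy: all eigenvalues of real-parameter spin Hamiltonians are doubly degenerate", {
  for (seed in 1:5) {
    p <- random_spin_params(seed + 100, theta = "dy3+")
    ev <- diagonalize(build_spin_hamiltonian(p))$values
    pairs <- matrix(ev, nrow = 2)
    expect_lt(max(abs(pairs[1, ] - pairs[2, ])), 1e-9)
  }
})

test_that("parameter tables round-trip through the text format", {
  p <- random_spin_params(31, theta = "dy3+")
  tf <- withr::local_tempfile(fileext = ".txt")
  write_parameter_table(p, tf)
  p2 <- read_parameter_table(tf, theta = "dy3+", L = 5, S = 5/2)
  expect_equal(p2$lambda, p$lambda, tolerance = 1e-15)
  expect_equal(p2$B, p$B, tolerance = 1e-15)
})
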