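# independent oracle: matrix-exponential solution of the (m+1)-dimensional
# linear system [n_0..n_{m-1}, C]
cascade_generator <- function(d) {
  tab <- release_rate_table(d)
  m <- d$m
  A <- matrix(0, m + 1, m + 1)
  for (j in seq_len(m)) {
    A[j, j] <- -(tab$alpha[j] + d$lambda_NP)
    if (j < m) A[j + 1, j] <- tab$alpha[j]
    A[m + 1, j] <- tab$r[j]
  }
  A[m + 1, m + 1] <- -d$lambda_drug
  A
}

expm_solution <- function(d, n0, C0, t) {
  A <- cascade_generator(d)
  as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% c(n0, C0))
}

test_that("uptake coefficient is the saturable ramp", {
  d <- np_design(rI = 0.0058, n_star = 500)
  expect_equal(uptake_coefficient(0, d), 0.0058)
  expect_equal(uptake_coefficient(500, d), 0)
  expect_equal(uptake_coefficient(250, d), 0.0029)
  expect_equal(uptake_coefficient(1000, d), 0)  # clamped past saturation
})

test_that("release-rate table follows the m-state age structure", {
  d4 <- np_design(m = 4, gamma1 = 1, C_star = 1)
  tab <- release_rate_table(d4)
  expect_equal(tab$f, c(1, 0.75, 0.5, 0.25))
  d2 <- np_design(m = 2, gamma1 = 1, C_star = 1)
  tab2 <- release_rate_table(d2)
  expect_equal(tab2$alpha[1], 2)
  expect_equal(tab2$r, c(1, 0.5))
  expect_equal(tab2$alpha[2], 0)  # final state: no exit in literal cascade
  d1 <- np_design(m = 1, gamma1 = 0.3, C_star = 1)
  tab1 <- release_rate_table(d1)
  expect_equal(tab1$r, 0.3)
  expect_equal(tab1$alpha, 0)
  # exhausted-state removal gives the final state an exit rate
  dx <- np_design(m = 4, gamma1 = 1, C_star = 1, exhausted_removal = TRUE)
  expect_equal(release_rate_table(dx)$alpha[4], 4 * 0.25)
  # midpoint load approximation
  dm <- np_design(m = 4, gamma1 = 1, C_star = 1, midpoint_load = TRUE)
  expect_equal(release_rate_table(dm)$load_frac,
               c(0.875, 0.625, 0.375, 0.125))
})

test_that("cascade transitions conserve NP number when decay is off", {
  d <- np_design(m = 5, gamma1 = 0.08, C_star = 10, lambda_NP = 0,
                 lambda_drug = 0)
  comp <- np_compartment(c(3, 1, 4, 1, 5))
  for (k in 1:50) {
    comp2 <- advance_intracellular(comp, 0, dt = 6, d = d, substeps = 1)
    expect_equal(total_np(comp2), total_np(comp), tolerance = 1e-10)
    comp <- comp2
  }
  # all-zero compartment with no influx stays zero
  z <- advance_intracellular(np_compartment(numeric(5)), 0, dt = 6, d = d)
  expect_equal(z$n, numeric(5))
  expect_equal(z$C, 0)
})

test_that("forward-Euler cascade matches the matrix-exponential oracle", {
  set.seed(123)
  for (m in c(1, 2, 3, 10)) {
    gamma1 <- runif(1, 0.01, 0.15)
    d <- np_design(m = m, gamma1 = gamma1, C_star = 10,
                   lambda_NP = runif(1, 0, 2e-3),
                   lambda_drug = runif(1, 0, 2e-3))
    n0 <- runif(m, 0, 10)
    comp <- np_compartment(n0, C = 0.5)
    t_end <- 1000
    nstep <- t_end / 6
    for (k in seq_len(nstep)) comp <- advance_intracellular(comp, 0, 6, d)
    exact <- expm_solution(d, n0, 0.5, t_end)
    got <- c(comp$n, comp$C)
    expect_lt(sqrt(sum((got - exact)^2) / sum(exact^2)), 0.01)
  }
})

test_that("single-step stability guard rejects too-coarse steps", {
  d <- np_design(m = 10, gamma1 = 2, C_star = 1)   # alpha_0 = 20 /min
  expect_error(advance_intracellular(np_compartment(numeric(10)), 0, dt = 6, d = d,
                                     substeps = 1),
               "stability")
})

test_that("literal cascade releases indefinitely; removal mode caps at C*", {
  # N NPs parked in the final state keep releasing at N gamma1 / m forever
  d <- np_design(m = 4, gamma1 = 0.1, C_star = 10, lambda_NP = 0,
                 lambda_drug = 0)
  comp <- cohort_release(8, 3, d)
  c1 <- advance_intracellular(comp, 0, dt = 100, d = d)
  expect_equal(c1$n, comp$n, tolerance = 1e-12)     # populations frozen
  expect_equal(c1$C, 8 * 0.1 * 0.25 * 100, tolerance = 1e-6)
  # with exhausted-state removal, lifetime release of N NPs <= N C*
  dr <- np_design(m = 4, gamma1 = 0.1, C_star = 10, lambda_NP = 0,
                  lambda_drug = 0, exhausted_removal = TRUE)
  comp <- cohort_release(5, 0, dr)
  released <- 0
  for (k in 1:300) {
    comp <- advance_intracellular(comp, 0, dt = 60, d = dr)
    released <- released + attr(comp, "released")
  }
  expect_lt(released, 5 * 10 + 1e-6)
  expect_gt(released, 5 * 10 * 0.95)   # nearly all drug eventually out
  expect_lt(total_np(comp), 0.05 * 5)  # spent NPs removed
})

test_that("cohort decay follows the scalar exponential when conserving", {
  lam <- 5e-4
  d <- np_design(m = 3, gamma1 = 0.05, C_star = 10, lambda_NP = lam,
                 lambda_drug = 0)
  comp <- cohort_release(100, 0, d)
  t_end <- 2000
  for (k in seq_len(t_end / 10)) comp <- advance_intracellular(comp, 0, 10, d)
  expect_equal(total_np(comp), 100 * exp(-lam * t_end), tolerance = 1e-3)
})

test_that("inheritance split is state-independent and ledgers the loss", {
  comp <- np_compartment(c(4, 2, 0), C = 6, auc = 2)
  sp <- split_on_division(comp, 0.5)
  expect_equal(sp$daughter1$n, c(2, 1, 0))
  expect_equal(sp$daughter2$n, c(2, 1, 0))
  expect_equal(sp$lost, 0)
  expect_equal(sp$daughter1$C, 3)
  expect_equal(sp$daughter1$auc, 1)
  sp0 <- split_on_division(comp, 0)
  expect_equal(total_np(sp0$daughter1), 0)
  expect_equal(sp0$lost, 6)
  expect_equal(sp0$daughter1$C, 3)  # drug still splits 50/50
  comp8 <- np_compartment(c(8, 0, 0))
  sp25 <- split_on_division(comp8, 0.25)
  expect_equal(total_np(sp25$daughter1), 2)
  expect_equal(sp25$lost, 4)
  expect_error(split_on_division(comp, 0.6), "0.5")
})

test_that("death clears the compartment and reports the count", {
  comp <- np_compartment(c(3, 4.5), C = 1)
  cl <- clear_on_death(comp)
  expect_equal(cl$cleared, 7.5)
  expect_equal(total_np(cl$comp), 0)
  cl0 <- clear_on_death(np_compartment(numeric(2)))
  expect_equal(cl0$cleared, 0)
})
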