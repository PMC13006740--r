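p_ox <- oxygen_response(b_bar = 0.00072, sigma1 = 5, sigma2 = 38,
                        rnec_bar = 1 / 360, sigma3 = 5, sigma4 = 2.5)

test_that("oxygen-dependent birth rate is a clamped linear ramp", {
  expect_equal(proliferation_rate(5, p_ox), 0)
  expect_equal(proliferation_rate(2, p_ox), 0)
  expect_equal(proliferation_rate(38, p_ox), 0.00072)
  expect_equal(proliferation_rate(100, p_ox), 0.00072)
  expect_equal(proliferation_rate((5 + 38) / 2, p_ox), 0.00072 / 2)
  # vectorized and monotone
  s <- seq(0, 60, by = 0.5)
  b <- proliferation_rate(s, p_ox)
  expect_true(all(diff(b) >= 0))
})

test_that("necrosis rate ramps up below the hypoxic threshold", {
  expect_equal(necrosis_rate(5, p_ox), 0)
  expect_equal(necrosis_rate(38, p_ox), 0)
  expect_equal(necrosis_rate(2.5, p_ox), 1 / 360)
  expect_equal(necrosis_rate(0, p_ox), 1 / 360)
  expect_equal(necrosis_rate((5 + 2.5) / 2, p_ox), 1 / 720)
  expect_error(oxygen_response(sigma1 = 40, sigma2 = 38), "sigma1")
})

test_that("pairwise mechanics are antisymmetric with compact support", {
  mech <- mechanics_params()
  # single cell: no force
  v <- pairwise_velocities(100, 100, 8.4, mech)
  expect_equal(v, matrix(0, 1, 2))
  # beyond max adhesion distance: zero
  v <- pairwise_velocities(c(0, 100), c(0, 0), c(8.4, 8.4), mech)
  expect_equal(v, matrix(0, 2, 2))
  # overlapping equal cells: equal and opposite along the center line
  v <- pairwise_velocities(c(0, 10), c(0, 0), c(8.4, 8.4), mech)
  expect_equal(v[1, ], -v[2, ])
  expect_gt(abs(v[1, 1]), 0)
  expect_equal(v[1, 2], 0)
  expect_lt(v[1, 1], 0)  # pushed apart (repulsion dominates at overlap)
  # momentum conservation for a random cluster
  set.seed(3)
  n <- 40
  v <- pairwise_velocities(runif(n, 0, 80), runif(n, 0, 80),
                           rep(8.4, n), mech)
  expect_lt(max(abs(colSums(v))), 1e-10)
})

test_that("coincident centers repel deterministically under a seed", {
  mech <- mechanics_params()
  set.seed(11)
  v1 <- pairwise_velocities(c(5, 5), c(5, 5), c(8, 8), mech)
  set.seed(11)
  v2 <- pairwise_velocities(c(5, 5), c(5, 5), c(8, 8), mech)
  expect_identical(v1, v2)
  expect_gt(sum(abs(v1)), 0)
  expect_equal(v1[1, ], -v1[2, ])
})

test_that("event sampling matches exponential-clock probabilities", {
  set.seed(5)
  # all rates zero: nothing ever fires
  expect_true(all(sample_cell_events(rep(0, 100), rep(0, 100),
                                     rep(0, 100), 6) == 0L))
  # empirical division frequency within 4 sigma of 1 - exp(-r dt)
  n <- 1e5
  r <- 0.002
  dt <- 6
  ev <- sample_cell_events(rep(r, n), rep(0, n), rep(0, n), dt)
  p <- -expm1(-r * dt)
  expect_lt(abs(mean(ev == 1L) - p), 4 * sqrt(p * (1 - p) / n))
  # precedence: necrosis wins when everything fires
  ev <- sample_cell_events(rep(100, 50), rep(100, 50), rep(100, 50), 10)
  expect_true(all(ev == 3L))
  expect_error(sample_cell_events(-1, 0, 0, 6), "non-negative")
})

test_that("division conserves volume and splits NPs by the inheritance rule", {
  st <- toy_tumor(1, seed = 2)
  cells <- st$cells
  cells$np[1, ] <- c(4, 2, 0, rep(0, ncol(cells$np) - 3))
  cells$C[1] <- 3
  vol0 <- cells$volume[1]
  set.seed(9)
  dv <- divide_cell(cells, 1, x_inherit = 0.5)
  expect_equal(sum(dv$cells$volume), vol0)
  expect_equal(dv$cells$np[1, ], dv$cells$np[2, ])
  expect_equal(sum(dv$cells$np), 6)        # parent total conserved at x=0.5
  expect_equal(dv$lost, 0)
  expect_equal(dv$cells$C, c(1.5, 1.5))
  # daughters sit radius/2 from the parent position, opposite directions
  expect_equal(dv$cells$x[1] + dv$cells$x[2], 2 * cells$x[1])
  d <- sqrt((dv$cells$x[1] - dv$cells$x[2])^2 +
              (dv$cells$y[1] - dv$cells$y[2])^2)
  expect_equal(d, cell_radius(vol0), tolerance = 1e-10)
  # x = 0: no inheritance, everything lost
  dv0 <- divide_cell(cells, 1, x_inherit = 0)
  expect_true(all(dv0$cells$np == 0))
  expect_equal(dv0$lost, 6)
  expect_error(divide_cell(cells, 1, 0.7), "0.5")
})

test_that("death progresses by timers; necrotic volume never grows", {
  st <- toy_tumor(3, seed = 4)
  cells <- st$cells
  cells$state[1] <- 1L  # apoptotic
  cells$timer[1] <- 100
  cells$state[2] <- 2L  # necrotic
  cells$timer[2] <- 500
  v0 <- cells$volume
  res <- progress_death(cells, dt = 50)
  expect_false(any(res$remove))
  expect_lt(res$cells$volume[1], v0[1])           # apoptotic shrinks
  expect_equal(res$cells$volume[2], v0[2])        # necrotic frozen
  expect_equal(res$cells$volume[3], v0[3])        # viable untouched
  # expiry triggers removal
  res2 <- progress_death(res$cells, dt = 100)
  expect_true(res2$remove[1])
  expect_false(res2$remove[2])
  # linear shrinkage reaches ~0 at expiry
  expect_lt(res2$cells$volume[1], 1e-8 + v0[1] * 1e-6)
})
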