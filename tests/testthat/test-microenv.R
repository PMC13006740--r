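test_that("field creation masks the domain boundary and counts voxels", {
  g <- np_grid(400, 400, dx = 20)
  expect_equal(c(g$nx, g$ny), c(20L, 20L))
  f <- np_field(g, "np", D = 6, lambda = 0, dirichlet_value = 0, initial = 0)
  expect_equal(sum(f$dirichlet_mask), 76)  # 4*20 - 4 corners counted once
  expect_true(all(f$values == 0))
  # zero boundary, no sources: stays identically zero
  f2 <- diffuse_decay_step(f, 0.01)
  expect_true(all(f2$values == 0))
  # oxygen and NP fields with very different D coexist on one grid
  o <- np_field(g, "oxygen", D = 1e5, lambda = 0.1, dirichlet_value = 38)
  expect_equal(o$D, 1e5)
  expect_equal(f$D, 6)
  expect_error(np_grid(-100, 100), "positive")
  expect_error(np_grid(410, 400, dx = 20), "multiple")
})

test_that("uniform field at the boundary value is a steady state", {
  g <- np_grid(400, 400, dx = 20)
  f <- np_field(g, "oxygen", D = 1e5, lambda = 0, dirichlet_value = 38)
  f2 <- diffuse_decay_step(f, 0.1)
  expect_equal(f2$values, f$values, tolerance = 1e-12)
})

test_that("implicit decay-only step has the backward-Euler closed form", {
  g <- np_grid(200, 200, dx = 20)
  f <- np_field(g, "np", D = 0, lambda = 0.2, dirichlet_value = 1,
                initial = 1)
  f$dirichlet_mask[] <- FALSE   # pure decay, no pinning
  f2 <- diffuse_decay_step(f, 0.5)
  expect_equal(unname(f2$values[1, 1]), 1 / (1 + 0.2 * 0.5),
               tolerance = 1e-14)
  expect_true(diff(range(f2$values)) < 1e-15)
})

test_that("implicit decay converges to exp(-lambda t) at first order", {
  g <- np_grid(100, 100, dx = 20)
  lambda <- 0.05
  t_end <- 10
  err <- vapply(c(1, 0.5, 0.25, 0.125), function(dt) {
    f <- np_field(g, "np", D = 0, lambda = lambda, dirichlet_value = 1,
                  initial = 1)
    f$dirichlet_mask[] <- FALSE
    for (k in seq_len(t_end / dt)) f <- diffuse_decay_step(f, dt)
    abs(f$values[2, 2] - exp(-lambda * t_end))
  }, numeric(1))
  order <- log2(err[-length(err)] / err[-1])
  expect_true(all(order > 0.9))  # measured convergence order >= 1
})

test_that("a spreading release matches a refined-grid reference solution", {
  # same PDE at 4x finer dx and dt is the oracle
  D <- 50
  t_end <- 20
  run <- function(dx, dt) {
    g <- np_grid(400, 400, dx = dx)
    f <- np_field(g, "np", D = D, lambda = 0, dirichlet_value = 0,
                  initial = 0)
    xc <- (seq_len(g$nx) - 0.5) * dx
    f$values <- exp(-outer((xc - 200)^2, (xc - 200)^2, "+") / (2 * 40^2))
    f$values[f$dirichlet_mask] <- 0
    for (k in seq_len(round(t_end / dt))) f <- diffuse_decay_step(f, dt)
    f
  }
  fc <- run(20, 0.25)
  ff <- run(5, 0.0625)
  # average the fine solution onto coarse voxels
  idx <- rep(seq_len(20), each = 4)
  fine_avg <- t(apply(apply(ff$values, 2, tapply, idx, mean), 1,
                      tapply, idx, mean))
  rel_l2 <- sqrt(sum((fc$values - fine_avg)^2) / sum(fine_avg^2))
  expect_lt(rel_l2, 0.02)
})

test_that("cell uptake is implicit, conservative, and shares by rate", {
  g <- np_grid(400, 400, dx = 20)
  f <- np_field(g, "np", D = 6, lambda = 0, dirichlet_value = 0, initial = 1)
  # U = 0: nothing happens
  res0 <- apply_cell_uptake(f, c(50, 90), c(50, 90), uv = c(0, 0), dt = 1)
  expect_equal(res0$field$values, f$values)
  expect_equal(res0$uptake, c(0, 0))
  # dt * U V / voxel_volume = 1 halves the voxel
  res1 <- apply_cell_uptake(f, 210, 210, uv = f$voxel_volume, dt = 1)
  expect_equal(unname(res1$field$values[11, 11]), 0.5)
  expect_equal(res1$uptake, 0.5 * f$voxel_volume)
  # random cells and rates: removed mass == summed uptake
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    x <- runif(n, 30, 370)
    y <- runif(n, 30, 370)
    uv <- runif(n, 0, 2e4)
    f$values <- matrix(runif(400, 0, 2), 20, 20)
    res <- apply_cell_uptake(f, x, y, uv, dt = 0.7)
    removed <- (sum(f$values) - sum(res$field$values)) * f$voxel_volume
    expect_equal(sum(res$uptake), removed, tolerance = 1e-10)
  }
  # a cell outside the domain is named in the error
  expect_error(apply_cell_uptake(f, -5, 50, uv = 1, dt = 1, ids = 99),
               "cell 99")
})

test_that("diffusion solver is deterministic", {
  g <- np_grid(300, 300, dx = 20)
  f <- np_field(g, "np", D = 30, lambda = 0.01, dirichlet_value = 0.5,
                initial = 0)
  a <- diffuse_decay_step(diffuse_decay_step(f, 0.3), 0.3)
  b <- diffuse_decay_step(diffuse_decay_step(f, 0.3), 0.3)
  expect_identical(a$values, b$values)
})

test_that("fused diffusion tier reproduces the composed single-step ops", {
  g <- np_grid(300, 300, dx = 20)
  f <- np_field(g, "np", D = 6, lambda = 1e-4, dirichlet_value = 0.02,
                initial = 0)
  n <- 12
  set.seed(7)
  x <- runif(n, 40, 260)
  y <- runif(n, 40, 260)
  vol <- rep(2494, n)
  rI <- 0.0058
  n_star <- 500
  nI <- rep(0, n)
  dt <- 2
  nsub <- 5
  bvals <- 0.02 * exp(-0.001 * seq_len(nsub))
  # reference: compose exported operations
  fr <- f
  acc <- numeric(n)
  for (s in seq_len(nsub)) {
    fr$dirichlet_value <- bvals[s]
    fr <- diffuse_decay_step(fr, dt)
    uv <- rI * pmax(0, 1 - nI / n_star) * vol
    res <- apply_cell_uptake(fr, x, y, uv, dt)
    fr <- res$field
    acc <- acc + res$uptake
    nI <- nI + res$uptake
  }
  ij <- cbind(floor(x / 20) + 1, floor(y / 20) + 1)
  fused <- nanoabm:::.diffusion_tier_cpp(
    f$values, f$dirichlet_mask, f$D, f$lambda, dt, f$dx, f$voxel_volume,
    bvals, ij[, 1], ij[, 2], numeric(n), vol, rep(0, n), rI, n_star,
    TRUE, FALSE)
  expect_equal(fused$values, fr$values, tolerance = 1e-13)
  expect_equal(fused$uptake, acc, tolerance = 1e-13)
})
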