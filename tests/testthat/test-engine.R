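# small fast configuration used across engine tests
quick_config <- function(...) {
  defaults <- list(grid = np_grid(200, 200, dx = 20),
                   oxygen = list(quasi_steady = TRUE, relax_iters = 10,
                                 relax_dt = 0.1),
                   dt_diffusion = 2, dt_mechanics = 2, dt_phenotype = 6,
                   t_end = 1440, initial_radius = 30, output_every = 360)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("initialization hex-packs the requested disk", {
  # oracle: direct enumeration of hex lattice points within the disk
  hex_count <- function(radius, spacing) {
    dy <- spacing * sqrt(3) / 2
    cnt <- 0
    for (j in -30:30) {
      off <- if (j %% 2 == 0) 0 else spacing / 2
      for (i in -30:30) {
        x <- i * spacing + off
        y <- j * dy
        if (x^2 + y^2 <= radius^2) cnt <- cnt + 1
      }
    }
    cnt
  }
  cfg <- quick_config(initial_radius = 0)
  st <- initialize_state(cfg, 1)
  expect_equal(length(st$cells$id), 1L)
  expect_equal(st$cells$x, 100)
  cfg <- sim_config(grid = np_grid(600, 600, dx = 20), initial_radius = 100,
                    t_end = 0)
  st <- initialize_state(cfg, 1)
  spacing <- 2 * cell_radius(cfg$cell_volume)
  expect_equal(length(st$cells$id), hex_count(100, spacing))
  expect_true(all(st$cells$state == 0L))
  # oxygen starts at the boundary value; NP interior is empty (the t = 0
  # injection lives only on the Dirichlet boundary voxels)
  expect_true(all(st$oxygen$values == 38))
  expect_true(all(st$np$values[!st$np$dirichlet_mask] == 0))
  expect_equal(unname(st$np$values[1, 1]),
               boundary_concentration(0, cfg$schedule))
  # tumor must fit in the domain
  expect_error(sim_config(grid = np_grid(200, 200), initial_radius = 150),
               "fit")
})

test_that("same seed gives bit-identical trajectories", {
  cfg <- quick_config(schedule = dose_schedule(times = 0, doses = 1))
  a <- run_simulation(cfg, seed = 7)
  b <- run_simulation(cfg, seed = 7)
  expect_identical(a$series, b$series)
  expect_identical(a$final_state$cells$np, b$final_state$cells$np)
  c2 <- run_simulation(cfg, seed = 8)
  expect_false(identical(a$series, c2$series))
})

test_that("t_end = 0 returns the initial state only", {
  cfg <- quick_config(t_end = 0)
  tr <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(tr$series), 1L)
  expect_equal(tr$series$time, 0)
})

test_that("a cell-free simulation still evolves the fields", {
  cfg <- quick_config(t_end = 72, initial_radius = 0,
                      schedule = dose_schedule(times = 0, doses = 1))
  st <- initialize_state(cfg, 1)
  st$cells <- nanoabm:::cells_subset(st$cells,
                                     rep(FALSE, length(st$cells$id)))
  for (k in 1:12) st <- sim_step(st, cfg)
  expect_equal(length(st$cells$id), 0L)
  expect_gt(field_total_mass(st$np), 0)  # NPs diffused in from the boundary
  expect_equal(st$time, 72)
})

test_that("mass ledger balances through a dosed, dividing run", {
  cfg <- quick_config(t_end = 2880,
                      schedule = dose_schedule(times = 0, doses = 1),
                      inheritance_x = 0.3)
  tr <- run_simulation(cfg, seed = 3, audit_every = TRUE)
  expect_lt(tr$max_audit_residual, 1e-6)
  # NPs actually moved: internalization happened
  expect_gt(tr$final_state$ledger$internalized, 0)
  # viable counts are non-negative integers
  expect_true(all(tr$series$viable >= 0))
  expect_true(all(tr$series$viable == round(tr$series$viable)))
})

test_that("dead cells neither divide nor take up NPs", {
  cfg <- quick_config(t_end = 144,
                      schedule = dose_schedule(times = 0, doses = 1))
  st <- initialize_state(cfg, 2)
  st$cells$state[] <- 2L                 # all necrotic
  st$cells$timer[] <- 1e6
  n0 <- length(st$cells$id)
  for (k in 1:24) st <- sim_step(st, cfg)
  expect_equal(length(st$cells$id), n0)
  expect_equal(st$ledger$internalized, 0)
  expect_true(all(st$cells$np == 0))
})

test_that("snapshot schema carries 10 + m columns", {
  cfg <- quick_config()
  st <- initialize_state(cfg, 1)
  snap <- state_snapshot(st)
  expect_equal(ncol(snap), 10 + cfg$design$m)
  expect_true(all(c("id", "x", "y", "volume", "state", "b_current",
                    "apoptosis_current", "total_np", "C", "E")
                  %in% names(snap)))
  expect_true(all(snap$state == "viable"))
})
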