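# Integrator correctness against closed forms of the linear sink
# x' = -(x - c): one Euler step multiplies the offset by (1 - h), one RK4
# step by the degree-4 Taylor polynomial of exp(-h), and the exact endpoint
# after time T is c + (x0 - c) exp(-T).

sink_field <- function(center = c(0.5, 0.5, 0.5), resolution = 11) {
  analytic_grid_field(function(p) center - p, lo = c(-1, -1, -1),
                      hi = c(2, 2, 2), resolution = resolution)
}

taylor4 <- function(h) 1 - h + h^2 / 2 - h^3 / 6 + h^4 / 24

test_that("single steps match their closed forms on the linear sink", {
  f <- sink_field(center = c(0, 0, 0))
  p0 <- c(1, 0, 0)
  expect_equal(euler_step(f, p0, 0.1), c(0.9, 0, 0), tolerance = 1e-12)
  expect_equal(rk4_step(f, p0, 0.1), c(taylor4(0.1), 0, 0),
               tolerance = 1e-12)
})

test_that("zero fields fix every point for both steppers", {
  f <- analytic_grid_field(function(p) c(0, 0, 0), resolution = 4)
  expect_equal(euler_step(f, c(0.3, 0.3, 0.3), 0.5), c(0.3, 0.3, 0.3))
  expect_equal(rk4_step(f, c(0.3, 0.3, 0.3), 0.5), c(0.3, 0.3, 0.3))
})

test_that("uniform fields advance both steppers identically (h * v)", {
  f <- analytic_grid_field(function(p) c(1, 0, 0), resolution = 4)
  expect_equal(euler_step(f, c(0, 0, 0), 0.1), c(0.1, 0, 0),
               tolerance = 1e-14)
  expect_equal(rk4_step(f, c(0, 0, 0), 0.1), c(0.1, 0, 0),
               tolerance = 1e-14)
  cfg_e <- integration_config("euler", 0.05, 10, 0)
  cfg_r <- integration_config("rk4", 0.05, 10, 0)
  t1 <- integrate_trajectory(f, c(0.1, 0.5, 0.5), cfg_e)
  t2 <- integrate_trajectory(f, c(0.1, 0.5, 0.5), cfg_r)
  expect_equal(t1$points, t2$points, tolerance = 1e-13)
  expect_equal(nrow(t1$points), 11L)
  expect_equal(t1$termination, "completed")
  # straight streamline: all points collinear with the flow direction
  expect_true(all(abs(diff(t1$points[, 2])) < 1e-14))
})

test_that("RK4 trajectories land on the analytic sink solution", {
  cen <- c(0.5, 0.5, 0.5)
  f <- sink_field(center = cen)
  seed <- c(1.6, -0.4, 0.9)
  cfg <- integration_config("rk4", step_size = 0.05, n_steps = 100,
                            diff_threshold = 0)
  tr <- integrate_trajectory(f, seed, cfg)
  expect_equal(tr$termination, "completed")
  analytic <- cen + (seed - cen) * exp(-5)
  expect_lt(sqrt(sum((tr$points[101, ] - analytic)^2)), 1e-6)
})

test_that("halving h shrinks endpoint error ~2x for Euler, ~16x for RK4", {
  cen <- c(0.5, 0.5, 0.5)
  f <- sink_field(center = cen)
  seed <- c(1.5, 1.5, 1.5)
  endpoint_error <- function(method, h, n) {
    cfg <- integration_config(method, step_size = h, n_steps = n,
                              diff_threshold = 0)
    tr <- integrate_trajectory(f, seed, cfg)
    analytic <- cen + (seed - cen) * exp(-h * n)
    sqrt(sum((tr$points[n + 1, ] - analytic)^2))
  }
  ratio <- function(method) {
    endpoint_error(method, 0.2, 10) / endpoint_error(method, 0.1, 20)
  }
  expect_gt(ratio("euler"), 1.8)
  expect_lt(ratio("euler"), 2.2)
  expect_gt(ratio("rk4"), 12)
  expect_lt(ratio("rk4"), 20)
})

test_that("termination rules: threshold stop, domain exit, outside seed", {
  fz <- analytic_grid_field(function(p) c(0, 0, 0), resolution = 4)
  tr <- integrate_trajectory(fz, c(0.5, 0.5, 0.5),
                             integration_config("euler", 0.1, 10, 1e-6))
  expect_equal(nrow(tr$points), 1L)
  expect_equal(tr$termination, "below-threshold")

  # zero threshold on a zero field still stops (no duplicate points)
  tr0 <- integrate_trajectory(fz, c(0.5, 0.5, 0.5),
                              integration_config("euler", 0.1, 10, 0))
  expect_equal(nrow(tr0$points), 1L)

  fu <- analytic_grid_field(function(p) c(1, 0, 0), resolution = 4)
  tr2 <- integrate_trajectory(fu, c(0.9, 0.5, 0.5),
                              integration_config("euler", 0.2, 50, 0))
  expect_equal(tr2$termination, "out-of-domain")
  up <- fu$grid$origin + fu$grid$spacing * (fu$grid$shape - 1)
  expect_true(all(tr2$points[, 1] <= up[1] + 1e-12))

  tr3 <- integrate_trajectory(fu, c(7, 7, 7), integration_config())
  expect_equal(nrow(tr3$points), 1L)
  expect_equal(tr3$termination, "out-of-domain")
})

test_that("no trajectory point ever leaves the grid box (random fields)", {
  for (s in 1:5) {
    set.seed(s)
    grid <- build_grid(matrix(runif(30), 10, 3), resolution = 6,
                       padding = 0.05)
    vecs <- matrix(rnorm(3 * prod(grid$shape)), ncol = 3)
    f <- grid_vector_field(grid, vecs, rep(1L, nrow(vecs)))
    up <- grid$origin + grid$spacing * (grid$shape - 1)
    for (k in 1:5) {
      seed_pt <- runif(3, grid$origin, up)
      tr <- integrate_trajectory(f, seed_pt,
                                 integration_config("rk4", 0.2, 40, 0))
      expect_true(all(t(tr$points) >= grid$origin - 1e-9))
      expect_true(all(t(tr$points) <= up + 1e-9))
    }
  }
})

test_that("cell seeds come from the coordinate table", {
  ds <- random_dataset(10, seed = 1)
  expect_equal(seed_from_cell(ds, "cell_3"), unname(ds$coords[4, ]))
  err <- expect_error(seed_from_cell(ds, "nope"),
                      class = "cellstream_lookup_error")
  expect_match(conditionMessage(err), "nope")
})

test_that("first CSV row seeds the trajectory of its cell id", {
  p <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(x = runif(5), y = runif(5), z = runif(5))
  write.table(df, p, sep = ",", row.names = FALSE, quote = FALSE)
  ds <- load_table(p, column_map = list(x = "x", y = "y", z = "z"))
  expect_equal(seed_from_cell(ds, "cell_0"),
               as.numeric(df[1, c("x", "y", "z")]))
})

test_that("streamline density subsampling is seeded and floor-counted", {
  ds <- random_dataset(400, seed = 10)
  g <- build_grid(ds$coords, resolution = 7, padding = 0)
  f <- average_velocities(ds, g)
  cfg <- integration_config("euler", 0.1, 5, 0)

  full <- generate_streamlines(f, cfg, density = 1)
  eligible <- sum(f$occupancy >= 1)
  # full density integrates every eligible node; only >= 2 point lines kept
  expect_lte(length(full$trajectories), eligible)
  expect_gt(length(full$trajectories), 0)

  a <- generate_streamlines(f, cfg, density = 0.5, seed = 99)
  b <- generate_streamlines(f, cfg, density = 0.5, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(
    as.data.frame(generate_streamlines(f, cfg, density = 0.5, seed = 100)),
    as.data.frame(a)))

  # floor convention on the seed count, checked by recount
  n_seeds <- length(unique(as.data.frame(a)$trajectory_id))
  expect_lte(n_seeds, floor(0.5 * eligible))
})

test_that("streamlets are prefixes with recorded truncation", {
  f <- analytic_grid_field(function(p) c(1, 0, 0), lo = c(0, 0, 0),
                           hi = c(10, 1, 1), resolution = 21)
  cfg <- integration_config("euler", 0.1, 10, 0)
  lines <- generate_streamlines(f, cfg, density = 1)
  orig_lens <- vapply(lines$trajectories, function(t) nrow(t$points), 1L)

  short <- make_streamlets(lines, 3)
  lens <- vapply(short$trajectories, function(t) nrow(t$points), 1L)
  expect_equal(lens, pmin(orig_lens, 4L))
  expect_equal(short$streamlet_steps, 3L)
  # prefixes of the originals
  expect_equal(short$trajectories[[1]]$points,
               lines$trajectories[[1]]$points[1:lens[1], ])
  # total point count conservation under truncation
  expect_equal(sum(lens), sum(pmin(orig_lens, 4L)))

  # streamlet budget beyond length leaves lines unchanged
  same <- make_streamlets(lines, 1000)
  expect_equal(vapply(same$trajectories, function(t) nrow(t$points), 1L),
               orig_lens)
})
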