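test_that("analytic fields are exact at zero noise and seeded-deterministic", {
  ds_u <- make_field_dataset(100, "uniform", noise_sd = 0, seed = 2)
  expect_true(all(ds_u$velocities[, 1] == 1 & ds_u$velocities[, 2] == 0 &
                    ds_u$velocities[, 3] == 0))

  cen <- c(0.2, 0.8, 0.5)
  ds_s <- make_field_dataset(100, "linear-sink",
                             field_params = list(center = cen),
                             noise_sd = 0, seed = 2)
  expect_equal(unname(ds_s$velocities),
               unname(sweep(-ds_s$coords, 2, cen, `+`)), tolerance = 1e-14)

  ds_b <- make_field_dataset(200, "bifurcation", noise_sd = 0, seed = 3)
  beyond <- ds_b$coords[, 1] > 0.5
  expect_true(all(ds_b$velocities[, 1] == 1))
  expect_true(all(ds_b$velocities[!beyond, 3] == 0))
  expect_equal(sign(ds_b$velocities[beyond, 3]),
               sign(ds_b$coords[beyond, 3] - 0.5))

  a <- make_field_dataset(50, "linear-sink", noise_sd = 0.3, n_features = 3,
                          seed = 9)
  b <- make_field_dataset(50, "linear-sink", noise_sd = 0.3, n_features = 3,
                          seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a, make_field_dataset(50, "linear-sink", noise_sd = 0.3, n_features = 3,
                          seed = 10)))
})

test_that("planted trend features hit their profile endpoints and peaks", {
  set.seed(70)
  co <- matrix(runif(1200), 400, 3)
  ds <- cell_embedding(co)
  path <- cbind(seq(0.05, 0.95, length.out = 11), 0.5, 0.5)
  ds <- make_trend_features(ds, path,
                            profiles = c("monotone-up", "monotone-down",
                                         "transient-peak"),
                            noise_sd = 0, seed = 1)
  vals <- ds$modalities$RNA
  expect_equal(ncol(vals), 3L)

  d_start <- sqrt(rowSums(sweep(co, 2, path[1, ])^2))
  d_end <- sqrt(rowSums(sweep(co, 2, path[11, ])^2))
  up <- vals[, 1]
  expect_equal(unname(up[which.min(d_start)]), 0)
  expect_equal(unname(up[which.min(d_end)]), 1)
  down <- vals[, 2]
  expect_equal(unname(down[which.min(d_start)]), 1)
  peak <- vals[, 3]
  # maximal cells are exactly those whose nearest path point is the midpoint
  nearest <- apply(co, 1, function(p) {
    which.min(colSums((t(path) - p)^2))
  })
  expect_setequal(which(peak == max(peak)), which(nearest == 6))
})

test_that("segment means along the planted path recover the profiles", {
  set.seed(71)
  co <- cbind(runif(600), runif(600, 0.4, 0.6), runif(600, 0.4, 0.6))
  ds <- cell_embedding(co)
  path <- cbind(seq(0, 1, length.out = 21), 0.5, 0.5)
  ds <- make_trend_features(ds, path,
                            profiles = c("monotone-up", "monotone-down"),
                            noise_sd = 0.02, seed = 4)
  tr <- cellstream:::new_trajectory(path, path[1, ], "completed",
                                    integration_config(n_steps = 20L))
  a <- assign_segments(tr, ds, n_segments = 8, radius = 0.5)
  tm <- segment_means(a, ds$modalities$RNA, "raw")
  up <- tm$means[1, ]
  down <- tm$means[2, ]
  # recovered profiles are monotone in the planted directions within noise
  expect_true(all(diff(up) > -0.05))
  expect_gt(up[8] - up[1], 0.6)
  expect_true(all(diff(down) < 0.05))
  expect_lt(down[8] - down[1], -0.6)
})

test_that("clonal fixtures return a truthful membership table", {
  fix <- make_clonal_dataset(300, n_clones = 8, sentinel_fraction = 0.1,
                             dispersed_fraction = 0.2, seed = 5)
  ds <- fix$dataset
  expect_equal(nrow(fix$membership) + sum(is.na(ds$clones)), 300L)

  # generator's own table is the oracle for expansion, clone by clone
  for (cl in unique(fix$membership$clone)) {
    members <- match(fix$membership$cell_id[fix$membership$clone == cl],
                     ds$cell_ids)
    res <- expand_clones(ds, members[1])
    expect_setequal(c(members[1], res$related_cells), members)
  }

  # a single clone with no sentinel connects every cell
  fix1 <- make_clonal_dataset(50, n_clones = 1, sentinel_fraction = 0,
                              dispersed_fraction = 0, seed = 6)
  res <- expand_clones(fix1$dataset, 17L)
  expect_setequal(res$related_cells, setdiff(1:50, 17L))
})

test_that("noiseless sink trajectories converge on the planted attractor", {
  cen <- c(0.5, 0.5, 0.5)
  ds <- make_field_dataset(4000, "linear-sink",
                           field_params = list(center = cen),
                           noise_sd = 0, seed = 12)
  g <- build_grid(ds$coords, resolution = 12, padding = 0)
  f <- average_velocities(ds, g, method = "gaussian-kernel")
  cfg <- integration_config("rk4", step_size = 0.1, n_steps = 100,
                            diff_threshold = 0)
  set.seed(13)
  for (k in 1:5) {
    seed_pt <- runif(3, 0.1, 0.9)
    tr <- integrate_trajectory(f, seed_pt, cfg)
    d0 <- sqrt(sum((seed_pt - cen)^2))
    d1 <- sqrt(sum((tr$points[nrow(tr$points), ] - cen)^2))
    expect_lt(d1, 0.05 * d0 + 1e-3)
  }
})

test_that("fixtures are written in every supported format and reload", {
  dir <- withr::local_tempdir()
  ds <- make_field_dataset(30, "uniform", n_features = 2, seed = 8)
  files <- write_fixture(ds, dir, "fx")
  expect_true(all(file.exists(files)))
  expect_setequal(tools::file_ext(files), c("csv", "h5ad"))
  back <- load_h5ad(file.path(dir, "fx.h5ad"))
  expect_equal(back$coords, ds$coords)

  fix <- make_clonal_dataset(20, 2, seed = 3)
  fix$dataset$modalities$RNA <- modality_matrix(matrix(1, 20, 1), "RNA", 20)
  fix$dataset$modalities$ADT <- modality_matrix(matrix(2, 20, 1), "ADT", 20)
  files2 <- write_fixture(fix$dataset, dir, "fx2",
                          membership = fix$membership)
  expect_true(any(grepl("h5mu$", files2)))
  expect_true(any(grepl("membership.json$", files2)))
  gt <- jsonlite::read_json(files2[grepl("membership", files2)],
                            simplifyVector = TRUE)
  expect_equal(nrow(fix$membership), length(gt$cell_id))
})
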