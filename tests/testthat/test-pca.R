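# Frame-set PCA, R-component fields, separation metric and NMD export.

test_that("PCA recovers planted structure and satisfies spectral identities", {
  # fluctuation along one coordinate of one atom only
  set.seed(1)
  arr <- array(0, c(200, 4, 3))
  arr[, 2, 1] <- rnorm(200, sd = 2)
  cs <- coord_series(arr, ca_topology(4), dt = 1, fitted = TRUE)
  pca <- covariance_pca(cs)
  expect_equal(cumulative_covariance(pca, 1), 1.0)
  axis <- numeric(12)
  axis[4] <- 1 # atom 2, x
  expect_gt(abs(sum(pca$vectors[, 1] * axis)), 1 - 1e-10)

  # orthonormality and total-variance conservation on generic data
  set.seed(2)
  arr2 <- array(rnorm(500 * 5 * 3), c(500, 5, 3))
  cs2 <- coord_series(arr2, ca_topology(5), dt = 1, fitted = TRUE)
  p2 <- covariance_pca(cs2)
  expect_lt(max(abs(crossprod(p2$vectors) - diag(15))), 1e-8)
  expect_lt(abs(sum(p2$values) - p2$trace) / p2$trace, 1e-6)

  # planted top eigenvector recovered from a generated ensemble
  sc <- make_opening_scenario(n_atoms = 20, n_frames = 20000, seed = 3)
  tr <- gen_gaussian_trajectory(sc$spec)
  p3 <- covariance_pca(tr)
  expect_gt(abs(sum(p3$vectors[, 1] * sc$v)), 0.99)

  expect_error(covariance_pca(cs, frame_interval = c(0, 1)),
               class = "allokin_invalid_spec")
})

test_that("white-noise eigenvalue spectrum is flat to within sampling spread", {
  n_at <- 10 # 30 dims, 50x frames
  spec <- gaussian_trajectory_spec(matrix(0, n_at, 3), diag(0.25, 3 * n_at),
                                   n_frames = 1500, seed = 17)
  p <- covariance_pca(gen_gaussian_trajectory(spec))
  expect_lt(max(p$values) / min(p$values), 2)
})

test_that("cumulative covariance fractions behave like partial sums", {
  fake <- structure(list(values = rep(2, 6)), class = "pca_result")
  expect_equal(cumulative_covariance(fake, 3), 0.5) # isotropic: m/d
  expect_equal(cumulative_covariance(fake, 6), 1.0)
  expect_error(cumulative_covariance(fake, 7), class = "allokin_invalid_spec")
  m_seq <- vapply(1:6, cumulative_covariance, numeric(1), pca = fake)
  expect_true(all(diff(m_seq) >= 0))
})

test_that("R-component fields follow the sqrt-eigenvalue convention", {
  sc <- make_opening_scenario(n_atoms = 12, n_frames = 4000, seed = 5)
  tr <- gen_gaussian_trajectory(sc$spec)
  p <- covariance_pca(tr)

  r1 <- r_components(p, 1)
  expect_equal(sum(r1^2), p$values[1], tolerance = 1e-10)
  expect_equal(r_components(p, 1, convention = "lambda"),
               r1 * sqrt(p$values[1]), tolerance = 1e-10)

  # zero eigenvalue: zero field (rank-deficient by construction)
  zero_idx <- which(p$values < 1e-10)
  if (length(zero_idx)) {
    expect_equal(max(abs(r_components(p, zero_idx[1]))), 0,
                 tolerance = 1e-8)
  }

  # doubling all fluctuations quadruples eigenvalues, doubles |r|
  tr2 <- tr
  mu <- colMeans(allokin:::series_xyz(tr))
  xyz2 <- sweep(sweep(allokin:::series_xyz(tr), 2, mu), 1:2, 2, "*")
  tr2$coords <- allokin:::xyz_to_array(sweep(xyz2, 2, mu, "+"),
                                       n_atoms(tr))
  p2x <- covariance_pca(tr2)
  expect_equal(p2x$values[1] / p$values[1], 4, tolerance = 1e-8)
  expect_equal(sqrt(sum(r_components(p2x, 1)^2)) /
                 sqrt(sum(r_components(p, 1)^2)), 2, tolerance = 1e-6)
})

test_that("separation metric quantifies opening motion between groups", {
  sc <- make_opening_scenario(n_atoms = 40, n_frames = 20000, amp = 2,
                              floor_sd = 0.1, seed = 7)
  tr <- gen_gaussian_trajectory(sc$spec)
  p <- covariance_pca(tr)
  prof <- separation_metric(p, sc$target, sc$barrier)

  # planted mode construction: target entries +u/sqrt(2 nT), barrier
  # -u/sqrt(2 nB); separation for PC1 = sqrt(lambda) * 2/sqrt(8)
  nT <- length(sc$target)
  expected <- sqrt(p$values[1]) * 2 / sqrt(2 * nT)
  expect_equal(abs(prof$separation[1]), expected, tolerance = 0.02)

  # the planted opening mode dominates the profile
  expect_equal(which.max(abs(prof$separation)), 1)

  # swapping target and barrier groups flips the axis u and the group
  # means together, so "moving apart" keeps its sign
  swapped <- separation_metric(p, sc$barrier, sc$target)
  expect_equal(swapped$separation, prof$separation, tolerance = 1e-10)
  expect_equal(attr(swapped, "u"), -attr(prof, "u"), tolerance = 1e-12)

  # orthogonal-mode components carry ~zero separation compared to PC1
  expect_lt(max(abs(prof$separation[-1])), 0.1 * abs(prof$separation[1]))

  expect_error(separation_metric(p, sc$target, sc$target),
               class = "allokin_invalid_selection")
  expect_error(separation_metric(p, integer(0), sc$barrier),
               class = "allokin_invalid_selection")
})

test_that("NMD export round trips and carries one mode line per component", {
  dir <- withr::local_tempdir()
  sc <- make_opening_scenario(n_atoms = 10, n_frames = 2000, seed = 9)
  p <- covariance_pca(gen_gaussian_trajectory(sc$spec))
  path <- file.path(dir, "modes.nmd")
  write_nmd(p, path, n_modes = 15)
  expect_equal(sum(grepl("^mode ", readLines(path))), 15)

  back <- read_nmd(path)
  expect_equal(back$values, p$values[1:15], tolerance = 1e-6)
  expect_equal(back$coordinates, p$mean, tolerance = 1e-6)
  for (m in 1:15) {
    expect_equal(back$vectors[, m], p$vectors[, m], tolerance = 1e-6)
  }

  empty <- p
  empty$mean <- p$mean[0, , drop = FALSE]
  expect_error(write_nmd(empty, path), class = "allokin_invalid_spec")
})
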