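# Ground-truth properties of the synthetic-data generators.

test_that("Gaussian trajectory reproduces prescribed correlations and rejects bad input", {
  n_at <- 10
  ref <- matrix(0, n_at, 3)

  # independence under diagonal covariance
  spec <- gaussian_trajectory_spec(ref, diag(0.25, 3 * n_at),
                                   n_frames = 50000, seed = 41)
  tr <- gen_gaussian_trajectory(spec)
  Cs <- correlation_matrix(tr)
  off <- Cs[upper.tri(Cs)]
  expect_lt(max(abs(off)), 0.02)

  # planted block of pairwise correlation 0.9 among residues 1-5
  Cb <- block_correlation(n_at, list(list(atoms = 1:5, rho = 0.9)))
  spec2 <- gaussian_trajectory_spec(ref, correlation_to_covariance(Cb, 0.5),
                                    n_frames = 50000, seed = 42)
  Cs2 <- correlation_matrix(gen_gaussian_trajectory(spec2))
  expect_lt(max(abs(Cs2 - Cb)), 0.02)

  # non-PSD covariance is rejected with a named validation error
  bad <- diag(3 * n_at)
  bad[1, 2] <- bad[2, 1] <- 2
  expect_error(
    gen_gaussian_trajectory(
      gaussian_trajectory_spec(ref, bad, n_frames = 10)),
    class = "allokin_invalid_covariance")
})

test_that("regime switch translates segment means by the prescribed offset", {
  n_at <- 4
  ref <- matrix(0, n_at, 3)
  shift <- matrix(rep(c(3, 4, 0), each = n_at), n_at, 3)
  spec <- gaussian_trajectory_spec(
    ref, diag(0.25, 3 * n_at), n_frames = 10000, switch_frame = 5000,
    reference_coords2 = ref + shift, seed = 7)
  tr <- gen_gaussian_trajectory(spec)
  before <- colMeans(tr$coords[1:5000, 1, ])
  after <- colMeans(tr$coords[5001:10000, 1, ])
  se <- 0.5 / sqrt(5000)
  expect_true(all(abs((after - before) - c(3, 4, 0)) < 3 * se))
})

test_that("generators are bit-identical for a fixed seed and leave the RNG stream alone", {
  spec <- gaussian_trajectory_spec(matrix(0, 3, 3), diag(9), n_frames = 50,
                                   seed = 9)
  set.seed(123)
  a <- gen_gaussian_trajectory(spec)
  probe1 <- rnorm(1)
  set.seed(123)
  b <- gen_gaussian_trajectory(spec)
  probe2 <- rnorm(1)
  expect_identical(a$coords, b$coords)
  expect_identical(probe1, probe2)

  dw <- doublewell_spec(2, 4, n_steps = 500, seed = 3)
  expect_identical(gen_langevin_doublewell(dw)$value,
                   gen_langevin_doublewell(dw)$value)

  us <- umbrella_spec(function(x) 0 * x, force_constant = 5,
                      window_centers = c(0, 1.5), n_samples = 100, seed = 4)
  expect_identical(gen_umbrella_samples(us)$windows[[1]]$x,
                   gen_umbrella_samples(us)$windows[[1]]$x)

  rs <- resistor_graph_spec("random", n = 6, seed = 5)
  expect_identical(igraph::as_edgelist(gen_resistor_graph(rs)$graph),
                   igraph::as_edgelist(gen_resistor_graph(rs)$graph))
})

test_that("Langevin walker respects barrier height, symmetry and fixed points", {
  # 10 kT barrier: essentially no crossings in 1e4 steps
  stayed <- vapply(1:20, function(s) {
    x <- gen_langevin_doublewell(
      doublewell_spec(10, 4, diffusion_coeff = 0.1, n_steps = 10000,
                      dt = 0.1, seed = s))$value
    all(x < 0) # left well is centered at -2, barrier top at 0
  }, logical(1))
  expect_gte(sum(stayed), 18)

  # 1 kT barrier: symmetric occupancy within 5 percent
  x <- gen_langevin_doublewell(
    doublewell_spec(1, 4, diffusion_coeff = 0.5, n_steps = 200000,
                    dt = 0.05, seed = 2))$value
  expect_lt(abs(mean(x < 0) - 0.5), 0.05)

  # zero noise from a well minimum stays put
  x0 <- gen_langevin_doublewell(
    doublewell_spec(5, 4, diffusion_coeff = 0, n_steps = 100, seed = 1))$value
  expect_equal(x0, rep(-2, 100), tolerance = 1e-12)

  # an unstable step size is reported as such
  expect_error(
    gen_langevin_doublewell(
      doublewell_spec(20, 2, diffusion_coeff = 5, n_steps = 1000, dt = 50,
                      x0 = 3, seed = 1)),
    class = "allokin_unstable_integration")
})

test_that("umbrella draws match the exact biased densities", {
  kT <- kT_at(300)
  flat <- function(x) 0 * x
  us <- umbrella_spec(flat, force_constant = 10,
                      window_centers = seq(2, 6, 1), n_samples = 10000,
                      kT = kT, seed = 11)
  ds <- gen_umbrella_samples(us)
  for (w in ds$windows) {
    # Gaussian limit: mean at the center, variance kT/k
    se <- sqrt(kT / 10) / sqrt(length(w$x))
    expect_lt(abs(mean(w$x) - w$center), 3 * se)
    expect_lt(abs(var(w$x) / (kT / 10) - 1), 0.05)
    # KS distance against an independently integrated biased CDF
    cdf <- oracle_biased_cdf(flat, 10, w$center, kT,
                             w$center - 3, w$center + 3)
    ks <- suppressWarnings(ks.test(w$x, cdf))$statistic
    expect_lt(ks, 1.63 / sqrt(length(w$x))) # 1 percent critical value
  }
})

test_that("auto-generated window ladders are spaced 1.5 Angstrom apart", {
  us <- umbrella_spec(function(x) 0 * x, force_constant = 5,
                      range = c(2, 14), n_samples = 10, seed = 1)
  expect_equal(unique(diff(us$window_centers)), 1.5)
})

test_that("resistor templates carry their closed-form currents", {
  p <- gen_resistor_graph(resistor_graph_spec("path", n = 3, seed = 1))
  expect_equal(p$currents$current, c(1, 1))

  d <- gen_resistor_graph(resistor_graph_spec("diamond", seed = 1))
  expect_equal(d$currents$current, rep(0.5, 4))

  # random connected graph: generator currents equal an independent
  # nodal solve with a different ground-node convention
  for (s in 1:5) {
    r <- gen_resistor_graph(resistor_graph_spec("random", n = 8,
                                                weights = c(0.5, 1.5),
                                                seed = s))
    ora <- oracle_currents(r$graph, as.integer(r$source),
                           as.integer(r$target))
    expect_lt(max(abs(r$currents$current - ora)), 1e-10)
  }
})

test_that("AR(1) mixing preserves the stationary covariance", {
  n_at <- 5
  Cb <- block_correlation(n_at, list(list(atoms = 1:3, rho = 0.6)))
  spec <- gaussian_trajectory_spec(matrix(0, n_at, 3),
                                   correlation_to_covariance(Cb, 0.4),
                                   n_frames = 50000, ar1 = 0.8, seed = 13)
  Cs <- correlation_matrix(gen_gaussian_trajectory(spec))
  # AR(1) thins the effective sample size by (1+phi)/(1-phi) = 9
  expect_lt(max(abs(Cs - Cb)), 0.06)
})
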