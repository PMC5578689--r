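# Wavelet event detection: residue signals, Morlet CWT, chi-squared
# denoising, density clustering and temporal partitioning.

test_that("residue signal measures displacement from the first frame", {
  # static trajectory: all-zero signal
  arr <- array(1.5, c(5, 4, 3))
  cs <- coord_series(arr, ca_topology(4), dt = 1, fitted = TRUE)
  expect_equal(residue_signal(cs), matrix(0, 4, 5), ignore_attr = TRUE)

  # residue 2 translated by (3,4,0) from frame 3 onward: signal 5
  arr2 <- arr
  arr2[3:5, 2, 1] <- arr2[3:5, 2, 1] + 3
  arr2[3:5, 2, 2] <- arr2[3:5, 2, 2] + 4
  cs2 <- coord_series(arr2, ca_topology(4), dt = 1, fitted = TRUE)
  sig <- residue_signal(cs2)
  expect_equal(sig[2, ], c(0, 0, 5, 5, 5), ignore_attr = TRUE)
  expect_equal(sig[1, ], rep(0, 5), ignore_attr = TRUE)

  # unfitted series warns
  cs3 <- coord_series(arr, ca_topology(4), dt = 1, fitted = FALSE)
  expect_warning(residue_signal(cs3), "fitted")
})

test_that("regime-switch displacement jump sits at the planted frame", {
  n_at <- 5
  ref <- matrix(0, n_at, 3)
  spec <- gaussian_trajectory_spec(
    ref, diag(0.01, 3 * n_at), n_frames = 400, switch_frame = 250,
    reference_coords2 = ref + 3, seed = 8)
  sig <- residue_signal(gen_gaussian_trajectory(spec))
  jump <- which(sig[1, ] > max(sig[1, ]) / 2)[1] - 1 # 0-based
  expect_lte(abs(jump - 250), 1)
})

test_that("Morlet CWT localizes periods and matches a direct convolution oracle", {
  spec <- wavelet_spec(n_scales = 60, min_timescale = 5, max_timescale = 500)
  spec256 <- wavelet_spec(n_scales = 60, min_timescale = 5,
                          max_timescale = 200)

  # zero signal: zero spectrogram
  z <- cwt_morlet(matrix(0, 1, 256), spec256, dt = 1)
  expect_equal(max(z$intensity), 0)

  # sinusoid of period P peaks at the nearest timescale
  for (P in c(25, 50, 100)) {
    x <- sin(2 * pi * (0:1023) / P)
    sp <- cwt_morlet(matrix(x, 1), spec, dt = 1)
    mid <- colMeans(sp$intensity[1, 400:600, ])
    peak <- sp$timescales[which.max(mid)]
    step <- exp(diff(log(range(sp$timescales))) / 59)
    expect_lt(abs(log(peak / P)), 1.05 * log(step))
  }

  # squared-modulus homogeneity: CWT(a s) = a^2 CWT(s)
  set.seed(3)
  x <- rnorm(256)
  s1 <- cwt_morlet(matrix(x, 1), spec256, dt = 1)
  s3 <- cwt_morlet(matrix(3 * x, 1), spec256, dt = 1)
  expect_equal(s3$intensity, 9 * s1$intensity, tolerance = 1e-10)

  # FFT implementation vs direct time-domain integral, interior frames
  # (zero-mean input so the implementation's demeaning is a no-op)
  xs <- rnorm(128)
  xs <- xs - mean(xs)
  for (ts in c(8, 20, 40)) {
    direct <- oracle_cwt_intensity(xs, 1, ts)
    sp <- cwt_morlet(matrix(xs, 1),
                     wavelet_spec(n_scales = 2, min_timescale = ts,
                                  max_timescale = ts * 1.0001), dt = 1)
    # the two routes discretize the same integral differently (frequency
    # vs time sampling of the wavelet), so agreement is to ~1e-4
    expect_equal(sp$intensity[1, 40:90, 1], direct[40:90],
                 tolerance = 1e-3)
  }

  # over-long max timescale is clipped with a warning
  expect_warning(
    cwt_morlet(matrix(rnorm(64), 1),
               wavelet_spec(n_scales = 5, min_timescale = 2,
                            max_timescale = 1000), dt = 1),
    "clipped")
})

test_that("chi-squared thresholding is idempotent with the standard default", {
  expect_equal(wavelet_spec()$chi2_cutoff, 1.6094)
  expect_equal(wavelet_spec()$correction, 1.01)
  expect_equal(wavelet_spec()$n_scales, 60L)

  set.seed(4)
  sig <- matrix(rnorm(3 * 400), 3, 400)
  sig[2, 201:400] <- sig[2, 201:400] + 8 # one loud residue half
  sp <- cwt_morlet(sig, wavelet_spec(n_scales = 20), dt = 1)
  pts <- chi2_threshold(sp)
  expect_gt(nrow(pts), 0)
  twice <- chi2_threshold(pts)
  expect_equal(as.data.frame(twice), as.data.frame(pts))

  # a cutoff above every normalized intensity leaves nothing
  hi <- chi2_threshold(sp, cutoff = 1e12)
  expect_equal(nrow(hi), 0)
})

test_that("density clustering separates blobs, enforces the size floor, and matches a brute-force oracle", {
  set.seed(10)
  blob <- function(cx, cy, n) {
    data.frame(frame = cx + rnorm(n, sd = 3), residue = cy + rnorm(n, sd = 3))
  }
  two <- rbind(blob(0, 0, 500), blob(200, 0, 500)) # separation 10 x eps
  cl <- density_cluster(two, eps = 20, min_pts = 50)
  expect_equal(cl$n_clusters, 2)
  expect_false(any(cl$labels == -1))
  expect_equal(length(unique(cl$labels[1:500])), 1)
  expect_equal(length(unique(cl$labels[501:1000])), 1)

  # fewer points than min_pts: everything is noise
  small <- blob(0, 0, 100)
  expect_true(all(density_cluster(small, eps = 20,
                                  min_pts = 350)$labels == -1))

  # label assignment is invariant under point order permutation
  perm <- sample(nrow(two))
  cl_p <- density_cluster(two[perm, ], eps = 20, min_pts = 50)
  expect_true(same_partition(cl$labels[perm], cl_p$labels))

  # random point sets against the O(n^2) reference implementation
  for (s in 1:5) {
    set.seed(s)
    pts <- data.frame(frame = runif(300, 0, 100),
                      residue = runif(300, 0, 100))
    got <- density_cluster(pts, eps = 8, min_pts = 10)
    ora <- oracle_dbscan(pts$frame, pts$residue, 8, 10)
    core <- ora$core
    expect_true(same_partition(got$labels[core], ora$core_labels[core]))
    for (i in which(!core)) {
      cand <- ora$border_candidates[[i]]
      if (length(cand) == 0) {
        expect_equal(got$labels[i], -1L)
      } else {
        # border point: must be claimed by one of the adjacent clusters
        claimable <- vapply(cand, function(cc) {
          got$labels[which(ora$core_labels == cc)[1]]
        }, integer(1))
        expect_true(got$labels[i] %in% claimable)
      }
    }
  }
})

test_that("temporal partitioning finds planted switches and gates on silhouette", {
  n_res <- 20
  ref <- lattice_coords(4, 5, 1, 4)$coords
  base_cov <- correlation_to_covariance(diag(n_res), sigma = 0.3)
  run_partition <- function(seed, switch_frame = NULL, scale = 3,
                            n_frames = 1000, switch2 = NULL) {
    cov2 <- base_cov * scale^2
    spec <- if (is.null(switch_frame)) {
      gaussian_trajectory_spec(ref, base_cov, n_frames = n_frames, dt = 10,
                               seed = seed)
    } else {
      gaussian_trajectory_spec(ref, base_cov, n_frames = n_frames, dt = 10,
                               switch_frame = switch_frame,
                               covariance2 = cov2, seed = seed)
    }
    tr <- gen_gaussian_trajectory(spec)
    if (!is.null(switch2)) {
      # third regime: quiet again after switch2 (splice two generations)
      spec_b <- gaussian_trajectory_spec(ref, base_cov,
                                         n_frames = n_frames, dt = 10,
                                         seed = seed + 1000)
      tr$coords[(switch2 + 1):n_frames, , ] <-
        gen_gaussian_trajectory(spec_b)$coords[(switch2 + 1):n_frames, , ]
    }
    sp <- cwt_morlet(residue_signal(tr), wavelet_spec(n_scales = 30))
    temporal_partition(sp)
  }

  # stationary input: one frame set
  p0 <- run_partition(31)
  expect_equal(p0$k, 1)
  expect_valid_partition(p0, 1000)

  # one variance switch at frame 600: two frame sets, boundary within 2%
  hits <- vapply(41:43, function(s) {
    p <- run_partition(s, switch_frame = 600)
    expect_valid_partition(p, 1000)
    p$k == 2 && abs(p$intervals$start[2] - 600) <= 20
  }, logical(1))
  expect_true(all(hits))

  # two switches (loud middle segment): three frame sets
  p3 <- run_partition(51, switch_frame = 350, switch2 = 700)
  expect_valid_partition(p3, 1000)
  expect_equal(p3$k, 3)
  expect_lte(abs(p3$intervals$start[2] - 350), 20)
  expect_lte(abs(p3$intervals$start[3] - 700), 20)

  # boundary error does not grow as the switch magnitude grows (up to
  # the embedded-frame stride, which quantizes boundary placement)
  p_ref <- NULL
  errs <- vapply(c(2, 3, 6), function(sc) {
    p <- run_partition(61, switch_frame = 600, scale = sc)
    p_ref <<- p
    if (p$k < 2) return(1000)
    min(abs(p$intervals$start[-1] - 600))
  }, numeric(1))
  expect_true(all(diff(errs) <= p_ref$frame_stride))
})
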