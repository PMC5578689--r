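# Independent oracles used to validate package implementations by a
# different computational route.

# Kabsch superposition RMSD via SVD (independent of bio3d's fitter).
oracle_kabsch_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Qc, Pc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((Qc %*% R - Pc)^2)))
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Dense nodal-analysis currents grounding node 1 (the package grounds the
# last node; different route, same physics).
oracle_currents <- function(graph, s, t) {
  n <- igraph::vcount(graph)
  W <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = FALSE))
  L <- diag(rowSums(W)) - W
  b <- numeric(n)
  b[s] <- 1
  b[t] <- -1
  keep <- 2:n
  v <- numeric(n)
  v[keep] <- solve(L[keep, keep], b[keep])
  el <- igraph::as_edgelist(graph, names = FALSE)
  abs(igraph::E(graph)$weight * (v[el[, 1]] - v[el[, 2]]))
}

# Brute-force O(n^2) DBSCAN reference: core = >= min_pts neighbors within
# eps (self included); clusters = connected components of the core-core
# eps graph; borders belong to any cluster owning a core within eps.
oracle_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  A <- D2 <= eps^2
  counts <- rowSums(A)
  core <- counts >= min_pts
  lab <- rep(-1L, n)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] != -1L) next
    cl <- cl + 1L
    stack <- i
    while (length(stack)) {
      j <- stack[[1]]
      stack <- stack[-1]
      if (lab[j] == -1L) {
        lab[j] <- cl
        nb <- which(A[j, ] & core & lab == -1L)
        stack <- c(stack, nb)
      }
    }
  }
  border_of <- lapply(seq_len(n), function(i) {
    if (core[i]) return(integer())
    unique(lab[core & A[i, ] & lab > 0])
  })
  list(core = core, core_labels = lab, border_candidates = border_of)
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  refines <- function(p, q) {
    all(tapply(q, p, function(v) length(unique(v))) == 1)
  }
  length(a) == length(b) && refines(a, b) && refines(b, a)
}

# Direct time-domain Morlet CWT intensity at one scale (Torrence-Compo
# normalization sqrt(dt/s) psi0*((t'-t)/s)), independent of the FFT path.
oracle_cwt_intensity <- function(x, dt, timescale, omega0 = 6) {
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s <- timescale / ff
  n <- length(x)
  tgrid <- (seq_len(n) - 1) * dt
  vapply(seq_len(n), function(b) {
    arg <- (tgrid - tgrid[b]) / s
    psi <- pi^(-0.25) * exp(1i * omega0 * arg) * exp(-arg^2 / 2)
    Mod(sum(x * sqrt(dt / s) * Conj(psi)))^2
  }, numeric(1))
}

# Analytic biased umbrella CDF by fine-grid trapezoid integration (a
# different grid and quadrature than the generator's inverse-CDF table).
oracle_biased_cdf <- function(U, k, center, kT, lo, hi, n = 200001) {
  g <- seq(lo, hi, length.out = n)
  ld <- -(U(g) + 0.5 * k * (g - center)^2) / kT
  d <- exp(ld - max(ld))
  cdf <- cumsum((d[-1] + d[-n]) / 2)
  cdf <- c(0, cdf / cdf[n - 1])
  function(x) approx(g, cdf, xout = x, yleft = 0, yright = 1)$y
}

# small helpers for partition assertions
expect_valid_partition <- function(part, nf) {
  iv <- part$intervals
  expect_equal(iv$start[1], 0)
  expect_equal(iv$end[nrow(iv)], nf)
  if (nrow(iv) > 1) {
    expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  }
  expect_true(all(iv$end > iv$start))
}

# planted-chain lattice scenario shared by network tests and acceptance
make_chain_scenario <- function(n_frames, seed, sigma = 0.25, rho = 0.9,
                                chain_len = 6) {
  lat <- lattice_coords(4, 4, 4, 4)
  n <- nrow(lat$coords)
  resno <- scattered_resno(n)
  top <- make_topology(rep("CA", n), resno = resno)
  chain_sites <- lat$cross_path[seq_len(chain_len)]
  C <- chain_correlation(n, chain_sites, rho = rho)
  spec <- gaussian_trajectory_spec(
    lat$coords, correlation_to_covariance(C, sigma = sigma),
    n_frames = n_frames, dt = 1, seed = seed, topology = top)
  list(spec = spec, C = C, chain = resno[chain_sites],
       chain_sites = chain_sites, resno = resno)
}

# planted-opening-mode PCA scenario: target group moves along +u, barrier
# group along -u, on top of a small isotropic floor
make_opening_scenario <- function(n_atoms = 40, n_frames = 20000,
                                  amp = 2.0, floor_sd = 0.1, seed = 1) {
  lat <- lattice_coords(5, 4, 2, 6)
  ref <- lat$coords[seq_len(n_atoms), , drop = FALSE]
  target <- 1:4
  barrier <- (n_atoms - 3):n_atoms
  ctr_t <- colMeans(ref[target, ])
  ctr_b <- colMeans(ref[barrier, ])
  u <- (ctr_t - ctr_b) / sqrt(sum((ctr_t - ctr_b)^2))
  v <- numeric(3 * n_atoms)
  for (a in target) v[(3 * (a - 1) + 1):(3 * a)] <- u
  for (a in barrier) v[(3 * (a - 1) + 1):(3 * a)] <- -u
  v <- v / sqrt(sum(v^2))
  covm <- amp^2 * outer(v, v) + diag(floor_sd^2, 3 * n_atoms)
  spec <- gaussian_trajectory_spec(ref, covm, n_frames = n_frames, dt = 1,
                                   seed = seed)
  list(spec = spec, v = v, u = u, target = target, barrier = barrier,
       amp = amp)
}
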