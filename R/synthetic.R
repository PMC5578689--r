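# Synthetic-data generators with known ground truth.
#
# These stand in for the expensive inputs the analyses normally consume:
# multivariate-Gaussian residue fluctuations replace equilibrium MD
# ensembles, an overdamped Langevin walker on a double well emulates the
# reversible making/breaking of a salt-bridge distance, exact Boltzmann
# draws under harmonic biases emulate umbrella-sampling windows, and small
# resistor graphs with analytically known currents exercise the network
# scoring. Every generator is deterministic given its seed and restores
# the caller's RNG stream.

#' Specification for a multivariate-Gaussian trajectory
#'
#' Frames are drawn about `reference_coords` with the prescribed `3N x 3N`
#' covariance (Angstrom^2; coordinate order atom1 x,y,z, atom2 x,y,z, ...).
#' An optional regime switch at `switch_frame` (0-based index of the first
#' frame of the second regime) changes the reference and/or covariance,
#' supplying the nonstationarity that event detection should find. Frames
#' are i.i.d. by default; `ar1` adds AR(1) temporal mixing that preserves
#' the stationary covariance.
#'
#' @param reference_coords `atoms x 3` matrix, Angstrom.
#' @param covariance `3N x 3N` positive semi-definite matrix, Angstrom^2.
#' @param n_frames number of frames.
#' @param dt ps per frame.
#' @param switch_frame optional 0-based frame index where regime 2 starts
#'   (`0 < switch_frame < n_frames`).
#' @param reference_coords2,covariance2 regime-2 reference/covariance;
#'   default to the regime-1 values.
#' @param ar1 AR(1) mixing coefficient in `[0, 1)`; 0 = i.i.d. frames.
#' @param seed integer seed.
#' @param topology optional topology; default one CA per residue.
#' @export
gaussian_trajectory_spec <- function(reference_coords, covariance, n_frames,
                                     dt = 10, switch_frame = NULL,
                                     reference_coords2 = NULL,
                                     covariance2 = NULL, ar1 = 0, seed = 1,
                                     topology = NULL) {
  reference_coords <- as.matrix(reference_coords)
  n_atoms <- nrow(reference_coords)
  if (ncol(reference_coords) != 3) {
    abort_allokin("reference_coords must be atoms x 3",
                  "allokin_invalid_spec")
  }
  if (!is.matrix(covariance) || nrow(covariance) != 3 * n_atoms) {
    abort_allokin("covariance must be (3*atoms) x (3*atoms)",
                  "allokin_invalid_covariance")
  }
  if (!is.null(switch_frame) &&
      (switch_frame <= 0 || switch_frame >= n_frames)) {
    abort_allokin("switch_frame must satisfy 0 < switch_frame < n_frames",
                  "allokin_invalid_spec")
  }
  if (ar1 < 0 || ar1 >= 1) {
    abort_allokin("ar1 must lie in [0, 1)", "allokin_invalid_spec")
  }
  structure(list(reference_coords = reference_coords,
                 covariance = covariance, n_frames = as.integer(n_frames),
                 dt = dt, switch_frame = switch_frame,
                 reference_coords2 = reference_coords2,
                 covariance2 = covariance2, ar1 = ar1, seed = seed,
                 topology = topology),
            class = "gaussian_trajectory_spec")
}

#' Generate a multivariate-Gaussian trajectory
#'
#' @param spec a [gaussian_trajectory_spec()].
#' @return a [coord_series()] (already in a common frame of reference, so
#'   `fitted = TRUE`).
#' @export
gen_gaussian_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gaussian_trajectory_spec"))
  n_at <- nrow(spec$reference_coords)
  d <- 3 * n_at
  R1 <- psd_sqrt(spec$covariance)
  with_local_seed(spec$seed, {
    Z <- matrix(stats::rnorm(spec$n_frames * d), spec$n_frames, d)
    if (spec$ar1 > 0) {
      phi <- spec$ar1
      sc <- sqrt(1 - phi^2)
      for (f in 2:spec$n_frames) {
        Z[f, ] <- phi * Z[f - 1, ] + sc * Z[f, ]
      }
    }
    Z
  }) -> Z
  # row-major reference offsets: covariance index (3(a-1)+k) is atom a coord k
  ref_row <- function(rc) as.vector(t(rc))
  split_at <- spec$switch_frame
  X <- matrix(0, spec$n_frames, d)
  if (is.null(split_at)) {
    X <- Z %*% R1
    X <- sweep(X, 2, ref_row(spec$reference_coords), "+")
  } else {
    R2 <- psd_sqrt(spec$covariance2 %||% spec$covariance)
    ref2 <- spec$reference_coords2 %||% spec$reference_coords
    i1 <- seq_len(split_at)               # frames 0 .. switch_frame-1
    i2 <- seq(split_at + 1, spec$n_frames)
    X[i1, ] <- sweep(Z[i1, , drop = FALSE] %*% R1, 2,
                     ref_row(spec$reference_coords), "+")
    X[i2, ] <- sweep(Z[i2, , drop = FALSE] %*% R2, 2, ref_row(ref2), "+")
  }
  top <- spec$topology %||% ca_topology(n_at)
  arr <- array(0, c(spec$n_frames, n_at, 3))
  for (k in 1:3) arr[, , k] <- X[, seq(k, d, 3)]
  coord_series(arr, top, dt = spec$dt, fitted = TRUE,
               provenance = sprintf("gen_gaussian_trajectory(seed=%s)",
                                    format(spec$seed)))
}

#' Build a 3N x 3N covariance from a residue correlation matrix
#'
#' Applies the same correlation to each Cartesian component (Kronecker
#' product with the 3x3 identity), so the displacement-vector correlation
#' between atoms i and j equals `C[i, j]` exactly.
#'
#' @param C `n x n` correlation matrix.
#' @param sigma per-coordinate fluctuation SD in Angstrom (scalar or
#'   per-atom vector).
#' @export
correlation_to_covariance <- function(C, sigma = 1) {
  n <- nrow(C)
  s <- rep_len(sigma, n)
  S <- outer(s, s) * C
  kronecker(S, diag(3))
}

#' Block/chain correlation matrix builders
#'
#' `block_correlation(n, blocks)` sets pairwise correlation `rho` inside
#' each block (a list of `list(atoms =, rho =)`); `chain_correlation(n,
#' path, rho)` sets `rho^|a-b|` between path members at path positions a,
#' b (an AR-style, always-PSD chain of high nearest-neighbor correlation).
#'
#' @param n number of atoms/residues.
#' @param blocks list of `list(atoms = indices, rho = value)`.
#' @export
block_correlation <- function(n, blocks = list()) {
  C <- diag(n)
  for (b in blocks) {
    idx <- b$atoms
    C[idx, idx] <- b$rho
  }
  diag(C) <- 1
  C
}

#' @rdname block_correlation
#' @param path ordered atom indices forming the correlated chain.
#' @param rho nearest-neighbor correlation along the chain.
#' @export
chain_correlation <- function(n, path, rho = 0.9) {
  C <- diag(n)
  pos <- seq_along(path)
  C[path, path] <- rho^abs(outer(pos, pos, "-"))
  diag(C) <- 1
  C
}

# -------------------------------------------------------------- double well

#' Specification for overdamped Langevin dynamics on a double well
#'
#' The potential is `U(x) = A ((x - c)^2 / w^2 - 1)^2` with `A =
#' barrier_height * kT` and minima at `c - w` and `c + w`
#' (`w = well_separation / 2`), emulating a distance coordinate that
#' reversibly hops between a formed and a broken state.
#'
#' @param barrier_height barrier in units of kT.
#' @param well_separation distance between the two minima, Angstrom.
#' @param diffusion_coeff diffusion coefficient, Angstrom^2/ps.
#' @param kT thermal energy, kcal/mol (default 300 K).
#' @param n_steps,dt number of steps and step size in ps.
#' @param center well midpoint `c`, Angstrom.
#' @param x0 starting point; default the left minimum.
#' @param seed integer seed.
#' @export
doublewell_spec <- function(barrier_height, well_separation,
                            diffusion_coeff = 0.1, kT = kT_at(300),
                            n_steps = 10000, dt = 0.1, center = 0,
                            x0 = NULL, seed = 1) {
  if (barrier_height <= 0 || well_separation <= 0) {
    abort_allokin("barrier_height and well_separation must be positive",
                  "allokin_invalid_spec")
  }
  structure(list(barrier_height = barrier_height,
                 well_separation = well_separation,
                 diffusion_coeff = diffusion_coeff, kT = kT,
                 n_steps = as.integer(n_steps), dt = dt, center = center,
                 x0 = x0, seed = seed),
            class = "doublewell_spec")
}

#' Double-well potential function for a spec
#'
#' @param spec a [doublewell_spec()].
#' @return function of x returning energy in kcal/mol.
#' @export
doublewell_potential <- function(spec) {
  A <- spec$barrier_height * spec$kT
  w <- spec$well_separation / 2
  ctr <- spec$center
  function(x) A * ((x - ctr)^2 / w^2 - 1)^2
}

#' Generate an overdamped Langevin path on the double well
#'
#' Euler-Maruyama integration of `dx = -(D/kT) U'(x) dt + sqrt(2 D dt) xi`.
#'
#' @param spec a [doublewell_spec()].
#' @return a [scalar_series()] of `n_steps` positions.
#' @export
gen_langevin_doublewell <- function(spec) {
  stopifnot(inherits(spec, "doublewell_spec"))
  A <- spec$barrier_height * spec$kT
  w <- spec$well_separation / 2
  D <- spec$diffusion_coeff
  kT <- spec$kT
  dt <- spec$dt
  ctr <- spec$center
  x <- spec$x0 %||% (ctr - w)
  noise_sd <- sqrt(2 * D * dt)
  mob <- D / kT
  out <- numeric(spec$n_steps)
  with_local_seed(spec$seed, {
    eta <- stats::rnorm(spec$n_steps, sd = noise_sd)
    for (i in seq_len(spec$n_steps)) {
      u <- x - ctr
      grad <- 4 * A * u * (u^2 / w^2 - 1) / w^2
      x <- x - mob * grad * dt + eta[i]
      if (!is.finite(x) || abs(x - ctr) > 50 * w) {
        abort_allokin(sprintf(
          "Langevin integration diverged (|x| blew up): step size dt = %g is too large",
          dt), "allokin_unstable_integration")
      }
      out[i] <- x
    }
  })
  scalar_series(out, dt = dt, label = "double-well x [A]")
}

# ---------------------------------------------------------------- umbrella

#' Specification for exact umbrella-sampling draws
#'
#' Each window draws i.i.d. samples from the exact biased Boltzmann
#' density `exp(-(U(x) + k/2 (x - x0)^2) / kT)` by inverse-CDF sampling on
#' a fine grid. Window centers default to a ladder spaced `window_width`
#' apart (1.5 Angstrom, the conventional umbrella window width for a
#' salt-bridge separation coordinate).
#'
#' @param true_pmf the underlying potential: a function of x (kcal/mol) or
#'   a two-column table `(x, U)` to interpolate.
#' @param force_constant harmonic bias force constant, kcal/mol/Angstrom^2.
#'   Required: there is no universal convention to default to.
#' @param window_centers restraint centers, Angstrom (strictly increasing).
#'   When `NULL`, generated as `seq(range[1], range[2], by = window_width)`.
#' @param window_width ladder spacing used when auto-generating centers.
#' @param range reaction-coordinate range for auto-generated centers.
#' @param n_samples draws per window.
#' @param kT thermal energy, kcal/mol.
#' @param dt ps between successive samples (timestamps only).
#' @param n_grid grid resolution for the inverse CDF.
#' @param seed integer seed.
#' @export
umbrella_spec <- function(true_pmf, force_constant, window_centers = NULL,
                          window_width = 1.5, range = c(0, 10),
                          n_samples = 10000, kT = kT_at(300), dt = 1,
                          n_grid = 8192, seed = 1) {
  if (force_constant <= 0) {
    abort_allokin("force_constant must be positive", "allokin_invalid_spec")
  }
  if (is.null(window_centers)) {
    window_centers <- seq(range[1], range[2], by = window_width)
  }
  if (any(diff(window_centers) <= 0)) {
    abort_allokin("window_centers must be strictly increasing",
                  "allokin_invalid_spec")
  }
  ufun <- if (is.function(true_pmf)) {
    true_pmf
  } else {
    tab <- as.data.frame(true_pmf)
    stats::approxfun(tab[[1]], tab[[2]], rule = 2)
  }
  structure(list(true_pmf = ufun, force_constant = force_constant,
                 window_centers = window_centers,
                 window_width = window_width, n_samples = as.integer(n_samples),
                 kT = kT, dt = dt, n_grid = n_grid, seed = seed),
            class = "umbrella_spec")
}

#' Generate exact biased samples for every umbrella window
#'
#' @param spec an [umbrella_spec()].
#' @return an [umbrella_dataset()].
#' @export
gen_umbrella_samples <- function(spec) {
  stopifnot(inherits(spec, "umbrella_spec"))
  k <- spec$force_constant
  kT <- spec$kT
  pad <- 6 * sqrt(kT / k)
  lo <- min(spec$window_centers) - pad
  hi <- max(spec$window_centers) + pad
  grid <- seq(lo, hi, length.out = spec$n_grid)
  U <- spec$true_pmf(grid)
  windows <- vector("list", length(spec$window_centers))
  with_local_seed(spec$seed, {
    for (i in seq_along(spec$window_centers)) {
      x0 <- spec$window_centers[i]
      logdens <- -(U + 0.5 * k * (grid - x0)^2) / kT
      if (!any(is.finite(logdens))) {
        abort_allokin("biased density is numerically zero everywhere on grid",
                      "allokin_degenerate_density")
      }
      dens <- exp(logdens - max(logdens, na.rm = TRUE))
      dens[!is.finite(dens)] <- 0
      cdf <- cumsum(dens)
      if (cdf[length(cdf)] <= 0) {
        abort_allokin("biased density is numerically zero everywhere on grid",
                      "allokin_degenerate_density")
      }
      cdf <- cdf / cdf[length(cdf)]
      u <- stats::runif(spec$n_samples)
      # invert the empirical grid CDF (monotone; strip flat duplicates)
      keep <- c(TRUE, diff(cdf) > 0)
      x <- stats::approx(cdf[keep], grid[keep], xout = u,
                         yleft = grid[1], yright = grid[length(grid)])$y
      windows[[i]] <- umbrella_window(
        time = (seq_len(spec$n_samples) - 1) * spec$dt, x = x,
        center = x0, force_constant = k)
    }
  })
  umbrella_dataset(windows, kT = kT, label = "synthetic reaction coordinate")
}

#' Rectangular-lattice residue geometry
#'
#' Places one site per residue on an `nx x ny x nz` grid with the given
#' spacing. With 4 Angstrom spacing, axis neighbors sit inside a typical
#' 4.5 Angstrom heavy-atom contact cutoff while diagonal neighbors
#' (5.66 Angstrom) stay outside, giving a clean, known contact graph.
#' The returned `path` walks the lattice in snake order, so consecutive
#' path entries are always geometric neighbors.
#'
#' Because sites are numbered along x first, consecutive `path` entries
#' are mostly sequence-adjacent residues; `cross_path` instead walks the
#' (y, z) plane at x = 1, so its steps connect residues far apart in
#' sequence — the right template for planting a tertiary-contact
#' transmission chain (sequence-adjacent contacts are conventionally
#' excluded from residue networks).
#'
#' @param nx,ny,nz grid dimensions.
#' @param spacing lattice constant, Angstrom.
#' @return list `coords` (`n x 3`), `path` (snake walk over all sites)
#'   and `cross_path` (snake walk over the x = 1 face).
#' @export
lattice_coords <- function(nx, ny, nz, spacing = 4) {
  coords <- matrix(0, nx * ny * nz, 3)
  path <- integer(nx * ny * nz)
  i <- 0L
  p <- 0L
  idx <- array(0L, c(nx, ny, nz))
  for (z in seq_len(nz)) {
    for (y in seq_len(ny)) {
      for (x in seq_len(nx)) {
        i <- i + 1L
        coords[i, ] <- spacing * c(x - 1, y - 1, z - 1)
        idx[x, y, z] <- i
      }
    }
  }
  row_count <- 0L
  for (z in seq_len(nz)) {
    ys <- if (z %% 2 == 1) seq_len(ny) else rev(seq_len(ny))
    for (y in ys) {
      row_count <- row_count + 1L
      xs <- if (row_count %% 2 == 1) seq_len(nx) else rev(seq_len(nx))
      for (x in xs) {
        p <- p + 1L
        path[p] <- idx[x, y, z]
      }
    }
  }
  cross <- integer(ny * nz)
  p <- 0L
  for (z in seq_len(nz)) {
    ys <- if (z %% 2 == 1) seq_len(ny) else rev(seq_len(ny))
    for (y in ys) {
      p <- p + 1L
      cross[p] <- idx[1, y, z]
    }
  }
  list(coords = coords, path = path, cross_path = cross)
}

#' Sequence-scrambled residue numbering for lattice models
#'
#' Folded protein domains double back on themselves, so spatial
#' neighbors are typically far apart in sequence. Numbering lattice
#' sites consecutively would make every x-step a sequence-adjacent pair
#' — exactly the contacts residue-network conventions exclude — so this
#' assigns residue numbers by a modular stride coprime to `n`, keeping
#' lattice neighbors non-adjacent in sequence.
#'
#' @param n number of sites.
#' @return integer residue numbers, a permutation of `1:n`.
#' @export
scattered_resno <- function(n) {
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  s <- max(2L, as.integer(ceiling(sqrt(n))))
  while (gcd2(s, n) != 1) s <- s + 1L
  as.integer(((seq_len(n) - 1L) * s) %% n + 1L)
}

# ------------------------------------------------------------ resistor graphs

#' Specification for a small resistor-network graph
#'
#' Templates: `"path"` (a series chain), `"diamond"` (two equal two-edge
#' parallel branches), `"ladder"` (a 2 x m grid), `"random"` (connected
#' Erdos-Renyi draw). Each comes with a canonical source/target pair and
#' exact unit-current edge flows computed by nodal analysis.
#'
#' @param template one of `"path"`, `"diamond"`, `"ladder"`, `"random"`.
#' @param n number of nodes (path/random) or rungs (ladder).
#' @param weights `"unit"` or a length-2 range for uniform random
#'   conductances.
#' @param p_edge edge probability for `"random"`.
#' @param max_retries connected-graph resampling attempts for `"random"`.
#' @param seed integer seed.
#' @export
resistor_graph_spec <- function(template = c("path", "diamond", "ladder",
                                             "random"),
                                n = 8, weights = "unit", p_edge = 0.4,
                                max_retries = 50, seed = 1) {
  template <- match.arg(template)
  structure(list(template = template, n = as.integer(n), weights = weights,
                 p_edge = p_edge, max_retries = max_retries, seed = seed),
            class = "resistor_graph_spec")
}

edge_weights_for <- function(spec, n_edges) {
  if (identical(spec$weights, "unit")) {
    rep(1, n_edges)
  } else {
    stats::runif(n_edges, spec$weights[1], spec$weights[2])
  }
}

#' Exact edge currents by nodal analysis (Kirchhoff solve)
#'
#' Injects +1 unit of current at `source` and removes it at `target`,
#' grounds one node, solves the reduced Kirchhoff system with a dense
#' `solve()`, and reports each edge's |current| = conductance x potential
#' difference. This is deliberately a different computational route from
#' the Laplacian-pseudoinverse betweenness scoring, so the two can check
#' each other.
#'
#' @param graph an igraph with edge attribute `weight` (conductance).
#' @param source,target node names or indices.
#' @return data.frame `(from, to, current)` in `igraph::E()` order.
#' @export
kirchhoff_edge_currents <- function(graph, source, target) {
  n <- igraph::vcount(graph)
  W <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = FALSE))
  L <- diag(rowSums(W)) - W
  s <- as.integer(igraph::V(graph)[source])
  t <- as.integer(igraph::V(graph)[target])
  b <- numeric(n)
  b[s] <- 1
  b[t] <- -1
  g <- n # ground the last node
  keep <- setdiff(seq_len(n), g)
  v <- numeric(n)
  v[keep] <- solve(L[keep, keep], b[keep])
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  cur <- abs(w * (v[el[, 1]] - v[el[, 2]]))
  nm <- igraph::vertex_attr(graph, "name") %||% as.character(seq_len(n))
  data.frame(from = nm[el[, 1]], to = nm[el[, 2]], current = cur,
             stringsAsFactors = FALSE)
}

#' Generate a resistor-network graph with known edge currents
#'
#' @param spec a [resistor_graph_spec()].
#' @return list with `graph` (igraph, `weight` = conductance), `source`,
#'   `target`, and `currents` (data.frame from, to, current for one unit
#'   of current driven source -> target).
#' @export
gen_resistor_graph <- function(spec) {
  stopifnot(inherits(spec, "resistor_graph_spec"))
  with_local_seed(spec$seed, {
    if (spec$template == "path") {
      el <- cbind(seq_len(spec$n - 1), seq(2, spec$n))
      g <- igraph::graph_from_edgelist(el, directed = FALSE)
      igraph::E(g)$weight <- edge_weights_for(spec, nrow(el))
      src <- 1; tgt <- spec$n
      # a single series path carries the full unit current on every edge
      analytic <- data.frame(from = as.character(el[, 1]),
                             to = as.character(el[, 2]),
                             current = 1, stringsAsFactors = FALSE)
    } else if (spec$template == "diamond") {
      el <- cbind(c(1, 2, 1, 3), c(2, 4, 3, 4))
      g <- igraph::graph_from_edgelist(el, directed = FALSE)
      w <- if (identical(spec$weights, "unit")) 1 else
        stats::runif(1, spec$weights[1], spec$weights[2])
      igraph::E(g)$weight <- rep(w, 4)
      src <- 1; tgt <- 4
      # two identical branches split the unit current evenly
      analytic <- data.frame(from = as.character(el[, 1]),
                             to = as.character(el[, 2]),
                             current = 0.5, stringsAsFactors = FALSE)
    } else if (spec$template == "ladder") {
      m <- spec$n
      id <- function(row, col) (col - 1) * 2 + row
      el <- NULL
      for (col in seq_len(m)) el <- rbind(el, c(id(1, col), id(2, col)))
      for (col in seq_len(m - 1)) {
        el <- rbind(el, c(id(1, col), id(1, col + 1)),
                    c(id(2, col), id(2, col + 1)))
      }
      g <- igraph::graph_from_edgelist(el, directed = FALSE)
      igraph::E(g)$weight <- edge_weights_for(spec, nrow(el))
      src <- id(1, 1); tgt <- id(2, m)
      analytic <- NULL
    } else { # random
      g <- NULL
      for (try in seq_len(spec$max_retries)) {
        cand <- igraph::sample_gnp(spec$n, spec$p_edge)
        if (igraph::ecount(cand) > 0 && igraph::is_connected(cand)) {
          g <- cand
          break
        }
      }
      if (is.null(g)) {
        abort_allokin(sprintf(
          "no connected random graph after %d retries (raise p_edge)",
          spec$max_retries), "allokin_disconnected_graph")
      }
      igraph::E(g)$weight <- edge_weights_for(spec, igraph::ecount(g))
      src <- 1; tgt <- spec$n
      analytic <- NULL
    }
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    if (is.null(analytic)) {
      analytic <- kirchhoff_edge_currents(g, src, tgt)
    }
    list(graph = g, source = as.character(src), target = as.character(tgt),
         currents = analytic)
  })
}
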