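# End-to-end synthetic demonstration pipeline: configuration, staged
# execution with machine-readable manifests, and a summary report. The
# stages mirror an analysis a practitioner would run on real kinase
# trajectories, but on generated data with known ground truth.
#
# Stages: simulate -> distances -> wavelet -> pca -> network -> wham ->
# report. Each writes its artifacts plus a manifest (inputs, parameters,
# package version, seed) under <outdir>/<stage>/. All randomness flows
# from the single top-level seed, expanded with a fixed per-stage offset,
# so reruns are byte-identical.

#' Default pipeline configuration
#'
#' Returns the full nested parameter list; [load_config()] merges a YAML
#' file and overrides on top of it (precedence: overrides > file >
#' defaults).
#'
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "allokin_run",
    log_level = "INFO",
    simulate = list(
      lattice = list(nx = 3, ny = 3, nz = 4, spacing = 4.0),
      fluct_sigma = 0.25,
      chain = list(length = 5, rho = 0.9),
      switch_frame = 1200, switch_scale = 3.0,
      n_frames = 2000, dt = 10,
      doublewell = list(barrier_kt = 2.0, well_separation = 4.0,
                        center = 6.0, diffusion = 0.1,
                        n_steps = 200000, dt = 0.1, save_stride = 10),
      umbrella = list(barrier_kcal = 3.0, well_separation = 4.0,
                      center = 6.0, force_constant = 10.0,
                      n_samples = 10000, dt = 2.0)
    ),
    distances = list(threshold = 5.0),
    wavelet = list(n_scales = 40, chi2_cutoff = 1.6094, correction = 1.01,
                   eps = 20.0, min_pts = 350, k_max = 6,
                   min_silhouette = 0.25),
    pca = list(n_components = 15),
    network = list(cutoff = 4.5, occupancy = 0.75, frame_stride = 1,
                   tolerance = 0.20),
    wham = list(n_bins = 100, tol = 1e-6, max_iter = 1e5,
                start_time = 2000, block_ps = 2000)
  )
}

#' Load pipeline configuration
#'
#' @param path optional YAML file.
#' @param overrides optional named list applied last.
#' @return the merged configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_allokin(paste("config file not found:", path), "allokin_io_error")
    }
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

log_msg <- function(cfg, level, ...) {
  lv <- c(DEBUG = 0, INFO = 1, WARNING = 2)
  if (lv[[level]] >= lv[[cfg$log_level %||% "INFO"]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$outdir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_manifest <- function(cfg, stage, params, inputs, outputs) {
  man <- list(stage = stage,
              package = "allokin",
              version = as.character(utils::packageVersion("allokin")),
              seed = cfg$seed, params = params,
              inputs = inputs, outputs = outputs)
  jsonlite::write_json(man, file.path(cfg$outdir, stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

stage_seed <- function(cfg, offset) as.integer(cfg$seed) * 100L + offset

# -------------------------------------------------------------------- stages

stage_simulate <- function(cfg) {
  d <- stage_dir(cfg, "simulate")
  sc <- cfg$simulate
  lat <- lattice_coords(sc$lattice$nx, sc$lattice$ny, sc$lattice$nz,
                        sc$lattice$spacing)
  n_res <- nrow(lat$coords)
  chain_sites <- lat$cross_path[seq_len(sc$chain$length)]
  resno <- scattered_resno(n_res)
  top <- make_topology(rep("CA", n_res), resno = resno)
  chain <- resno[chain_sites]
  C <- chain_correlation(n_res, chain_sites, rho = sc$chain$rho)
  cov1 <- correlation_to_covariance(C, sigma = sc$fluct_sigma)
  spec <- gaussian_trajectory_spec(
    lat$coords, cov1, n_frames = sc$n_frames, dt = sc$dt,
    switch_frame = sc$switch_frame,
    covariance2 = cov1 * sc$switch_scale^2,
    seed = stage_seed(cfg, 1L), topology = top)
  traj <- gen_gaussian_trajectory(spec)
  write_trajectory(traj, file.path(d, "traj.pdb"), file.path(d, "traj.dcd"))

  dw <- sc$doublewell
  dspec <- doublewell_spec(dw$barrier_kt, dw$well_separation,
                           diffusion_coeff = dw$diffusion,
                           n_steps = dw$n_steps, dt = dw$dt,
                           center = dw$center, seed = stage_seed(cfg, 2L))
  path_x <- gen_langevin_doublewell(dspec)
  # embed the 1D coordinate as a donor/acceptor atom pair so the distance
  # stage exercises real trajectory machinery (ASP CG fixed at the origin,
  # ARG CZ at (x, 0, 0)); frames stored every save_stride steps
  stride <- dw$save_stride %||% 1
  xkeep <- path_x$value[seq(1, length(path_x$value), by = stride)]
  sb_top <- make_topology(c("CG", "CZ"), resno = c(354, 375),
                          resname = c("ASP", "ARG"))
  sb_coords <- array(0, c(length(xkeep), 2, 3))
  sb_coords[, 2, 1] <- xkeep
  sb <- coord_series(sb_coords, sb_top, dt = dw$dt * stride, fitted = TRUE,
                     provenance = "double-well salt-bridge emulation")
  write_trajectory(sb, file.path(d, "saltbridge.pdb"),
                   file.path(d, "saltbridge.dcd"))

  um <- sc$umbrella
  udw <- doublewell_spec(um$barrier_kcal / kT_at(300), um$well_separation,
                         center = um$center, seed = 1)
  uspec <- umbrella_spec(doublewell_potential(udw),
                         force_constant = um$force_constant,
                         window_centers = seq(um$center - um$well_separation,
                                              um$center + um$well_separation,
                                              length.out = 13),
                         n_samples = um$n_samples, dt = um$dt,
                         seed = stage_seed(cfg, 3L))
  uds <- gen_umbrella_samples(uspec)
  write_umbrella_dataset(uds, file.path(d, "umbrella"))

  truth <- list(chain_residues = chain, switch_frame = sc$switch_frame,
                switch_scale = sc$switch_scale,
                doublewell = dw, umbrella_barrier = um$barrier_kcal)
  jsonlite::write_json(truth, file.path(d, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "simulate", sc, inputs = list(),
                 outputs = list("traj.pdb", "traj.dcd", "saltbridge.pdb",
                                "saltbridge.dcd", "umbrella/metadata.dat",
                                "ground_truth.json"))
  log_msg(cfg, "INFO", "simulate: wrote synthetic trajectory (", n_res,
          " residues, ", sc$n_frames, " frames), salt-bridge walk and ",
          length(uds$windows), " umbrella windows")
  invisible(d)
}

stage_distances <- function(cfg) {
  d <- stage_dir(cfg, "distances")
  sim <- file.path(cfg$outdir, "simulate")
  dw <- cfg$simulate$doublewell
  sb <- read_trajectory(file.path(sim, "saltbridge.pdb"),
                        file.path(sim, "saltbridge.dcd"),
                        dt = dw$dt * (dw$save_stride %||% 1))
  ds <- distance_series(sb, select_atoms(sb, resno = 375, name = "CZ"),
                        select_atoms(sb, resno = 354, name = "CG"),
                        mode = "atom", label = "R-D distance [A]")
  write_scalar_csv(ds, file.path(d, "saltbridge_distance.csv"))
  states <- salt_bridge_states(ds, cfg$distances$threshold)
  frac <- mean(states == "formed")
  jsonlite::write_json(
    list(threshold = cfg$distances$threshold, fraction_formed = frac,
         n_frames = length(states)),
    file.path(d, "saltbridge_summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "distances", cfg$distances,
                 inputs = list("simulate/saltbridge.dcd"),
                 outputs = list("saltbridge_distance.csv",
                                "saltbridge_summary.json"))
  log_msg(cfg, "INFO", sprintf(
    "distances: fraction of frames with formed salt bridge = %.3f", frac))
  invisible(d)
}

stage_wavelet <- function(cfg) {
  d <- stage_dir(cfg, "wavelet")
  sim <- file.path(cfg$outdir, "simulate")
  traj <- read_trajectory(file.path(sim, "traj.pdb"),
                          file.path(sim, "traj.dcd"),
                          dt = cfg$simulate$dt)
  traj <- rms_fit(traj)
  sig <- residue_signal(traj)
  wc <- cfg$wavelet
  spect <- cwt_morlet(sig, wavelet_spec(n_scales = wc$n_scales,
                                        correction = wc$correction,
                                        chi2_cutoff = wc$chi2_cutoff))
  pts <- chi2_threshold(spect)
  labs <- density_cluster(pts, eps = wc$eps, min_pts = wc$min_pts)
  pts$label <- labs$labels
  utils::write.csv(pts, file.path(d, "wavelet_points.csv"),
                   row.names = FALSE, quote = FALSE)
  part <- temporal_partition(spect, k_max = wc$k_max,
                             min_silhouette = wc$min_silhouette)
  jsonlite::write_json(
    list(intervals = part$intervals, k = part$k,
         silhouette = part$silhouette, frame_stride = part$frame_stride),
    file.path(d, "partition.json"), digits = NA)
  write_manifest(cfg, "wavelet", wc, inputs = list("simulate/traj.dcd"),
                 outputs = list("wavelet_points.csv", "partition.json"))
  log_msg(cfg, "INFO", "wavelet: ", nrow(pts), " points above threshold, ",
          labs$n_clusters, " clusters, k = ", part$k, " frame sets")
  invisible(d)
}

stage_pca <- function(cfg) {
  d <- stage_dir(cfg, "pca")
  sim <- file.path(cfg$outdir, "simulate")
  traj <- read_trajectory(file.path(sim, "traj.pdb"),
                          file.path(sim, "traj.dcd"),
                          dt = cfg$simulate$dt)
  part_path <- file.path(cfg$outdir, "wavelet", "partition.json")
  interval <- NULL
  if (file.exists(part_path)) {
    part <- jsonlite::read_json(part_path, simplifyVector = TRUE)
    iv <- part$intervals
    interval <- c(iv$start[nrow(iv)], iv$end[nrow(iv)]) # last frame set
  }
  traj <- rms_fit(traj)
  pca <- covariance_pca(traj, frame_interval = interval)
  m <- min(cfg$pca$n_components, length(pca$values))
  eig <- data.frame(component = seq_along(pca$values),
                    eigenvalue = pca$values,
                    cumulative = cumsum(pca$values) / sum(pca$values))
  utils::write.csv(eig, file.path(d, "eigenvalues.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- jsonlite::read_json(file.path(sim, "ground_truth.json"),
                               simplifyVector = TRUE)
  chain <- truth$chain_residues
  target <- match(chain[1], pca$resno)
  barrier <- match(chain[length(chain)], pca$resno)
  sepr <- separation_metric(pca, target, barrier, components = seq_len(m))
  utils::write.csv(sepr, file.path(d, "separation.csv"),
                   row.names = FALSE, quote = FALSE)
  write_nmd(pca, file.path(d, "modes.nmd"), n_modes = m)
  write_manifest(cfg, "pca",
                 c(cfg$pca, list(frame_interval = interval)),
                 inputs = list("simulate/traj.dcd", "wavelet/partition.json"),
                 outputs = list("eigenvalues.csv", "separation.csv",
                                "modes.nmd"))
  log_msg(cfg, "INFO", sprintf(
    "pca: top component explains %.1f%% of variance",
    100 * cumulative_covariance(pca, 1)))
  invisible(d)
}

stage_network <- function(cfg) {
  d <- stage_dir(cfg, "network")
  sim <- file.path(cfg$outdir, "simulate")
  traj <- read_trajectory(file.path(sim, "traj.pdb"),
                          file.path(sim, "traj.dcd"),
                          dt = cfg$simulate$dt)
  nc <- cfg$network
  C <- correlation_matrix(traj)
  cm <- contact_map(traj, cutoff = nc$cutoff, occupancy = nc$occupancy,
                    frame_stride = nc$frame_stride)
  g <- build_graph(C, cm)
  truth <- jsonlite::read_json(file.path(sim, "ground_truth.json"),
                               simplifyVector = TRUE)
  chain <- as.character(truth$chain_residues)
  scores <- current_flow_betweenness(g, S = chain[1],
                                     T = chain[length(chain)])
  sub <- extract_subnetwork(g, scores, tolerance = nc$tolerance)
  write_network_csv(scores, file.path(d, "edges.csv"), subnetwork = sub,
                    graphml_path = file.path(d, "network.graphml"))
  # residue -> coordinate map for 3D rendering of node scores
  ca <- select_atoms(traj, name = "CA")
  map <- data.frame(resno = traj$topology$resno[ca],
                    x = traj$coords[1, ca, 1], y = traj$coords[1, ca, 2],
                    z = traj$coords[1, ca, 3])
  utils::write.csv(map, file.path(d, "residue_coords.csv"),
                   row.names = FALSE, quote = FALSE)
  write_manifest(cfg, "network", nc, inputs = list("simulate/traj.dcd"),
                 outputs = list("edges.csv", "network.graphml",
                                "residue_coords.csv"))
  log_msg(cfg, "INFO", "network: ", nrow(scores$edges), " edges, ",
          sum(sub$edges$in_subnetwork), " in the suboptimal sub-network")
  invisible(d)
}

stage_wham <- function(cfg) {
  d <- stage_dir(cfg, "wham")
  sim <- file.path(cfg$outdir, "simulate")
  uds <- read_umbrella_dataset(file.path(sim, "umbrella", "metadata.dat"))
  wc <- cfg$wham
  prof <- wham_solve(uds, n_bins = wc$n_bins, tol = wc$tol,
                     max_iter = wc$max_iter)
  write_pmf_csv(prof, file.path(d, "pmf.csv"))
  cum <- cumulative_pmfs(uds, start_time = wc$start_time,
                         block_ps = wc$block_ps, n_bins = wc$n_bins,
                         tol = wc$tol, max_iter = wc$max_iter)
  for (i in seq_along(cum$profiles)) {
    write_pmf_csv(cum$profiles[[i]],
                  file.path(d, sprintf("pmf_cumulative_%02d.csv", i)))
  }
  ov <- window_overlap_report(uds, n_bins = wc$n_bins)
  utils::write.csv(ov, file.path(d, "window_overlap.csv"),
                   row.names = FALSE, quote = FALSE)
  bar <- pmf_barrier(prof)
  jsonlite::write_json(
    list(barrier_kcal = bar$barrier, well_positions = bar$wells,
         converged = cum$converged, max_abs_diff = cum$max_abs_diff),
    file.path(d, "wham_summary.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "wham", wc,
                 inputs = list("simulate/umbrella/metadata.dat"),
                 outputs = list("pmf.csv", "window_overlap.csv",
                                "wham_summary.json"))
  log_msg(cfg, "INFO", sprintf(
    "wham: barrier %.2f kcal/mol; cumulative convergence: %s",
    bar$barrier, cum$converged))
  invisible(d)
}

#' Barrier height of a (double-well) PMF profile
#'
#' Pairs the global minimum with the local minimum of greatest mutual
#' prominence: among all other local minima, the one maximizing
#' `saddle - max(W_well, W_global)` where the saddle is the highest free
#' energy between the two. Choosing by prominence rather than by depth
#' alone keeps bin-count noise near the well bottoms from masquerading
#' as a second well. The barrier is reported relative to the global
#' minimum (zero under the min-shift gauge).
#'
#' @param profile a `pmf_profile`.
#' @return list `barrier` (kcal/mol) and `wells` (bin-center positions).
#' @export
pmf_barrier <- function(profile) {
  ok <- which(profile$occupied)
  W <- profile$free_energy[ok]
  x <- profile$bin_center[ok]
  n <- length(W)
  if (n < 3) abort_allokin("profile too short", "allokin_invalid_spec")
  is_min <- c(W[1] < W[2],
              W[2:(n - 1)] <= W[1:(n - 2)] & W[2:(n - 1)] <= W[3:n],
              W[n] < W[n - 1])
  mins <- which(is_min)
  g <- which.min(W)
  others <- setdiff(mins, g)
  if (length(others) == 0) {
    return(list(barrier = NA_real_, wells = x[g]))
  }
  prominence <- vapply(others, function(m) {
    saddle <- max(W[min(m, g):max(m, g)])
    saddle - max(W[m], W[g])
  }, numeric(1))
  m_best <- others[which.max(prominence)]
  saddle <- max(W[min(m_best, g):max(m_best, g)])
  list(barrier = saddle - W[g], wells = sort(x[c(g, m_best)]))
}

#' Run the synthetic demonstration pipeline
#'
#' @param config a configuration list from [load_config()], or a YAML
#'   path.
#' @param stages which stages to run, in order.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "distances", "wavelet",
                                    "pca", "network", "wham", "report")) {
  if (is.character(config)) config <- load_config(config)
  for (s in stages) run_stage(s, config)
  invisible(config$outdir)
}

#' Run one pipeline stage
#'
#' @param stage stage name.
#' @param config configuration list.
#' @export
run_stage <- function(stage, config) {
  fn <- switch(stage,
               simulate = stage_simulate, distances = stage_distances,
               wavelet = stage_wavelet, pca = stage_pca,
               network = stage_network, wham = stage_wham,
               report = stage_report,
               abort_allokin(paste("unknown stage:", stage),
                             "allokin_invalid_config"))
  fn(config)
}

stage_report <- function(cfg) {
  d <- stage_dir(cfg, "report")
  grab <- function(...) {
    p <- file.path(cfg$outdir, ...)
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
  }
  part <- grab("wavelet", "partition.json")
  wham <- grab("wham", "wham_summary.json")
  sb <- grab("distances", "saltbridge_summary.json")
  sep_path <- file.path(cfg$outdir, "pca", "separation.csv")
  sepr <- if (file.exists(sep_path)) utils::read.csv(sep_path) else NULL
  edges_path <- file.path(cfg$outdir, "network", "edges.csv")
  edges <- if (file.exists(edges_path)) utils::read.csv(edges_path) else NULL
  top_edges <- if (!is.null(edges)) {
    utils::head(edges[order(-edges$ebtw),
                      c("from", "to", "correlation", "ebtw")], 10)
  } else {
    NULL
  }
  top_sep <- if (!is.null(sepr)) {
    utils::head(sepr[order(-abs(sepr$separation)), ], 3)
  } else {
    NULL
  }
  summary <- list(
    partition = part, salt_bridge = sb, wham = wham,
    top_separation_components = top_sep, top_ebtw_edges = top_edges)
  jsonlite::write_json(summary, file.path(d, "report.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  txt <- c(
    "allokin synthetic demonstration report",
    "======================================",
    if (!is.null(sb)) sprintf(
      "Salt bridge: formed in %.1f%% of frames (threshold %.1f A)",
      100 * sb$fraction_formed, sb$threshold),
    if (!is.null(part)) sprintf(
      "Temporal partition: %d frame set(s); boundaries at %s",
      part$k, paste(part$intervals$start, collapse = ", ")),
    if (!is.null(top_sep)) c(
      "Top separation components (component: separation):",
      sprintf("  PC%d: %.4g", top_sep$component, top_sep$separation)),
    if (!is.null(top_edges)) c(
      "Top current-flow betweenness edges (from-to: score):",
      sprintf("  %s-%s: %.4g", top_edges$from, top_edges$to,
              top_edges$ebtw)),
    if (!is.null(wham)) sprintf(
      "PMF barrier: %.2f kcal/mol (wells at %s A); converged: %s",
      wham$barrier_kcal,
      paste(sprintf("%.2f", wham$well_positions), collapse = ", "),
      wham$converged))
  writeLines(unlist(txt), file.path(d, "report.txt"))
  write_manifest(cfg, "report", list(), inputs = list(),
                 outputs = list("report.json", "report.txt"))
  log_msg(cfg, "INFO", "report: wrote ", file.path(d, "report.json"))
  invisible(d)
}
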