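# Wavelet-based event detection (WAFEX-style pipeline): per-residue
# Morlet spectrograms, chi-squared denoising, density clustering of the
# surviving (time, residue) points, and silhouette-scored temporal
# partitioning of the trajectory into frame sets.

#' Wavelet analysis parameters
#'
#' Defaults follow established practice for trajectory wavelet analysis:
#' 60 log-spaced timescales from the frame spacing up to the trajectory
#' duration, a Morlet mother wavelet, a multiplicative noise-correction
#' value of 1.01, and a chi-squared denoising cutoff of 1.6094.
#'
#' @param n_scales number of log-spaced timescales (>= 2).
#' @param min_timescale,max_timescale analysis band in ps; when `NULL`
#'   they default to the frame spacing and the trajectory duration.
#' @param omega0 Morlet center frequency (nondimensional; 6 is standard).
#' @param correction multiplicative correction applied to the per-residue
#'   noise level before thresholding.
#' @param chi2_cutoff denoising threshold on noise-normalized intensity.
#' @export
wavelet_spec <- function(n_scales = 60, min_timescale = NULL,
                         max_timescale = NULL, omega0 = 6,
                         correction = 1.01, chi2_cutoff = 1.6094) {
  if (n_scales < 2) abort_allokin("n_scales must be >= 2", "allokin_invalid_spec")
  if (!is.null(min_timescale) && !is.null(max_timescale) &&
      min_timescale >= max_timescale) {
    abort_allokin("min_timescale must be below max_timescale",
                  "allokin_invalid_spec")
  }
  structure(list(n_scales = as.integer(n_scales),
                 min_timescale = min_timescale,
                 max_timescale = max_timescale, omega0 = omega0,
                 correction = correction, chi2_cutoff = chi2_cutoff),
            class = "wavelet_spec")
}

#' Per-residue displacement signal
#'
#' For each residue, the Euclidean displacement of its heavy-atom
#' geometric center from its position in the first frame. The trajectory
#' should be RMS-fitted first so rigid-body motion does not masquerade as
#' internal motion; an unfitted series triggers a warning.
#'
#' @param series a `coord_series`.
#' @return matrix `residues x frames` (Angstrom) with residue ids as
#'   rownames and a `dt` attribute.
#' @export
residue_signal <- function(series) {
  if (!isTRUE(series$fitted)) {
    warning("series is not flagged as RMS-fitted; rigid-body motion will leak into the residue signal")
  }
  top <- series$topology
  heavy <- toupper(top$element) != "H"
  rid <- paste(top$chain, top$resno)
  rids <- unique(rid)
  nf <- n_frames(series)
  sig <- matrix(0, length(rids), nf)
  for (r in seq_along(rids)) {
    idx <- which(heavy & rid == rids[r])
    if (length(idx) == 0) idx <- which(rid == rids[r])
    ctr <- matrix(0, nf, 3)
    for (d in 1:3) {
      sub <- series$coords[, idx, d, drop = FALSE]
      ctr[, d] <- rowMeans(array(sub, c(nf, length(idx))))
    }
    sig[r, ] <- sqrt(rowSums(sweep(ctr, 2, ctr[1, ])^2))
  }
  rownames(sig) <- vapply(strsplit(rids, " "), `[`, character(1), 2)
  attr(sig, "dt") <- series$dt
  sig
}

# Morlet CWT of one signal via FFT (Torrence-Compo normalization).
# Returns frames x scales complex-modulus-squared intensities.
cwt_one <- function(x, dt, scales, omega0) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n)) * 2L # zero padding against wrap-around
  xpad <- c(x, rep(0, n2 - n))
  xhat <- stats::fft(xpad)
  k <- 0:(n2 - 1)
  omega <- 2 * pi * ifelse(k <= n2 / 2, k, k - n2) / (n2 * dt)
  out <- matrix(0, n, length(scales))
  norm0 <- pi^(-0.25)
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi_hat <- sqrt(2 * pi * s / dt) * norm0 *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    w <- stats::fft(xhat * psi_hat, inverse = TRUE) / n2
    out[, si] <- Mod(w[seq_len(n)])^2
  }
  out
}

morlet_fourier_factor <- function(omega0) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Continuous Morlet wavelet transform of a residue signal matrix
#'
#' Computes, for every residue, squared-modulus wavelet intensities across
#' `n_scales` log-spaced timescales (Fourier periods). Each signal is
#' demeaned first: the Morlet wavelet is blind to a constant offset, but
#' under zero padding an offset turns the record into a box whose
#' low-frequency content would swamp the longest scales. Boundary
#' effects are handled by zero padding; the cone-of-influence (e-folding
#' distance `sqrt(2) * scale` from either edge) is recorded as a mask.
#'
#' @param signal `residues x frames` matrix from [residue_signal()] (or a
#'   single numeric vector).
#' @param spec a [wavelet_spec()].
#' @param dt ps per frame; taken from the signal's `dt` attribute when
#'   present.
#' @return a `wavelet_spectrogram`: list with `intensity`
#'   (`residues x frames x scales`), `timescales` (ps), `coi`
#'   (`frames x scales` logical, TRUE = inside the cone of influence),
#'   `dt`, `residues`, `spec`.
#' @export
cwt_morlet <- function(signal, spec = wavelet_spec(), dt = NULL) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  dt <- dt %||% attr(signal, "dt") %||% 1
  nf <- ncol(signal)
  if (nf < 2) abort_allokin("need at least 2 frames", "allokin_invalid_spec")
  duration <- nf * dt
  tmin <- spec$min_timescale %||% (2 * dt)
  tmax <- spec$max_timescale %||% duration
  if (tmax > duration) {
    warning(sprintf("max_timescale %g ps exceeds trajectory duration %g ps; clipped",
                    tmax, duration))
    tmax <- duration
  }
  timescales <- exp(seq(log(tmin), log(tmax), length.out = spec$n_scales))
  ff <- morlet_fourier_factor(spec$omega0)
  scales <- timescales / ff
  nres <- nrow(signal)
  intensity <- array(0, c(nres, nf, spec$n_scales))
  for (r in seq_len(nres)) {
    intensity[r, , ] <- cwt_one(signal[r, ] - mean(signal[r, ]), dt,
                                scales, spec$omega0)
  }
  tgrid <- (seq_len(nf) - 1) * dt
  edge <- pmin(tgrid, rev(tgrid))
  coi <- outer(edge, sqrt(2) * scales, ">=")
  structure(list(intensity = intensity, timescales = timescales,
                 coi = coi, dt = dt,
                 residues = rownames(signal) %||% as.character(seq_len(nres)),
                 spec = spec),
            class = "wavelet_spectrogram")
}

#' @export
print.wavelet_spectrogram <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<wavelet_spectrogram> %d residues x %d frames x %d scales (%.3g..%.3g ps)\n",
              d[1], d[2], d[3], min(x$timescales), max(x$timescales)))
  invisible(x)
}

#' Chi-squared denoising threshold
#'
#' For each (residue, frame) point, takes the maximum intensity over the
#' scales inside the cone of influence at that frame (zero-padding
#' artifacts outside it are ignored), normalizes it by that residue's
#' robust noise level (the median
#' over frames of that same max-over-scales series, times the correction
#' value), and retains points whose normalized intensity exceeds the
#' cutoff. The median of the per-frame maxima is the null level the
#' cutoff is compared against, so a stationary-noise residue keeps only
#' its upper intensity tail while genuinely loud epochs survive intact.
#' Applying the threshold to an already-thresholded point set is a no-op.
#'
#' @param x a `wavelet_spectrogram` or a previously thresholded point set.
#' @param cutoff threshold on normalized intensity; default from the
#'   spectrogram's [wavelet_spec()].
#' @return data.frame `(residue, frame, intensity, normalized)` of class
#'   `wafex_points`; `frame` is 0-based, `residue` is the residue index
#'   (row number of the signal matrix).
#' @export
chi2_threshold <- function(x, cutoff = NULL) {
  if (inherits(x, "wafex_points")) {
    cutoff <- cutoff %||% attr(x, "cutoff")
    out <- x[x$normalized > cutoff, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "cutoff") <- cutoff
    class(out) <- class(x)
    return(out)
  }
  stopifnot(inherits(x, "wavelet_spectrogram"))
  cutoff <- cutoff %||% x$spec$chi2_cutoff
  if (cutoff <= 0) abort_allokin("cutoff must be positive", "allokin_invalid_spec")
  d <- dim(x$intensity)
  pts <- vector("list", d[1])
  for (r in seq_len(d[1])) {
    plane <- x$intensity[r, , ] # frames x scales
    plane[!x$coi] <- 0
    m <- apply(plane, 1, max)
    noise <- stats::median(m) * x$spec$correction
    normalized <- if (noise > 0) m / noise else rep(0, d[2])
    keep <- which(normalized > cutoff)
    if (length(keep)) {
      pts[[r]] <- data.frame(residue = r, frame = keep - 1L,
                             intensity = m[keep],
                             normalized = normalized[keep])
    }
  }
  out <- do.call(rbind, pts) %||%
    data.frame(residue = integer(), frame = integer(),
               intensity = numeric(), normalized = numeric())
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("wafex_points", "data.frame")
  out
}

#' Density-based clustering of thresholded wavelet points
#'
#' DBSCAN on the (frame, residue) plane: a core point has at least
#' `min_pts` neighbors (itself included) within `eps`; clusters are the
#' connected regions of core points plus their border points; everything
#' else is noise (`-1`). Axis units are frame indices and residue indices
#' by default; `frame_scale`/`residue_scale` rescale either axis before
#' distances are measured (the `eps` value applies to the scaled grid).
#' Neighbor search uses an eps-sized grid hash, so labels are independent
#' of point ordering.
#'
#' @param points a `wafex_points` data.frame (columns `frame`, `residue`).
#' @param eps neighborhood radius on the scaled grid.
#' @param min_pts minimum neighborhood size for a core point.
#' @param frame_scale,residue_scale axis scale factors.
#' @return list of class `cluster_labels`: `labels` (one per input point;
#'   `-1` = noise), `n_clusters`, `eps`, `min_pts`.
#' @export
density_cluster <- function(points, eps = 20.0, min_pts = 350,
                            frame_scale = 1, residue_scale = 1) {
  n <- nrow(points)
  lab <- rep(-1L, n)
  if (n > 0) {
    px <- points$frame * frame_scale
    py <- points$residue * residue_scale
    eps2 <- eps^2
    key <- paste(floor(px / eps), floor(py / eps))
    cells <- split(seq_len(n), key)
    cell_xy <- do.call(rbind, strsplit(names(cells), " ", fixed = TRUE))
    cellx <- as.numeric(cell_xy[, 1])
    celly <- as.numeric(cell_xy[, 2])
    # neighbor search per grid cell: candidates are the 3x3 block of
    # eps-sized cells; distances computed vectorized, in row chunks so
    # memory stays bounded. Neighbor lists are kept only for core points
    # (BFS expands from cores alone).
    nbrs <- vector("list", n)
    core <- logical(n)
    for (ci in seq_along(cells)) {
      mem <- cells[[ci]]
      cand <- integer(0)
      for (dx in -1:1) {
        for (dy in -1:1) {
          m <- cells[[paste(cellx[ci] + dx, celly[ci] + dy)]]
          if (!is.null(m)) cand <- c(cand, m)
        }
      }
      chunk <- max(1L, floor(5e7 / length(cand)))
      for (lo in seq(1, length(mem), by = chunk)) {
        rows <- mem[lo:min(lo + chunk - 1, length(mem))]
        M <- (outer(px[rows], px[cand], "-")^2 +
                outer(py[rows], py[cand], "-")^2) <= eps2
        is_core <- rowSums(M) >= min_pts
        core[rows] <- is_core
        if (any(is_core)) {
          hits <- which(M[is_core, , drop = FALSE], arr.ind = TRUE)
          lst <- split(cand[hits[, 2]], hits[, 1])
          cr <- rows[is_core]
          for (r in seq_along(cr)) nbrs[[cr[r]]] <- lst[[as.character(r)]]
        }
      }
    }
    cl <- 0L
    for (i in seq_len(n)) {
      if (!core[i] || lab[i] != -1L) next
      cl <- cl + 1L
      lab[i] <- cl
      queue <- nbrs[[i]]
      head <- 1L
      while (head <= length(queue)) {
        j <- queue[[head]]
        head <- head + 1L
        if (lab[j] == -1L) {
          lab[j] <- cl
          if (core[j]) {
            fresh <- nbrs[[j]][lab[nbrs[[j]]] == -1L]
            if (length(fresh)) queue <- c(queue, fresh)
          }
        }
      }
    }
  }
  structure(list(labels = lab, n_clusters = max(c(0L, lab)),
                 eps = eps, min_pts = min_pts),
            class = "cluster_labels")
}

#' Partition a trajectory into contiguous frame sets
#'
#' Embeds each frame as the vector of log wavelet intensities over
#' (residue, scale), clusters frames by Ward-linkage agglomeration on
#' Euclidean distances, picks the cut `k` in `2..k_max` that maximizes
#' the mean silhouette score, and falls back to a single frame set when
#' the best silhouette is below `min_silhouette` (no credible temporal
#' structure). Because agglomerative clusters need not respect time
#' ordering, labels are majority-smoothed along the frame axis and runs
#' shorter than `min_run_frac` of the trajectory are merged, yielding
#' disjoint, contiguous, exhaustive half-open intervals.
#'
#' For long trajectories frames are strided before clustering (at most
#' `max_embedded` embedded frames) and boundaries are mapped back to
#' original frame indices; the stride is recorded in the result. Only
#' timescales up to `max_embed_timescale` (default 1/64 of the
#' trajectory duration) enter the embedding: the largest embedded scale
#' sets the boundary resolution (a wavelet smears any discontinuity
#' over roughly its own support), so scales comparable to the whole
#' trajectory blur every boundary to uselessness while adding no
#' information about where a regime change lies; their zero-padding
#' edge distortion would also make the first and last frames look like
#' a regime of their own.
#'
#' @param spectrogram a `wavelet_spectrogram`.
#' @param k_max largest number of frame sets considered.
#' @param min_silhouette silhouette gate below which `k = 1` is returned.
#' @param log_floor additive floor before taking logs (padded-boundary
#'   zeros).
#' @param max_embedded cap on the number of frames entering clustering.
#' @param max_embed_timescale longest timescale (ps) included in the
#'   frame embedding; `NULL` = duration / 64.
#' @param smooth_window odd window length (in embedded frames) for
#'   majority smoothing.
#' @param min_run_frac minimum run length as a fraction of the trajectory.
#' @return a `frame_partition`: list with `intervals` (data.frame
#'   `start`, `end`; 0-based half-open, covering all frames), `k`,
#'   `silhouette` (data.frame `k`, `score`), `frame_stride`.
#' @export
temporal_partition <- function(spectrogram, k_max = 6, min_silhouette = 0.25,
                               log_floor = 1e-12, max_embedded = 800,
                               smooth_window = 11, min_run_frac = 0.02,
                               max_embed_timescale = NULL) {
  stopifnot(inherits(spectrogram, "wavelet_spectrogram"))
  d <- dim(spectrogram$intensity)
  nf <- d[2]
  if (nf < 2) abort_allokin("need at least 2 frames", "allokin_invalid_spec")
  cap <- max_embed_timescale %||% (nf * spectrogram$dt / 64)
  scale_keep <- which(spectrogram$timescales <= cap)
  if (length(scale_keep) == 0) scale_keep <- 1L
  ns <- length(scale_keep)
  stride <- max(1L, ceiling(nf / max_embedded))
  idx <- seq(1L, nf, by = stride)
  # frames outside the cone of influence at the largest embedded scale
  # are zero-padding artifacts that would cluster together purely
  # because their intensities decay; they are excluded from clustering
  # and absorbed into the outermost intervals afterwards
  in_coi <- spectrogram$coi[idx, scale_keep[ns]]
  if (sum(in_coi) >= 4) idx <- idx[in_coi]
  ni <- length(idx)
  X <- matrix(0, ni, d[1] * ns)
  for (r in seq_len(d[1])) {
    X[, ((r - 1) * ns + 1):(r * ns)] <-
      log(spectrogram$intensity[r, idx, scale_keep] + log_floor)
  }
  dm <- stats::dist(X)
  hc <- stats::hclust(dm, method = "ward.D2")
  ks <- seq(2L, min(k_max, ni - 1))
  sil <- vapply(ks, function(k) {
    ct <- stats::cutree(hc, k)
    mean(cluster::silhouette(ct, dm)[, "sil_width"])
  }, numeric(1))
  sil_tab <- data.frame(k = ks, score = sil)
  best <- which.max(sil)
  if (length(sil) == 0 || sil[best] < min_silhouette) {
    return(structure(list(
      intervals = data.frame(start = 0L, end = nf),
      k = 1L, silhouette = sil_tab, frame_stride = stride),
      class = "frame_partition"))
  }
  labels <- stats::cutree(hc, ks[best])
  # majority smoothing along the time axis
  half <- smooth_window %/% 2
  smoothed <- labels
  for (i in seq_len(ni)) {
    win <- labels[max(1, i - half):min(ni, i + half)]
    tab <- table(win)
    smoothed[i] <- as.integer(names(tab)[which.max(tab)])
  }
  # collapse to runs; merge runs that are too short into their neighbor
  runs <- rle(smoothed)
  min_run <- max(2L, ceiling(min_run_frac * ni))
  while (length(runs$lengths) > 1 && min(runs$lengths) < min_run) {
    i <- which.min(runs$lengths)
    into <- if (i == 1) 2 else if (i == length(runs$lengths)) i - 1 else {
      if (runs$lengths[i - 1] >= runs$lengths[i + 1]) i - 1 else i + 1
    }
    runs$values[i] <- runs$values[into]
    # re-collapse equal neighbors
    v <- rep(runs$values, runs$lengths)
    runs <- rle(v)
  }
  ends_idx <- cumsum(runs$lengths) # in embedded-frame positions
  starts_idx <- c(1L, utils::head(ends_idx, -1) + 1L)
  start_frames <- idx[starts_idx] - 1L # 0-based
  start_frames[1] <- 0L # absorb any trimmed leading edge
  end_frames <- c(utils::tail(start_frames, -1), nf)
  structure(list(
    intervals = data.frame(start = start_frames, end = end_frames),
    k = length(start_frames), silhouette = sil_tab, frame_stride = stride),
    class = "frame_partition")
}

#' @export
print.frame_partition <- function(x, ...) {
  cat(sprintf("<frame_partition> k = %d (stride %d)\n", x$k, x$frame_stride))
  print(x$intervals)
  invisible(x)
}
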