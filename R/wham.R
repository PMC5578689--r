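# Weighted histogram analysis method (WHAM) for 1D umbrella-sampling
# post-processing, with cumulative-block convergence diagnostics and a
# window-overlap guard.

#' One umbrella window
#'
#' @param time sample timestamps in ps.
#' @param x reaction-coordinate samples in Angstrom.
#' @param center harmonic restraint center, Angstrom.
#' @param force_constant restraint force constant, kcal/mol/Angstrom^2;
#'   zero denotes an unbiased window.
#' @export
umbrella_window <- function(time, x, center, force_constant) {
  if (length(x) == 0) {
    abort_allokin("window has no samples", "allokin_invalid_spec")
  }
  if (force_constant < 0) {
    abort_allokin("force_constant must be non-negative",
                  "allokin_invalid_spec")
  }
  structure(list(time = as.numeric(time), x = as.numeric(x),
                 center = center, force_constant = force_constant),
            class = "umbrella_window")
}

#' Umbrella-sampling dataset
#'
#' @param windows list of [umbrella_window()]s with distinct centers.
#' @param kT thermal energy, kcal/mol.
#' @param label reaction-coordinate label.
#' @export
umbrella_dataset <- function(windows, kT = kT_at(300), label = "x") {
  if (length(windows) < 1) {
    abort_allokin("need at least one window", "allokin_invalid_spec")
  }
  centers <- vapply(windows, `[[`, numeric(1), "center")
  if (anyDuplicated(centers)) {
    abort_allokin("window centers must be distinct", "allokin_invalid_spec")
  }
  structure(list(windows = windows[order(centers)], kT = kT, label = label),
            class = "umbrella_dataset")
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  centers <- vapply(x$windows, `[[`, numeric(1), "center")
  cat(sprintf("<umbrella_dataset> %d windows, centers %.3g..%.3g A, kT = %.4g kcal/mol\n",
              length(x$windows), min(centers), max(centers), x$kT))
  invisible(x)
}

#' Write/read an umbrella dataset in the conventional WHAM layout
#'
#' One two-column plain-text file (time, x) per window plus a metadata
#' file listing, per line: window filename, restraint center, force
#' constant.
#'
#' @param dataset an `umbrella_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix window filename prefix.
#' @return path to the metadata file.
#' @export
write_umbrella_dataset <- function(dataset, dir, prefix = "window") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- character(length(dataset$windows))
  for (i in seq_along(dataset$windows)) {
    w <- dataset$windows[[i]]
    fn <- sprintf("%s_%03d.dat", prefix, i)
    utils::write.table(data.frame(time = w$time, x = w$x),
                       file.path(dir, fn), row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    meta[i] <- sprintf("%s %.10g %.10g", fn, w$center, w$force_constant)
  }
  meta_path <- file.path(dir, "metadata.dat")
  writeLines(meta, meta_path)
  invisible(meta_path)
}

#' @rdname write_umbrella_dataset
#' @param meta_path metadata file written by [write_umbrella_dataset()]
#'   (window paths resolved relative to its directory).
#' @param kT thermal energy, kcal/mol.
#' @export
read_umbrella_dataset <- function(meta_path, kT = kT_at(300)) {
  dir <- dirname(meta_path)
  lines <- readLines(meta_path)
  lines <- lines[nzchar(trimws(lines))]
  windows <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    tab <- utils::read.table(file.path(dir, tok[1]))
    umbrella_window(time = tab[[1]], x = tab[[2]],
                    center = as.numeric(tok[2]),
                    force_constant = as.numeric(tok[3]))
  })
  umbrella_dataset(windows, kT = kT)
}

#' Self-consistent WHAM solve
#'
#' Iterates the standard WHAM equations on a fixed bin grid:
#' `P(x_b) propto sum_i h_i(x_b) / sum_j n_j exp((F_j - b_j(x_b)) / kT)`
#' and `F_j = -kT log sum_b P(x_b) exp(-b_j(x_b) / kT)` with
#' `b_j(x) = k_j / 2 (x - x_j)^2`, until the largest window free-energy
#' shift falls below `tol * kT`. The profile is `W(x) = -kT log P(x)`,
#' shifted so its minimum over occupied bins is zero. Bins with zero
#' samples are returned as `NA` and flagged, never interpolated. No
#' autocorrelation/statistical-inefficiency weighting is applied.
#'
#' @param dataset an `umbrella_dataset`.
#' @param n_bins number of equal-width bins.
#' @param tol convergence tolerance in units of kT.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param range bin range `c(lo, hi)`; default the sample range.
#' @return a `pmf_profile`: data.frame-like list with `bin_center`,
#'   `free_energy` (kcal/mol, min-shifted), `count`, plus `kT`,
#'   `converged`, `n_iter`, `window_free_energies`.
#' @export
wham_solve <- function(dataset, n_bins = 100, tol = 1e-6, max_iter = 1e5,
                       range = NULL) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  kT <- dataset$kT
  xs <- lapply(dataset$windows, `[[`, "x")
  rng <- range %||% base::range(unlist(xs))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  J <- length(dataset$windows)
  H <- matrix(0, J, n_bins) # per-window histograms
  for (j in seq_len(J)) {
    b <- findInterval(xs[[j]], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    H[j, ] <- tabulate(b, n_bins)
  }
  nvec <- rowSums(H)
  Htot <- colSums(H)
  occupied <- Htot > 0
  # adjacent-window overlap guard: negligible shared probability mass
  # between neighboring windows makes the free-energy stitching unreliable
  for (j in seq_len(J - 1)) {
    shared <- sum(pmin(H[j, ] / nvec[j], H[j + 1, ] / nvec[j + 1]))
    if (shared < 0.05) {
      warning(sprintf(
        "windows %d (center %.3g) and %d (center %.3g) overlap by only %.3f of their mass: gap in sampling",
        j, dataset$windows[[j]]$center, j + 1,
        dataset$windows[[j + 1]]$center, shared))
    }
  }
  bias <- matrix(0, J, n_bins)
  for (j in seq_len(J)) {
    w <- dataset$windows[[j]]
    bias[j, ] <- 0.5 * w$force_constant * (centers - w$center)^2
  }
  Eb <- exp(-bias / kT) # J x bins
  Fj <- numeric(J)
  P <- numeric(n_bins)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(nvec * exp(Fj / kT) * Eb)
    P <- ifelse(denom > 0, Htot / denom, 0)
    Z <- as.vector(Eb %*% P)
    Fnew <- -kT * log(Z)
    Fnew <- Fnew - Fnew[1] # gauge: first window at zero
    delta <- max(abs(Fnew - Fj))
    Fj <- Fnew
    if (delta < tol * kT) break
    if (iter >= max_iter) {
      abort_allokin(sprintf(
        "WHAM did not converge in %d iterations (residual %.3g kT)",
        as.integer(max_iter), delta / kT), "allokin_wham_not_converged")
    }
  }
  P <- P / sum(P)
  W <- rep(NA_real_, n_bins)
  W[occupied] <- -kT * log(P[occupied])
  W <- W - min(W, na.rm = TRUE)
  structure(list(bin_center = centers, free_energy = W, count = Htot,
                 occupied = occupied, kT = kT, converged = TRUE,
                 n_iter = iter, window_free_energies = Fj,
                 range = rng, n_bins = n_bins),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d bins over [%.3g, %.3g] A; %d occupied; %d WHAM iterations\n",
              x$n_bins, x$range[1], x$range[2], sum(x$occupied), x$n_iter))
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(bin_center = x$bin_center, free_energy = x$free_energy,
             count = x$count)
}

#' Write a PMF profile as CSV (bin_center, free_energy, count)
#' @param x a `pmf_profile`.
#' @param path output file.
#' @export
write_pmf_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cumulative-block PMFs for convergence checking
#'
#' Recomputes the PMF over cumulative sample subsets
#' `[start_time, start_time + m * block_ps]` for `m = 1, 2, ...` (the
#' final block uses all post-`start_time` data). Convergence is declared
#' when successive profiles differ by less than `conv_tol` (kcal/mol,
#' max-abs over bins occupied in both).
#'
#' @param dataset an `umbrella_dataset` whose samples carry timestamps.
#' @param start_time discard samples before this time (ps).
#' @param block_ps cumulative block length (ps).
#' @param n_bins,tol,max_iter passed to [wham_solve()].
#' @param conv_tol successive-profile tolerance, kcal/mol.
#' @return list with `profiles` (list of `pmf_profile`), `block_ends`
#'   (ps), `max_abs_diff` (successive differences), `converged`.
#' @export
cumulative_pmfs <- function(dataset, start_time, block_ps, n_bins = 100,
                            tol = 1e-6, max_iter = 1e5, conv_tol = 0.2) {
  tmax <- max(vapply(dataset$windows, function(w) max(w$time), numeric(1)))
  if (start_time >= tmax) {
    abort_allokin(sprintf("start_time %g ps is beyond the data (max %g ps)",
                          start_time, tmax), "allokin_invalid_spec")
  }
  ends <- seq(start_time + block_ps, tmax, by = block_ps)
  if (length(ends) == 0 || utils::tail(ends, 1) < tmax) {
    ends <- c(ends, tmax)
  }
  # common bin range so profiles are comparable bin-by-bin
  rng <- base::range(unlist(lapply(dataset$windows, `[[`, "x")))
  subset_to <- function(tcut) {
    keep <- lapply(dataset$windows, function(w) {
      i <- w$time >= start_time & w$time <= tcut
      umbrella_window(w$time[i], w$x[i], w$center, w$force_constant)
    })
    umbrella_dataset(keep, kT = dataset$kT, label = dataset$label)
  }
  profiles <- lapply(ends, function(tc) {
    wham_solve(subset_to(tc), n_bins = n_bins, tol = tol,
               max_iter = max_iter, range = rng)
  })
  diffs <- numeric(0)
  if (length(profiles) > 1) {
    diffs <- vapply(seq_len(length(profiles) - 1), function(i) {
      a <- profiles[[i]]
      b <- profiles[[i + 1]]
      both <- a$occupied & b$occupied
      max(abs(a$free_energy[both] - b$free_energy[both]))
    }, numeric(1))
  }
  list(profiles = profiles, block_ends = ends, max_abs_diff = diffs,
       converged = length(diffs) > 0 && utils::tail(diffs, 1) < conv_tol)
}

#' Adjacent-window overlap report
#'
#' Shared sampling between each adjacent window pair, measured as the
#' histogram intersection `sum_b min(p_a(b), p_b(b))` of the two
#' windows' normalized bin histograms on a common grid: 1 for identical
#' windows, 0 for disjoint sample ranges. Values near zero flag sampling
#' gaps that would make WHAM stitching unreliable.
#'
#' @param dataset an `umbrella_dataset` (>= 2 windows).
#' @param n_bins number of bins on the common grid.
#' @return data.frame `(window_a, window_b, center_a, center_b, overlap)`.
#' @export
window_overlap_report <- function(dataset, n_bins = 100) {
  if (length(dataset$windows) < 2) {
    abort_allokin("need at least two windows", "allokin_invalid_spec")
  }
  rng <- base::range(unlist(lapply(dataset$windows, `[[`, "x")))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  hist_p <- lapply(dataset$windows, function(w) {
    b <- findInterval(w$x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, n_bins) / length(w$x)
  })
  J <- length(hist_p)
  data.frame(
    window_a = seq_len(J - 1), window_b = seq(2, J),
    center_a = vapply(dataset$windows[-J], `[[`, numeric(1), "center"),
    center_b = vapply(dataset$windows[-1], `[[`, numeric(1), "center"),
    overlap = vapply(seq_len(J - 1), function(j) {
      sum(pmin(hist_p[[j]], hist_p[[j + 1]]))
    }, numeric(1)))
}
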