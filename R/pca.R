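# Frame-set-restricted PCA of backbone fluctuations, amplitude-scaled
# mode vectors ("R-component" fields), the target-to-barrier separation
# metric, cumulative covariance, and NMD export for visualization.

#' PCA of coordinate fluctuations over a frame interval
#'
#' Eigendecomposition of the 3N x 3N covariance of the selected atoms'
#' coordinates over the chosen frames. The covariance is unweighted
#' (plain coordinate covariance, the common choice for trajectory PCA);
#' group centers elsewhere use masses. Eigenvector signs are fixed by
#' making each vector's largest-magnitude entry positive, so results are
#' deterministic.
#'
#' @param series a fitted `coord_series`.
#' @param frame_interval `c(start, end)` 0-based half-open frame interval,
#'   or `NULL` for all frames.
#' @param selection atoms to analyze; default backbone atoms (all atoms
#'   when no backbone names exist, as in CA-only synthetic topologies).
#' @return a `pca_result`: `mean` (atoms x 3), `values` (eigenvalues,
#'   Angstrom^2, descending), `vectors` (orthonormal columns, 3N), `trace`
#'   (total fluctuation variance), `selection`, `masses`, `interval`.
#' @export
covariance_pca <- function(series, frame_interval = NULL, selection = NULL) {
  if (is.null(selection)) {
    selection <- select_atoms(series, backbone = TRUE)
    if (length(selection) == 0) {
      selection <- select_atoms(series, indices = seq_len(n_atoms(series)))
    }
  }
  sel <- as_selection(selection, series)
  if (length(sel) == 0) {
    abort_allokin("empty selection", "allokin_invalid_selection")
  }
  frames <- interval_frames(frame_interval, n_frames(series))
  if (length(frames) < 2) {
    abort_allokin("need at least 2 frames for PCA", "allokin_invalid_spec")
  }
  if (!isTRUE(series$fitted)) {
    warning("series is not flagged as RMS-fitted; PCA will mix rigid-body and internal motion")
  }
  nsel <- length(sel)
  X <- matrix(0, length(frames), 3 * nsel)
  for (d in 1:3) {
    X[, seq(d, 3 * nsel, 3)] <- series$coords[frames, sel, d]
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covm <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen(covm, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # deterministic sign: largest-|entry| positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(
    mean = matrix(mu, nsel, 3, byrow = TRUE),
    values = vals, vectors = vecs, trace = sum(diag(covm)),
    selection = as.integer(sel), masses = series$topology$mass[sel],
    atom_names = series$topology$name[sel],
    resno = series$topology$resno[sel],
    resname = series$topology$resname[sel],
    interval = frame_interval %||% c(0L, n_frames(series))),
    class = "pca_result")
}

interval_frames <- function(frame_interval, nf) {
  if (is.null(frame_interval)) return(seq_len(nf))
  if (frame_interval[1] < 0 || frame_interval[2] > nf ||
      frame_interval[1] >= frame_interval[2]) {
    abort_allokin("frame_interval out of range", "allokin_invalid_spec")
  }
  seq(frame_interval[1] + 1L, frame_interval[2])
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d atoms, %d components; top eigenvalues: %s\n",
              nrow(x$mean), length(x$values),
              paste(signif(utils::head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Cumulative covariance fraction of the leading components
#'
#' @param pca a `pca_result`.
#' @param m number of leading components.
#' @return `sum(lambda[1:m]) / sum(lambda)` in `[0, 1]`.
#' @export
cumulative_covariance <- function(pca, m) {
  if (m < 1 || m > length(pca$values)) {
    abort_allokin("m out of range", "allokin_invalid_spec")
  }
  tot <- sum(pca$values)
  if (tot == 0) return(0)
  sum(pca$values[seq_len(m)]) / tot
}

#' Amplitude-scaled mode vectors (R-component field)
#'
#' Per-atom 3-vectors of principal component `m` scaled by the component's
#' amplitude. The default convention is `sqrt(lambda) * v` (RMS
#' displacement amplitude in Angstrom, suitable for drawing arrows on
#' structures); `lambda * v` is available via `convention = "lambda"`.
#' Under the default, the squared norms over atoms sum to the eigenvalue.
#'
#' @param pca a `pca_result`.
#' @param m component index.
#' @param convention `"sqrt_lambda"` (default) or `"lambda"`.
#' @return matrix `atoms x 3`.
#' @export
r_components <- function(pca, m, convention = c("sqrt_lambda", "lambda")) {
  convention <- match.arg(convention)
  if (m < 1 || m > length(pca$values)) {
    abort_allokin("component index out of range", "allokin_invalid_spec")
  }
  amp <- if (convention == "sqrt_lambda") sqrt(pca$values[m]) else pca$values[m]
  matrix(amp * pca$vectors[, m], ncol = 3, byrow = TRUE)
}

#' Separation metric between a target and a barrier group along a mode
#'
#' Measures, for each principal component, how much the component moves a
#' target group (e.g. the activation-loop arginine) away from a barrier
#' group (e.g. the steric-barrier stretch of the alphaC helix). `u` is
#' the unit vector from the barrier group's mass center to the target
#' group's mass center on the interval-average structure; the separation
#' is the mean projection of the target atoms' R-component vectors on `u`
#' minus the mean projection of the barrier atoms' (positive = opening).
#'
#' @param pca a `pca_result`.
#' @param target_sel,barrier_sel indices into the PCA atom set (positions
#'   within `pca$selection`), disjoint and non-empty.
#' @param components which components to profile (default first 15).
#' @param convention R-component convention, see [r_components()].
#' @return data.frame `(component, separation, log_abs, sign)` with the
#'   unit vector in attribute `u`.
#' @export
separation_metric <- function(pca, target_sel, barrier_sel,
                              components = seq_len(min(15, length(pca$values))),
                              convention = "sqrt_lambda") {
  target_sel <- as.integer(target_sel)
  barrier_sel <- as.integer(barrier_sel)
  if (length(target_sel) == 0 || length(barrier_sel) == 0) {
    abort_allokin("target and barrier selections must be non-empty",
                  "allokin_invalid_selection")
  }
  if (length(intersect(target_sel, barrier_sel)) > 0) {
    abort_allokin("target and barrier selections must be disjoint",
                  "allokin_invalid_selection")
  }
  wcom <- function(idx) {
    w <- pca$masses[idx] / sum(pca$masses[idx])
    colSums(pca$mean[idx, , drop = FALSE] * w)
  }
  u <- wcom(target_sel) - wcom(barrier_sel)
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) {
    abort_allokin("group mass centers coincide; separation direction undefined",
                  "allokin_degenerate_geometry")
  }
  u <- u / nu
  sep <- vapply(components, function(m) {
    r <- r_components(pca, m, convention)
    proj <- r %*% u
    mean(proj[target_sel]) - mean(proj[barrier_sel])
  }, numeric(1))
  out <- data.frame(component = components, separation = sep,
                    log_abs = log(abs(sep)), sign = sign(sep))
  attr(out, "u") <- u
  out
}

# ----------------------------------------------------------------- NMD I/O

#' Write principal components in NMD format
#'
#' NormalModeWizard dialect: `name`, `atomnames`, `resnames`, `resids`,
#' `coordinates`, then one `mode <index> <eigenvalue> <vector>` line per
#' exported component (15 by default).
#'
#' @param pca a `pca_result`.
#' @param path output file.
#' @param n_modes number of modes to export.
#' @param name dataset name recorded in the file.
#' @export
write_nmd <- function(pca, path, n_modes = 15, name = "allokin_pca") {
  n_modes <- min(n_modes, length(pca$values))
  if (n_modes < 1 || nrow(pca$mean) == 0) {
    abort_allokin("nothing to export", "allokin_invalid_spec")
  }
  if (nrow(pca$vectors) != 3 * nrow(pca$mean)) {
    abort_allokin("atom count mismatch between mean and eigenvectors",
                  "allokin_atom_mismatch")
  }
  fmt <- function(x) sprintf("%.8g", x)
  lines <- c(
    paste("name", name),
    paste("atomnames", paste(pca$atom_names, collapse = " ")),
    paste("resnames", paste(pca$resname, collapse = " ")),
    paste("resids", paste(pca$resno, collapse = " ")),
    paste("coordinates", paste(fmt(as.vector(t(pca$mean))), collapse = " "))
  )
  for (m in seq_len(n_modes)) {
    lines <- c(lines, paste("mode", m, fmt(pca$values[m]),
                            paste(fmt(pca$vectors[, m]), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an NMD file written by [write_nmd()]
#'
#' @param path NMD file.
#' @return list with `name`, `atom_names`, `resname`, `resno`,
#'   `coordinates` (atoms x 3), `values` (eigenvalues), `vectors`
#'   (columns).
#' @export
read_nmd <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    strsplit(sub(paste0("^", key, " "), "", ln[1]), " +")[[1]]
  }
  coords <- as.numeric(field("coordinates"))
  n_atoms <- length(coords) / 3
  mode_lines <- grep("^mode ", lines, value = TRUE)
  values <- numeric(length(mode_lines))
  vectors <- matrix(0, 3 * n_atoms, length(mode_lines))
  for (i in seq_along(mode_lines)) {
    tok <- strsplit(mode_lines[i], " +")[[1]]
    values[i] <- as.numeric(tok[3])
    vec <- as.numeric(tok[-(1:3)])
    if (length(vec) != 3 * n_atoms) {
      abort_allokin(sprintf("mode %s has %d components for %d atoms",
                            tok[2], length(vec), n_atoms),
                    "allokin_atom_mismatch")
    }
    vectors[, i] <- vec
  }
  list(name = paste(field("name"), collapse = " "),
       atom_names = field("atomnames"), resname = field("resnames"),
       resno = as.integer(field("resids")),
       coordinates = matrix(coords, n_atoms, 3, byrow = TRUE),
       values = values, vectors = vectors)
}
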