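# Trajectory container, PDB/DCD I/O, superposition and scalar time series.
#
# Units follow the formats' native conventions throughout: coordinates in
# Angstrom, time in ps, masses in amu. Residue numbering is 1-based,
# mirroring PDB author numbering (the field cites residues such as R375 by
# that convention).

#' Build an atom topology table
#'
#' @param name atom names (PDB atom name column, e.g. "CA", "CZ").
#' @param resno 1-based residue numbers.
#' @param resname residue names (three-letter codes).
#' @param chain chain identifiers.
#' @param element element symbols; guessed from `name` when `NULL`.
#' @param mass atomic masses in amu; looked up from `element` when `NULL`.
#' @return a `data.frame` with one row per atom.
#' @export
make_topology <- function(name, resno, resname = "ALA", chain = "A",
                          element = NULL, mass = NULL) {
  n <- length(name)
  resno <- rep_len(resno, n)
  element <- element %||% guess_element(name)
  mass <- mass %||% mass_of_element(element)
  top <- data.frame(
    eleno = seq_len(n), name = name, resno = resno,
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    element = rep_len(element, n), mass = rep_len(mass, n),
    stringsAsFactors = FALSE
  )
  top
}

#' One C-alpha pseudo-atom per residue
#'
#' Convenience topology for synthetic ensembles where each residue is
#' represented by a single carbon site.
#'
#' @param n_residues number of residues.
#' @inheritParams make_topology
#' @export
ca_topology <- function(n_residues, chain = "A", resname = "ALA") {
  make_topology(rep("CA", n_residues), seq_len(n_residues),
                resname = resname, chain = chain)
}

#' Coordinate series (trajectory) constructor
#'
#' @param coords numeric array `frames x atoms x 3` in Angstrom.
#' @param topology atom table from [make_topology()].
#' @param dt time between frames in ps.
#' @param fitted logical; whether frames share a common (superposed) frame
#'   of reference.
#' @param provenance character vector describing how the series was made.
#' @return an object of class `coord_series`.
#' @export
coord_series <- function(coords, topology, dt = 1, fitted = FALSE,
                         provenance = character()) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort_allokin("coords must be a frames x atoms x 3 array",
                  "allokin_invalid_coords")
  }
  if (dim(coords)[2] != nrow(topology)) {
    abort_allokin(sprintf(
      "atom count mismatch: coords have %d atoms, topology has %d",
      dim(coords)[2], nrow(topology)), "allokin_atom_mismatch")
  }
  if (dim(coords)[1] < 1) {
    abort_allokin("need at least one frame", "allokin_invalid_coords")
  }
  if (!all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1, all))[1]
    abort_allokin(sprintf("non-finite coordinates at frame %d", bad),
                  "allokin_invalid_coords")
  }
  structure(list(coords = coords, topology = topology, dt = dt,
                 fitted = fitted, provenance = provenance),
            class = "coord_series")
}

#' @export
print.coord_series <- function(x, ...) {
  cat(sprintf("<coord_series> %d frames x %d atoms (%d residues), dt = %g ps%s\n",
              n_frames(x), n_atoms(x),
              length(unique(paste(x$topology$chain, x$topology$resno))),
              x$dt, if (x$fitted) ", fitted" else ""))
  invisible(x)
}

#' @rdname coord_series
#' @param x a `coord_series`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname coord_series
#' @export
n_atoms <- function(x) dim(x$coords)[2]

# frames x 3N matrix in x1 y1 z1 x2 ... order (bio3d xyz layout)
series_xyz <- function(series) {
  d <- dim(series$coords)
  out <- matrix(0, d[1], 3 * d[2])
  out[, seq(1, 3 * d[2], 3)] <- series$coords[, , 1]
  out[, seq(2, 3 * d[2], 3)] <- series$coords[, , 2]
  out[, seq(3, 3 * d[2], 3)] <- series$coords[, , 3]
  out
}

xyz_to_array <- function(xyz, n_atoms) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  arr <- array(0, c(nrow(xyz), n_atoms, 3))
  arr[, , 1] <- xyz[, seq(1, 3 * n_atoms, 3)]
  arr[, , 2] <- xyz[, seq(2, 3 * n_atoms, 3)]
  arr[, , 3] <- xyz[, seq(3, 3 * n_atoms, 3)]
  arr
}

#' Scalar per-frame time series
#'
#' @param value numeric vector, one value per frame.
#' @param dt ps per frame.
#' @param label descriptive label (units included by convention).
#' @export
scalar_series <- function(value, dt = 1, label = "value") {
  structure(list(value = as.numeric(value), dt = dt, label = label),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> '%s', %d frames, dt = %g ps\n",
              x$label, length(x$value), x$dt))
  invisible(x)
}

#' @export
as.data.frame.scalar_series <- function(x, ...) {
  data.frame(frame = seq_along(x$value) - 1L,
             time_ps = (seq_along(x$value) - 1) * x$dt,
             value = x$value)
}

#' Write a scalar series as CSV (frame, time_ps, value)
#' @param x a `scalar_series`.
#' @param path output file.
#' @export
write_scalar_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------- selection

#' Select atoms from a topology
#'
#' Selection criteria are combined with AND; vector-valued criteria match
#' any of their values. Residue numbers are 1-based PDB author numbering.
#'
#' @param x a `coord_series` or topology `data.frame`.
#' @param resno residue numbers to keep.
#' @param resname residue names to keep.
#' @param name atom names to keep (e.g. `"CA"`).
#' @param element element symbols to keep.
#' @param chain chain identifiers to keep.
#' @param backbone keep protein backbone atoms (N, CA, C, O) only.
#' @param heavy drop hydrogens.
#' @param indices explicit atom indices (applied before other criteria).
#' @return integer atom indices of class `atom_selection` with a
#'   `provenance` attribute recording the expression.
#' @export
select_atoms <- function(x, resno = NULL, resname = NULL, name = NULL,
                         element = NULL, chain = NULL, backbone = FALSE,
                         heavy = FALSE, indices = NULL) {
  top <- if (inherits(x, "coord_series")) x$topology else x
  keep <- rep(TRUE, nrow(top))
  prov <- character()
  if (!is.null(indices)) {
    if (anyDuplicated(indices) || any(indices < 1 | indices > nrow(top))) {
      abort_allokin("indices out of range or duplicated",
                    "allokin_invalid_selection")
    }
    keep <- keep & seq_len(nrow(top)) %in% indices
    prov <- c(prov, sprintf("indices[%d]", length(indices)))
  }
  if (!is.null(resno)) {
    keep <- keep & top$resno %in% resno
    prov <- c(prov, paste0("resno %in% {", paste(range(resno), collapse = ".."), "}"))
  }
  if (!is.null(resname)) {
    keep <- keep & top$resname %in% resname
    prov <- c(prov, paste0("resname %in% {", paste(resname, collapse = ","), "}"))
  }
  if (!is.null(name)) {
    keep <- keep & top$name %in% name
    prov <- c(prov, paste0("name %in% {", paste(name, collapse = ","), "}"))
  }
  if (!is.null(element)) {
    keep <- keep & toupper(top$element) %in% toupper(element)
    prov <- c(prov, paste0("element %in% {", paste(element, collapse = ","), "}"))
  }
  if (!is.null(chain)) {
    keep <- keep & top$chain %in% chain
    prov <- c(prov, paste0("chain %in% {", paste(chain, collapse = ","), "}"))
  }
  if (backbone) {
    keep <- keep & top$name %in% c("N", "CA", "C", "O")
    prov <- c(prov, "backbone")
  }
  if (heavy) {
    keep <- keep & toupper(top$element) != "H"
    prov <- c(prov, "heavy")
  }
  sel <- which(keep)
  structure(sel, class = "atom_selection",
            provenance = paste(prov, collapse = " & "))
}

as_selection <- function(x, series) {
  if (inherits(x, "atom_selection")) return(x)
  select_atoms(series, indices = as.integer(x))
}

# ---------------------------------------------------------------------- I/O

#' Read a trajectory from PDB (+ optional DCD)
#'
#' The PDB file supplies the topology; coordinates come from the DCD when
#' given, otherwise from the PDB MODEL records (one frame per model).
#'
#' @param topology_path PDB file.
#' @param coords_path optional DCD file with the frames.
#' @param dt ps between frames (not stored by either format reliably).
#' @return a [coord_series()].
#' @export
read_trajectory <- function(topology_path, coords_path = NULL, dt = 1) {
  if (!file.exists(topology_path)) {
    abort_allokin(paste("no such topology file:", topology_path),
                  "allokin_io_error")
  }
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- guess_element(at$elety)
  }
  element[is.na(element) | element == ""] <- guess_element(at$elety[is.na(element) | element == ""])
  top <- data.frame(
    eleno = seq_len(nrow(at)), name = at$elety, resno = at$resno,
    resname = at$resid, chain = ifelse(is.na(at$chain), "A", at$chain),
    element = toupper(element), mass = mass_of_element(element),
    stringsAsFactors = FALSE
  )
  if (is.null(coords_path)) {
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else {
    if (!file.exists(coords_path)) {
      abort_allokin(paste("no such coordinate file:", coords_path),
                    "allokin_io_error")
    }
    xyz <- bio3d::read.dcd(coords_path, verbose = FALSE)
  }
  if (ncol(xyz) != 3 * nrow(top)) {
    abort_allokin(sprintf(
      "atom count mismatch: topology has %d atoms, frames have %g",
      nrow(top), ncol(xyz) / 3), "allokin_atom_mismatch")
  }
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1, all))[1]
    abort_allokin(sprintf("truncated/invalid coordinates at frame %d", bad),
                  "allokin_io_error")
  }
  coord_series(xyz_to_array(xyz, nrow(top)), top, dt = dt,
               provenance = c(paste("read:", topology_path),
                              if (!is.null(coords_path)) paste("read:", coords_path)))
}

#' Write a trajectory as PDB (+ optional DCD)
#'
#' With `coords_path` the PDB holds the topology and first frame and the
#' DCD holds all frames; without it a multi-model PDB is written.
#'
#' @param series a `coord_series`.
#' @param topology_path PDB output path.
#' @param coords_path optional DCD output path.
#' @export
write_trajectory <- function(series, topology_path, coords_path = NULL) {
  xyz <- series_xyz(series)
  top <- series$topology
  pdb_xyz <- if (is.null(coords_path)) xyz else xyz[1, , drop = FALSE]
  bio3d::write.pdb(file = topology_path, xyz = pdb_xyz,
                   resno = top$resno, resid = top$resname,
                   eleno = top$eleno, elety = top$name,
                   chain = top$chain, elesy = top$element)
  if (!is.null(coords_path)) write_dcd(xyz, coords_path, dt = series$dt)
  invisible(topology_path)
}

# Minimal CHARMM-format DCD writer (native endianness, no unit cell).
write_dcd <- function(xyz, path, dt = 1) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natom <- ncol(xyz) / 3L
  nframes <- nrow(xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nframes   # NSET
  icntrl[2] <- 1L        # ISTART
  icntrl[3] <- 1L        # NSAVC
  icntrl[4] <- nframes   # NSTEP
  icntrl[20] <- 24L      # CHARMM version flag
  writeBin(icntrl[1:9], con, size = 4)
  writeBin(as.numeric(dt), con, size = 4) # DELTA as 4-byte float
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  title <- sprintf("%-80s", "Written by allokin")
  writeBin(as.integer(4 + 80), con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(as.integer(4 + 80), con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(natom), con, size = 4)
  writeBin(4L, con, size = 4)
  # frame records assembled as one raw matrix (columns = frames) so the
  # whole body is a single writeBin call; per-record layout is
  # [int 4N][N floats][int 4N] for x, y, z
  marker <- writeBin(as.integer(4 * natom), raw(), size = 4)
  arr <- xyz_to_array(xyz, natom)
  v <- as.vector(aperm(arr, c(2, 3, 1))) # atom fastest, then x/y/z, then frame
  float_raw <- matrix(writeBin(as.numeric(v), raw(), size = 4),
                      nrow = 12 * natom)
  rec <- 8 + 4 * natom
  fb <- matrix(as.raw(0), nrow = 3 * rec, ncol = nframes)
  for (d in 0:2) {
    off <- d * rec
    fb[off + 1:4, ] <- marker
    fb[off + 4 + seq_len(4 * natom), ] <-
      float_raw[d * 4 * natom + seq_len(4 * natom), ]
    fb[off + rec - 3:0, ] <- marker
  }
  writeBin(as.vector(fb), con)
  invisible(path)
}

# ------------------------------------------------------------- superposition

avg_xyz <- function(xyz) colMeans(xyz)

check_fit_selection <- function(ref_xyz, sel) {
  if (length(sel) < 3) {
    abort_allokin("rms_fit needs at least 3 fitting atoms",
                  "allokin_invalid_selection")
  }
  pts <- matrix(ref_xyz[bio3d::atom2xyz(sel)], ncol = 3, byrow = TRUE)
  ctr <- sweep(pts, 2, colMeans(pts))
  if (qr(ctr)$rank < 2) {
    abort_allokin("fitting atoms are collinear; superposition is degenerate",
                  "allokin_invalid_selection")
  }
}

#' Least-squares superposition of all frames onto a reference
#'
#' Removes rigid-body rotation and translation by the Kabsch least-squares
#' fit over `fit_selection`. The default reference is the trajectory
#' average structure computed with a two-pass scheme: fit all frames to the
#' first frame, average, then refit to that average.
#'
#' @param series a `coord_series`.
#' @param fit_selection atoms used for the fit; default backbone atoms
#'   (all atoms when the topology has no backbone names).
#' @param reference `"average"` (default), `"first"`, or a 1-based frame
#'   index.
#' @return the fitted `coord_series` (`fitted = TRUE`).
#' @export
rms_fit <- function(series, fit_selection = NULL, reference = "average") {
  if (is.null(fit_selection)) {
    fit_selection <- select_atoms(series, backbone = TRUE)
    if (length(fit_selection) == 0) {
      fit_selection <- select_atoms(series, indices = seq_len(n_atoms(series)))
    }
  }
  sel <- as_selection(fit_selection, series)
  xyz <- series_xyz(series)
  check_fit_selection(xyz[1, ], sel)
  inds <- bio3d::atom2xyz(sel)
  fit_to <- function(ref, m) {
    bio3d::fit.xyz(fixed = ref, mobile = m,
                   fixed.inds = inds, mobile.inds = inds)
  }
  if (identical(reference, "average")) {
    pass1 <- fit_to(xyz[1, ], xyz)
    ref <- avg_xyz(pass1)
    fitted <- fit_to(ref, xyz)
  } else if (identical(reference, "first")) {
    fitted <- fit_to(xyz[1, ], xyz)
  } else if (is.numeric(reference) && length(reference) == 1) {
    fitted <- fit_to(xyz[reference, ], xyz)
  } else {
    abort_allokin("reference must be 'average', 'first' or a frame index",
                  "allokin_invalid_argument")
  }
  coord_series(xyz_to_array(fitted, n_atoms(series)), series$topology,
               dt = series$dt, fitted = TRUE,
               provenance = c(series$provenance,
                              sprintf("rms_fit[%s]", attr(sel, "provenance"))))
}

# ------------------------------------------------------------- scalar series

group_com <- function(series, sel, mass_weighted = TRUE) {
  sel <- as_selection(sel, series)
  if (length(sel) == 0) {
    abort_allokin("empty selection", "allokin_invalid_selection")
  }
  w <- if (mass_weighted) series$topology$mass[sel] else rep(1, length(sel))
  w <- w / sum(w)
  out <- matrix(0, n_frames(series), 3)
  for (d in 1:3) {
    sub <- matrix(series$coords[, sel, d], nrow = n_frames(series))
    out[, d] <- as.vector(sub %*% w)
  }
  out
}

#' Per-frame distance between two atoms or mass centers
#'
#' @param series a `coord_series`.
#' @param selA,selB atom selections; in `"atom"` mode both must select a
#'   single atom; in `"com"` mode the mass-weighted center of each group is
#'   used.
#' @param mode `"atom"` or `"com"`.
#' @param label label for the resulting series.
#' @return a [scalar_series()] of distances in Angstrom.
#' @export
distance_series <- function(series, selA, selB, mode = c("atom", "com"),
                            label = NULL) {
  mode <- match.arg(mode)
  selA <- as_selection(selA, series)
  selB <- as_selection(selB, series)
  if (length(selA) == 0 || length(selB) == 0) {
    abort_allokin("empty selection", "allokin_invalid_selection")
  }
  if (mode == "atom" && (length(selA) != 1 || length(selB) != 1)) {
    abort_allokin("atom-atom mode requires single-atom selections",
                  "allokin_invalid_selection")
  }
  a <- group_com(series, selA, mass_weighted = (mode == "com"))
  b <- group_com(series, selB, mass_weighted = (mode == "com"))
  d <- sqrt(rowSums((a - b)^2))
  scalar_series(d, dt = series$dt,
                label = label %||% sprintf("distance_%s [A]", mode))
}

#' Label salt-bridge formed/broken states from a distance series
#'
#' A frame is labeled `formed` when the donor-acceptor distance is below
#' the threshold (default 5 Angstrom, the conventional salt-bridge
#' criterion for e.g. an Arg guanidinium to Asp carboxylate contact).
#'
#' @param x a `scalar_series` of distances in Angstrom.
#' @param threshold distance threshold in Angstrom.
#' @return factor with levels `formed`, `broken`, one per frame.
#' @export
salt_bridge_states <- function(x, threshold = 5.0) {
  v <- if (inherits(x, "scalar_series")) x$value else as.numeric(x)
  factor(ifelse(v < threshold, "formed", "broken"),
         levels = c("formed", "broken"))
}

#' Restrict a trajectory to a subset of atoms
#'
#' @param series a `coord_series`.
#' @param keep atoms to retain (an `atom_selection` or integer indices).
#' @return the stripped `coord_series`; original residue numbering is
#'   preserved in the topology and the selection recorded in provenance.
#' @export
strip_series <- function(series, keep) {
  sel <- as_selection(keep, series)
  if (length(sel) == 0) {
    abort_allokin("strip would remove every atom", "allokin_invalid_selection")
  }
  top <- series$topology[sel, , drop = FALSE]
  top$eleno <- seq_len(nrow(top))
  rownames(top) <- NULL
  coord_series(series$coords[, sel, , drop = FALSE], top, dt = series$dt,
               fitted = series$fitted,
               provenance = c(series$provenance,
                              sprintf("strip[%s]", attr(sel, "provenance"))))
}
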