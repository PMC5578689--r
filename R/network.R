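# Residue correlation/contact networks and current-flow betweenness
# scoring of allosteric communication, with suboptimal sub-network
# extraction.
#
# The model: treat the residue contact network as a network of electrical
# resistors, each edge's resistance the reciprocal of the absolute
# fluctuation correlation between its endpoints. Driving one unit of
# current from a set of source residues to a set of target residues, the
# current an edge carries ranks its importance for transmitting motion
# between the two sites. Potentials come from the Moore-Penrose
# pseudoinverse of the weighted graph Laplacian (computed densely; these
# networks are small, typically well under 500 nodes).

#' Residue fluctuation correlation matrix
#'
#' Pearson correlation of displacement vectors: `C_ij = <dr_i . dr_j> /
#' sqrt(<|dr_i|^2> <|dr_j|^2>)` over the selected atoms' (default one CA
#' per residue) displacements from their interval mean.
#'
#' @param series a fitted `coord_series`.
#' @param frame_interval 0-based half-open `c(start, end)` or `NULL`.
#' @param selection one atom per residue (default atoms named `CA`).
#' @return `n x n` matrix with unit diagonal; rows/columns named by
#'   residue number. Zero-variance residues get zero off-diagonals with a
#'   warning.
#' @export
correlation_matrix <- function(series, frame_interval = NULL,
                               selection = NULL) {
  if (is.null(selection)) {
    selection <- select_atoms(series, name = "CA")
    if (length(selection) == 0) {
      selection <- select_atoms(series, indices = seq_len(n_atoms(series)))
    }
  }
  sel <- as_selection(selection, series)
  frames <- interval_frames(frame_interval, n_frames(series))
  if (length(frames) < 2) {
    abort_allokin("need at least 2 frames", "allokin_invalid_spec")
  }
  n <- length(sel)
  G <- matrix(0, n, n)
  for (d in 1:3) {
    Xd <- series$coords[frames, sel, d, drop = FALSE][, , 1]
    Xd <- matrix(Xd, length(frames), n)
    Xd <- sweep(Xd, 2, colMeans(Xd))
    G <- G + crossprod(Xd)
  }
  G <- G / length(frames)
  v <- diag(G)
  zero <- v <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance residues; their correlations set to 0",
                    sum(zero)))
    v[zero] <- 1
  }
  C <- G / sqrt(outer(v, v))
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  dimnames(C) <- list(series$topology$resno[sel], series$topology$resno[sel])
  C
}

#' Residue contact map from heavy-atom distances
#'
#' Residues `i`, `j` with `|i - j| > exclude_neighbors` are in contact
#' when any heavy-atom pair is within `cutoff` in at least an `occupancy`
#' fraction of the analyzed frames (the established dynamical-network
#' convention: 4.5 Angstrom, 75 percent).
#'
#' @param series a `coord_series`.
#' @param cutoff heavy-atom distance cutoff, Angstrom.
#' @param occupancy minimum fraction of frames in contact.
#' @param exclude_neighbors sequence-neighbor exclusion span (1 = skip
#'   adjacent residues).
#' @param frame_stride analyze every `frame_stride`-th frame.
#' @return symmetric logical `n x n` matrix (zero diagonal) with
#'   attributes `cutoff` and `occupancy`; residue numbers as dimnames.
#' @export
contact_map <- function(series, cutoff = 4.5, occupancy = 0.75,
                        exclude_neighbors = 1, frame_stride = 1) {
  top <- series$topology
  heavy <- which(toupper(top$element) != "H")
  rid_all <- paste(top$chain, top$resno)
  rids <- unique(rid_all)
  n <- length(rids)
  atom_groups <- lapply(rids, function(r) intersect(heavy, which(rid_all == r)))
  resno <- vapply(rids, function(r) top$resno[rid_all == r][1], numeric(1))
  frames <- seq(1, n_frames(series), by = frame_stride)
  nf <- length(frames)
  M <- matrix(FALSE, n, n)
  cut2 <- cutoff^2
  for (i in seq_len(n - 1)) {
    gi <- atom_groups[[i]]
    if (length(gi) == 0) next
    for (j in seq(i + 1, n)) {
      if (abs(resno[j] - resno[i]) <= exclude_neighbors) next
      gj <- atom_groups[[j]]
      if (length(gj) == 0) next
      within <- rep(FALSE, nf)
      for (a in gi) {
        for (b in gj) {
          d2 <- (series$coords[frames, a, 1] - series$coords[frames, b, 1])^2 +
            (series$coords[frames, a, 2] - series$coords[frames, b, 2])^2 +
            (series$coords[frames, a, 3] - series$coords[frames, b, 3])^2
          within <- within | (d2 <= cut2)
          if (all(within)) break
        }
        if (all(within)) break
      }
      M[i, j] <- M[j, i] <- mean(within) >= occupancy
    }
  }
  dimnames(M) <- list(resno, resno)
  attr(M, "cutoff") <- cutoff
  attr(M, "occupancy") <- occupancy
  M
}

#' Build the correlation-resistance residue graph
#'
#' Edges are the contact pairs; each edge's conductance is the absolute
#' correlation `|C_ij|` (resistance `1/|C_ij|`). Edges whose correlation
#' magnitude falls below `floor` carry essentially no signal and are
#' dropped with a warning.
#'
#' @param C correlation matrix from [correlation_matrix()].
#' @param contacts logical contact matrix from [contact_map()].
#' @param floor minimum conductance retained.
#' @return an igraph with vertex `name` = residue label and edge
#'   attributes `weight` (conductance), `resistance`, `correlation`.
#' @export
build_graph <- function(C, contacts, floor = 1e-6) {
  if (!all(dim(C) == dim(contacts))) {
    abort_allokin("correlation and contact matrices must agree in size",
                  "allokin_invalid_spec")
  }
  n <- nrow(C)
  labels <- rownames(C) %||% as.character(seq_len(n))
  idx <- which(contacts & upper.tri(contacts), arr.ind = TRUE)
  w <- abs(C[idx])
  drop <- w < floor
  if (any(drop)) {
    warning(sprintf("dropped %d contact edges with |correlation| < %g",
                    sum(drop), floor))
    idx <- idx[!drop, , drop = FALSE]
    w <- w[!drop]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
               weight = w, resistance = 1 / w, correlation = C[idx]),
    directed = FALSE,
    vertices = data.frame(name = labels))
  g
}

#' Moore-Penrose pseudoinverse of the weighted graph Laplacian
#'
#' `L = D - W` on the conductances; the pseudoinverse satisfies the four
#' Penrose conditions (checked in the test suite to 1e-8) and inherits
#' the Laplacian's zero row sums.
#'
#' @param graph an igraph with `weight` edge conductances.
#' @return dense matrix `L+` with the graph's vertex names as dimnames.
#' @export
laplacian_pseudoinverse <- function(graph) {
  W <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = FALSE))
  L <- diag(rowSums(W)) - W
  Lp <- MASS::ginv(L)
  nm <- igraph::vertex_attr(graph, "name") %||%
    as.character(seq_len(igraph::vcount(graph)))
  dimnames(Lp) <- list(nm, nm)
  Lp
}

#' Current-flow betweenness of every edge for a source/target query
#'
#' For each source-target pair `(s, t)`, one unit of current is driven
#' from `s` to `t`; the potential difference across edge `(i, j)` is
#' `L+_{is} + L+_{jt} - L+_{it} - L+_{js}` and the current the edge
#' carries is the conductance times that difference. The edge score is
#' the sum of absolute currents over all pairs in `S x T` (no pair
#' normalization by default; set `normalized = TRUE` to divide by
#' `|S| |T|` for cross-query comparison). Node scores are half the sum of
#' incident edge scores.
#'
#' @param graph an igraph with `weight` conductances.
#' @param S,T source and target vertex names (or indices); must be
#'   disjoint — the score definition assumes distinct source and target
#'   sets.
#' @param normalized divide scores by `|S| |T|`.
#' @return a `betweenness_scores` list: `edges` (data.frame from, to,
#'   weight, correlation, ebtw), `nodes` (data.frame node, score), `S`,
#'   `T`, `normalized`.
#' @export
current_flow_betweenness <- function(graph, S, T, normalized = FALSE) {
  nm <- igraph::vertex_attr(graph, "name") %||%
    as.character(seq_len(igraph::vcount(graph)))
  S <- as.character(S)
  T <- as.character(T)
  if (length(S) == 0 || length(T) == 0) {
    abort_allokin("S and T must be non-empty", "allokin_invalid_spec")
  }
  if (length(intersect(S, T)) > 0) {
    abort_allokin(
      "S and T must be disjoint: the betweenness sum assumes distinct source and target sets",
      "allokin_invalid_spec")
  }
  if (!all(c(S, T) %in% nm)) {
    abort_allokin("S/T contain unknown node names", "allokin_invalid_spec")
  }
  comp <- igraph::components(graph)
  cs <- unique(comp$membership[match(c(S, T), nm)])
  if (length(cs) > 1) {
    abort_allokin("sources and targets lie in different connected components",
                  "allokin_disconnected_graph")
  }
  sub <- igraph::induced_subgraph(graph, which(comp$membership == cs))
  Lp <- laplacian_pseudoinverse(sub)
  el <- igraph::as_edgelist(sub, names = TRUE)
  w <- igraph::E(sub)$weight
  si <- match(S, rownames(Lp))
  ti <- match(T, rownames(Lp))
  i <- match(el[, 1], rownames(Lp))
  j <- match(el[, 2], rownames(Lp))
  score <- numeric(nrow(el))
  for (s in si) {
    for (t in ti) {
      score <- score + abs(Lp[i, s] + Lp[j, t] - Lp[i, t] - Lp[j, s])
    }
  }
  score <- w * score
  if (normalized) score <- score / (length(S) * length(T))
  corr <- igraph::E(sub)$correlation %||% rep(NA_real_, length(w))
  edges <- data.frame(from = el[, 1], to = el[, 2], weight = w,
                      correlation = corr, ebtw = score,
                      stringsAsFactors = FALSE)
  node_score <- vapply(rownames(Lp), function(v) {
    sum(edges$ebtw[edges$from == v | edges$to == v]) / 2
  }, numeric(1))
  structure(list(edges = edges,
                 nodes = data.frame(node = rownames(Lp), score = node_score,
                                    stringsAsFactors = FALSE),
                 S = S, T = T, normalized = normalized),
            class = "betweenness_scores")
}

#' @export
print.betweenness_scores <- function(x, ...) {
  cat(sprintf("<betweenness_scores> %d edges, S={%s}, T={%s}\n",
              nrow(x$edges), paste(x$S, collapse = ","),
              paste(x$T, collapse = ",")))
  top <- x$edges[order(-x$edges$ebtw), ][seq_len(min(5, nrow(x$edges))), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Extract the optimal and suboptimal transmission sub-network
#'
#' Each edge gets a length `1 / (ebtw + epsilon)` (high-current edges are
#' short). The optimal path is the shortest S-to-T path under these
#' lengths; an edge joins the sub-network when the shortest S-to-T path
#' constrained to pass through it is at most `(1 + tolerance)` times the
#' optimal length (default 20 percent).
#'
#' @param graph the scored igraph (same vertex set as `scores`).
#' @param scores a `betweenness_scores` for the same S/T query.
#' @param tolerance allowed fractional excess over the optimal length.
#' @param epsilon guard added to scores before taking reciprocals.
#' @return a `subnetwork` list: `optimal_path` (vertex names),
#'   `optimal_length`, `edges` (the score table plus `in_subnetwork`),
#'   `tolerance`.
#' @export
extract_subnetwork <- function(graph, scores, tolerance = 0.20,
                               epsilon = 1e-12) {
  stopifnot(inherits(scores, "betweenness_scores"))
  ed <- scores$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$from, to = ed$to,
               weight = 1 / (ed$ebtw + epsilon)),
    directed = FALSE)
  nm <- igraph::V(g)$name
  S <- intersect(scores$S, nm)
  T <- intersect(scores$T, nm)
  dS <- igraph::distances(g, v = S, weights = igraph::E(g)$weight)
  dT <- igraph::distances(g, v = T, weights = igraph::E(g)$weight)
  best <- Inf
  best_pair <- NULL
  for (s in S) {
    for (t in T) {
      d <- dS[s, t]
      if (d < best) {
        best <- d
        best_pair <- c(s, t)
      }
    }
  }
  if (!is.finite(best)) {
    abort_allokin("no path between sources and targets",
                  "allokin_disconnected_graph")
  }
  sp <- igraph::shortest_paths(g, from = best_pair[1], to = best_pair[2],
                               weights = igraph::E(g)$weight)$vpath[[1]]
  # constrained-through-edge length: best of entering at either endpoint
  i <- match(ed$from, nm)
  j <- match(ed$to, nm)
  len <- 1 / (ed$ebtw + epsilon)
  dS_i <- apply(dS[, i, drop = FALSE], 2, min)
  dS_j <- apply(dS[, j, drop = FALSE], 2, min)
  dT_i <- apply(dT[, i, drop = FALSE], 2, min)
  dT_j <- apply(dT[, j, drop = FALSE], 2, min)
  through <- pmin(dS_i + len + dT_j, dS_j + len + dT_i)
  ed$constrained_length <- through
  ed$in_subnetwork <- through <= (1 + tolerance) * best + 1e-12 * best
  structure(list(optimal_path = igraph::as_ids(sp), optimal_length = best,
                 edges = ed, tolerance = tolerance),
            class = "subnetwork")
}

#' Export a scored network as an edge-list CSV (and optionally GraphML)
#'
#' @param scores a `betweenness_scores`.
#' @param path CSV output path.
#' @param subnetwork optional `subnetwork` whose membership column to
#'   include.
#' @param graphml_path optional GraphML output path.
#' @export
write_network_csv <- function(scores, path, subnetwork = NULL,
                              graphml_path = NULL) {
  ed <- scores$edges
  if (!is.null(subnetwork)) {
    key <- paste(ed$from, ed$to)
    sub_key <- paste(subnetwork$edges$from, subnetwork$edges$to)
    ed$in_subnetwork <- subnetwork$edges$in_subnetwork[match(key, sub_key)]
  }
  utils::write.csv(ed, path, row.names = FALSE, quote = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}
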