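# Correlation/contact networks and current-flow betweenness.

test_that("correlation matrix has unit diagonal and tracks planted streams", {
  set.seed(1)
  arr <- array(0, c(2000, 4, 3))
  base <- matrix(rnorm(2000 * 3), 2000, 3)
  arr[, 1, ] <- base
  arr[, 2, ] <- base          # identical stream
  arr[, 3, ] <- -base         # negated stream
  arr[, 4, ] <- matrix(rnorm(2000 * 3), 2000, 3)
  cs <- coord_series(arr, ca_topology(4), dt = 1, fitted = TRUE)
  C <- correlation_matrix(cs)
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_equal(C[1, 3], -1, tolerance = 1e-12)
  expect_lt(abs(C[1, 4]), 0.1)

  # zero-variance residue: zeroed off-diagonals with a warning
  arr0 <- arr
  arr0[, 4, ] <- 0
  cs0 <- coord_series(arr0, ca_topology(4), dt = 1, fitted = TRUE)
  expect_warning(C0 <- correlation_matrix(cs0), "zero-variance")
  expect_equal(C0[4, 1:3], rep(0, 3), ignore_attr = TRUE)
  expect_equal(C0[4, 4], 1)
})

test_that("contact map applies cutoff, occupancy and neighbor exclusion", {
  mk <- function(dists) {
    nf <- length(dists)
    arr <- array(0, c(nf, 2, 3))
    arr[, 2, 1] <- dists
    top <- make_topology(c("CA", "CA"), resno = c(1, 3))
    coord_series(arr, top, dt = 1)
  }
  expect_true(contact_map(mk(rep(4.0, 8)))[1, 2])
  expect_false(contact_map(mk(rep(5.0, 8)))[1, 2])
  # in contact exactly half the frames with 75% occupancy required
  expect_false(contact_map(mk(rep(c(4.0, 6.0), 4)))[1, 2])
  expect_true(contact_map(mk(rep(c(4.0, 6.0), 4)), occupancy = 0.5)[1, 2])

  # sequence-adjacent residues are excluded regardless of distance
  adj <- mk(rep(4.0, 4))
  adj$topology$resno <- c(1, 2)
  expect_false(contact_map(adj)[1, 2])
})

test_that("graph construction maps correlations to conductances with a floor", {
  C <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3)
  contacts <- matrix(c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                       FALSE, TRUE, FALSE), 3)
  dimnames(C) <- dimnames(contacts) <- list(1:3, 1:3)
  g <- build_graph(C, contacts)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::E(g)$resistance, c(1, 1))

  C2 <- C
  C2[1, 2] <- C2[2, 1] <- 0 # dead edge drops out
  expect_warning(g2 <- build_graph(C2, contacts), "dropped")
  expect_equal(igraph::ecount(g2), 1)
})

test_that("Laplacian pseudoinverse satisfies the Penrose conditions", {
  # K2 closed form
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  igraph::E(g2)$weight <- 0.5
  igraph::V(g2)$name <- c("a", "b")
  Lp <- laplacian_pseudoinverse(g2)
  expect_equal(Lp, matrix(c(1, -1, -1, 1), 2) / (4 * 0.5),
               ignore_attr = TRUE, tolerance = 1e-10)

  for (s in 1:20) {
    r <- gen_resistor_graph(resistor_graph_spec("random", n = 8,
                                                weights = c(0.2, 2),
                                                seed = s))
    W <- as.matrix(igraph::as_adjacency_matrix(r$graph, attr = "weight",
                                               sparse = FALSE))
    L <- diag(rowSums(W)) - W
    Lp <- laplacian_pseudoinverse(r$graph)
    expect_lt(max(abs(L %*% Lp %*% L - L)), 1e-8)
    expect_lt(max(abs(Lp %*% L %*% Lp - Lp)), 1e-8)
    expect_lt(max(abs(L %*% Lp - t(L %*% Lp))), 1e-8)
    expect_lt(max(abs(Lp %*% L - t(Lp %*% L))), 1e-8)
    expect_lt(max(abs(rowSums(L))), 1e-8)
    expect_lt(max(abs(rowSums(Lp))), 1e-8)
  }
})

test_that("current-flow betweenness equals resistor currents and closed forms", {
  # series path: every edge carries the unit current
  p <- gen_resistor_graph(resistor_graph_spec("path", n = 3))
  sc <- current_flow_betweenness(p$graph, "1", "3")
  expect_equal(sc$edges$ebtw, c(1, 1), tolerance = 1e-12)

  # symmetric diamond: every edge carries half
  d <- gen_resistor_graph(resistor_graph_spec("diamond"))
  scd <- current_flow_betweenness(d$graph, "1", "4")
  expect_equal(scd$edges$ebtw, rep(0.5, 4), tolerance = 1e-12)

  # random weighted graphs against the independent nodal oracle
  for (n in c(8, 12)) {
    for (s in 1:5) {
      r <- gen_resistor_graph(resistor_graph_spec("random", n = n,
                                                  weights = c(0.3, 1.8),
                                                  seed = 100 * n + s))
      sc <- current_flow_betweenness(r$graph, r$source, r$target)
      ora <- oracle_currents(r$graph, as.integer(r$source),
                             as.integer(r$target))
      expect_lt(max(abs(sc$edges$ebtw - ora)), 1e-10)
    }
  }

  # overlapping S and T violate the distinctness assumption
  expect_error(current_flow_betweenness(p$graph, "1", c("1", "3")),
               class = "allokin_invalid_spec",
               regexp = "distinct")
})

test_that("betweenness is conductance-scale-free and |S||T| on bridges", {
  r <- gen_resistor_graph(resistor_graph_spec("ladder", n = 4,
                                              weights = c(0.5, 1.5),
                                              seed = 3))
  sc1 <- current_flow_betweenness(r$graph, r$source, r$target)
  g10 <- r$graph
  igraph::E(g10)$weight <- igraph::E(g10)$weight * 10
  sc10 <- current_flow_betweenness(g10, r$source, r$target)
  expect_equal(sc10$edges$ebtw, sc1$edges$ebtw, tolerance = 1e-10)

  # barbell: two triangles joined by one bridge; every s-t pair's unit
  # current crosses it, so the bridge scores |S| * |T| = 4
  el <- rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(5, 6),
              c(4, 6))
  gb <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(gb)$weight <- runif(7, 0.5, 2)
  igraph::V(gb)$name <- as.character(1:6)
  scb <- current_flow_betweenness(gb, S = c("1", "2"), T = c("5", "6"))
  bridge <- scb$edges$ebtw[(scb$edges$from == "3" & scb$edges$to == "4") |
                             (scb$edges$from == "4" & scb$edges$to == "3")]
  expect_equal(bridge, 4, tolerance = 1e-10)

  # normalized variant divides by |S||T|
  scn <- current_flow_betweenness(gb, S = c("1", "2"), T = c("5", "6"),
                                  normalized = TRUE)
  expect_equal(scn$edges$ebtw, scb$edges$ebtw / 4, tolerance = 1e-12)
})

test_that("sub-network extraction honors the path-length tolerance", {
  # two parallel two-edge branches with controlled lengths
  mk_scores <- function(e_fast, e_slow) {
    edges <- data.frame(
      from = c("s", "a", "s", "b"), to = c("a", "t", "b", "t"),
      weight = 1, correlation = 1,
      ebtw = c(e_fast, e_fast, e_slow, e_slow))
    structure(list(edges = edges, S = "s", T = "t", normalized = FALSE),
              class = "betweenness_scores")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("s", "a", "s", "b"), to = c("a", "t", "b", "t")),
    directed = FALSE)

  # branch lengths 10 and 11.5 (ratio 1.15): both survive at 20%
  sub <- extract_subnetwork(g, mk_scores(1 / 5, 1 / 5.75))
  expect_true(all(sub$edges$in_subnetwork))
  expect_equal(sub$optimal_length, 10, tolerance = 1e-6)

  # branch lengths 10 and 13 (ratio 1.3): slow branch is cut
  sub2 <- extract_subnetwork(g, mk_scores(1 / 5, 1 / 6.5))
  expect_equal(sub2$edges$in_subnetwork, c(TRUE, TRUE, FALSE, FALSE))

  # zero tolerance keeps exactly the optimal path
  sub0 <- extract_subnetwork(g, mk_scores(1 / 5, 1 / 5.75), tolerance = 0)
  expect_equal(sub0$edges$in_subnetwork, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sub0$optimal_path, c("s", "a", "t"))

  # unique-path graph: the path is the sub-network at any tolerance
  pg <- gen_resistor_graph(resistor_graph_spec("path", n = 4))
  psc <- current_flow_betweenness(pg$graph, "1", "4")
  for (tol in c(0, 0.2, 5)) {
    ps <- extract_subnetwork(pg$graph, psc, tolerance = tol)
    expect_true(all(ps$edges$in_subnetwork))
    expect_equal(ps$optimal_path, as.character(1:4))
  }

  # monotone growth of the included edge set with tolerance
  r <- gen_resistor_graph(resistor_graph_spec("random", n = 10,
                                              weights = c(0.3, 1.5),
                                              seed = 8))
  rsc <- current_flow_betweenness(r$graph, r$source, r$target)
  sets <- lapply(c(0, 0.1, 0.2, 0.5), function(tol) {
    which(extract_subnetwork(r$graph, rsc, tolerance = tol)$edges$in_subnetwork)
  })
  for (i in 2:4) expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("disconnected source/target queries fail loudly", {
  g <- igraph::graph_from_edgelist(rbind(c(1, 2), c(3, 4)),
                                   directed = FALSE)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- as.character(1:4)
  expect_error(current_flow_betweenness(g, "1", "4"),
               class = "allokin_disconnected_graph")
})
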