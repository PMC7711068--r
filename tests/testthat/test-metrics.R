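# Node-, edge- and network-level metrics against hand calculations and the
# brute-force all-shortest-paths oracle.

path3 <- matrix(c(0, 1, 0,
                  1, 0, 1,
                  0, 1, 0), 3, 3)
triangle <- matrix(1, 3, 3) - diag(3)
star4 <- rbind(c(0, 1, 1, 1, 1),
               c(1, 0, 0, 0, 0),
               c(1, 0, 0, 0, 0),
               c(1, 0, 0, 0, 0),
               c(1, 0, 0, 0, 0))
p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
k4 <- matrix(1, 4, 4) - diag(4)
two_dyads <- matrix(0, 4, 4); two_dyads[1, 2] <- two_dyads[2, 1] <- 1
two_dyads[3, 4] <- two_dyads[4, 3] <- 1

test_that("hand-computed node metrics on canonical small graphs", {
  nm <- node_metrics(graph_as_aan(path3))
  expect_equal(nm$degree, c(1, 2, 1))
  expect_equal(nm$betweenness, c(0, 1, 0))
  nm_tri <- node_metrics(graph_as_aan(triangle))
  expect_equal(nm_tri$transitivity, rep(1, 3))
  nm_star <- node_metrics(graph_as_aan(star4))
  expect_equal(nm_star$closeness[1], 1)             # 4 reachable / distance 4
  expect_equal(nm_star$closeness[2], 4 / 7)         # 1/(7/4)
  expect_equal(nm_star$avg_shortest_path[2], 7 / 4)
})

test_that("hand-computed network metrics", {
  nm_k4 <- network_metrics(graph_as_aan(k4))
  expect_equal(nm_k4$density, 1.0)
  expect_equal(nm_k4$diameter, 1)
  expect_equal(nm_k4$L_net, 1.0)
  nm_p4 <- network_metrics(graph_as_aan(p4))
  expect_equal(nm_p4$diameter, 3)
  expect_equal(nm_p4$density, 0.5)
  expect_equal(nm_p4$L_net, 10 / 6)
  # disconnected: connected pairs only
  nm_dy <- network_metrics(graph_as_aan(two_dyads))
  expect_equal(nm_dy$L_net, 1)
  expect_equal(nm_dy$diameter, 1)
})

test_that("a bridge between two triangles has maximal edge betweenness", {
  am <- matrix(0, 6, 6)
  am[1, 2] <- am[2, 3] <- am[1, 3] <- 1       # triangle 1-2-3
  am[4, 5] <- am[5, 6] <- am[4, 6] <- 1       # triangle 4-5-6
  am[3, 4] <- 1                               # bridge
  am <- pmax(am, t(am))
  net <- graph_as_aan(am)
  em <- edge_metrics(net)
  bridge <- em$node_i == "A:3" & em$node_j == "A:4"
  expect_true(all(em$edge_betweenness[bridge] >
                    em$edge_betweenness[!bridge]))
  # and matches the oracle exactly
  o <- oracle_metrics(am)
  expect_equal(em$edge_betweenness, o$edge_betweenness, tolerance = 1e-12)
})

test_that("long-range labels follow sequence separation and chain identity", {
  nodes <- data.frame(node_id = c("A:5", "A:7", "A:30", "B:2"),
                      label = "ALA", chain = c("A", "A", "A", "B"),
                      resno = c(5, 7, 30, 2), icode = "",
                      node_kind = "amino_acid", ss = "coil",
                      stringsAsFactors = FALSE)
  edges <- data.frame(i = c(1, 1, 1), j = c(2, 3, 4),
                      energy = NA_real_, distance = NA_real_, weight = 1,
                      long_range = FALSE)
  net <- aanet:::.make_aan("CALPHA", nodes, edges, params = list())
  em <- edge_metrics(net, lr_sep = 12)
  lr <- stats::setNames(em$long_range, paste(em$node_i, em$node_j))
  expect_false(lr[["A:5 A:7"]])    # |dseq| = 2
  expect_true(lr[["A:5 A:30"]])    # |dseq| = 25 >= 12
  expect_true(lr[["A:5 B:2"]])     # different chains
})

test_that("weighted degree sums neighbour weights", {
  am <- matrix(0, 3, 3); am[1, 2] <- am[2, 1] <- am[1, 3] <- am[3, 1] <- 1
  net <- graph_as_aan(am, "NACEN", node_weights = c(1, 2, 3))
  wm <- node_weighted_metrics(net)
  expect_equal(wm$weighted_degree, c(5, 1, 1))
  expect_error(node_weighted_metrics(graph_as_aan(am, "NACEN",
                                                  node_weights = c(1, -2, 3))),
               "contract violation")
})

test_that("uniform node weights reproduce unweighted centralities", {
  set.seed(11)
  for (k in 1:5) {
    am <- random_adjacency(8, 0.4)
    net_u <- graph_as_aan(am)
    net_w <- graph_as_aan(am, "NACEN", node_weights = rep(1, 8))
    nm <- node_metrics(net_u)
    wm <- node_weighted_metrics(net_w)
    expect_equal(wm$weighted_betweenness, nm$betweenness, tolerance = 1e-9)
    expect_equal(wm$weighted_closeness, nm$closeness, tolerance = 1e-9)
    # a uniform weight w != 1 still preserves rankings
    net_w2 <- graph_as_aan(am, "NACEN", node_weights = rep(2.5, 8))
    wm2 <- node_weighted_metrics(net_w2)
    expect_identical(rank(-wm2$weighted_closeness), rank(-nm$closeness))
    expect_equal(wm2$weighted_betweenness, nm$betweenness, tolerance = 1e-9)
  }
})

test_that("node-weighted path metrics match the oracle on l = (w_i + w_j)/2", {
  set.seed(21)
  for (k in 1:5) {
    n <- 7
    am <- random_adjacency(n, 0.45)
    w <- stats::runif(n, 0.5, 3)
    net <- graph_as_aan(am, "NACEN", node_weights = w)
    wm <- node_weighted_metrics(net)
    lengths <- (outer(w, w, "+") / 2)
    o <- oracle_metrics(am, lengths = lengths)
    expect_equal(wm$weighted_betweenness, o$betweenness, tolerance = 1e-9)
    expect_equal(wm$weighted_closeness, o$closeness, tolerance = 1e-9)
  }
})

test_that("EACEN path metrics use length 1/w and match the oracle", {
  set.seed(31)
  for (k in 1:5) {
    n <- 7
    am <- random_adjacency(n, 0.45)
    wts <- am
    wts[am != 0] <- 0
    idx <- which(upper.tri(am) & am != 0, arr.ind = TRUE)
    vals <- stats::runif(nrow(idx), 0.1, 1)
    wts[idx] <- vals
    wts[idx[, 2:1, drop = FALSE]] <- vals
    net <- graph_as_aan(wts, "EACEN")
    nm <- node_metrics(net)
    em <- edge_metrics(net)
    o <- oracle_metrics(wts, lengths = ifelse(wts != 0, 1 / wts, Inf))
    expect_equal(nm$betweenness, o$betweenness, tolerance = 1e-9)
    expect_equal(nm$closeness, o$closeness, tolerance = 1e-9)
    # align oracle edge order (column-major) with the package's (i, j) sort
    ord <- order(o$edges[, 1], o$edges[, 2])
    expect_equal(em$edge_betweenness, o$edge_betweenness[ord],
                 tolerance = 1e-9)
  }
})

test_that("metrics are invariant under node relabelling", {
  set.seed(41)
  am <- random_adjacency(9, 0.35)
  perm <- sample(9)
  am_p <- am[perm, perm]
  nm <- node_metrics(graph_as_aan(am))
  nm_p <- node_metrics(graph_as_aan(am_p))
  # row i of the permuted graph is row perm[i] of the original
  for (col in c("degree", "betweenness", "closeness", "transitivity")) {
    expect_equal(nm_p[[col]], nm[[col]][perm], tolerance = 1e-12)
  }
  expect_equal(network_metrics(graph_as_aan(am)),
               network_metrics(graph_as_aan(am_p)))
})

test_that("degree sum and density identities hold on generated fixtures", {
  set.seed(51)
  for (k in 1:10) {
    am <- random_adjacency(5 + k %% 6, 0.4)
    net <- graph_as_aan(am)
    nm <- node_metrics(net)
    row <- network_metrics(net)
    expect_equal(sum(nm$degree), 2 * row$m)
    expect_equal(row$density, 2 * row$m / (row$n * (row$n - 1)))
  }
})

test_that("NACEN metrics report includes the weighted columns and conventions", {
  s <- parse_structure(make_peptide("helix_peptide", 10))
  net <- build_nacen(s, make_toy_energy_table(5), weight_mode = "polarity")
  rep <- metrics_report(net)
  expect_true(all(c("weighted_degree", "weighted_betweenness",
                    "weighted_closeness") %in% names(rep$node_table)))
  expect_identical(nrow(rep$node_table), nrow(net$nodes))
  expect_identical(nrow(rep$edge_table), nrow(net$edges))
  expect_match(rep$conventions[["weighted_length"]], "w_i \\+ w_j")
  expect_true(rep$network_row$density >= 0 && rep$network_row$density <= 1)
})
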