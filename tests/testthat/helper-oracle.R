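# Brute-force all-pairs shortest-path oracle, independent of igraph: plain
# Dijkstra with shortest-path counting on an adjacency matrix. Used to check
# every centrality the package reports.

# dist + path-count vectors from one source over a symmetric length matrix
# (len[i,j] = edge length, Inf = no edge)
.oracle_sssp <- function(len, s, eps = 1e-10) {
  n <- nrow(len)
  d <- rep(Inf, n)
  sigma <- rep(0, n)
  d[s] <- 0
  sigma[s] <- 1
  done <- rep(FALSE, n)
  for (k in seq_len(n)) {
    cand <- which(!done & is.finite(d))
    if (length(cand) == 0) break
    u <- cand[which.min(d[cand])]
    done[u] <- TRUE
    for (v in which(is.finite(len[u, ]))) {
      nd <- d[u] + len[u, v]
      if (nd < d[v] - eps) {
        d[v] <- nd
        sigma[v] <- sigma[u]
      } else if (abs(nd - d[v]) <= eps && is.finite(d[v])) {
        sigma[v] <- sigma[v] + sigma[u]
      }
    }
  }
  list(d = d, sigma = sigma)
}

# All node/edge/network metrics by enumeration. am: symmetric 0/1 (or
# weight) adjacency; lengths: optional symmetric matrix of edge lengths
# (defaults to 1 per edge).
oracle_metrics <- function(am, lengths = NULL, eps = 1e-10) {
  n <- nrow(am)
  adj <- am != 0
  len <- if (is.null(lengths)) ifelse(adj, 1, Inf) else
    ifelse(adj, lengths, Inf)
  diag(len) <- Inf
  ss <- lapply(seq_len(n), function(s) .oracle_sssp(len, s, eps))
  d <- do.call(rbind, lapply(ss, `[[`, "d"))
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  m <- nrow(edges)

  btw <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (abs(d[s, v] + d[t, v] - d[s, t]) <= eps &&
          is.finite(d[s, v]) && is.finite(d[t, v])) {
        btw[v] <- btw[v] +
          ss[[s]]$sigma[v] * ss[[t]]$sigma[v] / ss[[s]]$sigma[t]
      }
    }
  }

  ebtw <- rep(0, max(m, 0))
  if (m > 0 && n >= 2) {
    for (e in seq_len(m)) {
      u <- edges[e, 1]; v <- edges[e, 2]
      l_uv <- len[u, v]
      for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (!is.finite(d[s, t])) next
        cnt <- 0
        if (is.finite(d[s, u]) && is.finite(d[t, v]) &&
            abs(d[s, u] + l_uv + d[t, v] - d[s, t]) <= eps) {
          cnt <- cnt + ss[[s]]$sigma[u] * ss[[t]]$sigma[v]
        }
        if (is.finite(d[s, v]) && is.finite(d[t, u]) &&
            abs(d[s, v] + l_uv + d[t, u] - d[s, t]) <= eps) {
          cnt <- cnt + ss[[s]]$sigma[v] * ss[[t]]$sigma[u]
        }
        ebtw[e] <- ebtw[e] + cnt / ss[[s]]$sigma[t]
      }
    }
  }

  dd <- d
  diag(dd) <- NA
  reach <- rowSums(is.finite(dd), na.rm = TRUE)
  total <- rowSums(ifelse(is.finite(dd), dd, 0), na.rm = TRUE)
  closeness <- ifelse(reach > 0 & total > 0, reach / total, 0)
  avg <- ifelse(reach > 0, total / reach, NA_real_)

  trans <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb][upper.tri(adj[nb, nb])])
    links / (k * (k - 1) / 2)
  }, 0)

  finite_pairs <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  list(degree = rowSums(adj),
       betweenness = btw,
       closeness = closeness,
       avg_shortest_path = avg,
       transitivity = trans,
       edge_betweenness = ebtw,
       edges = edges,
       n = n, m = m,
       L_net = if (m > 0 && length(finite_pairs) > 0) mean(finite_pairs)
               else NA_real_,
       density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
       diameter = if (m > 0 && length(finite_pairs) > 0) max(finite_pairs)
                  else 0)
}

# Wrap an arbitrary symmetric adjacency/weight matrix as an aan object so
# package metrics can run on it (one pseudo-chain, sequential residues).
graph_as_aan <- function(am, model_type = "AACEN", node_weights = NULL) {
  n <- nrow(am)
  nodes <- data.frame(node_id = paste0("A:", seq_len(n)),
                      label = rep("ALA", n), chain = rep("A", n),
                      resno = seq_len(n), icode = rep("", n),
                      node_kind = rep("amino_acid", n),
                      ss = rep("coil", n), stringsAsFactors = FALSE)
  if (!is.null(node_weights)) nodes$weight <- node_weights
  idx <- which(upper.tri(am) & am != 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      energy = rep(NA_real_, nrow(idx)),
                      distance = rep(NA_real_, nrow(idx)),
                      weight = am[idx],
                      long_range = rep(FALSE, nrow(idx)))
  aanet:::.make_aan(model_type, nodes, edges, params = list())
}

# deterministic random symmetric 0/1 adjacency
random_adjacency <- function(n, p = 0.35) {
  am <- matrix(0, n, n)
  up <- which(upper.tri(am))
  am[up] <- as.numeric(stats::runif(length(up)) < p)
  am + t(am)
}

# all 2^(n(n-1)/2) labelled graphs on n nodes
all_adjacencies <- function(n) {
  k <- n * (n - 1) / 2
  lapply(seq_len(2^k) - 1, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(k)]
    am <- matrix(0, n, n)
    am[upper.tri(am)] <- bits
    am + t(am)
  })
}

# write fixture PDB text to a temp file
tmp_pdb <- function(text) {
  f <- tempfile(fileext = ".pdb")
  writeLines(strsplit(text, "\n", fixed = TRUE)[[1]], f)
  f
}
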