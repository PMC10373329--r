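# Graph fixtures and independent brute-force oracles.

# build a molgraph directly from an edge list (all carbon, non-aromatic)
make_molgraph <- function(n, edges, symbol = rep("C", n), aromatic = rep(FALSE, n)) {
  ed <- if (length(edges)) {
    data.frame(u = pmin(edges[, 1], edges[, 2]),
               v = pmax(edges[, 1], edges[, 2]), order = 1)
  } else {
    data.frame(u = integer(0), v = integer(0), order = numeric(0))
  }
  structure(list(n = n, symbol = symbol, aromatic = aromatic, edges = ed),
            class = "molgraph")
}

adj_from_molgraph <- function(g) {
  adj <- vector("list", g$n)
  for (i in seq_len(nrow(g$edges))) {
    u <- g$edges$u[i]; v <- g$edges$v[i]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

# oracle: exhaustive DFS enumeration of simple paths of exactly `len` edges
oracle_path_count <- function(g, v, len) {
  adj <- adj_from_molgraph(g)
  count <- 0L
  walk <- function(current, visited, depth) {
    if (depth == len) {
      count <<- count + 1L
      return(invisible())
    }
    for (w in adj[[current]]) {
      if (!w %in% visited) walk(w, c(visited, w), depth + 1L)
    }
  }
  walk(v, v, 0L)
  count
}

# oracle: Morgan EC of order k as A^k %*% degree (matrix-power route)
oracle_morgan_ec <- function(g, order) {
  A <- matrix(0L, g$n, g$n)
  for (i in seq_len(nrow(g$edges))) {
    A[g$edges$u[i], g$edges$v[i]] <- 1L
    A[g$edges$v[i], g$edges$u[i]] <- 1L
  }
  ec <- rowSums(A)
  M <- diag(g$n)
  for (k in seq_len(order)) M <- M %*% A
  as.integer(round(M %*% ec))
}

graph_is_connected <- function(n, edges) {
  if (n == 1) return(TRUE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  seen <- rep(FALSE, n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# every labelled graph on n vertices (n small), connected ones only
all_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    edges <- pairs[sel, , drop = FALSE]
    if (graph_is_connected(n, edges)) {
      out[[length(out) + 1L]] <- make_molgraph(n, edges)
    }
  }
  out
}

random_connected_graph <- function(n) {
  repeat {
    pairs <- t(utils::combn(n, 2))
    sel <- stats::runif(nrow(pairs)) < 0.4
    # always keep a random spanning tree to help connectivity
    perm <- sample(n)
    tree <- cbind(perm[-1], perm[vapply(2:n, function(i) sample(i - 1, 1), 1L)])
    edges <- unique(rbind(pairs[sel, , drop = FALSE],
                          cbind(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))))
    if (graph_is_connected(n, edges)) return(make_molgraph(n, edges))
  }
}

benzene <- function() build_graph("c1ccccc1")
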