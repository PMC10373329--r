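# Hydrogen-suppressed molecular graph and its vertex invariants.
#
# Graph-side attribute keys (element-tagged; aromatic atoms keep their
# lowercase symbol):
#   EC:<sym>|1=<v>, EC:<sym>|2=<v>         Morgan extended connectivity
#   PT:<sym>|2=<v>, PT:<sym>|3=<v>         simple-path counts from the vertex
#   SHELL:<sym>|2=<v>, SHELL:<sym>|3=<v>   vertices at exact distance 2 / 3
#   COMBO:<sym>|ec1+2=, ec1-2=, pt2+3=, pt2-3=, s2+3=, s2-3=
#                                          sums and absolute differences
#   RING:<size>|ar=<0/1>|het=<0/1>|n=<k>   SSSR ring classes (sizes 5 and 6)

#' Build the hydrogen-suppressed molecular graph from SMILES
#'
#' A minimal parser for the supported dialect: atoms become vertices in
#' token order; branches, ring closures and explicit `-`/`=`/`#` bonds
#' become edges; an implicit bond between two aromatic (lowercase) atoms is
#' flagged aromatic. Stereo markers (`@`) do not affect the graph.
#'
#' @param smiles A single SMILES string.
#' @return A `molgraph`: list with `n`, `symbol` (per-vertex token, case
#'   preserved), `aromatic` (logical), and `edges` (data frame `u`, `v`,
#'   `order` where order is `1`, `2`, `3` or `1.5` for aromatic).
#' @export
build_graph <- function(smiles) {
  tokens <- tokenize_smiles(smiles)
  atom <- is_atom_token(tokens)
  n <- sum(atom)
  if (n == 0) stop("SMILES contains no atoms", call. = FALSE)
  symbol <- character(n)
  aromatic <- logical(n)
  eu <- integer(0); ev <- integer(0); eo <- numeric(0)
  add_edge <- function(a, b, ord) {
    if (a == b) stop("self-bond in SMILES", call. = FALSE)
    eu <<- c(eu, min(a, b)); ev <<- c(ev, max(a, b)); eo <<- c(eo, ord)
  }
  bond_order <- function(sym, a, b) {
    if (!is.na(sym)) return(switch(sym, "-" = 1, "=" = 2, "#" = 3))
    if (aromatic[a] && aromatic[b]) 1.5 else 1
  }
  prev <- NA_integer_          # attachment point for the next atom
  stack <- integer(0)          # saved attachment points at '('
  pending <- NA_character_     # explicit bond symbol awaiting its atom
  ring_open <- list()          # digit -> c(vertex, pending bond or NA)
  vi <- 0L
  for (k in seq_along(tokens)) {
    t <- tokens[k]
    if (atom[k]) {
      vi <- vi + 1L
      symbol[vi] <- t
      aromatic[vi] <- t %in% c("b", "c", "n", "o", "p", "s")
      if (!is.na(prev)) add_edge(prev, vi, bond_order(pending, prev, vi))
      pending <- NA_character_
      prev <- vi
    } else if (t == "(") {
      if (is.na(prev)) stop("branch before any atom", call. = FALSE)
      stack <- c(stack, prev)
    } else if (t == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES", call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (t %in% c("-", "=", "#")) {
      pending <- t
    } else if (t == "@") {
      # stereochemistry is outside the graph model
    } else if (t %in% as.character(1:9)) {
      if (is.na(prev)) stop("ring closure before any atom", call. = FALSE)
      if (!is.null(ring_open[[t]])) {
        opener <- ring_open[[t]]
        sym <- if (!is.na(pending)) pending else opener$bond
        add_edge(opener$vertex, prev, bond_order(sym, opener$vertex, prev))
        ring_open[[t]] <- NULL
      } else {
        ring_open[[t]] <- list(vertex = prev, bond = pending)
      }
      pending <- NA_character_
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES", call. = FALSE)
  if (length(ring_open)) {
    stop("unmatched ring-closure digit(s): ",
         paste(names(ring_open), collapse = ", "), call. = FALSE)
  }
  edges <- data.frame(u = eu, v = ev, order = eo)
  if (anyDuplicated(edges[, c("u", "v")])) stop("parallel bond in SMILES", call. = FALSE)
  structure(list(n = n, symbol = symbol, aromatic = aromatic, edges = edges),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("Hydrogen-suppressed graph:", x$n, "atoms,", nrow(x$edges), "bonds\n")
  invisible(x)
}

adjacency_list <- function(graph) {
  adj <- vector("list", graph$n)
  for (i in seq_len(nrow(graph$edges))) {
    u <- graph$edges$u[i]; v <- graph$edges$v[i]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

graph_distances <- function(graph) {
  if (nrow(graph$edges) == 0) {
    d <- matrix(Inf, graph$n, graph$n); diag(d) <- 0
    return(d)
  }
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  g <- igraph::add_edges(g, t(as.matrix(graph$edges[, c("u", "v")])))
  igraph::distances(g)
}

#' Morgan extended connectivity
#'
#' Order 0 is the vertex degree; order k sums the order k-1 values over the
#' neighbours of each vertex.
#'
#' @param graph A `molgraph`.
#' @param order Non-negative integer.
#' @return Integer vector of per-vertex extended connectivities.
#' @export
morgan_ec <- function(graph, order) {
  stopifnot(order >= 0)
  adj <- adjacency_list(graph)
  ec <- vapply(adj, length, integer(1))
  if (order == 0) return(ec)
  for (k in seq_len(order)) {
    ec <- vapply(adj, function(nb) if (length(nb)) sum(ec[nb]) else 0L, integer(1))
  }
  ec
}

#' Simple-path counts from each vertex
#'
#' Number of simple paths (no repeated vertex) of exactly `length` edges
#' starting at each vertex; each distinct vertex sequence counts once.
#'
#' @param graph A `molgraph`.
#' @param length Path length in edges, 2 or 3.
#' @return Integer vector of per-vertex path counts.
#' @export
path_counts <- function(graph, length) {
  stopifnot(length %in% c(2L, 3L))
  adj <- adjacency_list(graph)
  deg <- vapply(adj, base::length, integer(1))
  n <- graph$n
  if (length == 2L) {
    return(vapply(seq_len(n), function(v) {
      if (!deg[v]) return(0L)
      sum(deg[adj[[v]]] - 1L)
    }, integer(1)))
  }
  # length 3: v-u-w-x with all four vertices distinct
  vapply(seq_len(n), function(v) {
    total <- 0L
    for (u in adj[[v]]) {
      for (w in adj[[u]]) {
        if (w == v) next
        # x ranges over neighbours of w other than u, and other than v
        total <- total + deg[w] - 1L - (v %in% adj[[w]])
      }
    }
    total
  }, integer(1))
}

#' Valence shells
#'
#' Number of vertices at shortest-path distance exactly `radius` from each
#' vertex.
#'
#' @param graph A `molgraph`.
#' @param radius Topological distance, typically 2 or 3.
#' @return Integer vector of per-vertex shell sizes.
#' @export
valence_shells <- function(graph, radius) {
  d <- graph_distances(graph)
  as.integer(rowSums(d == radius))
}

# Smallest set of smallest rings: shortest cycle through every edge,
# then a greedy independent subset of the cycle space over GF(2).
perceive_rings <- function(graph) {
  m <- nrow(graph$edges)
  n_cycles <- m - graph$n + length(unique(components_id(graph)))
  if (n_cycles <= 0) return(list())
  adj <- adjacency_list(graph)
  edge_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ids <- edge_id(graph$edges$u, graph$edges$v)
  # BFS shortest path from a to b avoiding the direct edge a-b
  candidates <- list()
  for (i in seq_len(m)) {
    a <- graph$edges$u[i]; b <- graph$edges$v[i]
    parent <- rep(NA_integer_, graph$n)
    seen <- rep(FALSE, graph$n)
    seen[a] <- TRUE
    queue <- a
    while (length(queue) && !seen[b]) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) {
          seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
        }
      }
    }
    if (!seen[b]) next
    path <- b
    while (path[1] != a) path <- c(parent[path[1]], path)
    candidates[[length(candidates) + 1L]] <- path  # cycle = path + closing edge
  }
  if (!length(candidates)) return(list())
  candidates <- candidates[order(vapply(candidates, base::length, integer(1)))]
  # greedy GF(2) independence on edge-incidence vectors
  basis <- matrix(0L, nrow = 0, ncol = m)
  rings <- list()
  for (cyc in candidates) {
    if (length(rings) == n_cycles) break
    ev <- integer(m)
    cyc_edges <- c(edge_id(cyc[-length(cyc)], cyc[-1]), edge_id(cyc[length(cyc)], cyc[1]))
    ev[match(cyc_edges, ids)] <- 1L
    red <- ev
    if (nrow(basis)) {
      for (r in seq_len(nrow(basis))) {
        pivot <- which(basis[r, ] == 1L)[1]
        if (red[pivot] == 1L) red <- (red + basis[r, ]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      # keep row-echelon-ish ordering by pivot position
      basis <- basis[order(apply(basis, 1, function(x) which(x == 1L)[1])), , drop = FALSE]
      rings[[length(rings) + 1L]] <- cyc
    }
  }
  rings
}

components_id <- function(graph) {
  comp <- seq_len(graph$n)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(graph$edges))) {
      u <- graph$edges$u[i]; v <- graph$edges$v[i]
      if (comp[u] != comp[v]) {
        comp[comp == max(comp[u], comp[v])] <- min(comp[u], comp[v])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Ring-class attribute keys
#'
#' One key per (size, aromatic, heteroatom) class of the molecule's smallest
#' set of smallest rings; only five- and six-membered rings generate keys.
#' A ring is aromatic when all its atoms are aromatic-flagged and hetero
#' when it contains a non-carbon atom. The class count is part of the key.
#'
#' @param graph A `molgraph`.
#' @return Named integer vector of `RING:` attribute keys (values all 1).
#' @export
ring_codes <- function(graph) {
  rings <- perceive_rings(graph)
  rings <- rings[vapply(rings, base::length, integer(1)) %in% c(5L, 6L)]
  if (!length(rings)) return(stats::setNames(integer(0), character(0)))
  cls <- vapply(rings, function(r) {
    ar <- all(graph$aromatic[r])
    het <- any(toupper(graph$symbol[r]) != "C")
    sprintf("%d|ar=%d|het=%d", length(r), as.integer(ar), as.integer(het))
  }, character(1))
  tab <- table(cls)
  keys <- sprintf("RING:%s|n=%d", names(tab), as.integer(tab))
  stats::setNames(rep(1L, length(keys)), keys)
}

#' Graph-side attribute profile of a molecule
#'
#' Per-vertex keys for the two Morgan extended-connectivity orders, the
#' path counts of lengths 2 and 3, the valence shells at distances 2 and 3,
#' their sums and absolute differences, plus the ring-class keys. Every
#' per-vertex key is tagged with the vertex's element symbol (lowercase for
#' aromatic atoms).
#'
#' @param graph A `molgraph`.
#' @param ec_orders The two Morgan orders used, default `c(1, 2)`.
#' @return Named integer vector of attribute counts.
#' @export
graph_attributes <- function(graph, ec_orders = c(1L, 2L)) {
  stopifnot(length(ec_orders) == 2)
  sym <- graph$symbol
  ec1 <- morgan_ec(graph, ec_orders[1])
  ec2 <- morgan_ec(graph, ec_orders[2])
  pt2 <- path_counts(graph, 2L)
  pt3 <- path_counts(graph, 3L)
  s2 <- valence_shells(graph, 2L)
  s3 <- valence_shells(graph, 3L)
  keys <- c(
    sprintf("EC:%s|1=%d", sym, ec1),
    sprintf("EC:%s|2=%d", sym, ec2),
    sprintf("COMBO:%s|ec1+2=%d", sym, ec1 + ec2),
    sprintf("COMBO:%s|ec1-2=%d", sym, abs(ec1 - ec2)),
    sprintf("PT:%s|2=%d", sym, pt2),
    sprintf("PT:%s|3=%d", sym, pt3),
    sprintf("COMBO:%s|pt2+3=%d", sym, pt2 + pt3),
    sprintf("COMBO:%s|pt2-3=%d", sym, abs(pt2 - pt3)),
    sprintf("SHELL:%s|2=%d", sym, s2),
    sprintf("SHELL:%s|3=%d", sym, s3),
    sprintf("COMBO:%s|s2+3=%d", sym, s2 + s3),
    sprintf("COMBO:%s|s2-3=%d", sym, abs(s2 - s3))
  )
  tab <- table(keys)
  c(stats::setNames(as.integer(tab), names(tab)), ring_codes(graph))
}

#' Full hybrid attribute profile (SMILES plus graph)
#'
#' @param smiles A single SMILES string.
#' @param halo_key Passed to [global_attributes()].
#' @return Named integer vector of attribute counts over all namespaces.
#' @export
attribute_profile <- function(smiles, halo_key = TRUE) {
  c(smiles_attribute_profile(smiles, halo_key = halo_key),
    graph_attributes(build_graph(smiles)))
}
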