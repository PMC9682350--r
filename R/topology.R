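# Topological 2D descriptors computed from the heavy-atom bond graph.
#
# These complement the physicochemical properties exposed by the OpenBabel
# backend with classic graph-invariant families (distance, connectivity,
# path-count and Burden-matrix descriptors). Descriptors undefined for a
# structure (single heavy atom, disconnected graph, ...) are returned as
# NA: that is the missing-not-at-random mechanism the cleaning and
# imputation stages are designed around, so NA is never coerced to 0 here.

ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453,
                 Br = 79.904, I = 126.904, Na = 22.990, K = 39.098,
                 Li = 6.94, Ca = 40.078, Mg = 24.305, Se = 78.971,
                 As = 74.922, Zn = 65.38, Fe = 55.845)
PAULING_EN <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
                Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96,
                I = 2.66, Na = 0.93, K = 0.82, Li = 0.98, Ca = 1.00,
                Mg = 1.31, Se = 2.55, As = 2.18, Zn = 1.65, Fe = 1.83)

# Extract heavy-atom elements and the bond list from a ChemmineR SDF.
mol_graph <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  bb <- tryCatch(ChemmineR::bondblock(sdf_mol), error = function(e) NULL)
  elements <- sub("_.*$", "", rownames(ab))
  edges <- NULL
  if (!is.null(bb) && length(dim(bb)) == 2 && nrow(bb) > 0 && ncol(bb) >= 3) {
    edges <- cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  list(elements = elements, edges = edges, n = length(elements))
}

# Count simple paths with exactly k edges (each path counted once).
count_simple_paths <- function(adj_list, k) {
  n <- length(adj_list)
  total <- 0L
  visited <- logical(n)
  dfs <- function(v, depth) {
    if (depth == k) {
      total <<- total + 1L
      return(invisible())
    }
    visited[v] <<- TRUE
    for (w in adj_list[[v]]) {
      if (!visited[w]) dfs(w, depth + 1L)
    }
    visited[v] <<- FALSE
  }
  for (v in seq_len(n)) dfs(v, 0L)
  total %/% 2L
}

burden_eigen_range <- function(g, weights) {
  n <- g$n
  B <- matrix(0.001, n, n)
  if (!is.null(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      e <- g$edges[i, ]
      w <- e[["order"]] * 0.1
      B[e[["from"]], e[["to"]]] <- w
      B[e[["to"]], e[["from"]]] <- w
    }
  }
  diag(B) <- weights
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  c(hi = max(ev), lo = min(ev))
}

# Full topological descriptor vector for one molecule (named, NA when
# undefined).
topology_descriptors <- function(sdf_mol) {
  g <- mol_graph(sdf_mol)
  n <- g$n
  out <- c(nHeavyAtoms = n, nBonds = if (is.null(g$edges)) 0 else nrow(g$edges))
  na_block <- function(names) stats::setNames(rep(NA_real_, length(names)), names)
  dist_names <- c("wiener", "diameter", "radius", "balabanJ", "eccConn")
  conn_names <- c("zagreb1", "zagreb2", "randic")
  path_names <- paste0("MPC", 2:6)
  bcut_names <- c("BCUTm_hi", "BCUTm_lo", "BCUTen_hi", "BCUTen_lo")

  if (n < 2 || is.null(g$edges)) {
    out <- c(out, na_block(dist_names), na_block(conn_names),
             na_block(path_names), na_block(bcut_names))
    names(out) <- paste0("TOPO_", names(out))
    return(out)
  }

  gi <- igraph::graph_from_edgelist(g$edges[, 1:2, drop = FALSE],
                                    directed = FALSE)
  gi <- igraph::add_vertices(gi, max(0, n - igraph::vcount(gi)))
  deg <- igraph::degree(gi)
  adj_list <- lapply(igraph::adjacent_vertices(gi, seq_len(n)), as.integer)

  # Connectivity indices are defined for any graph with edges.
  ef <- g$edges[, 1]
  et <- g$edges[, 2]
  conn <- c(zagreb1 = sum(deg^2),
            zagreb2 = sum(deg[ef] * deg[et]),
            randic = sum(1 / sqrt(deg[ef] * deg[et])))

  # Distance-based indices require a connected graph.
  if (igraph::is_connected(gi)) {
    D <- igraph::distances(gi)
    ecc <- apply(D, 1, max)
    q <- nrow(g$edges)
    mu <- q - n + 1
    s <- rowSums(D)
    bal <- if (any(s[ef] * s[et] == 0)) NA_real_ else
      q / (mu + 1) * sum(1 / sqrt(s[ef] * s[et]))
    dist_desc <- c(wiener = sum(D) / 2, diameter = max(ecc),
                   radius = min(ecc), balabanJ = bal,
                   eccConn = sum(deg * ecc))
  } else {
    dist_desc <- na_block(dist_names)
  }

  paths <- vapply(2:6, function(k) as.numeric(count_simple_paths(adj_list, k)),
                  numeric(1))
  names(paths) <- path_names

  mass <- ATOMIC_MASS[g$elements]
  en <- PAULING_EN[g$elements]
  bcut <- if (anyNA(mass) || anyNA(en)) na_block(bcut_names) else {
    bm <- burden_eigen_range(g, unname(mass) / 12.011)
    be <- burden_eigen_range(g, unname(en) / 2.55)
    c(BCUTm_hi = bm[["hi"]], BCUTm_lo = bm[["lo"]],
      BCUTen_hi = be[["hi"]], BCUTen_lo = be[["lo"]])
  }

  out <- c(out, dist_desc, conn, paths, bcut)
  names(out) <- paste0("TOPO_", names(out))
  out
}
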