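# Independent brute-force oracles. Deliberately naive: none of them share
# code paths (igraph, sparse power iteration, phyper) with the package.

# strongly connected components by pairwise reachability on a dense
# boolean adjacency matrix (Warshall closure)
oracle_scc <- function(nodes, edges) {
  n <- length(nodes)
  reach <- diag(TRUE, n)
  dimnames(reach) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    reach[edges$from[i], edges$to[i]] <- TRUE
  }
  for (k in seq_len(n)) {
    reach <- reach | outer(reach[, k], reach[k, ], `&`)
  }
  mutual <- reach & t(reach)
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[mutual[i, ]] <- cid
    }
  }
  split(nodes, comp)
}

# signed-walk enumeration oracle for SRWR: dynamic programme over
# (node, walker sign) per walk length, explicit loops over edges.
# Walks start at a seed with its original sign; a walk of length L
# contributes c * (1-c)^L of its probability to the channel matching the
# product of edge signs times the starting sign. Graphs must have no
# dangling nodes. Walk length is extended until the geometric tail
# (1-c)^(L+1) drops below tail_tol.
oracle_srwr_walks <- function(nodes, edges, seed_signs, c_, tail_tol = 1e-7) {
  n <- length(nodes)
  outdeg <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(nrow(edges))) {
    outdeg[edges$from[i]] <- outdeg[edges$from[i]] + 1
  }
  stopifnot(all(outdeg > 0))
  wpos <- stats::setNames(numeric(n), nodes)
  wneg <- stats::setNames(numeric(n), nodes)
  q <- 1 / length(seed_signs)
  for (g in names(seed_signs)) {
    if (seed_signs[[g]] > 0) wpos[g] <- wpos[g] + q else
      wneg[g] <- wneg[g] + q
  }
  p <- c_ * wpos
  nn <- c_ * wneg
  L <- 0
  while ((1 - c_)^(L + 1) >= tail_tol) {
    L <- L + 1
    npos <- stats::setNames(numeric(n), nodes)
    nneg <- stats::setNames(numeric(n), nodes)
    for (i in seq_len(nrow(edges))) {
      u <- edges$from[i]; v <- edges$to[i]
      step <- 1 / outdeg[u]
      if (edges$sign[i] > 0) {
        npos[v] <- npos[v] + wpos[u] * step
        nneg[v] <- nneg[v] + wneg[u] * step
      } else {
        npos[v] <- npos[v] + wneg[u] * step
        nneg[v] <- nneg[v] + wpos[u] * step
      }
    }
    wpos <- npos; wneg <- nneg
    p <- p + c_ * (1 - c_)^L * wpos
    nn <- nn + c_ * (1 - c_)^L * wneg
  }
  list(p = p, n = nn)
}

# exhaustive metapath enumeration for PathSim: count
# compound -> target -> function -> target' -> compound' instances
oracle_pathsim <- function(target_sets, annotations) {
  ids <- names(target_sets)
  k <- length(ids)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cnt <- 0
    for (t1 in target_sets[[i]]) for (t2 in target_sets[[j]]) {
      f1 <- annotations[[t1]]
      f2 <- annotations[[t2]]
      if (!is.null(f1) && !is.null(f2)) {
        cnt <- cnt + length(intersect(f1, f2))
      }
    }
    m[i, j] <- cnt
  }
  sim <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sim[i, j] <- 2 * m[i, j] / (m[i, i] + m[j, j])
  }
  list(counts = m, sim = sim)
}

# BFS all-pairs hop distances on an undirected edge list (no igraph)
oracle_distances <- function(nodes, pairs) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$from[i]; b <- pairs$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- setdiff(unique(unlist(adj[frontier])),
                     nodes[is.finite(d[s, ])])
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# closest-distance separation score from an oracle distance matrix
oracle_sab <- function(dmat, a, b) {
  closest <- function(from, to_set, excl = FALSE) {
    vapply(from, function(x) {
      pool <- if (excl) setdiff(to_set, x) else to_set
      if (length(pool) == 0) return(0)
      min(dmat[x, pool])
    }, numeric(1))
  }
  fin_mean <- function(v) mean(v[is.finite(v)])
  d_ab <- fin_mean(c(closest(a, b), closest(b, a)))
  d_aa <- fin_mean(closest(a, a, excl = TRUE))
  d_bb <- fin_mean(closest(b, b, excl = TRUE))
  list(d_aa = d_aa, d_bb = d_bb, d_ab = d_ab,
       s_ab = d_ab - (d_aa + d_bb) / 2)
}

# upper-tail hypergeometric by direct summation of binomial coefficients
oracle_hypergeom <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# a random signed digraph as a plain edge tibble (independent of the
# package generators); ensures no duplicate ordered pairs, optionally no
# dangling nodes
random_signed_edges <- function(n, p_edge = 0.4, p_neg = 0.3,
                                no_dangling = FALSE) {
  nodes <- LETTERS[seq_len(n)]
  grid <- expand.grid(from = nodes, to = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  keep <- stats::runif(nrow(grid)) < p_edge
  e <- grid[keep, ]
  if (no_dangling) {
    missing <- setdiff(nodes, unique(e$from))
    for (u in missing) {
      v <- sample(setdiff(nodes, u), 1)
      e <- rbind(e, data.frame(from = u, to = v))
    }
  }
  e$sign <- ifelse(stats::runif(nrow(e)) < p_neg, -1L, 1L)
  tibble::as_tibble(e)
}
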