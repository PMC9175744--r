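#' @importFrom rlang .data
NULL

# normalise a seed argument to a tibble(gene, sign, weight).
# Accepted forms: character vector (all +1, uniform weights), named integer
# vector of signs, or a data frame with columns gene, sign [, weight].
as_seed_tbl <- function(seeds, signed = TRUE) {
  if (is.data.frame(seeds)) {
    if (!"gene" %in% names(seeds)) {
      rlang::abort("seed data frame needs a 'gene' column",
                   class = "signetpharm_value_error")
    }
    tb <- tibble::tibble(
      gene = as.character(seeds$gene),
      sign = if ("sign" %in% names(seeds)) as.integer(seeds$sign) else
        rep(1L, nrow(seeds)),
      weight = if ("weight" %in% names(seeds)) as.numeric(seeds$weight) else
        rep(1, nrow(seeds))
    )
  } else if (!is.null(names(seeds)) && is.numeric(seeds)) {
    tb <- tibble::tibble(gene = names(seeds), sign = as.integer(seeds),
                         weight = 1)
  } else {
    tb <- tibble::tibble(gene = as.character(seeds), sign = 1L, weight = 1)
  }
  if (anyDuplicated(tb$gene)) {
    rlang::abort("duplicate seed genes", class = "signetpharm_value_error")
  }
  if (any(is.na(tb$sign))) {
    rlang::warn("seeds with unknown sign treated as +1 (activation)")
    tb$sign[is.na(tb$sign)] <- 1L
  }
  if (!all(tb$sign %in% c(-1L, 1L))) {
    rlang::abort("seed signs must be +1 or -1",
                 class = "signetpharm_value_error")
  }
  if (any(tb$weight < 0) || sum(tb$weight) <= 0) {
    rlang::abort("seed weights must be non-negative with positive sum",
                 class = "signetpharm_value_error")
  }
  tb
}

# signed sparse transition operators. Returns list(Wp_t, Wn_t, dangling)
# where Wp_t/Wn_t are transposed column operators (n x n, entry [u, v] =
# prob of stepping v -> u through a positive/negative edge) and dangling is
# a logical vector over nodes with no out-edges. Transition mass at a node
# is uniform over ALL its out-edges; the edge sign only routes the channel.
transition_ops <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  e <- graph$edges
  if (!graph$directed && nrow(e) > 0) {
    e <- dplyr::bind_rows(e, tibble::tibble(from = e$to, to = e$from,
                                            sign = e$sign))
  }
  i_from <- match(e$from, nodes)
  i_to <- match(e$to, nodes)
  outdeg <- tabulate(i_from, nbins = n)
  w <- 1 / outdeg[i_from]
  pos <- e$sign == 1L
  Wp_t <- Matrix::sparseMatrix(i = i_to[pos], j = i_from[pos],
                               x = w[pos], dims = c(n, n))
  Wn_t <- Matrix::sparseMatrix(i = i_to[!pos], j = i_from[!pos],
                               x = w[!pos], dims = c(n, n))
  list(Wp_t = Wp_t, Wn_t = Wn_t, dangling = outdeg == 0)
}

seed_restart_vectors <- function(graph, seed_tbl) {
  nodes <- graph$nodes
  on_graph <- seed_tbl$gene %in% nodes
  dropped <- seed_tbl$gene[!on_graph]
  if (length(dropped) > 0) {
    rlang::inform(paste0(length(dropped),
                         " seed gene(s) absent from the graph were dropped"))
  }
  seed_tbl <- seed_tbl[on_graph, ]
  if (nrow(seed_tbl) == 0) {
    rlang::abort("no seed gene is present on the graph",
                 class = "signetpharm_value_error")
  }
  w <- seed_tbl$weight / sum(seed_tbl$weight)
  qp <- qn <- numeric(length(nodes))
  ip <- match(seed_tbl$gene[seed_tbl$sign == 1L], nodes)
  im <- match(seed_tbl$gene[seed_tbl$sign == -1L], nodes)
  qp[ip] <- w[seed_tbl$sign == 1L]
  qn[im] <- w[seed_tbl$sign == -1L]
  list(qp = qp, qn = qn, dropped = dropped, used = seed_tbl$gene)
}

#' Random walk with restart
#'
#' Network influence of a seed gene set: the stationary distribution of a
#' walker that, at each step, follows a uniformly random out-edge with
#' probability `1 - restart` and teleports back to the seed distribution
#' with probability `restart`. Edge signs are ignored. Mass arriving at a
#' dangling node (no out-edges) returns to the seed distribution, so the
#' result always sums to one.
#'
#' @param graph a [signed_graph] (directed or undirected).
#' @param seeds seed genes: character vector, named sign vector, or a data
#'   frame with columns `gene` and optionally `sign`, `weight`. Seeds
#'   absent from the graph are dropped with a message.
#' @param restart restart (teleport) probability in (0, 1]; default 0.75.
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter iteration cap; exceeding it is an error that reports the
#'   last residual.
#' @return tibble of class `influence_vector` with columns `node`, `score`
#'   (non-negative, sums to 1). Attributes: `restart`, `iterations`,
#'   `residual`, `dropped_seeds`.
#' @export
#' @examples
#' g <- signed_graph(data.frame(from = "A", to = "B"))
#' rwr(g, "A", restart = 0.5) # 2/3 on A, 1/3 on the dangling node B
rwr <- function(graph, seeds, restart = 0.75, tol = 1e-10,
                max_iter = 10000) {
  stopifnot(is_signed_graph(graph))
  check_propagation_config(restart, tol, max_iter)
  ops <- transition_ops(graph)
  sv <- seed_restart_vectors(graph, as_seed_tbl(seeds))
  q <- sv$qp + sv$qn
  W_t <- ops$Wp_t + ops$Wn_t
  s <- q
  c_ <- restart
  for (it in seq_len(max_iter)) {
    d_mass <- sum(s[ops$dangling])
    s_new <- as.numeric((1 - c_) * (W_t %*% s + d_mass * q) + c_ * q)
    res <- sum(abs(s_new - s))
    s <- s_new
    if (res < tol) {
      out <- tibble::tibble(node = graph$nodes, score = s)
      class(out) <- c("influence_vector", class(out))
      attr(out, "restart") <- restart
      attr(out, "iterations") <- it
      attr(out, "residual") <- res
      attr(out, "dropped_seeds") <- sv$dropped
      return(out)
    }
  }
  rlang::abort(
    sprintf("RWR did not converge in %d iterations (last L1 residual %.3g)",
            max_iter, res),
    class = "signetpharm_convergence_error"
  )
}

#' Signed random walk with restart
#'
#' Propagates a drug perturbation over an activation/inhibition signaling
#' network. The walker carries a sign: crossing a negative (inhibition)
#' edge flips it, crossing a positive edge keeps it, and on restart the
#' walker regains the original sign of its seed (drug targets annotated as
#' activated get `+1`, inhibited `-1`). This yields a positive channel `p`
#' and a negative channel `n` per node; the *activation score*
#' `r = p - n` is negative where the seeded perturbation exerts net
#' predicted inhibition. The coupled fixed point solved is
#' \deqn{p = (1-c)(W_+^T p + W_-^T n) + c q_+,\quad
#'       n = (1-c)(W_-^T p + W_+^T n) + c q_-}
#' with out-transition mass uniform over all out-edges and edge sign
#' routing the channel; dangling mass returns to the seed distribution
#' with original signs, so `sum(p + n) == 1`.
#'
#' @inheritParams rwr
#' @param seeds signed seeds (see [rwr()]); `NA` signs are treated as `+1`
#'   with a warning.
#' @return tibble of class `srwr_scores` with columns `node`, `p`, `n`,
#'   `r` and the attributes of [rwr()].
#' @export
#' @examples
#' g <- signed_graph(data.frame(from = "A", to = "B", sign = -1))
#' srwr(g, c(A = 1), restart = 0.5) # r = -1/3 on B: predicted inhibition
srwr <- function(graph, seeds, restart = 0.75, tol = 1e-10,
                 max_iter = 10000) {
  stopifnot(is_signed_graph(graph))
  if (!graph$directed) {
    rlang::abort("srwr needs a directed signed graph",
                 class = "signetpharm_value_error")
  }
  check_propagation_config(restart, tol, max_iter)
  ops <- transition_ops(graph)
  sv <- seed_restart_vectors(graph, as_seed_tbl(seeds))
  c_ <- restart
  p <- sv$qp
  n <- sv$qn
  for (it in seq_len(max_iter)) {
    d_mass <- sum(p[ops$dangling]) + sum(n[ops$dangling])
    p_new <- as.numeric((1 - c_) * (ops$Wp_t %*% p + ops$Wn_t %*% n +
                                      d_mass * sv$qp) + c_ * sv$qp)
    n_new <- as.numeric((1 - c_) * (ops$Wn_t %*% p + ops$Wp_t %*% n +
                                      d_mass * sv$qn) + c_ * sv$qn)
    res <- sum(abs(p_new - p)) + sum(abs(n_new - n))
    p <- p_new
    n <- n_new
    if (res < tol) {
      out <- tibble::tibble(node = graph$nodes, p = p, n = n, r = p - n)
      class(out) <- c("srwr_scores", class(out))
      attr(out, "restart") <- restart
      attr(out, "iterations") <- it
      attr(out, "residual") <- res
      attr(out, "dropped_seeds") <- sv$dropped
      return(out)
    }
  }
  rlang::abort(
    sprintf("SRWR did not converge in %d iterations (last L1 residual %.3g)",
            max_iter, res),
    class = "signetpharm_convergence_error"
  )
}

check_propagation_config <- function(restart, tol, max_iter) {
  if (!is.numeric(restart) || restart <= 0 || restart > 1) {
    rlang::abort("restart probability must be in (0, 1]",
                 class = "signetpharm_value_error")
  }
  if (!is.numeric(tol) || tol <= 0) {
    rlang::abort("tolerance must be positive",
                 class = "signetpharm_value_error")
  }
  if (max_iter < 1) {
    rlang::abort("max_iter must be at least 1",
                 class = "signetpharm_value_error")
  }
  invisible(TRUE)
}

#' Select the strongest predicted inhibitions (or activations)
#'
#' Ranks all nodes by absolute activation score `|r|` (descending), keeps
#' the top `ceiling(fraction * n_nodes)` rank positions — ties exactly at
#' the boundary are all retained — and returns the nodes in that stratum
#' whose score has the requested direction (`r < 0` for `"inhibited"`,
#' `r > 0` for `"activated"`).
#'
#' @param scores an `srwr_scores` tibble from [srwr()].
#' @param fraction top fraction of nodes to keep, in (0, 1]; the paper-style
#'   convention for "top 10 percent" is `fraction = 0.1` with the node count
#'   of the propagated graph as denominator.
#' @param direction `"inhibited"` or `"activated"`.
#' @return tibble with columns `node`, `p`, `n`, `r`, `rank` (rank by
#'   `|r|` over all nodes), filtered to the requested stratum.
#' @export
select_top_signed <- function(scores, fraction = 0.1,
                              direction = c("inhibited", "activated")) {
  direction <- match.arg(direction)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    rlang::abort("fraction must be in (0, 1]",
                 class = "signetpharm_value_error")
  }
  if (all(scores$r == 0)) {
    rlang::warn("all activation scores are zero; returning an empty set")
    out <- scores[0, ]
    out$rank <- integer()
    return(out)
  }
  n <- nrow(scores)
  k <- ceiling(fraction * n)
  a <- abs(scores$r)
  cutoff <- sort(a, decreasing = TRUE)[k]
  ranked <- dplyr::mutate(scores, rank = rank(-abs(.data$r),
                                              ties.method = "min"))
  stratum <- dplyr::filter(ranked, abs(.data$r) >= cutoff)
  keep <- if (direction == "inhibited") stratum$r < 0 else stratum$r > 0
  dplyr::arrange(stratum[keep, ], .data$rank, .data$node)
}
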