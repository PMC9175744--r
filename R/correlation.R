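#' Influence vector of a gene set
#'
#' [rwr()] with uniform restart mass over the members of a gene set that
#' are present on the graph — the per-node network influence of the set.
#'
#' @param graph a [signed_graph].
#' @param gene_set character vector of genes (or data frame with a `gene`
#'   column). Members absent from the graph are dropped with a message.
#' @inheritParams rwr
#' @return an `influence_vector` tibble (see [rwr()]).
#' @export
influence_vector <- function(graph, gene_set, restart = 0.75,
                             tol = 1e-10, max_iter = 10000) {
  genes <- as_gene_vector(gene_set)
  rwr(graph, genes, restart = restart, tol = tol, max_iter = max_iter)
}

#' Z-score consistency of the correlation formula
#'
#' The permutation-null standardisation used throughout:
#' `z = (cor - null_mean) / null_sd`.
#'
#' @param cor observed Pearson correlation of the two influence vectors.
#' @param null_mean,null_sd mean and standard deviation of the correlation
#'   under the random-gene-set null.
#' @return the Z-score.
#' @export
#' @examples
#' zscore_from_moments(0.207, 0.005, 0.0145722) # about 13.86
zscore_from_moments <- function(cor, null_mean, null_sd) {
  if (any(null_sd <= 0)) {
    rlang::abort("null_sd must be positive",
                 class = "signetpharm_degenerate_null_error")
  }
  (cor - null_mean) / null_sd
}

#' Drug-target / disease-gene correlation Z-score
#'
#' Measures how strongly a drug's targets and a disease's genes influence
#' the same parts of the network. Both sets are diffused with [rwr()]
#' (restart 0.75 by default); the observed statistic is the Pearson
#' correlation of the two influence vectors over *all* graph nodes. The
#' null redraws the disease set uniformly from the graph's nodes (same
#' post-intersection cardinality, no degree matching) `n_null` times,
#' recomputes its influence vector, and correlates it with the fixed drug
#' vector; the Z-score standardises the observed correlation by the null's
#' mean and standard deviation.
#'
#' @param graph a [signed_graph] (the background network).
#' @param drug_targets,disease_genes character vectors (or data frames with
#'   a `gene` column).
#' @inheritParams rwr
#' @param n_null number of random null sets (default 1000).
#' @param rng_seed integer seed; identical inputs and seed give
#'   bit-identical results.
#' @return object of class `correlation_result`: list with elements `cor`,
#'   `null_mean`, `null_sd`, `z_score`, `n_null`, `rng_seed`, `null_cors`
#'   (the full null sample), `n_drug_used`, `n_disease_used`,
#'   `dropped_drug`, `dropped_disease`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
correlation_zscore <- function(graph, drug_targets, disease_genes,
                               restart = 0.75, tol = 1e-10,
                               max_iter = 10000, n_null = 1000,
                               rng_seed = 1L) {
  stopifnot(is_signed_graph(graph))
  if (n_null < 2) {
    rlang::abort("n_null must be at least 2",
                 class = "signetpharm_value_error")
  }
  drug <- as_gene_vector(drug_targets, "drug_targets")
  disease <- as_gene_vector(disease_genes, "disease_genes")
  drug_used <- intersect(drug, graph$nodes)
  disease_used <- intersect(disease, graph$nodes)
  if (length(drug_used) == 0 || length(disease_used) == 0) {
    rlang::abort("a gene set has empty intersection with the graph",
                 class = "signetpharm_value_error")
  }
  if (length(disease_used) > length(graph$nodes)) {
    rlang::abort("disease set larger than the graph; cannot resample",
                 class = "signetpharm_value_error")
  }
  v_drug <- rwr(graph, drug_used, restart, tol, max_iter)$score
  v_dis <- rwr(graph, disease_used, restart, tol, max_iter)$score
  obs <- stats::cor(v_drug, v_dis)
  m <- length(disease_used)
  null_cors <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_null), function(i) {
      rnd <- sample(graph$nodes, m, replace = FALSE)
      stats::cor(v_drug, rwr(graph, rnd, restart, tol, max_iter)$score)
    }, numeric(1))
  })
  null_mean <- mean(null_cors)
  null_sd <- stats::sd(null_cors)
  if (null_sd == 0) {
    rlang::abort("degenerate null: all null correlations identical",
                 class = "signetpharm_degenerate_null_error")
  }
  structure(
    list(
      cor = obs,
      null_mean = null_mean,
      null_sd = null_sd,
      z_score = zscore_from_moments(obs, null_mean, null_sd),
      n_null = as.integer(n_null),
      rng_seed = as.integer(rng_seed),
      null_cors = null_cors,
      n_drug_used = length(drug_used),
      n_disease_used = length(disease_used),
      dropped_drug = setdiff(drug, drug_used),
      dropped_disease = setdiff(disease, disease_used)
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result: cor = %.4f, null %.4f +/- %.5f (n = %d), z = %.3f>\n",
    x$cor, x$null_mean, x$null_sd, x$n_null, x$z_score))
  invisible(x)
}

#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(cor = x$cor, null_mean = x$null_mean, null_sd = x$null_sd,
                 z_score = x$z_score)
}

#' @export
glance.correlation_result <- function(x, ...) {
  tibble::tibble(cor = x$cor, null_mean = x$null_mean, null_sd = x$null_sd,
                 z_score = x$z_score, n_null = x$n_null,
                 n_drug_used = x$n_drug_used,
                 n_disease_used = x$n_disease_used,
                 rng_seed = x$rng_seed)
}

#' @export
autoplot.correlation_result <- function(object, ...) {
  df <- tibble::tibble(cor = object$null_cors)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cor)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$cor, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "Pearson correlation of influence vectors",
      y = "null sets",
      title = sprintf("observed cor = %.3f, z = %.2f",
                      object$cor, object$z_score)
    ) +
    ggplot2::theme_minimal()
}
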