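new_similarity_matrix <- function(sim, kind, excluded = character()) {
  structure(list(sim = sim, kind = kind, excluded = excluded),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix (%s): %d x %d>\n", x$kind,
              nrow(x$sim), ncol(x$sim)))
  print(round(x$sim, 3))
  invisible(x)
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- x$sim
  tibble::tibble(
    drug_a = rep(rownames(m), times = ncol(m)),
    drug_b = rep(colnames(m), each = nrow(m)),
    similarity = as.vector(m)
  )
}

#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy.similarity_matrix(object)
  ord <- rownames(object$sim)
  df$drug_a <- factor(df$drug_a, levels = ord)
  df$drug_b <- factor(df$drug_b, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$drug_a, y = .data$drug_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = object$kind) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Pairwise chemical-structure similarity
#'
#' Tanimoto similarity on circular fingerprints for every pair of drugs
#' with a usable SMILES. Drugs lacking SMILES are excluded with a warning
#' and recorded in the result's `excluded` field.
#'
#' @param drugs tibble with columns `drug_id` and `smiles` (as from
#'   [read_drug_table()]).
#' @inheritParams morgan_fingerprint
#' @return a `similarity_matrix` (symmetric, unit diagonal, entries in
#'   `[0, 1]`) of kind `"structure"`.
#' @export
structure_similarity_matrix <- function(drugs, radius = 2, n_bits = 2048) {
  usable <- !is.na(drugs$smiles) & nzchar(drugs$smiles)
  if (any(!usable)) {
    rlang::warn(paste0("excluding drug(s) without SMILES: ",
                       paste(drugs$drug_id[!usable], collapse = ", ")))
  }
  ids <- drugs$drug_id[usable]
  if (length(ids) < 2) {
    rlang::abort("need at least 2 drugs with SMILES",
                 class = "signetpharm_value_error")
  }
  fps <- lapply(drugs$smiles[usable], morgan_fingerprint,
                radius = radius, n_bits = n_bits)
  k <- length(ids)
  m <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      union <- sum(fps[[i]] | fps[[j]])
      m[i, j] <- m[j, i] <-
        if (union == 0) 0 else sum(fps[[i]] & fps[[j]]) / union
    }
  }
  dimnames(m) <- list(ids, ids)
  new_similarity_matrix(m, "structure", excluded = drugs$drug_id[!usable])
}

#' Interactome separation of two target modules
#'
#' Network-medicine separation score
#' \deqn{s_{AB} = \langle d_{AB}\rangle - \frac{\langle d_{AA}\rangle +
#'   \langle d_{BB}\rangle}{2}}
#' on an undirected interactome, using the closest-distance convention:
#' `d_AB` averages, over every member of A, its shortest distance to the
#' nearest member of B (zero when it is itself in B) and symmetrically for
#' B; `d_AA` averages each member's distance to its nearest *other* member
#' (singleton modules score 0). Unreachable terms are excluded from the
#' means. Negative `s_AB` indicates topologically overlapping target
#' modules; positive, separated ones.
#'
#' @param interactome an undirected [signed_graph].
#' @param targets_a,targets_b character vectors of target genes; members
#'   absent from the interactome are dropped with a message.
#' @return object of class `proximity_result` with fields `d_aa`, `d_bb`,
#'   `d_ab`, `s_ab`, `n_a`, `n_b`, `dropped_a`, `dropped_b`. Has a
#'   [tidy()] method.
#' @export
sab_separation <- function(interactome, targets_a, targets_b) {
  stopifnot(is_signed_graph(interactome))
  a_all <- as_gene_vector(targets_a, "targets_a")
  b_all <- as_gene_vector(targets_b, "targets_b")
  a <- intersect(a_all, interactome$nodes)
  b <- intersect(b_all, interactome$nodes)
  for (nm in list(c("A", length(a)), c("B", length(b)))) {
    if (as.integer(nm[2]) == 0) {
      rlang::abort(paste0("target set ", nm[1],
                          " is empty after interactome intersection"),
                   class = "signetpharm_value_error")
    }
  }
  dropped_a <- setdiff(a_all, a)
  dropped_b <- setdiff(b_all, b)
  if (length(dropped_a) + length(dropped_b) > 0) {
    rlang::inform(sprintf(
      "dropped %d target(s) of A and %d of B absent from the interactome",
      length(dropped_a), length(dropped_b)))
  }
  ig <- as_igraph(interactome)
  dmat <- igraph::distances(ig, v = union(a, b), to = union(a, b))
  closest <- function(from, to_set, exclude_self = FALSE) {
    vapply(from, function(x) {
      pool <- if (exclude_self) setdiff(to_set, x) else to_set
      if (length(pool) == 0) return(0)        # singleton module: d = 0
      min(dmat[x, pool])
    }, numeric(1))
  }
  mean_finite <- function(v, what) {
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      rlang::abort(paste0("all ", what, " distances are unreachable"),
                   class = "signetpharm_disconnected_error")
    }
    mean(v)
  }
  d_ab <- mean_finite(c(closest(a, b), closest(b, a)), "cross-module")
  d_aa <- mean_finite(closest(a, a, exclude_self = TRUE), "within-A")
  d_bb <- mean_finite(closest(b, b, exclude_self = TRUE), "within-B")
  structure(
    list(d_aa = d_aa, d_bb = d_bb, d_ab = d_ab,
         s_ab = d_ab - (d_aa + d_bb) / 2,
         n_a = length(a), n_b = length(b),
         dropped_a = dropped_a, dropped_b = dropped_b),
    class = "proximity_result"
  )
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "<proximity_result: d_AA = %.3f, d_BB = %.3f, d_AB = %.3f, s_AB = %.3f>\n",
    x$d_aa, x$d_bb, x$d_ab, x$s_ab))
  invisible(x)
}

#' @export
tidy.proximity_result <- function(x, ...) {
  tibble::tibble(d_aa = x$d_aa, d_bb = x$d_bb, d_ab = x$d_ab,
                 s_ab = x$s_ab, n_a = x$n_a, n_b = x$n_b)
}

#' Pairwise target-module separation matrix
#'
#' [sab_separation()] for every pair of drugs; the diagonal holds
#' `s_ab(A, A)`, which is non-positive for modules of two or more genes.
#' Unlike Tanimoto/PathSim this is a *separation* (smaller = more similar),
#' so it is returned as kind `"separation"` and is not fed to
#' [cluster_similarity()] directly.
#'
#' @param interactome an undirected [signed_graph].
#' @param target_sets named list of character vectors (one per drug).
#' @return a `similarity_matrix` of kind `"separation"` (entries
#'   unbounded; symmetric).
#' @export
sab_matrix <- function(interactome, target_sets) {
  ids <- names(target_sets)
  k <- length(ids)
  if (k < 2) {
    rlang::abort("need at least 2 target sets",
                 class = "signetpharm_value_error")
  }
  m <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in i:k) {
      r <- sab_separation(interactome, target_sets[[i]], target_sets[[j]])
      m[i, j] <- m[j, i] <- r$s_ab
    }
  }
  new_similarity_matrix(m, "separation")
}

#' Metapath (PathSim) functional similarity of drugs
#'
#' Similarity on the tripartite compound-target-function network along the
#' metapath compound -> target -> function -> target -> compound.
#' `M[i, j]` counts metapath instances between drugs i and j (pairs of
#' annotated targets sharing a function term); the PathSim score is
#' `2 * M[i, j] / (M[i, i] + M[j, j])`, so a drug is always at similarity
#' 1 with itself and two drugs whose targets share no function term score
#' 0. Drugs with no annotated target (zero self-paths) are excluded with a
#' warning and reported in `excluded` — a drug without any recorded target,
#' like salvianolic acid Y, simply has no functional fingerprint.
#'
#' @param drugs tibble with columns `drug_id` and `targets` (list column
#'   of named sign vectors, signs unused here), as from
#'   [read_drug_table()]; alternatively a named list of character vectors.
#' @param annotations gene-to-function map: named list (gene -> character
#'   vector of term ids) or a data frame with columns `gene`, `term`.
#' @return a `similarity_matrix` of kind `"pathsim"`.
#' @export
pathsim_matrix <- function(drugs, annotations) {
  if (is.data.frame(drugs)) {
    target_sets <- stats::setNames(lapply(drugs$targets, names),
                                   drugs$drug_id)
  } else {
    target_sets <- lapply(drugs, as.character)
  }
  if (is.data.frame(annotations)) {
    annotations <- split(as.character(annotations$term),
                         as.character(annotations$gene))
  }
  genes <- sort(unique(c(unlist(target_sets), names(annotations))))
  terms <- sort(unique(unlist(annotations)))
  if (length(terms) == 0) {
    rlang::abort("no drug has annotated targets",
                 class = "signetpharm_value_error")
  }
  # gene x term incidence
  ga <- matrix(0, length(genes), length(terms),
               dimnames = list(genes, terms))
  for (g in names(annotations)) {
    ga[g, unique(annotations[[g]])] <- 1
  }
  ids <- names(target_sets)
  # compound x term path counts: row i = number of (target, term) paths
  ct <- matrix(0, length(ids), length(terms),
               dimnames = list(ids, terms))
  for (i in seq_along(ids)) {
    tg <- intersect(unique(target_sets[[i]]), genes)
    if (length(tg) > 0) ct[i, ] <- colSums(ga[tg, , drop = FALSE])
  }
  m_counts <- ct %*% t(ct)
  self <- diag(m_counts)
  usable <- self > 0
  if (!any(usable)) {
    rlang::abort("no drug has annotated targets",
                 class = "signetpharm_value_error")
  }
  if (any(!usable)) {
    rlang::warn(paste0("excluding drug(s) with no annotated target: ",
                       paste(ids[!usable], collapse = ", ")))
  }
  mc <- m_counts[usable, usable, drop = FALSE]
  sf <- self[usable]
  sim <- 2 * mc / outer(sf, sf, `+`)
  dimnames(sim) <- list(ids[usable], ids[usable])
  out <- new_similarity_matrix(sim, "pathsim", excluded = ids[!usable])
  out$path_counts <- mc
  out
}

#' Hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering on the distance `1 - similarity`, cut at
#' `n_clusters`. Cluster labels are re-numbered contiguously from 1 in
#' order of first appearance along the input drug order, so the partition
#' is invariant (up to renaming) under permutation of the input.
#'
#' @param simmat a `similarity_matrix` with entries in `[0, 1]` (kinds
#'   `"structure"` or `"pathsim"`).
#' @param n_clusters number of clusters, between 1 and the matrix size.
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return tibble of class `cluster_assignment` with columns `drug`,
#'   `cluster`; attributes `linkage`, `n_clusters` and `hclust` (the tree,
#'   for dendrograms).
#' @export
cluster_similarity <- function(simmat, n_clusters = 6,
                               linkage = "complete") {
  stopifnot(inherits(simmat, "similarity_matrix"))
  m <- simmat$sim
  k <- nrow(m)
  if (n_clusters < 1 || n_clusters > k) {
    rlang::abort("n_clusters must be between 1 and the number of drugs",
                 class = "signetpharm_value_error")
  }
  if (any(m < -1e-9) || any(m > 1 + 1e-9)) {
    rlang::abort("similarity entries must lie in [0, 1]; separation-type
matrices are not directly clusterable", class = "signetpharm_value_error")
  }
  hc <- stats::hclust(stats::as.dist(1 - m), method = linkage)
  raw <- stats::cutree(hc, k = n_clusters)
  labels <- match(raw, unique(raw[rownames(m)]))
  out <- tibble::tibble(drug = rownames(m), cluster = as.integer(labels))
  class(out) <- c("cluster_assignment", class(out))
  attr(out, "linkage") <- linkage
  attr(out, "n_clusters") <- as.integer(n_clusters)
  attr(out, "hclust") <- hc
  out
}
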