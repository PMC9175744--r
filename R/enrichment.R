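#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` when drawing `n` items without replacement from a population
#' of `N` containing `K` successes — the enrichment statistic used to ask
#' whether a selected gene set overlaps a validation set more than chance.
#' Inclusive upper tail: `k = 0` gives exactly 1. Computed on the log scale
#' via the stable hypergeometric CDF.
#'
#' @param N population size.
#' @param K successes in the population (validation genes).
#' @param n draws (selected genes).
#' @param k observed overlap.
#' @return the p-value in `(0, 1]`. All arguments vectorise.
#' @export
#' @examples
#' hypergeom_upper(10, 5, 4, 4) # 5 / 210
hypergeom_upper <- function(N, K, n, k) {
  bad <- k > pmin(K, n) | K > N | n > N | k < 0 | N < 0
  if (any(bad)) {
    rlang::abort("need 0 <= k <= min(K, n) and K, n <= N",
                 class = "signetpharm_value_error")
  }
  ifelse(k == 0, 1,
         stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Enrichment of a selected gene set in a validation set
#'
#' Counts the overlap of `selected` and `validation` within `population`
#' (both are intersected with the population first; drops are reported)
#' and scores it with [hypergeom_upper()].
#'
#' @param selected genes picked by the analysis (e.g. the output of
#'   [select_top_signed()]; character vector or data frame with a `node`
#'   or `gene` column).
#' @param validation the external gene set (e.g. disease genes).
#' @param population the background universe; defaults in pipeline use the
#'   node set of the propagated graph.
#' @return object of class `enrichment_result` with fields `population_size`,
#'   `validation_size`, `selection_size`, `overlap`, `p_value`,
#'   `dropped_selected`, `dropped_validation`. Has a [tidy()] method.
#' @export
enrich_validate <- function(selected, validation, population) {
  sel_all <- as_gene_vector(selected, "selected")
  val_all <- as_gene_vector(validation, "validation")
  pop <- as_gene_vector(population, "population")
  if (length(pop) == 0) {
    rlang::abort("empty population", class = "signetpharm_value_error")
  }
  sel <- intersect(sel_all, pop)
  val <- intersect(val_all, pop)
  k <- length(intersect(sel, val))
  structure(
    list(
      population_size = length(pop),
      validation_size = length(val),
      selection_size = length(sel),
      overlap = k,
      p_value = hypergeom_upper(length(pop), length(val), length(sel), k),
      dropped_selected = setdiff(sel_all, sel),
      dropped_validation = setdiff(val_all, val)
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result: %d/%d selected in %d/%d validation, p = %.4g>\n",
    x$overlap, x$selection_size, x$validation_size, x$population_size,
    x$p_value))
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(population_size = x$population_size,
                 validation_size = x$validation_size,
                 selection_size = x$selection_size,
                 overlap = x$overlap, p_value = x$p_value)
}

#' Enrichment against several validation sets
#'
#' One [enrich_validate()] row per validation set, with optional
#' Benjamini-Hochberg adjustment across the sets (the per-set raw p-values
#' are always reported).
#'
#' @inheritParams enrich_validate
#' @param validations named list of gene sets.
#' @param bh logical: add a `p_adjust` column (Benjamini-Hochberg).
#' @return tibble with one row per validation set.
#' @export
enrich_table <- function(selected, validations, population, bh = FALSE) {
  rows <- purrr::imap(validations, function(v, nm) {
    dplyr::mutate(tidy(enrich_validate(selected, v, population)),
                  validation_set = nm, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (bh) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Intersection summary across gene sets
#'
#' Cardinality bookkeeping for a Venn-style comparison: the size of the
#' global intersection and, per set, the percentage of its members in that
#' intersection. Percentages are rounded half up to `digits` decimals; the
#' printed label additionally trims trailing zeros (so 48.10 prints as
#' "48.1"), matching the mixed precision customary in results tables.
#'
#' @param sets named list (>= 2) of character vectors, or a named list of
#'   cardinalities together with `intersection_size` when only the counts
#'   are known.
#' @param intersection_size optional integer; supply it when `sets` holds
#'   integer cardinalities rather than member vectors.
#' @param digits rounding for the percentage (default 2).
#' @return tibble of class `overlap_summary` with columns `set`, `size`,
#'   `intersection`, `pct`, `pct_label`; attribute `intersection_size`.
#' @export
#' @examples
#' overlap_summary(list(disease = 1159, known = 79, components = 227),
#'                 intersection_size = 38)
overlap_summary <- function(sets, intersection_size = NULL, digits = 2) {
  if (length(sets) < 2) {
    rlang::abort("need at least 2 sets", class = "signetpharm_value_error")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    rlang::abort("sets must be named", class = "signetpharm_value_error")
  }
  if (is.null(intersection_size)) {
    members <- lapply(sets, as_gene_vector)
    inter <- Reduce(intersect, members)
    intersection_size <- length(inter)
    sizes <- lengths(members)
  } else {
    sizes <- unlist(sets)
    if (any(intersection_size > sizes)) {
      rlang::abort("intersection cannot exceed any set size",
                   class = "signetpharm_value_error")
    }
  }
  sizes <- unname(sizes)
  pct <- round_half_up(100 * intersection_size / sizes, digits)
  label <- vapply(pct, function(p) {
    s <- formatC(p, format = "f", digits = digits)
    s <- sub("0+$", "", s)
    sub("\\.$", "", s)
  }, "")
  out <- tibble::tibble(set = names(sets), size = as.integer(sizes),
                        intersection = as.integer(intersection_size),
                        pct = pct, pct_label = label)
  class(out) <- c("overlap_summary", class(out))
  attr(out, "intersection_size") <- as.integer(intersection_size)
  out
}
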