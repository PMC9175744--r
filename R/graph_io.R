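#' Signed graph container
#'
#' Light container for gene networks. A *signed directed graph* models a
#' signaling network whose edges carry activation (`+1`) or inhibition (`-1`)
#' signs; an undirected, unsigned variant models a protein-protein
#' interactome. Gene identifiers are opaque, case-sensitive strings; no
#' symbol-to-ID mapping is attempted.
#'
#' @param edges data frame with character columns `from`, `to` and an
#'   optional integer column `sign` (values `+1`/`-1`; defaults to `+1`).
#' @param nodes optional character vector of node identifiers; the union of
#'   edge endpoints is always included, so this only adds isolated nodes.
#' @param directed logical; `FALSE` stores each unordered pair once (the
#'   interactome dialect) and requires all signs to be `+1` or absent.
#' @param allow_self_loops logical; self-loops are rejected by default.
#' @return an object of class `signed_graph`: a list with elements
#'   `nodes` (sorted character), `edges` (tibble `from`, `to`, `sign`) and
#'   `directed`.
#' @export
#' @examples
#' g <- signed_graph(data.frame(from = "A", to = "B", sign = -1))
#' g$edges
signed_graph <- function(edges, nodes = NULL, directed = TRUE,
                         allow_self_loops = FALSE) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    rlang::abort("edges needs 'from' and 'to' columns",
                 class = "signetpharm_value_error")
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            sign = integer())
  }
  if (!"sign" %in% names(edges)) edges$sign <- rep(1L, nrow(edges))
  # fresh tibble: drops stray attributes and extra columns from the input
  edges <- tibble::tibble(from = as.character(edges$from),
                          to = as.character(edges$to),
                          sign = as.integer(edges$sign))
  if (!all(edges$sign %in% c(-1L, 1L))) {
    rlang::abort("edge signs must be +1 or -1",
                 class = "signetpharm_value_error")
  }
  if (!directed && any(edges$sign == -1L)) {
    rlang::abort("undirected interactomes are unsigned (all signs +1)",
                 class = "signetpharm_value_error")
  }
  if (!allow_self_loops && any(edges$from == edges$to)) {
    rlang::abort("self-loops are not allowed",
                 class = "signetpharm_value_error")
  }
  if (!directed) {
    # canonical order within each unordered pair
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rlang::abort(
      paste0("duplicate ", if (directed) "directed" else "undirected",
             " edge: ", gsub("\r", " -- ", dup)),
      class = "signetpharm_value_error"
    )
  }
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges, directed = directed),
            class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat(sprintf("<signed_graph: %s, %d nodes, %d edges (%d negative)>\n",
              if (x$directed) "directed" else "undirected",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' @rdname signed_graph
#' @param x object to test or convert.
#' @export
is_signed_graph <- function(x) inherits(x, "signed_graph")

#' @rdname signed_graph
#' @export
as_igraph <- function(x) {
  stopifnot(is_signed_graph(x))
  igraph::graph_from_data_frame(x$edges, directed = x$directed,
                                vertices = x$nodes)
}

sign_tokens <- c("+1" = 1L, "1" = 1L, "activate" = 1L,
                 "-1" = -1L, "−1" = -1L, "inhibit" = -1L)

#' Read a signed edge list
#'
#' Dialect: tab- or space-separated columns `source target [sign]`; `#`
#' starts a comment. A comment of the form `# nodes: a b c` (as written by
#' [write_signed_edgelist()]) declares isolated nodes. Sign tokens are
#' `+1`, `1`, `activate`, `-1`, `inhibit`; a missing sign column means `+1`.
#' Duplicate (source, target) lines are an error rather than being merged,
#' to surface data problems early.
#'
#' @param path file to read.
#' @param directed logical; `FALSE` reads the undirected interactome dialect.
#' @return a [signed_graph].
#' @export
read_signed_edgelist <- function(path, directed = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path),
                 class = "signetpharm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  nodes <- character()
  hdr <- grepl("^#\\s*nodes:", lines)
  if (any(hdr)) {
    nodes <- unlist(strsplit(sub("^#\\s*nodes:\\s*", "", lines[hdr]),
                             "[ \t]+"))
    nodes <- nodes[nzchar(nodes)]
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "[ \t]+")
  n_field <- lengths(rows)
  if (any(n_field < 2)) {
    bad <- idx[which(n_field < 2)[1]]
    rlang::abort(paste0("malformed line ", bad, ": fewer than 2 fields"),
                 class = "signetpharm_parse_error")
  }
  from <- vapply(rows, `[`, "", 1)
  to <- vapply(rows, `[`, "", 2)
  sgn <- rep(1L, length(rows))
  has_sign <- n_field >= 3
  if (any(has_sign)) {
    tok <- vapply(rows[has_sign], `[`, "", 3)
    unknown <- !(tok %in% names(sign_tokens))
    if (any(unknown)) {
      bad <- idx[has_sign][which(unknown)[1]]
      rlang::abort(
        paste0("unknown sign token '", tok[unknown][1], "' on line ", bad),
        class = "signetpharm_value_error"
      )
    }
    sgn[has_sign] <- sign_tokens[tok]
  }
  key <- if (directed) paste(from, to, sep = "\r") else
    paste(pmin(from, to), pmax(from, to), sep = "\r")
  if (anyDuplicated(key)) {
    bad <- idx[which(duplicated(key))[1]]
    rlang::abort(paste0("duplicate edge on line ", bad),
                 class = "signetpharm_parse_error")
  }
  signed_graph(tibble::tibble(from = from, to = to, sign = sgn),
               nodes = nodes, directed = directed)
}

#' Write a signed edge list
#'
#' Deterministic: a `# nodes:` header preserving isolated nodes, then edges
#' sorted lexicographically by source, then target. [read_signed_edgelist()]
#' inverts it exactly.
#'
#' @param graph a [signed_graph].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signed_edgelist <- function(graph, path) {
  stopifnot(is_signed_graph(graph))
  e <- dplyr::arrange(graph$edges, .data$from, .data$to)
  lines <- c(
    paste0("# nodes: ", paste(graph$nodes, collapse = "\t")),
    sprintf("%s\t%s\t%+d", e$from, e$to, e$sign)
  )
  ok <- tryCatch({
    writeLines(lines, path); TRUE
  }, error = function(err) FALSE, warning = function(w) FALSE)
  if (!ok) {
    rlang::abort(paste0("cannot write: ", path),
                 class = "signetpharm_io_error")
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. The description is discarded and duplicate members collapsed.
#'
#' @param path GMT file.
#' @return named list of character vectors (one per set, input order).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path),
                 class = "signetpharm_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(list(), character()))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(rows) < 3
  if (any(short)) {
    rlang::abort(
      paste0("GMT line ", which(short)[1], " has fewer than 3 fields"),
      class = "signetpharm_parse_error"
    )
  }
  sets <- lapply(rows, function(r) unique(r[-(1:2)][nzchar(r[-(1:2)])]))
  names(sets) <- vapply(rows, `[`, "", 1)
  if (anyDuplicated(names(sets))) {
    rlang::abort("duplicate set names in GMT",
                 class = "signetpharm_parse_error")
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of descriptions (recycled
#'   `"na"` if missing).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read and write drug profile tables
#'
#' CSV/TSV with columns `drug_id`, `smiles`, `targets`; `targets` holds
#' semicolon-joined `gene` or `gene:sign` tokens (sign `+1`/`-1`; a bare
#' gene means the direction of action is unrecorded and is stored as `NA`).
#'
#' @param path file to read (delimiter inferred from the extension:
#'   `.csv` comma, otherwise tab).
#' @return tibble with columns `drug_id` (character), `smiles` (character,
#'   `NA` when absent) and `targets` (list column of named integer vectors,
#'   names = target genes, values = signs, `NA` = unknown).
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path),
                 class = "signetpharm_io_error")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "#")
  need <- c("drug_id", "smiles", "targets")
  if (!all(need %in% names(df))) {
    rlang::abort("drug table needs columns drug_id, smiles, targets",
                 class = "signetpharm_parse_error")
  }
  parse_targets <- function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(stats::setNames(integer(), character()))
    }
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    toks <- trimws(toks[nzchar(trimws(toks))])
    parts <- strsplit(toks, ":", fixed = TRUE)
    genes <- vapply(parts, `[`, "", 1)
    sgn <- vapply(parts, function(p) {
      if (length(p) < 2) return(NA_integer_)
      if (!p[2] %in% names(sign_tokens)) {
        rlang::abort(paste0("unknown sign token '", p[2], "' in targets"),
                     class = "signetpharm_value_error")
      }
      sign_tokens[[p[2]]]
    }, integer(1))
    if (anyDuplicated(genes)) {
      rlang::abort("duplicate target gene within one drug",
                   class = "signetpharm_value_error")
    }
    stats::setNames(sgn, genes)
  }
  tibble::tibble(
    drug_id = as.character(df$drug_id),
    smiles = ifelse(nzchar(as.character(df$smiles)),
                    as.character(df$smiles), NA_character_),
    targets = lapply(as.character(df$targets), parse_targets)
  )
}

#' @rdname read_drug_table
#' @param drugs tibble as returned by [read_drug_table()].
#' @export
write_drug_table <- function(drugs, path) {
  fmt <- vapply(drugs$targets, function(tg) {
    if (length(tg) == 0) return("")
    tok <- ifelse(is.na(tg), names(tg),
                  paste0(names(tg), ":", sprintf("%+d", tg)))
    paste(tok, collapse = ";")
  }, "")
  df <- data.frame(drug_id = drugs$drug_id,
                   smiles = ifelse(is.na(drugs$smiles), "", drugs$smiles),
                   targets = fmt)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Giant strongly connected component
#'
#' Induced subgraph on the largest strongly connected component of a
#' directed signed graph — the standard preprocessing step before signed
#' propagation, so that every node can both reach and be reached by the
#' seeds. Size ties are broken toward the component containing the
#' lexicographically smallest node.
#'
#' @param graph a directed [signed_graph].
#' @return the induced [signed_graph] on the winning component.
#' @export
giant_strongly_connected <- function(graph) {
  stopifnot(is_signed_graph(graph))
  if (!graph$directed) {
    rlang::abort("giant_strongly_connected needs a directed graph",
                 class = "signetpharm_value_error")
  }
  if (length(graph$nodes) == 0) {
    rlang::abort("empty graph", class = "signetpharm_value_error")
  }
  ig <- as_igraph(graph)
  comp <- igraph::components(ig, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # among tied components, take the one whose smallest member sorts first
    mins <- vapply(best, function(ci) {
      min(graph$nodes[comp$membership == ci])
    }, "")
    best <- best[order(mins)][1]
  }
  keep <- graph$nodes[comp$membership == best]
  induced_subgraph_sg(graph, keep)
}

# induced subgraph on a node subset, preserving signs
induced_subgraph_sg <- function(graph, nodes) {
  e <- dplyr::filter(graph$edges,
                     .data$from %in% nodes & .data$to %in% nodes)
  signed_graph(e, nodes = nodes, directed = graph$directed)
}
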