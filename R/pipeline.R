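#' Pipeline configuration
#'
#' Collects every input path and tuning parameter of [run_pipeline()] and
#' validates that the referenced files exist up front, so a misconfigured
#' run fails before any computation.
#'
#' @param network path to the signed directed network (edge-list dialect of
#'   [read_signed_edgelist()]).
#' @param interactome path to the undirected interactome edge list.
#' @param disease_sets path to a GMT file; the first set is the disease
#'   module, all sets serve as enrichment validation sets.
#' @param drugs path to a drug table ([read_drug_table()]).
#' @param annotations optional path to a TSV with columns `gene`, `term`
#'   (functional annotation for PathSim); `NULL` skips the PathSim stage.
#' @param out_dir output directory, created at run time.
#' @param query_drug `drug_id` whose targets seed propagation and
#'   correlation; default the first row of the drug table.
#' @param restart,tol,max_iter propagation settings (see [rwr()]).
#' @param n_null null-set count for [correlation_zscore()].
#' @param top_fraction fraction for [select_top_signed()] (default 0.1).
#' @param n_clusters cluster count for [cluster_similarity()] (default 6);
#'   capped at the number of drugs available.
#' @param rng_seed integer seed funnelled to every random stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(network, interactome, disease_sets, drugs,
                            annotations = NULL, out_dir,
                            query_drug = NULL, restart = 0.75,
                            tol = 1e-10, max_iter = 10000, n_null = 1000,
                            top_fraction = 0.1, n_clusters = 6,
                            rng_seed = 1L) {
  paths <- c(network = network, interactome = interactome,
             disease_sets = disease_sets, drugs = drugs)
  if (!is.null(annotations)) paths <- c(paths, annotations = annotations)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    rlang::abort(paste0("missing input file(s): ",
                        paste(names(missing), "=", missing,
                              collapse = ", ")),
                 class = "signetpharm_io_error")
  }
  structure(list(network = network, interactome = interactome,
                 disease_sets = disease_sets, drugs = drugs,
                 annotations = annotations, out_dir = out_dir,
                 query_drug = query_drug, restart = restart, tol = tol,
                 max_iter = max_iter, n_null = as.integer(n_null),
                 top_fraction = top_fraction,
                 n_clusters = as.integer(n_clusters),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

write_tsv_det <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Run the full mechanism-inference pipeline
#'
#' Executes, on user-supplied (or synthetic, see [make_demo_fixture()])
#' inputs: (1) overlap bookkeeping of the disease set against every drug's
#' targets; (2) the drug-disease correlation Z-score on the signed network
#' for every drug; (3) SRWR propagation of the query drug's signed targets
#' over the giant strongly connected component, top-fraction selection of
#' predicted inhibitions, and hypergeometric enrichment against every
#' disease set; (4) structure, metapath and interactome-separation
#' similarity with hierarchical clustering (stages without usable input —
#' e.g. no SMILES, no annotations — are skipped and logged). All outputs
#' are plain-text tables plus a JSON log recording the seed, a
#' configuration hash and package versions; a rerun with the same
#' configuration is bit-identical (wall-clock timings go to a separate
#' `timings.tsv`, the only non-deterministic file).
#'
#' @param config a [pipeline_config].
#' @return named character vector of the output files written, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  stage_status <- list()
  timings <- list()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stage_status[[name]] <<- paste0("error: ", conditionMessage(e))
      write_log()
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "signetpharm_pipeline_error", parent = e)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    stage_status[[name]] <<- "ok"
    res
  }
  out_path <- function(f) file.path(config$out_dir, f)
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  cfg_hash <- fnv1a_string(paste(utils::capture.output(utils::str(cfg_for_hash)),
                                 collapse = "\n"))
  write_log <- function() {
    log <- list(
      rng_seed = config$rng_seed,
      config_hash = sprintf("%04x%04x", floor(cfg_hash / 65536),
                            cfg_hash %% 65536),
      package_version = as.character(utils::packageVersion("signetpharm")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      stages = stage_status
    )
    jsonlite::write_json(log, out_path("run_log.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }

  inputs <- run_stage("load", function() {
    list(
      network = read_signed_edgelist(config$network, directed = TRUE),
      interactome = read_signed_edgelist(config$interactome,
                                         directed = FALSE),
      sets = read_gmt(config$disease_sets),
      drugs = read_drug_table(config$drugs),
      annotations = if (!is.null(config$annotations)) {
        utils::read.table(config$annotations, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      }
    )
  })
  disease <- inputs$sets[[1]]
  drugs <- inputs$drugs
  query <- config$query_drug %||% drugs$drug_id[1]
  if (!query %in% drugs$drug_id) {
    rlang::abort(paste0("query drug '", query, "' not in the drug table"),
                 class = "signetpharm_value_error")
  }
  target_sets <- stats::setNames(lapply(drugs$targets, names),
                                 drugs$drug_id)

  ov <- run_stage("overlap", function() {
    summary <- overlap_summary(c(list(disease = disease),
                                 target_sets[lengths(target_sets) > 0]))
    write_tsv_det(summary, out_path("overlap_summary.tsv"))
    summary
  })
  outputs["overlap_summary"] <- out_path("overlap_summary.tsv")

  cors <- run_stage("correlation", function() {
    res <- purrr::imap(target_sets[lengths(target_sets) > 0],
                       function(tg, id) {
      glance(correlation_zscore(
        inputs$network, tg, disease, restart = config$restart,
        tol = config$tol, max_iter = config$max_iter,
        n_null = config$n_null, rng_seed = config$rng_seed))
    })
    tab <- dplyr::bind_rows(res, .id = "drug_id")
    jsonlite::write_json(tab, out_path("correlation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tab
  })
  outputs["correlation"] <- out_path("correlation.json")

  prop <- run_stage("srwr", function() {
    gsc <- giant_strongly_connected(inputs$network)
    seeds <- target_sets[[query]]
    sgn <- drugs$targets[[match(query, drugs$drug_id)]]
    seeds_on <- intersect(seeds, gsc$nodes)
    if (length(seeds_on) == 0) {
      rlang::abort("no query drug target lies on the GSC")
    }
    scores <- suppressWarnings(
      srwr(gsc, sgn[seeds_on], restart = config$restart,
           tol = config$tol, max_iter = config$max_iter))
    write_tsv_det(
      dplyr::mutate(scores, rank = rank(-abs(.data$r),
                                        ties.method = "min")),
      out_path("srwr_scores.tsv"))
    top <- select_top_signed(scores, config$top_fraction, "inhibited")
    writeLines(top$node, out_path("top_inhibited.txt"))
    list(gsc = gsc, scores = scores, top = top)
  })
  outputs["srwr_scores"] <- out_path("srwr_scores.tsv")
  outputs["top_inhibited"] <- out_path("top_inhibited.txt")

  run_stage("enrichment", function() {
    tab <- enrich_table(prop$top$node, inputs$sets, prop$gsc$nodes,
                        bh = length(inputs$sets) > 1)
    write_tsv_det(tab, out_path("enrichment.tsv"))
    tab
  })
  outputs["enrichment"] <- out_path("enrichment.tsv")

  sim_written <- run_stage("similarity", function() {
    written <- character()
    with_smiles <- sum(!is.na(drugs$smiles) & nzchar(drugs$smiles))
    if (with_smiles >= 2) {
      sm <- suppressWarnings(structure_similarity_matrix(drugs))
      write_tsv_det(tidy(sm), out_path("similarity_structure.tsv"))
      cl <- cluster_similarity(sm, min(config$n_clusters, nrow(sm$sim)))
      write_tsv_det(cl, out_path("clusters_structure.tsv"))
      written <- c(written, "similarity_structure", "clusters_structure")
    }
    if (!is.null(inputs$annotations)) {
      ps <- suppressWarnings(pathsim_matrix(drugs, inputs$annotations))
      write_tsv_det(tidy(ps), out_path("similarity_pathsim.tsv"))
      if (nrow(ps$sim) >= 2) {
        cl <- cluster_similarity(ps, min(config$n_clusters, nrow(ps$sim)))
        write_tsv_det(cl, out_path("clusters_pathsim.tsv"))
      }
      written <- c(written, "similarity_pathsim", "clusters_pathsim")
    }
    usable <- target_sets[vapply(target_sets, function(tg) {
      length(intersect(tg, inputs$interactome$nodes)) > 0
    }, logical(1))]
    if (length(usable) >= 2) {
      sab <- suppressMessages(sab_matrix(inputs$interactome, usable))
      write_tsv_det(tidy(sab), out_path("separation_sab.tsv"))
      written <- c(written, "separation_sab")
    }
    written
  })
  for (w in sim_written) {
    outputs[w] <- out_path(paste0(sub("clusters_", "clusters_", w), ".tsv"))
  }

  run_stage("timings", function() {
    write_tsv_det(
      tibble::tibble(stage = names(timings),
                     seconds = round(unlist(timings), 3)),
      out_path("timings.tsv"))
  })
  write_log()
  outputs["run_log"] <- out_path("run_log.json")
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
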