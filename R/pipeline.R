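#' Assemble a pipeline configuration
#'
#' @param network_file Edge-list TSV path.
#' @param driver_file Driver TSV path.
#' @param out_dir Output directory (created if needed).
#' @param expression_file Optional differential-expression TSV
#'   (symbol, log2fc, adj_p).
#' @param alias_file Optional alias TSV; defaults to the shipped fixture;
#'   NA disables aliasing.
#' @param alpha,tol,max_iter Propagation parameters.
#' @param k Subnetwork size (default 100, the usual reporting depth).
#' @param force_include_seeds Keep mapped drivers in the top-K
#'   (default TRUE).
#' @param sig_threshold Adjusted-p flag threshold (default 0.05).
#' @param col_a,col_b,weight_col,header Edge-list parsing options.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(network_file, driver_file, out_dir,
                            expression_file = NULL, alias_file = NULL,
                            alpha = 0.5, tol = 1e-6, max_iter = 1000L,
                            k = 100L, force_include_seeds = TRUE,
                            sig_threshold = 0.05,
                            col_a = 1L, col_b = 2L, weight_col = NULL,
                            header = FALSE) {
  structure(list(network_file = network_file, driver_file = driver_file,
                 out_dir = out_dir, expression_file = expression_file,
                 alias_file = alias_file, alpha = alpha, tol = tol,
                 max_iter = as.integer(max_iter), k = as.integer(k),
                 force_include_seeds = force_include_seeds,
                 sig_threshold = sig_threshold, col_a = col_a, col_b = col_b,
                 weight_col = weight_col, header = header),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected. `overrides` (a named list) takes precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full prioritization pipeline
#'
#' Parse network -> load drivers -> build seed vector -> propagate -> rank
#' -> select top-K -> induced subgraph -> annotate with expression -> export
#' (scores TSV, SIF, GraphML, node/edge TSVs) plus a run manifest recording
#' input checksums, parameters, the parse report, unmapped seeds,
#' convergence status and forced-seed substitutions. The pipeline is fully
#' deterministic: re-running an identical configuration reproduces identical
#' outputs byte for byte.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the `subnetwork`, the full ranking, the
#'   manifest, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  aliases <- pipeline_stage("aliases", {
    if (is.null(config$alias_file)) read_alias_table()
    else if (identical(config$alias_file, NA) ||
             identical(config$alias_file, "none")) NULL
    else read_alias_table(config$alias_file)
  })
  net <- pipeline_stage("parse_network",
    parse_edge_list(config$network_file, col_a = config$col_a,
                    col_b = config$col_b, weight_col = config$weight_col,
                    header = config$header, aliases = aliases))
  seeds <- pipeline_stage("load_drivers",
    load_driver_table(config$driver_file, aliases = aliases))
  Wn <- pipeline_stage("normalize", normalize_adjacency(net))
  sv <- pipeline_stage("seed_vector", build_seed_vector(seeds, Wn))
  params <- propagation_params(config$alpha, config$tol, config$max_iter)
  scores <- pipeline_stage("propagate", propagate(Wn, sv, params))
  ranked <- pipeline_stage("rank", rank_genes(scores, sv, net))
  top <- pipeline_stage("select",
    select_top_k(ranked, config$k, config$force_include_seeds))
  sub <- pipeline_stage("subnetwork", induced_subgraph(net, top, seeds))
  coverage <- NA_real_
  if (!is.null(config$expression_file)) {
    expr <- pipeline_stage("expression", {
      utils::read.delim(config$expression_file, sep = "\t",
                        stringsAsFactors = FALSE)
    })
    sub <- pipeline_stage("annotate",
      annotate_expression(sub, expr, config$sig_threshold))
    coverage <- attr(sub, "coverage")
  }

  paths <- list(scores = file.path(config$out_dir, "scores.tsv"),
                sif = file.path(config$out_dir, "subnetwork.sif"),
                graphml = file.path(config$out_dir, "subnetwork.graphml"),
                tsv_prefix = file.path(config$out_dir, "subnetwork"),
                manifest = file.path(config$out_dir, "manifest.json"))
  pipeline_stage("export", {
    write_scores(ranked, paths$scores)
    export_subnetwork(sub, paths$sif, "sif")
    export_subnetwork(sub, paths$graphml, "graphml")
    export_subnetwork(sub, paths$tsv_prefix, "tsv")
  })

  input_files <- c(network = config$network_file,
                   drivers = config$driver_file,
                   expression = config$expression_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("polarnet")),
    inputs = lapply(input_files,
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    parameters = unclass(config)[c("alpha", "tol", "max_iter", "k",
                                   "force_include_seeds", "sig_threshold")],
    parse_report = net$report,
    n_nodes = n_nodes(net), n_edges = n_edges(net),
    unmapped_seeds = sv$unmapped,
    converged = scores$converged,
    iterations_used = scores$iterations_used,
    forced_seed_substitutions = attr(top, "substitutions"),
    expression_coverage = coverage)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(subnetwork = sub, ranked = ranked, manifest = manifest,
                 paths = paths))
}
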