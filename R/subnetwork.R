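DIRECTION_LEVELS <- c("up_in_WT", "up_in_KO", "unmeasured")

new_subnetwork <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d nodes, %d edges (%d seeds, %d annotated)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$is_seed),
              sum(x$nodes$direction != "unmeasured")))
  invisible(x)
}

#' Induced subgraph on selected genes
#'
#' Restricts the network to the selected genes: the edge table contains
#' exactly the edges of `net` with both endpoints selected; isolated
#' selected genes are retained in the node table. Ranking columns (score,
#' rank, is_seed) are carried over when `genes` is a ranking data.frame;
#' polarization labels of drivers can be attached via `seeds`.
#'
#' @param net A `ppi_network`.
#' @param genes Ranking data.frame from [select_top_k()]/[rank_genes()], or
#'   a character vector of symbols.
#' @param seeds Optional `seed_set` supplying driver polarization labels.
#' @return A `subnetwork`: node table (symbol, score, rank, is_seed,
#'   polarization, log2fc, adj_p, direction) and edge table (from, to,
#'   weight).
#' @export
induced_subgraph <- function(net, genes, seeds = NULL) {
  if (is.character(genes)) {
    genes <- data.frame(symbol = normalize_symbol(genes),
                        score = NA_real_, rank = NA_integer_,
                        is_seed = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(genes) >= 1L)
  sel <- genes$symbol
  keep <- net$edges$from %in% sel & net$edges$to %in% sel
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(symbol = genes$symbol,
                      score = genes$score,
                      rank = genes$rank,
                      is_seed = genes$is_seed,
                      polarization = NA_character_,
                      log2fc = NA_real_,
                      adj_p = NA_real_,
                      direction = "unmeasured",
                      stringsAsFactors = FALSE)
  if (!is.null(seeds)) {
    m <- match(nodes$symbol, seeds$drivers$symbol)
    nodes$polarization <- seeds$drivers$polarization[m]
  }
  new_subnetwork(nodes, edges)
}

#' Annotate a subnetwork with expression changes
#'
#' Joins a differential-expression table onto the node table. The sign
#' convention is log2fc = WT minus knockout, so a positive value means
#' higher expression in WT (the direction reported for M2 markers);
#' `direction` is up_in_WT / up_in_KO by sign, `unmeasured` for unmatched
#' nodes. Topology is never altered and no node is dropped; `sig_threshold`
#' only sets the `significant` flag.
#'
#' @param sub A `subnetwork`.
#' @param expression data.frame with columns symbol, log2fc and optionally
#'   adj_p; symbols must be unique.
#' @param sig_threshold Adjusted-p cutoff for the significance flag
#'   (default 0.05).
#' @return The annotated `subnetwork`; the fraction of nodes with a matched
#'   record is attached as attribute `"coverage"`.
#' @export
annotate_expression <- function(sub, expression, sig_threshold = 0.05) {
  stopifnot(inherits(sub, "subnetwork"))
  if (nrow(expression) > 0L) {
    expression$symbol <- normalize_symbol(expression$symbol)
    if (anyDuplicated(expression$symbol)) {
      stop("duplicate symbols in expression table: annotation ambiguous")
    }
    if (!"adj_p" %in% names(expression)) expression$adj_p <- NA_real_
    bad_p <- !is.na(expression$adj_p) &
      (expression$adj_p < 0 | expression$adj_p > 1)
    if (any(bad_p) || any(!is.finite(expression$log2fc))) {
      stop("expression records need finite log2fc and adj_p in [0, 1]")
    }
    m <- match(sub$nodes$symbol, expression$symbol)
    hit <- !is.na(m)
    sub$nodes$log2fc[hit] <- expression$log2fc[m[hit]]
    sub$nodes$adj_p[hit] <- expression$adj_p[m[hit]]
    sub$nodes$direction <- ifelse(is.na(sub$nodes$log2fc), "unmeasured",
                                  ifelse(sub$nodes$log2fc >= 0,
                                         "up_in_WT", "up_in_KO"))
  }
  sub$nodes$significant <- !is.na(sub$nodes$adj_p) &
    sub$nodes$adj_p < sig_threshold
  attr(sub, "coverage") <- mean(sub$nodes$direction != "unmeasured")
  sub
}

#' Augment a seed set with newly validated drivers
#'
#' Supports the iterative workflow: once predicted candidates are validated
#' as M1/M2 drivers they are merged into the seed set (dedup by symbol,
#' weights summed, evidence unioned) and the pipeline is re-run. The input
#' seed set is unmodified.
#'
#' @param seeds A `seed_set`.
#' @param validated A `seed_set`, or a data.frame with columns symbol,
#'   polarization, and optionally evidence, weight.
#' @return The merged `seed_set`.
#' @export
iterate_seeds <- function(seeds, validated) {
  if (inherits(validated, "seed_set")) validated <- validated$drivers
  ev_old <- vapply(seeds$drivers$evidence, paste, "", collapse = ",")
  ev_new <- if ("evidence" %in% names(validated)) {
    if (is.list(validated$evidence)) {
      vapply(validated$evidence, paste, "", collapse = ",")
    } else validated$evidence
  } else "rtpcr"
  seed_set(symbol = c(seeds$drivers$symbol, validated$symbol),
           polarization = c(seeds$drivers$polarization,
                            validated$polarization),
           evidence = c(ev_old, rep_len(ev_new, nrow(validated))),
           weight = c(seeds$drivers$weight,
                      if ("weight" %in% names(validated)) validated$weight
                      else rep(1, nrow(validated))),
           provenance = paste0(seeds$provenance, " + iterated"))
}

#' Export a subnetwork
#'
#' Writers for downstream network viewers: `"sif"` (one line per edge,
#' "A<TAB>pp<TAB>B"; isolated nodes as bare-symbol lines), `"graphml"`
#' (node attributes score, is_seed, polarization, log2fc, direction), or
#' `"tsv"` (node table + edge table pair, a lossless round trip via
#' [read_subnetwork_tsv()]).
#'
#' @param sub A `subnetwork`.
#' @param path Output path. For `"tsv"` this is a prefix: writes
#'   `<path>_nodes.tsv` and `<path>_edges.tsv`.
#' @param format One of "sif", "graphml", "tsv".
#' @return Invisibly, the path(s) written.
#' @export
export_subnetwork <- function(sub, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  switch(format,
    sif = {
      con_lines <- character()
      if (nrow(sub$edges) > 0L) {
        con_lines <- paste(sub$edges$from, "pp", sub$edges$to, sep = "\t")
      }
      isolated <- setdiff(sub$nodes$symbol,
                          c(sub$edges$from, sub$edges$to))
      writeLines(c(con_lines, isolated), path)
      invisible(path)
    },
    graphml = {
      write_graphml(sub, path)
      invisible(path)
    },
    tsv = {
      paths <- paste0(path, c("_nodes.tsv", "_edges.tsv"))
      utils::write.table(sub$nodes, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(sub$edges, paths[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      invisible(paths)
    })
}

#' Re-import a TSV-exported subnetwork
#'
#' @param prefix The prefix passed to [export_subnetwork()] with
#'   `format = "tsv"`.
#' @return A `subnetwork` identical to the exported one.
#' @export
read_subnetwork_tsv <- function(prefix) {
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(prefix, "_edges.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  nodes$symbol <- as.character(nodes$symbol)
  nodes$polarization <- as.character(nodes$polarization)
  nodes$direction <- as.character(nodes$direction)
  for (col in c("score", "log2fc", "adj_p")) {
    if (col %in% names(nodes)) nodes[[col]] <- as.numeric(nodes[[col]])
  }
  if ("rank" %in% names(nodes)) nodes$rank <- as.integer(nodes$rank)
  new_subnetwork(nodes, edges)
}

write_graphml <- function(sub, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c(id = "score", type = "double"),
    c(id = "rank", type = "int"),
    c(id = "is_seed", type = "boolean"),
    c(id = "polarization", type = "string"),
    c(id = "log2fc", type = "double"),
    c(id = "direction", type = "string"))
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[["id"]], `for` = "node",
                        attr.name = k[["id"]], attr.type = k[["type"]])
  }
  xml2::xml_add_child(doc, "key", id = "weight", `for` = "edge",
                      attr.name = "weight", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "subnetwork",
                           edgedefault = "undirected")
  for (i in seq_len(nrow(sub$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = sub$nodes$symbol[i])
    add_data <- function(key, value) {
      if (length(value) == 1L && !is.na(value)) {
        d <- xml2::xml_add_child(nd, "data", key = key)
        xml2::xml_text(d) <- as.character(value)
      }
    }
    add_data("score", sub$nodes$score[i])
    add_data("rank", sub$nodes$rank[i])
    add_data("is_seed", tolower(as.character(sub$nodes$is_seed[i])))
    add_data("polarization", sub$nodes$polarization[i])
    add_data("log2fc", sub$nodes$log2fc[i])
    add_data("direction", sub$nodes$direction[i])
  }
  for (i in seq_len(nrow(sub$edges))) {
    e <- xml2::xml_add_child(g, "edge",
                             source = sub$edges$from[i],
                             target = sub$edges$to[i])
    d <- xml2::xml_add_child(e, "data", key = "weight")
    xml2::xml_text(d) <- as.character(sub$edges$weight[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
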