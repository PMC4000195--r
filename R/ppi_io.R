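#' Normalize a gene symbol
#'
#' Uppercases and trims a symbol token. Symbols containing internal
#' whitespace or empty after trimming are rejected.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x))) stop("empty gene symbol")
  if (any(grepl("[[:space:]]", x))) stop("gene symbol contains whitespace")
  x
}

#' Read a gene alias table
#'
#' Two-column TSV (alias, symbol) mapping common/protein names to official
#' gene symbols, e.g. COX2 -> PTGS2, uPA -> PLAU. The package ships an
#' editable fixture covering the M1/M2 marker panel.
#'
#' @param path Path to the alias TSV. Defaults to the shipped fixture.
#' @return Named character vector: names are aliases, values are symbols,
#'   both uppercased.
#' @export
read_alias_table <- function(path = system.file("extdata", "gene_aliases.tsv",
                                                package = "polarnet")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("alias", "symbol") %in% names(tab)))
  stats::setNames(normalize_symbol(tab$symbol), normalize_symbol(tab$alias))
}

#' Apply an alias table to symbols
#'
#' @param symbols Character vector of (raw) symbols.
#' @param aliases Named character vector from [read_alias_table()], or NULL
#'   for no aliasing.
#' @return Normalized symbols with aliases resolved.
#' @export
resolve_aliases <- function(symbols, aliases = NULL) {
  symbols <- normalize_symbol(symbols)
  if (is.null(aliases)) return(symbols)
  hit <- symbols %in% names(aliases)
  symbols[hit] <- unname(aliases[symbols[hit]])
  symbols
}

new_ppi_network <- function(nodes, edges, report = NULL) {
  structure(list(nodes = nodes, edges = edges, report = report),
            class = "ppi_network")
}

# Canonical undirected edge orientation: from < to lexicographically.
orient_edges <- function(from, to) {
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  list(from = from, to = to)
}

#' Parse a tab-delimited PPI edge list
#'
#' Builds a simple undirected network over gene symbols from a tab-delimited
#' stream. Column indices are configurable so both bare two-column files and
#' BioGRID-style multi-column files (select the two "Official Symbol"
#' columns) parse. Self-loops are dropped; duplicate edges (undirected) are
#' collapsed keeping the maximum weight; symbols are uppercased. A parse
#' report (lines read, edges kept, self-loops dropped, duplicates collapsed)
#' is attached to the result.
#'
#' @param path Path to the edge-list file, or a character vector of lines
#'   via `lines =`.
#' @param col_a,col_b 1-based column indices of the two symbol columns.
#' @param weight_col Optional 1-based column index of an edge weight
#'   (positive real); default all weights 1.
#' @param skip_comments Drop lines starting with "#" (default TRUE).
#' @param header Skip one leading non-comment line (default FALSE).
#' @param aliases Optional alias table applied to both symbol columns.
#' @param lines Character vector of lines, used instead of `path`.
#' @return A `ppi_network`: list with `nodes` (sorted character vector),
#'   `edges` (data.frame from, to, weight with from < to), and `report`.
#' @export
parse_edge_list <- function(path = NULL, col_a = 1L, col_b = 2L,
                            weight_col = NULL, skip_comments = TRUE,
                            header = FALSE, aliases = NULL, lines = NULL) {
  if (col_a == col_b) stop("col_a and col_b must differ")
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  n_read <- length(lines)
  if (skip_comments) lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines) >= 1L) lines <- lines[-1L]
  if (length(lines) == 0L) stop("no edges: input contains no data lines")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(col_a, col_b, weight_col)
  short <- which(lengths(fields) < need)
  if (length(short) > 0L) {
    stop(sprintf("line %d has %d columns; %d required",
                 short[1L], lengths(fields)[short[1L]], need))
  }
  a <- resolve_aliases(vapply(fields, `[[`, "", col_a), aliases)
  b <- resolve_aliases(vapply(fields, `[[`, "", col_b), aliases)
  w <- if (is.null(weight_col)) rep(1, length(a)) else {
    w <- as.numeric(vapply(fields, `[[`, "", weight_col))
    if (any(!is.finite(w) | w <= 0)) stop("edge weights must be positive reals")
    w
  }

  loop <- a == b
  n_loops <- sum(loop)
  a <- a[!loop]; b <- b[!loop]; w <- w[!loop]
  if (length(a) == 0L) stop("no edges: all records were self-loops")

  o <- orient_edges(a, b)
  key <- paste(o$from, o$to, sep = "\t")
  n_dup <- sum(duplicated(key))
  w_max <- tapply(w, key, max)
  keys <- names(w_max)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                      to   = vapply(parts, `[[`, "", 2L),
                      weight = as.numeric(w_max),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  report <- list(lines_read = n_read, edges_kept = nrow(edges),
                 self_loops_dropped = n_loops, duplicates_collapsed = n_dup)
  new_ppi_network(nodes, edges, report)
}

#' Construct a PPI network from vectors
#'
#' @param from,to Endpoint symbol vectors (same length).
#' @param weight Positive edge weights, recycled; default 1.
#' @param nodes Optional extra node symbols (isolated nodes permitted).
#' @return A `ppi_network`.
#' @export
ppi_network <- function(from = character(), to = character(), weight = 1,
                        nodes = character()) {
  from <- normalize_symbol(from); to <- normalize_symbol(to)
  stopifnot(length(from) == length(to))
  weight <- rep_len(as.numeric(weight), length(from))
  keep <- from != to
  o <- orient_edges(from[keep], to[keep])
  key <- paste(o$from, o$to, sep = "\t")
  first <- !duplicated(key)
  if (length(key) > 0L) {
    w <- as.numeric(tapply(weight[keep], key, max)[key[first]])
  } else w <- numeric()
  edges <- data.frame(from = o$from[first], to = o$to[first], weight = w,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(edges$from, edges$to,
                             if (length(nodes)) normalize_symbol(nodes))))
  new_ppi_network(all_nodes, edges)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes and edges
#' @param net A `ppi_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Weighted node degrees
#'
#' @param net A `ppi_network`.
#' @return Named numeric vector of weighted degrees over all nodes
#'   (isolated nodes have degree 0).
#' @export
node_degrees <- function(net) {
  deg <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0L) {
    tf <- tapply(net$edges$weight, net$edges$from, sum)
    tt <- tapply(net$edges$weight, net$edges$to, sum)
    deg[names(tf)] <- deg[names(tf)] + tf
    deg[names(tt)] <- deg[names(tt)] + tt
  }
  deg
}

#' Write a network as a canonical edge-list TSV
#'
#' Two columns (from, to) or three with `weight = TRUE`. Round-trips through
#' [parse_edge_list()] to an identical node and edge set (isolated nodes are
#' not representable in an edge list and are dropped on write).
#'
#' @param net A `ppi_network`.
#' @param path Output path.
#' @param weight Include the weight column (default FALSE).
#' @export
write_edge_list <- function(net, path, weight = FALSE) {
  cols <- if (weight) c("from", "to", "weight") else c("from", "to")
  utils::write.table(net$edges[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Symmetric degree-normalized adjacency
#'
#' Builds W' = D^(-1/2) W D^(-1/2) over the network's nodes, the propagation
#' operator of the random walk with restart: W'[i,j] =
#' w(i,j)/sqrt(deg(i) deg(j)) for edges, 0 otherwise. Node ordering is
#' lexicographic for determinism; rows of isolated nodes are all-zero. The
#' spectral radius of W' is at most 1, which guarantees convergence of the
#' propagation iteration for any mixing parameter alpha < 1.
#'
#' @param net A `ppi_network` with at least one node.
#' @return A `normalized_adjacency`: list with `ordering` (character) and
#'   `W` (sparse symmetric \link[Matrix]{Matrix}).
#' @export
normalize_adjacency <- function(net) {
  stopifnot(inherits(net, "ppi_network"), length(net$nodes) >= 1L)
  ordering <- sort(net$nodes)
  n <- length(ordering)
  idx <- stats::setNames(seq_len(n), ordering)
  if (nrow(net$edges) > 0L) {
    i <- idx[net$edges$from]; j <- idx[net$edges$to]
    deg <- node_degrees(net)[ordering]
    val <- net$edges$weight / sqrt(deg[i] * deg[j])
    W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(val, val),
                              dims = c(n, n), dimnames = list(ordering, ordering))
  } else {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n), dimnames = list(ordering, ordering))
  }
  structure(list(ordering = ordering, W = W), class = "normalized_adjacency")
}

#' Spectral radius by power iteration
#'
#' Testing utility for small symmetric operators: dominant eigenvalue
#' magnitude of `W` by power iteration.
#'
#' @param W A square matrix (dense or sparse).
#' @param n_iter Iterations (default 500).
#' @return Nonnegative scalar estimate of the spectral radius.
#' @export
spectral_radius <- function(W, n_iter = 500L) {
  n <- nrow(W)
  v <- rep(1 / sqrt(n), n)
  lambda <- 0
  for (k in seq_len(n_iter)) {
    v2 <- as.numeric(W %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) return(0)
    lambda <- nv
    v <- v2 / nv
  }
  abs(lambda)
}
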