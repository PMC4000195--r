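# Every generator seeds R's RNG locally and restores it on exit, so each is
# a pure function of its parameters and rng_seed.
with_rng_seed <- function(seed, code) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

synthetic_symbols <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a scale-free synthetic PPI network
#'
#' Preferential attachment (Barabasi-Albert) graph standing in for a real
#' interactome, whose degree distribution is heavy-tailed like observed PPI
#' networks. Nodes are labelled G0001, G0002, ... Deterministic given
#' `rng_seed`.
#'
#' @param n_nodes Number of nodes (>= attachment + 1).
#' @param attachment Edges added per incoming node (default 3).
#' @param rng_seed Integer seed.
#' @return A `ppi_network` with unit edge weights.
#' @export
generate_network <- function(n_nodes, attachment = 3L, rng_seed = 1L) {
  stopifnot(n_nodes >= attachment + 1L, attachment >= 1L)
  g <- with_rng_seed(rng_seed,
    igraph::sample_pa(n_nodes, m = attachment, directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  syms <- synthetic_symbols(n_nodes)
  ppi_network(from = syms[el[, 1]], to = syms[el[, 2]],
              nodes = syms)
}

#' Plant a densely interconnected module
#'
#' Selects `size` nodes uniformly at random, adds each missing within-module
#' edge independently with probability `within_p` (never removing edges),
#' and reveals `n_reveal` members as known driver seeds; the rest are the
#' held-out ground truth for recovery benchmarking. Module members are split
#' alternately into M1/M2 classes so both polarization classes are
#' recoverable.
#'
#' @param net A `ppi_network`.
#' @param size Module size (<= node count).
#' @param within_p Probability of each within-module edge (in [0, 1]).
#' @param n_reveal Number of revealed seeds (< size).
#' @param rng_seed Integer seed.
#' @return list(network = augmented `ppi_network`, truth = `synthetic_truth`
#'   with module_members, revealed_seeds, held_out, module_class, the node
#'   universe, and a parameter echo).
#' @export
plant_module <- function(net, size = 30L, within_p = 0.3, n_reveal = 10L,
                         rng_seed = 1L) {
  stopifnot(size <= length(net$nodes), n_reveal < size,
            within_p >= 0, within_p <= 1)
  out <- with_rng_seed(rng_seed, {
    members <- sort(sample(net$nodes, size))
    pairs <- t(utils::combn(members, 2L))
    existing <- paste(net$edges$from, net$edges$to, sep = "\t")
    cand <- paste(pairs[, 1], pairs[, 2], sep = "\t")
    missing <- which(!cand %in% existing)
    add <- missing[stats::runif(length(missing)) < within_p]
    revealed <- sort(sample(members, n_reveal))
    list(members = members, add = pairs[add, , drop = FALSE],
         revealed = revealed)
  })
  edges <- net$edges
  if (nrow(out$add) > 0L) {
    edges <- rbind(edges,
                   data.frame(from = out$add[, 1], to = out$add[, 2],
                              weight = 1, stringsAsFactors = FALSE))
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  aug <- new_ppi_network(net$nodes, edges)

  module_class <- stats::setNames(
    rep(c("M2", "M1"), length.out = length(out$members)), out$members)
  truth <- structure(list(
    module_members = out$members,
    revealed_seeds = out$revealed,
    held_out = setdiff(out$members, out$revealed),
    module_class = module_class,
    all_genes = net$nodes,
    params = list(n_nodes = length(net$nodes), module_size = size,
                  within_p = within_p, n_reveal = n_reveal,
                  edges_added = nrow(out$add), rng_seed = as.integer(rng_seed))),
    class = "synthetic_truth")
  list(network = aug, truth = truth)
}

#' Seed set for the revealed drivers of a planted module
#'
#' @param truth A `synthetic_truth`.
#' @return A `seed_set` over the revealed seeds with their planted M1/M2
#'   classes and "rtpcr" evidence.
#' @export
truth_seed_set <- function(truth) {
  seed_set(symbol = truth$revealed_seeds,
           polarization = unname(truth$module_class[truth$revealed_seeds]),
           evidence = "rtpcr",
           provenance = "synthetic planted-module drivers")
}

#' Simulate a two-group differential-expression table
#'
#' Emulates the WT vs. knockout two-group microarray design: `n_per_group`
#' replicates per group on log2 scale with i.i.d. Gaussian noise. Module
#' genes classed M2 get a +`effect_log2` mean shift in the WT group, M1
#' genes a -`effect_log2` shift, background genes none. Per gene, log2fc is
#' the WT minus KO group mean and adj_p a Benjamini-Hochberg-adjusted
#' two-sample t-test p-value.
#'
#' @param truth A `synthetic_truth`.
#' @param effect_log2 Mean shift magnitude (log2 units, default 2).
#' @param noise_sd Residual standard deviation (log2 units, default 0.5).
#' @param n_per_group Replicates per group (>= 2, default 5).
#' @param rng_seed Integer seed.
#' @param genes Gene panel; defaults to the truth's node universe.
#' @return data.frame (symbol, log2fc, p_value, adj_p) with the per-sample
#'   log2 expression matrix in attribute `"matrix"` (genes x samples,
#'   columns WT1..WTn, KO1..KOn).
#' @export
generate_expression <- function(truth, effect_log2 = 2, noise_sd = 0.5,
                                n_per_group = 5L, rng_seed = 1L,
                                genes = truth$all_genes) {
  stopifnot(n_per_group >= 2L, noise_sd > 0)
  n_g <- length(genes)
  shift <- numeric(n_g)
  cls <- truth$module_class[genes]
  shift[!is.na(cls) & cls == "M2"] <- effect_log2
  shift[!is.na(cls) & cls == "M1"] <- -effect_log2
  mat <- with_rng_seed(rng_seed, {
    base <- matrix(stats::rnorm(n_g * 2L * n_per_group, sd = noise_sd),
                   nrow = n_g)
    base[, seq_len(n_per_group)] <- base[, seq_len(n_per_group)] + shift
    base
  })
  dimnames(mat) <- list(genes, c(paste0("WT", seq_len(n_per_group)),
                                 paste0("KO", seq_len(n_per_group))))
  wt <- mat[, seq_len(n_per_group), drop = FALSE]
  ko <- mat[, n_per_group + seq_len(n_per_group), drop = FALSE]
  log2fc <- rowMeans(wt) - rowMeans(ko)
  p <- vapply(seq_len(n_g), function(i) {
    stats::t.test(wt[i, ], ko[i, ], var.equal = TRUE)$p.value
  }, numeric(1))
  out <- data.frame(symbol = genes, log2fc = unname(log2fc),
                    p_value = unname(p),
                    adj_p = unname(stats::p.adjust(p, method = "BH")),
                    stringsAsFactors = FALSE)
  attr(out, "matrix") <- mat
  out
}

#' Simulate a qPCR Ct table
#'
#' Gaussian Ct readings around specified per-gene target and reference
#' means, one row per replicate, for exercising the relative-expression
#' quantification.
#'
#' @param genes Gene symbols.
#' @param ct_gene_mean,ct_reference_mean Mean cycles per gene (recycled).
#' @param noise_sd Ct noise standard deviation (cycles); 0 gives the means
#'   exactly.
#' @param n_replicates Rows per gene (default 3).
#' @param rng_seed Integer seed.
#' @return data.frame (sample_id, gene, ct_gene, ct_reference).
#' @export
generate_ct_table <- function(genes, ct_gene_mean, ct_reference_mean = 18,
                              noise_sd = 0.1, n_replicates = 3L,
                              rng_seed = 1L) {
  stopifnot(noise_sd >= 0, n_replicates >= 1L)
  genes <- normalize_symbol(genes)
  ct_gene_mean <- rep_len(ct_gene_mean, length(genes))
  ct_reference_mean <- rep_len(ct_reference_mean, length(genes))
  n <- length(genes) * n_replicates
  tab <- data.frame(
    sample_id = paste0("S", rep(seq_len(n_replicates), times = length(genes))),
    gene = rep(genes, each = n_replicates),
    ct_gene = rep(ct_gene_mean, each = n_replicates),
    ct_reference = rep(ct_reference_mean, each = n_replicates),
    stringsAsFactors = FALSE)
  if (noise_sd > 0) {
    noise <- with_rng_seed(rng_seed,
      matrix(stats::rnorm(2L * n, sd = noise_sd), ncol = 2L))
    tab$ct_gene <- tab$ct_gene + noise[, 1]
    tab$ct_reference <- tab$ct_reference + noise[, 2]
  }
  tab
}

#' Write a complete synthetic study to disk
#'
#' Generates and writes the exact inputs the pipeline consumes: an edge-list
#' TSV, a driver TSV (the revealed seeds), an expression TSV, and a truth
#' JSON (parameters plus module membership).
#'
#' @param dir Output directory (created if needed).
#' @param n_nodes,attachment,module_size,within_p,n_reveal,effect_log2,noise_sd,n_per_group
#'   Generation parameters; defaults are the package's reference study
#'   conditions.
#' @param rng_seed Integer seed.
#' @return Invisibly, a list with the file paths and the in-memory objects.
#' @export
simulate_study <- function(dir, n_nodes = 1000L, attachment = 3L,
                           module_size = 30L, within_p = 0.3,
                           n_reveal = 10L, effect_log2 = 2, noise_sd = 0.5,
                           n_per_group = 5L, rng_seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng_seed <- as.integer(rng_seed)
  net0 <- generate_network(n_nodes, attachment, rng_seed)
  planted <- plant_module(net0, module_size, within_p, n_reveal,
                          rng_seed + 1L)
  seeds <- truth_seed_set(planted$truth)
  expr <- generate_expression(planted$truth, effect_log2, noise_sd,
                              n_per_group, rng_seed + 2L)
  paths <- list(network = file.path(dir, "network_edges.tsv"),
                drivers = file.path(dir, "drivers.tsv"),
                expression = file.path(dir, "expression.tsv"),
                truth = file.path(dir, "truth.json"))
  write_edge_list(planted$network, paths$network)
  utils::write.table(
    data.frame(symbol = seeds$drivers$symbol,
               polarization = seeds$drivers$polarization,
               evidence = vapply(seeds$drivers$evidence, paste, "",
                                 collapse = ","),
               weight = seeds$drivers$weight),
    paths$drivers, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr[, c("symbol", "log2fc", "adj_p")],
                     paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(params = c(planted$truth$params,
                    list(attachment = attachment, effect_log2 = effect_log2,
                         noise_sd = noise_sd, n_per_group = n_per_group,
                         rng_seed = rng_seed)),
         module_members = planted$truth$module_members,
         revealed_seeds = planted$truth$revealed_seeds,
         held_out = planted$truth$held_out),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(paths = paths, network = planted$network,
                 truth = planted$truth, seeds = seeds, expression = expr))
}
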