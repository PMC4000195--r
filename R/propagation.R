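#' Propagation parameters
#'
#' @param alpha Mixing (restart) parameter in [0, 1): the fraction of score
#'   mass diffused over the network per step; 1 - alpha is returned to the
#'   seed prior. Default 0.5.
#' @param tol L1 convergence tolerance on successive iterates. Default 1e-6.
#' @param max_iter Iteration cap. Default 1000.
#' @return A `propagation_params` list.
#' @export
propagation_params <- function(alpha = 0.5, tol = 1e-6, max_iter = 1000L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha < 1,
            tol > 0, max_iter >= 1L)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "propagation_params")
}

new_score_vector <- function(ordering, f, iterations, converged) {
  structure(list(ordering = ordering, f = stats::setNames(f, ordering),
                 iterations_used = iterations, converged = converged),
            class = "score_vector")
}

#' Network propagation by random walk with restart
#'
#' Iterates F <- alpha * W' F + (1 - alpha) * Y from F = Y until the L1
#' change between successive iterates falls below `tol` (or `max_iter` is
#' reached), where W' is the symmetric degree-normalized adjacency and Y the
#' seed prior. Because the spectral radius of W' is at most 1, the iteration
#' is a contraction for alpha < 1 and converges to the unique fixed point
#' F = (1 - alpha)(I - alpha W')^{-1} Y. Nodes in components containing no
#' seed score exactly 0.
#'
#' @param Wn A `normalized_adjacency`.
#' @param seeds A `seed_vector` sharing `Wn`'s ordering.
#' @param params A `propagation_params`.
#' @return A `score_vector`: `ordering`, nonnegative named `f`,
#'   `iterations_used`, `converged`.
#' @export
propagate <- function(Wn, seeds, params = propagation_params()) {
  stopifnot(inherits(Wn, "normalized_adjacency"),
            inherits(seeds, "seed_vector"),
            identical(Wn$ordering, seeds$ordering))
  y <- unname(seeds$y)
  stopifnot(abs(sum(y) - 1) < 1e-12)
  alpha <- params$alpha
  f <- y
  converged <- FALSE
  iters <- 0L
  for (t in seq_len(params$max_iter)) {
    f_new <- alpha * as.numeric(Wn$W %*% f) + (1 - alpha) * y
    iters <- t
    if (any(!is.finite(f_new))) stop("non-finite values in propagation")
    if (sum(abs(f_new - f)) < params$tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  new_score_vector(Wn$ordering, f, iters, converged)
}

#' Closed-form propagation scores (dense linear-solve oracle)
#'
#' Computes the exact fixed point F = (1 - alpha)(I - alpha W')^{-1} Y by a
#' dense solve. Intended as the independent oracle for [propagate()] on
#' small networks; refuses dimensions above `max_n`.
#'
#' @param Wn A `normalized_adjacency`.
#' @param seeds A `seed_vector` sharing the ordering.
#' @param alpha Mixing parameter in [0, 1).
#' @param max_n Dimension cap for the dense solve (default 2000).
#' @return A `score_vector` with `converged = TRUE`.
#' @export
solve_closed_form <- function(Wn, seeds, alpha = 0.5, max_n = 2000L) {
  stopifnot(inherits(Wn, "normalized_adjacency"),
            identical(Wn$ordering, seeds$ordering),
            alpha >= 0, alpha < 1)
  n <- length(Wn$ordering)
  if (n > max_n) {
    stop(sprintf("dimension %d exceeds dense-solve cap %d; use propagate()",
                 n, max_n))
  }
  A <- diag(n) - alpha * as.matrix(Wn$W)
  f <- as.numeric(solve(A, (1 - alpha) * unname(seeds$y)))
  new_score_vector(Wn$ordering, f, 0L, TRUE)
}

#' Rank genes by propagation score
#'
#' Sorts by score (descending), breaking ties by weighted degree
#' (descending) then symbol (ascending), for a fully deterministic ranking.
#'
#' @param scores A `score_vector`.
#' @param seeds A `seed_vector` sharing the ordering.
#' @param net The `ppi_network` the scores were computed on (for degrees).
#' @return data.frame (symbol, score, rank, is_seed, degree), ranks 1..n.
#' @export
rank_genes <- function(scores, seeds, net) {
  stopifnot(inherits(scores, "score_vector"),
            identical(scores$ordering, seeds$ordering))
  deg <- node_degrees(net)[scores$ordering]
  d <- data.frame(symbol = scores$ordering,
                  score = unname(scores$f),
                  is_seed = unname(seeds$y > 0),
                  degree = unname(deg),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$score, -d$degree, d$symbol), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d[, c("symbol", "score", "rank", "is_seed", "degree")]
}

#' Select the top-K ranked genes
#'
#' Returns the first `min(k, n)` genes. With `force_include_seeds`, any
#' mapped seed ranked below k replaces the lowest-ranked non-seed in the
#' selection (so the subnetwork always contains the known drivers); the
#' substitutions performed are recorded in the `"substitutions"` attribute.
#'
#' @param ranked Output of [rank_genes()].
#' @param k Positive integer.
#' @param force_include_seeds Default TRUE.
#' @return data.frame subset of `ranked` (original ranks preserved), ordered
#'   by rank.
#' @export
select_top_k <- function(ranked, k, force_include_seeds = TRUE) {
  stopifnot(k >= 1L)
  n <- nrow(ranked)
  k <- min(as.integer(k), n)
  sel <- ranked[seq_len(k), , drop = FALSE]
  subs <- data.frame(dropped = character(), added = character(),
                     stringsAsFactors = FALSE)
  if (force_include_seeds) {
    missing_seeds <- ranked[ranked$is_seed & ranked$rank > k, , drop = FALSE]
    for (i in seq_len(nrow(missing_seeds))) {
      non_seed <- which(!sel$is_seed)
      if (length(non_seed) == 0L) break
      drop_i <- non_seed[length(non_seed)]  # lowest-ranked non-seed
      subs <- rbind(subs, data.frame(dropped = sel$symbol[drop_i],
                                     added = missing_seeds$symbol[i],
                                     stringsAsFactors = FALSE))
      sel <- rbind(sel[-drop_i, , drop = FALSE],
                   missing_seeds[i, , drop = FALSE])
    }
    sel <- sel[order(sel$rank), , drop = FALSE]
  }
  rownames(sel) <- NULL
  attr(sel, "substitutions") <- subs
  sel
}

#' Write a ranking as TSV
#' @param ranked Output of [rank_genes()] or [select_top_k()].
#' @param path Output path.
#' @export
write_scores <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
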