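test_that("alpha = 0 returns the seed vector exactly", {
  net <- random_network(15, 0.3, seed = 2)
  Wn <- normalize_adjacency(net)
  sv <- random_seed_vector(Wn, 3, seed = 2)
  sc <- propagate(Wn, sv, propagation_params(alpha = 0))
  expect_identical(unname(sc$f), unname(sv$y))
  expect_true(sc$converged)
})

test_that("a single isolated seeded node converges to (1 - alpha) * Y", {
  net <- ppi_network("A", "B", nodes = c("A", "B", "Z"))
  Wn <- normalize_adjacency(net)
  sv <- build_seed_vector(seed_set("Z"), Wn)
  sc <- propagate(Wn, sv, propagation_params(alpha = 0.5, tol = 1e-12))
  expect_equal(unname(sc$f["Z"]), 0.5)
  expect_equal(unname(sc$f[c("A", "B")]), c(0, 0))
})

test_that("iterative propagation matches the closed-form solve on a seeded path", {
  net <- path_network(c("A", "B", "C"))
  Wn <- normalize_adjacency(net)
  sv <- build_seed_vector(seed_set("A"), Wn)
  sc <- propagate(Wn, sv, propagation_params(alpha = 0.5, tol = 1e-10))
  cf <- solve_closed_form(Wn, sv, alpha = 0.5)
  expect_equal(unname(sc$f), unname(cf$f), tolerance = 1e-8)
  expect_true(sc$f["A"] > sc$f["B"])
  expect_true(sc$f["B"] > sc$f["C"])
})

test_that("closed form is the exact fixed point (residual oracle)", {
  for (seed in 1:5) {
    net <- random_network(50, 0.15, seed = seed)
    Wn <- normalize_adjacency(net)
    sv <- random_seed_vector(Wn, 5, seed = seed + 100)
    cf <- solve_closed_form(Wn, sv, alpha = 0.7)
    resid <- cf$f - 0.7 * as.numeric(Wn$W %*% cf$f) - 0.3 * sv$y
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("closed form refuses dimensions above the dense cap", {
  net <- random_network(12, 0.3, seed = 1)
  Wn <- normalize_adjacency(net)
  sv <- random_seed_vector(Wn, 2, seed = 1)
  expect_error(solve_closed_form(Wn, sv, 0.5, max_n = 10), "cap")
})

test_that("complete-graph symmetry with uniform seeds gives equal scores", {
  syms <- c("A", "B", "C")
  net <- ppi_network(from = c("A", "A", "B"), to = c("B", "C", "C"))
  Wn <- normalize_adjacency(net)
  sv <- build_seed_vector(seed_set(syms), Wn)
  cf <- solve_closed_form(Wn, sv, alpha = 0.6)
  expect_equal(max(cf$f) - min(cf$f), 0, tolerance = 1e-12)
})

test_that("scores decay strictly with distance from an endpoint seed on a path", {
  net <- path_network(sprintf("P%02d", 1:8))
  Wn <- normalize_adjacency(net)
  sv <- build_seed_vector(seed_set("P01"), Wn)
  sc <- propagate(Wn, sv, propagation_params(alpha = 0.5, tol = 1e-12))
  f <- sc$f[sprintf("P%02d", 1:8)]
  expect_true(all(diff(f) < 0))
})

test_that("seed-free components score exactly 0", {
  # two components; seeds only in the first
  net <- ppi_network(from = c("A", "B", "X"), to = c("B", "C", "Y"))
  Wn <- normalize_adjacency(net)
  sv <- build_seed_vector(seed_set(c("A", "B")), Wn)
  sc <- propagate(Wn, sv, propagation_params(alpha = 0.9, tol = 1e-12))
  expect_identical(unname(sc$f[c("X", "Y")]), c(0, 0))
})

test_that("propagation is equivariant under node relabeling", {
  net <- random_network(20, 0.2, seed = 9)
  Wn <- normalize_adjacency(net)
  sv <- random_seed_vector(Wn, 4, seed = 9)
  sc <- propagate(Wn, sv, propagation_params(tol = 1e-12))
  # relabel by reversing names: Znnn ordering reverses lexicographic order
  relabel <- setNames(sprintf("Z%03d", rev(seq_along(net$nodes))), net$nodes)
  net2 <- ppi_network(from = unname(relabel[net$edges$from]),
                      to = unname(relabel[net$edges$to]),
                      nodes = unname(relabel))
  Wn2 <- normalize_adjacency(net2)
  seeds2 <- seed_set(unname(relabel[names(sv$y)[sv$y > 0]]))
  sv2 <- build_seed_vector(seeds2, Wn2)
  sc2 <- propagate(Wn2, sv2, propagation_params(tol = 1e-12))
  expect_equal(unname(sc2$f[unname(relabel[names(sc$f)])]),
               unname(sc$f), tolerance = 1e-12)
})

test_that("iterations to convergence do not increase as alpha decreases", {
  for (seed in c(3, 17)) {
    net <- random_network(40, 0.1, seed = seed)
    Wn <- normalize_adjacency(net)
    sv <- random_seed_vector(Wn, 4, seed = seed)
    iters <- vapply(c(0.9, 0.5, 0.1), function(a) {
      propagate(Wn, sv, propagation_params(alpha = a, tol = 1e-8))$iterations_used
    }, numeric(1))
    expect_true(all(diff(iters) <= 0))
  }
})

test_that("ranking sorts by score, then degree, then symbol", {
  # B and A isolated twins: equal score (0), equal degree (0) -> A first
  net <- ppi_network("X", "Y", nodes = c("X", "Y", "A", "B"))
  Wn <- normalize_adjacency(net)
  sv <- build_seed_vector(seed_set("X"), Wn)
  sc <- propagate(Wn, sv, propagation_params(tol = 1e-12))
  ranked <- rank_genes(sc, sv, net)
  expect_equal(ranked$rank, 1:4)
  expect_true(all(diff(ranked$score) <= 0))
  expect_lt(which(ranked$symbol == "A"), which(ranked$symbol == "B"))
})

test_that("a seeded node outranks its unseeded twin in a symmetric graph", {
  # square A-B-C-D-A: A and C are symmetric twins of B and D
  net <- ppi_network(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "A"))
  Wn <- normalize_adjacency(net)
  sv <- build_seed_vector(seed_set("A"), Wn)
  sc <- propagate(Wn, sv, propagation_params(tol = 1e-12))
  ranked <- rank_genes(sc, sv, net)
  expect_equal(ranked$symbol[1], "A")
})

test_that("ranking equals sorting the closed-form scores with the same tie rule", {
  net <- random_network(20, 0.25, seed = 13)
  Wn <- normalize_adjacency(net)
  sv <- random_seed_vector(Wn, 3, seed = 13)
  sc <- propagate(Wn, sv, propagation_params(tol = 1e-12))
  ranked <- rank_genes(sc, sv, net)
  cf <- solve_closed_form(Wn, sv, 0.5)
  deg <- node_degrees(net)[cf$ordering]
  expected <- cf$ordering[order(-cf$f, -deg, cf$ordering)]
  expect_equal(ranked$symbol, expected)
})

test_that("top-K selection clamps, sizes exactly, and force-includes seeds", {
  net <- random_network(30, 0.2, seed = 21)
  Wn <- normalize_adjacency(net)
  sv <- random_seed_vector(Wn, 5, seed = 21)
  sc <- propagate(Wn, sv, propagation_params(tol = 1e-12))
  ranked <- rank_genes(sc, sv, net)
  expect_equal(nrow(select_top_k(ranked, 1000)), nrow(ranked))
  expect_equal(nrow(select_top_k(ranked, 10)), 10)
})

test_that("a seed ranked below K is substituted in and logged", {
  # low-degree seed far from the other seeds ranks poorly at small alpha
  ranked <- data.frame(
    symbol = sprintf("G%02d", 1:12),
    score = seq(1.2, 0.1, length.out = 12),
    rank = 1:12,
    is_seed = c(TRUE, rep(FALSE, 10), TRUE),
    degree = 12:1, stringsAsFactors = FALSE)
  sel <- select_top_k(ranked, 5, force_include_seeds = TRUE)
  expect_equal(nrow(sel), 5)
  expect_true(all(ranked$symbol[ranked$is_seed] %in% sel$symbol))
  subs <- attr(sel, "substitutions")
  expect_equal(subs$dropped, "G05")
  expect_equal(subs$added, "G12")
  sel_off <- select_top_k(ranked, 5, force_include_seeds = FALSE)
  expect_false("G12" %in% sel_off$symbol)
})
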