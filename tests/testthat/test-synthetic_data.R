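test_that("preferential attachment with m = 1 yields a tree, reproducibly", {
  net <- generate_network(10, 1, rng_seed = 5)
  expect_equal(n_nodes(net), 10)
  expect_equal(n_edges(net), 9)
  net2 <- generate_network(10, 1, rng_seed = 5)
  expect_identical(net$edges, net2$edges)
  net3 <- generate_network(10, 1, rng_seed = 6)
  expect_false(identical(net$edges, net3$edges))
  expect_error(generate_network(3, 3), "n_nodes")
})

test_that("generated degree distributions are heavy-tailed", {
  ratios <- vapply(1:20, function(s) {
    deg <- node_degrees(generate_network(1000, 3, rng_seed = s))
    max(deg) / stats::median(deg)
  }, numeric(1))
  expect_true(all(ratios > 5))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_network(50, 2, rng_seed = 99))
  expect_identical(runif(1), before)
})

test_that("planting with within_p = 1 makes the module a clique, 0 changes nothing", {
  net <- generate_network(100, 2, rng_seed = 8)
  clq <- plant_module(net, size = 10, within_p = 1, n_reveal = 3,
                      rng_seed = 8)
  members <- clq$truth$module_members
  internal <- clq$network$edges$from %in% members &
    clq$network$edges$to %in% members
  expect_equal(sum(internal), choose(10, 2))
  same <- plant_module(net, size = 10, within_p = 0, n_reveal = 3,
                       rng_seed = 8)
  expect_identical(same$network$edges, net$edges)
  expect_error(plant_module(net, 10, within_p = 1.2, n_reveal = 3), "within_p")
})

test_that("planting never removes edges and the truth partitions the module", {
  net <- generate_network(200, 3, rng_seed = 14)
  out <- plant_module(net, 20, 0.4, 5, rng_seed = 14)
  old <- paste(net$edges$from, net$edges$to)
  new <- paste(out$network$edges$from, out$network$edges$to)
  expect_true(all(old %in% new))
  expect_identical(out$network$nodes, net$nodes)
  tr <- out$truth
  expect_true(all(tr$revealed_seeds %in% tr$module_members))
  expect_length(intersect(tr$held_out, tr$revealed_seeds), 0)
  expect_setequal(c(tr$held_out, tr$revealed_seeds), tr$module_members)
  expect_setequal(unique(tr$module_class), c("M1", "M2"))
})

test_that("added within-module edges stay inside binomial bounds", {
  # size 30, within_p 0.3: baseline edges among 30 random nodes of a sparse
  # PA graph are few, so added ~ Binom(C(30,2) - baseline, 0.3)
  added <- vapply(1:50, function(s) {
    net <- generate_network(500, 2, rng_seed = 1000 + s)
    out <- plant_module(net, 30, 0.3, 10, rng_seed = 2000 + s)
    out$truth$params$edges_added
  }, numeric(1))
  n_pairs <- choose(30, 2)
  # 99% band around the mean count, allowing for up to ~10 pre-existing edges
  expect_gt(mean(added), qbinom(0.005, n_pairs - 15, 0.3))
  expect_lt(mean(added), qbinom(0.995, n_pairs, 0.3))
})

test_that("expression log2fc hits +/- effect in the near-noiseless limit", {
  net <- generate_network(100, 2, rng_seed = 3)
  out <- plant_module(net, 10, 0.5, 3, rng_seed = 3)
  expr <- generate_expression(out$truth, effect_log2 = 2, noise_sd = 1e-9,
                              rng_seed = 3)
  cls <- out$truth$module_class
  m2 <- expr$log2fc[expr$symbol %in% names(cls)[cls == "M2"]]
  m1 <- expr$log2fc[expr$symbol %in% names(cls)[cls == "M1"]]
  bg <- expr$log2fc[!expr$symbol %in% names(cls)]
  expect_equal(m2, rep(2, length(m2)), tolerance = 1e-6)
  expect_equal(m1, rep(-2, length(m1)), tolerance = 1e-6)
  expect_equal(bg, rep(0, length(bg)), tolerance = 1e-6)
})

test_that("null expression keeps the type-I error near nominal", {
  net <- generate_network(400, 2, rng_seed = 21)
  out <- plant_module(net, 10, 0.5, 3, rng_seed = 21)
  hits <- 0; total <- 0
  for (s in 1:5) {
    expr <- generate_expression(out$truth, effect_log2 = 0, noise_sd = 0.5,
                                rng_seed = 300 + s)
    hits <- hits + sum(expr$p_value < 0.05)
    total <- total + nrow(expr)
  }
  # binomial 99.9% band around 0.05
  band <- qbinom(c(0.0005, 0.9995), total, 0.05) / total
  expect_gte(hits / total, band[1])
  expect_lte(hits / total, band[2])
})

test_that("background log2fc is centred at zero", {
  net <- generate_network(300, 2, rng_seed = 31)
  out <- plant_module(net, 10, 0.5, 3, rng_seed = 31)
  expr <- generate_expression(out$truth, effect_log2 = 2, noise_sd = 0.5,
                              rng_seed = 31)
  bg <- expr$log2fc[!expr$symbol %in% out$truth$module_members]
  se <- 0.5 * sqrt(2 / 5) / sqrt(length(bg))
  expect_lt(abs(mean(bg)), 4 * se)
})

test_that("expression tables are reproducible and shaped by n_per_group", {
  net <- generate_network(50, 2, rng_seed = 41)
  out <- plant_module(net, 6, 0.5, 2, rng_seed = 41)
  e1 <- generate_expression(out$truth, rng_seed = 7)
  e2 <- generate_expression(out$truth, rng_seed = 7)
  expect_identical(e1, e2)
  expect_equal(dim(attr(e1, "matrix")), c(50, 10))
  e3 <- generate_expression(out$truth, n_per_group = 3, rng_seed = 7)
  expect_equal(dim(attr(e3, "matrix")), c(50, 6))
  expect_error(generate_expression(out$truth, n_per_group = 1), "n_per_group")
})

test_that("Ct tables honour their means, seeds, and ordering contract", {
  tab0 <- generate_ct_table(c("ARG1", "TNF"), c(22, 26), 18, noise_sd = 0,
                            n_replicates = 2)
  expect_equal(tab0$ct_gene, c(22, 22, 26, 26))
  expect_equal(tab0$ct_reference, rep(18, 4))
  t1 <- generate_ct_table(c("A", "B"), c(20, 25), 18, 0.2, rng_seed = 9)
  t2 <- generate_ct_table(c("A", "B"), c(20, 25), 18, 0.2, rng_seed = 9)
  expect_identical(t1, t2)
  # relative expression ranks genes by specified delta-Ct
  tab <- generate_ct_table(c("HI", "MID", "LO"), c(20, 23, 27), 18,
                           noise_sd = 0.05, n_replicates = 3, rng_seed = 2)
  means <- tapply(relative_expression(tab$ct_gene, tab$ct_reference),
                  tab$gene, mean)
  expect_equal(names(sort(means, decreasing = TRUE)), c("HI", "MID", "LO"))
})

test_that("simulate_study writes a consistent, parseable input bundle", {
  dir <- withr::local_tempdir()
  study <- simulate_study(dir, n_nodes = 120, module_size = 12,
                          n_reveal = 4, rng_seed = 17)
  net <- parse_edge_list(study$paths$network, aliases = NULL)
  expect_setequal(net$edges$from, study$network$edges$from)
  seeds <- load_driver_table(study$paths$drivers, aliases = NULL)
  expect_setequal(seeds$drivers$symbol, study$truth$revealed_seeds)
  truth <- jsonlite::read_json(study$paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$held_out, study$truth$held_out)
  expr <- read.delim(study$paths$expression)
  expect_equal(nrow(expr), 120)
})
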