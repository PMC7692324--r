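test_that("the generator is deterministic given a seed", {
  cfg <- simulation_config(c("A", "B"), 5, 4, 30,
                           planted = data.frame(call_class = "cancer_hyper",
                                                target_cancer = "A",
                                                count = 4),
                           missing_rate = 0.05,
                           expression = list(rho = -0.8), seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$truth, c2$truth)
})

test_that("adding background probes never perturbs earlier draws", {
  base <- simulation_config(c("A", "B"), 5, 4, 10, seed = 21)
  more <- simulation_config(c("A", "B"), 5, 4, 40, seed = 21)
  b1 <- simulate_cohort(base)$beta
  b2 <- simulate_cohort(more)$beta
  expect_identical(b1, b2[seq_len(nrow(b1)), ])
})

test_that("state distributions land where their Beta shapes say", {
  set.seed(1)
  draws <- rbeta(1e4, 50, 5)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 50 / 55), 3 * se)
  # cohort built from those shapes: high-state groups sit near 0.91
  co <- simulate_cohort(simulation_config(
    c("A", "B"), 50, 50, 0,
    planted = data.frame(call_class = "tissue_hyper", target_cancer = "A",
                         count = 50), seed = 2))
  a_samples <- co$manifest$sample_id[co$manifest$cancer_code == "A"]
  vals <- co$beta[, a_samples]
  expect_lt(abs(mean(vals) - 50 / 55), 3 * sd(vals) / sqrt(length(vals)))
  expect_true(all(co$beta >= 0 & co$beta <= 1))
})

test_that("missing-rate zero yields a complete matrix, positive rate holes", {
  co0 <- simulate_cohort(simulation_config(c("A", "B"), 5, 5, 50, seed = 3))
  expect_false(anyNA(co0$beta))
  co1 <- simulate_cohort(simulation_config(c("A", "B"), 5, 5, 50,
                                           missing_rate = 0.2, seed = 3))
  frac <- mean(is.na(co1$beta))
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
})

test_that("config validation rejects infeasible setups", {
  expect_error(simulation_config("A"), "between 2 and 12")
  expect_error(simulation_config(LETTERS[1:13]), "between 2 and 12")
  expect_error(simulation_config(c("A", "B"),
                                 planted = data.frame(call_class = "bogus",
                                                      target_cancer = "A",
                                                      count = 1)),
               "unknown call_class")
  expect_error(simulation_config(c("A", "B"),
                                 planted = data.frame(call_class = "cancer_hyper",
                                                      target_cancer = "Z",
                                                      count = 1)),
               "not in cancer_codes")
  expect_error(simulation_config(c("A", "B"), missing_rate = 1), "missing_rate")
})

test_that("noise-free expression is exactly anti-correlated with beta", {
  co <- simulate_cohort(simulation_config(
    c("A", "B"), 8, 8, 0,
    planted = data.frame(call_class = "cancer_hypo", target_cancer = "A",
                         count = 5), seed = 4))
  expr <- simulate_expression(co, rho = -1)
  for (i in seq_len(nrow(co$truth))) {
    r <- cor(co$beta[co$truth$probe_id[i], ], log2(expr[i, ] + 1))
    expect_equal(r, -1, tolerance = 1e-12)
  }
  expect_true(all(expr >= 0))
  expect_error(simulate_expression(co, rho = -1.2), "rho")
})

test_that("independent expression shows no systematic correlation", {
  co <- simulate_cohort(simulation_config(
    c("A", "B"), 15, 15, 0,
    planted = data.frame(call_class = "cancer_hypo", target_cancer = "A",
                         count = 100), seed = 5))
  expr <- simulate_expression(co, rho = 0)
  r <- vapply(seq_len(nrow(co$truth)), function(i) {
    cor(co$beta[co$truth$probe_id[i], ], log2(expr[i, ] + 1))
  }, numeric(1))
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
})

test_that("written cohorts round-trip through the package readers", {
  co <- simulate_cohort(simulation_config(
    c("A", "B"), 4, 4, 10,
    planted = data.frame(call_class = "cancer_hyper", target_cancer = "A",
                         count = 3),
    expression = list(rho = -0.9), seed = 6))
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  expect_identical(read_beta_matrix(paths["beta"]), co$beta)
  expect_identical(read_sample_manifest(paths["manifest"]), co$manifest)
  ann <- read_probe_annotation(paths["annotation"])
  expect_identical(ann$probe_id, co$annotation$probe_id)
  expect_identical(ann$region_class, co$annotation$region_class)
  expect_identical(ann$gene_symbols, co$annotation$gene_symbols)
  sets <- read_gene_sets(paths["gene_sets"])
  expect_identical(sets$planted$genes, co$gene_sets$planted$genes)
  expect_identical(unname(read_expression_matrix(paths["expression"])),
                   unname(co$expression))
})
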