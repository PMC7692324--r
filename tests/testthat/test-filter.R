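test_that("group quartiles match hand interpolation and ignore missing values", {
  manifest <- make_manifest("BRCA", 4, 4)
  m <- rbind(
    cg1 = c(0.1, 0.2, 0.3, 0.4, rep(0.5, 4)),   # tumor spread, normal constant
    cg2 = c(0.1, 0.2, 0.3, 0.4, rep(0.5, 4)))
  colnames(m) <- manifest$sample_id
  m["cg2", 4] <- NA  # one tumor value missing
  prof <- group_quartiles(m, manifest, filter_config())
  # linear interpolation between order statistics, checked against the
  # independent oracle and the hand values 0.175 / 0.325
  expect_equal(prof$q1["cg1", "BRCA|primary_tumor"], 0.175)
  expect_equal(prof$q3["cg1", "BRCA|primary_tumor"], 0.325)
  expect_equal(prof$q1["cg1", "BRCA|primary_tumor"],
               oracle_quantile(c(0.1, 0.2, 0.3, 0.4), 0.25))
  # constant group collapses to q1 = q3 = c
  expect_equal(prof$q1["cg1", "BRCA|normal_tissue"], 0.5)
  expect_equal(prof$q3["cg1", "BRCA|normal_tissue"], 0.5)
  # missing values are excluded before quantiles
  expect_equal(prof$q1["cg2", "BRCA|primary_tumor"],
               oracle_quantile(c(0.1, 0.2, 0.3), 0.25))
  expect_identical(unname(prof$n["cg2", "BRCA|primary_tumor"]), 3)
})

test_that("appending a missing value leaves quartiles unchanged", {
  manifest <- make_manifest("BRCA", 5, 2)
  m <- matrix(c(0.1, 0.2, 0.3, 0.4, NA, 0.5, 0.5), 1,
              dimnames = list("cg1", manifest$sample_id))
  prof <- group_quartiles(m, manifest, filter_config())
  expect_equal(unname(prof$q1["cg1", "BRCA|primary_tumor"]), 0.175)
  expect_equal(unname(prof$q3["cg1", "BRCA|primary_tumor"]), 0.325)
})

test_that("a cancer code lacking one tissue type errors at configuration time", {
  manifest <- make_manifest("BRCA", 2, 2)
  manifest <- manifest[manifest$tissue_type == "primary_tumor", ]
  m <- matrix(0.5, 1, nrow(manifest),
              dimnames = list("cg1", manifest$sample_id))
  expect_error(group_quartiles(m, manifest, filter_config()),
               "lacking a tissue type")
})

test_that("forced group patterns produce the four classes with strict boundaries", {
  manifest <- make_manifest(c("BRCA", "COAD", "LUSC"), 3, 3)
  g <- function(...) {
    v <- c(...)
    names(v) <- as.vector(outer(c("primary_tumor", "normal_tissue"),
                                c("BRCA", "COAD", "LUSC"),
                                function(t, c1) paste(c1, t, sep = "|")))[c(1, 2, 3, 4, 5, 6)]
    v
  }
  probes <- list(
    ch = g(0.8, 0.1, 0.1, 0.1, 0.1, 0.1),   # target tumor high, rest low
    cl = g(0.05, 0.9, 0.9, 0.9, 0.9, 0.9),  # target tumor low, rest high
    th = g(0.9, 0.9, 0.1, 0.1, 0.1, 0.1),   # target tumor+normal high
    tl = g(0.05, 0.05, 0.9, 0.9, 0.9, 0.9), # target tumor+normal low
    boundary = g(0.6, 0.1, 0.1, 0.1, 0.1, 0.1),  # Q1 exactly at threshold
    mid = g(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  m <- make_group_matrix(manifest, probes)
  res <- run_filter(m, manifest)
  calls <- setNames(res$calls$call_class, res$calls$probe_id)
  expect_identical(unname(calls[c("ch", "cl", "th", "tl")]),
                   c("cancer_hyper", "cancer_hypo", "tissue_hyper",
                     "tissue_hypo"))
  expect_identical(unname(res$calls$target_cancer[match(
    c("ch", "cl", "th", "tl"), res$calls$probe_id)]), rep("BRCA", 4))
  # strict inequality: Q1 exactly 0.6 never fires a hyper rule
  expect_identical(unname(calls["boundary"]), "none")
  expect_identical(unname(calls["mid"]), "none")
  # classify_probe agrees with the run
  prof <- res$profile
  expect_identical(classify_probe(prof, "ch", "BRCA"), "cancer_hyper")
  expect_identical(classify_probe(prof, "ch", "COAD"), "none")
})

test_that("mid-range background probes receive no calls", {
  manifest <- make_manifest(c("BRCA", "COAD"), 4, 4)
  set.seed(5)
  m <- matrix(rbeta(5 * nrow(manifest), 10, 10), 5,
              dimnames = list(sprintf("bg%d", 1:5), manifest$sample_id))
  res <- run_filter(m, manifest)
  expect_identical(sum(res$calls$call_class != "none"), 0L)
  expect_true(all(res$tally == 0L))
})

test_that("a single cancer code is rejected: rules quantify over other cancers", {
  manifest <- make_manifest("BRCA", 3, 3)
  m <- matrix(0.5, 2, nrow(manifest),
              dimnames = list(c("a", "b"), manifest$sample_id))
  expect_error(run_filter(m, manifest), ">= 2 cancer codes")
})

test_that("probes with an undersized group are uncallable, not an error", {
  manifest <- make_manifest(c("BRCA", "COAD"), 3, 3)
  m <- make_group_matrix(manifest, list(
    ch = c("BRCA|primary_tumor" = 0.9, "BRCA|normal_tissue" = 0.1,
           "COAD|primary_tumor" = 0.1, "COAD|normal_tissue" = 0.1)))
  m["ch", manifest$sample_id[manifest$cancer_code == "COAD" &
                             manifest$tissue_type == "normal_tissue"][1:2]] <- NA
  res <- run_filter(m, manifest)  # COAD normal has 1 < min_group_size values
  expect_identical(res$calls$call_class, "none")
})

test_that("permuting sample columns never changes any call", {
  set.seed(42)
  manifest <- make_manifest(c("BRCA", "COAD"), 4, 3)
  planted <- data.frame(call_class = c("cancer_hyper", "tissue_hypo"),
                        target_cancer = c("BRCA", "COAD"), count = 3)
  co <- simulate_cohort(simulation_config(c("BRCA", "COAD"), 4, 3, 20,
                                          planted, seed = 42))
  res1 <- run_filter(co$beta, co$manifest)
  perm <- sample(ncol(co$beta))
  res2 <- run_filter(co$beta[, perm], co$manifest[perm, ])
  expect_identical(res1$calls, res2$calls)
  expect_identical(res1$tally, res2$tally)
})

test_that("no probe satisfies two classes for the same target cancer", {
  set.seed(7)
  manifest <- make_manifest(c("A", "B"), 4, 4)
  cfg <- filter_config()
  for (i in 1:200) {
    vals <- runif(nrow(manifest))
    m <- matrix(vals, 1, dimnames = list("p", manifest$sample_id))
    prof <- group_quartiles(m, manifest, cfg)
    for (t in c("A", "B")) {
      hyper <- cfg$hyper_threshold; hypo <- cfg$hypo_threshold
      q1 <- prof$q1[1, ]; q3 <- prof$q3[1, ]
      o <- setdiff(c("A", "B"), t)
      fired <- c(
        q1[paste0(t, "|primary_tumor")] > hyper &&
          q3[paste0(t, "|normal_tissue")] < hypo &&
          all(q3[paste0(o, c("|primary_tumor", "|normal_tissue"))] < hypo),
        q3[paste0(t, "|primary_tumor")] < hypo &&
          q1[paste0(t, "|normal_tissue")] > hyper &&
          all(q1[paste0(o, c("|primary_tumor", "|normal_tissue"))] > hyper),
        q1[paste0(t, "|primary_tumor")] > hyper &&
          q1[paste0(t, "|normal_tissue")] > hyper &&
          all(q3[paste0(o, c("|primary_tumor", "|normal_tissue"))] < hypo),
        q3[paste0(t, "|primary_tumor")] < hypo &&
          q3[paste0(t, "|normal_tissue")] < hypo &&
          all(q1[paste0(o, c("|primary_tumor", "|normal_tissue"))] > hyper))
      expect_lte(sum(fired), 1L)
    }
  }
})

test_that("tallies are zero-filled and sum to the non-none call count", {
  calls <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    call_class = c("cancer_hyper", "cancer_hyper", "tissue_hypo", "none"),
    target_cancer = c("BRCA", "BRCA", "COAD", ""))
  tal <- tally_calls(calls, c("BRCA", "COAD", "LUSC"))
  expect_identical(dim(tal), c(4L, 3L))
  expect_identical(tal["cancer_hyper", "BRCA"], 2L)
  expect_identical(tal["tissue_hypo", "COAD"], 1L)
  expect_identical(sum(tal), 3L)
  expect_true(all(tal[, "LUSC"] == 0L))
  # empty call set -> all-zero grid
  expect_true(all(tally_calls(calls[calls$call_class == "none", ],
                              c("BRCA")) == 0L))
})

test_that("filter config validates threshold ordering", {
  expect_error(filter_config(hyper_threshold = 0.3, hypo_threshold = 0.6),
               "hypo_threshold < hyper_threshold")
  expect_error(filter_config(min_group_size = 0), "min_group_size")
})

test_that("call exports mirror the tally layout with verbatim class labels", {
  manifest <- make_manifest(c("BRCA", "COAD"), 3, 3)
  m <- make_group_matrix(manifest, list(
    ch = c("BRCA|primary_tumor" = 0.9, "BRCA|normal_tissue" = 0.1,
           "COAD|primary_tumor" = 0.1, "COAD|normal_tissue" = 0.1)))
  res <- run_filter(m, manifest)
  dir <- tempfile()
  paths <- write_call_table(res, dir)
  tal <- read.delim(paths[3])
  expect_identical(tal$Sites[1], "Cancer-specific hypermethylation")
  expect_identical(tal$BRCA[1], 1L)
  calls <- read.delim(paths[1])
  expect_true(all(c("probe_id", "call_class", "target_cancer") %in%
                  colnames(calls)))
  expect_true(any(grepl("^Q1", colnames(calls))))
})
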