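test_that("generation is reproducible and shaped by the spec", {
  spec <- synthetic_spec(20, 15, 10,
                         planted_pairs = data.frame(rho1 = 0.8, rho2 = -0.5),
                         seed = 42)
  a <- generate_expression_pair(spec)
  b <- generate_expression_pair(spec)
  expect_identical(a$cond1, b$cond1)
  expect_identical(a$cond2, b$cond2)
  expect_identical(dim(a$cond1), c(20L, 10L))
  expect_identical(dim(a$cond2), c(15L, 10L))
  expect_identical(colnames(a$cond1), colnames(a$cond2))
  expect_identical(a$planted$gene_a, "g001")
  expect_identical(a$planted$gene_b, "g002")
  expect_no_error(validate_expression(a$cond1))

  other <- generate_expression_pair(synthetic_spec(20, 15, 10,
    planted_pairs = data.frame(rho1 = 0.8, rho2 = -0.5), seed = 43))
  expect_false(identical(a$cond1, other$cond1))
})

test_that("spec validation rejects infeasible requests", {
  expect_error(synthetic_spec(10, 10, 3,
    planted_pairs = data.frame(rho1 = c(0.5, 0.5), rho2 = c(0.5, 0.5))),
    "disjoint")
  expect_error(synthetic_spec(10, 10, 4,
    planted_pairs = data.frame(rho1 = 1, rho2 = 0.5)), "strictly inside")
  expect_error(synthetic_spec(2, 10, 4), "at least 3 samples")
  expect_error(synthetic_spec(10, 10, 4, noise_sd = -1), "non-negative")
})

test_that("without planted pairs all correlations sit at the null scale", {
  spec <- synthetic_spec(100, 100, 30, seed = 7)
  d <- generate_expression_pair(spec)
  for (m in list(d$cond1, d$cond2)) {
    cc <- pearson_all_pairs(rank_transform(m))
    off <- cc[upper.tri(cc)]
    expect_lt(max(abs(off)), 0.45) # null sd ~ 1/sqrt(n - 1) = 0.1
    expect_lt(abs(mean(off)), 0.05)
  }
})

test_that("the normal copula hits the requested population Spearman", {
  # one strong pair, huge sample: the empirical Spearman pins down the
  # population value far more tightly than the 0.1 acceptance band
  spec <- synthetic_spec(20000, 3, 2,
                         planted_pairs = data.frame(rho1 = 0.9, rho2 = 0),
                         seed = 5)
  d <- generate_expression_pair(spec)
  rho <- stats::cor(d$cond1[, 1], d$cond1[, 2], method = "spearman")
  expect_lt(abs(rho - 0.9), 0.02)

  spec2 <- synthetic_spec(200, 200, 4,
                          planted_pairs = data.frame(rho1 = 0.9, rho2 = 0.9),
                          seed = 11)
  d2 <- generate_expression_pair(spec2)
  for (m in list(d2$cond1, d2$cond2)) {
    expect_lt(abs(stats::cor(m[, 1], m[, 2], method = "spearman") - 0.9), 0.1)
  }
})

test_that("measurement noise attenuates the planted correlation", {
  base <- synthetic_spec(500, 3, 2,
                         planted_pairs = data.frame(rho1 = 0.9, rho2 = 0),
                         noise_sd = 0, seed = 3)
  noisy <- synthetic_spec(500, 3, 2,
                          planted_pairs = data.frame(rho1 = 0.9, rho2 = 0),
                          noise_sd = 2, seed = 3)
  r0 <- stats::cor(generate_expression_pair(base)$cond1[, 1:2],
                   method = "spearman")[1, 2]
  r2 <- stats::cor(generate_expression_pair(noisy)$cond1[, 1:2],
                   method = "spearman")[1, 2]
  expect_lt(r2, r0 - 0.2)
})

test_that("a sign-flipped planted pair tops the D ranking end to end", {
  spec <- synthetic_spec(60, 60, 40,
    planted_pairs = data.frame(rho1 = c(0.9, 0.9), rho2 = c(0.9, -0.9)),
    seed = 19)
  d <- generate_expression_pair(spec)
  res <- run_csd(d$cond1, d$cond2, n_iterations = 100, n_edges = 5,
                 seed = 8, verbose = FALSE)
  top_d <- res$network[res$network$link_type == "D", ]
  expect_identical(top_d$gene_a[1], "g003")
  expect_identical(top_d$gene_b[1], "g004")
  top_c <- res$network[res$network$link_type == "C", ]
  expect_identical(top_c$gene_a[1], "g001")
  expect_identical(top_c$gene_b[1], "g002")
})

test_that("synthetic datasets round-trip through the TSV expression format", {
  spec <- synthetic_spec(10, 8, 6,
                         planted_pairs = data.frame(rho1 = 0.7, rho2 = 0.7),
                         seed = 2)
  d <- generate_expression_pair(spec)
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- write_synthetic(d, prefix)
  expect_equal(read_expression(paths[1]), d$cond1)
  expect_equal(read_expression(paths[2]), d$cond2)
  planted <- data.table::fread(paths[3], data.table = FALSE)
  expect_identical(planted$gene_a, "g001")
})

test_that("a single parallel gives the trivial overlap curve of ones", {
  spec <- synthetic_spec(20, 20, 8, seed = 1)
  res <- seed_overlap_experiment(spec, n_parallels = 1, n_iterations = 20,
                                 max_rank = 10, seed = 4)
  expect_identical(nrow(res), 30L)
  expect_true(all(res$overlap == 1))
})

test_that("strong planted structure lifts the seed overlap above the null", {
  planted <- data.frame(rho1 = rep(0.9, 10), rho2 = rep(0.9, 10))
  strong <- synthetic_spec(80, 80, 40, planted_pairs = planted, seed = 6)
  null_spec <- synthetic_spec(80, 80, 40, seed = 6)
  res_strong <- seed_overlap_experiment(strong, n_parallels = 3,
                                        n_iterations = 100, max_rank = 10,
                                        seed = 2)
  res_null <- seed_overlap_experiment(null_spec, n_parallels = 3,
                                      n_iterations = 100, max_rank = 10,
                                      seed = 2)
  at10 <- function(r, lt) r$overlap[r$link_type == lt & r$rank_cutoff == 10]
  # the parallels share the data, so even the null keeps some overlap; the
  # planted structure must pin the full top-10 down across all seeds
  expect_gte(at10(res_strong, "C"), 0.9)
  expect_gt(at10(res_strong, "C"), at10(res_null, "C") + 0.2)
})
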