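# response_sets: duration partitioning, Sankey factor breakdown, and the
# cross-duration effect-size comparison.

test_that("partition_by_duration reproduces the published count algebra", {
  # 330 day-1 and 347 day-5 response genes sharing 121
  g1 <- sprintf("g%04d", 1:330)
  g5 <- sprintf("g%04d", c(1:121, 1000:1225))
  part <- partition_by_duration(g1, g5)
  expect_equal(part$n_day1, 330L)
  expect_equal(part$n_day5, 347L)
  expect_equal(length(part$shared), 121L)
  expect_equal(length(part$pooled), 556L)
  expect_equal(length(part$unique_day1), 209L)
  expect_equal(length(part$unique_day5), 226L)

  d <- partition_by_duration(c("a", "b", "c"), c("x", "y", "z", "w"))
  expect_equal(length(d$pooled), 7L)
  expect_equal(length(d$shared), 0L)
  s <- partition_by_duration(c("a", "b"), c("b", "a"))
  expect_equal(length(s$shared), 2L)
  expect_equal(length(s$unique_day1), 0L)
  expect_error(partition_by_duration(c("a", "a"), "b"), "duplicate")
})

test_that("partition counts obey inclusion-exclusion for random list pairs", {
  set.seed(555)
  pool <- sprintf("g%03d", 1:120)
  for (i in 1:1000) {
    a <- sample(pool, sample(0:60, 1))
    b <- sample(pool, sample(0:60, 1))
    p <- partition_by_duration(a, b)
    expect_equal(length(p$pooled),
                 p$n_day1 + p$n_day5 - length(p$shared))
    expect_equal(sort(c(p$shared, p$unique_day1, p$unique_day5)),
                 sort(p$pooled))
    expect_equal(length(intersect(p$unique_day1, p$shared)), 0L)
  }
})

make_flag_table <- function(n_e_only, n_eg, n_es, n_egs, n_extra = 10) {
  total <- n_e_only + n_eg + n_es + n_egs + n_extra
  df <- data.frame(
    gene_id = sprintf("g%04d", seq_len(total)),
    significant_exposure = rep(c(TRUE, FALSE),
                               c(total - n_extra, n_extra)),
    significant_genotype = rep(c(FALSE, TRUE, FALSE, TRUE, FALSE),
                               c(n_e_only, n_eg, n_es, n_egs, n_extra)),
    significant_sex = rep(c(FALSE, FALSE, TRUE, TRUE, FALSE),
                          c(n_e_only, n_eg, n_es, n_egs, n_extra)))
  class(df) <- c("EffectTable", "data.frame")
  df
}

test_that("cross_factor_breakdown reproduces the 56% / 41% arithmetic", {
  # day 1: 330 exposure-response genes, 70 + genotype, 93 + sex, 21 all three
  b1 <- cross_factor_breakdown(make_flag_table(330 - 70 - 93 - 21, 70, 93, 21))
  expect_equal(b1$total, 330L)
  expect_equal(b1$exposure_and_genotype_only, 70L)
  expect_equal(b1$percent_multifactor, 56)
  # day 5: 347 genes, 130 + genotype, 7 + sex, 4 all three
  b5 <- cross_factor_breakdown(make_flag_table(347 - 130 - 7 - 4, 130, 7, 4))
  expect_equal(b5$percent_multifactor, 41)
  b0 <- cross_factor_breakdown(make_flag_table(12, 0, 0, 0))
  expect_equal(b0$percent_multifactor, 0)
  expect_error(cross_factor_breakdown(data.frame(gene_id = "g")),
               "lacks flag column")
})

test_that("breakdown categories are disjoint and exhaustive", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    df <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     significant_exposure = sample(c(TRUE, FALSE), n, TRUE),
                     significant_genotype = sample(c(TRUE, FALSE), n, TRUE),
                     significant_sex = sample(c(TRUE, FALSE), n, TRUE))
    class(df) <- c("EffectTable", "data.frame")
    b <- cross_factor_breakdown(df)
    expect_equal(b$exposure_only + b$exposure_and_genotype_only +
                 b$exposure_and_sex_only + b$exposure_genotype_sex,
                 sum(df$significant_exposure))
  }
})

fake_effects <- function(gene_ids, beta) {
  df <- data.frame(gene_id = gene_ids, beta_exposure = beta,
                   p_exposure = 0.5, q_exposure = 0.5,
                   significant_exposure = TRUE)
  class(df) <- c("EffectTable", "data.frame")
  df
}

test_that("compare_duration_betas: exact lines, flags, and oracle r", {
  genes <- sprintf("g%02d", 1:12)
  set.seed(8)
  b1 <- rnorm(12)
  same <- compare_duration_betas(fake_effects(genes, b1),
                                 fake_effects(genes, b1), "exposure", genes)
  expect_equal(same$r, 1)
  expect_equal(same$slope, 1)

  half <- compare_duration_betas(fake_effects(genes, b1),
                                 fake_effects(genes, 0.5 * b1),
                                 "exposure", genes)
  expect_equal(half$slope, 0.5, tolerance = 1e-12)

  b5 <- 0.7 * b1 + rnorm(12, 0, 0.2)
  cmp <- compare_duration_betas(fake_effects(genes, b1),
                                fake_effects(genes, b5), "exposure", genes)
  # brute-force covariance oracle
  r_oracle <- sum((b1 - mean(b1)) * (b5 - mean(b5))) /
    sqrt(sum((b1 - mean(b1))^2) * sum((b5 - mean(b5))^2))
  expect_equal(cmp$r, r_oracle, tolerance = 1e-12)

  itab <- data.frame(gene_id = genes[1:3], duration_dependent = c(TRUE, FALSE, TRUE))
  flagged <- compare_duration_betas(fake_effects(genes, b1),
                                    fake_effects(genes, b5), "exposure",
                                    genes, interaction = itab)
  expect_equal(flagged$flagged_genes, genes[c(1, 3)])
  expect_equal(sum(flagged$pairs$flagged), 2L)

  expect_error(compare_duration_betas(fake_effects(genes, b1),
                                      fake_effects(genes[-1], b5[-1]),
                                      "exposure", genes),
               "missing from an effect table")
})

test_that("true interaction genes are recovered from synthetic data", {
  d <- generate_design(5, c(1, 5))
  sim <- generate_expression(d, n_genes = 600, noise_sd = 0.3,
                             affected_fraction = c(exposure = 0.1,
                                                   genotype = 0, sex = 0),
                             interaction_fraction = 0.4,
                             effect_size_range = c(1.0, 2.0), seed = 61)
  parts <- split_by_duration(sim$expr, d)
  e1 <- fit_gene_models(parts[["1"]]$expr, parts[["1"]]$design)
  e5 <- fit_gene_models(parts[["5"]]$expr, parts[["5"]]$design)
  pooled <- partition_by_duration(call_response_genes(e1)$gene_id,
                                  call_response_genes(e5)$gene_id)$pooled
  itab <- fit_interaction_models(sim$expr, d, pooled)
  true_int <- sim$truth$gene_id[sim$truth$beta_interaction != 0]
  recovered <- itab$gene_id[itab$duration_dependent]
  expect_gte(length(intersect(recovered, true_int)) / length(true_int), 0.8)
})
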