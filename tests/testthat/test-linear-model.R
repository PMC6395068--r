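# linear_model: design encoding, per-gene OLS vs normal-equations oracle,
# significance calling, interaction fits.

test_that("encode_design produces the documented coding and rank checks", {
  d <- balanced_design(2)
  X <- encode_design(d)
  expect_equal(colnames(X), c("intercept", "exposure", "genotype", "sex"))
  smoke_row <- X[d$exposure == "smoke", ][1, ]
  expect_equal(unname(smoke_row[1:2]), c(1, 1))
  # balanced factorial: factor columns orthogonal after centering
  C <- scale(X[, -1], scale = FALSE)
  expect_equal(max(abs(crossprod(C) - diag(diag(crossprod(C))))), 0)

  all_sham <- d[d$exposure == "sham", ]
  class(all_sham) <- c("SampleDesign", "data.frame")
  expect_error(encode_design(all_sham), "factor 'exposure'")
  expect_error(encode_design(generate_design(2, c(1, 5))), "single exposure")
})

test_that("zero-noise genes are recovered exactly; constant genes get p = 1", {
  d <- balanced_design(2)
  expr <- manual_expression(d, list(
    gA = function(e, g, s, d5) 7 + 1.5 * e,
    gB = function(e, g, s, d5) rep(5, length(e)),
    gC = function(e, g, s, d5) 6 - 0.8 * g + 0.3 * s))
  eff <- suppressWarnings(fit_gene_models(expr, d))
  a <- eff[eff$gene_id == "gA", ]
  expect_equal(a$beta_exposure, 1.5)
  expect_equal(c(a$beta_genotype, a$beta_sex), c(0, 0))
  expect_equal(c(a$p_genotype, a$p_sex), c(1, 1))
  expect_equal(a$p_exposure, 0)
  b <- eff[eff$gene_id == "gB", ]
  expect_equal(unlist(b[paste0("beta_", c("exposure", "genotype", "sex"))]),
               c(beta_exposure = 0, beta_genotype = 0, beta_sex = 0))
  expect_equal(unlist(b[paste0("p_", c("exposure", "genotype", "sex"))]),
               c(p_exposure = 1, p_genotype = 1, p_sex = 1))
  cc <- eff[eff$gene_id == "gC", ]
  expect_equal(c(cc$beta_genotype, cc$beta_sex), c(-0.8, 0.3))
})

test_that("fitted betas and p values match the normal-equations oracle", {
  d <- balanced_design(2)
  expr <- manual_expression(d, list(
    g1 = function(e, g, s, d5) 8 + 0.9 * e - 0.4 * s,
    g2 = function(e, g, s, d5) 6 + 0.2 * g,
    g3 = function(e, g, s, d5) 7.5 - 1.1 * e + 0.6 * g),
    noise_sd = 0.4, seed = 23)
  eff <- fit_gene_models(expr, d)
  X <- encode_design(d)
  for (gid in rownames(expr)) {
    o <- normal_equations_oracle(unclass(expr)[gid, ], X)
    row <- eff[eff$gene_id == gid, ]
    expect_equal(row$beta_exposure, unname(o$beta["exposure"]),
                 tolerance = 1e-9)
    expect_equal(row$beta_genotype, unname(o$beta["genotype"]),
                 tolerance = 1e-9)
    expect_equal(row$beta_sex, unname(o$beta["sex"]), tolerance = 1e-9)
    expect_equal(row$p_exposure, unname(o$p["exposure"]), tolerance = 1e-9)
  }
})

test_that("estimates are invariant to sample and gene order; q >= p", {
  d1 <- generate_design(3, 1)
  sim <- generate_expression(d1, n_genes = 60, seed = 8)
  eff <- fit_gene_models(sim$expr, d1)
  # shuffle genes
  set.seed(4)
  perm <- sample(nrow(sim$expr))
  eff_g <- fit_gene_models(sim$expr[perm, ], generate_design(3, 1))
  expect_equal(eff_g[match(eff$gene_id, eff_g$gene_id), ]$beta_exposure,
               eff$beta_exposure)
  # shuffle samples
  eff_s <- fit_gene_models(sim$expr[, sample(ncol(sim$expr))],
                           generate_design(3, 1))
  expect_equal(eff_s$beta_exposure, eff$beta_exposure, tolerance = 1e-12)
  for (f in c("exposure", "genotype", "sex"))
    expect_true(all(eff[[paste0("q_", f)]] >= eff[[paste0("p_", f)]] - 1e-15))
})

test_that("adding a constant to one gene changes only its intercept", {
  d <- balanced_design(2)
  expr <- random_expression(10, nrow(d), seed = 12)
  colnames(expr) <- d$sample_id
  expr <- expression_matrix(unclass(expr))
  X <- encode_design(d)
  fit1 <- smokefact:::ols_all_genes(unclass(expr), X)
  bumped <- unclass(expr)
  bumped["g03", ] <- bumped["g03", ] + 2.5
  fit2 <- smokefact:::ols_all_genes(bumped, X)
  expect_equal(fit2$beta["g03", "intercept"],
               fit1$beta["g03", "intercept"] + 2.5)
  expect_equal(fit2$beta[, c("exposure", "genotype", "sex")],
               fit1$beta[, c("exposure", "genotype", "sex")])
  expect_equal(fit2$p[, c("exposure", "genotype", "sex")],
               fit1$p[, c("exposure", "genotype", "sex")])
})

test_that("call_response_genes applies both thresholds and orders output", {
  eff <- data.frame(
    gene_id = c("gUp", "gSmallBeta", "gBigQ", "gDown"),
    beta_exposure = c(0.50, 0.30, -1.2, -0.9),
    p_exposure = c(1e-4, 1e-5, 0.15, 1e-4),
    q_exposure = c(0.01, 0.001, 0.20, 0.01))
  crit <- significance_criteria()
  eff$significant_exposure <- eff$q_exposure < crit$q_threshold &
    abs(eff$beta_exposure) > crit$beta_threshold
  class(eff) <- c("EffectTable", "data.frame")
  out <- call_response_genes(eff, "exposure")
  expect_equal(out$gene_id, c("gDown", "gUp"))   # |beta| desc
  expect_equal(out$direction, c("down", "up"))
  expect_false("gSmallBeta" %in% out$gene_id)    # |0.30| <= 0.379
  expect_false("gBigQ" %in% out$gene_id)         # q >= 0.05
  expect_error(call_response_genes(eff, "smell"), "unknown factor")
})

test_that("fold-change / beta threshold conversion", {
  expect_equal(round(fold_change_to_beta(1.3), 3), 0.379)
  expect_equal(fold_change_to_beta(2), 1)
  expect_equal(fold_change_to_beta(1), 0)
  expect_error(fold_change_to_beta(-1), "fc must be > 0")
})

test_that("interaction model: zero-noise coding arithmetic and oracle", {
  d <- generate_design(2, c(1, 5))
  expr <- manual_expression(d, list(
    gSame = function(e, g, s, d5) 7 + 1 * e,             # same effect
    gFlip = function(e, g, s, d5) 7 + 1 * e - 2 * e * d5, # +1 then -1
    gNoisy = function(e, g, s, d5) 6 + 0.5 * e + 0.7 * e * d5))
  noisy_vals <- unclass(expr)
  set.seed(2)
  noisy_vals["gNoisy", ] <- noisy_vals["gNoisy", ] + rnorm(ncol(expr), 0, 0.3)
  expr <- expression_matrix(noisy_vals)
  tab <- suppressWarnings(
    fit_interaction_models(expr, d, c("gSame", "gFlip", "gNoisy")))
  expect_equal(tab$beta_interaction[tab$gene_id == "gSame"], 0)
  expect_equal(tab$beta_interaction[tab$gene_id == "gFlip"], -2)
  X <- encode_interaction_design(d)
  o <- normal_equations_oracle(unclass(expr)["gNoisy", ], X)
  expect_equal(tab$beta_interaction[tab$gene_id == "gNoisy"],
               unname(o$beta["interaction"]), tolerance = 1e-9)
  expect_equal(tab$p_interaction[tab$gene_id == "gNoisy"],
               unname(o$p["interaction"]), tolerance = 1e-9)
  expect_error(fit_interaction_models(expr, d, "gMissing"),
               "gene 'gMissing'")
})
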