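# Shared fixture builders. Everything is generated in code at test time;
# no stored binary data.

# balanced single-duration factorial design, n samples per cell
balanced_design <- function(n_per_cell = 2L, duration = 1L) {
  generate_design(n_per_cell = n_per_cell, durations = duration)
}

# deterministic expression matrix from an explicit signal function:
# fun(x_e, x_g, x_s) -> per-sample value for the one gene described
manual_expression <- function(design, gene_funs, noise_sd = 0, seed = 1L) {
  x_e <- as.numeric(design$exposure == "smoke")
  x_g <- as.numeric(design$genotype == "bENaC")
  x_s <- as.numeric(design$sex == "male")
  x_d5 <- as.numeric(design$duration_days == 5L)
  vals <- t(vapply(gene_funs, function(f) f(x_e, x_g, x_s, x_d5),
                   numeric(nrow(design))))
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + matrix(rnorm(length(vals), 0, noise_sd), nrow(vals))
  }
  expression_matrix(vals, gene_ids = names(gene_funs),
                    sample_ids = design$sample_id)
}

# random expression fixture with ids, for round-trip tests
random_expression <- function(n_genes = 6L, n_samples = 5L, seed = 1L) {
  set.seed(seed)
  expression_matrix(
    matrix(round(rnorm(n_genes * n_samples, 8, 2), 6), n_genes),
    gene_ids = sprintf("g%02d", seq_len(n_genes)),
    sample_ids = sprintf("s%02d", seq_len(n_samples)))
}

# exhaustive hypergeometric upper tail by direct binomial-coefficient sums
hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# per-gene OLS by explicit normal equations, one gene at a time
normal_equations_oracle <- function(y, X) {
  XtXinv <- solve(t(X) %*% X)
  beta <- drop(XtXinv %*% t(X) %*% y)
  resid <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * diag(XtXinv))
  p <- 2 * pt(-abs(beta / se), df)
  list(beta = beta, p = p)
}

# rebuild an hclust object from hierarchical_order output (for cutree)
as_hclust <- function(ho) {
  structure(list(merge = ho$merge, height = ho$height,
                 order = match(ho$order, ho$labels), labels = ho$labels),
            class = "hclust")
}
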