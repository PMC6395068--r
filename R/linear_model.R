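# Per-gene multivariable additive linear models. Every gene is fitted by
# ordinary least squares against [intercept, exposure, genotype, sex]
# (identity link, gaussian errors — deliberately not a moderated-t
# variant); p values come from the per-coefficient t statistic, q values
# from BH within each factor across all genes. The exposure-by-duration
# interaction is a separate post-hoc fit over both durations.

#' Convert a fold-change ratio to a log2 effect-size threshold
#'
#' @param fc fold change ratio (> 0); 1.3 gives the usual 0.379 cutoff.
#' @return `log2(fc)`.
#' @export
fold_change_to_beta <- function(fc) {
  if (!is.numeric(fc) || any(fc <= 0)) stop("fc must be > 0", call. = FALSE)
  log2(fc)
}

#' Significance criteria for calling response genes
#'
#' A gene is called significant for a factor when its BH q value is below
#' `q_threshold` AND its |beta| exceeds `log2(fold_change_threshold)`.
#'
#' @param q_threshold FDR cutoff, default 0.05.
#' @param fold_change_threshold ratio, default 1.3.
#' @return list of class `SignificanceCriteria` with `q_threshold` and
#'   `beta_threshold`.
#' @export
significance_criteria <- function(q_threshold = 0.05,
                                  fold_change_threshold = 1.3) {
  bt <- fold_change_to_beta(fold_change_threshold)
  if (bt <= 0) stop("fold_change_threshold must exceed 1", call. = FALSE)
  structure(list(q_threshold = q_threshold, beta_threshold = bt),
            class = "SignificanceCriteria")
}

#' Encode a single-duration design as a numeric model matrix
#'
#' Columns `[intercept, exposure, genotype, sex]` with treatment coding
#' smoke = 1 (vs sham), bENaC = 1 (vs WT), male = 1 (vs female). Requires a
#' single exposure duration and both levels of every factor (otherwise the
#' model is rank deficient and the offending factor is named).
#'
#' @param design `SampleDesign`, one duration.
#' @return numeric matrix, samples x 4, rownames = sample ids.
#' @export
encode_design <- function(design) {
  if (length(unique(design$duration_days)) != 1L)
    stop("encode_design expects a single exposure duration; ",
         "use encode_interaction_design for cross-duration fits",
         call. = FALSE)
  X <- cbind(intercept = 1,
             exposure = as.numeric(design$exposure == "smoke"),
             genotype = as.numeric(design$genotype == "bENaC"),
             sex      = as.numeric(design$sex == "male"))
  rownames(X) <- design$sample_id
  for (f in MODEL_FACTORS) {
    if (length(unique(X[, f])) < 2L)
      stop("factor '", f, "' has a single level; design is rank deficient",
           call. = FALSE)
  }
  X
}

#' Encode the cross-duration interaction design
#'
#' Columns `[intercept, exposure, duration (day 5 = 1), exposure x duration]`.
#'
#' @param design `SampleDesign` covering both durations.
#' @return numeric matrix, samples x 4.
#' @export
encode_interaction_design <- function(design) {
  durs <- sort(unique(design$duration_days))
  if (length(durs) != 2L)
    stop("interaction design needs exactly two durations, got ",
         paste(durs, collapse = ", "), call. = FALSE)
  expo <- as.numeric(design$exposure == "smoke")
  day5 <- as.numeric(design$duration_days == max(durs))
  if (length(unique(expo)) < 2L)
    stop("factor 'exposure' has a single level; design is rank deficient",
         call. = FALSE)
  X <- cbind(intercept = 1, exposure = expo, duration = day5,
             interaction = expo * day5)
  rownames(X) <- design$sample_id
  X
}

# Vectorized OLS of every gene (rows of E) on design X: one pass of normal
# equations for all genes at once. Returns per-gene beta / p matrices.
# Zero-residual fits get the degenerate convention p = 1 for beta == 0 and
# p = 0 otherwise (warned once) so exact synthetic data remains testable.
ols_all_genes <- function(E, X) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop("fewer residual degrees of freedom than required: n = ", n,
         ", parameters = ", p, call. = FALSE)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("design matrix is rank deficient", call. = FALSE)
  XtXinv <- solve(XtX)
  B <- E %*% X %*% XtXinv                    # genes x p coefficients
  R <- E - B %*% t(X)                        # residuals
  df <- n - p
  s2 <- rowSums(R^2) / df
  se <- sqrt(outer(s2, diag(XtXinv)))
  tt <- B / se
  P <- 2 * stats::pt(-abs(tt), df)
  degen <- s2 <= .Machine$double.eps * 100 * rowMeans(E^2 + 1)
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero residual variance; using the ",
            "degenerate convention p = 1 for zero coefficients, p = 0 ",
            "otherwise", call. = FALSE)
    zero_b <- abs(B[degen, , drop = FALSE]) < 1e-10
    P[degen, ] <- ifelse(zero_b, 1, 0)
  }
  colnames(B) <- colnames(P) <- colnames(X)
  rownames(B) <- rownames(P) <- rownames(E)
  list(beta = B, p = P, df = df)
}

#' Fit the additive per-gene linear model and call significance
#'
#' Fits every gene by OLS on `[intercept, exposure, genotype, sex]`,
#' derives two-sided t-test p values per coefficient, BH-adjusts them to q
#' values per factor across all genes, and flags significance by
#' `q < q_threshold & |beta| > beta_threshold`.
#'
#' @param expr `ExpressionMatrix`.
#' @param design `SampleDesign` for the same samples (any row order; matched
#'   by identifier). Must be a single exposure duration.
#' @param criteria a [significance_criteria()].
#' @return data.frame of class `EffectTable`: `gene_id` plus, for each of
#'   exposure/genotype/sex, columns `beta_*`, `p_*`, `q_*`, `significant_*`.
#' @export
fit_gene_models <- function(expr, design, criteria = significance_criteria()) {
  design <- align_design(expr, design)
  X <- encode_design(design)
  fit <- ols_all_genes(unclass(expr), X)
  out <- data.frame(gene_id = rownames(expr), stringsAsFactors = FALSE)
  for (f in MODEL_FACTORS) {
    beta <- fit$beta[, f]
    p <- fit$p[, f]
    q <- bh_adjust(p)
    out[[paste0("beta_", f)]] <- unname(beta)
    out[[paste0("p_", f)]] <- unname(p)
    out[[paste0("q_", f)]] <- unname(q)
    out[[paste0("significant_", f)]] <-
      unname(q < criteria$q_threshold & abs(beta) > criteria$beta_threshold)
  }
  attr(out, "criteria") <- criteria
  attr(out, "df_residual") <- fit$df
  class(out) <- c("EffectTable", "data.frame")
  out
}

#' List response genes for one factor, with direction
#'
#' Genes flagged significant for the factor, tagged `up` (beta > 0) or
#' `down` (beta < 0), ordered by |beta| descending with ties broken by
#' identifier.
#'
#' @param effects an `EffectTable` from [fit_gene_models()].
#' @param factor one of `"exposure"`, `"genotype"`, `"sex"`.
#' @return data.frame with `gene_id`, `beta`, `q`, `direction`.
#' @export
call_response_genes <- function(effects, factor = "exposure") {
  if (!factor %in% MODEL_FACTORS)
    stop("unknown factor '", factor, "'", call. = FALSE)
  sig <- effects[[paste0("significant_", factor)]]
  beta <- effects[[paste0("beta_", factor)]]
  q <- effects[[paste0("q_", factor)]]
  keep <- which(sig)
  ord <- keep[order(-abs(beta[keep]), effects$gene_id[keep])]
  data.frame(gene_id = effects$gene_id[ord],
             beta = beta[ord], q = q[ord],
             direction = ifelse(beta[ord] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Post-hoc exposure-by-duration interaction test
#'
#' For a supplied list of exposure-response genes (significant at 1 and/or
#' 5 days), refits expression over BOTH durations on
#' `[intercept, exposure, duration, exposure x duration]` and BH-adjusts
#' the interaction p values over the listed genes only (default) or over
#' all genes in the matrix (`scope = "all"`).
#'
#' @param expr `ExpressionMatrix` covering both durations.
#' @param design matching `SampleDesign` with both durations.
#' @param exposure_genes character vector of gene ids to report.
#' @param q_threshold cutoff for the `duration_dependent` flag.
#' @param scope `"listed"` (BH over the listed genes) or `"all"`.
#' @return data.frame of class `InteractionTable` with `gene_id`,
#'   `beta_exposure`, `beta_duration`, `beta_interaction`, `p_interaction`,
#'   `q_interaction`, `duration_dependent`.
#' @export
fit_interaction_models <- function(expr, design, exposure_genes,
                                   q_threshold = 0.05,
                                   scope = c("listed", "all")) {
  scope <- match.arg(scope)
  missing_g <- setdiff(exposure_genes, rownames(expr))
  if (length(missing_g))
    stop("gene '", missing_g[1L], "' absent from expression matrix",
         call. = FALSE)
  design <- align_design(expr, design)
  X <- encode_interaction_design(design)
  fit_rows <- if (scope == "all") rownames(expr) else exposure_genes
  fit <- ols_all_genes(unclass(expr)[fit_rows, , drop = FALSE], X)
  q_all <- bh_adjust(fit$p[, "interaction"])
  idx <- match(exposure_genes, fit_rows)
  out <- data.frame(gene_id = exposure_genes,
                    beta_exposure = unname(fit$beta[idx, "exposure"]),
                    beta_duration = unname(fit$beta[idx, "duration"]),
                    beta_interaction = unname(fit$beta[idx, "interaction"]),
                    p_interaction = unname(fit$p[idx, "interaction"]),
                    q_interaction = unname(q_all[idx]),
                    stringsAsFactors = FALSE)
  out$duration_dependent <- out$q_interaction < q_threshold
  class(out) <- c("InteractionTable", "data.frame")
  out
}
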