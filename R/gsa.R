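# Gene-set association testing: per-gene signed -log(p) statistics from
# the additive linear model, a sum/sqrt(m) composite score per set, and an
# empirical significance threshold from whole-row permutations of sample
# labels. The permutation loop calls fit_gene_models() itself, so the null
# always uses exactly the model the observed scores used.

P_FLOOR_DEFAULT <- 1e-300

#' Match collection symbols to expression gene identifiers
#'
#' Case-insensitive exact symbol matching (mouse/human symbol sharing is
#' case-blind); sets with no matched genes are dropped and counted. The
#' matched member lists use the expression matrix's identifiers.
#'
#' @param expr_genes character vector of expression gene identifiers.
#' @param collection `GeneSetCollection`.
#' @param min_size drop sets with fewer matched genes than this
#'   (default 5; tiny m inflates the score's 1/sqrt(m) scale).
#' @return named list of matched identifier vectors, with attributes
#'   `n_dropped_empty` and `n_dropped_small`.
#' @export
match_symbols <- function(expr_genes, collection, min_size = 5L) {
  lut <- stats::setNames(expr_genes, toupper(expr_genes))
  matched <- lapply(collection$sets, function(members) {
    hit <- lut[toupper(members)]
    unname(hit[!is.na(hit)])
  })
  empty <- lengths(matched) == 0L
  small <- !empty & lengths(matched) < min_size
  out <- matched[!empty & !small]
  attr(out, "n_dropped_empty") <- sum(empty)
  attr(out, "n_dropped_small") <- sum(small)
  out
}

#' Per-gene signed -log(p) statistics for one factor
#'
#' `stat_g = sign(beta_g) * (-log(p_g))`, natural log by default (base 10
#' available); every gene is included regardless of significance. p values
#' are floored at `p_floor` before the log so the statistic stays finite;
#' p = 1 gives a statistic of exactly 0.
#'
#' @param effects `EffectTable`.
#' @param factor one of exposure/genotype/sex.
#' @param log_base `"natural"` or `"10"`.
#' @param p_floor lower clamp on p values, default 1e-300.
#' @return named numeric vector of per-gene statistics.
#' @export
gene_stats <- function(effects, factor = "exposure",
                       log_base = c("natural", "10"),
                       p_floor = P_FLOOR_DEFAULT) {
  log_base <- match.arg(as.character(log_base), c("natural", "10"))
  if (!factor %in% MODEL_FACTORS)
    stop("unknown factor '", factor, "'", call. = FALSE)
  if (p_floor <= 0) stop("p_floor must be positive", call. = FALSE)
  p <- pmax(effects[[paste0("p_", factor)]], p_floor)
  beta <- effects[[paste0("beta_", factor)]]
  lg <- if (log_base == "10") -log10(p) else -log(p)
  stats::setNames(sign(beta) * lg, effects$gene_id)
}

#' Composite gene-set association score
#'
#' Sum of the member genes' signed -log(p) statistics divided by the
#' square root of the member count — an average-like score whose null
#' spread is comparable across set sizes.
#'
#' @param stats named per-gene statistic vector from [gene_stats()].
#' @param matched character vector of member identifiers, all present in
#'   `stats`, nonempty.
#' @return the score.
#' @export
gsa_score <- function(stats, matched) {
  if (length(matched) == 0L) stop("empty matched gene list", call. = FALSE)
  miss <- setdiff(matched, names(stats))
  if (length(miss))
    stop("gene '", miss[1L], "' has no statistic", call. = FALSE)
  sum(stats[matched]) / sqrt(length(matched))
}

score_all_sets <- function(stats, matched_sets) {
  vapply(matched_sets, function(m) gsa_score(stats, m), 0)
}

#' Permutation null distribution of set scores
#'
#' For each permutation the whole design row set is shuffled against the
#' expression columns (all factor columns move together, severing every
#' factor-expression link at once), the full per-gene model is refitted
#' with [fit_gene_models()], statistics recomputed, and all set scores
#' recorded. Deterministic for a fixed seed. Permutations yielding a
#' rank-deficient design are redrawn (impossible for whole-row shuffles of
#' a full-rank design, but checked).
#'
#' @param expr `ExpressionMatrix` (single duration).
#' @param design matching `SampleDesign`.
#' @param matched_sets matched member lists from [match_symbols()].
#' @param factor factor whose statistics are scored.
#' @param n_perm number of permutations, default 1000.
#' @param seed RNG seed.
#' @param log_base,p_floor as in [gene_stats()].
#' @return list of class `PermutationNull`: `scores` (sets x n_perm
#'   matrix), `n_perm`, `seed`, `n_redrawn`.
#' @export
permutation_null <- function(expr, design, matched_sets,
                             factor = "exposure", n_perm = 1000L, seed = 1L,
                             log_base = "natural",
                             p_floor = P_FLOOR_DEFAULT) {
  design <- align_design(expr, design)
  n <- nrow(design)
  scores <- matrix(NA_real_, nrow = length(matched_sets), ncol = n_perm,
                   dimnames = list(names(matched_sets), NULL))
  set.seed(substream(seed, 11L))
  n_redrawn <- 0L
  for (b in seq_len(n_perm)) {
    repeat {
      perm <- sample.int(n)
      pd <- design
      pd[, c("exposure", "genotype", "sex", "duration_days")] <-
        design[perm, c("exposure", "genotype", "sex", "duration_days")]
      class(pd) <- c("SampleDesign", "data.frame")
      eff <- tryCatch(fit_gene_models(expr, pd),
                      error = function(e) NULL)
      if (!is.null(eff)) break
      n_redrawn <- n_redrawn + 1L
    }
    st <- gene_stats(eff, factor = factor, log_base = log_base,
                     p_floor = p_floor)
    scores[, b] <- score_all_sets(st, matched_sets)
  }
  structure(list(scores = scores, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), n_redrawn = n_redrawn),
            class = "PermutationNull")
}

# plug-in FDR estimate for one tail: mean null exceedances over observed
# exceedances, evaluated at each candidate threshold (the observed scores
# in that tail); returns the most inclusive threshold meeting `fdr`, or
# NULL when none does.
tail_threshold <- function(observed, null_scores, fdr, tail) {
  cand <- if (tail == "pos") sort(observed[observed > 0])
          else sort(observed[observed < 0], decreasing = TRUE)
  if (!length(cand)) return(NULL)
  n_perm <- ncol(null_scores)
  for (t in cand) {
    n_obs <- if (tail == "pos") sum(observed >= t) else sum(observed <= t)
    n_null <- if (tail == "pos") sum(null_scores >= t) else
      sum(null_scores <= t)
    if ((n_null / n_perm) / n_obs <= fdr) return(t)
  }
  NULL
}

#' Call significant gene sets against the permutation null
#'
#' Per tail, the significance threshold is the most inclusive observed
#' score t such that the estimated FDR — mean number of null scores beyond
#' t per permutation, divided by the number of observed scores beyond t —
#' is at most the target. By default each tail is tested at `fdr/2` so the
#' two tails jointly spend the stated FDR (`tail_mode = "per-tail-full"`
#' gives each tail the full budget instead). Per-set empirical p values are
#' `(1 + #(|null_s| >= |obs_s|)) / (1 + n_perm)`.
#'
#' @param observed named numeric vector of observed set scores.
#' @param null a [permutation_null()] result over the same sets.
#' @param fdr target FDR, default 0.05.
#' @param tail_mode `"split"` (default) or `"per-tail-full"`.
#' @return data.frame of class `GSAResult`: `set`, `m`, `score`,
#'   `empirical_p`, `significant`, `direction`; attributes
#'   `threshold_pos` / `threshold_neg` (NA when no score qualifies).
#' @export
call_significant_sets <- function(observed, null, fdr = 0.05,
                                  tail_mode = c("split", "per-tail-full")) {
  tail_mode <- match.arg(tail_mode)
  if (!identical(names(observed), rownames(null$scores)))
    stop("observed scores and null matrix cover different sets",
         call. = FALSE)
  per_tail_fdr <- if (tail_mode == "split") fdr / 2 else fdr
  t_pos <- tail_threshold(observed, null$scores, per_tail_fdr, "pos")
  t_neg <- tail_threshold(observed, null$scores, per_tail_fdr, "neg")
  sig <- (!is.null(t_pos) & observed >= if (is.null(t_pos)) Inf else t_pos) |
         (!is.null(t_neg) & observed <= if (is.null(t_neg)) -Inf else t_neg)
  emp_p <- vapply(seq_along(observed), function(i)
    (1 + sum(abs(null$scores[i, ]) >= abs(observed[i]))) / (1 + null$n_perm),
    0)
  out <- data.frame(set = names(observed),
                    m = NA_integer_,
                    score = unname(observed),
                    empirical_p = emp_p,
                    significant = unname(sig),
                    direction = ifelse(observed >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold_pos") <- if (is.null(t_pos)) NA_real_ else t_pos
  attr(out, "threshold_neg") <- if (is.null(t_neg)) NA_real_ else t_neg
  attr(out, "fdr") <- fdr
  attr(out, "tail_mode") <- tail_mode
  class(out) <- c("GSAResult", "data.frame")
  out
}

#' Run the full gene-set association analysis
#'
#' Symbol matching, observed scores, permutation null and significance
#' calls for each requested factor, on one duration's data.
#'
#' @param expr `ExpressionMatrix` (single duration).
#' @param design matching `SampleDesign`.
#' @param collection `GeneSetCollection`.
#' @param factors factors to score, default all three.
#' @param config a [run_config()] supplying `n_permutations`, `rng_seed`
#'   and the log base.
#' @param fdr permutation FDR target, default 0.05.
#' @param min_size minimum matched set size, default 5.
#' @param tail_mode see [call_significant_sets()].
#' @return named list (one `GSAResult` per factor); each table's `m`
#'   column holds the matched member counts.
#' @export
run_gsa <- function(expr, design, collection,
                    factors = MODEL_FACTORS, config = run_config(),
                    fdr = 0.05, min_size = 5L,
                    tail_mode = "split") {
  matched <- match_symbols(rownames(expr), collection, min_size = min_size)
  if (length(matched) == 0L)
    stop("no gene set matched the expression identifiers", call. = FALSE)
  effects <- fit_gene_models(expr, design,
                             significance_criteria(config$q_threshold,
                                                   config$fold_change_threshold))
  out <- list()
  for (f in factors) {
    st <- gene_stats(effects, factor = f,
                     log_base = config$log_base_for_gsa)
    observed <- score_all_sets(st, matched)
    null <- permutation_null(expr, design, matched, factor = f,
                             n_perm = config$n_permutations,
                             seed = config$rng_seed,
                             log_base = config$log_base_for_gsa)
    res <- call_significant_sets(observed, null, fdr = fdr,
                                 tail_mode = tail_mode)
    res$m <- lengths(matched)[res$set]
    attr(res, "log_base") <- config$log_base_for_gsa
    out[[f]] <- res
  }
  out
}
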