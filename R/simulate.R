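# Ground-truth simulator for the factorial smoke-exposure design. The
# generated world matches the structure the analysis assumes: an additive
# 3-factor log2 effect per gene, an optional extra exposure effect at day 5
# (the interaction), gaussian residual noise, and gene sets whose members
# carry concordant signed exposure effects (enriched) or none (null).

# stage-specific substream seeds derived from one user seed, kept < 2^31
substream <- function(seed, stage) {
  (as.integer(seed) * 7919L + stage * 104729L) %% 2147483587L
}

#' Generate a full-factorial sample design
#'
#' Builds the 2 x 2 x 2 exposure/genotype/sex factorial with `n_per_cell`
#' replicates per cell for each requested duration, with deterministic
#' sample naming (`d<duration>_<exposure>_<genotype>_<sex>_r<i>`).
#'
#' @param n_per_cell replicates per factorial cell, >= 2 (the model is not
#'   fittable below that).
#' @param durations integer subset of `c(1, 5)`.
#' @return a [sample_design()].
#' @export
generate_design <- function(n_per_cell = 5L, durations = c(1L, 5L)) {
  if (n_per_cell < 2L)
    stop("n_per_cell must be >= 2 for the model to be fittable",
         call. = FALSE)
  durations <- as.integer(durations)
  if (!length(durations) || !all(durations %in% c(1L, 5L)))
    stop("durations must be a subset of c(1, 5)", call. = FALSE)
  grid <- expand.grid(rep = seq_len(n_per_cell),
                      sex = FACTOR_LEVELS$sex,
                      genotype = FACTOR_LEVELS$genotype,
                      exposure = FACTOR_LEVELS$exposure,
                      duration = durations,
                      stringsAsFactors = FALSE)
  ids <- sprintf("d%d_%s_%s_%s_r%d", grid$duration, grid$exposure,
                 grid$genotype, grid$sex, grid$rep)
  sample_design(ids, grid$exposure, grid$genotype, grid$sex, grid$duration)
}

#' Simulate a log2 expression matrix with known per-gene effects
#'
#' Every gene g and sample s receives
#' `baseline(g) + beta_exposure(g) x_e(s) + beta_genotype(g) x_g(s) +
#'  beta_sex(g) x_s(s) + beta_interaction(g) x_e(s) x_day5(s) + noise`.
#' Affected genes per factor are chosen without replacement at the exact
#' requested count (`round(fraction * n_genes)`); effect signs are +/- with
#' equal probability and magnitudes uniform on `effect_size_range`.
#' Interaction effects go to a random subset of the exposure-affected genes.
#' Baselines are uniform on 4-12 log2 units (typical normalized array
#' range). Draws are split into per-stage substreams of the one seed, so
#' the same seed always reproduces the same matrix bit for bit.
#'
#' @param design `SampleDesign` (e.g. from [generate_design()]).
#' @param n_genes number of genes, >= 1.
#' @param affected_fraction named fractions per factor, e.g.
#'   `c(exposure = .05, genotype = .05, sex = .05)`.
#' @param effect_size_range log2 magnitude interval, within (0, 8].
#' @param interaction_fraction fraction of exposure-affected genes that get
#'   a duration-dependent extra effect (default 0.3 — a minority of
#'   response genes are duration dependent).
#' @param noise_sd residual standard deviation (log2 units), >= 0.
#' @param seed integer RNG seed.
#' @return list with `expr` (an [expression_matrix()]) and `truth`, a
#'   data.frame with per-gene `baseline`, the four betas and `noise_sd`.
#' @export
generate_expression <- function(design, n_genes = 2000L,
                                affected_fraction = c(exposure = 0.05,
                                                      genotype = 0.05,
                                                      sex = 0.05),
                                effect_size_range = c(0.4, 2.0),
                                interaction_fraction = 0.3,
                                noise_sd = 0.3,
                                seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  af <- affected_fraction[MODEL_FACTORS]
  names(af) <- MODEL_FACTORS
  af[is.na(af)] <- 0
  if (any(af < 0 | af > 1) || interaction_fraction < 0 ||
      interaction_fraction > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(effect_size_range) != 2L || effect_size_range[1L] <= 0 ||
      effect_size_range[2L] > 8 ||
      effect_size_range[1L] > effect_size_range[2L])
    stop("effect_size_range must be an increasing interval within (0, 8]",
         call. = FALSE)

  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  draw_effects <- function(frac, stage) {
    set.seed(substream(seed, stage))
    beta <- numeric(n_genes)
    n_hit <- round(frac * n_genes)
    if (n_hit > 0) {
      hit <- sample.int(n_genes, n_hit)
      mag <- stats::runif(n_hit, effect_size_range[1L], effect_size_range[2L])
      sgn <- sample(c(-1, 1), n_hit, replace = TRUE)
      beta[hit] <- sgn * mag
    }
    beta
  }
  set.seed(substream(seed, 1L))
  baseline <- stats::runif(n_genes, 4, 12)
  beta_e <- draw_effects(af[["exposure"]], 2L)
  beta_g <- draw_effects(af[["genotype"]], 3L)
  beta_s <- draw_effects(af[["sex"]], 4L)

  set.seed(substream(seed, 5L))
  beta_i <- numeric(n_genes)
  expo_hit <- which(beta_e != 0)
  n_int <- round(interaction_fraction * length(expo_hit))
  if (n_int > 0) {
    int_idx <- expo_hit[sample.int(length(expo_hit), n_int)]
    mag <- stats::runif(n_int, effect_size_range[1L], effect_size_range[2L])
    sgn <- sample(c(-1, 1), n_int, replace = TRUE)
    beta_i[int_idx] <- sgn * mag
  }

  x_e <- as.numeric(design$exposure == "smoke")
  x_g <- as.numeric(design$genotype == "bENaC")
  x_s <- as.numeric(design$sex == "male")
  x_d5 <- as.numeric(design$duration_days == 5L)
  signal <- baseline +
    outer(beta_e, x_e) + outer(beta_g, x_g) + outer(beta_s, x_s) +
    outer(beta_i, x_e * x_d5)

  set.seed(substream(seed, 6L))
  noise <- matrix(stats::rnorm(n_genes * nrow(design), 0, noise_sd),
                  nrow = n_genes)
  vals <- signal + noise
  expr <- expression_matrix(vals, gene_ids = gene_ids,
                            sample_ids = design$sample_id)
  truth <- data.frame(gene_id = gene_ids, baseline = baseline,
                      beta_exposure = beta_e, beta_genotype = beta_g,
                      beta_sex = beta_s, beta_interaction = beta_i,
                      noise_sd = noise_sd, stringsAsFactors = FALSE)
  list(expr = expr, truth = truth)
}

#' Generate gene sets with known enrichment status
#'
#' Enriched sets draw at least `signal_fraction` (default 0.8) of their
#' members from exposure-response genes whose beta sign agrees with the
#' set's label (`enriched_up` / `enriched_down`), topped up from null genes;
#' null sets draw uniformly from null genes (all four betas zero). The
#' universe is the full simulated gene complement.
#'
#' @param truth the per-gene truth table from [generate_expression()].
#' @param n_sets number of sets.
#' @param size_range inclusive member-count interval, within `[5, n_genes]`.
#' @param enriched_fraction fraction of sets that carry signal.
#' @param seed integer RNG seed.
#' @param signal_fraction minimum fraction of concordant members per
#'   enriched set.
#' @return list with `collection` (a [gene_set_collection()]) and
#'   `set_truth`, a data.frame of set names and labels
#'   (`enriched_up`, `enriched_down`, `null`).
#' @export
generate_gene_sets <- function(truth, n_sets = 20L, size_range = c(10L, 40L),
                               enriched_fraction = 0.25, seed = 1L,
                               signal_fraction = 0.8) {
  n_genes <- nrow(truth)
  if (size_range[1L] < 5L || size_range[2L] > n_genes ||
      size_range[1L] > size_range[2L])
    stop("size_range must lie within [5, n_genes]", call. = FALSE)
  set.seed(substream(seed, 7L))
  n_enr <- round(enriched_fraction * n_sets)
  labels <- c(rep(c("enriched_up", "enriched_down"), length.out = n_enr),
              rep("null", n_sets - n_enr))
  up_pool <- truth$gene_id[truth$beta_exposure > 0]
  down_pool <- truth$gene_id[truth$beta_exposure < 0]
  null_pool <- truth$gene_id[truth$beta_exposure == 0 &
                             truth$beta_genotype == 0 &
                             truth$beta_sex == 0 &
                             truth$beta_interaction == 0]
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET_%02d_%s", seq_len(n_sets), toupper(labels))
  for (i in seq_len(n_sets)) {
    m <- sample(seq(size_range[1L], size_range[2L]), 1L)
    if (labels[i] == "null") {
      if (length(null_pool) < m)
        stop("not enough null genes for requested set sizes", call. = FALSE)
      sets[[i]] <- sample(null_pool, m)
    } else {
      pool <- if (labels[i] == "enriched_up") up_pool else down_pool
      n_sig <- ceiling(signal_fraction * m)
      if (length(pool) < n_sig)
        stop("not enough ", labels[i], " genes for requested enriched sets",
             call. = FALSE)
      fill <- m - n_sig
      if (length(null_pool) < fill)
        stop("not enough null genes to pad enriched sets", call. = FALSE)
      sets[[i]] <- c(sample(pool, n_sig), sample(null_pool, fill))
    }
  }
  collection <- gene_set_collection(
    sets,
    descriptions = stats::setNames(labels, names(sets)),
    universe = truth$gene_id)
  list(collection = collection,
       set_truth = data.frame(set = names(sets), label = labels,
                              stringsAsFactors = FALSE))
}
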