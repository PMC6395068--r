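# Set algebra over response-gene lists: partition by exposure duration,
# breakdown of exposure-response genes by additional genotype/sex
# modulation (the Sankey counts), and cross-duration comparison of effect
# sizes (the correlation scatter).

#' Partition response genes by exposure duration
#'
#' Exact union/intersection/difference of the two duplicate-free response
#' lists, with the inclusion-exclusion identity
#' `|pooled| = n_day1 + n_day5 - |shared|` holding by construction.
#'
#' @param genes_day1,genes_day5 character vectors, duplicate-free.
#' @return list of class `DurationPartition` with counts `n_day1`,
#'   `n_day5`, and lists `shared`, `unique_day1`, `unique_day5`, `pooled`.
#' @export
partition_by_duration <- function(genes_day1, genes_day5) {
  if (anyDuplicated(genes_day1))
    stop("duplicate gene in genes_day1: ",
         genes_day1[duplicated(genes_day1)][1L], call. = FALSE)
  if (anyDuplicated(genes_day5))
    stop("duplicate gene in genes_day5: ",
         genes_day5[duplicated(genes_day5)][1L], call. = FALSE)
  shared <- intersect(genes_day1, genes_day5)
  structure(list(n_day1 = length(genes_day1), n_day5 = length(genes_day5),
                 shared = shared,
                 unique_day1 = setdiff(genes_day1, genes_day5),
                 unique_day5 = setdiff(genes_day5, genes_day1),
                 pooled = union(genes_day1, genes_day5)),
            class = "DurationPartition")
}

#' @export
print.DurationPartition <- function(x, ...) {
  cat(sprintf(paste0("DurationPartition: %d day-1 and %d day-5 response ",
                     "genes; %d shared, %d + %d unique, %d pooled\n"),
              x$n_day1, x$n_day5, length(x$shared),
              length(x$unique_day1), length(x$unique_day5),
              length(x$pooled)))
  invisible(x)
}

#' Break exposure-response genes down by additional factors
#'
#' Among genes significant for exposure, counts four mutually exclusive
#' categories: exposure only, exposure + genotype (not sex),
#' exposure + sex (not genotype), and all three factors. The multifactor
#' percentage is `(geno_only + sex_only + all_three) / total`, rounded
#' half-up to a whole percent.
#'
#' @param effects an `EffectTable` with all three significance flags.
#' @return list of class `FactorBreakdown`.
#' @export
cross_factor_breakdown <- function(effects) {
  need <- paste0("significant_", MODEL_FACTORS)
  miss <- setdiff(need, names(effects))
  if (length(miss))
    stop("EffectTable lacks flag column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  e <- effects$significant_exposure
  g <- effects$significant_genotype
  s <- effects$significant_sex
  counts <- c(exposure_only = sum(e & !g & !s),
              exposure_and_genotype_only = sum(e & g & !s),
              exposure_and_sex_only = sum(e & !g & s),
              exposure_genotype_sex = sum(e & g & s))
  total <- sum(counts)
  multi <- sum(counts[-1L])
  structure(c(as.list(counts),
              list(total = total,
                   percent_multifactor =
                     if (total == 0L) 0 else round_half_up(100 * multi / total))),
            class = "FactorBreakdown")
}

#' Compare per-gene effect sizes between the two exposure durations
#'
#' For the pooled response genes of one factor, pairs each gene's beta at
#' day 1 with its beta at day 5, reports the Pearson correlation test and
#' the least-squares line with 95% confidence/prediction bands, and flags
#' the genes with a significant exposure-by-duration interaction (the red
#' points of the scatter).
#'
#' @param effects_day1,effects_day5 `EffectTable`s from the two durations.
#' @param factor one of exposure/genotype/sex.
#' @param gene_scope character vector of genes to compare (usually the
#'   pooled response genes for the factor); must appear in both tables.
#' @param interaction optional `InteractionTable` supplying the
#'   `duration_dependent` flags.
#' @param level band coverage, default 0.95.
#' @return list with `r`, `p`, `slope`, `intercept`, `bands`,
#'   `flagged_genes`, and the `pairs` data.frame
#'   (gene_id, beta_day1, beta_day5, flagged).
#' @export
compare_duration_betas <- function(effects_day1, effects_day5,
                                   factor = "exposure", gene_scope,
                                   interaction = NULL, level = 0.95) {
  if (!factor %in% MODEL_FACTORS)
    stop("unknown factor '", factor, "'", call. = FALSE)
  for (tab in list(effects_day1, effects_day5)) {
    miss <- setdiff(gene_scope, tab$gene_id)
    if (length(miss))
      stop("gene '", miss[1L], "' missing from an effect table",
           call. = FALSE)
  }
  col <- paste0("beta_", factor)
  b1 <- effects_day1[[col]][match(gene_scope, effects_day1$gene_id)]
  b5 <- effects_day5[[col]][match(gene_scope, effects_day5$gene_id)]
  flagged <- character(0)
  if (!is.null(interaction))
    flagged <- intersect(gene_scope,
                         interaction$gene_id[interaction$duration_dependent])
  ct <- pearson_correlation_test(b1, b5)
  line <- ols_line_with_intervals(b1, b5, level = level)
  list(r = ct$r, p = ct$p, slope = line$slope, intercept = line$intercept,
       bands = line$bands, flagged_genes = flagged,
       pairs = data.frame(gene_id = gene_scope, beta_day1 = b1,
                          beta_day5 = b5,
                          flagged = gene_scope %in% flagged,
                          stringsAsFactors = FALSE))
}
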