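# Domain containers shared across the pipeline. All are light S3 wrappers
# around base structures so that downstream code can use ordinary matrix /
# data.frame idioms while constructors enforce the invariants once.

#' Factor names modelled by the additive per-gene linear model
#' @keywords internal
MODEL_FACTORS <- c("exposure", "genotype", "sex")

# Declared levels; the FIRST level is the reference, so positive beta means
# higher in smoke / bENaC / male.
FACTOR_LEVELS <- list(
  exposure = c("sham", "smoke"),
  genotype = c("WT", "bENaC"),
  sex      = c("female", "male")
)

#' Construct an expression matrix container
#'
#' An `ExpressionMatrix` is a numeric genes-by-samples matrix of normalized
#' log2 intensities with unique gene and sample identifiers as dimnames.
#' All values must be finite; missing values are a hard error (normalized
#' array data is assumed complete; nothing is imputed).
#'
#' @param values numeric matrix, genes as rows, samples as columns.
#' @param gene_ids,sample_ids optional identifier vectors; taken from
#'   `dimnames(values)` when omitted.
#' @return an object of class `ExpressionMatrix` (a named numeric matrix).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene identifier: ", dup[1L], call. = FALSE)
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample identifier: ", dup[1L], call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (log2 intensity)\n",
              nrow(x), ncol(x)))
  cat("  genes:  ", paste(utils::head(rownames(x), 4L), collapse = ", "),
      if (nrow(x) > 4L) ", ..." else "", "\n", sep = "")
  cat("  samples:", paste(utils::head(colnames(x), 4L), collapse = ", "),
      if (ncol(x) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, drop = FALSE) {
  out <- unclass(x)[i, j, drop = drop]
  if (is.matrix(out) && !is.null(dimnames(out)))
    class(out) <- c("ExpressionMatrix", class(out))
  out
}

#' Split a paired expression matrix and design by exposure duration
#'
#' @param expr `ExpressionMatrix`
#' @param design matching `SampleDesign`
#' @return named list (one element per duration, e.g. `"1"`, `"5"`), each
#'   with `expr` and `design` restricted to that duration's samples.
#' @export
split_by_duration <- function(expr, design) {
  design <- align_design(expr, design)
  lapply(split(seq_len(nrow(design)), design$duration_days), function(idx) {
    d <- design[idx, , drop = FALSE]
    rownames(d) <- NULL
    class(d) <- c("SampleDesign", "data.frame")
    list(expr = expr[, d$sample_id], design = d)
  })
}

#' Construct and validate a sample design table
#'
#' A `SampleDesign` records, per sample, the levels of the three modelled
#' factors and the exposure duration in days. Levels are fixed:
#' exposure in (sham, smoke), genotype in (WT, bENaC), sex in
#' (female, male); reference levels are sham/WT/female so that positive
#' model coefficients read as "up in smoke", "up in bENaC", "up in male".
#'
#' @param sample_id character, unique.
#' @param exposure,genotype,sex character vectors over the declared levels.
#' @param duration_days integer vector; by default only 1 and 5 are accepted,
#'   override with `allowed_durations` for other designs.
#' @param allowed_durations integer set of acceptable durations.
#' @return data.frame of class `SampleDesign`.
#' @export
sample_design <- function(sample_id, exposure, genotype, sex, duration_days,
                          allowed_durations = c(1L, 5L)) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (any(duplicated(sample_id)))
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1L],
         call. = FALSE)
  cols <- list(exposure = exposure, genotype = genotype, sex = sex)
  for (f in names(cols)) {
    v <- as.character(cols[[f]])
    if (length(v) != n)
      stop("column '", f, "' length mismatch", call. = FALSE)
    bad <- setdiff(unique(v), FACTOR_LEVELS[[f]])
    if (length(bad))
      stop(sprintf("invalid %s level '%s' (allowed: %s)", f, bad[1L],
                   paste(FACTOR_LEVELS[[f]], collapse = ", ")), call. = FALSE)
    cols[[f]] <- factor(v, levels = FACTOR_LEVELS[[f]])
  }
  duration_days <- as.integer(duration_days)
  if (length(duration_days) != n)
    stop("column 'duration_days' length mismatch", call. = FALSE)
  bad <- setdiff(unique(duration_days), as.integer(allowed_durations))
  if (length(bad))
    stop(sprintf("invalid duration_days value %d (allowed: %s)", bad[1L],
                 paste(allowed_durations, collapse = ", ")), call. = FALSE)
  out <- data.frame(sample_id = sample_id, exposure = cols$exposure,
                    genotype = cols$genotype, sex = cols$sex,
                    duration_days = duration_days,
                    stringsAsFactors = FALSE)
  class(out) <- c("SampleDesign", "data.frame")
  out
}

#' Reconcile an expression matrix with a design table by sample identifier
#'
#' Pairing is by identifier, never by position: the design is reordered to
#' the matrix column order, and the two must contain exactly the same sample
#' set. A shuffled design therefore yields identical downstream results.
#'
#' @param expr `ExpressionMatrix`
#' @param design `SampleDesign`
#' @return the design, rows ordered as `colnames(expr)`.
#' @export
align_design <- function(expr, design) {
  ids <- colnames(expr)
  missing_d <- setdiff(ids, design$sample_id)
  if (length(missing_d))
    stop("sample '", missing_d[1L], "' absent from design", call. = FALSE)
  extra <- setdiff(design$sample_id, ids)
  if (length(extra))
    stop("design sample '", extra[1L], "' absent from expression matrix",
         call. = FALSE)
  out <- design[match(ids, design$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SampleDesign", "data.frame")
  out
}

#' Construct a gene-set collection
#'
#' Member symbols are deduplicated case-insensitively within each set (first
#' casing kept for display); set names must be unique. An optional universe
#' restricts which symbols count in enrichment computations.
#'
#' @param sets named list of character member vectors.
#' @param descriptions optional named character, one per set.
#' @param universe optional character vector of eligible symbols.
#' @return object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every set must be named", call. = FALSE)
  if (any(duplicated(names(sets))))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1L],
         call. = FALSE)
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    m[!duplicated(toupper(m))]
  })
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- stats::setNames(as.character(descriptions)[
      match(names(sets), names(descriptions))], names(sets))
    descriptions[is.na(descriptions)] <- ""
  }
  if (!is.null(universe)) {
    universe <- as.character(universe)
    universe <- universe[!duplicated(toupper(universe))]
  }
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("GeneSetCollection: %d sets (sizes %s-%s)%s\n",
              length(x$sets),
              if (length(sizes)) min(sizes) else 0,
              if (length(sizes)) max(sizes) else 0,
              if (is.null(x$universe)) ""
              else sprintf(", universe of %d symbols", length(x$universe))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Run configuration with the pipeline defaults
#'
#' Central store for the tunable thresholds: `q_threshold` (BH FDR cutoff,
#' default 0.05), `fold_change_threshold` (ratio, default 1.3, i.e. a
#' log2 effect-size cutoff of ~0.379), `n_permutations` (default 1000),
#' `kmeans_k` (default 5), `kmeans_restarts` (default 50), `rng_seed`, and
#' the logarithm base used by the gene-set statistic (`"natural"` or `"10"`).
#'
#' @param q_threshold probability in (0,1).
#' @param fold_change_threshold ratio > 1.
#' @param n_permutations positive count.
#' @param kmeans_k,kmeans_restarts positive counts.
#' @param rng_seed integer seed.
#' @param log_base_for_gsa `"natural"` or `"10"`.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(q_threshold = 0.05, fold_change_threshold = 1.3,
                       n_permutations = 1000L, kmeans_k = 5L,
                       kmeans_restarts = 50L, rng_seed = 1L,
                       log_base_for_gsa = c("natural", "10")) {
  log_base_for_gsa <- match.arg(as.character(log_base_for_gsa),
                                c("natural", "10"))
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)", call. = FALSE)
  if (!is.numeric(fold_change_threshold) || fold_change_threshold <= 1)
    stop("fold_change_threshold must be > 1", call. = FALSE)
  if (n_permutations < 1)
    stop("n_permutations must be >= 1", call. = FALSE)
  if (kmeans_k < 1 || kmeans_restarts < 1)
    stop("kmeans_k and kmeans_restarts must be >= 1", call. = FALSE)
  structure(list(q_threshold = q_threshold,
                 fold_change_threshold = fold_change_threshold,
                 n_permutations = as.integer(n_permutations),
                 kmeans_k = as.integer(kmeans_k),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 rng_seed = as.integer(rng_seed),
                 log_base_for_gsa = log_base_for_gsa),
            class = "RunConfig")
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, x[[nm]]))
  invisible(x)
}
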