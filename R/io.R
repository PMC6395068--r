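# Readers and writers for the plain-text interchange formats: expression
# TSV (genes as rows, `gene_id` header token required so a transposed file
# is rejected), design TSV/CSV, GMT gene sets, and results tables. Readers
# fail loudly with the offending location; nothing is silently coerced.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene identifiers
#' (header token `gene_id`) and whose remaining columns are numeric log2
#' intensities under sample-identifier headers. Row and column order are
#' preserved. Duplicated identifiers, non-numeric cells and NA tokens are
#' hard errors naming the location.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty expression file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "gene_id")
    stop("expression file must be gene-by-sample with a 'gene_id' first ",
         "header column (got '", header[1L], "')", call. = FALSE)
  sample_ids <- header[-1L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header)))
    stop("row ", which(nf != length(header))[1L] + 1L,
         " has ", nf[nf != length(header)][1L], " fields, expected ",
         length(header), call. = FALSE)
  gene_ids <- vapply(fields, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(length(sample_ids)))
  )
  vals <- matrix(vals, nrow = length(sample_ids))  # samples x genes here
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value at row %d (gene '%s'), column '%s'",
                 bad[1L, 2L] + 1L, gene_ids[bad[1L, 2L]],
                 sample_ids[bad[1L, 1L]]), call. = FALSE)
  }
  expression_matrix(t(vals), gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; numeric cells are written with 15
#' significant digits so a read/write cycle is value-identical to well below
#' 1e-9.
#'
#' @param expr `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression_matrix <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  rows <- apply(expr, 1L, function(v)
    paste(sprintf("%.15g", v), collapse = "\t"))
  writeLines(paste(rownames(expr), rows, sep = "\t"), con)
  invisible(path)
}

#' Read a sample design table
#'
#' Accepts tab- or comma-delimited text with columns `sample_id`,
#' `exposure`, `genotype`, `sex`, `duration_days`. Unknown factor levels and
#' missing columns raise errors naming the offender. Extra columns are
#' ignored.
#'
#' @param path file path; delimiter sniffed from the header line.
#' @param allowed_durations acceptable durations, default `c(1, 5)`.
#' @return a [sample_design()].
#' @export
read_design <- function(path, allowed_durations = c(1L, 5L)) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "exposure", "genotype", "sex", "duration_days")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dur <- suppressWarnings(as.integer(df$duration_days))
  if (anyNA(dur))
    stop("non-integer duration_days value '",
         df$duration_days[is.na(dur)][1L], "'", call. = FALSE)
  sample_design(df$sample_id, df$exposure, df$genotype, df$sex, dur,
                allowed_durations = allowed_durations)
}

#' Write a design table as TSV
#' @param design `SampleDesign`
#' @param path output path
#' @export
write_design <- function(design, path) {
  df <- as.data.frame(design)
  df$exposure <- as.character(df$exposure)
  df$genotype <- as.character(df$genotype)
  df$sex <- as.character(df$sex)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated member symbols
#' (the MSigDB convention). Members are deduplicated case-insensitively,
#' keeping the first casing seen. Lines with fewer than three fields are
#' format errors reported with their line number.
#'
#' @param path GMT file path.
#' @param universe optional symbol universe to attach.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, descriptions = stats::setNames(desc, nm),
                      universe = universe)
}

#' Write a collection to GMT
#' @param collection `GeneSetCollection`
#' @param path output path
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table (effects, gene-set scores, enrichment) as TSV
#'
#' Generic tab-delimited writer used for every result table the pipeline
#' emits. Numeric columns are written with 15 significant digits so a
#' write/read cycle agrees to well within 1e-9; column order is the column
#' order of the table (deterministic by construction upstream).
#'
#' @param table data.frame.
#' @param path output path.
#' @export
write_results_table <- function(table, path) {
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.15g", df[[j]])
    if (is.logical(df[[j]])) df[[j]] <- ifelse(df[[j]], "TRUE", "FALSE")
    if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' Columns are re-typed conservatively: values parseable as numbers become
#' numeric, TRUE/FALSE become logical, everything else stays character.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (all(v %in% c("TRUE", "FALSE"))) {
      df[[j]] <- v == "TRUE"
    } else {
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) df[[j]] <- num
    }
  }
  df
}

#' Read a flat key=value run-configuration file
#'
#' Unknown keys are rejected; values are coerced to the types of the
#' [run_config()] defaults. Blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("config line ", bad[1L], " is not key=value", call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  allowed <- names(formals(run_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config key '", unknown[1L], "'", call. = FALSE)
  args <- as.list(vals)
  names(args) <- keys
  numkeys <- setdiff(allowed, "log_base_for_gsa")
  for (k in intersect(keys, numkeys)) args[[k]] <- as.numeric(args[[k]])
  do.call(run_config, args)
}
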