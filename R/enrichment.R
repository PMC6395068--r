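# Discrete-list overlap enrichment: a query gene list against a gene-set
# collection (hypergeometric upper tail, BH across sets — the MSigDB-style
# overlap computation) and pairwise list-vs-list Fisher tests against
# published signatures. The universe size is always an explicit argument:
# overlap p values are meaningless without it and no default is safe.

#' Overlap enrichment of a gene list against a collection
#'
#' For each set, counts the case-insensitive overlap with the query and
#' computes the hypergeometric upper-tail p for drawing at least that many
#' set members in a query-sized draw from the universe; q values are BH
#' across all tested sets. When the collection declares a universe, set
#' members and query are first restricted to it. Sets empty after
#' restriction are dropped (not reported at p = 1).
#'
#' @param query character vector, duplicate-free.
#' @param collection `GeneSetCollection`.
#' @param universe_size universe size N; must be at least the query size
#'   and every set size.
#' @return data.frame of class `EnrichmentTable`, rows sorted by q then
#'   set name: `set`, `genes_in_set`, `genes_in_overlap`, `p`, `q`.
#' @export
enrich_list <- function(query, collection, universe_size) {
  if (anyDuplicated(toupper(query)))
    stop("duplicate gene in query: ",
         query[duplicated(toupper(query))][1L], call. = FALSE)
  universe_size <- as.integer(universe_size)
  qry <- toupper(query)
  if (!is.null(collection$universe)) {
    uni <- toupper(collection$universe)
    qry <- intersect(qry, uni)
    sets <- lapply(collection$sets, function(m) intersect(toupper(m), uni))
  } else {
    sets <- lapply(collection$sets, toupper)
  }
  sets <- sets[lengths(sets) > 0L]
  if (universe_size < length(qry))
    stop("universe_size smaller than the query", call. = FALSE)
  if (length(sets) && universe_size < max(lengths(sets)))
    stop("universe_size smaller than a gene set", call. = FALSE)
  n <- length(qry)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(qry, sets[[nm]]))
    p <- hypergeom_upper_tail(overlap2x2(k, K, n, universe_size))
    data.frame(set = nm, genes_in_set = K, genes_in_overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(0), genes_in_set = integer(0),
                      genes_in_overlap = integer(0), p = numeric(0))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Fisher overlap test between two gene lists
#'
#' Case-insensitive intersection of two duplicate-free lists inside a
#' shared universe, with the one-sided (enrichment) Fisher exact p and the
#' sample odds ratio.
#'
#' @param list_a,list_b character vectors, duplicate-free.
#' @param universe_size universe size N >= both list sizes.
#' @return list with `k`, `overlap` (the shared identifiers, casing from
#'   `list_a`), `odds_ratio`, `p`.
#' @export
overlap_two_lists <- function(list_a, list_b, universe_size) {
  for (l in list(list_a, list_b)) {
    if (anyDuplicated(toupper(l)))
      stop("duplicate gene in input list: ",
           l[duplicated(toupper(l))][1L], call. = FALSE)
  }
  universe_size <- as.integer(universe_size)
  if (universe_size < max(length(list_a), length(list_b)))
    stop("universe_size smaller than an input list", call. = FALSE)
  ov <- list_a[toupper(list_a) %in% toupper(list_b)]
  ft <- fisher_exact_overlap(overlap2x2(length(ov), length(list_b),
                                        length(list_a), universe_size))
  list(k = length(ov), overlap = ov, odds_ratio = ft$odds_ratio, p = ft$p)
}
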