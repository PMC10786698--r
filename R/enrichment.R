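# hypergeometric gene-set enrichment over user-supplied annotations

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene identifiers
#'   (as read from a GMT file); every set must be nonempty.
#' @param universe optional character vector of background gene
#'   identifiers; defaults to the union of all set members (the
#'   common default of enrichment tools when no background is given).
#'   Set members outside a supplied universe are dropped.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_param("sets must be a named list")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(vapply(sets, length, integer(1)) == 0L))
    stop_param("empty annotation set")
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, intersect, y = universe)
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation test
#'
#' For each annotation set, tests whether the query gene list
#' overlaps it more than expected by chance: with `N` universe genes,
#' `K` of them in the set, and `n` query genes mapped to at least one
#' set, the p-value is the hypergeometric upper tail
#' `P(X >= k)` for the observed overlap `k`. GeneRatio is `k / n` —
#' the ratio of query genes mapped to the set to the total mapped
#' query set. P-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param query character vector of query gene identifiers (e.g.
#'   GWAS-associated genes).
#' @param collection a [gene_set_collection()] (or a named list of
#'   sets, converted with the default universe).
#' @return tibble sorted by adjusted then raw p: `set`, `k`, `n`,
#'   `K`, `N`, `gene_ratio`, `bg_ratio`, `p`, `p_adjusted`, `genes`
#'   (overlap, comma-separated). Attribute `unmapped` lists query
#'   genes in no set.
#' @export
enrich <- function(query, collection) {
  if (!inherits(collection, "gene_set_collection"))
    collection <- gene_set_collection(collection)
  query <- unique(as.character(query))
  universe <- collection$universe
  sets <- collection$sets
  mapped_space <- unique(unlist(sets, use.names = FALSE))
  q_in_universe <- intersect(query, universe)
  q_mapped <- intersect(q_in_universe, mapped_space)
  unmapped <- setdiff(query, q_mapped)
  n <- length(q_mapped)
  if (n == 0L)
    stop_param("no query genes map to any annotation set")
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    members <- sets[[nm]]
    K <- length(members)
    overlap <- intersect(q_mapped, members)
    k <- length(overlap)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set = nm, k = k, n = n, K = K, N = N,
                   gene_ratio = k / n, bg_ratio = K / N,
                   p = min(p, 1),
                   genes = paste(sort(overlap), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p_adjusted, out$p, out$set),
             c("set", "k", "n", "K", "N", "gene_ratio", "bg_ratio",
               "p", "p_adjusted", "genes")]
  attr(out, "unmapped") <- unmapped
  out
}
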