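#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for enrichment in a query list drawn from a finite
#' universe: with N = universe size, K = set size within the universe,
#' n = query size and k = observed overlap, the one-sided upper-tail p-value
#' is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Sets are intersected
#' with the universe before testing; sets with empty intersection are skipped
#' with a note. BH adjustment is computed across the tested sets. Two
#' significance flags are reported: the raw-p presentation convention
#' (`p < p_threshold`, e.g. 0.03 for GO-style and 0.1 for pathway-style
#' displays) and the FDR convention (`fdr < fdr_threshold`).
#'
#' The universe should be the set of genes the analysis could have selected
#' from - typically all genes surviving the expression filter for the
#' contrast - not a whole-genome annotation.
#'
#' @param query character vector of gene ids; must be a subset of `universe`.
#' @param universe character vector of background gene ids.
#' @param sets a [read_gmt()] collection (or named list of character
#'   vectors).
#' @param p_threshold raw-p presentation threshold (default 0.03).
#' @param fdr_threshold BH threshold (default 0.05).
#' @return a `data.frame` sorted by p-value: `set`, `overlap` (k),
#'   `set_size` (K), `query_size` (n), `universe_size` (N), `pvalue`, `fdr`,
#'   `significant_raw`, `significant_fdr`, `genes` (comma-separated overlap).
#' @examples
#' overrepresentation(c("a", "b"), letters[1:10],
#'                    list(S1 = c("a", "b", "c"), S2 = c("x", "y")))
#' @export
overrepresentation <- function(query, universe, sets, p_threshold = 0.03,
                               fdr_threshold = 0.05) {
  query <- unique(query); universe <- unique(universe)
  check_number(p_threshold, "p_threshold", min = 0, strict_min = TRUE)
  check_number(fdr_threshold, "fdr_threshold", min = 0, strict_min = TRUE)
  bad <- setdiff(query, universe)
  if (length(bad))
    stopf("query gene(s) not in universe: %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  N <- length(universe); n <- length(query)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    message(sprintf("overrepresentation: skipping %d set(s) with no universe overlap: %s",
                    sum(empty),
                    paste(utils::head(names(sets)[empty], 5L),
                          collapse = ", ")))
    sets <- sets[!empty]
  }
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    hit <- intersect(sets[[nm]], query)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, pvalue = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), pvalue = numeric(0),
                      fdr = numeric(0), significant_raw = logical(0),
                      significant_fdr = logical(0), genes = character(0),
                      stringsAsFactors = FALSE))
  out$fdr <- bh_adjust(out$pvalue)
  out$significant_raw <- out$pvalue < p_threshold
  out$significant_fdr <- out$fdr < fdr_threshold
  out <- out[order(out$pvalue, out$set), c("set", "overlap", "set_size",
                                           "query_size", "universe_size",
                                           "pvalue", "fdr",
                                           "significant_raw",
                                           "significant_fdr", "genes")]
  rownames(out) <- NULL
  out
}
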