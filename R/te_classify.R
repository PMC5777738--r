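# Translational-efficiency statistic, z-scoring, translational calls,
# four-way transcriptional/translational classification and set
# intersections.

#' Select polysome-significant genes
#'
#' Genes with BH-adjusted FDR strictly below the threshold in a P-pool
#' differential-expression result. The conventional thresholds are 0.05 for
#' a non-tumoural line and 0.10 for a tumoural line.
#'
#' @param de_p a [test_contrast()] result for the polysomal pool.
#' @param fdr_threshold threshold in (0, 1].
#' @return character vector of gene ids.
#' @export
select_polysome_significant <- function(de_p, fdr_threshold) {
  check_number(fdr_threshold, "fdr_threshold", min = 0, strict_min = TRUE)
  if (fdr_threshold > 1) stopf("'fdr_threshold' must be in (0, 1]")
  de_p$gene_id[de_p$fdr < fdr_threshold]
}

#' Compute the translational-efficiency statistic
#'
#' In `"ratio"` mode (the classical definition) `Te = log2FC_P / log2FC_T`;
#' genes with `|log2FC_T| < denom_tolerance` are marked `excluded`
#' (`"zero_denominator"`) and `|Te|` is winsorized at `te_cap` so single
#' near-zero denominators cannot dominate the later z-scoring. In
#' `"difference"` mode `Te = log2FC_P - log2FC_T` (the delta-TE form), which
#' is stable everywhere and excludes nothing.
#'
#' @param de_p,de_t [test_contrast()] results for the P and T pools of the
#'   same cell line and treatment.
#' @param genes gene ids to evaluate (default: all genes shared by both
#'   results, i.e. typically the polysome-significant selection).
#' @param mode `"ratio"` (default) or `"difference"`.
#' @param denom_tolerance exclusion tolerance on `|log2FC_T|` (ratio mode).
#' @param te_cap winsorization cap on `|Te|` (ratio mode).
#' @return a `data.frame` of class `"te_table"`: `gene_id`, `log2FC_P`,
#'   `log2FC_T`, `te`, `call` (`"excluded"` or `NA` until classified),
#'   `exclusion_reason`; attributes record the mode and cap.
#' @export
compute_te <- function(de_p, de_t, genes = NULL,
                       mode = c("ratio", "difference"),
                       denom_tolerance = 1e-8, te_cap = 50) {
  mode <- match.arg(mode)
  check_number(denom_tolerance, "denom_tolerance", min = 0)
  check_number(te_cap, "te_cap", min = 0, strict_min = TRUE)
  if (is.null(genes)) genes <- intersect(de_p$gene_id, de_t$gene_id)
  miss_p <- setdiff(genes, de_p$gene_id)
  miss_t <- setdiff(genes, de_t$gene_id)
  if (length(miss_p) || length(miss_t))
    stopf("gene(s) missing from %s-pool result: %s",
          if (length(miss_p)) "P" else "T",
          paste(utils::head(c(miss_p, miss_t), 5L), collapse = ", "))
  fc_p <- de_p$log2FC[match(genes, de_p$gene_id)]
  fc_t <- de_t$log2FC[match(genes, de_t$gene_id)]
  if (mode == "ratio") {
    excl <- abs(fc_t) < denom_tolerance
    te <- ifelse(excl, NA_real_, fc_p / fc_t)
    te <- pmin(pmax(te, -te_cap), te_cap)
    reason <- ifelse(excl, "zero_denominator", NA_character_)
    call <- ifelse(excl, "excluded", NA_character_)
  } else {
    te <- fc_p - fc_t
    reason <- NA_character_
    call <- NA_character_
    excl <- rep(FALSE, length(te))
  }
  structure(data.frame(gene_id = genes, log2FC_P = fc_p, log2FC_T = fc_t,
                       te = te, z = NA_real_, call = call,
                       exclusion_reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("te_table", "data.frame"),
            te_mode = mode, te_cap = te_cap)
}

#' z-score the Te statistic
#'
#' Standardizes Te over the non-excluded genes of one contrast using the
#' sample standard deviation (n - 1); the resulting z-scores have mean 0 and
#' sample SD 1 by construction.
#'
#' @param te a [compute_te()] result with >= 2 non-excluded genes.
#' @param robust if `TRUE`, center by the median and scale by the MAD
#'   instead (the mean-0/SD-1 invariant then no longer holds).
#' @return `te` with the `z` column filled.
#' @export
zscore_te <- function(te, robust = FALSE) {
  ok <- is.na(te$call) | te$call != "excluded"
  if (sum(ok) < 2L) stopf("need >= 2 non-excluded genes to z-score")
  v <- te$te[ok]
  if (robust) {
    ctr <- stats::median(v); sc <- stats::mad(v)
  } else {
    ctr <- mean(v); sc <- stats::sd(v)
  }
  if (sc == 0) stopf("degenerate Te distribution (all values identical)")
  te$z[ok] <- (v - ctr) / sc
  te
}

#' Call translationally activated and inactivated genes
#'
#' Strict thresholds as conventionally printed: `z > z_threshold` is
#' `activated` (increased translational efficiency), `z < -z_threshold` is
#' `inactivated`, anything else `unchanged`; excluded genes stay `excluded`.
#'
#' @param te a z-scored [compute_te()] result.
#' @param z_threshold positive threshold (default 1.5).
#' @return `te` with the `call` column filled.
#' @export
classify_translational <- function(te, z_threshold = 1.5) {
  check_number(z_threshold, "z_threshold", min = 0, strict_min = TRUE)
  if (all(is.na(te$z))) stopf("z-scores not computed; run zscore_te() first")
  keep_excl <- !is.na(te$call) & te$call == "excluded"
  te$call <- ifelse(keep_excl, "excluded",
                    ifelse(te$z > z_threshold, "activated",
                           ifelse(te$z < -z_threshold, "inactivated",
                                  "unchanged")))
  attr(te, "z_threshold") <- z_threshold
  te
}

#' Four-way transcriptional/translational gene classification
#'
#' Partitions the tested gene universe of one contrast, with translational
#' evidence taking precedence:
#' \enumerate{
#'   \item `translational` - `|z| > z_threshold` (activated or inactivated
#'     Te);
#'   \item `transcriptional` - significant in both pools
#'     (`FDR_T < fdr_threshold` and `FDR_P < fdr_threshold`) with concordant
#'     fold-change signs;
#'   \item `transcriptional_no_translation` - significant in the total pool
#'     only;
#'   \item `non_significant` - everything else.
#' }
#' Genes absent from the Te table (not selected, or excluded) carry no
#' translational evidence and fall through to the FDR rules.
#'
#' @param de_t,de_p [test_contrast()] results on the same gene universe.
#' @param te a z-scored Te table whose genes are a subset of that universe.
#' @param fdr_threshold significance threshold for both pools.
#' @param z_threshold translational threshold (default 1.5).
#' @return a `data.frame`: `gene_id`, `class`, and the evidence columns
#'   `fdr_T`, `fdr_P`, `log2FC_T`, `log2FC_P`, `z`.
#' @export
classify_four_way <- function(de_t, de_p, te, fdr_threshold,
                              z_threshold = 1.5) {
  check_number(fdr_threshold, "fdr_threshold", min = 0, strict_min = TRUE)
  if (!setequal(de_t$gene_id, de_p$gene_id))
    stopf("T and P results cover different gene universes")
  extra <- setdiff(te$gene_id, de_t$gene_id)
  if (length(extra))
    stopf("Te table contains gene(s) outside the universe: %s",
          paste(utils::head(extra, 5L), collapse = ", "))
  genes <- de_t$gene_id
  fdr_t <- de_t$fdr
  i_p <- match(genes, de_p$gene_id)
  fdr_p <- de_p$fdr[i_p]
  fc_t <- de_t$log2FC
  fc_p <- de_p$log2FC[i_p]
  z <- te$z[match(genes, te$gene_id)]
  translational <- !is.na(z) & abs(z) > z_threshold
  sig_t <- fdr_t < fdr_threshold
  sig_p <- fdr_p < fdr_threshold
  cls <- ifelse(translational, "translational",
         ifelse(sig_t & sig_p & sign(fc_t) == sign(fc_p), "transcriptional",
         ifelse(sig_t & !sig_p, "transcriptional_no_translation",
                "non_significant")))
  data.frame(gene_id = genes, class = cls, fdr_T = fdr_t, fdr_P = fdr_p,
             log2FC_T = fc_t, log2FC_P = fc_p, z = z,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact intersection (Venn) counts for 2-4 gene sets
#'
#' @param sets named list of 2-4 character vectors.
#' @return list of class `"venn_counts"`: `regions` (data.frame with a
#'   membership `region` key like `"A&B"`, per-region `count`), `members`
#'   (list of per-region gene vectors) and `union_size`.
#' @examples
#' intersect_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
intersect_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L)
    stopf("need a named list of 2-4 gene sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stopf("sets must have unique non-empty names")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL,
                                                             names(sets)))
  key <- apply(memb, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&")
  }))
  members <- lapply(combos, function(cb) universe[key == cb])
  names(members) <- combos
  regions <- data.frame(region = combos,
                        count = vapply(members, length, integer(1)),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(regions = regions, members = members,
                 union_size = length(universe)),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("venn_counts: union of %d genes\n", x$union_size))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Write Venn counts as a structured text report
#' @param venn an [intersect_sets()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_venn <- function(venn, path) {
  lines <- c(sprintf("union\t%d", venn$union_size),
             vapply(venn$regions$region, function(rg) {
               sprintf("%s\t%d\t%s", rg, length(venn$members[[rg]]),
                       paste(venn$members[[rg]], collapse = ","))
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
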