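# Negative-binomial two-group differential expression: expression filter,
# method-of-moments dispersion estimation with shrinkage, an exact-style
# conditional test per contrast, and Benjamini-Hochberg adjustment.

#' Remove genes below an expression floor
#'
#' Keeps genes with library-size CPM (unit factors) of at least `min_cpm` in
#' at least `min_samples` samples; row order is preserved.
#'
#' @param counts count matrix.
#' @param design matching sample sheet (used for the `min_samples` default).
#' @param min_cpm CPM threshold (0 disables the filter).
#' @param min_samples required number of samples; default is the smallest
#'   (cell line, treatment, pool) group size.
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, design, min_cpm = 1.0,
                                  min_samples = NULL) {
  design <- match_design(counts, design)
  check_number(min_cpm, "min_cpm", min = 0)
  if (is.null(min_samples)) {
    grp <- table(do.call(paste, design[c("cell_line", "treatment", "pool")]))
    min_samples <- min(grp)
  }
  min_samples <- check_count(min_samples, "min_samples", min = 1L)
  if (min_samples > ncol(counts))
    stopf("min_samples (%d) exceeds the number of samples (%d)",
          min_samples, ncol(counts))
  if (min_cpm == 0) return(counts)
  cpm0 <- t(t(counts) / colSums(counts)) * 1e6
  keep <- rowSums(cpm0 >= min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Estimate negative-binomial dispersions by method of moments
#'
#' Counts are brought to a common scale (effective library sizes rescaled to
#' their mean); within each replicate group a per-gene moment estimate
#' `max(0, (s2 - m) / m^2)` of the dispersion phi is computed and pooled
#' across groups by residual degrees of freedom. The common dispersion is the
#' ratio estimator `sum(s2 - m) / sum(m^2)` over all genes and groups (a
#' mean-squared weighted mean of the unfloored per-gene estimates, avoiding
#' the upward bias that per-gene flooring would transfer), floored at 0.
#' Per-gene estimates are shrunk toward the common value with weight
#' `n0 / (n0 + df_g)`, i.e. `n0` prior degrees of freedom.
#'
#' @param counts count matrix.
#' @param design matching sample sheet; groups are
#'   (cell line, treatment, pool).
#' @param factors a [tmm_factors()] result.
#' @param prior_df prior degrees of freedom `n0` for shrinkage (default 10).
#' @return list of class `"dispersion_estimates"`: `common`, `per_gene`
#'   (named, shrunk), `per_gene_mom` (unshrunk), `df` (per-gene residual df)
#'   and `prior_df`.
#' @export
estimate_dispersions <- function(counts, design, factors, prior_df = 10) {
  design <- match_design(counts, design)
  check_number(prior_df, "prior_df", min = 0)
  el <- effective_lib_sizes(counts, factors)
  z <- t(t(counts) / el) * mean(el)
  grp <- do.call(paste, design[c("cell_line", "treatment", "pool")])
  sizes <- table(grp)
  if (!any(sizes >= 2L))
    stopf("no (cell line, treatment, pool) group has >= 2 replicates; provide replication or a fixed dispersion")
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  mom_num <- rep(0, nrow(counts)); df_g <- 0
  for (g in names(sizes)[sizes >= 2L]) {
    zg <- z[, grp == g, drop = FALSE]
    m <- rowMeans(zg)
    s2 <- apply(zg, 1L, stats::var)
    df <- ncol(zg) - 1L
    ok <- m > 0
    phi_raw <- ifelse(ok, (s2 - m) / m^2, 0)
    mom_num <- mom_num + df * pmax(0, phi_raw)
    num <- num + ifelse(ok, s2 - m, 0)
    den <- den + ifelse(ok, m^2, 0)
    df_g <- df_g + df
  }
  per_gene_mom <- mom_num / df_g
  common <- max(0, sum(num) / sum(den))
  w <- prior_df / (prior_df + df_g)
  per_gene <- w * common + (1 - w) * per_gene_mom
  structure(list(common = common,
                 per_gene = stats::setNames(per_gene, rownames(counts)),
                 per_gene_mom = stats::setNames(per_gene_mom,
                                                rownames(counts)),
                 df = df_g, prior_df = prior_df),
            class = "dispersion_estimates")
}

# Two-sided conditional NB exact p-value for one gene.
# Conditional on the total t of the equalized counts, the treatment-group sum
# follows P(a) proportional to choose(a + rA - 1, a) * choose(t - a + rB - 1,
# t - a) with rX = n_X / phi (the per-sample means cancel under H0); at
# phi = 0 this is Binomial(t, nA / (nA + nB)). Two-sided p sums all outcomes
# no more probable than the observed one (1e-12 relative slack on ties).
nb_exact_pvalue <- function(a, t, nA, nB, phi) {
  if (t == 0L) return(1)
  as_ <- 0:t
  if (phi < 1e-12) {
    logw <- stats::dbinom(as_, t, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi; rB <- nB / phi
    # lgamma(a + r) - lgamma(r) as a running sum of log(r + i): stable for
    # arbitrarily large r (small phi), where lgamma differences cancel badly
    la <- c(0, cumsum(log(rA + 0:(t - 1))))
    lb <- c(0, cumsum(log(rB + 0:(t - 1))))
    logw <- la[as_ + 1L] + lb[t - as_ + 1L] -
      lgamma(as_ + 1) - lgamma(t - as_ + 1)
  }
  logw <- logw - max(logw)
  w <- exp(logw)
  # ties included on the log scale; the 1e-9 slack absorbs the rounding
  # noise of the large cumulative log terms while staying far below the
  # separation (~1/t) between genuinely distinct outcome probabilities
  min(1, sum(w[logw <= logw[a + 1L] + 1e-9]) / sum(w))
}

#' Test one treatment-vs-control contrast within a pool and cell line
#'
#' Samples of the requested (cell line, pool) with the contrasted treatment
#' or the control are selected; their counts are equalized to the mean
#' effective library size by linear rescaling rounded half-to-even, and each
#' gene is tested with a conditional NB exact-style test (see
#' [nb_exact_pvalue()]) at its shrunk dispersion. The log2 fold change is
#' `log2((mean_trt + prior) / (mean_ctl + prior))` on the equalized scale.
#'
#' @param counts count matrix.
#' @param design matching sample sheet.
#' @param factors a [tmm_factors()] result.
#' @param dispersions an [estimate_dispersions()] result covering the same
#'   genes (or a single fixed dispersion value).
#' @param cell_line,pool,treatment contrast coordinates; `pool` is `"T"` or
#'   `"P"`.
#' @param control control treatment label (default `"N"`, normoxia).
#' @param prior_count prior added to each group mean in the fold change
#'   (default 0.5; keeps zeros finite).
#' @return a `data.frame` of class `"de_result"`: `gene_id`, `log2FC`,
#'   `pvalue`, `fdr` (Benjamini-Hochberg over the contrast's genes),
#'   `mean_abundance`, plus constant `cell_line`, `pool`, `treatment`,
#'   `control` columns.
#' @export
test_contrast <- function(counts, design, factors, dispersions,
                          cell_line, pool, treatment, control = "N",
                          prior_count = 0.5) {
  design <- match_design(counts, design)
  check_number(prior_count, "prior_count", min = 0)
  if (is.numeric(dispersions) && length(dispersions) == 1L) {
    phi <- stats::setNames(rep(dispersions, nrow(counts)), rownames(counts))
  } else {
    if (!inherits(dispersions, "dispersion_estimates"))
      stopf("'dispersions' must come from estimate_dispersions() or be a single value")
    phi <- dispersions$per_gene
    if (!identical(names(phi), rownames(counts)))
      stopf("dispersion estimates were computed on a different gene universe")
  }
  sel_t <- design$cell_line == cell_line & design$pool == pool &
    design$treatment == treatment
  sel_c <- design$cell_line == cell_line & design$pool == pool &
    design$treatment == control
  if (!any(sel_t)) stopf("no samples for (%s, %s, %s)", cell_line, pool,
                         treatment)
  if (!any(sel_c)) stopf("no control samples for (%s, %s, %s)", cell_line,
                         pool, control)
  idx <- c(which(sel_t), which(sel_c))
  el <- effective_lib_sizes(counts, factors)[idx]
  pseudo <- round(t(t(counts[, idx, drop = FALSE]) * (mean(el) / el)))
  nA <- sum(sel_t); nB <- sum(sel_c)
  sumA <- rowSums(pseudo[, seq_len(nA), drop = FALSE])
  tot <- sumA + rowSums(pseudo[, nA + seq_len(nB), drop = FALSE])
  pv <- vapply(seq_len(nrow(pseudo)), function(g) {
    nb_exact_pvalue(sumA[g], tot[g], nA, nB, phi[g])
  }, numeric(1))
  mA <- sumA / nA
  mB <- (tot - sumA) / nB
  data.frame(gene_id = rownames(counts),
             log2FC = log2((mA + prior_count) / (mB + prior_count)),
             pvalue = pv,
             fdr = bh_adjust(pv),
             mean_abundance = rowMeans(pseudo),
             cell_line = cell_line, pool = pool, treatment = treatment,
             control = control,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_(i) = min_(j >= i) m * p_(j) / j`, capped at 1 and mapped back
#' to the input order; controls the expected false discovery proportion.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values in input order.
#' @examples
#' bh_adjust(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.02 0.04 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stopf("p-values must be in [0, 1] with no missing values")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  adj <- pmin(1, cummin(m * pvalues[o] / (m:1)))
  adj[order(o)]
}
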