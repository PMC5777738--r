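#' TMM (trimmed mean of M-values) scaling factors
#'
#' Between-sample normalization robust to composition bias. For each sample s
#' against the reference r, genes expressed in both are mapped to
#' `M_g = log2((y_gs / L_s) / (y_gr / L_r))` and
#' `A_g = 0.5 * log2((y_gs / L_s) * (y_gr / L_r))`; the top and bottom
#' `trim_m` of genes by M and `trim_a` by A are dropped, and the factor is
#' `2 ^ weighted.mean(M)` with inverse asymptotic-variance (delta-method
#' binomial) weights `w_g = 1 / ((L_s - y_gs) / (L_s y_gs) +
#' (L_r - y_gr) / (L_r y_gr))`. Factors are rescaled to geometric mean 1 so
#' they are comparable across runs. Effective library sizes are
#' `factor * library size`.
#'
#' @param counts gene-by-sample count matrix (>= 2 samples, positive library
#'   sizes).
#' @param trim_m,trim_a two-sided trim fractions on M and A (defaults 0.30
#'   and 0.05, the published TMM defaults).
#' @param reference a sample id, or `NULL` to auto-select the sample whose
#'   75th percentile of count proportions is closest to the mean 75th
#'   percentile across samples.
#' @return list of class `"tmm_factors"`: `factors` (named, geometric mean
#'   1), `lib_sizes` (column sums) and `reference`.
#' @examples
#' m <- matrix(rpois(60, 50), 10, 6,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' tmm_factors(m)$factors
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        reference = NULL) {
  validate_counts(counts)
  if (ncol(counts) < 2L) stopf("TMM needs >= 2 samples")
  check_number(trim_m, "trim_m", min = 0)
  check_number(trim_a, "trim_a", min = 0)
  if (trim_m >= 0.5 || trim_a >= 0.5) stopf("trim fractions must be < 0.5")
  lib <- colSums(counts)
  if (any(lib <= 0))
    stopf("sample '%s' has zero library size", colnames(counts)[lib <= 0][1L])
  if (is.null(reference)) {
    q75 <- apply(counts, 2L, function(y) stats::quantile(y / sum(y), 0.75))
    reference <- colnames(counts)[which.min(abs(q75 - mean(q75)))]
  } else if (!reference %in% colnames(counts)) {
    stopf("reference sample '%s' not found", reference)
  }
  yr <- counts[, reference]
  Lr <- lib[reference]
  f <- vapply(colnames(counts), function(s) {
    .tmm_pair(counts[, s], yr, lib[s], Lr, trim_m, trim_a, s, reference)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = f, lib_sizes = lib, reference = reference),
            class = "tmm_factors")
}

.tmm_pair <- function(ys, yr, Ls, Lr, trim_m, trim_a, s, r) {
  keep <- ys > 0 & yr > 0
  if (!any(keep))
    stopf("sample '%s' shares no positively expressed gene with reference '%s'; filter low-expression genes first",
          s, r)
  ys <- ys[keep]; yr <- yr[keep]
  ps <- ys / Ls; pr <- yr / Lr
  M <- log2(ps / pr)
  A <- 0.5 * log2(ps * pr)
  w <- 1 / ((Ls - ys) / (Ls * ys) + (Lr - yr) / (Lr * yr))
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel)) return(1)
  2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

#' Counts per million, optionally log2 with a prior count
#'
#' Linear scale with `prior = 0` gives plain
#' `y_gs / (f_s * L_s) * 1e6` on effective library sizes. With a positive
#' prior (always used on the log scale) the prior is scaled per sample as
#' `prior * EL_s / mean(EL)` and applied symmetrically,
#' `CPM = (y + prior_s) / (EL_s + 2 * prior_s) * 1e6`, keeping zero counts
#' finite inside `log2`.
#'
#' @param counts count matrix.
#' @param factors a [tmm_factors()] result for the same samples, or `NULL`
#'   for unit factors.
#' @param prior non-negative prior count (default 0.5).
#' @param log_scale return log2-CPM if `TRUE`.
#' @return a numeric matrix with attributes `scale` (`"cpm"` or
#'   `"log2cpm"`), `prior` and `factors`.
#' @export
cpm <- function(counts, factors = NULL, prior = 0.5, log_scale = FALSE) {
  validate_counts(counts)
  check_number(prior, "prior", min = 0)
  if (is.null(factors))
    factors <- structure(list(factors = stats::setNames(rep(1, ncol(counts)),
                                                        colnames(counts)),
                              lib_sizes = colSums(counts), reference = NA),
                         class = "tmm_factors")
  el <- effective_lib_sizes(counts, factors)
  if (!log_scale && prior == 0) {
    out <- t(t(counts) / el) * 1e6
  } else {
    pr <- prior * el / mean(el)
    out <- t((t(counts) + pr) / (el + 2 * pr)) * 1e6
    if (log_scale) out <- log2(out)
  }
  structure(out, scale = if (log_scale) "log2cpm" else "cpm", prior = prior,
            factors = factors$factors)
}

#' Write an expression (CPM) matrix with a provenance header
#'
#' Adds `#` comment lines recording scale, prior and per-sample factors
#' before the tab-separated table.
#'
#' @param expr a [cpm()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# scale=%s prior=%g", attr(expr, "scale"),
                   attr(expr, "prior")),
           sprintf("# factors=%s",
                   paste(sprintf("%s:%.6f", names(attr(expr, "factors")),
                                 attr(expr, "factors")), collapse = ",")))
  writeLines(hdr, con, useBytes = TRUE)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
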