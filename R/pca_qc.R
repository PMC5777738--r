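#' Principal component analysis of samples
#'
#' SVD of the sample-by-gene matrix (samples as observations), after
#' centering each gene and optionally scaling it to unit variance.
#' Zero-variance genes are dropped with a note when scaling (they are
#' undefined there) and harmless otherwise. A deterministic sign convention
#' is applied: each loading vector is oriented so its largest-magnitude
#' entry is positive, making coordinates reproducible across platforms.
#'
#' Intended input is log2-CPM (`cpm(..., log_scale = TRUE)`): on the log
#' scale a unit distance is a fold change, which is what sample-level
#' clustering should reflect.
#'
#' @param expr gene-by-sample numeric matrix (log scale).
#' @param center,scale. centering/scaling flags (defaults on/off).
#' @param k number of components (default: full rank).
#' @param samples optional character vector restricting to a sample subset.
#' @return list of class `"pca_result"`: `coordinates` (samples x k),
#'   `loadings` (genes x k), `variance_fraction` (length k, fractions of the
#'   total variance so they sum to 1 at full rank), `center`, `scale`.
#' @export
pca_samples <- function(expr, center = TRUE, scale. = FALSE, k = NULL,
                        samples = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stopf("'expr' must be a numeric matrix (genes x samples)")
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(expr))
    if (length(miss)) stopf("unknown sample(s): %s",
                            paste(miss, collapse = ", "))
    expr <- expr[, samples, drop = FALSE]
  }
  x <- t(expr)  # samples x genes
  if (scale.) {
    v <- apply(x, 2L, stats::var)
    if (all(v == 0)) stopf("all genes have zero variance; cannot scale")
    if (any(v == 0)) {
      message(sprintf("pca_samples: dropping %d zero-variance gene(s) before scaling",
                      sum(v == 0)))
      x <- x[, v > 0, drop = FALSE]
    }
  }
  x <- scale(x, center = center, scale = scale.)
  full <- min(nrow(x) - if (center) 1L else 0L, ncol(x))
  if (full < 1L) stopf("need at least two distinct samples")
  if (is.null(k)) k <- full
  k <- check_count(k, "k", min = 1L)
  if (k > full) stopf("k (%d) exceeds the available rank (%d)", k, full)
  sv <- svd(x)
  d2 <- sv$d^2
  vf <- d2[seq_len(k)] / sum(d2)
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  dimnames(coords) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(coordinates = coords, loadings = load,
                 variance_fraction = vf, center = center, scale = scale.),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

# Mean silhouette width of a 2-group labelling on 1-D coordinates
# (euclidean); used to quantify group separation on a single component.
silhouette_1d <- function(coord, group) {
  group <- as.character(group)
  stopifnot(length(unique(group)) == 2L)
  s <- vapply(seq_along(coord), function(i) {
    own <- group == group[i]
    a <- mean(abs(coord[i] - coord[own & seq_along(coord) != i]))
    b <- mean(abs(coord[i] - coord[!own]))
    if (is.nan(a)) a <- 0
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
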