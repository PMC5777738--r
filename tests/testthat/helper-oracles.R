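# Independent brute-force oracles and shared fixtures. The oracles favour
# explicit enumeration over vectorized shortcuts so they stay independent of
# the implementation paths they check.

# Trimmed weighted mean of M-values for one sample against a reference,
# enumerating the trimmed gene set gene by gene.
oracle_tmm_pair <- function(ys, yr, Ls, Lr, trim_m, trim_a) {
  M <- A <- w <- numeric(0)
  for (g in seq_along(ys)) {
    if (ys[g] > 0 && yr[g] > 0) {
      ps <- ys[g] / Ls
      pr <- yr[g] / Lr
      M <- c(M, log2(ps / pr))
      A <- c(A, 0.5 * log2(ps * pr))
      w <- c(w, 1 / ((Ls - ys[g]) / (Ls * ys[g]) +
                       (Lr - yr[g]) / (Lr * yr[g])))
    }
  }
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  num <- den <- 0
  any_kept <- FALSE
  for (g in seq_len(n)) {
    if (rM[g] >= loM && rM[g] <= hiM && rA[g] >= loA && rA[g] <= hiA) {
      num <- num + w[g] * M[g]
      den <- den + w[g]
      any_kept <- TRUE
    }
  }
  if (!any_kept) return(1)
  2^(num / den)
}

oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  q75 <- sapply(seq_len(ncol(counts)),
                function(s) quantile(counts[, s] / lib[s], 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  f <- sapply(seq_len(ncol(counts)), function(s) {
    oracle_tmm_pair(counts[, s], counts[, ref], lib[s], lib[ref],
                    trim_m, trim_a)
  })
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# BH step-up by direct evaluation of min_{j >= i} m p_(j) / j per rank.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, m * p[o[i:m]] / (i:m))
  }
  adj
}

# Hypergeometric upper tail by summing binomial-coefficient ratios.
oracle_hyper_tail <- function(k, N, K, n) {
  tot <- 0
  for (kk in k:min(K, n)) {
    tot <- tot + choose(K, kk) * choose(N - K, n - kk)
  }
  tot / choose(N, n)
}

# Conditional binomial two-sided p by full enumeration of outcomes.
oracle_cond_binom <- function(a, t, nA, nB) {
  if (t == 0) return(1)
  w <- dbinom(0:t, t, nA / (nA + nB))
  sum(w[w <= w[a + 1] * (1 + 1e-12)])
}

# Rank-based AUROC of a score for a binary label.
auroc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small single-cell-line N-vs-H experiment used across tests.
small_sim <- function(n_genes = 300, replicates = 3, dispersion = 0.1,
                      proportions = c(null = 1), effect = 1,
                      lib = 2e5, seed = 1, cell_lines = "A",
                      treatments = c("N", "H")) {
  simulate_experiment(sim_config(
    n_genes = n_genes, cell_lines = cell_lines, treatments = treatments,
    replicates = replicates, class_proportions = proportions,
    effect_size_log2 = effect, dispersion = dispersion,
    library_size_mean = lib, seed = seed))
}

# A toy de_result pair with prescribed fold changes, for Te-stage tests.
fake_de_pair <- function(fc_p, fc_t, fdr_p = NULL, fdr_t = NULL) {
  n <- length(fc_p)
  ids <- sprintf("g%03d", seq_len(n))
  if (is.null(fdr_p)) fdr_p <- rep(0.01, n)
  if (is.null(fdr_t)) fdr_t <- rep(0.01, n)
  list(p = data.frame(gene_id = ids, log2FC = fc_p, pvalue = fdr_p,
                      fdr = fdr_p, mean_abundance = 100, cell_line = "A",
                      pool = "P", treatment = "H", control = "N",
                      stringsAsFactors = FALSE),
       t = data.frame(gene_id = ids, log2FC = fc_t, pvalue = fdr_t,
                      fdr = fdr_t, mean_abundance = 100, cell_line = "A",
                      pool = "T", treatment = "H", control = "N",
                      stringsAsFactors = FALSE))
}

# Write a small GMT file and return its path.
write_test_gmt <- function(dir, sets = NULL) {
  if (is.null(sets))
    sets <- list(hypoxia_response = sprintf("g%04d", 1:20),
                 glycolysis = sprintf("g%04d", 15:40),
                 unrelated = sprintf("x%03d", 1:10))
  path <- file.path(dir, "sets.gmt")
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1)), path)
  path
}
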