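test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("BH matches the brute-force oracle and stays monotone", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))
    adj <- bh_adjust(p)
    expect_identical(adj, oracle_bh(p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= 0))
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("low-expression filtering matches direct enumeration", {
  sim <- small_sim(n_genes = 30, replicates = 2, lib = 1e4, seed = 2)
  counts <- sim$counts
  counts[1, ] <- 0
  cpm0 <- t(t(counts) / colSums(counts)) * 1e6
  for (min_cpm in c(0.5, 1, 5, 50)) {
    kept <- filter_low_expression(counts, sim$design, min_cpm = min_cpm,
                                  min_samples = 3)
    manual <- rownames(counts)[sapply(seq_len(nrow(counts)), function(g)
      sum(cpm0[g, ] >= min_cpm) >= 3)]
    expect_identical(rownames(kept), manual)
  }
  expect_false("g0001" %in%
                 rownames(filter_low_expression(counts, sim$design,
                                                min_cpm = 0.01)))
  expect_identical(filter_low_expression(counts, sim$design, min_cpm = 0),
                   counts)
  expect_error(filter_low_expression(counts, sim$design, min_samples = 99),
               "exceeds")
})

test_that("dispersion estimation recovers planted values", {
  sim <- small_sim(n_genes = 150, replicates = 2, seed = 6)
  f <- tmm_factors(sim$counts)
  # constant counts within every group -> zero within-group variance
  const <- matrix(rep(c(5L, 9L, 40L), each = ncol(sim$counts)), 3,
                  ncol(sim$counts), byrow = TRUE,
                  dimnames = list(paste0("g", 1:3), colnames(sim$counts)))
  fc <- tmm_factors(const)
  dz <- estimate_dispersions(const, sim$design, fc)
  expect_equal(unname(dz$per_gene_mom), rep(0, 3))

  # Poisson counts: per-gene estimates concentrate near zero
  simp <- simulate_experiment(sim_config(
    n_genes = 2000, cell_lines = "A", treatments = c("N", "H"),
    replicates = 4, class_proportions = c(null = 1), dispersion = 0,
    library_size_mean = 1e6, seed = 41))
  fp <- tmm_factors(simp$counts)
  dp <- estimate_dispersions(simp$counts, simp$design, fp)
  expect_lte(median(dp$per_gene), 0.02)

  # NB counts at phi = 0.1 with ample replication
  simnb <- simulate_experiment(sim_config(
    n_genes = 2000, cell_lines = "A", treatments = c("N", "H"),
    replicates = 8, class_proportions = c(null = 1), dispersion = 0.1,
    baseline_log_mean = 5, library_size_mean = 2e6, seed = 42))
  fnb <- tmm_factors(simnb$counts)
  dnb <- estimate_dispersions(simnb$counts, simnb$design, fnb)
  expect_gte(dnb$common, 0.07)
  expect_lte(dnb$common, 0.13)
})

test_that("dispersion estimation demands replication", {
  m <- matrix(rpois(8, 50), 2, 4,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  d <- data.frame(sample_id = paste0("s", 1:4), cell_line = "A",
                  treatment = c("N", "H", "PP", "HPP"), pool = "T",
                  replicate = 1L)
  expect_error(estimate_dispersions(m, d, tmm_factors(m)),
               "replicates|replication")
})

test_that("exact test equals conditional binomial at zero dispersion", {
  for (tot in c(0, 1, 7, 40)) {
    for (a in 0:tot) {
      expect_equal(polyTE:::nb_exact_pvalue(a, tot, 2, 2, 0),
                   oracle_cond_binom(a, tot, 2, 2), tolerance = 1e-12)
      # NB path converges to the Poisson limit as phi -> 0
      expect_equal(polyTE:::nb_exact_pvalue(a, tot, 3, 2, 1e-9),
                   oracle_cond_binom(a, tot, 3, 2), tolerance = 1e-6)
    }
  }
})

test_that("null contrasts give approximately uniform p-values", {
  sim <- simulate_experiment(sim_config(
    n_genes = 2000, cell_lines = "A", treatments = c("N", "H"),
    replicates = 3, class_proportions = c(null = 1), dispersion = 0.1,
    library_size_mean = 1e6, seed = 51))
  f <- tmm_factors(sim$counts)
  d <- estimate_dispersions(sim$counts, sim$design, f)
  de <- test_contrast(sim$counts, sim$design, f, d, "A", "P", "H")
  frac <- mean(de$pvalue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("planted fold changes are recovered", {
  # 400 genes with a 4-fold increase at control mean 500 (phi = 0.05,
  # 4 vs 4 samples) on a large null background so TMM can anchor the scale
  set.seed(61)
  n_bg <- 4000; n_fg <- 400
  bg <- matrix(rnbinom(n_bg * 8, mu = 1000, size = 1 / 0.05), n_bg, 8)
  fg <- cbind(matrix(rnbinom(n_fg * 4, mu = 2000, size = 1 / 0.05), n_fg, 4),
              matrix(rnbinom(n_fg * 4, mu = 500, size = 1 / 0.05), n_fg, 4))
  counts <- rbind(bg, fg)
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_bg + n_fg)),
                           paste0("s", 1:8))
  design <- data.frame(sample_id = paste0("s", 1:8), cell_line = "A",
                       treatment = rep(c("H", "N"), each = 4), pool = "P",
                       replicate = rep(1:4, 2))
  f <- tmm_factors(counts)
  de <- test_contrast(counts, design, f, 0.05, "A", "P", "H")
  fgr <- de[(n_bg + 1):(n_bg + n_fg), ]
  expect_lt(abs(median(fgr$log2FC) - 2), 0.15)
  expect_gt(mean(fgr$fdr < 0.05), 0.9)
  expect_lt(abs(median(de$log2FC[1:n_bg])), 0.1)
})

test_that("log2FC is antisymmetric and replicate labels are irrelevant", {
  sim <- small_sim(n_genes = 60, replicates = 3, lib = 5e4, seed = 71,
                   proportions = c(null = 0.8, transcriptional = 0.2))
  f <- tmm_factors(sim$counts)
  d <- estimate_dispersions(sim$counts, sim$design, f)
  fwd <- test_contrast(sim$counts, sim$design, f, d, "A", "T", "H",
                       control = "N")
  rev <- test_contrast(sim$counts, sim$design, f, d, "A", "T", "N",
                       control = "H")
  expect_equal(fwd$log2FC, -rev$log2FC)
  expect_equal(fwd$pvalue, rev$pvalue)

  shuffled <- sim$design
  hp <- shuffled$treatment == "H" & shuffled$pool == "T"
  shuffled$replicate[hp] <- rev(shuffled$replicate[hp])
  again <- test_contrast(sim$counts, shuffled, f, d, "A", "T", "H")
  expect_equal(again$pvalue, fwd$pvalue)
})
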