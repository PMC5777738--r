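test_that("polysome-significant selection uses a strict FDR cut", {
  de <- fake_de_pair(fc_p = c(1, 1, 1), fc_t = c(0, 0, 0),
                     fdr_p = c(0.04, 0.07, 0.05))$p
  expect_equal(select_polysome_significant(de, 0.05), "g001")
  expect_setequal(select_polysome_significant(de, 0.10),
                  c("g001", "g002", "g003"))
  empty <- de[0, ]
  expect_length(select_polysome_significant(empty, 0.05), 0)
  expect_error(select_polysome_significant(de, 0), "fdr_threshold")
  expect_error(select_polysome_significant(de, 1.5), "\\(0, 1\\]")
})

test_that("Te follows its defining arithmetic in both modes", {
  de <- fake_de_pair(fc_p = c(3, 3, 2), fc_t = c(1.5, 1.5, 0))
  te_r <- compute_te(de$p, de$t, c("g001", "g003"))
  expect_equal(te_r$te[te_r$gene_id == "g001"], 2)
  excl <- te_r[te_r$gene_id == "g003", ]
  expect_equal(excl$call, "excluded")
  expect_equal(excl$exclusion_reason, "zero_denominator")
  te_d <- compute_te(de$p, de$t, mode = "difference")
  expect_equal(te_d$te, c(1.5, 1.5, 2))
  expect_true(all(is.na(te_d$exclusion_reason)))
  expect_error(compute_te(de$p, de$t, c("g001", "nope")), "nope")
})

test_that("near-zero denominators are winsorized at the cap", {
  de <- fake_de_pair(fc_p = c(5, 1, -1), fc_t = c(1e-4, 1, 1))
  te <- compute_te(de$p, de$t)
  expect_equal(te$te[1], 50)  # 5e4 capped
  te2 <- compute_te(de$p, de$t, te_cap = 10)
  expect_equal(te2$te[1], 10)
})

test_that("z-scores standardize Te with the sample SD", {
  de <- fake_de_pair(fc_p = c(2, 4, 6), fc_t = rep(0, 3))
  te <- zscore_te(compute_te(de$p, de$t, mode = "difference"))
  expect_equal(te$z, c(-1, 0, 1))
  # affine invariance
  de2 <- fake_de_pair(fc_p = 3 * c(2, 4, 6) + 7, fc_t = rep(0, 3))
  te2 <- zscore_te(compute_te(de2$p, de2$t, mode = "difference"))
  expect_equal(te2$z, te$z)
  # z moments are pinned by construction
  set.seed(81)
  den <- fake_de_pair(fc_p = rnorm(500), fc_t = rep(0, 500))
  ten <- zscore_te(compute_te(den$p, den$t, mode = "difference"))
  expect_lt(abs(mean(ten$z)), 1e-9)
  expect_lt(abs(sd(ten$z) - 1), 1e-9)

  flat <- fake_de_pair(fc_p = rep(2, 4), fc_t = rep(0, 4))
  expect_error(zscore_te(compute_te(flat$p, flat$t, mode = "difference")),
               "degenerate Te distribution")
  one <- fake_de_pair(fc_p = 1, fc_t = 0)
  expect_error(zscore_te(compute_te(one$p, one$t, mode = "difference")),
               ">= 2")
})

test_that("a standard-normal Te tail yields the expected activation rate", {
  set.seed(82)
  de <- fake_de_pair(fc_p = rnorm(1000), fc_t = rep(0, 1000))
  te <- classify_translational(
    zscore_te(compute_te(de$p, de$t, mode = "difference")))
  frac <- mean(te$call == "activated")
  expect_gte(frac, 0.04)  # normal tail beyond 1.5 is ~0.0668
  expect_lte(frac, 0.10)
})

test_that("translational calls use strict thresholds at 1.5", {
  de <- fake_de_pair(fc_p = c(0, 0, 0), fc_t = c(0, 0, 0))
  te <- compute_te(de$p, de$t, mode = "difference")
  te$z <- c(1.6, -1.6, 1.5)
  te <- classify_translational(te)
  expect_equal(te$call, c("activated", "inactivated", "unchanged"))
  expect_error(classify_translational(te, z_threshold = 0), "z_threshold")
})

test_that("the four-way classification applies its precedence order", {
  de <- fake_de_pair(fc_p = c(2, 0.1, 0.2, -1),
                     fc_t = c(2, 0.1, 0.3, 1),
                     fdr_p = c(0.01, 0.9, 0.2, 0.01),
                     fdr_t = c(0.01, 0.8, 0.01, 0.01))
  te <- compute_te(de$p, de$t, mode = "difference")
  te$z <- c(0.2, 0.1, 2.3, 0.4)
  cls <- classify_four_way(de$t, de$p, te, fdr_threshold = 0.05)
  expect_equal(cls$class[cls$gene_id == "g001"], "transcriptional")
  expect_equal(cls$class[cls$gene_id == "g002"], "non_significant")
  expect_equal(cls$class[cls$gene_id == "g003"], "translational")
  # significant in both pools but discordant signs: not "transcriptional"
  expect_equal(cls$class[cls$gene_id == "g004"], "non_significant")

  # T-only significance without translational evidence
  de2 <- fake_de_pair(fc_p = 1, fc_t = 1, fdr_p = 0.5, fdr_t = 0.01)
  te2 <- compute_te(de2$p, de2$t, mode = "difference")
  te2$z <- 0.1
  cls2 <- classify_four_way(de2$t, de2$p, te2, 0.05)
  expect_equal(cls2$class, "transcriptional_no_translation")
})

test_that("classes partition the gene universe on random inputs", {
  set.seed(83)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    de <- fake_de_pair(fc_p = rnorm(n), fc_t = rnorm(n),
                       fdr_p = runif(n), fdr_t = runif(n))
    te_genes <- sample(de$p$gene_id, sample(0:n, 1))
    cls <- if (length(te_genes) >= 2) {
      te <- zscore_te(compute_te(de$p, de$t, te_genes, mode = "difference"))
      classify_four_way(de$t, de$p, te, 0.1)
    } else {
      te <- compute_te(de$p, de$t, de$p$gene_id, mode = "difference")
      classify_four_way(de$t, de$p, te, 0.1)
    }
    expect_setequal(cls$gene_id, de$p$gene_id)
    expect_equal(nrow(cls), n)
    expect_true(all(cls$class %in% c("translational", "transcriptional",
                                     "transcriptional_no_translation",
                                     "non_significant")))
  }
})

test_that("four-way classification rejects mismatched universes", {
  de <- fake_de_pair(fc_p = c(1, 2), fc_t = c(1, 2))
  te <- compute_te(de$p, de$t, mode = "difference")
  expect_error(classify_four_way(de$t[1, ], de$p, te, 0.05),
               "different gene universes")
  te_bad <- te; te_bad$gene_id[1] <- "alien"
  expect_error(classify_four_way(de$t, de$p, te_bad, 0.05), "alien")
})

test_that("set intersections enumerate every region exactly", {
  v <- intersect_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(v$union_size, 4)
  r <- setNames(v$regions$count, v$regions$region)
  expect_equal(unname(r[c("A", "B", "A&B")]), c(1, 1, 2))
  expect_setequal(v$members[["A&B"]], c("b", "c"))
  expect_equal(sum(v$regions$count), v$union_size)

  dis <- intersect_sets(list(A = c("a"), B = c("b")))
  expect_equal(dis$regions$count[dis$regions$region == "A&B"], 0)
  same <- intersect_sets(list(A = c("x", "y"), B = c("x", "y")))
  r2 <- setNames(same$regions$count, same$regions$region)
  expect_equal(unname(r2[c("A", "B", "A&B")]), c(0, 0, 2))

  v3 <- intersect_sets(list(A = letters[1:4], B = letters[3:6],
                            C = letters[5:8]))
  expect_equal(sum(v3$regions$count), v3$union_size)
  expect_error(intersect_sets(list(A = "a")), "2-4")
  expect_error(intersect_sets(list(c("a"), c("b"))), "names")
})

test_that("venn reports round-trip the region structure", {
  v <- intersect_sets(list(A = c("a", "b"), B = c("b", "c")))
  p <- tempfile()
  write_venn(v, p)
  lines <- readLines(p)
  expect_equal(lines[1], "union\t3")
  expect_true(any(grepl("^A&B\t1\tb$", lines)))
})
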