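make_counts <- function(mat, cond = rep(c("sibling", "null"),
                                        each = ncol(mat) / 2)) {
  dimnames(mat) <- list(sprintf("g%02d", seq_len(nrow(mat))),
                        sprintf("s%d", seq_len(ncol(mat))))
  count_matrix(mat, cond)
}

test_that("detection fractions are per-gene cluster means", {
  det <- Matrix::Matrix(matrix(c(1, 0, 1, 1,
                                 0, 0, 0, 1), nrow = 2, byrow = TRUE,
                               dimnames = list(c("g1", "g2"), NULL)),
                        sparse = TRUE)
  colnames(det) <- paste0("c", 1:4)
  atlas <- atlas_detection(det, c("projection", "projection", "other",
                                  "other"))
  frac <- detection_fraction(atlas, "projection")
  expect_equal(unname(frac), c(0.5, 0))    # 1 of 2 cells; 0 of 2 cells
  expect_error(detection_fraction(atlas, "missing"), "empty")
})

test_that("NB Wald test handles degenerate genes and input validation", {
  # stable genes dominate, so size factors are ~1 and per-gene behavior is
  # directly interpretable
  m <- matrix(rep(c(5L, 20L, 80L, 150L, 40L, 10L, 60L, 25L, 90L, 35L),
                  times = 6), nrow = 10)
  m <- rbind(m, 0L,                              # all-zero gene
             c(2L, 3L, 4L, 30L, 40L, 50L))       # ~10x up in null
  cm <- make_counts(m)
  de <- nb_wald_test(cm)
  expect_equal(de$log2_fold_change[1], 0)        # identical counts: no change
  expect_equal(de$p_value[1], 1, tolerance = 1e-9)
  expect_true(de$all_zero[11])
  expect_true(is.na(de$p_value[11]))
  expect_gt(de$log2_fold_change[12], 2)          # null/sibling contrast

  expect_error(nb_wald_test(make_counts(m, rep("a", 6))), "two condition")
  one <- make_counts(m[, 1:3], c("a", "a", "b"))
  expect_error(nb_wald_test(one), "at least 2 samples")
  expect_error(count_matrix(matrix(-1, 1, 2,
                                   dimnames = list("g", c("a", "b"))),
                            c("a", "b")), "negative")
})

test_that("size factors and fold-change direction agree with DESeq2", {
  sim <- simulate_counts_and_atlas(
    sim_config(seed = 71, n_genes = 300, planted_gene_fraction = 0.1,
               planted_lfc = 3, atlas_n_cells = 10))
  cm <- sim$counts
  sf_ours <- attr(nb_wald_test(cm), "size_factors")
  sf_deseq <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  expect_equal(unname(sf_ours), unname(sf_deseq), tolerance = 1e-6)

  de <- nb_wald_test(cm)
  truth <- sim$ground_truth$true_lfc
  planted <- truth != 0
  expect_gt(cor(sign(de$log2_fold_change[planted]), sign(truth[planted])),
            0.99)
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(bh_adjust(0.05), 0.05)                   # m = 1 identity
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(81)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                          # BH never shrinks p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the reference filter subsets by detection and re-adjusts p-values", {
  sim <- simulate_counts_and_atlas(
    sim_config(seed = 72, n_genes = 150, atlas_n_cells = 200))
  det <- detection_fraction(sim$atlas)
  cand <- de_candidates(nb_wald_test(sim$counts), det)

  expect_equal(nrow(apply_reference_filter(cand, 0)), nrow(cand))
  filt <- apply_reference_filter(cand, 30)
  expect_true(all(filt$detection_fraction >= 0.30))
  # raw p-values are universe-independent; only the adjustment changes
  expect_equal(filt$p_value,
               cand$p_value[match(filt$gene_id, cand$gene_id)])
  expect_equal(filt$p_adjusted, bh_adjust(filt$p_value))
  expect_error(apply_reference_filter(cand, 150), "\\[0, 100\\]")
})

test_that("bundled candidate table reproduces the published filter counts", {
  cand <- example_candidate_table()
  expect_equal(nrow(cand), 14L)
  # no candidate reaches 10% reference detection: zero genes survive
  surv10 <- apply_reference_filter(cand, 10, readjust = FALSE)
  expect_equal(nrow(surv10), 0L)
  expect_equal(sum(surv10$passes_significance), 0L)
  # at 0% every printed candidate passes the significance criteria
  surv0 <- apply_reference_filter(cand, 0, readjust = FALSE)
  expect_equal(sum(surv0$passes_significance), 14L)
})

test_that("the in-situ candidate set splits on the stated significance criteria", {
  tab <- example_insitu_candidates()
  pass <- tab$p_adjusted < 0.05 & abs(tab$log2_fold_change) > 2
  expect_equal(sum(pass), 6L)
  expect_setequal(tab$gene[!pass], c("mapk6", "evx2"))
})

test_that("threshold sweep universes shrink monotonically and track detection", {
  sim <- simulate_counts_and_atlas(
    sim_config(seed = 73, n_genes = 200, atlas_n_cells = 100))
  sw <- threshold_sweep(sim$counts, sim$atlas)
  expect_equal(sw$threshold_pct, c(0, 1, 3, 5, 10, 30, 50))
  expect_true(all(diff(sw$universe_size) <= 0))

  # all-detected atlas: every universe identical
  det <- Matrix::Matrix(1, nrow = 200, ncol = 20, sparse = TRUE,
                        dimnames = list(rownames(sim$counts$counts),
                                        paste0("c", 1:20)))
  atlas1 <- atlas_detection(det, rep("projection", 20))
  sw1 <- threshold_sweep(sim$counts, atlas1)
  expect_true(all(sw1$universe_size == 200))
  expect_true(all(sw1$deg_count == sw1$deg_count[1]))

  # planted effects confined to high-detection genes: DEG count is stable
  # up to the planting detection level, then drops
  sim2 <- simulate_counts_and_atlas(
    sim_config(seed = 74, n_genes = 200, planted_gene_fraction = 0.1,
               planted_lfc = 4, atlas_n_cells = 300,
               detection_rate_beta = c(0.4, 8)),
    planted_detection_rate = 0.4)
  sw2 <- threshold_sweep(sim2$counts, sim2$atlas)
  low <- sw2$deg_count[sw2$threshold_pct <= 30]
  expect_true(all(low >= 0.9 * low[1]))
  expect_lt(sw2$deg_count[sw2$threshold_pct == 50], 0.5 * low[1])
})

test_that("planted genes rank above null genes by Wald statistic", {
  sim <- simulate_counts_and_atlas(
    sim_config(seed = 75, n_genes = 500, planted_gene_fraction = 0.05,
               planted_lfc = 4, nb_dispersion = 0.05, atlas_n_cells = 10))
  de <- nb_wald_test(sim$counts)
  truth <- sim$ground_truth$true_lfc != 0
  ok <- !is.na(de$wald_stat)
  auc <- auc_oracle(abs(de$wald_stat)[truth & ok],
                    abs(de$wald_stat)[!truth & ok])
  expect_gte(auc, 0.95)
})

test_that("joint significance criteria are stricter than the p-adjusted cut alone", {
  sim <- simulate_counts_and_atlas(
    sim_config(seed = 76, n_genes = 500, planted_gene_fraction = 0,
               atlas_n_cells = 10))
  cand <- de_candidates(nb_wald_test(sim$counts),
                        detection_fraction(sim$atlas))
  frac_both <- mean(cand$passes_significance, na.rm = TRUE)
  frac_padj <- mean(cand$p_adjusted < 0.05, na.rm = TRUE)
  expect_lte(frac_both, frac_padj)
})
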