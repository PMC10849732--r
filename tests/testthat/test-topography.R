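test_that("coordinate standardization subtracts the origin and is translation invariant", {
  p <- data.frame(neuron_id = c("a", "b"), x_um = c(10, 15),
                  y_um = c(10, 17), z_um = c(10, 12))
  out <- standardize_coordinates(p, origin = c(10, 10, 10))
  expect_equal(out$x_um, c(0, 5))
  expect_equal(out$y_um, c(0, 7))
  expect_equal(out$z_um, c(0, 2))

  shifted <- p
  shifted[c("x_um", "y_um", "z_um")] <- p[c("x_um", "y_um", "z_um")] + 10
  out2 <- standardize_coordinates(shifted, origin = c(20, 20, 20))
  expect_equal(out2[c("x_um", "y_um", "z_um")],
               out[c("x_um", "y_um", "z_um")])

  expect_error(standardize_coordinates(p, origin = c(0, 0, 0),
                                       convention = "nonsense"))
  expect_error(standardize_coordinates(p[0, ], origin = c(0, 0, 0)),
               "non-empty")
})

test_that("dorsoventral sections use half-open bins with ties going deeper", {
  b <- seq(0, 40, by = 5)
  expect_equal(assign_dv_section(0, b), 1L)
  expect_equal(assign_dv_section(39, b), 8L)
  # brute-force check across every internal boundary
  for (i in 2:8) {
    expect_equal(assign_dv_section(b[i], b), i)         # tie -> deeper
    expect_equal(assign_dv_section(b[i] - 1e-9, b), i - 1L)
  }
  expect_error(assign_dv_section(40, b), "outside")
  expect_error(assign_dv_section(-0.1, b), "outside")
  expect_error(assign_dv_section(1, b[1:5]), "9 strictly increasing")
})

test_that("bootstrap distributions are reproducible, normalized and consistent", {
  # constant input: zero SD everywhere
  bd <- bootstrap_distribution(rep(3.2, 50), n_iterations = 50, seed = 1)
  expect_true(all(bd$sd_density == 0))

  # same seed twice: identical output
  v <- rnorm(80)
  expect_identical(bootstrap_distribution(v, seed = 11),
                   bootstrap_distribution(v, seed = 11))
  expect_false(identical(bootstrap_distribution(v, seed = 11),
                         bootstrap_distribution(v, seed = 12)))

  # each iteration's density integrates to 1
  set.seed(5)
  vals <- rnorm(200, mean = 10, sd = 2)
  bd2 <- bootstrap_distribution(vals, n_iterations = 100, seed = 2)
  width <- diff(bd2$breaks)[1]
  expect_equal(sum(bd2$mean_density) * width, 1, tolerance = 1e-6)

  # bootstrap consistency: mean of bootstrap means near the sample mean
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(bd2$boot_means) - mean(vals)), 3 * se)

  expect_error(bootstrap_distribution(1), "at least 2")
  expect_error(bootstrap_distribution(1:5, n_iterations = 0), "at least 1")
})

test_that("KS axis test matches the brute-force ECDF oracle", {
  expect_equal(ks_axis_test(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_axis_test(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_axis_test(rnorm(20), rnorm(20) + 50)$D, 1)

  set.seed(31)
  for (i in 1:20) {
    a <- sample(1:30, sample(5:20, 1), replace = TRUE) + runif(1)
    b <- sample(1:30, sample(5:20, 1), replace = TRUE)
    expect_equal(ks_axis_test(a, b)$D, ks_D_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(ks_axis_test(1, c(1, 2)), "at least 2")
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(32)
  a <- rnorm(25); b <- rnorm(30, 1)
  d0 <- ks_axis_test(a, b)$D
  expect_equal(ks_axis_test(exp(a), exp(b))$D, d0)
  expect_equal(ks_axis_test(a^3, b^3)$D, d0)
})

test_that("MANOVA separates distinct clusters and is exact for coincident means", {
  set.seed(41)
  # duplicated data with equal means: Wilks lambda = 1
  base <- data.frame(x_um = rnorm(20), y_um = rnorm(20), z_um = rnorm(20))
  dup <- rbind(cbind(base, g = "a"), cbind(base, g = "b"))
  res <- manova_separation(dup, group = "g")
  expect_equal(res$statistic, 1, tolerance = 1e-9)

  # fully separated clusters: overwhelming significance
  far <- data.frame(x_um = c(rnorm(25), rnorm(25, 10)),
                    y_um = c(rnorm(25), rnorm(25, 10)),
                    z_um = c(rnorm(25), rnorm(25, 10)),
                    g = rep(c("a", "b"), each = 25))
  expect_lt(manova_separation(far, group = "g")$p_value, 1e-6)

  # Pillai option runs and agrees qualitatively
  expect_lt(manova_separation(far, group = "g",
                              statistic = "Pillai")$p_value, 1e-6)

  few <- data.frame(x_um = rnorm(4), y_um = rnorm(4), z_um = rnorm(4),
                    g = rep(c("a", "b"), 2))
  expect_error(manova_separation(few, group = "g"), "more observations")
})

test_that("MANOVA p-values are calibrated under the null", {
  set.seed(42)
  pvals <- vapply(1:200, function(i) {
    d <- data.frame(x_um = rnorm(40), y_um = rnorm(40), z_um = rnorm(40),
                    g = rep(c("a", "b"), each = 20))
    manova_separation(d, group = "g")$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("rank-sum count comparison matches exact enumeration", {
  # identical vectors: exact p = 1
  res <- count_comparison(c(5, 6, 7, 5, 6, 7), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 1)

  # {1,2,3} vs {4,5,6}: two-sided exact p = 2/20 = 0.1
  res2 <- count_comparison(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res2$p_value, 0.1)
  expect_true(res2$exact)
  expect_equal(res2$p_value,
               ranksum_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  # random untied cases agree with enumeration
  set.seed(51)
  for (i in 1:10) {
    a <- sample(1:100, sample(3:6, 1))
    b <- sample(101:200, sample(3:6, 1)) - runif(1, 50, 150)
    got <- count_comparison(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
    expect_equal(got$p_value, ranksum_exact_oracle(a, b), tolerance = 1e-9)
  }

  # tied-heavy input: tie-corrected normal approximation, p in (0, 1],
  # close to the enumeration oracle
  a <- c(1, 1, 2, 2, 3)
  b <- c(2, 2, 3, 3, 3)
  got <- count_comparison(c(a, b), rep(c("a", "b"), each = 5))
  expect_false(got$exact)
  expect_gt(got$p_value, 0)
  expect_lte(got$p_value, 1)
  expect_lt(abs(got$p_value - ranksum_exact_oracle(a, b)), 0.15)

  expect_error(count_comparison(1:5, rep("a", 5)), "two genotypes")
})

test_that("topography statistics ignore neuron labels", {
  set.seed(61)
  pos <- data.frame(x_um = rnorm(30), y_um = rnorm(30), z_um = rnorm(30),
                    g = rep(c("a", "b"), each = 15))
  shuffled <- pos[sample(nrow(pos)), ]
  expect_equal(manova_separation(pos, "g")$p_value,
               manova_separation(shuffled, "g")$p_value)
  expect_equal(ks_axis_test(pos$z_um[pos$g == "a"], pos$z_um[pos$g == "b"])$D,
               ks_axis_test(sample(pos$z_um[pos$g == "a"]),
                            pos$z_um[pos$g == "b"])$D)
})
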