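make_flat_trace <- function(f, n = 195) {
  data.frame(neuron_id = "n1", fish_id = "f1", genotype = "sibling",
             repeat_index = 1, roi_size = 1, frame = seq_len(n),
             f = rep_len(f, n))
}

test_that("ROI normalization divides frames and refuses to run twice", {
  tr <- data.frame(neuron_id = "a", roi_size = 2, frame = 1:3, f = 200)
  out <- normalize_trace(tr)
  expect_equal(out$f, rep(100, 3))
  expect_true(attr(out, "roi_normalized"))
  expect_error(normalize_trace(out), "already")

  id <- data.frame(neuron_id = "a", roi_size = 1, frame = 1:3, f = c(1, 2, 3))
  expect_equal(normalize_trace(id)$f, c(1, 2, 3))

  # two traces identical up to the ROI factor coincide after normalization
  base <- c(100, 120, 90)
  t1 <- data.frame(neuron_id = "a", roi_size = 3, frame = 1:3, f = 3 * base)
  t2 <- data.frame(neuron_id = "a", roi_size = 7, frame = 1:3, f = 7 * base)
  expect_equal(normalize_trace(t1)$f, normalize_trace(t2)$f)

  bad <- data.frame(neuron_id = "a", roi_size = 0, frame = 1, f = 1)
  expect_error(normalize_trace(bad), "positive")
})

test_that("tonic dFF extraction matches direct arithmetic", {
  sch <- tonic_schedule(3)
  f <- rep(100, 195)
  f[61:63] <- 150                          # post-nose-down response window
  sc <- extract_tonic_response(f, sch)
  expect_equal(sc$dff_down, 0.5)
  expect_equal(sc$baseline_mean_down, 100)
  expect_true(sc$significant_down)         # baseline SD is 0 here

  flat <- extract_tonic_response(rep(100, 195), sch)
  expect_equal(flat$dff_down, 0)
  expect_equal(flat$dff_up, 0)
  expect_false(flat$significant_down)
  expect_false(flat$significant_up)

  expect_error(extract_tonic_response(rep(100, 100), sch), "frames")
  expect_error(extract_tonic_response(rep(0, 195), sch), "degenerate")
})

test_that("tuning index matches the arithmetic oracle on an exhaustive grid", {
  vals <- seq(0, 2, by = 0.25)
  for (up in vals) for (down in vals) {
    got <- tuning_index(up, down)
    if (up + down == 0) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, (up - down) / (up + down))
    }
  }
  expect_equal(tuning_index(1, 1), 0)
  expect_equal(tuning_index(2, 0), 1)
  expect_equal(tuning_index(1.5, 0.5), 0.5)
  expect_error(tuning_index(NA, NA), "NA")
})

test_that("tuning index is antisymmetric, scale invariant and clamps negatives", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(1, 0, 3); b <- runif(1, 0, 3); k <- runif(1, 0.1, 10)
    expect_equal(tuning_index(a, b), -tuning_index(b, a))
    expect_equal(tuning_index(k * a, k * b), tuning_index(a, b))
  }
  # suppression clamps to zero, keeping the index in [-1, 1]
  expect_equal(tuning_index(1, -0.5), 1)
  expect_equal(tuning_index(-2, -3), NA_real_)
})

test_that("subtype classification applies the 0.1 threshold and significance", {
  expect_equal(classify_subtype(0.05, TRUE, TRUE), "untuned")
  expect_equal(classify_subtype(0.85, TRUE, FALSE), "nose_up")
  expect_equal(classify_subtype(-0.4, FALSE, TRUE), "nose_down")
  expect_equal(classify_subtype(0.5, FALSE, FALSE), "untuned")  # no sig resp
  expect_equal(classify_subtype(-0.09, TRUE, TRUE), "untuned")
  expect_equal(classify_subtype(NA_real_, TRUE, TRUE), "untuned")
  expect_equal(classify_subtype(0.1, TRUE, FALSE), "nose_up")   # boundary in
})

test_that("impulse scoring flags responders and is symmetric for equal transients", {
  sch <- impulse_schedule(3)
  flat <- extract_impulse_response(rep(100, 195) + rep(c(0.01, -0.01), len = 195),
                                   sch)
  expect_false(flat$responsive)

  f <- rep(100, 195)
  f[61:63] <- 140
  f[151:153] <- 140
  sc <- extract_impulse_response(f, sch)
  expect_true(sc$responsive)
  expect_equal(sc$impulse_tuning_index, 0)
  expect_equal(sc$dff_1, sc$dff_2)
})

test_that("repeat aggregation averages dFF and recomputes classification", {
  one <- data.frame(dff_down = 0.4, dff_up = 1.2, baseline_sd_down = 0.05,
                    baseline_sd_up = 0.05, significant_down = TRUE,
                    significant_up = TRUE)
  agg <- aggregate_repeats(rbind(one, one, one))
  expect_equal(agg$dff_up, 1.2)
  expect_equal(agg$dff_down, 0.4)
  expect_equal(agg$tuning_index, tuning_index(1.2, 0.4))

  three <- one[rep(1, 3), ]
  three$dff_up <- c(0.9, 1.0, 1.1)
  expect_equal(aggregate_repeats(three)$dff_up, 1.0)
  expect_error(aggregate_repeats(one[0, ]), "at least one")
})

test_that("planted subtypes are recovered with high sensitivity on noisy data", {
  # response amplitude 10x the baseline noise SD (in matched units)
  cfg <- sim_config(seed = 21, n_fish_per_genotype = 5,
                    n_neurons_per_fish = 20, baseline_sd = 5,
                    baseline_level = 100, response_amplitude = 0.5,
                    subtype_fractions = c(nose_up = 1, nose_down = 0,
                                          untuned = 0))
  sim <- simulate_tonic_traces(cfg)
  sc <- score_tilt_traces(sim$traces, sim$schedule)
  expect_gte(mean(sc$significant_up), 0.99)
  expect_lte(mean(sc$significant_down), 0.05)
  expect_gte(mean(sc$subtype == "nose_up"), 0.99)
})

test_that("impulse responders are recovered with high sensitivity and low FPR", {
  cfg <- sim_config(seed = 22, n_fish_per_genotype = 5,
                    n_neurons_per_fish = 25, baseline_sd = 5,
                    response_amplitude = 0.5, responsive_fraction = 0.5)
  sim <- simulate_impulse_traces(cfg)
  sc <- score_impulse_traces(sim$traces, sim$schedule)
  m <- merge(as.data.frame(sc), sim$ground_truth, by = "neuron_id")
  expect_gte(mean(m$responsive.x[m$responsive.y]), 0.99)
  expect_lte(mean(m$responsive.x[!m$responsive.y]), 0.05)
})

test_that("aggregation over repeats reduces classification error on noisy traces", {
  cfg <- sim_config(seed = 23, n_fish_per_genotype = 5,
                    n_neurons_per_fish = 20, baseline_sd = 12,
                    response_amplitude = 0.35)
  sim <- simulate_tonic_traces(cfg)
  sc <- score_tilt_traces(sim$traces, sim$schedule)
  truth <- sim$ground_truth$subtype[match(sc$neuron_id,
                                          sim$ground_truth$neuron_id)]
  acc_agg <- mean(sc$subtype == truth)

  per_rep <- attr(sc, "per_repeat")
  r1 <- per_rep[per_rep$repeat_index == 1, ]
  idx1 <- tuning_index(r1$dff_up, r1$dff_down)
  call1 <- classify_subtype(idx1, r1$significant_up, r1$significant_down)
  truth1 <- sim$ground_truth$subtype[match(r1$neuron_id,
                                           sim$ground_truth$neuron_id)]
  expect_gte(acc_agg, mean(call1 == truth1))
})

test_that("significance calls are invariant to ROI size", {
  cfg <- sim_config(seed = 24, n_fish_per_genotype = 2,
                    n_neurons_per_fish = 10)
  sim <- simulate_tonic_traces(cfg)
  sc1 <- score_tilt_traces(sim$traces, sim$schedule)
  scaled <- sim$traces
  scaled$f <- scaled$f / scaled$roi_size * 5   # re-express at ROI size 5
  scaled$roi_size <- 5
  sc2 <- score_tilt_traces(scaled, sim$schedule)
  expect_equal(sc1$significant_up, sc2$significant_up)
  expect_equal(sc1$dff_up, sc2$dff_up, tolerance = 1e-12)
  expect_equal(sc1$subtype, sc2$subtype)
})
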