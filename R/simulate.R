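#' Simulate tonic tilt-response fluorescence traces
#'
#' Generates raw fluorescence traces for a population of vestibular
#' projection neurons presented with the tonic pitch-tilt schedule
#' ([tonic_schedule()]): 5 s horizontal baseline, 15 s nose-down tilt,
#' 15 s horizontal, 15 s nose-up tilt, 15 s horizontal, imaged at
#' `config$frame_rate` frames/s for three stimulus repeats.
#'
#' Each neuron is assigned a ground-truth subtype by
#' `config$subtype_fractions`. Nose-up neurons carry a calcium transient
#' starting at the restoration to horizontal that follows the nose-up tilt,
#' nose-down neurons at the restoration following the nose-down tilt, and
#' untuned neurons carry equal transients in both windows. The transient is
#' an indicator-like kernel: an instantaneous rise of `response_amplitude`
#' (dFF units) decaying exponentially with time constant
#' `decay_time_constant`. Raw fluorescence for frame time `t` is
#' `roi_size * (baseline_level * (1 + A * k(t)) + noise)` with additive
#' Gaussian noise of SD `baseline_sd`; the multiplicative ROI factor is what
#' [normalize_trace()] removes.
#'
#' @param config a [sim_config()].
#' @return a list with `traces` (long-format data.frame: `neuron_id`,
#'   `fish_id`, `genotype`, `repeat_index`, `roi_size`, `frame`, `f`),
#'   `ground_truth` (`neuron_id`, `subtype`), and `schedule`.
#' @examples
#' sim <- simulate_tonic_traces(sim_config(seed = 7, n_fish_per_genotype = 1,
#'                                         n_neurons_per_fish = 2))
#' table(sim$ground_truth$subtype)
#' @export
simulate_tonic_traces <- function(config) {
  validate_sim_config(config)
  schedule <- tonic_schedule(config$frame_rate)
  on <- segment_onsets(schedule)
  onset_down <- on[3]   # restoration after nose-down tilt
  onset_up   <- on[5]   # restoration after nose-up tilt
  with_sim_seed(config$seed, 101L, {
    pop <- simulate_population(config)
    amp <- amplitude_matrix_tonic(pop$subtype, config$response_amplitude)
    traces <- build_traces(pop, amp, c(onset_down, onset_up), schedule, config)
    list(traces = traces,
         ground_truth = data.frame(neuron_id = pop$neuron_id,
                                   subtype = pop$subtype,
                                   stringsAsFactors = FALSE),
         schedule = schedule)
  })
}

#' Simulate impulse tilt-response fluorescence traces
#'
#' Generates traces for the impulse schedule ([impulse_schedule()]): a 20-s
#' horizontal baseline, a 10-ms impulse, 30 s horizontal, a second 10-ms
#' impulse, and a final horizontal window. A `responsive_fraction` of
#' neurons carries transients after both impulses (equal amplitudes by
#' default, so the impulse selectivity index is near zero, as observed for
#' canal-driven responses); the rest carry none.
#'
#' @inheritParams simulate_tonic_traces
#' @return as [simulate_tonic_traces()], with ground truth column
#'   `responsive` (logical).
#' @export
simulate_impulse_traces <- function(config) {
  validate_sim_config(config)
  schedule <- impulse_schedule(config$frame_rate)
  on <- segment_onsets(schedule)
  onsets <- c(on[3], on[5])   # restoration after each impulse
  with_sim_seed(config$seed, 202L, {
    pop <- simulate_population(config)
    n <- nrow(pop)
    n_resp <- round(config$responsive_fraction * n)
    responsive <- rep(FALSE, n)
    if (n_resp > 0) responsive[sample.int(n, n_resp)] <- TRUE
    amp <- cbind(ifelse(responsive, config$response_amplitude, 0),
                 ifelse(responsive, config$response_amplitude, 0))
    traces <- build_traces(pop, amp, onsets, schedule, config)
    list(traces = traces,
         ground_truth = data.frame(neuron_id = pop$neuron_id,
                                   responsive = responsive,
                                   stringsAsFactors = FALSE),
         schedule = schedule)
  })
}

# Neuron roster shared by the trace generators: ids, fish, genotype, ROI
# size, and a ground-truth subtype drawn from config$subtype_fractions.
simulate_population <- function(config) {
  genotypes <- c("sibling", "null")
  fish <- expand.grid(fish_rank = seq_len(config$n_fish_per_genotype),
                      genotype = genotypes, stringsAsFactors = FALSE)
  fish$fish_id <- sprintf("%s_f%02d", fish$genotype, fish$fish_rank)
  n_per <- config$n_neurons_per_fish
  pop <- fish[rep(seq_len(nrow(fish)), each = n_per), c("fish_id", "genotype")]
  n <- nrow(pop)
  pop$neuron_id <- sprintf("n%04d", seq_len(n))
  pop$roi_size <- stats::runif(n, config$roi_size_range[1],
                               config$roi_size_range[2])
  sf <- config$subtype_fractions
  pop$subtype <- sample(names(sf), n, replace = TRUE, prob = sf)
  rownames(pop) <- NULL
  pop
}

# Per-neuron transient amplitudes (dFF units) in the two tonic response
# windows (columns: after nose-down restoration, after nose-up restoration).
amplitude_matrix_tonic <- function(subtype, amplitude) {
  cbind(ifelse(subtype %in% c("nose_down", "untuned"), amplitude, 0),
        ifelse(subtype %in% c("nose_up", "untuned"), amplitude, 0))
}

# Exponential-decay indicator kernel evaluated at frame times, summed over
# transient onsets.
kernel_signal <- function(t, onsets, amplitudes, tau) {
  sig <- numeric(length(t))
  for (j in seq_along(onsets)) {
    after <- t >= onsets[j]
    sig[after] <- sig[after] +
      amplitudes[j] * exp(-(t[after] - onsets[j]) / tau)
  }
  sig
}

# Long-format raw trace table for one schedule; three repeats per neuron.
build_traces <- function(pop, amp, onsets, schedule, config) {
  nf <- schedule$n_frames
  t <- (seq_len(nf) - 1L) / schedule$frame_rate
  n <- nrow(pop)
  n_rep <- 3L
  out <- vector("list", n * n_rep)
  k <- 0L
  for (i in seq_len(n)) {
    clean <- config$baseline_level *
      (1 + kernel_signal(t, onsets, amp[i, ], config$decay_time_constant))
    for (r in seq_len(n_rep)) {
      noise <- if (config$baseline_sd > 0)
        stats::rnorm(nf, 0, config$baseline_sd) else 0
      k <- k + 1L
      out[[k]] <- data.frame(
        neuron_id = pop$neuron_id[i], fish_id = pop$fish_id[i],
        genotype = pop$genotype[i], repeat_index = r,
        roi_size = pop$roi_size[i], frame = seq_len(nf),
        f = pop$roi_size[i] * (clean + noise),
        stringsAsFactors = FALSE)
    }
  }
  traces <- do.call(rbind, out)
  attr(traces, "roi_normalized") <- FALSE
  traces
}

#' Simulate topographic soma positions
#'
#' Draws soma coordinates (um, relative to the dorsomedial origin of the
#' nucleus; z grows ventrally) for neurons of each genotype and subtype.
#' Nose-up somata occupy a dorsal band `[0, h + o*h]` and nose-down somata a
#' ventral band `[h - o*h, dv_extent]` where `h = dv_extent / 2` and
#' `o = dv_overlap`, so `dv_overlap = 0` gives disjoint dorsoventral
#' supports; untuned somata are spread across the full depth. With
#' `topographic = FALSE` all subtypes share the full-depth distribution
#' (a spatial null). Mediolateral (x) and rostrocaudal (y) positions are
#' uniform over fixed nucleus extents (30 and 60 um).
#'
#' @inheritParams simulate_tonic_traces
#' @return list with `positions` (`neuron_id`, `genotype`, `subtype`,
#'   `x_um`, `y_um`, `z_um`) and `ground_truth` (`neuron_id`, `subtype`,
#'   `dv_section` over eight equal sections spanning the dorsoventral
#'   extent).
#' @export
simulate_positions <- function(config) {
  validate_sim_config(config)
  with_sim_seed(config$seed, 303L, {
    pop <- simulate_population(config)
    n <- nrow(pop)
    D <- config$dv_extent
    h <- D / 2
    o <- config$dv_overlap
    z <- numeric(n)
    for (i in seq_len(n)) {
      rng <- if (!config$topographic) c(0, D)
      else switch(pop$subtype[i],
                  nose_up   = c(0, h + o * h),
                  nose_down = c(h - o * h, D),
                  c(0, D))
      z[i] <- stats::runif(1, rng[1], rng[2])
    }
    positions <- data.frame(
      neuron_id = pop$neuron_id, genotype = pop$genotype,
      subtype = pop$subtype,
      x_um = stats::runif(n, 0, 30),
      y_um = stats::runif(n, 0, 60),
      z_um = z, stringsAsFactors = FALSE)
    boundaries <- seq(0, D, length.out = 9L)
    # top of the deepest section is closed so the extreme soma is assignable
    zb <- pmin(z, D - 1e-9)
    list(positions = positions,
         ground_truth = data.frame(
           neuron_id = pop$neuron_id, subtype = pop$subtype,
           dv_section = assign_dv_section(zb, boundaries),
           stringsAsFactors = FALSE))
  })
}

#' Simulate a bulk count matrix and a reference detection atlas
#'
#' Bulk counts are negative-binomial per gene with log-normal baseline means
#' (median `mean_count`) and dispersion `nb_dispersion` (or per-gene
#' log-normal draws when `NA`). A `planted_gene_fraction` of genes carries a
#' true log2 fold change of `planted_lfc` in the null condition (half up,
#' half down). The atlas is a binary genes x cells detection matrix with
#' per-gene Bernoulli detection rates drawn from
#' `Beta(detection_rate_beta)`; the first `atlas_projection_fraction` of
#' cells form the labelled projection-neuron cluster.
#'
#' @inheritParams simulate_tonic_traces
#' @param planted_detection_rate optional single rate in `[0, 1]` forced on
#'   planted genes' atlas detection (used to tie planted effects to a known
#'   detection level); `NA` leaves them on the common Beta draw.
#' @return list with `counts` (a [count_matrix()]), `atlas` (an
#'   [atlas_detection()]), and `ground_truth` (`gene_id`, `true_lfc`,
#'   `detection_rate`).
#' @export
simulate_counts_and_atlas <- function(config, planted_detection_rate = NA) {
  validate_sim_config(config)
  if (!is.na(planted_detection_rate) &&
      (planted_detection_rate < 0 || planted_detection_rate > 1))
    stop("invalid config: planted_detection_rate must be in [0, 1]",
         call. = FALSE)
  with_sim_seed(config$seed, 404L, {
    G <- config$n_genes
    n <- config$n_samples_per_condition
    gene_id <- sprintf("gene%05d", seq_len(G))
    mu0 <- stats::rlnorm(G, meanlog = log(config$mean_count), sdlog = 1)
    disp <- if (is.na(config$nb_dispersion))
      stats::rlnorm(G, meanlog = log(0.05), sdlog = 0.5)
    else rep(config$nb_dispersion, G)

    n_pl <- round(config$planted_gene_fraction * G)
    true_lfc <- numeric(G)
    if (n_pl > 0) {
      planted <- sample.int(G, n_pl)
      signs <- rep_len(c(1, -1), n_pl)
      true_lfc[planted] <- signs * config$planted_lfc
    }
    mu_sib <- mu0
    mu_null <- mu0 * 2^true_lfc

    counts <- matrix(0L, nrow = G, ncol = 2L * n,
                     dimnames = list(gene_id,
                                     c(sprintf("sibling_%d", seq_len(n)),
                                       sprintf("null_%d", seq_len(n)))))
    for (j in seq_len(n)) {
      counts[, j]     <- stats::rnbinom(G, mu = mu_sib, size = 1 / disp)
      counts[, n + j] <- stats::rnbinom(G, mu = mu_null, size = 1 / disp)
    }
    condition <- rep(c("sibling", "null"), each = n)
    cm <- count_matrix(counts, condition)

    C <- config$atlas_n_cells
    n_proj <- max(1L, round(config$atlas_projection_fraction * C))
    cluster <- c(rep("projection", n_proj), rep("other", C - n_proj))
    rate <- stats::rbeta(G, config$detection_rate_beta[1],
                         config$detection_rate_beta[2])
    if (!is.na(planted_detection_rate) && n_pl > 0)
      rate[true_lfc != 0] <- planted_detection_rate
    det <- matrix(stats::rbinom(G * C, 1L, rep(rate, times = C)),
                  nrow = G, ncol = C,
                  dimnames = list(gene_id, sprintf("cell%05d", seq_len(C))))
    atlas <- atlas_detection(Matrix::Matrix(det, sparse = TRUE), cluster)

    list(counts = cm, atlas = atlas,
         ground_truth = data.frame(gene_id = gene_id, true_lfc = true_lfc,
                                   detection_rate = rate,
                                   stringsAsFactors = FALSE))
  })
}
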