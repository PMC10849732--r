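#' Configuration for the synthetic-data generator
#'
#' Builds a validated configuration object consumed by
#' [simulate_tonic_traces()], [simulate_impulse_traces()],
#' [simulate_positions()] and [simulate_counts_and_atlas()]. Every generator
#' is a pure function of `(seed, config)`: the same configuration produces
#' byte-identical outputs.
#'
#' Defaults emulate the structure of tilt-in-place calcium imaging of
#' vestibular projection neurons (GCaMP6s indicator, 3 frames/s, 65-s
#' epochs, three stimulus repeats) and of a bulk RNA-seq comparison between
#' phox2a null mutants and sibling controls backed by a single-cell
#' reference atlas with a labelled projection-neuron cluster.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_fish_per_genotype number of fish simulated per genotype.
#' @param n_neurons_per_fish neurons recorded per fish.
#' @param subtype_fractions named numeric over `nose_up`, `nose_down`,
#'   `untuned`; must sum to 1.
#' @param responsive_fraction fraction of neurons responsive to impulse
#'   stimuli.
#' @param baseline_level baseline fluorescence (a.u., per unit ROI), > 0.
#' @param baseline_sd additive Gaussian noise SD (a.u.), >= 0.
#' @param response_amplitude peak transient amplitude in dFF units, >= 0.
#' @param decay_time_constant indicator decay time constant tau (s); the
#'   default 1.8 s is GCaMP6s-like.
#' @param frame_rate imaging frame rate (frames/s).
#' @param roi_size_range min/max ROI area (um^2); ROI size multiplies raw
#'   fluorescence so the scoring module's ROI normalization is exercised.
#' @param dv_extent dorsoventral depth of the nucleus (um); z grows ventrally
#'   from the dorsomedial origin.
#' @param dv_overlap fraction in `[0, 1]` by which the dorsal (nose-up) and
#'   ventral (nose-down) soma distributions overlap; 0 gives disjoint
#'   supports.
#' @param topographic if `FALSE`, all subtypes share one spatial
#'   distribution (null configuration for calibration tests).
#' @param n_genes number of genes in the bulk count matrix.
#' @param n_samples_per_condition bulk samples per condition (>= 2).
#' @param nb_dispersion per-gene NB dispersion; a single value is used for
#'   all genes, `NA` draws per-gene dispersions from a log-normal.
#' @param mean_count median of the log-normal distribution of per-gene
#'   baseline mean counts.
#' @param planted_lfc absolute log2 fold change planted in perturbed genes.
#' @param planted_gene_fraction fraction of genes carrying the planted
#'   effect (half up-, half down-regulated).
#' @param atlas_n_cells number of cells in the reference atlas.
#' @param atlas_projection_fraction fraction of atlas cells in the labelled
#'   projection-neuron cluster.
#' @param detection_rate_beta shape parameters `c(a, b)` of the Beta
#'   distribution from which per-gene atlas detection rates are drawn.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_fish_per_genotype = 2, n_neurons_per_fish = 5)
#' cfg$frame_rate
#' @export
sim_config <- function(seed = 1L,
                       n_fish_per_genotype = 4L,
                       n_neurons_per_fish = 20L,
                       subtype_fractions = c(nose_up = 0.46, nose_down = 0.47,
                                             untuned = 0.07),
                       responsive_fraction = 0.6,
                       baseline_level = 100,
                       baseline_sd = 5,
                       response_amplitude = 1.5,
                       decay_time_constant = 1.8,
                       frame_rate = 3,
                       roi_size_range = c(30, 100),
                       dv_extent = 40,
                       dv_overlap = 0.25,
                       topographic = TRUE,
                       n_genes = 2000L,
                       n_samples_per_condition = 3L,
                       nb_dispersion = 0.05,
                       mean_count = 100,
                       planted_lfc = 4,
                       planted_gene_fraction = 0.05,
                       atlas_n_cells = 1468L,
                       atlas_projection_fraction = 0.32,
                       detection_rate_beta = c(0.6, 1.4)) {
  cfg <- list(
    seed = as.integer(seed),
    n_fish_per_genotype = as.integer(n_fish_per_genotype),
    n_neurons_per_fish = as.integer(n_neurons_per_fish),
    subtype_fractions = subtype_fractions,
    responsive_fraction = responsive_fraction,
    baseline_level = baseline_level,
    baseline_sd = baseline_sd,
    response_amplitude = response_amplitude,
    decay_time_constant = decay_time_constant,
    frame_rate = frame_rate,
    roi_size_range = roi_size_range,
    dv_extent = dv_extent,
    dv_overlap = dv_overlap,
    topographic = isTRUE(topographic),
    n_genes = as.integer(n_genes),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    nb_dispersion = nb_dispersion,
    mean_count = mean_count,
    planted_lfc = planted_lfc,
    planted_gene_fraction = planted_gene_fraction,
    atlas_n_cells = as.integer(atlas_n_cells),
    atlas_projection_fraction = atlas_projection_fraction,
    detection_rate_beta = detection_rate_beta
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) stop("invalid config: ", msg, call. = FALSE)
  sf <- cfg$subtype_fractions
  if (!all(c("nose_up", "nose_down", "untuned") %in% names(sf)))
    fail("subtype_fractions must be named nose_up/nose_down/untuned")
  if (abs(sum(sf) - 1) > 1e-9) fail("subtype_fractions must sum to 1")
  if (any(sf < 0)) fail("subtype_fractions must be non-negative")
  if (cfg$frame_rate <= 0) fail("frame_rate must be positive")
  if (cfg$baseline_level <= 0) fail("baseline_level must be positive")
  if (cfg$baseline_sd < 0) fail("baseline_sd must be non-negative")
  if (cfg$response_amplitude < 0) fail("response_amplitude must be >= 0")
  if (cfg$decay_time_constant <= 0) fail("decay_time_constant must be > 0")
  if (length(cfg$roi_size_range) != 2L || any(cfg$roi_size_range <= 0) ||
      diff(cfg$roi_size_range) < 0)
    fail("roi_size_range must be positive and increasing")
  if (cfg$dv_extent <= 0) fail("dv_extent must be positive")
  if (cfg$dv_overlap < 0 || cfg$dv_overlap > 1)
    fail("dv_overlap must be in [0, 1]")
  if (cfg$responsive_fraction < 0 || cfg$responsive_fraction > 1)
    fail("responsive_fraction must be in [0, 1]")
  if (cfg$n_samples_per_condition < 2L)
    fail("n_samples_per_condition must be >= 2")
  if (!is.na(cfg$nb_dispersion) && cfg$nb_dispersion <= 0)
    fail("nb_dispersion must be positive (or NA for log-normal draws)")
  if (cfg$planted_gene_fraction < 0 || cfg$planted_gene_fraction > 1)
    fail("planted_gene_fraction must be in [0, 1]")
  if (cfg$atlas_projection_fraction <= 0 || cfg$atlas_projection_fraction > 1)
    fail("atlas_projection_fraction must be in (0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d fish/genotype x %d neurons | frame rate %g fps\n",
              x$seed, x$n_fish_per_genotype, x$n_neurons_per_fish,
              x$frame_rate))
  cat(sprintf("  subtypes up/down/untuned: %s\n",
              paste(format(x$subtype_fractions), collapse = "/")))
  cat(sprintf("  bulk: %d genes x %d+%d samples | atlas: %d cells (%g%% projection)\n",
              x$n_genes, x$n_samples_per_condition, x$n_samples_per_condition,
              x$atlas_n_cells, 100 * x$atlas_projection_fraction))
  invisible(x)
}

# Run expr with a private, restored RNG state seeded from `seed`+`offset`,
# so generators are pure in (seed, config) and do not disturb the caller's
# RNG stream. Offsets keep the per-module streams distinct.
with_sim_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  expr
}
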