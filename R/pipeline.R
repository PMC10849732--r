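#' Run the full analysis pipeline
#'
#' Drives the end-to-end chain: simulate (or load) inputs, score tonic and
#' impulse traces, map topography (per-axis KS, MANOVA, bootstrap
#' distributions), compare groups, run the filtered differential-expression
#' sweep, and write a machine-readable summary. Identical configuration and
#' seed give a byte-identical JSON summary.
#'
#' The configuration is a named list (or a YAML file with the same
#' structure) with optional entries:
#' \describe{
#'   \item{seed}{integer; fanned out to the generators (required for
#'     reproducibility; default 1).}
#'   \item{sim}{named overrides passed to [sim_config()].}
#'   \item{thresholds}{detection ladder in percent
#'     (default 0, 1, 3, 5, 10, 30, 50).}
#'   \item{alpha, lfc_cutoff}{DE significance criteria (0.05, 2).}
#'   \item{bootstrap}{list with `n_iterations` (100) and `n_bins` (20).}
#'   \item{inputs}{optional paths: `counts` (MTX directory or wide TSV),
#'     `atlas` (MTX directory), `traces_tonic`, `traces_impulse`,
#'     `positions` (CSV). Paths are validated before any computation; any
#'     input not supplied is simulated.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @param out_dir output directory; created if needed. `NULL` skips file
#'   output.
#' @return (invisibly) a list with `scores_tonic`, `scores_impulse`,
#'   `topography`, `group_stats`, `sweep`, and `summary` (the JSON content).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or YAML path",
                             call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  thresholds <- config$thresholds %||% c(0, 1, 3, 5, 10, 30, 50)
  alpha <- config$alpha %||% 0.05
  lfc_cutoff <- config$lfc_cutoff %||% 2
  boot <- config$bootstrap %||% list()
  n_iter <- boot$n_iterations %||% 100L
  n_bins <- boot$n_bins %||% 20L

  inputs <- config$inputs %||% list()
  for (nm in names(inputs))
    if (!file.exists(inputs[[nm]]) && !dir.exists(inputs[[nm]]))
      stop("configured input path does not exist: ", nm, " = ",
           inputs[[nm]], call. = FALSE)

  cfg <- do.call(sim_config, c(list(seed = seed), config$sim %||% list()))

  # --- score -----------------------------------------------------------
  tonic <- if (!is.null(inputs$traces_tonic))
    list(traces = read_traces(inputs$traces_tonic),
         schedule = tonic_schedule(cfg$frame_rate))
  else simulate_tonic_traces(cfg)
  scores_tonic <- score_tilt_traces(tonic$traces, tonic$schedule)

  impulse <- if (!is.null(inputs$traces_impulse))
    list(traces = read_traces(inputs$traces_impulse),
         schedule = impulse_schedule(cfg$frame_rate))
  else simulate_impulse_traces(cfg)
  scores_impulse <- score_impulse_traces(impulse$traces, impulse$schedule)

  # --- map -------------------------------------------------------------
  pos <- if (!is.null(inputs$positions)) read_positions(inputs$positions)
  else simulate_positions(cfg)$positions
  tuned <- pos[pos$subtype %in% c("nose_up", "nose_down"), ]
  ks_z <- ks_axis_test(tuned$z_um[tuned$subtype == "nose_up"],
                       tuned$z_um[tuned$subtype == "nose_down"])
  man <- manova_separation(tuned, group = "subtype")
  boot_up <- bootstrap_distribution(
    tuned$z_um[tuned$subtype == "nose_up"], n_iterations = n_iter,
    seed = seed, n_bins = n_bins, range = c(0, cfg$dv_extent), axis = "z")
  boot_down <- bootstrap_distribution(
    tuned$z_um[tuned$subtype == "nose_down"], n_iterations = n_iter,
    seed = seed + 1L, n_bins = n_bins, range = c(0, cfg$dv_extent),
    axis = "z")

  # --- compare ---------------------------------------------------------
  summaries <- summarize_groups(scores_tonic, by = "genotype")
  an_up <- anova_multcomp(scores_tonic$dff_up, scores_tonic$genotype)

  # --- filter ----------------------------------------------------------
  bulk <- if (!is.null(inputs$counts) && !is.null(inputs$atlas))
    list(counts = read_counts(inputs$counts), atlas = read_atlas(inputs$atlas))
  else simulate_counts_and_atlas(cfg)
  sweep <- threshold_sweep(bulk$counts, bulk$atlas, thresholds = thresholds,
                           alpha = alpha, lfc_cutoff = lfc_cutoff)

  summary <- list(
    seed = seed,
    n_neurons = nrow(scores_tonic),
    subtype_proportions = as.list(round(
      prop.table(table(factor(scores_tonic$subtype,
                              c("nose_up", "nose_down", "untuned")))), 6)),
    mean_dff_up = round(mean(scores_tonic$dff_up), 6),
    mean_dff_down = round(mean(scores_tonic$dff_down), 6),
    impulse_responsive_fraction = round(mean(scores_impulse$responsive), 6),
    topography = list(ks_z_D = round(ks_z$D, 6),
                      ks_z_p = signif(ks_z$p_value, 6),
                      manova_wilks = round(man$statistic, 6),
                      manova_p = signif(man$p_value, 6)),
    anova_dff_up = list(F = round(an_up$F, 6),
                        p = signif(an_up$p_value, 6)),
    de_sweep = lapply(seq_len(nrow(sweep)), function(i)
      list(threshold_pct = sweep$threshold_pct[i],
           universe_size = sweep$universe_size[i],
           deg_count = sweep$deg_count[i])),
    thresholds = as.numeric(thresholds), alpha = alpha,
    lfc_cutoff = lfc_cutoff)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(scores_tonic),
                       file.path(out_dir, "scores_tonic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(scores_impulse),
                       file.path(out_dir, "scores_impulse.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_positions(pos, file.path(out_dir, "positions.csv"))
    utils::write.table(sweep, file.path(out_dir, "de_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(scores_tonic = scores_tonic,
                 scores_impulse = scores_impulse,
                 topography = list(ks_z = ks_z, manova = man,
                                   bootstrap = list(nose_up = boot_up,
                                                    nose_down = boot_down)),
                 group_stats = list(summaries = summaries,
                                    anova_dff_up = an_up),
                 sweep = sweep, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
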