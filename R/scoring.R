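#' Normalize raw traces by ROI size
#'
#' Divides raw fluorescence by each neuron's ROI area (um^2) to remove the
#' magnification-dependent scale, and marks the table as normalized so a
#' second normalization is rejected.
#'
#' @param traces long-format trace table as produced by
#'   [simulate_tonic_traces()] (columns `roi_size` and `f` required).
#' @return the table with `f` divided by `roi_size` and attribute
#'   `roi_normalized = TRUE`.
#' @examples
#' tr <- data.frame(neuron_id = "a", roi_size = 2, frame = 1:3, f = 200)
#' normalize_trace(tr)$f   # 100 100 100
#' @export
normalize_trace <- function(traces) {
  if (isTRUE(attr(traces, "roi_normalized")))
    stop("traces are already ROI-normalized", call. = FALSE)
  if (!all(c("roi_size", "f") %in% names(traces)))
    stop("`traces` must have columns `roi_size` and `f`", call. = FALSE)
  if (any(traces$roi_size <= 0))
    stop("roi_size must be positive", call. = FALSE)
  traces$f <- traces$f / traces$roi_size
  attr(traces, "roi_normalized") <- TRUE
  traces
}

# Mean dFF over a response window against a baseline window, with the
# baseline SD expressed in dFF units (per-frame baseline samples transformed
# to dFF so the 2-SD significance criterion is unit-consistent).
window_dff <- function(f, baseline_idx, response_idx) {
  b <- mean(f[baseline_idx])
  if (!is.finite(b) || b == 0)
    stop("degenerate baseline: mean fluorescence is zero", call. = FALSE)
  dff <- (mean(f[response_idx]) - b) / b
  sd_dff <- stats::sd(f[baseline_idx] / b - 1)
  list(dff = dff, baseline_mean = b, baseline_sd_dff = sd_dff)
}

#' Score one tonic trace
#'
#' Computes the per-direction dFF responses of a single 65-s tonic trace.
#' The nose-down response is the mean fluorescence over the first second of
#' restoration to horizontal after the nose-down tilt, normalized by the
#' mean over the initial 5-s baseline; the nose-up response uses the first
#' second after the nose-up tilt against the last 3 s of the horizontal
#' segment that follows the nose-down tilt. A response is significant when
#' it exceeds twice the baseline SD (in dFF units).
#'
#' @param f numeric vector of ROI-normalized fluorescence, one value per
#'   frame, length `schedule$n_frames`.
#' @param schedule a tonic [tonic_schedule()].
#' @return one-row data.frame: `dff_down`, `dff_up`, `baseline_mean_down`,
#'   `baseline_mean_up`, `baseline_sd_down`, `baseline_sd_up` (dFF units),
#'   `significant_down`, `significant_up`.
#' @export
extract_tonic_response <- function(f, schedule) {
  if (!inherits(schedule, "tilt_schedule") || schedule$type != "tonic")
    stop("`schedule` must be a tonic tilt_schedule", call. = FALSE)
  if (length(f) != schedule$n_frames)
    stop(sprintf("trace has %d frames but schedule expects %d",
                 length(f), schedule$n_frames), call. = FALSE)
  w <- schedule_windows(schedule)
  down <- window_dff(f, w$baseline_down, w$response_down)
  up <- window_dff(f, w$baseline_up, w$response_up)
  data.frame(
    dff_down = down$dff, dff_up = up$dff,
    baseline_mean_down = down$baseline_mean, baseline_mean_up = up$baseline_mean,
    baseline_sd_down = down$baseline_sd_dff, baseline_sd_up = up$baseline_sd_dff,
    significant_down = down$dff > 2 * down$baseline_sd_dff,
    significant_up = up$dff > 2 * up$baseline_sd_dff)
}

#' Directional selectivity (tuning) index
#'
#' The normalized difference of the nose-up and nose-down dFF responses,
#' `(up - down) / (up + down)`, after clamping each response below at zero.
#' Values span -1 to 1; positive values indicate nose-up selectivity,
#' negative nose-down. When both clamped responses are zero the index is
#' undefined and `NA` is returned.
#'
#' @param dff_up,dff_down dFF responses to each tilt direction.
#' @return numeric in `[-1, 1]`, or `NA` when undefined.
#' @examples
#' tuning_index(2, 0)    # 1: maximally nose-up selective
#' tuning_index(1, 1)    # 0: untuned
#' @export
tuning_index <- function(dff_up, dff_down) {
  if (all(is.na(c(dff_up, dff_down))))
    stop("both dFF inputs are NA", call. = FALSE)
  up <- pmax(dff_up, 0)
  down <- pmax(dff_down, 0)
  ifelse(up + down == 0, NA_real_, (up - down) / (up + down))
}

#' Classify a neuron's tilt subtype
#'
#' Applies the directional-selectivity rule: `nose_up` when the tuning index
#' is at least 0.1 and the nose-up response is significant, `nose_down` when
#' the index is at most -0.1 and the nose-down response is significant, and
#' `untuned` otherwise (including an undefined index or no significant
#' response in the preferred direction).
#'
#' @param index tuning index (may be `NA`).
#' @param significant_up,significant_down logical significance calls.
#' @param threshold minimum absolute index for a directional label
#'   (default 0.1).
#' @return character: `"nose_up"`, `"nose_down"` or `"untuned"`.
#' @export
classify_subtype <- function(index, significant_up, significant_down,
                             threshold = 0.1) {
  n <- length(index)
  out <- rep("untuned", n)
  ok <- !is.na(index)
  out[ok & index >= threshold & significant_up] <- "nose_up"
  out[ok & index <= -threshold & significant_down] <- "nose_down"
  out
}

#' Score one impulse trace
#'
#' Computes the dFF response in the first second after each of the two
#' impulses against the 20-s pre-impulse baseline. A neuron is responsive
#' when either impulse response exceeds twice the baseline SD (dFF units).
#' The impulse selectivity index pairs the first impulse as numerator:
#' `tuning_index(dff_1, dff_2)`.
#'
#' @param f numeric vector of ROI-normalized fluorescence.
#' @param schedule an [impulse_schedule()].
#' @return one-row data.frame: `dff_1`, `dff_2`, `dff_mean`,
#'   `baseline_sd` (dFF units), `responsive`,
#'   `impulse_tuning_index`.
#' @export
extract_impulse_response <- function(f, schedule) {
  if (!inherits(schedule, "tilt_schedule") || schedule$type != "impulse")
    stop("`schedule` must be an impulse tilt_schedule", call. = FALSE)
  if (length(f) != schedule$n_frames)
    stop(sprintf("trace has %d frames but schedule expects %d",
                 length(f), schedule$n_frames), call. = FALSE)
  w <- schedule_windows(schedule)
  r1 <- window_dff(f, w$baseline, w$response_1)
  r2 <- window_dff(f, w$baseline, w$response_2)
  sd_dff <- r1$baseline_sd_dff
  data.frame(
    dff_1 = r1$dff, dff_2 = r2$dff, dff_mean = mean(c(r1$dff, r2$dff)),
    baseline_sd = sd_dff,
    responsive = r1$dff > 2 * sd_dff | r2$dff > 2 * sd_dff,
    impulse_tuning_index = tuning_index(r1$dff, r2$dff))
}

#' Aggregate per-repeat tonic scores
#'
#' Averages dFF responses and baseline SDs over stimulus repeats, then
#' recomputes significance, the tuning index and the subtype label on the
#' aggregated values.
#'
#' @param scores data.frame of per-repeat scores as from
#'   [extract_tonic_response()] (>= 1 row).
#' @param threshold subtype threshold passed to [classify_subtype()].
#' @return one-row data.frame with aggregated `dff_down`, `dff_up`,
#'   `baseline_sd_down`, `baseline_sd_up`, recomputed `significant_*`,
#'   `tuning_index` and `subtype`.
#' @export
aggregate_repeats <- function(scores, threshold = 0.1) {
  if (!is.data.frame(scores) || nrow(scores) < 1L)
    stop("`scores` must contain at least one repeat", call. = FALSE)
  dff_down <- mean(scores$dff_down)
  dff_up <- mean(scores$dff_up)
  sd_down <- mean(scores$baseline_sd_down)
  sd_up <- mean(scores$baseline_sd_up)
  sig_down <- dff_down > 2 * sd_down
  sig_up <- dff_up > 2 * sd_up
  idx <- tuning_index(dff_up, dff_down)
  data.frame(
    dff_down = dff_down, dff_up = dff_up,
    baseline_sd_down = sd_down, baseline_sd_up = sd_up,
    significant_down = sig_down, significant_up = sig_up,
    tuning_index = idx,
    subtype = classify_subtype(idx, sig_up, sig_down, threshold),
    stringsAsFactors = FALSE)
}

# Split a (raw or normalized) trace table into per-neuron, per-repeat frame
# vectors plus metadata; normalizes by ROI size if not yet done.
prepare_traces <- function(traces, schedule) {
  if (!isTRUE(attr(traces, "roi_normalized")))
    traces <- normalize_trace(traces)
  need <- c("neuron_id", "repeat_index", "frame", "f")
  if (!all(need %in% names(traces)))
    stop("trace table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(traces$fish_id)) traces$fish_id <- NA_character_
  if (is.null(traces$genotype)) traces$genotype <- NA_character_
  traces <- traces[order(traces$neuron_id, traces$repeat_index,
                         traces$frame), ]
  split(traces, list(traces$neuron_id, traces$repeat_index), drop = TRUE)
}

#' Score a full table of tonic traces
#'
#' Runs the per-repeat tonic scoring and repeat aggregation over a
#' long-format trace table, producing one classified row per neuron.
#'
#' @param traces long-format trace table (raw or ROI-normalized).
#' @param schedule a [tonic_schedule()]; its frame rate must match the data.
#' @param threshold subtype threshold (default 0.1).
#' @return a `tilt_scores` data.frame: `neuron_id`, `fish_id`, `genotype`,
#'   aggregated responses, significance flags, `tuning_index`, `subtype`.
#' @examples
#' sim <- simulate_tonic_traces(sim_config(seed = 1, n_fish_per_genotype = 1,
#'                                         n_neurons_per_fish = 4))
#' score_tilt_traces(sim$traces, sim$schedule)
#' @export
score_tilt_traces <- function(traces, schedule = tonic_schedule(),
                              threshold = 0.1) {
  pieces <- prepare_traces(traces, schedule)
  per_rep <- lapply(pieces, function(d) {
    cbind(data.frame(neuron_id = d$neuron_id[1],
                     fish_id = d$fish_id[1], genotype = d$genotype[1],
                     repeat_index = d$repeat_index[1],
                     stringsAsFactors = FALSE),
          extract_tonic_response(d$f, schedule))
  })
  per_rep <- do.call(rbind, per_rep)
  rownames(per_rep) <- NULL
  agg <- lapply(split(per_rep, per_rep$neuron_id), function(s) {
    cbind(s[1, c("neuron_id", "fish_id", "genotype")],
          aggregate_repeats(s, threshold))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  structure(out, class = c("tilt_scores", "data.frame"),
            per_repeat = per_rep, stimulus = "tonic")
}

#' Score a full table of impulse traces
#'
#' Per-repeat impulse scoring and aggregation (means over repeats of the
#' per-impulse responses and baseline SD; responsiveness and the impulse
#' selectivity index recomputed on the aggregated values).
#'
#' @inheritParams score_tilt_traces
#' @param schedule an [impulse_schedule()].
#' @return a `tilt_scores` data.frame with `dff_1`, `dff_2`, `dff_mean`,
#'   `responsive` and `impulse_tuning_index` per neuron.
#' @export
score_impulse_traces <- function(traces, schedule = impulse_schedule()) {
  pieces <- prepare_traces(traces, schedule)
  per_rep <- lapply(pieces, function(d) {
    cbind(data.frame(neuron_id = d$neuron_id[1],
                     fish_id = d$fish_id[1], genotype = d$genotype[1],
                     repeat_index = d$repeat_index[1],
                     stringsAsFactors = FALSE),
          extract_impulse_response(d$f, schedule))
  })
  per_rep <- do.call(rbind, per_rep)
  rownames(per_rep) <- NULL
  agg <- lapply(split(per_rep, per_rep$neuron_id), function(s) {
    dff_1 <- mean(s$dff_1); dff_2 <- mean(s$dff_2)
    sd_dff <- mean(s$baseline_sd)
    cbind(s[1, c("neuron_id", "fish_id", "genotype")],
          data.frame(dff_1 = dff_1, dff_2 = dff_2,
                     dff_mean = mean(c(dff_1, dff_2)), baseline_sd = sd_dff,
                     responsive = dff_1 > 2 * sd_dff | dff_2 > 2 * sd_dff,
                     impulse_tuning_index = tuning_index(dff_1, dff_2)))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  structure(out, class = c("tilt_scores", "data.frame"),
            per_repeat = per_rep, stimulus = "impulse")
}

#' @export
print.tilt_scores <- function(x, ...) {
  cat(sprintf("<tilt_scores: %s stimulus, %d neurons>\n",
              attr(x, "stimulus"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more neurons\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.tilt_scores <- function(object, ...) {
  if (identical(attr(object, "stimulus"), "tonic")) {
    tab <- table(object$subtype)
    cat("Subtype counts (proportions):\n")
    print(round(cbind(n = tab, prop = prop.table(tab)), 3))
    cat(sprintf("mean dFF nose-up %.3f, nose-down %.3f\n",
                mean(object$dff_up), mean(object$dff_down)))
  } else {
    cat(sprintf("responsive: %d / %d (%.1f%%)\n", sum(object$responsive),
                nrow(object), 100 * mean(object$responsive)))
    cat(sprintf("mean impulse dFF %.3f, mean selectivity index %.3f\n",
                mean(object$dff_mean),
                mean(object$impulse_tuning_index, na.rm = TRUE)))
  }
  invisible(object)
}
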