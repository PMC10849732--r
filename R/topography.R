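#' Standardize soma coordinates to an origin convention
#'
#' Expresses raw coordinates (um) as offsets from an anatomical origin:
#' either the dorsomedial-most point of the tangential nucleus
#' (`"tangential_dorsomedial"`) or the corner of the standard-sized
#' rectangular box used for the extraocular motor nuclei
#' (`"niii_box_corner"`). Translating all raw inputs and the origin landmark
#' by the same offset leaves the standardized output unchanged.
#'
#' @param positions data.frame with columns `x_um`, `y_um`, `z_um` (other
#'   columns pass through).
#' @param origin numeric length-3 landmark coordinates `c(x, y, z)` in the
#'   same raw frame.
#' @param convention origin convention label.
#' @return `positions` with coordinates re-expressed relative to `origin`.
#' @examples
#' p <- data.frame(neuron_id = "a", x_um = 15, y_um = 17, z_um = 12)
#' standardize_coordinates(p, origin = c(10, 10, 10))
#' @export
standardize_coordinates <- function(positions,
                                    origin = c(0, 0, 0),
                                    convention = c("tangential_dorsomedial",
                                                   "niii_box_corner")) {
  convention <- match.arg(convention)
  if (!is.data.frame(positions) || nrow(positions) == 0L)
    stop("`positions` must be a non-empty data.frame", call. = FALSE)
  cols <- c("x_um", "y_um", "z_um")
  if (!all(cols %in% names(positions)))
    stop("`positions` must have columns x_um, y_um, z_um", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be three finite coordinates", call. = FALSE)
  if (!all(is.finite(as.matrix(positions[cols]))))
    stop("coordinates must be finite", call. = FALSE)
  positions[cols] <- sweep(as.matrix(positions[cols]), 2, origin)
  attr(positions, "origin_convention") <- convention
  positions
}

#' Assign dorsoventral section indices
#'
#' Bins dorsoventral depths into eight sections bounded by `boundaries`
#' (nine strictly increasing values: the dorsal limit, seven internal cut
#' points, and the ventral limit). Bins are half-open `[b_i, b_{i+1})`, so a
#' depth exactly on an internal boundary is assigned to the deeper
#' (higher-index) section. Depths outside the bounded range are an error.
#'
#' @param z numeric dorsoventral depths (um, growing ventrally).
#' @param boundaries strictly increasing numeric of length 9.
#' @return integer section indices in `1..8`.
#' @examples
#' assign_dv_section(c(0, 39), seq(0, 40, by = 5))   # 1 and 8
#' @export
assign_dv_section <- function(z, boundaries) {
  if (length(boundaries) != 9L || any(diff(boundaries) <= 0))
    stop("`boundaries` must be 9 strictly increasing values (7 internal cuts)",
         call. = FALSE)
  if (any(!is.finite(z)))
    stop("depths must be finite", call. = FALSE)
  if (any(z < boundaries[1] | z >= boundaries[9]))
    stop("depth outside the sectioned range [",
         boundaries[1], ", ", boundaries[9], ")", call. = FALSE)
  findInterval(z, boundaries)
}

#' Bootstrap a spatial probability distribution
#'
#' Resamples a one-axis coordinate sample with replacement `n_iterations`
#' times (default 100), bins each resample into a common set of equal-width
#' bins, and returns the per-bin mean and standard deviation of the binned
#' probability densities. Each iteration's density integrates to 1.
#'
#' @param values numeric coordinates along one axis (>= 2 values).
#' @param n_iterations number of bootstrap resamples (default 100).
#' @param seed integer seed for reproducibility.
#' @param n_bins number of equal-width bins (default 20) over `range`.
#' @param range bin range; defaults to the sample range (degenerate ranges
#'   are widened symmetrically by half a unit).
#' @param axis label stored with the result.
#' @return object of class `bootstrap_distribution`: list with `breaks`,
#'   `mids`, `mean_density`, `sd_density`, `n_iterations`, `seed`, `axis`,
#'   and `sample_mean`/`boot_means` diagnostics.
#' @export
bootstrap_distribution <- function(values, n_iterations = 100L, seed = 1L,
                                   n_bins = 20L, range = NULL, axis = "z") {
  if (length(values) < 2L)
    stop("need at least 2 values to bootstrap", call. = FALSE)
  if (n_iterations < 1L)
    stop("`n_iterations` must be at least 1", call. = FALSE)
  if (is.null(range)) range <- base::range(values)
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  width <- diff(breaks)[1]
  n <- length(values)
  dens <- matrix(0, nrow = n_iterations, ncol = n_bins)
  boot_means <- numeric(n_iterations)
  with_sim_seed(seed, 0L, {
    for (i in seq_len(n_iterations)) {
      v <- values[sample.int(n, n, replace = TRUE)]
      boot_means[i] <- mean(v)
      counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                      all.inside = TRUE), nbins = n_bins)
      dens[i, ] <- counts / (n * width)
    }
  })
  structure(
    list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
         mean_density = colMeans(dens), sd_density = apply(dens, 2, stats::sd),
         n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         axis = axis, sample_mean = mean(values), boot_means = boot_means),
    class = "bootstrap_distribution")
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_distribution: axis %s, %d iterations, %d bins over [%.3g, %.3g]>\n",
    x$axis, x$n_iterations, length(x$mids), min(x$breaks), max(x$breaks)))
  invisible(x)
}

#' @export
plot.bootstrap_distribution <- function(x, ...) {
  up <- x$mean_density + x$sd_density
  lo <- pmax(x$mean_density - x$sd_density, 0)
  graphics::plot(x$mids, x$mean_density, type = "l",
                 xlab = sprintf("%s (um)", x$axis), ylab = "density",
                 ylim = c(0, max(up)), ...)
  graphics::polygon(c(x$mids, rev(x$mids)), c(up, rev(lo)),
                    col = grDevices::adjustcolor("grey40", 0.3), border = NA)
  invisible(x)
}

#' Per-axis Kolmogorov-Smirnov comparison
#'
#' Two-tailed, two-sample KS test of one coordinate axis between two groups
#' (asymptotic p-value). `D` is the supremum difference of the two empirical
#' CDFs.
#'
#' @param group_a,group_b numeric samples (>= 2 observations each).
#' @return list with `D` and `p_value`.
#' @export
ks_axis_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("both groups need at least 2 observations", call. = FALSE)
  res <- suppressWarnings(stats::ks.test(group_a, group_b,
                                         alternative = "two.sided",
                                         exact = FALSE))
  list(D = unname(res$statistic), p_value = unname(res$p.value))
}

#' MANOVA test of spatial separation between groups
#'
#' One-way multivariate analysis of variance of soma coordinates with group
#' as the factor. The default statistic is Wilks' lambda with its F
#' approximation; Pillai's trace is available. Lambda equals 1 exactly when
#' the group mean vectors coincide (zero between-group scatter).
#'
#' @param positions data.frame containing the coordinate columns and a
#'   grouping column.
#' @param group name of the grouping column (or a vector of labels).
#' @param axes coordinate column names (default `x_um`, `y_um`, `z_um`).
#' @param statistic `"Wilks"` (default) or `"Pillai"`.
#' @return list with `statistic` (lambda or Pillai trace), `approx_F`,
#'   `df`, and `p_value`.
#' @export
manova_separation <- function(positions, group = "subtype",
                              axes = c("x_um", "y_um", "z_um"),
                              statistic = c("Wilks", "Pillai")) {
  statistic <- match.arg(statistic)
  g <- if (length(group) == 1L && is.character(group)) {
    if (!group %in% names(positions))
      stop("grouping column `", group, "` not found", call. = FALSE)
    factor(positions[[group]])
  } else factor(group)
  if (nlevels(g) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (!all(axes %in% names(positions)))
    stop("missing coordinate columns: ",
         paste(setdiff(axes, names(positions)), collapse = ", "),
         call. = FALSE)
  Y <- as.matrix(positions[axes])
  if (min(table(g)) <= length(axes))
    stop("each group needs more observations than axes", call. = FALSE)
  fit <- stats::manova(Y ~ g)
  sm <- tryCatch(summary(fit, test = statistic)$stats,
                 error = function(e)
                   stop("degenerate input: within-group scatter is singular; ",
                        "drop collinear axes or add observations",
                        call. = FALSE))
  list(statistic = unname(sm[1, 2]), approx_F = unname(sm[1, 3]),
       df = unname(sm[1, 4:5]), p_value = unname(sm[1, 6]),
       test = statistic)
}

#' Pairwise rank-sum comparison of per-fish neuron counts
#'
#' Two-tailed Wilcoxon rank-sum tests between every pair of genotypes.
#' Exact p-values are used when both groups have at most 10 fish and no
#' ties; otherwise the tie-corrected normal approximation.
#'
#' @param counts numeric per-fish neuron counts.
#' @param genotype group label per fish.
#' @return data.frame with one row per genotype pair: `group_a`, `group_b`,
#'   `W`, `p_value`, `exact`.
#' @export
count_comparison <- function(counts, genotype) {
  g <- factor(genotype)
  if (nlevels(g) < 2L)
    stop("need at least two genotypes to compare", call. = FALSE)
  pairs <- utils::combn(levels(g), 2)
  out <- apply(pairs, 2, function(pr) {
    a <- counts[g == pr[1]]
    b <- counts[g == pr[2]]
    use_exact <- length(a) <= 10L && length(b) <= 10L &&
      !anyDuplicated(c(a, b))
    res <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = use_exact, correct = !use_exact))
    data.frame(group_a = pr[1], group_b = pr[2],
               W = unname(res$statistic), p_value = res$p.value,
               exact = use_exact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
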