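#' Per-gene detection fraction in a reference cluster
#'
#' Fraction of cells in an atlas cluster (default the projection-neuron
#' cluster) in which each gene is detected.
#'
#' @param atlas an [atlas_detection()].
#' @param cluster cluster label (default `"projection"`).
#' @return named numeric in `[0, 1]`, one value per gene.
#' @export
detection_fraction <- function(atlas, cluster = "projection") {
  if (!inherits(atlas, "atlas_detection"))
    stop("`atlas` must be an atlas_detection object", call. = FALSE)
  sel <- atlas$cluster == cluster
  if (!any(sel))
    stop("cluster `", cluster, "` is empty", call. = FALSE)
  frac <- Matrix::rowSums(atlas$detection[, sel, drop = FALSE]) / sum(sel)
  stats::setNames(as.numeric(frac), rownames(atlas$detection))
}

# Median-of-ratios size factors (the standard bulk normalization): per
# sample, the median across genes of the ratio to the gene's geometric mean,
# computed over genes expressed in every sample.
size_factors <- function(counts) {
  log_counts <- log(counts)
  log_geo <- rowMeans(log_counts)
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene is expressed in every sample; cannot normalize",
         call. = FALSE)
  apply(log_counts[use, , drop = FALSE], 2,
        function(lc) exp(stats::median(lc - log_geo[use])))
}

#' Two-group negative-binomial Wald test
#'
#' Per-gene differential expression between the two conditions of a
#' [count_matrix()]. Counts are normalized with median-of-ratios size
#' factors; per-gene NB dispersion is estimated by the method of moments on
#' normalized counts, pooled across the two groups, bounded below by the
#' across-gene median dispersion and by a floor of `1e-8` (the lower bound
#' keeps the Wald test calibrated when replicates are few);
#' the log2 fold change (second condition level over first) is computed from
#' normalized group means with a pseudocount of 0.5; and the Wald statistic
#' is the log2 fold change divided by its delta-method standard error, with
#' a two-sided p-value from the normal reference. Genes with all-zero counts
#' are excluded from testing and flagged.
#'
#' @param counts a [count_matrix()] with two condition levels and at least
#'   two samples per condition.
#' @param contrast optional character of length 2 giving the condition
#'   levels as `c(numerator, denominator)`; defaults to the factor's level
#'   order, so with the conventional labels the contrast is null vs
#'   sibling.
#' @return object of class `nb_de`: data.frame with one row per gene
#'   (`gene_id`, `base_mean`, `dispersion`, `log2_fold_change`, `se_lfc`,
#'   `wald_stat`, `p_value`, `all_zero`), with the size factors stored as an
#'   attribute.
#' @examples
#' sim <- simulate_counts_and_atlas(sim_config(seed = 2, n_genes = 50,
#'                                             atlas_n_cells = 20))
#' head(nb_wald_test(sim$counts))
#' @export
nb_wald_test <- function(counts, contrast = NULL) {
  if (!inherits(counts, "count_matrix"))
    stop("`counts` must be a count_matrix", call. = FALSE)
  cond <- counts$condition
  if (nlevels(cond) != 2L)
    stop("exactly two condition levels are required", call. = FALSE)
  if (min(table(cond)) < 2L)
    stop("each condition needs at least 2 samples", call. = FALSE)
  if (is.null(contrast)) contrast <- levels(cond)
  if (!all(contrast %in% levels(cond)))
    stop("unknown contrast levels", call. = FALSE)
  k <- counts$counts
  sf <- size_factors(k)
  norm <- sweep(k, 2, sf, "/")

  num <- cond == contrast[1]
  den <- cond == contrast[2]
  n1 <- sum(num); n2 <- sum(den)
  m1 <- rowMeans(norm[, num, drop = FALSE])
  m2 <- rowMeans(norm[, den, drop = FALSE])
  v1 <- apply(norm[, num, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, den, drop = FALSE], 1, stats::var)

  # Method-of-moments dispersion, pooled across groups: for NB,
  # var = mu + alpha * mu^2, so alpha = (var - mu) / mu^2 per group,
  # averaged with df weights. With few replicates the per-gene estimate is
  # noisy and its low tail inflates Wald type-I error, so each gene is
  # bounded below by the across-gene median dispersion (a conservative
  # max-of-central-tendency rule) and by the 1e-8 floor.
  mom <- function(v, m) ifelse(m > 0, (v - m) / m^2, NA_real_)
  a1 <- mom(v1, m1); a2 <- mom(v2, m2)
  w1 <- n1 - 1; w2 <- n2 - 1
  alpha <- ifelse(
    is.na(a1) & is.na(a2), NA_real_,
    (ifelse(is.na(a1), 0, w1 * a1) + ifelse(is.na(a2), 0, w2 * a2)) /
      (ifelse(is.na(a1), 0, w1) + ifelse(is.na(a2), 0, w2)))
  central <- stats::median(alpha, na.rm = TRUE)
  if (!is.finite(central)) central <- 0
  alpha <- pmax(alpha, central, 1e-8)

  pc <- 0.5
  lfc <- log2(m1 + pc) - log2(m2 + pc)

  # Delta method: Var(log2(mean + pc)) ~= Var(mean) / ((mean + pc) ln 2)^2,
  # with Var(mean) from the NB variance function at the estimated dispersion.
  var_mean <- function(m, n) (m + alpha * m^2) / n
  se <- sqrt(var_mean(m1, n1) / ((m1 + pc) * log(2))^2 +
             var_mean(m2, n2) / ((m2 + pc) * log(2))^2)

  all_zero <- rowSums(k) == 0
  wald <- ifelse(all_zero | se == 0, NA_real_, lfc / se)
  p <- 2 * stats::pnorm(-abs(wald))

  out <- data.frame(
    gene_id = rownames(k), base_mean = (m1 + m2) / 2, dispersion = alpha,
    log2_fold_change = ifelse(all_zero, NA_real_, lfc), se_lfc = se,
    wald_stat = wald, p_value = p, all_zero = all_zero,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("nb_de", "data.frame"), size_factors = sf,
            contrast = contrast)
}

#' @export
print.nb_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("<nb_de: %d genes, log2FC = %s vs %s (%d all-zero excluded)>\n",
              nrow(x), ct[1], ct[2], sum(x$all_zero)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over a stated gene universe.
#' `NA` p-values (e.g. untested all-zero genes) are passed through and do
#' not count toward the universe size unless `m` says otherwise.
#'
#' @param p numeric p-values in `[0, 1]` (NA allowed).
#' @param m universe size; defaults to the number of non-missing p-values.
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, m = sum(!is.na(p))) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH", n = max(m, sum(!is.na(p))))
}

#' Build a differential-expression candidate table
#'
#' Combines an [nb_wald_test()] result (or any table with `gene_id`,
#' `log2_fold_change`, `p_value`) with reference detection fractions, BH
#' adjustment over the current universe, and the significance criteria
#' (adjusted p < `alpha` and |log2FC| > `lfc_cutoff`).
#'
#' @param de data.frame with `gene_id`, `log2_fold_change`, `p_value`.
#' @param detection named detection fractions from [detection_fraction()];
#'   genes absent from the atlas are assigned detection 0 and counted.
#' @param alpha adjusted-p significance level (default 0.05).
#' @param lfc_cutoff absolute log2 fold-change cutoff (default 2).
#' @return object of class `de_candidates`: per-gene `detection_fraction`,
#'   `p_adjusted`, `passes_significance`, plus the input columns.
#' @export
de_candidates <- function(de, detection = NULL, alpha = 0.05,
                          lfc_cutoff = 2) {
  out <- as.data.frame(de)
  if (!all(c("gene_id", "log2_fold_change", "p_value") %in% names(out)))
    stop("`de` must have gene_id, log2_fold_change and p_value",
         call. = FALSE)
  if (is.null(detection)) {
    if (is.null(out$detection_fraction))
      stop("supply `detection` or a detection_fraction column", call. = FALSE)
  } else {
    miss <- setdiff(out$gene_id, names(detection))
    if (length(miss))
      message(length(miss), " gene(s) absent from the atlas; detection set to 0")
    out$detection_fraction <- unname(detection[out$gene_id])
    out$detection_fraction[is.na(out$detection_fraction)] <- 0
  }
  out$p_adjusted <- bh_adjust(out$p_value)
  out$passes_significance <- !is.na(out$p_adjusted) &
    out$p_adjusted < alpha & abs(out$log2_fold_change) > lfc_cutoff
  structure(out, class = c("de_candidates", "data.frame"),
            alpha = alpha, lfc_cutoff = lfc_cutoff)
}

#' @export
print.de_candidates <- function(x, ...) {
  cat(sprintf("<de_candidates: %d genes, %d pass p_adj < %g & |log2FC| > %g>\n",
              nrow(x), sum(x$passes_significance, na.rm = TRUE),
              attr(x, "alpha"), attr(x, "lfc_cutoff")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

#' Apply a reference-atlas detection filter
#'
#' Restricts a candidate table to genes detected in at least `threshold`
#' percent of reference projection neurons, then recomputes the BH-adjusted
#' p-values and significance calls on the reduced universe (each filter
#' threshold defines its own analysis universe).
#'
#' @param candidates a [de_candidates()] table.
#' @param threshold detection threshold in percent, within `[0, 100]`.
#' @param readjust recompute the BH adjustment from raw p-values on the
#'   reduced universe (default). Set `FALSE` to keep existing `p_adjusted`
#'   values, e.g. for published tables that only print adjusted p-values.
#' @return filtered `de_candidates` with recomputed `p_adjusted` and
#'   `passes_significance`.
#' @export
apply_reference_filter <- function(candidates, threshold, readjust = TRUE) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 100)
    stop("`threshold` must be a percentage in [0, 100]", call. = FALSE)
  if (is.null(candidates$detection_fraction))
    stop("`candidates` lacks detection fractions", call. = FALSE)
  keep <- candidates$detection_fraction >= threshold / 100
  out <- candidates[keep, , drop = FALSE]
  if (readjust) out$p_adjusted <- bh_adjust(out$p_value)
  out$passes_significance <- !is.na(out$p_adjusted) &
    out$p_adjusted < attr(candidates, "alpha") &
    abs(out$log2_fold_change) > attr(candidates, "lfc_cutoff")
  rownames(out) <- NULL
  structure(out, class = class(candidates),
            alpha = attr(candidates, "alpha"),
            lfc_cutoff = attr(candidates, "lfc_cutoff"),
            threshold_pct = threshold)
}

#' Sweep the detection-filter threshold ladder
#'
#' For each threshold, restricts the gene universe to genes above the
#' detection fraction, re-runs the NB Wald test on that universe (default)
#' or reuses the full-universe statistics, re-adjusts p-values, and counts
#' genes passing the significance criteria.
#'
#' @param counts a [count_matrix()].
#' @param atlas an [atlas_detection()].
#' @param thresholds detection thresholds in percent
#'   (default `c(0, 1, 3, 5, 10, 30, 50)`).
#' @param alpha,lfc_cutoff significance criteria (defaults 0.05 and 2).
#' @param cluster atlas cluster supplying detection fractions.
#' @param retest if `TRUE` (default) the NB test is re-run on each filtered
#'   universe (dispersions and size factors re-estimated); if `FALSE` only
#'   the BH adjustment is redone on the subset.
#' @return data.frame with one row per threshold: `threshold_pct`,
#'   `universe_size`, `deg_count`.
#' @export
threshold_sweep <- function(counts, atlas,
                            thresholds = c(0, 1, 3, 5, 10, 30, 50),
                            alpha = 0.05, lfc_cutoff = 2,
                            cluster = "projection", retest = TRUE) {
  det <- detection_fraction(atlas, cluster)
  full <- nb_wald_test(counts)
  rows <- lapply(thresholds, function(th) {
    keep_genes <- names(det)[det >= th / 100]
    keep <- rownames(counts$counts) %in% keep_genes
    if (!any(keep))
      return(data.frame(threshold_pct = th, universe_size = 0L,
                        deg_count = 0L))
    de <- if (retest && th > 0) {
      sub <- count_matrix(counts$counts[keep, , drop = FALSE],
                          counts$condition)
      nb_wald_test(sub)
    } else {
      full[keep, , drop = FALSE]
    }
    cand <- de_candidates(de, det, alpha = alpha, lfc_cutoff = lfc_cutoff)
    data.frame(threshold_pct = th, universe_size = nrow(cand),
               deg_count = sum(cand$passes_significance, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
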