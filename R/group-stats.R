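#' One-way ANOVA with pairwise multiple comparisons
#'
#' One-way analysis of variance of a response metric across genotype groups
#' followed by pairwise comparisons: Tukey's honest significant difference
#' (default) or Bonferroni-adjusted pairwise t tests. Each pair is reported
#' with its adjusted p-value and Cohen's d.
#'
#' @param values numeric response values.
#' @param group group label per value (>= 2 groups, each with >= 2 values).
#' @param method `"tukey"` (default) or `"bonferroni"`.
#' @return list with `F`, `p_value`, `df`, and `pairwise` (data.frame:
#'   `group_a`, `group_b`, `diff`, `p_adjusted`, `cohens_d`).
#' @export
anova_multcomp <- function(values, group, method = c("tukey", "bonferroni")) {
  method <- match.arg(method)
  g <- factor(group)
  if (nlevels(g) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (min(table(g)) < 2L)
    stop("every group needs at least two values", call. = FALSE)
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  pairs <- utils::combn(levels(g), 2)
  d <- apply(pairs, 2, function(pr)
    cohens_d(values[g == pr[1]], values[g == pr[2]]))
  diffs <- apply(pairs, 2, function(pr)
    mean(values[g == pr[1]]) - mean(values[g == pr[2]]))
  padj <- if (method == "tukey") {
    tk <- stats::TukeyHSD(fit)$g
    key <- paste(pairs[2, ], pairs[1, ], sep = "-")   # TukeyHSD order
    unname(tk[key, "p adj"])
  } else {
    pt <- stats::pairwise.t.test(values, g, p.adjust.method = "bonferroni")
    mapply(function(a, b) {
      p <- pt$p.value
      if (b %in% rownames(p) && a %in% colnames(p) && !is.na(p[b, a]))
        p[b, a] else p[a, b]
    }, pairs[1, ], pairs[2, ], USE.NAMES = FALSE)
  }
  list(F = an[1, "F value"], p_value = an[1, "Pr(>F)"],
       df = unname(an[["Df"]]),
       pairwise = data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                             diff = diffs, p_adjusted = padj, cohens_d = d,
                             stringsAsFactors = FALSE))
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b numeric samples, each with at least 2 values.
#' @return signed effect size (antisymmetric in its arguments).
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    stop("both groups need at least 2 values", call. = FALSE)
  sp <- sqrt(((na - 1) * stats::var(group_a) +
              (nb - 1) * stats::var(group_b)) / (na + nb - 2))
  if (sp == 0)
    stop("degenerate input: pooled standard deviation is zero", call. = FALSE)
  (mean(group_a) - mean(group_b)) / sp
}

#' Group summaries of scored responses
#'
#' Mean, standard deviation and n of one or more response metrics per
#' group, shaped like the published genotype-comparison tables (rows are
#' metrics, one block of `mean`, `sd`, `n` per group).
#'
#' @param scores data.frame of per-neuron scores (e.g. a
#'   [score_tilt_traces()] result).
#' @param by grouping column name (default `"genotype"`).
#' @param metrics response columns to summarize; defaults to the numeric
#'   score columns present.
#' @return data.frame with columns `metric`, `group`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(scores, by = "genotype", metrics = NULL) {
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("`scores` must be a non-empty data.frame", call. = FALSE)
  if (!by %in% names(scores))
    stop("grouping column `", by, "` not found", call. = FALSE)
  if (is.null(metrics)) {
    known <- c("dff_up", "dff_down", "tuning_index", "dff_mean", "dff_1",
               "dff_2", "impulse_tuning_index")
    metrics <- intersect(known, names(scores))
    if (!length(metrics))
      metrics <- names(scores)[vapply(scores, is.numeric, logical(1))]
  }
  g <- factor(scores[[by]])
  rows <- lapply(metrics, function(m) {
    v <- scores[[m]]
    do.call(rbind, lapply(levels(g), function(lev) {
      vv <- v[g == lev & !is.na(v)]
      data.frame(metric = m, group = lev, n = length(vv),
                 mean = if (length(vv)) mean(vv) else NA_real_,
                 sd = if (length(vv) > 1) stats::sd(vv) else 0,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
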