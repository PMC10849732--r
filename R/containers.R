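#' Bulk count matrix with condition labels
#'
#' Lightweight container for a genes x samples matrix of non-negative
#' integer counts with a two-level condition label per sample (the DE
#' contrast is `null` vs `sibling`).
#'
#' @param counts integer matrix, genes in rows, samples in columns; must
#'   have row and column names.
#' @param condition character/factor of length `ncol(counts)`.
#' @return object of class `count_matrix`: list with `counts` and
#'   `condition` (factor).
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene row names and sample column names",
         call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene %s, sample %s",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (any(counts != round(counts)))
    stop("`counts` must be integer-valued", call. = FALSE)
  if (length(condition) != ncol(counts))
    stop("`condition` must label every sample", call. = FALSE)
  if (anyNA(condition)) stop("`condition` contains NA", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, condition = factor(as.character(condition))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix: %d genes x %d samples (%s)>\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", levels(x$condition),
                            tabulate(x$condition)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Reference single-cell detection atlas
#'
#' Binary genes x cells detection matrix with a cluster label per cell. The
#' `projection` cluster supplies the per-gene detection fractions used to
#' filter bulk DE candidates.
#'
#' @param detection genes x cells matrix (dense or `Matrix` sparse) with
#'   entries in `{0, 1}` and gene row names.
#' @param cluster character of length `ncol(detection)`.
#' @return object of class `atlas_detection`.
#' @export
atlas_detection <- function(detection, cluster) {
  if (is.null(rownames(detection)))
    stop("`detection` must have gene row names", call. = FALSE)
  # pattern/logical encodings (e.g. MatrixMarket pattern files) -> numeric
  if (inherits(detection, "nMatrix") || inherits(detection, "lMatrix") ||
      is.logical(detection))
    detection <- detection * 1
  vals <- if (inherits(detection, "sparseMatrix")) detection@x
          else as.numeric(detection)
  if (length(vals) && (any(vals < 0 | vals > 1) || any(vals %% 1 != 0)))
    stop("`detection` must be binary (0/1)", call. = FALSE)
  if (length(cluster) != ncol(detection))
    stop("`cluster` must label every cell", call. = FALSE)
  structure(list(detection = detection, cluster = as.character(cluster)),
            class = "atlas_detection")
}

#' @export
print.atlas_detection <- function(x, ...) {
  tab <- table(x$cluster)
  cat(sprintf("<atlas_detection: %d genes x %d cells; clusters: %s>\n",
              nrow(x$detection), ncol(x$detection),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.atlas_detection <- function(x) dim(x$detection)
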