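#' Read a bulk count matrix
#'
#' Accepts either a MatrixMarket directory (`counts.mtx` with `genes.tsv`
#' and `samples.tsv` sidecars, the latter with columns `sample_id` and
#' `condition`) or a wide tab-separated file whose first column is
#' `gene_id` and whose remaining columns are samples. For wide TSV input
#' the condition labels are taken from `condition` if given, otherwise
#' parsed from sample names of the form `<condition>_<replicate>`.
#'
#' @param path directory containing `counts.mtx`, or a `.tsv`/`.txt` file.
#' @param condition optional condition label per sample.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, condition = NULL) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "counts.mtx")
    genes <- file.path(path, "genes.tsv")
    samples <- file.path(path, "samples.tsv")
    for (f in c(mtx, genes, samples))
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    m <- as.matrix(Matrix::readMM(mtx))
    gene_id <- utils::read.delim(genes, header = FALSE,
                                 stringsAsFactors = FALSE)[[1]]
    smp <- utils::read.delim(samples, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "condition") %in% names(smp)))
      stop("samples.tsv needs columns sample_id and condition", call. = FALSE)
    if (nrow(m) != length(gene_id) || ncol(m) != nrow(smp))
      stop(sprintf("dimension mismatch: matrix %d x %d, %d genes, %d samples",
                   nrow(m), ncol(m), length(gene_id), nrow(smp)),
           call. = FALSE)
    dimnames(m) <- list(gene_id, smp$sample_id)
    count_matrix(m, smp$condition)
  } else if (file.exists(path)) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (names(tab)[1] != "gene_id")
      stop("wide TSV must start with a gene_id column", call. = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$gene_id
    if (is.null(condition))
      condition <- sub("_[^_]*$", "", colnames(m))
    count_matrix(m, condition)
  } else stop("path not found: ", path, call. = FALSE)
}

#' Write a bulk count matrix
#'
#' Writes either MatrixMarket + sidecars (when `format = "mtx"`, into a
#' directory) or a single wide TSV. [read_counts()] round-trips both.
#'
#' @param counts a [count_matrix()].
#' @param path output directory (mtx) or file (tsv).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(counts$counts, sparse = TRUE),
                    file.path(path, "counts.mtx"))
    writeLines(rownames(counts$counts), file.path(path, "genes.tsv"))
    utils::write.table(
      data.frame(sample_id = colnames(counts$counts),
                 condition = as.character(counts$condition)),
      file.path(path, "samples.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = rownames(counts$counts),
                      counts$counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a reference detection atlas
#'
#' Reads a MatrixMarket directory: `atlas.mtx` (binary genes x cells),
#' `genes.tsv`, and `cells.tsv` with columns `cell_id` and `cluster`.
#'
#' @param path directory.
#' @return an [atlas_detection()].
#' @export
read_atlas <- function(path) {
  mtx <- file.path(path, "atlas.mtx")
  genes <- file.path(path, "genes.tsv")
  cells <- file.path(path, "cells.tsv")
  for (f in c(mtx, genes, cells))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  m <- Matrix::readMM(mtx)
  gene_id <- utils::read.delim(genes, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
  cl <- utils::read.delim(cells, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% names(cl)))
    stop("cells.tsv needs columns cell_id and cluster", call. = FALSE)
  if (nrow(m) != length(gene_id) || ncol(m) != nrow(cl))
    stop("dimension mismatch between atlas.mtx and sidecars", call. = FALSE)
  dimnames(m) <- list(gene_id, cl$cell_id)
  atlas_detection(m, cl$cluster)
}

#' @rdname read_atlas
#' @param atlas an [atlas_detection()].
#' @export
write_atlas <- function(atlas, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(atlas$detection, "dMatrix"),
                  file.path(path, "atlas.mtx"))
  writeLines(rownames(atlas$detection), file.path(path, "genes.tsv"))
  utils::write.table(
    data.frame(cell_id = colnames(atlas$detection), cluster = atlas$cluster),
    file.path(path, "cells.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' Per-threshold pass flags for a candidate table
#'
#' For each detection threshold, a gene passes when it survives the filter
#' and meets the significance criteria recomputed on that threshold's
#' universe ([apply_reference_filter()]).
#'
#' @param candidates a [de_candidates()] table.
#' @param thresholds detection thresholds in percent.
#' @return logical matrix, genes x thresholds (columns `pass_<t>pct`).
#' @export
threshold_flags <- function(candidates,
                            thresholds = c(0, 1, 3, 5, 10, 30, 50)) {
  flags <- vapply(thresholds, function(th) {
    filt <- apply_reference_filter(candidates, th)
    candidates$gene_id %in% filt$gene_id[filt$passes_significance]
  }, logical(nrow(candidates)))
  flags <- matrix(flags, nrow = nrow(candidates))
  dimnames(flags) <- list(candidates$gene_id,
                          sprintf("pass_%gpct", thresholds))
  flags
}

#' Write a DE candidate table
#'
#' Tab-separated output of the candidate table with one boolean column per
#' detection threshold.
#'
#' @param candidates a [de_candidates()] table.
#' @param path output file.
#' @param thresholds thresholds for the per-threshold pass columns.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path,
                             thresholds = c(0, 1, 3, 5, 10, 30, 50)) {
  out <- cbind(as.data.frame(candidates),
               as.data.frame(threshold_flags(candidates, thresholds)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write long-format trace tables
#'
#' CSV with one row per frame per neuron per repeat (columns `neuron_id`,
#' `fish_id`, `genotype`, `repeat_index`, `roi_size`, `frame`, `f`).
#'
#' @param traces trace table; @param path file path.
#' @return the table (read) or `path` invisibly (write).
#' @export
read_traces <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "repeat_index", "roi_size", "frame", "f")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trace CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  attr(tr, "roi_normalized") <- FALSE
  tr
}

#' @rdname read_traces
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write soma coordinate tables
#'
#' CSV with columns `neuron_id`, `genotype`, a label column (`subtype` or
#' `responsive`), and `x_um`, `y_um`, `z_um`.
#'
#' @param positions coordinate table; @param path file path.
#' @return the table (read) or `path` invisibly (write).
#' @export
read_positions <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("coordinate CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  p
}

#' @rdname read_positions
#' @export
write_positions <- function(positions, path) {
  utils::write.csv(positions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
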