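#' Worked-example candidate tables
#'
#' Small tab-separated tables bundled with the package, transcribed from a
#' published comparison of vestibular projection-neuron transcriptomes
#' between phox2a null mutants and sibling controls:
#'
#' \describe{
#'   \item{`example_candidate_table()`}{the differentially expressed
#'     candidates surviving the 1\% reference filter, with each gene's
#'     detection percentage in the reference projection-neuron cluster,
#'     log2 fold change, and adjusted p-value. Because only adjusted
#'     p-values are printed, the table is loaded with
#'     `p_value = NA`; use [apply_reference_filter()] with
#'     `readjust = FALSE` on it.}
#'   \item{`example_insitu_candidates()`}{the eight candidate genes
#'     evaluated by in situ hybridization, with printed log2 fold change
#'     and adjusted p-value.}
#' }
#'
#' @return a [de_candidates()] table (`example_candidate_table`) or a plain
#'   data.frame (`example_insitu_candidates`).
#' @examples
#' cand <- example_candidate_table()
#' # no candidate reaches 10% detection in the reference cluster:
#' nrow(apply_reference_filter(cand, 10, readjust = FALSE))
#' @export
example_candidate_table <- function() {
  path <- system.file("extdata", "projection_de_candidates.tsv",
                      package = "tiltseq", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(
    gene_id = tab$gene, direction = tab$direction,
    log2_fold_change = tab$log2_fold_change,
    p_value = NA_real_,
    p_adjusted = tab$p_adjusted,
    detection_fraction = tab$detection_pct / 100,
    stringsAsFactors = FALSE)
  out$passes_significance <- out$p_adjusted < 0.05 &
    abs(out$log2_fold_change) > 2
  structure(out, class = c("de_candidates", "data.frame"),
            alpha = 0.05, lfc_cutoff = 2)
}

#' @rdname example_candidate_table
#' @export
example_insitu_candidates <- function() {
  path <- system.file("extdata", "insitu_candidates.tsv",
                      package = "tiltseq", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
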