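# Pool 1: genes with a significant level of active transcription in at
# least one of the four non-input samples.

#' Configuration for the active-transcription filter
#'
#' A gene is kept if its maximal non-input average peak value exceeds
#' `min_peak` or exceeds the input-sample peak, and (when `require_sicer`
#' is TRUE) at least one non-input sample carries a significant SICER
#' call.  Genes absent from the SICER-analyzed universe should carry
#' all-FALSE flags and are thereby removed.
#'
#' @param min_peak Threshold on the average peak value (strictly above).
#' @param require_sicer Require >= 1 significant SICER call.
#' @return An `active_filter_config` list.
#' @export
active_filter_config <- function(min_peak = 0.5, require_sicer = TRUE) {
  stopifnot(is.numeric(min_peak), length(min_peak) == 1L, min_peak > 0)
  structure(list(min_peak = min_peak,
                 require_sicer = isTRUE(require_sicer)),
            class = "active_filter_config")
}

#' Is a gene actively transcribed in at least one sample?
#'
#' Vectorized over the rows of a peak table.
#'
#' @param tbl A validated peak table.
#' @param config An [active_filter_config()].
#' @return Logical vector, one element per row of `tbl`.
#' @export
is_active <- function(tbl, config = active_filter_config()) {
  validate_peak_table(tbl)
  max_signal <- pmax(tbl$wt, tbl$ko, tbl$wt_pj34, tbl$ko_pj34)
  keep <- (max_signal > config$min_peak) | (max_signal > tbl$input)
  if (config$require_sicer)
    keep <- keep &
      (tbl$sig_wt | tbl$sig_ko | tbl$sig_wt_pj34 | tbl$sig_ko_pj34)
  keep
}

#' Build Pool 1 (actively transcribed genes)
#'
#' @param tbl A validated peak table with unique gene ids.
#' @param config An [active_filter_config()].
#' @return Character vector of Pool 1 gene ids, with a `summary`
#'   attribute `list(n_input, n_pool1)`.
#' @export
build_pool1 <- function(tbl, config = active_filter_config()) {
  keep <- is_active(tbl, config)
  genes <- tbl$gene_id[keep]
  message(sprintf("Pool 1: %d of %d genes show active transcription",
                  length(genes), nrow(tbl)))
  structure(genes,
            summary = list(n_input = nrow(tbl), n_pool1 = length(genes)))
}
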