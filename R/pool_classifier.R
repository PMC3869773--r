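# The fold-change decision tree that splits Pool 1 into the dependence
# categories:
#   Pool 2 - PARP-14-dependent (positively or negatively regulated);
#   Pool 3 - dependent on PARP-14 and ART activity;
#   Pool 4 - independent of ART activity;
#   Pool 5 - dependent on the ART activity of PARP-14 only;
#   Pool 6 - dependent on ART activity of PARP-14 and/or other PARPs.
# All decisions are pure ratio thresholds on average peak values; no
# statistical test is involved.

#' Classifier configuration
#'
#' Thresholds for the dependence decision tree.  A gene is positively
#' regulated by PARP-14 when the WT/KO peak ratio exceeds `up_ratio`, or
#' falls in the rescue band `band_up` while either sample's peak exceeds
#' `band_min_peak`; negative regulation mirrors this with `down_ratio` and
#' `band_down`.  `no_change_band` is the ratio interval treated as "no
#' significant difference" for the two PJ34 comparisons.  Band endpoint
#' semantics (they matter only on exact ties): the no-change band
#' `[0.83, 1.2]` is closed and dominant, so the rescue bands are the
#' open intervals `(1.2, 1.4)` and `(0.7, 0.83)` -- a WT/KO ratio of
#' exactly 1.2 or 0.83 is "no change", and the unconditional thresholds
#' stay strict (`> 1.4`, `< 0.7`).
#'
#' @param up_ratio WT/KO ratio above which a gene is positively regulated.
#' @param down_ratio WT/KO ratio below which a gene is negatively regulated.
#' @param band_up,band_down Rescue bands (length-2 numeric intervals).
#' @param band_min_peak Minimal peak (in either sample) for band rescue.
#' @param no_change_band Closed ratio interval meaning "no change".
#' @param pseudocount Added to both terms of a ratio when the denominator
#'   is zero.
#' @param require_sicer_on_higher Require the sample with the higher
#'   signal (WT for positive calls, KO for negative) to carry a
#'   significant SICER call.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(up_ratio = 1.4, down_ratio = 0.7,
                              band_up = c(1.2, 1.4),
                              band_down = c(0.7, 0.83),
                              band_min_peak = 2,
                              no_change_band = c(0.83, 1.2),
                              pseudocount = 0.01,
                              require_sicer_on_higher = TRUE) {
  ok <- 0 < down_ratio && down_ratio <= band_down[1L] &&
    band_down[2L] <= no_change_band[1L] && no_change_band[1L] < 1 &&
    1 < no_change_band[2L] && no_change_band[2L] <= band_up[1L] &&
    band_up[2L] <= up_ratio
  if (!ok)
    .stop_fmt("thresholds must satisfy 0 < down_ratio <= band_down <= no_change_band < 1 < no_change_band <= band_up <= up_ratio")
  stopifnot(pseudocount > 0, band_min_peak > 0)
  structure(list(up_ratio = up_ratio, down_ratio = down_ratio,
                 band_up = band_up, band_down = band_down,
                 band_min_peak = band_min_peak,
                 no_change_band = no_change_band,
                 pseudocount = pseudocount,
                 require_sicer_on_higher = isTRUE(require_sicer_on_higher)),
            class = "classifier_config")
}

#' Ratio of two peak values with zero-denominator protection
#'
#' Returns `numerator / denominator`, except that when the denominator is
#' zero the pseudocount is added to both terms, keeping the result finite
#' and strictly positive.
#'
#' @param numerator,denominator Non-negative peak values (vectorized).
#' @param pseudocount Positive value added to both terms when the
#'   denominator is zero.
#' @return Numeric vector of ratios.
#' @export
compute_ratio <- function(numerator, denominator, pseudocount = 0.01) {
  if (any(numerator < 0) || any(denominator < 0))
    .stop_fmt("peak values must be non-negative")
  stopifnot(pseudocount > 0)
  c0 <- ifelse(denominator == 0, pseudocount, 0)
  (numerator + c0) / (denominator + c0)
}

.in_band <- function(x, band) x >= band[1L] & x <= band[2L]

#' Classify PARP-14 dependence (the Pool 2 decision)
#'
#' With `r = WT/KO`: positive if `r > up_ratio`, or `r` in `(1.2, 1.4)`
#' with `max(WT, KO) > band_min_peak`; negative if `r < down_ratio`, or
#' `r` in `(0.7, 0.83)` with the same peak condition; otherwise none.
#' When `require_sicer_on_higher` is set, a positive call additionally
#' requires the WT SICER flag and a negative call the KO flag.
#'
#' @param tbl A validated peak table (rows assumed to be Pool 1 members).
#' @param config A [classifier_config()].
#' @return Character vector in `{"positive", "negative", "none"}`.
#' @export
classify_parp14_dependence <- function(tbl, config = classifier_config()) {
  validate_peak_table(tbl)
  r <- compute_ratio(tbl$wt, tbl$ko, config$pseudocount)
  peak_hi <- pmax(tbl$wt, tbl$ko)
  pos <- r > config$up_ratio |
    (r > config$band_up[1L] & r < config$band_up[2L] &
       peak_hi > config$band_min_peak)
  neg <- r < config$down_ratio |
    (r > config$band_down[1L] & r < config$band_down[2L] &
       peak_hi > config$band_min_peak)
  if (config$require_sicer_on_higher) {
    pos <- pos & tbl$sig_wt
    neg <- neg & tbl$sig_ko
  }
  ifelse(pos, "positive", ifelse(neg, "negative", "none"))
}

#' Classify ART dependence (the Pool 3 / Pool 4 split)
#'
#' A Pool 2 gene is ART-independent (Pool 4) when the WT / WT+PJ34 ratio
#' lies in the no-change band; otherwise it is Pool 3.
#'
#' @param tbl A validated peak table restricted to Pool 2 genes.
#' @param sign The `classify_parp14_dependence()` result for these rows;
#'   calling this on a "none" gene is a contract error.
#' @param config A [classifier_config()].
#' @return Character vector in `{"pool3", "pool4"}`.
#' @export
classify_art_dependence <- function(tbl, sign, config = classifier_config()) {
  if (any(sign == "none"))
    .stop_fmt("classify_art_dependence() called on a gene not in Pool 2")
  r <- compute_ratio(tbl$wt, tbl$wt_pj34, config$pseudocount)
  ifelse(.in_band(r, config$no_change_band), "pool4", "pool3")
}

#' Classify PARP-14-specific ART dependence (the Pool 5 / Pool 6 split)
#'
#' A Pool 3 gene depends on the ART activity of PARP-14 only (Pool 5)
#' when the KO / KO+PJ34 ratio lies in the no-change band; otherwise ART
#' activity of other PARPs is implicated (Pool 6).
#'
#' @param tbl A validated peak table restricted to Pool 3 genes.
#' @param pool34 The [classify_art_dependence()] result for these rows;
#'   calling this on a Pool 4 gene is a contract error.
#' @param config A [classifier_config()].
#' @return Character vector in `{"pool5", "pool6"}`.
#' @export
classify_parp14_specific_art <- function(tbl, pool34,
                                         config = classifier_config()) {
  if (any(pool34 != "pool3"))
    .stop_fmt("classify_parp14_specific_art() called on a gene not in Pool 3")
  r <- compute_ratio(tbl$ko, tbl$ko_pj34, config$pseudocount)
  ifelse(.in_band(r, config$no_change_band), "pool5", "pool6")
}

#' Assign every gene to the Pools 1-6 decision tree
#'
#' Runs the active-transcription filter and the full dependence decision
#' tree over a peak table.  The ART classifications are computed only for
#' Pool 2 genes, mirroring the nested construction of the pools.
#'
#' @param tbl A validated peak table with unique gene ids.
#' @param active_config An [active_filter_config()].
#' @param config A [classifier_config()].
#' @return data.frame with one row per input gene: `gene_id`,
#'   `in_pool1` .. `in_pool6`, `regulation_sign` and the three decision
#'   ratios `wt_ko_ratio`, `wt_wtpj_ratio`, `ko_kopj_ratio`.  A `summary`
#'   attribute carries the pool sizes and the sign split (see
#'   [pool_summary()]).
#' @export
assign_pools <- function(tbl,
                         active_config = active_filter_config(),
                         config = classifier_config()) {
  validate_peak_table(tbl)
  pool1 <- is_active(tbl, active_config)

  wt_ko <- compute_ratio(tbl$wt, tbl$ko, config$pseudocount)
  wt_wtpj <- compute_ratio(tbl$wt, tbl$wt_pj34, config$pseudocount)
  ko_kopj <- compute_ratio(tbl$ko, tbl$ko_pj34, config$pseudocount)

  sign <- rep("none", nrow(tbl))
  sign[pool1] <- classify_parp14_dependence(tbl[pool1, , drop = FALSE],
                                            config)
  pool2 <- pool1 & sign != "none"
  pool4 <- pool2 & .in_band(wt_wtpj, config$no_change_band)
  pool3 <- pool2 & !pool4
  pool5 <- pool3 & .in_band(ko_kopj, config$no_change_band)
  pool6 <- pool3 & !pool5

  out <- data.frame(gene_id = tbl$gene_id,
                    in_pool1 = pool1, in_pool2 = pool2, in_pool3 = pool3,
                    in_pool4 = pool4, in_pool5 = pool5, in_pool6 = pool6,
                    regulation_sign = sign,
                    wt_ko_ratio = wt_ko,
                    wt_wtpj_ratio = wt_wtpj,
                    ko_kopj_ratio = ko_kopj,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- pool_summary(out)
  out
}

#' Summarize a pool assignment
#'
#' @param assignments data.frame as returned by [assign_pools()].
#' @return Named integer vector with the six pool sizes and the
#'   positive/negative split.
#' @export
pool_summary <- function(assignments) {
  c(n_pool1 = sum(assignments$in_pool1),
    n_pool2 = sum(assignments$in_pool2),
    n_pool3 = sum(assignments$in_pool3),
    n_pool4 = sum(assignments$in_pool4),
    n_pool5 = sum(assignments$in_pool5),
    n_pool6 = sum(assignments$in_pool6),
    n_positive = sum(assignments$regulation_sign == "positive"),
    n_negative = sum(assignments$regulation_sign == "negative"))
}
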