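# Hypergeometric enrichment, fold enrichment and Benjamini-Hochberg
# correction, shared by the gene-set (pathway-table style) and motif
# analyses.  The urn construction follows the ZOOPS enrichment
# convention: the population is target-union-background and the sample is
# the target list.

#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items
#' without replacement from a population of `N` containing `K` successes.
#'
#' @param k Successes observed in the sample (hits in targets).
#' @param n Sample size (number of targets).
#' @param K Successes in the population.
#' @param N Population size.
#' @return The tail probability, in `[0, 1]`.  Vectorized.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | n < 0 | K < 0
  if (any(bad))
    .stop_fmt("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Binomial upper-tail alternative
#'
#' `P[X >= k]` for `X ~ Binomial(n, p0)` with `p0` the background hit
#' rate, the "or binomial" alternative to the hypergeometric score.
#'
#' @param k Hits in the target set; `n` target-set size.
#' @param n Target-set size.
#' @param k_b,n_b Background hits and background size (define `p0`).
#' @return The tail probability.  Vectorized.
#' @export
binom_upper_tail <- function(k, n, k_b, n_b) {
  stopifnot(all(n_b > 0), all(k >= 0), all(k <= n))
  stats::pbinom(k - 1, n, k_b / n_b, lower.tail = FALSE)
}

#' Fold enrichment of target over background proportions
#'
#' `(k_t/n_t) / (k_b/n_b)`.  When the background has no hits but the
#' target does, returns `Inf` (infinite-fold sentinel); when neither has
#' hits, returns 1 (degenerate: nothing observed anywhere).
#'
#' @param k_t,n_t Hits and total in the target set.
#' @param k_b,n_b Hits and total in the background set.
#' @return Numeric vector of fold enrichments.
#' @export
fold_enrichment <- function(k_t, n_t, k_b, n_b) {
  if (any(n_t <= 0) || any(n_b <= 0))
    .stop_fmt("target and background totals must be positive")
  ifelse(k_b == 0 & k_t == 0, 1,
         ifelse(k_b == 0, Inf, (k_t / n_t) / (k_b / n_b)))
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false-discovery-rate adjustment; output is returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (q-values), same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    .stop_fmt("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment report
#'
#' For each gene set, counts members among the target genes and among the
#' background genes, scores the target count with the upper-tail
#' hypergeometric probability (population = target union background,
#' sample = target), and applies Benjamini-Hochberg correction across
#' sets.  Target and background must be disjoint: the background is the
#' set of genes showing no regulation, not the whole universe.
#'
#' Two percentage columns are emitted: `percent_target` (the pathway's
#' hits as a percentage of the target list) and `percent_of_set` (the
#' percentage of the pathway regulated).
#'
#' @param target Character vector of regulated gene ids.
#' @param background Character vector of unregulated gene ids (disjoint
#'   from `target`).
#' @param sets List of gene sets as from [read_gene_sets()].
#' @param method `"hypergeometric"` (default) or `"binomial"`.
#' @return data.frame sorted by p-value with columns `set_id`, `name`,
#'   `k_target`, `n_target`, `k_background`, `n_background`,
#'   `percent_target`, `percent_of_set`, `fold`, `p_value`, `bh_q`.
#' @export
gene_set_enrichment <- function(target, background, sets,
                                method = c("hypergeometric", "binomial")) {
  method <- match.arg(method)
  target <- unique(as.character(target))
  background <- unique(as.character(background))
  overlap <- intersect(target, background)
  if (length(overlap))
    .stop_fmt("target and background overlap (%d genes, e.g. '%s')",
              length(overlap), overlap[1L])
  n_t <- length(target); n_b <- length(background)
  stopifnot(n_t > 0, n_b > 0, length(sets) > 0)

  k_t <- vapply(sets, function(s) length(intersect(s$members, target)),
                integer(1))
  k_b <- vapply(sets, function(s) length(intersect(s$members, background)),
                integer(1))
  set_size <- vapply(sets, function(s) length(s$members), integer(1))
  p <- if (method == "hypergeometric")
    hypergeom_upper_tail(k_t, n_t, k_t + k_b, n_t + n_b)
  else binom_upper_tail(k_t, n_t, k_b, n_b)

  out <- data.frame(
    set_id = vapply(sets, `[[`, character(1), "set_id"),
    name = vapply(sets, `[[`, character(1), "name"),
    k_target = k_t, n_target = n_t,
    k_background = k_b, n_background = n_b,
    percent_target = 100 * k_t / n_t,
    percent_of_set = 100 * k_t / set_size,
    fold = fold_enrichment(k_t, n_t, k_b, n_b),
    p_value = p,
    bh_q = benjamini_hochberg(p),
    stringsAsFactors = FALSE)
  out[order(out$p_value, -out$fold, out$set_id), , drop = FALSE]
}
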