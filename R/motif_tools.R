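# Promoter extraction, mismatch-tolerant (Hamming) motif scanning of
# sequences and gene loci, ZOOPS occurrence counting, simplified
# exhaustive k-mer de novo motif discovery, and the low-complexity
# repeat filter.

#' Construct a fixed-length DNA motif with a mismatch budget
#'
#' @param sequence DNA word over A/C/G/T, length 6-20.
#' @param motif_id Identifier; defaults to the sequence itself.
#' @param max_mismatches Allowed Hamming distance when scanning.  The
#'   default budget is 1 for motifs up to 10 bases and 2 for longer ones
#'   (the budgets used for the 10-mer and 12-mer binding-site scans).
#' @return A `motif` object (list with `motif_id`, `sequence`,
#'   `max_mismatches`).
#' @export
motif <- function(sequence, motif_id = sequence, max_mismatches = NULL) {
  sequence <- toupper(as.character(sequence))
  len <- nchar(sequence)
  if (len < 6L || len > 20L)
    .stop_fmt("motif length must be 6-20 bases, got %d", len)
  if (grepl("[^ACGT]", sequence))
    .stop_fmt("motif may contain only A, C, G, T: '%s'", sequence)
  if (is.null(max_mismatches))
    max_mismatches <- if (len <= 10L) 1L else 2L
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L || max_mismatches >= len)
    .stop_fmt("max_mismatches must be in [0, motif length)")
  structure(list(motif_id = as.character(motif_id), sequence = sequence,
                 max_mismatches = max_mismatches),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif %s: %s, <=%d mismatch(es)>\n",
              x$motif_id, x$sequence, x$max_mismatches))
  invisible(x)
}

#' Promoter and locus windows
#'
#' `promoter_window()` describes the strand-aware sequence window around
#' the TSS used for de novo discovery (default 1000 bases upstream to 100
#' downstream, 1100 bases total).  `locus_window()` describes the flank
#' added on each side of the gene body for binding-site scans (default
#' +/- 10 kb).
#'
#' @param upstream,downstream Bases upstream/downstream of the TSS.
#' @return A window list.
#' @export
promoter_window <- function(upstream = 1000L, downstream = 100L) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  list(upstream = as.integer(upstream), downstream = as.integer(downstream))
}

#' @rdname promoter_window
#' @param flank Bases added on each side of the gene body.
#' @export
locus_window <- function(flank = 10000L) {
  stopifnot(flank >= 0)
  list(flank = as.integer(flank))
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

#' Extract strand-aware promoter sequences
#'
#' For a `+`-strand gene the genomic window is `[tss - upstream,
#' tss + downstream)`; for a `-`-strand gene it is `[tss - downstream + 1,
#' tss + upstream + 1)` reverse-complemented, so every output sequence
#' reads 5' to 3' of the gene with the TSS `upstream` bases in.  Windows
#' are clipped at contig edges with a warning.
#'
#' @param models Gene models as from [read_gene_models()].
#' @param genome Named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param window A [promoter_window()].
#' @return Named character vector of promoter sequences (one per gene).
#' @export
extract_promoters <- function(models, genome, window = promoter_window()) {
  missing <- setdiff(unique(models$chrom), names(genome))
  if (length(missing))
    .stop_fmt("chromosome '%s' not present in the genome", missing[1L])
  out <- character(nrow(models))
  clipped <- 0L
  for (i in seq_len(nrow(models))) {
    chrom_seq <- genome[[models$chrom[i]]]
    len <- nchar(chrom_seq)
    tss <- models$tss[i]
    if (models$strand[i] == "+") {
      s <- tss - window$upstream; e <- tss + window$downstream
    } else {
      s <- tss - window$downstream + 1L; e <- tss + window$upstream + 1L
    }
    cs <- max(s, 0L); ce <- min(e, len)
    if (cs > s || ce < e) clipped <- clipped + 1L
    piece <- substr(chrom_seq, cs + 1L, ce)
    if (models$strand[i] == "-") piece <- .revcomp(piece)
    out[i] <- piece
  }
  if (clipped)
    warning(sprintf("%d promoter window(s) clipped at contig edges", clipped),
            call. = FALSE)
  stats::setNames(out, models$gene_id)
}

# mismatch count of `motif_chars` at every offset of `seq_chars`
.hamming_profile <- function(seq_chars, motif_chars) {
  L <- length(seq_chars); k <- length(motif_chars)
  n <- L - k + 1L
  if (n < 1L) return(integer(0))
  mis <- integer(n)
  for (j in seq_len(k))
    mis <- mis + (seq_chars[j:(j + n - 1L)] != motif_chars[j])
  mis
}

#' Scan a sequence for a motif allowing mismatches
#'
#' Reports every offset (0-based) where the Hamming distance between the
#' motif and the sequence window is within the motif's mismatch budget.
#' `N` bases never match a motif base (they always count as mismatches).
#' With `both_strands`, occurrences of the reverse complement are
#' reported as `-`-strand hits at their forward-coordinate offsets.
#'
#' @param seq A single DNA string over A/C/G/T/N.
#' @param motif A [motif()] object.
#' @param both_strands Scan the reverse complement as well.
#' @return data.frame with columns `offset`, `strand`, `mismatches`,
#'   sorted by offset then strand (`+` before `-`).  A sequence shorter
#'   than the motif yields zero rows.
#' @export
scan_sequence <- function(seq, motif, both_strands = TRUE) {
  stopifnot(inherits(motif, "motif"), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    .stop_fmt("sequence contains characters outside A/C/G/T/N")
  sx <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hits <- list()
  fwd <- .hamming_profile(sx, strsplit(motif$sequence, "", fixed = TRUE)[[1L]])
  idx <- which(fwd <= motif$max_mismatches)
  if (length(idx))
    hits[["+"]] <- data.frame(offset = idx - 1L, strand = "+",
                              mismatches = fwd[idx],
                              stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- .hamming_profile(sx, strsplit(.revcomp(motif$sequence), "",
                                        fixed = TRUE)[[1L]])
    idx <- which(rc <= motif$max_mismatches)
    if (length(idx))
      hits[["-"]] <- data.frame(offset = idx - 1L, strand = "-",
                                mismatches = rc[idx],
                                stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan a gene locus (gene body plus flanks) for a motif
#'
#' Scans the genomic window `[start - flank, end + flank)` (clipped at
#' contig edges with a warning) and reports hits in genomic coordinates.
#'
#' @param model A single-row gene model (data.frame row or list with
#'   `gene_id`, `chrom`, `start`, `end`).
#' @param genome Named character vector of contig sequences.
#' @param motif A [motif()] object.
#' @param window A [locus_window()].
#' @param both_strands Scan both strands (default; the validation scans
#'   of the cytokine loci do not fix a strand).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open genomic), `strand`, `mismatches`.
#' @export
scan_locus <- function(model, genome, motif, window = locus_window(),
                       both_strands = TRUE) {
  chrom <- as.character(model$chrom)
  if (!chrom %in% names(genome))
    .stop_fmt("chromosome '%s' not present in the genome", chrom)
  len <- nchar(genome[[chrom]])
  s <- model$start - window$flank; e <- model$end + window$flank
  cs <- max(s, 0L); ce <- min(e, len)
  if (cs > s || ce < e)
    warning("locus window clipped at contig edges", call. = FALSE)
  piece <- substr(genome[[chrom]], cs + 1L, ce)
  hits <- scan_sequence(piece, motif, both_strands = both_strands)
  k <- nchar(motif$sequence)
  data.frame(gene_id = rep(as.character(model$gene_id), nrow(hits)),
             chrom = rep(chrom, nrow(hits)),
             start = cs + hits$offset,
             end = cs + hits$offset + k,
             strand = hits$strand,
             mismatches = hits$mismatches,
             stringsAsFactors = FALSE)
}

#' ZOOPS occurrence count
#'
#' Number of sequences containing at least one hit of the motif (multiple
#' hits in one sequence count once; zero-or-one-occurrence-per-sequence
#' scoring).
#'
#' @param seqs Character vector of sequences.
#' @param motif A [motif()] object.
#' @param both_strands Count hits on either strand.
#' @return Integer count in `[0, length(seqs)]`.
#' @export
zoops_count <- function(seqs, motif, both_strands = TRUE) {
  if (!length(seqs)) return(0L)
  sum(vapply(seqs, function(s)
    nrow(scan_sequence(s, motif, both_strands = both_strands)) > 0L,
    logical(1), USE.NAMES = FALSE))
}

#' Low-complexity / tandem-repeat motif filter
#'
#' Rejects (returns TRUE for) motifs that are tandem repeats of a unit of
#' length <= 3 covering >= 80% of the motif, or whose mononucleotide
#' Shannon entropy is below 1 bit.  De novo discovery drops such motifs
#' as repeat-sequence false positives.
#'
#' @param motif_sequence Character vector of DNA words.
#' @return Logical vector; TRUE means rejected.
#' @export
repeat_filter <- function(motif_sequence) {
  vapply(toupper(motif_sequence), function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1L]]
    L <- length(x)
    tab <- table(factor(x, levels = c("A", "C", "G", "T", "N")))
    p <- tab[tab > 0] / L
    entropy <- -sum(p * log2(p))
    if (entropy < 1) return(TRUE)
    for (u in 1:3) {
      if (L <= u) next
      matches <- sum(x[(u + 1L):L] == x[1:(L - u)])
      if ((matches + u) / L >= 0.8) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' De novo k-mer motif discovery under a ZOOPS model
#'
#' Enumerates every k-mer present in the target sequences, counts the
#' sequences (targets and background separately) containing the k-mer
#' within `max_mm` mismatches under ZOOPS scoring, scores each candidate
#' with the upper-tail hypergeometric probability (population = targets
#' union background, sample = targets), and applies Benjamini-Hochberg
#' correction across all candidates.  Candidates are reported when their
#' fold enrichment reaches `min_fold` and their adjusted value is at most
#' `max_q`; low-complexity words are dropped (see [repeat_filter()]).
#' The survivors are then greedily clustered in order of increasing
#' p-value, absorbing every candidate able to explain the same
#' occurrences as the cluster seed (within `2 * max_mm` in a shift-aware
#' Hamming metric, the triangle bound for two words matching a common
#' site), and each cluster is reported through its consensus member --
#' the word with the highest exact-match ZOOPS count in the targets.
#'
#' Counting is forward-strand on the supplied sequences, which are
#' expected to be promoter-local (5' to 3' of the gene).
#'
#' @param target_seqs,background_seqs Character vectors of DNA sequences.
#' @param k Motif length (8-14).
#' @param max_mm Mismatch budget for occurrence counting.
#' @param min_fold Minimal target/background fold enrichment.
#' @param max_q Maximal Benjamini-Hochberg adjusted value.
#' @param max_motifs Maximal number of motifs reported.
#' @return data.frame with one row per reported motif: `motif`,
#'   `k_target`, `n_target`, `k_background`, `n_background`,
#'   `k_target_exact` (ZOOPS count at zero mismatches, used to break
#'   ranking ties in favour of the consensus word), `fold`, `p_value`,
#'   `bh_q`; the number of candidates scored is attached as attribute
#'   `n_candidates`.
#' @export
denovo_discover <- function(target_seqs, background_seqs, k = 10L,
                            max_mm = 1L, min_fold = 3.5, max_q = 0.05,
                            max_motifs = 10L) {
  stopifnot(length(target_seqs) > 0, length(background_seqs) > 0)
  k <- as.integer(k); max_mm <- as.integer(max_mm)
  if (k < 8L || k > 14L) .stop_fmt("k must be in 8..14, got %d", k)
  if (max_mm < 0L || max_mm > 2L)
    .stop_fmt("max_mm must be 0, 1 or 2 for exhaustive discovery")
  if (k > min(nchar(c(target_seqs, background_seqs))))
    .stop_fmt("k exceeds the shortest input sequence")

  counts <- kmer_zoops_counts(toupper(target_seqs),
                              toupper(background_seqs), k, max_mm)
  n_t <- length(target_seqs); n_b <- length(background_seqs)
  if (!nrow(counts)) {
    empty <- data.frame(motif = character(0), k_target = integer(0),
                        n_target = integer(0), k_background = integer(0),
                        n_background = integer(0), fold = numeric(0),
                        p_value = numeric(0), bh_q = numeric(0),
                        stringsAsFactors = FALSE)
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  p <- hypergeom_upper_tail(counts$k_target, n_t,
                            counts$k_target + counts$k_background,
                            n_t + n_b)
  q <- benjamini_hochberg(p)
  fold <- fold_enrichment(counts$k_target, n_t, counts$k_background, n_b)

  cand <- data.frame(motif = counts$kmer,
                     k_target = counts$k_target, n_target = n_t,
                     k_background = counts$k_background, n_background = n_b,
                     k_target_exact = counts$k_target_exact,
                     fold = fold, p_value = p, bh_q = q,
                     stringsAsFactors = FALSE)
  n_candidates <- nrow(cand)
  cand <- cand[cand$fold >= min_fold & cand$bh_q <= max_q, , drop = FALSE]
  cand <- cand[!repeat_filter(cand$motif), , drop = FALSE]
  cand <- cand[order(cand$p_value, -cand$fold, cand$motif), , drop = FALSE]

  # A strong word drags a cloud of redundant candidates through the
  # filter: its Hamming neighbours, and frame shifts whose overhang is
  # absorbed by the mismatch budget (a 1-shift of a planted 10-mer
  # matches every planted site within 1 mismatch).  Two words able to
  # match the same occurrence within max_mm mismatches differ by at most
  # 2 * max_mm in the shift-aware metric (triangle bound), so cluster the
  # survivors at that radius and report each cluster's consensus: the
  # member with the highest exact-match ZOOPS count.
  cluster_seed <- integer(0)
  cluster_of <- rep(NA_integer_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!is.na(cluster_of[i])) next
    if (length(cluster_seed) >= max_motifs) next
    cluster_seed <- c(cluster_seed, i)
    open <- which(is.na(cluster_of))
    rel <- open[vapply(cand$motif[open], .motif_related,
                       logical(1), b = cand$motif[i],
                       max_mm = 2L * max_mm)]
    cluster_of[rel] <- length(cluster_seed)
  }
  rep_rows <- vapply(seq_along(cluster_seed), function(cl) {
    members <- which(cluster_of == cl)
    members[order(-cand$k_target_exact[members],
                  cand$p_value[members], cand$motif[members])][1L]
  }, integer(1))
  out <- cand[rep_rows, , drop = FALSE]
  out <- out[order(out$p_value, -out$fold, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- n_candidates
  out
}

.hamming_distance <- function(a, b) {
  xa <- strsplit(a, "", fixed = TRUE)[[1L]]
  xb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(xa) == length(xb))
  sum(xa != xb)
}

# are two equal-length words redundant under the mismatch budget?
# TRUE when some alignment with frame shift |s| has (overlap mismatches
# + |s|) <= max_mm: shift positions behave like budget-absorbed
# mismatches when counting occurrences.
.motif_related <- function(a, b, max_mm) {
  xa <- strsplit(a, "", fixed = TRUE)[[1L]]
  xb <- strsplit(b, "", fixed = TRUE)[[1L]]
  k <- length(xa)
  for (s in -max_mm:max_mm) {
    ov <- k - abs(s)
    if (ov <= 0) next
    mism <- if (s >= 0) sum(xa[(1 + s):k] != xb[1:ov])
    else sum(xa[1:ov] != xb[(1 - s):k])
    if (mism + abs(s) <= max_mm) return(TRUE)
  }
  FALSE
}
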