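# In-code fixtures shared across the suite.

# a peak-table row builder with sensible defaults
peak_row <- function(gene_id, wt = 1, ko = 1, wt_pj34 = 1, ko_pj34 = 1,
                     input = 0.2, sig_wt = TRUE, sig_ko = TRUE,
                     sig_wt_pj34 = TRUE, sig_ko_pj34 = TRUE) {
  data.frame(gene_id = gene_id, wt = wt, ko = ko, wt_pj34 = wt_pj34,
             ko_pj34 = ko_pj34, input = input, sig_wt = sig_wt,
             sig_ko = sig_ko, sig_wt_pj34 = sig_wt_pj34,
             sig_ko_pj34 = sig_ko_pj34, stringsAsFactors = FALSE)
}

peak_table <- function(...) do.call(rbind, list(...))

# a random but always-valid peak table (no planted structure)
random_peak_table <- function(n, seed) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             wt = rlnorm(n, 0, 1), ko = rlnorm(n, 0, 1),
             wt_pj34 = rlnorm(n, 0, 1), ko_pj34 = rlnorm(n, 0, 1),
             input = rlnorm(n, log(0.3), 0.5),
             sig_wt = runif(n) < 0.8, sig_ko = runif(n) < 0.8,
             sig_wt_pj34 = runif(n) < 0.8, sig_ko_pj34 = runif(n) < 0.8,
             stringsAsFactors = FALSE)
}

# independent enumeration oracle for the upper-tail hypergeometric:
# exact binomial-coefficient sums (all terms integers well inside double
# precision for N <= 30)
hyper_tail_oracle <- function(k, n, K, N) {
  js <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# independent exhaustive Hamming scanner (substring-by-substring),
# deliberately naive and structured differently from the package path
naive_scan <- function(seq, pattern, max_mm) {
  k <- nchar(pattern); L <- nchar(seq)
  hits <- data.frame(offset = integer(0), mismatches = integer(0))
  if (L < k) return(hits)
  pat <- strsplit(pattern, "")[[1]]
  for (o in 0:(L - k)) {
    win <- strsplit(substr(seq, o + 1, o + k), "")[[1]]
    mm <- sum(win != pat)
    if (mm <= max_mm)
      hits <- rbind(hits, data.frame(offset = o, mismatches = mm))
  }
  hits
}

revcomp_str <- function(s)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# the printed DAPA probe sequences (intact and scrambled-core variants)
# used as fixed scanner inputs
dapa_probes <- list(
  il4          = "GCCAAGCTTGTGAGTCTGAGTTCAAGGATCCACACGGTGCAAAGAGAGAC",
  il4_scramble = "GCCAAGCTTGTGAGTCTGAGCGTGCATGCACACACGGTGCAAAGAGAGAC",
  il5          = "TTACTAAAAGGCCAACCCAGACTGAGTGGAGATAAGAGGATGCTTCTTGG",
  il5_scramble = "TTACTAAAAGGCCAACCCAGCAGATTGCTTTATAAGAGGATGCTTCTTGG")

motif1 <- function() motif("CACTGAGTGGAG", "Motif1")   # 12-mer, budget 2
motif3 <- function() motif("TCCAAGGATC", "Motif3")     # 10-mer, budget 1

# class-proportion preset for motif-discovery simulations:
# one third targets (Pool 5 positive), two thirds unregulated background
discovery_proportions <- function() {
  c(inactive = 0, no_change = 2/3, pool4_pos = 0, pool4_neg = 0,
    pool5_pos = 1/3, pool5_neg = 0, pool6_pos = 0, pool6_neg = 0)
}
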