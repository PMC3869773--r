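# Promoter extraction, Hamming scanning (checked against a naive oracle
# and against Biostrings), ZOOPS counting, the repeat filter, and de
# novo discovery on small planted designs.

test_that("scan_sequence finds the DAPA probe motifs at their cores", {
  # Il4 probe vs the 10-mer (<= 1 mismatch): one forward hit at the
  # TTCAAGGATC segment, one substitution from TCCAAGGATC
  hits <- scan_sequence(dapa_probes$il4, motif3(), both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 20L)
  expect_equal(hits$mismatches, 1L)
  expect_equal(substr(dapa_probes$il4, 21, 30), "TTCAAGGATC")

  # Il5 probe vs the 12-mer (<= 2 mismatches): includes the GACTGAGTGGAG
  # segment at one substitution
  hits <- scan_sequence(dapa_probes$il5, motif1(), both_strands = FALSE)
  expect_gte(nrow(hits), 1L)
  expect_true(any(hits$offset == 19L & hits$mismatches == 1L))
  expect_equal(substr(dapa_probes$il5, 20, 31), "GACTGAGTGGAG")

  # scrambled cores lose the hits entirely
  expect_equal(nrow(scan_sequence(dapa_probes$il4_scramble, motif3(),
                                  both_strands = FALSE)), 0L)
  expect_equal(nrow(scan_sequence(dapa_probes$il5_scramble, motif1(),
                                  both_strands = FALSE)), 0L)

  # every probe scan agrees with the naive exhaustive oracle
  for (probe in dapa_probes) {
    for (m in list(motif1(), motif3())) {
      got <- scan_sequence(probe, m, both_strands = FALSE)
      want <- naive_scan(probe, m$sequence, m$max_mismatches)
      expect_equal(got$offset, want$offset)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("scan_sequence edge semantics: identity, short input, N bases", {
  m <- motif3()
  hits <- scan_sequence(m$sequence, m, both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$mismatches, 0L)
  # shorter than the motif: empty result, not an error
  expect_equal(nrow(scan_sequence("ACGT", m)), 0L)
  # N counts as a mismatch against any motif base
  expect_equal(scan_sequence("TCCAANGATC", motif("TCCAAGGATC", max_mismatches = 1),
                             both_strands = FALSE)$mismatches, 1L)
  expect_equal(nrow(scan_sequence("TCNAANGATC",
                                  motif("TCCAAGGATC", max_mismatches = 1),
                                  both_strands = FALSE)), 0L)
  expect_error(scan_sequence("ACGU", m), "A/C/G/T/N")
})

test_that("scanning agrees with Biostrings on random sequences", {
  set.seed(77)
  for (i in 1:10) {
    seq <- random_dna(500)
    m <- motif(random_dna(10), max_mismatches = sample(0:2, 1))
    got <- scan_sequence(seq, m, both_strands = FALSE)
    ref <- Biostrings::matchPattern(m$sequence, Biostrings::DNAString(seq),
                                    max.mismatch = m$max_mismatches)
    expect_equal(got$offset, BiocGenerics::start(ref) - 1L)
  }
})

test_that("hit sets are monotone in the budget and reflect under revcomp", {
  set.seed(55)
  for (i in 1:5) {
    seq <- random_dna(400)
    word <- random_dna(10)
    n_hits <- vapply(0:2, function(mm)
      nrow(scan_sequence(seq, motif(word, max_mismatches = mm))),
      integer(1))
    expect_true(all(diff(n_hits) >= 0))

    # with both strands, reverse-complementing the input reflects hits
    m <- motif(word, max_mismatches = 1)
    fwd <- scan_sequence(seq, m, both_strands = TRUE)
    rev <- scan_sequence(revcomp_str(seq), m, both_strands = TRUE)
    k <- nchar(word); L <- nchar(seq)
    reflected <- sort(L - k - rev$offset)
    expect_equal(sort(fwd$offset), reflected)
    expect_equal(nrow(fwd), nrow(rev))
  }
  # with max_mm = 0 the scan reduces to exact substring search
  seq <- random_dna(2000, seed = 12)
  word <- substr(seq, 101, 110)
  got <- scan_sequence(seq, motif(word, max_mismatches = 0),
                       both_strands = FALSE)
  exact <- gregexpr(word, seq, fixed = TRUE)[[1]]
  expect_equal(got$offset, as.integer(exact) - 1L)
})

test_that("promoter extraction honours strand, window and clipping", {
  # + strand: [tss - up, tss + down); - strand mirrored and revcomped
  genome <- c(chrA = random_dna(5000, seed = 21))
  models <- data.frame(gene_id = c("gp", "gm"), chrom = "chrA",
                       start = c(2000L, 1000L), end = c(2500L, 2600L),
                       strand = c("+", "-"),
                       tss = c(2000L, 2599L), stringsAsFactors = FALSE)
  proms <- extract_promoters(models, genome)
  expect_equal(nchar(proms[["gp"]]), 1100L)
  expect_equal(proms[["gp"]], substr(genome[["chrA"]], 1001, 2100))
  expect_equal(proms[["gm"]],
               revcomp_str(substr(genome[["chrA"]], 2501, 3600)))

  # a gene near the contig start gets clipped with a warning
  mshort <- data.frame(gene_id = "gc", chrom = "chrA", start = 200L,
                       end = 700L, strand = "+", tss = 200L,
                       stringsAsFactors = FALSE)
  expect_warning(p <- extract_promoters(mshort, genome), "clipped")
  expect_equal(nchar(p[["gc"]]), 300L)

  expect_error(extract_promoters(
    data.frame(gene_id = "g", chrom = "chrZ", start = 1L, end = 2L,
               strand = "+", tss = 1L), genome), "chrZ")

  # a synthetic genome written with a known promoter literal
  lit <- random_dna(1100, seed = 33)
  g2 <- c(c1 = paste0(random_dna(1000, seed = 34), lit,
                      random_dna(600, seed = 35)))
  mlit <- data.frame(gene_id = "glit", chrom = "c1", start = 2000L,
                     end = 2400L, strand = "+", tss = 2000L,
                     stringsAsFactors = FALSE)
  expect_equal(extract_promoters(mlit, g2)[["glit"]], lit)
})

test_that("scan_locus reports genomic coordinates within the flank", {
  set.seed(61)
  m <- motif3()
  contig <- random_dna(30000)
  # plant an exact copy 3 kb upstream of the gene body
  gene_start <- 15000L; gene_end <- 16000L
  plant_at <- gene_start - 3000L
  substr(contig, plant_at + 1L, plant_at + 10L) <- m$sequence
  genome <- c(ctg = contig)
  model <- list(gene_id = "g1", chrom = "ctg", start = gene_start,
                end = gene_end)
  hits <- scan_locus(model, genome, m)
  planted_hit <- hits[hits$mismatches == 0 & hits$strand == "+", ]
  expect_true(plant_at %in% planted_hit$start)
  expect_equal(planted_hit$end[planted_hit$start == plant_at],
               plant_at + 10L)

  # flank 0 excludes a copy planted only in the flanks
  hits0 <- scan_locus(model, genome, m, window = locus_window(0))
  expect_false(plant_at %in% hits0$start)

  # a minus-strand copy is found only when both strands are scanned
  contig2 <- random_dna(30000)
  substr(contig2, 12001, 12010) <- revcomp_str(m$sequence)
  genome2 <- c(ctg = contig2)
  both <- scan_locus(model, genome2, m, both_strands = TRUE)
  fwd <- scan_locus(model, genome2, m, both_strands = FALSE)
  expect_true(any(both$start == 12000L & both$strand == "-" &
                    both$mismatches == 0))
  expect_false(any(fwd$start == 12000L & fwd$mismatches == 0))
})

test_that("zoops_count counts sequences, not occurrences", {
  m <- motif("TCCAAGGATC", max_mismatches = 0)
  seqs <- c(paste0("AAAA", m$sequence, "TTTT"),                  # 1 hit
            paste0(m$sequence, "GG", m$sequence),                # 2 hits
            random_dna(40, seed = 71), random_dna(40),
            paste0("C", m$sequence), random_dna(40),
            random_dna(40), paste0(m$sequence, "A"),
            random_dna(40), random_dna(40))
  expect_equal(zoops_count(seqs, m), 4L)
  expect_equal(zoops_count(character(0), m), 0L)
})

test_that("background ZOOPS rate matches the analytic expectation", {
  # for an exact k-mer on one strand of an i.i.d. uniform sequence of
  # length L, P(>= 1 hit) ~ 1 - (1 - 4^-k)^(L-k+1)
  set.seed(101)
  k <- 8L; L <- 1100L; n <- 500L
  m <- motif(random_dna(k), max_mismatches = 0)
  seqs <- vapply(seq_len(n), function(i) random_dna(L), character(1))
  got <- zoops_count(seqs, m, both_strands = FALSE)
  p_hit <- 1 - (1 - 4^-k)^(L - k + 1)
  expect_lt(abs(got - n * p_hit), 4 * sqrt(n * p_hit * (1 - p_hit)) + 1)
})

test_that("repeat_filter rejects low-complexity words, keeps real motifs", {
  expect_true(repeat_filter("ACACACACAC"))
  expect_true(repeat_filter("AAAAAAAAAA"))
  expect_true(repeat_filter("AGGAGGAGGAGG"))   # trinucleotide tandem
  expect_false(repeat_filter("CACTGAGTGGAG"))  # the validated 12-mer
  expect_false(repeat_filter("TCCAAGGATC"))    # the validated 10-mer
  expect_equal(repeat_filter(c("ACACACACAC", "TCCAAGGATC")),
               c(TRUE, FALSE))
})

test_that("de novo discovery recovers a planted word on a small design", {
  set.seed(88)
  word <- "CAGTCCGATA"
  n_t <- 60L; n_b <- 120L; L <- 300L
  targets <- vapply(seq_len(n_t), function(i) random_dna(L), character(1))
  background <- vapply(seq_len(n_b), function(i) random_dna(L),
                       character(1))
  plant <- function(s) {
    o <- sample(L - 10L, 1)
    substr(s, o, o + 9L) <- word
    s
  }
  idx <- sample(n_t, 30)  # 50% of targets
  targets[idx] <- vapply(targets[idx], plant, character(1),
                         USE.NAMES = FALSE)
  idxb <- sample(n_b, 6)  # 5% of background
  background[idxb] <- vapply(background[idxb], plant, character(1),
                             USE.NAMES = FALSE)
  res <- denovo_discover(targets, background, k = 10, max_mm = 1)
  expect_gte(nrow(res), 1L)
  expect_equal(res$motif[1], word)
  expect_gte(res$fold[1], 3.5)
  expect_gte(res$k_target[1], 30)

  # no self-enrichment: identical target and background sets
  same <- denovo_discover(targets, targets, k = 10, max_mm = 1)
  expect_equal(nrow(same), 0L)

  expect_error(denovo_discover(targets, background, k = 6), "8..14")
  expect_error(denovo_discover("ACGTACG", background, k = 10),
               "shortest")
})

test_that("a planted homopolymer is caught by the repeat filter", {
  set.seed(99)
  targets <- vapply(1:40, function(i) random_dna(200), character(1))
  background <- vapply(1:80, function(i) random_dna(200), character(1))
  targets <- vapply(targets, function(s) {
    substr(s, 50, 59) <- "AAAAAAAAAA"; s
  }, character(1), USE.NAMES = FALSE)
  res <- denovo_discover(targets, background, k = 10, max_mm = 1)
  expect_false(any(res$motif == "AAAAAAAAAA"))
  expect_false(any(repeat_filter(res$motif)))
})
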