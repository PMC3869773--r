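# Readers and writers: identity round-trips, coordinate conventions,
# and the error contracts for malformed inputs.

test_that("peak table round-trips through TSV and write is canonical", {
  tbl <- random_peak_table(100, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_peak_table(tbl, f1)
  back <- read_gene_peak_table(f1)
  expect_equal(back$gene_id, tbl$gene_id)
  expect_equal(back$wt, tbl$wt, tolerance = 1e-12)
  expect_equal(back$sig_ko, tbl$sig_ko)

  # write -> read -> write is byte-stable
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_gene_peak_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("peak table reader maps custom columns and rejects bad input", {
  tbl <- peak_table(peak_row("g1", wt = 0.6), peak_row("g2", wt = 1.2),
                    peak_row("g3", ko = 2.0))
  f <- withr::local_tempfile(fileext = ".tsv")
  # custom headers
  out <- tbl
  names(out) <- c("gene", "a_wt", "a_ko", "a_wtp", "a_kop", "a_in",
                  "s1", "s2", "s3", "s4")
  write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_gene_peak_table(
    f,
    column_map = c(WT = "a_wt", KO = "a_ko", WT_PJ34 = "a_wtp",
                   KO_PJ34 = "a_kop", INPUT = "a_in"),
    flag_map = c(WT = "s1", KO = "s2", WT_PJ34 = "s3", KO_PJ34 = "s4"),
    gene_col = "gene")
  expect_equal(nrow(got), 3L)
  expect_equal(got$wt, tbl$wt)

  # missing INPUT column
  out2 <- out; out2$a_in <- NULL
  write.table(out2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_peak_table(
    f,
    column_map = c(WT = "a_wt", KO = "a_ko", WT_PJ34 = "a_wtp",
                   KO_PJ34 = "a_kop", INPUT = "a_in"),
    flag_map = c(WT = "s1", KO = "s2", WT_PJ34 = "s3", KO_PJ34 = "s4"),
    gene_col = "gene"), "a_in")

  # duplicate gene id and negative peak
  dup <- rbind(tbl, peak_row("g1"))
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(dup, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_gene_peak_table(f3), "g1")
  neg <- tbl; neg$wt[2] <- -0.5
  expect_error(validate_peak_table(neg), "row 2")
})

test_that("gene models derive the TSS per strand and validate lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tg1\t0\t+",
               "chr1\t100\t200\tg2\t0\t-"), f)
  m <- read_gene_models(f)
  expect_equal(m$tss, c(100L, 199L))
  expect_equal(m$gene_id, c("g1", "g2"))

  writeLines("chr1\t300\t200\tg1\t0\t+", f)
  expect_error(read_gene_models(f), "line 1")
  writeLines("chr1\t100\t200\tg1\t0\t.", f)
  expect_error(read_gene_models(f), "strand")

  # 1-based inputs are shifted at the boundary
  writeLines("chr1\t101\t200\tg1\t0\t+", f)
  expect_equal(read_gene_models(f, one_based = TRUE)$start, 100L)

  # writer round-trip
  writeLines(c("chr2\t5\t50\tgx\t0\t-"), f)
  m <- read_gene_models(f)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(m, f2)
  expect_equal(read_gene_models(f2), m)
})

test_that("FASTA reader uppercases, validates the alphabet and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 description here", "acgt"), f)
  expect_equal(read_fasta(f), c(s1 = "ACGT"))

  writeLines(c(">s1", "ACGX"), f)
  expect_error(read_fasta(f), "position 4")

  set.seed(9)
  seqs <- setNames(vapply(1:50, function(i) random_dna(30 + i),
                          character(1)),
                   sprintf("seq%02d", 1:50))
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f2)
  expect_identical(read_fasta(f2), seqs)
})

test_that("GMT reader collapses duplicates and enforces field counts", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("set1\tdesc\tg1\tg2\tg3\tg4\tg5",
               "set2\tdesc\tg1\tg1\tg2"), f)
  expect_warning(sets <- read_gene_sets(f), "duplicate")
  expect_length(sets, 2L)
  expect_length(sets[[1]]$members, 5L)
  expect_length(sets[[2]]$members, 2L)  # duplicate counted once

  writeLines("set1\tdesc", f)
  expect_error(read_gene_sets(f), "line 1")

  writeLines(character(0), f)
  expect_equal(read_gene_sets(f), list())
})

test_that("motif files parse into motif objects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Motif1\tCACTGAGTGGAG\t2", "Motif3 TCCAAGGATC 1"), f)
  ms <- read_motif_file(f)
  expect_equal(ms[[1]]$sequence, "CACTGAGTGGAG")
  expect_equal(ms[[1]]$max_mismatches, 2L)
  expect_equal(ms[[2]]$motif_id, "Motif3")
  writeLines("only_two_fields ACGTACGT", f)
  expect_error(read_motif_file(f), "line 1")
})

test_that("SICER island files map to gene flags by >=1 bp gene-body overlap", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tg1\t0\t+",
               "chr1\t500\t700\tg2\t0\t-"), bed)
  models <- read_gene_models(bed)

  mk_islands <- function(lines) {
    f <- tempfile(fileext = ".bed")
    writeLines(lines, f)
    f
  }
  # WT island overlaps g1 by 1 bp (ends at 101, gene starts at 100);
  # KO island falls in the gap; the PJ34 islands cover g2 only
  files <- c(WT = mk_islands("chr1\t50\t101"),
             KO = mk_islands("chr1\t250\t400"),
             WT_PJ34 = mk_islands("chr1\t600\t650"),
             KO_PJ34 = mk_islands("chr1\t400\t501"))
  flags <- sicer_flags_from_islands(models, files)
  expect_equal(flags$sig_wt, c(TRUE, FALSE))
  expect_equal(flags$sig_ko, c(FALSE, FALSE))
  expect_equal(flags$sig_wt_pj34, c(FALSE, TRUE))
  expect_equal(flags$sig_ko_pj34, c(FALSE, TRUE))
  unlink(files)
})

test_that("pool reports round-trip", {
  tbl <- random_peak_table(30, seed = 3)
  asn <- assign_pools(tbl)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pool_report(asn, f)
  back <- read_pool_report(f)
  expect_equal(back$in_pool2, asn$in_pool2)
  expect_equal(back$regulation_sign, asn$regulation_sign)
  expect_equal(back$wt_ko_ratio, asn$wt_ko_ratio, tolerance = 1e-12)
})
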