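# Readers and writers for the external representations used by the
# pipeline: per-gene peak tables (TSV), BED6 gene models and SICER island
# files, FASTA sequence sets, GMT gene sets, plain-text motif files, and
# pool reports.  Coordinates are 0-based half-open (BED convention)
# everywhere internally; 1-based inputs are converted at the boundary via
# the `one_based` flag of the readers.

#' Validate a gene peak table
#'
#' A peak table is a data.frame with one row per gene and canonical
#' columns `gene_id`, `wt`, `ko`, `wt_pj34`, `ko_pj34`, `input`
#' (non-negative average peak values) and `sig_wt`, `sig_ko`,
#' `sig_wt_pj34`, `sig_ko_pj34` (logical SICER significance flags for the
#' four non-input samples).
#'
#' @param tbl data.frame to validate.
#' @return The validated table, invisibly.
#' @export
validate_peak_table <- function(tbl) {
  needed <- c("gene_id", unname(.peak_cols), unname(.flag_cols))
  missing <- setdiff(needed, names(tbl))
  if (length(missing))
    .stop_fmt("peak table is missing column(s): %s",
              paste(missing, collapse = ", "))
  if (anyDuplicated(tbl$gene_id)) {
    dup <- tbl$gene_id[duplicated(tbl$gene_id)][1L]
    .stop_fmt("duplicate gene_id in peak table: '%s'", dup)
  }
  for (cl in unname(.peak_cols)) {
    v <- tbl[[cl]]
    if (!is.numeric(v) || anyNA(v))
      .stop_fmt("column '%s' must be numeric with no missing values", cl)
    if (any(v < 0))
      .stop_fmt("negative peak value in column '%s' at row %d",
                cl, which(v < 0)[1L])
  }
  for (cl in unname(.flag_cols))
    if (!is.logical(tbl[[cl]]) || anyNA(tbl[[cl]]))
      .stop_fmt("flag column '%s' must be logical with no missing values", cl)
  invisible(tbl)
}

#' Read a per-gene average-peak-value table
#'
#' Reads a TSV with a header row into the canonical peak-table layout.
#' `column_map` / `flag_map` translate condition labels to the column
#' names used in the file; by default the canonical names are expected.
#'
#' @param path Path to a tab-separated file with a header.
#' @param column_map Named character vector mapping each of
#'   [PEAK_CONDITIONS] to a column name in the file.
#' @param flag_map Named character vector mapping each of
#'   [SIGNAL_CONDITIONS] to a significance-flag column name; flag cells
#'   must parse as 0/1 or TRUE/FALSE.
#' @param gene_col Name of the gene-identifier column.
#' @return A validated peak table (data.frame), file order preserved.
#' @export
read_gene_peak_table <- function(path,
                                 column_map = NULL,
                                 flag_map = NULL,
                                 gene_col = "gene_id") {
  if (is.null(column_map)) column_map <- .peak_cols
  if (is.null(flag_map)) flag_map <- .flag_cols
  if (!all(PEAK_CONDITIONS %in% names(column_map)))
    .stop_fmt("column_map must name all of: %s",
              paste(PEAK_CONDITIONS, collapse = ", "))
  if (!all(SIGNAL_CONDITIONS %in% names(flag_map)))
    .stop_fmt("flag_map must name all of: %s",
              paste(SIGNAL_CONDITIONS, collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  for (cl in c(gene_col, unname(column_map[PEAK_CONDITIONS]),
               unname(flag_map[SIGNAL_CONDITIONS])))
    if (!cl %in% names(raw))
      .stop_fmt("input table '%s' is missing column '%s'", path, cl)

  out <- data.frame(gene_id = as.character(raw[[gene_col]]),
                    stringsAsFactors = FALSE)
  for (cond in PEAK_CONDITIONS) {
    v <- raw[[column_map[[cond]]]]
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v))
      .stop_fmt("non-numeric peak value in column '%s' at row %d",
                column_map[[cond]], which(is.na(v))[1L])
    out[[.peak_cols[[cond]]]] <- v
  }
  for (cond in SIGNAL_CONDITIONS) {
    v <- raw[[flag_map[[cond]]]]
    lv <- .parse_flag(v)
    if (anyNA(lv))
      .stop_fmt("unparseable significance flag in column '%s' at row %d",
                flag_map[[cond]], which(is.na(lv))[1L])
    out[[.flag_cols[[cond]]]] <- lv
  }
  validate_peak_table(out)
  out
}

.parse_flag <- function(v) {
  if (is.logical(v)) return(v)
  s <- toupper(trimws(as.character(v)))
  ifelse(s %in% c("1", "TRUE", "T"), TRUE,
         ifelse(s %in% c("0", "FALSE", "F"), FALSE, NA))
}

#' Write a gene peak table as TSV
#'
#' Numeric fields are written with R's default (canonical) formatting so
#' that write -> read -> write is byte-stable.
#'
#' @param tbl A validated peak table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_peak_table <- function(tbl, path) {
  validate_peak_table(tbl)
  out <- tbl
  for (cl in unname(.flag_cols)) out[[cl]] <- as.integer(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED6-like file
#'
#' Columns: chrom, start, end, name, score, strand.  The transcription
#' start site (TSS) is derived per strand: `start` for `+` genes and
#' `end - 1` for `-` genes (0-based).
#'
#' @param path Path to a BED6 file (no header).
#' @param one_based If TRUE, input start coordinates are 1-based inclusive
#'   and are converted to 0-based half-open on read.
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss.
#' @export
read_gene_models <- function(path, one_based = FALSE) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character"))
  if (one_based) raw$start <- raw$start - 1L
  bad <- which(!(raw$strand %in% c("+", "-")))
  if (length(bad))
    .stop_fmt("line %d: strand must be '+' or '-', got '%s'",
              bad[1L], raw$strand[bad[1L]])
  bad <- which(raw$start >= raw$end)
  if (length(bad))
    .stop_fmt("line %d: start (%d) must be < end (%d)",
              bad[1L], raw$start[bad[1L]], raw$end[bad[1L]])
  data.frame(gene_id = raw$name, chrom = raw$chrom,
             start = raw$start, end = raw$end, strand = raw$strand,
             tss = ifelse(raw$strand == "+", raw$start, raw$end - 1L),
             stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#'
#' @param models data.frame as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  out <- data.frame(models$chrom, models$start, models$end,
                    models$gene_id, 0L, models$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and validated against the alphabet ACGTN.
#' IDs are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1L)
  names(seqs) <- ids
  empty <- which(nchar(seqs) == 0L)
  if (length(empty))
    .stop_fmt("empty FASTA record: '%s'", ids[empty[1L]])
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    .stop_fmt("illegal character in sequence '%s' at position %d",
              ids[i], bad[i])
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line: set id, description, then one or more member gene ids, all
#' tab-separated.  Duplicate members within a line are collapsed with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return List of gene sets, each `list(set_id, name, members)`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      .stop_fmt("GMT line %d has %d field(s); need set id, description and >=1 member",
                i, length(f))
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate members collapsed",
                      i, f[1L]), call. = FALSE)
      members <- unique(members)
    }
    out[[i]] <- list(set_id = f[1L], name = f[2L], members = members)
  }
  out
}

#' Read a plain-text motif file
#'
#' One motif per line: id, sequence, maximum mismatches (whitespace
#' separated).
#'
#' @param path Path to the motif file.
#' @return List of [motif()] objects.
#' @export
read_motif_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (length(f) != 3L)
      .stop_fmt("motif file line %d: need 'id sequence max_mismatches'", i)
    motif(f[2L], motif_id = f[1L], max_mismatches = as.integer(f[3L]))
  })
}

#' Derive per-gene SICER significance flags from island BED files
#'
#' The study's SICER runs call significant islands of Pol II enrichment
#' per sample; this helper maps them to per-gene booleans by >= 1 bp
#' overlap between an island and the gene body.
#'
#' @param models Gene models as from [read_gene_models()].
#' @param island_files Named character vector of BED paths (>= 3 columns:
#'   chrom, start, end), one per condition in [SIGNAL_CONDITIONS].
#' @return data.frame with `gene_id` and the four `sig_*` flag columns.
#' @export
sicer_flags_from_islands <- function(models, island_files) {
  if (!all(SIGNAL_CONDITIONS %in% names(island_files)))
    .stop_fmt("island_files must name all of: %s",
              paste(SIGNAL_CONDITIONS, collapse = ", "))
  genes <- GenomicRanges::GRanges(
    models$chrom,
    IRanges::IRanges(start = models$start + 1L, end = models$end))
  out <- data.frame(gene_id = models$gene_id, stringsAsFactors = FALSE)
  for (cond in SIGNAL_CONDITIONS) {
    isl <- utils::read.table(island_files[[cond]], header = FALSE,
                             sep = "\t", stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
      as.character(isl[[1L]]),
      IRanges::IRanges(start = as.integer(isl[[2L]]) + 1L,
                       end = as.integer(isl[[3L]])))
    hit <- GenomicRanges::countOverlaps(genes, gr, minoverlap = 1L) > 0L
    out[[.flag_cols[[cond]]]] <- hit
  }
  out
}

#' Write / read a pool-assignment report
#'
#' Columns: gene_id, the six pool membership flags, the regulation sign
#' and the three decision ratios.
#'
#' @param assignments data.frame as returned by [assign_pools()].
#' @param path File path.
#' @return `path` (writer) or the assignment data.frame (reader).
#' @export
write_pool_report <- function(assignments, path) {
  out <- assignments
  for (cl in grep("^in_pool", names(out), value = TRUE))
    out[[cl]] <- as.integer(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_report
#' @export
read_pool_report <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (cl in grep("^in_pool", names(raw), value = TRUE))
    raw[[cl]] <- as.logical(raw[[cl]])
  raw
}
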