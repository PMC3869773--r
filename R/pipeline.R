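# End-to-end orchestration: simulate or ingest a peak table, filter to
# Pool 1, classify the dependence pools, and optionally run gene-set
# enrichment, de novo motif discovery and the three-way overlap, writing
# each stage's artifacts before the next starts.

#' Run the classification pipeline from a configuration
#'
#' The configuration is a YAML file (or an equivalent nested list) with
#' one section per stage:
#'
#' * `simulate`: arguments for [simulation_config()] (mutually exclusive
#'   with `input`);
#' * `input`: `peak_table` path (TSV read by [read_gene_peak_table()]);
#' * `filter`: `min_peak`, `require_sicer`;
#' * `classify`: any [classifier_config()] threshold;
#' * `gene_sets` (optional): `gmt` path; the target list is the
#'   positively regulated Pool 2 genes and the background the active
#'   unregulated genes;
#' * `denovo` (optional, simulation-backed runs only): `k`, `max_mm`,
#'   `min_fold`, promoter discovery over the simulated genome;
#' * `overlap` (optional): paths `a`, `b`, `c` of one-gene-per-line
#'   lists.
#'
#' Stages run in fixed order; rerunning with an identical configuration
#' reproduces identical outputs.
#'
#' @param config Path to a YAML file or a nested list.
#' @param outdir Output directory (created if needed); defaults to
#'   `config$outdir` or a temporary directory.
#' @return The run summary (also written as `summary.json`), invisibly:
#'   pool counts, sign split, artifact file names (relative to the run
#'   directory, which is returned as `outdir`), seed and a configuration
#'   hash.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) outdir <- tempfile("polpool_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  has_sim <- !is.null(config$simulate)
  has_input <- !is.null(config$input$peak_table)
  if (has_sim == has_input)
    .stop_fmt("configuration error: exactly one of 'simulate' or 'input.peak_table' must be given")

  cfg_hash <- .config_hash(config)

  # --- stage: input -------------------------------------------------
  sim <- NULL
  if (has_sim) {
    sim_cfg <- do.call(simulation_config, config$simulate)
    sim <- simulate_peak_table(sim_cfg)
    tbl <- sim$table
    utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tbl <- tryCatch(read_gene_peak_table(config$input$peak_table),
                    error = function(e)
                      .stop_fmt("stage 'input' failed on '%s': %s",
                                config$input$peak_table,
                                conditionMessage(e)))
  }
  write_gene_peak_table(tbl, file.path(outdir, "peaks.tsv"))
  message(sprintf("[input] %d genes", nrow(tbl)))

  # --- stage: filter + classify ------------------------------------
  af <- do.call(active_filter_config,
                config$filter %||% list())
  cc <- do.call(classifier_config, config$classify %||% list())
  assignments <- assign_pools(tbl, af, cc)
  counts <- pool_summary(assignments)
  write_pool_report(assignments, file.path(outdir, "pools.tsv"))
  writeLines(assignments$gene_id[assignments$in_pool1],
             file.path(outdir, "pool1.txt"))
  message(sprintf("[classify] pool1=%d pool2=%d (pos=%d neg=%d) pool3=%d pool4=%d pool5=%d pool6=%d",
                  counts["n_pool1"], counts["n_pool2"],
                  counts["n_positive"], counts["n_negative"],
                  counts["n_pool3"], counts["n_pool4"],
                  counts["n_pool5"], counts["n_pool6"]))

  # artifact paths are recorded relative to the run directory so that
  # summaries of identical runs are byte-identical wherever they land
  artifacts <- list(peak_table = "peaks.tsv", pools = "pools.tsv",
                    pool1 = "pool1.txt")

  # --- stage: gene-set enrichment (optional) -----------------------
  if (!is.null(config$gene_sets)) {
    sets <- read_gene_sets(config$gene_sets$gmt)
    target <- assignments$gene_id[assignments$regulation_sign == "positive"]
    background <- assignments$gene_id[assignments$in_pool1 &
                                        !assignments$in_pool2]
    enr <- gene_set_enrichment(target, background, sets)
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$enrichment <- "enrichment.tsv"
    message(sprintf("[enrich] %d gene sets scored", nrow(enr)))
  }

  # --- stage: de novo motif discovery (optional, simulation-backed) -
  if (!is.null(config$denovo)) {
    if (!has_sim)
      .stop_fmt("stage 'denovo' requires a simulation-backed run")
    gen <- simulate_genome_with_motifs(sim$config, truth = sim$truth)
    proms <- extract_promoters(gen$models, gen$genome)
    targets <- proms[gen$truth$is_target]
    background <- proms[gen$truth$class == "no_change"]
    dn <- denovo_discover(targets, background,
                          k = config$denovo$k %||% 10L,
                          max_mm = config$denovo$max_mm %||% 1L,
                          min_fold = config$denovo$min_fold %||% 3.5)
    utils::write.table(dn, file.path(outdir, "denovo_motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$denovo <- "denovo_motifs.tsv"
    message(sprintf("[denovo] %d motif(s) reported", nrow(dn)))
  }

  # --- stage: three-way overlap (optional) -------------------------
  if (!is.null(config$overlap)) {
    ov <- config$overlap
    vv <- venn3(readLines(ov$a), readLines(ov$b), readLines(ov$c),
                set_names = c(ov$name_a %||% "A", ov$name_b %||% "B",
                              ov$name_c %||% "C"))
    # named atomic vectors serialize as arrays; keep the region names
    json_vv <- list(region_counts = as.list(vv$region_counts),
                    region_members = vv$region_members)
    jsonlite::write_json(json_vv, file.path(outdir, "venn.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    artifacts$venn <- "venn.json"
    message(sprintf("[overlap] union of %d genes partitioned",
                    sum(vv$region_counts)))
  }

  summary <- list(seed = if (has_sim) sim$config$seed else NULL,
                  config_hash = cfg_hash,
                  n_input = nrow(tbl),
                  counts = as.list(counts),
                  artifacts = artifacts)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  summary$outdir <- outdir
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable hash of a configuration: canonical JSON -> md5
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
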