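# Synthetic peak tables, gene models and genome sequences with known
# ground truth.  Planted dependence classes are threshold-separated by a
# multiplicative margin, so classifier recovery is exact by construction
# whenever the (bounded) noise cannot cross a threshold.

#' Planted dependence classes
#'
#' The per-gene class labels the generator can plant: an inactive
#' stratum, a no-change stratum, and the six pool-by-sign combinations
#' of the decision tree.
#'
#' @format Character vector of length 8.
#' @export
SIM_CLASSES <- c("inactive", "no_change",
                 "pool4_pos", "pool4_neg",
                 "pool5_pos", "pool5_neg",
                 "pool6_pos", "pool6_neg")

# default class proportions: the study-scale instance (25,677 genes in
# the unfiltered universe; 8,062 active; 2,744 PARP-14-dependent split
# 1,647 / 756 / 341 across Pools 4/5/6 with a 2,314:430 positive:negative
# ratio applied uniformly across pools)
.default_proportions <- function() {
  pos_frac <- 2314 / 2744
  p <- c(inactive = (25677 - 8062) / 25677,
         no_change = (8062 - 2744) / 25677,
         pool4_pos = 1647 / 25677 * pos_frac,
         pool4_neg = 1647 / 25677 * (1 - pos_frac),
         pool5_pos = 756 / 25677 * pos_frac,
         pool5_neg = 756 / 25677 * (1 - pos_frac),
         pool6_pos = 341 / 25677 * pos_frac,
         pool6_neg = 341 / 25677 * (1 - pos_frac))
  p / sum(p)
}

#' Simulation configuration
#'
#' Parameters of the synthetic four-condition peak-table and
#' motif-planting generators.  Defaults reproduce the statistical
#' structure of the study: class proportions follow the printed
#' gene-count instance, baselines are log-normal (positive, right-skewed
#' like tag densities), and planted ratios clear every classifier
#' threshold by the multiplicative `effect_margin` so that recovery is
#' exact.  Multiplicative log-normal noise is clamped to two standard
#' deviations; when `exp(4 * noise_sd) < effect_margin` no noised ratio
#' can cross a threshold and recovery is exact (a warning is issued for
#' configurations that break this guarantee).
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named numeric over [SIM_CLASSES], summing
#'   to 1 (normalized if within 1e-6).
#' @param base_peak_log_mean,base_peak_log_sd Log-normal baseline of the
#'   higher-signal sample's peak value.
#' @param effect_margin Multiplicative margin by which planted ratios
#'   clear thresholds (> 1).
#' @param input_level Mean input peak for active genes.
#' @param inactive_input_level Input peak for inactive genes (set above
#'   their signal so both keep-clauses fail).
#' @param noise_sd Log-scale standard deviation of the per-condition
#'   multiplicative noise (clamped at 2 sd).
#' @param motif_plant_rate_target,motif_plant_rate_background Probability
#'   of planting one motif copy in the promoter of a target
#'   (positively-regulated Pool 2) vs any other gene.
#' @param planted_motif A [motif()] object to plant.
#' @param seed Integer seed driving all draws.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L,
                              class_proportions = NULL,
                              base_peak_log_mean = log(1.5),
                              base_peak_log_sd = 0.6,
                              effect_margin = 1.2,
                              input_level = 0.2,
                              inactive_input_level = 0.6,
                              noise_sd = 0.02,
                              motif_plant_rate_target = 0.4,
                              motif_plant_rate_background = 0.05,
                              planted_motif = motif("CAGTCCGATA"),
                              seed = 1L) {
  if (is.null(class_proportions)) class_proportions <- .default_proportions()
  if (is.character(planted_motif)) planted_motif <- motif(planted_motif)
  if (!all(SIM_CLASSES %in% names(class_proportions)))
    .stop_fmt("class_proportions must name all of: %s",
              paste(SIM_CLASSES, collapse = ", "))
  class_proportions <- class_proportions[SIM_CLASSES]
  if (abs(sum(class_proportions) - 1) > 1e-6)
    .stop_fmt("class_proportions must sum to 1 (got %.6f)",
              sum(class_proportions))
  class_proportions <- class_proportions / sum(class_proportions)
  if (effect_margin <= 1) .stop_fmt("effect_margin must exceed 1")
  if (exp(4 * noise_sd) >= effect_margin)
    warning(sprintf("exp(4 * noise_sd) = %.3f >= effect_margin = %.3f: noise can cross thresholds, recovery is no longer guaranteed exact",
                    exp(4 * noise_sd), effect_margin), call. = FALSE)
  stopifnot(motif_plant_rate_target >= 0, motif_plant_rate_target <= 1,
            motif_plant_rate_background >= 0,
            motif_plant_rate_background <= 1,
            inherits(planted_motif, "motif"))
  structure(list(n_genes = as.integer(n_genes),
                 class_proportions = class_proportions,
                 base_peak_log_mean = base_peak_log_mean,
                 base_peak_log_sd = base_peak_log_sd,
                 effect_margin = effect_margin,
                 input_level = input_level,
                 inactive_input_level = inactive_input_level,
                 noise_sd = noise_sd,
                 motif_plant_rate_target = motif_plant_rate_target,
                 motif_plant_rate_background = motif_plant_rate_background,
                 planted_motif = planted_motif,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# clamped multiplicative log-normal noise factors
.noise_factors <- function(n, sd) {
  eps <- pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
  exp(eps)
}

.truth_pools <- function(class) {
  pool2 <- class %in% c("pool4_pos", "pool4_neg", "pool5_pos", "pool5_neg",
                        "pool6_pos", "pool6_neg")
  data.frame(
    in_pool1 = class != "inactive",
    in_pool2 = pool2,
    in_pool3 = class %in% c("pool5_pos", "pool5_neg", "pool6_pos",
                            "pool6_neg"),
    in_pool4 = class %in% c("pool4_pos", "pool4_neg"),
    in_pool5 = class %in% c("pool5_pos", "pool5_neg"),
    in_pool6 = class %in% c("pool6_pos", "pool6_neg"))
}

#' Simulate a four-condition peak table with planted dependence classes
#'
#' Draws a class for every gene, then constructs the four condition peaks
#' so that every relevant decision ratio lands on the planted side of its
#' threshold with margin: the WT/KO ratio is `up_ratio * margin` for
#' positive genes and `down_ratio / margin` for negative ones; the PJ34
#' ratios sit at 1 (inside the no-change band) or at
#' `band_upper * margin` (outside it) according to the planted pool.
#' Inactive genes receive sub-threshold peaks, an input above their
#' signal, and all-FALSE SICER flags; active genes carry TRUE flags.
#'
#' @param config A [simulation_config()].
#' @param classifier_cfg The [classifier_config()] whose thresholds the
#'   planted margins are built against.
#' @return List with `table` (a peak table), `truth` (data.frame of
#'   planted class, sign and pool memberships per gene), and `config`.
#' @export
simulate_peak_table <- function(config = simulation_config(),
                                classifier_cfg = classifier_config()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- config$n_genes
  m <- config$effect_margin
  class <- sample(SIM_CLASSES, n, replace = TRUE,
                  prob = config$class_proportions)
  sign <- ifelse(grepl("_pos$", class), "positive",
                 ifelse(grepl("_neg$", class), "negative", "none"))
  active <- class != "inactive"

  # baseline = the higher-signal sample's peak; floored so the active
  # filter threshold is cleared with margin even at maximal down-noise
  floor_peak <- 0.5 * m
  b <- stats::rlnorm(n, config$base_peak_log_mean, config$base_peak_log_sd)
  while (any(low <- active & b < floor_peak))
    b[low] <- stats::rlnorm(sum(low), config$base_peak_log_mean,
                            config$base_peak_log_sd)

  up <- classifier_cfg$up_ratio * m            # planted positive WT/KO
  dn <- classifier_cfg$down_ratio / m          # planted negative WT/KO
  out_band <- classifier_cfg$no_change_band[2L] * m  # outside no-change

  wt <- ko <- numeric(n)
  wt[sign == "positive"] <- b[sign == "positive"]
  ko[sign == "positive"] <- b[sign == "positive"] / up
  wt[sign == "negative"] <- b[sign == "negative"] * dn
  ko[sign == "negative"] <- b[sign == "negative"]
  nc <- sign == "none" & active
  wt[nc] <- b[nc]; ko[nc] <- b[nc]

  art_ratio <- ifelse(class %in% c("pool5_pos", "pool5_neg", "pool6_pos",
                                   "pool6_neg"), out_band, 1)
  parp_art_ratio <- ifelse(class %in% c("pool6_pos", "pool6_neg"),
                           out_band, 1)
  wt_pj <- wt / art_ratio
  ko_pj <- ko / parp_art_ratio
  input <- rep(config$input_level, n)

  # inactive genes: low flat signal, input above it, no SICER calls
  n_in <- sum(!active)
  if (n_in) {
    for (v in c("wt", "ko", "wt_pj", "ko_pj"))
      assign(v, replace(get(v), !active, stats::runif(n_in, 0.02, 0.35)))
    input[!active] <- config$inactive_input_level
  }

  tbl <- data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
                    wt = wt * .noise_factors(n, config$noise_sd),
                    ko = ko * .noise_factors(n, config$noise_sd),
                    wt_pj34 = wt_pj * .noise_factors(n, config$noise_sd),
                    ko_pj34 = ko_pj * .noise_factors(n, config$noise_sd),
                    input = input * .noise_factors(n, config$noise_sd),
                    sig_wt = active, sig_ko = active,
                    sig_wt_pj34 = active, sig_ko_pj34 = active,
                    stringsAsFactors = FALSE)
  truth <- cbind(data.frame(gene_id = tbl$gene_id, class = class,
                            sign = sign, stringsAsFactors = FALSE),
                 .truth_pools(class))
  list(table = tbl, truth = truth, config = config)
}

#' Simulate a genome with motif copies planted in promoters
#'
#' Lays one gene per contig on an i.i.d. uniform-ACGT background, draws a
#' dependence class per gene (or reuses the classes of a supplied
#' `truth`), and plants one copy of the configured motif in the promoter
#' window of each selected gene: positively-regulated Pool 2 genes
#' ("targets") are selected at `motif_plant_rate_target`, every other
#' gene at `motif_plant_rate_background`.  The copy is written in
#' promoter orientation at a uniformly drawn window offset, so the
#' extracted promoter contains the motif verbatim.
#'
#' @param config A [simulation_config()].
#' @param gene_length Gene-body length in bases.
#' @param contig_margin Bases flanking the gene body on each side of its
#'   contig; must exceed the promoter window for unclipped extraction.
#' @param window A [promoter_window()].
#' @param truth Optional truth data.frame from [simulate_peak_table()]
#'   run with the same config, to keep gene classes consistent across
#'   the two generators.
#' @return List with `genome` (named character vector), `models` (gene
#'   models data.frame), `truth` (per-gene class, target status, planted
#'   flag, local and genomic plant coordinates), and `config`.
#' @export
simulate_genome_with_motifs <- function(config = simulation_config(),
                                        gene_length = 500L,
                                        contig_margin = 1200L,
                                        window = promoter_window(),
                                        truth = NULL) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 7919L)  # deterministic sub-stream
  n <- config$n_genes
  if (is.null(truth)) {
    class <- sample(SIM_CLASSES, n, replace = TRUE,
                    prob = config$class_proportions)
  } else {
    stopifnot(nrow(truth) == n)
    class <- truth$class
  }
  is_target <- class %in% c("pool4_pos", "pool5_pos", "pool6_pos")
  strand <- sample(c("+", "-"), n, replace = TRUE)
  contig_len <- gene_length + 2L * as.integer(contig_margin)
  mot <- config$planted_motif
  kmot <- nchar(mot$sequence)
  win_len <- window$upstream + window$downstream
  stopifnot(contig_margin >= window$upstream + 1L,
            win_len >= kmot)

  genome <- character(n)
  models <- data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
                       chrom = sprintf("contig%05d", seq_len(n)),
                       start = rep(as.integer(contig_margin), n),
                       end = rep(as.integer(contig_margin) + gene_length, n),
                       strand = strand, stringsAsFactors = FALSE)
  models$tss <- ifelse(strand == "+", models$start, models$end - 1L)

  rate <- ifelse(is_target, config$motif_plant_rate_target,
                 config$motif_plant_rate_background)
  planted <- stats::runif(n) < rate
  local_offset <- ifelse(planted,
                         floor(stats::runif(n) * (win_len - kmot + 1)), NA)
  genomic_start <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    contig <- paste(sample(c("A", "C", "G", "T"), contig_len,
                           replace = TRUE), collapse = "")
    if (planted[i]) {
      u <- local_offset[i]
      tss <- models$tss[i]
      if (strand[i] == "+") {
        g <- (tss - window$upstream) + u
        substr(contig, g + 1L, g + kmot) <- mot$sequence
      } else {
        # local index u maps to genomic end tss + upstream - u + 1
        g <- tss + window$upstream + 1L - u - kmot
        substr(contig, g + 1L, g + kmot) <- .revcomp(mot$sequence)
      }
      genomic_start[i] <- g
    }
    genome[i] <- contig
  }
  names(genome) <- models$chrom
  truth_out <- data.frame(gene_id = models$gene_id, class = class,
                          is_target = is_target, planted = planted,
                          local_offset = local_offset,
                          genomic_start = genomic_start,
                          plant_strand = ifelse(planted, strand,
                                                NA_character_),
                          stringsAsFactors = FALSE)
  list(genome = genome, models = models, truth = truth_out,
       config = config)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
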