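#' Simulate true expression profiles with ground truth
#'
#' Assigns each ohnolog family a differential-expression status (probability
#' `frac_de`) and, for DE families, an archetype time profile. Archetypes
#' are inherited down the family tree: at each retained duplication node of
#' WGD level k the younger (right) branch switches to a different archetype
#' with probability `frac_subfunctionalized[k]`, so retained pairs are
#' concordant except for a controlled subfunctionalized subset. A fraction
#' `frac_pseudogene` of retained recent pairs has one member pseudogenized:
#' forced flat at a lowered baseline.
#'
#' @param genome a `wgd_genome` or `ohnolog_families` table.
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{truth}{data.frame `gene_id`, `archetype` (`"flat"` for non-DE
#'       and pseudogenes), `pseudogene` (logical), `baseline` (log2).}
#'     \item{pairs}{data.frame of retained WGD1 pairs: `gene_a`, `gene_b`,
#'       `subfunctionalized` (both non-flat with distinct archetypes).}
#'     \item{means}{numeric matrix, gene x timepoint true log2 means.}
#'   }
#' @export
simulate_expression <- function(genome, config) {
  validate_sim_config(config)
  families <- if (inherits(genome, "wgd_genome")) genome$families else genome
  arch_names <- names(config$archetypes)
  tp <- experiment_timepoints(config$experiment)
  set.seed(config$seed + 2L)

  genes <- families$gene_id
  archetype <- stats::setNames(rep("flat", length(genes)), genes)
  fam_ids <- unique(families$family_id)
  path_by_fam <- split(families$wgd_path, families$family_id)[fam_ids]
  gene_by_fam <- split(families$gene_id, families$family_id)[fam_ids]
  de_fam <- stats::runif(length(fam_ids)) < config$frac_de
  for (fi in which(de_fam)) {
    fam_arch <- sample(arch_names, 1L)
    archetype[gene_by_fam[[fi]]] <-
      assign_archetypes(path_by_fam[[fi]], fam_arch, 3L, config)
  }

  # pseudogenization of one member of some retained recent pairs
  pseudo <- stats::setNames(rep(FALSE, length(genes)), genes)
  pairs0 <- wgd1_pairs(families)
  if (nrow(pairs0)) {
    hit <- stats::runif(nrow(pairs0)) < config$frac_pseudogene
    pick_b <- stats::runif(nrow(pairs0)) < 0.5
    victims <- ifelse(pick_b, pairs0$gene_b, pairs0$gene_a)[hit]
    pseudo[victims] <- TRUE
    archetype[victims] <- "flat"
  }

  # basal expression is strongly correlated within a family: ohnologs keep
  # similar expression levels (dosage balance), so most baseline spread is
  # between families
  fam_id <- families$family_id[match(genes, families$gene_id)]
  fam_base <- stats::rnorm(length(unique(fam_id)), config$baseline_mean,
                           config$baseline_sd * sqrt(0.8))
  names(fam_base) <- unique(fam_id)
  baseline <- fam_base[fam_id] +
    stats::rnorm(length(genes), 0, config$baseline_sd * sqrt(0.2))
  baseline[pseudo] <- baseline[pseudo] - config$pseudogene_baseline_shift
  names(baseline) <- genes

  means <- matrix(baseline, nrow = length(genes), ncol = length(tp),
                  dimnames = list(genes, tp))
  de <- archetype != "flat"
  if (any(de)) {
    offsets <- do.call(rbind, config$archetypes)[archetype[de], , drop = FALSE]
    means[de, ] <- means[de, , drop = FALSE] + offsets
  }

  pairs <- wgd1_pairs(families)
  if (nrow(pairs)) {
    a <- archetype[pairs$gene_a]; b <- archetype[pairs$gene_b]
    pairs$subfunctionalized <- a != "flat" & b != "flat" & a != b
  }

  truth <- data.frame(gene_id = genes, archetype = unname(archetype),
                      pseudogene = unname(pseudo),
                      baseline = unname(baseline), stringsAsFactors = FALSE)
  list(truth = truth, pairs = pairs, means = means)
}

# walk a family's retained duplication nodes from the oldest level down,
# switching the right branch to a new archetype with the per-level
# subfunctionalization probability
assign_archetypes <- function(paths, arch, level, config) {
  if (length(paths) == 1L || level == 0L) {
    return(rep(arch, length(paths)))
  }
  comp1 <- parse_wgd_path(paths[1])
  if (!(as.character(level) %in% names(comp1))) {
    return(assign_archetypes(paths, arch, level - 1L, config))
  }
  side <- vapply(paths, function(p) parse_wgd_path(p)[[as.character(level)]],
                 character(1))
  left <- side == "L"
  arch_r <- arch
  if (stats::runif(1) < config$frac_subfunctionalized[level]) {
    pool <- setdiff(names(config$archetypes), arch)
    arch_r <- sample(pool, 1L)
  }
  out <- character(length(paths))
  out[left] <- assign_archetypes(paths[left], arch, level - 1L, config)
  out[!left] <- assign_archetypes(paths[!left], arch_r, level - 1L, config)
  out
}

# all retained WGD1 pairs in a family table
wgd1_pairs <- function(families) {
  partner <- wgd1_partner_map(families)
  keep <- !is.na(partner) & names(partner) < partner  # each pair once
  data.frame(gene_a = names(partner)[keep],
             gene_b = unname(partner[keep]),
             subfunctionalized = logical(sum(keep)),
             stringsAsFactors = FALSE)
}

# stage-wise nuclear morphology ranges used by the generator (fractions of
# cells showing each state); draws are uniform within each range
morphology_ranges <- function() {
  list(
    VEG  = list(vegetative = c(0.95, 1.00), meiosis = c(0, 0),
                skein = c(0, 0), fragmented = c(0, 0),
                anlagen = c(0, 0), karyonide = c(0, 0)),
    MEI  = list(vegetative = c(0.50, 0.70), meiosis = c(0.20, 0.39),
                skein = c(0.00, 0.05), fragmented = c(0.00, 0.03),
                anlagen = c(0, 0), karyonide = c(0, 0)),
    FRAG = list(vegetative = c(0.10, 0.25), meiosis = c(0.20, 0.29),
                skein = c(0.05, 0.10), fragmented = c(0.37, 0.43),
                anlagen = c(0, 0), karyonide = c(0, 0)),
    DEV1 = list(vegetative = c(0.00, 0.05), meiosis = c(0.00, 0.05),
                skein = c(0.00, 0.05), fragmented = c(0.35, 0.50),
                anlagen = c(0.35, 0.44), karyonide = c(0, 0)),
    DEV2 = list(vegetative = c(0.00, 0.02), meiosis = c(0, 0),
                skein = c(0, 0), fragmented = c(0.00, 0.20),
                anlagen = c(0.73, 0.95), karyonide = c(0.00, 0.03)),
    DEV3 = list(vegetative = c(0.00, 0.02), meiosis = c(0, 0),
                skein = c(0, 0), fragmented = c(0.00, 0.10),
                anlagen = c(0.73, 0.90), karyonide = c(0.02, 0.08))
  )
}

# nominal collection times (hours) per autogamy stage; DEV3 is >= 10 h
# after DEV2 so time metadata can resolve the two stages
stage_hours <- c(VEG = 0, MEI = 5, FRAG = 8, DEV1 = 11, DEV2 = 15, DEV3 = 25,
                 T0 = 0, T1 = 0.6, T2 = 2.1)

#' Simulate probe-level signals and the sample sheet
#'
#' Per sample (timepoint x replicate), each probe's log2 signal is its
#' gene's true mean plus a fixed per-probe affinity offset, an additive
#' cross-hybridization contribution from a near-identical recent paralog
#' (linear scale, weight `crosshyb_weight`), and Gaussian noise. Autogamy
#' sample sheets carry nuclear-morphology fractions drawn uniformly within
#' each stage's observed range. With `raw = TRUE` the matrix is returned on
#' the linear intensity scale with additive Gaussian optical background, as
#' input for [background_correct()].
#'
#' @param means gene x timepoint true log2 means (from
#'   [simulate_expression()]).
#' @param probes probe table (from [simulate_transcripts_probes()]).
#' @param config a [sim_config()].
#' @param families optional `ohnolog_families` table enabling
#'   cross-hybridization between recent pairs (identity >=
#'   `crosshyb_min_identity`).
#' @param raw return linear-scale intensities with additive background
#'   instead of clean log2 signals.
#' @return list with `matrix` (probe x sample), `sheet` (sample sheet
#'   data.frame) and `scale` (`"log2"` or `"linear"`).
#' @export
simulate_probe_signals <- function(means, probes, config, families = NULL,
                                   raw = FALSE) {
  validate_sim_config(config)
  tp <- experiment_timepoints(config$experiment)
  stopifnot(all(tp %in% colnames(means)))
  if (!all(probes$gene_id %in% rownames(means))) {
    stop("every probe's gene must have an expression profile")
  }
  set.seed(config$seed + 3L)

  sheet <- make_sample_sheet(config)
  g <- probes$gene_id
  affinity <- stats::rnorm(nrow(probes), 0, config$probe_affinity_sd)

  # per-gene cross-hybridizing partner (recent pairs above the identity
  # threshold); contribution is additive on the linear scale
  partner <- NULL
  if (!is.null(families) && config$crosshyb_weight > 0 &&
      config$pair_identity >= config$crosshyb_min_identity) {
    partner <- wgd1_partner_map(families)
  }

  mat <- matrix(NA_real_, nrow = nrow(probes), ncol = nrow(sheet),
                dimnames = list(probes$probe_id, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    m <- means[g, sheet$timepoint[j]]
    if (!is.null(partner)) {
      pg <- partner[g]
      has <- !is.na(pg)
      lin <- 2^m
      lin[has] <- lin[has] + config$crosshyb_weight * 2^means[pg[has], sheet$timepoint[j]]
      m <- log2(lin)
    }
    mat[, j] <- m + affinity + stats::rnorm(nrow(probes), 0, config$noise_sd)
  }
  scale <- "log2"
  if (raw) {
    mat <- 2^mat + matrix(stats::rnorm(length(mat), config$bg_mean, config$bg_sd),
                          nrow = nrow(mat))
    mat[mat <= 0] <- min(mat[mat > 0])
    scale <- "linear"
  }
  list(matrix = mat, sheet = sheet, scale = scale)
}

make_sample_sheet <- function(config) {
  tp <- experiment_timepoints(config$experiment)
  sheet <- expand.grid(replicate = seq_len(config$n_replicates),
                       timepoint = tp, stringsAsFactors = FALSE)
  sheet <- sheet[order(match(sheet$timepoint, tp), sheet$replicate), ]
  sheet <- data.frame(
    sample_id = sprintf("%s_%s_r%d", substr(config$experiment, 1, 3),
                        sheet$timepoint, sheet$replicate),
    experiment = config$experiment,
    timepoint = sheet$timepoint,
    replicate = sheet$replicate,
    replicate_group = sheet$timepoint,
    time_h = unname(stage_hours[sheet$timepoint]),
    stringsAsFactors = FALSE
  )
  morph_cols <- names(morphology_ranges()[[1]])
  for (cc in morph_cols) sheet[[cc]] <- NA_real_
  if (config$experiment == "autogamy") {
    rng <- morphology_ranges()
    for (i in seq_len(nrow(sheet))) {
      r <- rng[[sheet$timepoint[i]]]
      draw <- vapply(r, function(ab) stats::runif(1, ab[1], ab[2]), numeric(1))
      if (sum(draw) > 1) draw <- draw / sum(draw)
      sheet[i, morph_cols] <- draw
    }
  }
  rownames(sheet) <- NULL
  sheet
}

#' One-shot synthetic dataset
#'
#' Runs the full generator chain: genome, transcripts and probes, expression
#' truth, probe signals and sample sheet.
#'
#' @param config a [sim_config()].
#' @param raw emit linear-scale probe intensities with background (see
#'   [simulate_probe_signals()]).
#' @param sequences generate transcripts/probe sequences (slower); if
#'   `FALSE`, a sequence-free probe table (6 probes per gene, 3 per strand)
#'   is fabricated directly.
#' @return list: `config`, `genome`, `transcripts` (or NULL), `probes`,
#'   `truth`, `pairs`, `means`, `matrix`, `sheet`, `scale`.
#' @export
simulate_dataset <- function(config, raw = FALSE, sequences = FALSE) {
  genome <- simulate_genome(config)
  transcripts <- NULL
  if (sequences) {
    sp <- simulate_transcripts_probes(genome, config)
    transcripts <- sp$transcripts
    probes <- sp$probes
  } else {
    genes <- genome$genes
    probes <- data.frame(
      probe_id = sprintf("%s_p%d", rep(genes, each = 6L), rep(1:6, length(genes))),
      gene_id = rep(genes, each = 6L),
      strand = rep(c("+", "-"), 3L * length(genes)),
      offset = rep(c(0L, 100L, 200L, 300L, 400L, 500L), length(genes)),
      sequence = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  expr <- simulate_expression(genome, config)
  sig <- simulate_probe_signals(expr$means, probes, config,
                                families = genome$families, raw = raw)
  list(config = config, genome = genome, transcripts = transcripts,
       probes = probes, truth = expr$truth, pairs = expr$pairs,
       means = expr$means, matrix = sig$matrix, sheet = sig$sheet,
       scale = sig$scale)
}
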