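#' Default expression archetypes
#'
#' Named mean log2 time profiles (offsets from baseline) for each supported
#' experiment. Autogamy profiles are defined over the six nuclear-morphology
#' stages VEG, MEI, FRAG, DEV1, DEV2, DEV3; reciliation and exocytosis
#' recovery over a control point and two post-stimulus points (T0, T1, T2).
#' The autogamy set carries the six co-expression cluster names (early peak,
#' early induction, intermediate induction, late induction, early repression,
#' late repression), reciliation three and exocytosis two.
#'
#' @param experiment one of `"autogamy"`, `"reciliation"`, `"exocytosis"`.
#' @return named list of numeric profile vectors, one per archetype, each
#'   named by timepoint label.
#' @export
default_archetypes <- function(experiment = c("autogamy", "reciliation", "exocytosis")) {
  experiment <- match.arg(experiment)
  tp <- experiment_timepoints(experiment)
  prof <- switch(experiment,
    autogamy = list(
      "early peak"             = c(0,  3.0,  2.0,  0.5,  0.0,  0.0),
      "early induction"        = c(0,  2.0,  2.5,  2.5,  2.5,  2.5),
      "intermediate induction" = c(0,  0.5,  2.0,  3.0,  2.5,  2.0),
      "late induction"         = c(0,  0.0,  0.0,  0.5,  2.5,  3.0),
      "early repression"       = c(0, -2.0, -2.5, -2.5, -2.5, -2.5),
      "late repression"        = c(0,  0.0, -0.5, -1.5, -2.5, -3.0)
    ),
    reciliation = list(
      "early peak"        = c(0,  3.0,  1.0),
      "gradual induction" = c(0,  1.5,  3.0),
      "repression"        = c(0, -1.5, -2.5)
    ),
    exocytosis = list(
      "induced"   = c(0,  2.5,  3.0),
      "repressed" = c(0, -2.0, -2.5)
    )
  )
  lapply(prof, function(p) stats::setNames(p, tp))
}

#' Timepoint labels for an experiment
#' @param experiment experiment name.
#' @return character vector of ordered timepoint labels.
#' @export
experiment_timepoints <- function(experiment = c("autogamy", "reciliation", "exocytosis")) {
  experiment <- match.arg(experiment)
  switch(experiment,
    autogamy    = c("VEG", "MEI", "FRAG", "DEV1", "DEV2", "DEV3"),
    reciliation = c("T0", "T1", "T2"),
    exocytosis  = c("T0", "T1", "T2")
  )
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic paleopolyploid
#' data generator. Defaults encode the study conditions the generator
#' emulates: three nested WGDs with both-copy retention probabilities of
#' 51%, 24% and 8% at the recent, intermediate and old event; an AT-rich
#' genome (ORF GC 30%) probed by GC-biased 50-mers (36%); basal log2
#' expression centred near 10 so sample signal densities centre between 9
#' and 11; and archetype time profiles named after the co-expression
#' clusters of each experiment.
#'
#' @param n_ancestral number of pre-WGD ancestral genes.
#' @param retention_probs length-3 both-copy retention probabilities for the
#'   recent, intermediate and old WGD (in that order).
#' @param experiment experiment whose archetypes and timepoints are simulated.
#' @param archetypes named list of mean log2 profiles; defaults to
#'   [default_archetypes()] for `experiment`.
#' @param frac_de fraction of genes (pairs, for retained duplicates) assigned
#'   a non-flat archetype.
#' @param frac_subfunctionalized length-3 fraction of DE retained pairs at
#'   WGD depth 1..3 given two distinct archetypes.
#' @param frac_pseudogene fraction of retained recent pairs in which one
#'   member is pseudogenizing (flat, low baseline).
#' @param baseline_mean,baseline_sd parameters of the basal log2 expression
#'   (log-normal on the intensity scale).
#' @param noise_sd per-probe Gaussian noise sd, log2 scale.
#' @param probe_affinity_sd sd of the fixed per-probe additive offset, log2.
#' @param crosshyb_weight additive linear-scale fraction of a near-identical
#'   recent paralog's signal picked up by a probe.
#' @param crosshyb_min_identity minimum pair sequence identity for
#'   cross-hybridization to occur.
#' @param pair_identity sequence identity between transcripts of a retained
#'   recent pair.
#' @param n_replicates biological replicates per time point (>= 2).
#' @param transcript_length length of simulated transcripts (nt).
#' @param gc_orf,gc_probe target GC fraction of ORFs and probes.
#' @param pseudogene_baseline_shift log2 drop applied to pseudogene baseline.
#' @param bg_mean,bg_sd mean and sd of the additive Gaussian background used
#'   when raw linear-scale intensities are requested.
#' @param seed RNG seed (mandatory for pipeline runs).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_ancestral = 500,
                       retention_probs = c(0.51, 0.24, 0.08),
                       experiment = "autogamy",
                       archetypes = NULL,
                       frac_de = 0.15,
                       frac_subfunctionalized = c(0.05, 0.10, 0.16),
                       frac_pseudogene = 0.1,
                       baseline_mean = 10,
                       baseline_sd = 0.8,
                       noise_sd = 0.25,
                       probe_affinity_sd = 0.5,
                       crosshyb_weight = 0.3,
                       crosshyb_min_identity = 0.9,
                       pair_identity = 0.95,
                       n_replicates = 3,
                       transcript_length = 1500,
                       gc_orf = 0.30,
                       gc_probe = 0.36,
                       pseudogene_baseline_shift = 2,
                       bg_mean = 64,
                       bg_sd = 16,
                       seed = 1L) {
  experiment <- match.arg(experiment, c("autogamy", "reciliation", "exocytosis"))
  if (is.null(archetypes)) archetypes <- default_archetypes(experiment)
  cfg <- list(
    n_ancestral = as.integer(n_ancestral),
    retention_probs = as.numeric(retention_probs),
    experiment = experiment,
    archetypes = archetypes,
    frac_de = frac_de,
    frac_subfunctionalized = rep_len(as.numeric(frac_subfunctionalized), 3L),
    frac_pseudogene = frac_pseudogene,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    noise_sd = noise_sd,
    probe_affinity_sd = probe_affinity_sd,
    crosshyb_weight = crosshyb_weight,
    crosshyb_min_identity = crosshyb_min_identity,
    pair_identity = pair_identity,
    n_replicates = as.integer(n_replicates),
    transcript_length = as.integer(transcript_length),
    gc_orf = gc_orf,
    gc_probe = gc_probe,
    pseudogene_baseline_shift = pseudogene_baseline_shift,
    bg_mean = bg_mean,
    bg_sd = bg_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$retention_probs) != 3L ||
      any(!is.finite(cfg$retention_probs)) ||
      any(cfg$retention_probs < 0) || any(cfg$retention_probs > 1)) {
    stop("retention_probs must be 3 probabilities in [0, 1]")
  }
  fr <- c(cfg$frac_de, cfg$frac_subfunctionalized, cfg$frac_pseudogene)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("frac_de, frac_subfunctionalized and frac_pseudogene must be in [0, 1]")
  }
  if (cfg$n_ancestral < 1L) stop("n_ancestral must be >= 1")
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2 to permit replicate QC")
  n_arch <- length(cfg$archetypes)
  expected <- c(autogamy = 6L, reciliation = 3L, exocytosis = 2L)[[cfg$experiment]]
  if (n_arch != expected) {
    stop(sprintf("experiment '%s' requires %d archetypes, got %d",
                 cfg$experiment, expected, n_arch))
  }
  tp <- experiment_timepoints(cfg$experiment)
  for (nm in names(cfg$archetypes)) {
    if (length(cfg$archetypes[[nm]]) != length(tp)) {
      stop(sprintf("archetype '%s' must have one value per timepoint", nm))
    }
  }
  if (cfg$noise_sd < 0 || cfg$probe_affinity_sd < 0) stop("noise sds must be >= 0")
  if (cfg$gc_orf < 0 || cfg$gc_orf > 1 || cfg$gc_probe < 0 || cfg$gc_probe > 1) {
    stop("GC targets must be in [0, 1]")
  }
  if (cfg$transcript_length < 6L * 50L) {
    stop("transcript too short for 6 non-overlapping 50-mer probes")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_ancestral, "ancestral genes,", x$experiment, "experiment\n")
  cat("  retention (recent/intermediate/old):",
      paste(x$retention_probs, collapse = "/"), "\n")
  cat("  frac_de:", x$frac_de, " subfunctionalized:",
      paste(x$frac_subfunctionalized, collapse = "/"),
      " pseudogene:", x$frac_pseudogene, "\n")
  cat("  replicates/timepoint:", x$n_replicates, " seed:", x$seed, "\n")
  invisible(x)
}

#' Read or write a simulation configuration file
#'
#' The configuration is stored as a structured key-value (YAML) file;
#' archetype profiles appear as nested named sequences.
#'
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  arch <- raw$archetypes
  if (!is.null(arch)) arch <- lapply(arch, function(p) unlist(p))
  raw$archetypes <- arch
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  out <- unclass(cfg)
  out$archetypes <- lapply(out$archetypes, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}
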