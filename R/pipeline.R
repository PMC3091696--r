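#' Pipeline configuration
#'
#' Assembles the configuration of an end-to-end run. Either a simulation
#' config (synthetic input) or a set of input paths (probe matrix TSV +
#' probe table + sample sheet + ohnolog families) must be supplied.
#'
#' @param experiment experiment name.
#' @param simulate a [sim_config()] to generate the inputs, or NULL.
#' @param inputs named list of paths: `probe_matrix`, `probes`,
#'   `sample_sheet`, `families` (+ optional `subsets`, a named list of gene
#'   list files), used when `simulate` is NULL.
#' @param scale scale of the probe matrix input: `"log2"` (already
#'   background-corrected) or `"linear"` (raw; normexp correction applied).
#' @param de a [de_config()].
#' @param k number of gene clusters; default by experiment (autogamy 6,
#'   reciliation 3, exocytosis 2).
#' @param enrichment an [enrichment_config()] applied to each subset, or
#'   NULL to skip; pipeline enrichment scores subsets in label mode against
#'   the run's DE set.
#' @param select_n cluster only the `select_n` most variable DE genes
#'   (NULL = all DE genes).
#' @param simulate_only stop after writing the simulated inputs.
#' @param outdir output directory (created if missing).
#' @param seed mandatory RNG seed for all stochastic steps.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(experiment = "autogamy", simulate = NULL,
                            inputs = NULL, scale = c("log2", "linear"),
                            de = de_config(), k = NULL,
                            enrichment = enrichment_config(mode = "label"),
                            select_n = NULL, simulate_only = FALSE,
                            outdir = tempfile("wgdexpr_run_"),
                            seed = 1L) {
  scale <- match.arg(scale)
  if (is.null(simulate) && is.null(inputs)) {
    stop("either a simulation config or input paths must be given")
  }
  if (!is.null(inputs)) {
    need <- c("probe_matrix", "probes", "sample_sheet", "families")
    missing_paths <- setdiff(need, names(inputs))
    if (length(missing_paths)) {
      stop("missing input paths: ", paste(missing_paths, collapse = ", "))
    }
    for (nm in need) {
      if (!file.exists(inputs[[nm]])) stop("input file not found: ", inputs[[nm]])
    }
  }
  if (is.null(k)) {
    k <- c(autogamy = 6L, reciliation = 3L, exocytosis = 2L)[[experiment]]
  }
  if (simulate_only && is.null(simulate)) {
    stop("simulate_only requires a simulation config")
  }
  structure(list(experiment = experiment, simulate = simulate,
                 inputs = inputs, scale = scale, de = de, k = k,
                 enrichment = enrichment, select_n = select_n,
                 simulate_only = isTRUE(simulate_only),
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes: simulate (optional) -> background correction (linear input
#' only) -> quantile normalization -> gene summarization -> sample QC ->
#' morphology staging (autogamy) -> differential expression -> co-expression
#' clustering -> subset enrichment (optional) -> ohnolog retention and
#' cluster-concordance analysis. Every intermediate table is written to the
#' output directory together with a JSON manifest (inputs, package version,
#' seed, parameters, stages completed). Identical config and seed give
#' identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main in-memory results (`gene_matrix`,
#'   `sheet`, `qc`, `de`, `clusters`, `retention`, `ohnologs`, `enrichment`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    sim <- run_stage("simulate", simulate_dataset(sim_cfg,
                                                  raw = config$scale == "linear"))
    probe_matrix <- sim$matrix
    probes <- sim$probes
    sheet <- sim$sheet
    families <- sim$genome$families
    write_matrix_tsv(probe_matrix, out("probe_matrix.tsv"))
    write_probes(probes, out("probes.tsv"))
    write_sample_sheet(sheet, out("sample_sheet.tsv"))
    write_families(families, out("families.tsv"))
    write_truth(sim$truth, out("truth.tsv"))
    done("simulate")
    if (config$simulate_only) {
      manifest <- list(package = "wgdexpr",
                       version = as.character(utils::packageVersion("wgdexpr")),
                       experiment = config$experiment, seed = config$seed,
                       scale = sim$scale, simulated = TRUE,
                       stages_completed = stages,
                       outputs = list.files(config$outdir))
      jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                           digits = NA, null = "null")
      return(invisible(list(manifest = manifest)))
    }
  } else {
    probe_matrix <- run_stage("load", read_matrix_tsv(config$inputs$probe_matrix))
    probes <- read_probes(config$inputs$probes)
    sheet <- read_sample_sheet(config$inputs$sample_sheet)
    families <- read_families(config$inputs$families)
    done("load")
  }

  # --- preprocessing --------------------------------------------------
  if (config$scale == "linear") {
    probe_matrix <- run_stage("background_correct",
                              background_correct(probe_matrix, scale = "linear"))
    write_matrix_tsv(probe_matrix, out("probe_matrix_bgcorrected.tsv"))
  }
  done("background_correct")

  probe_matrix <- run_stage("quantile_normalize", quantile_normalize(probe_matrix))
  write_matrix_tsv(probe_matrix, out("probe_matrix_normalized.tsv"))
  done("quantile_normalize")

  gene_matrix <- run_stage("summarize_genes",
                           summarize_genes(probe_matrix, probes))
  write_matrix_tsv(gene_matrix, out("gene_matrix.tsv"), id_col = "gene_id")
  done("summarize_genes")

  qc <- run_stage("qc", qc_samples(gene_matrix, sheet))
  utils::write.table(qc$samples, out("qc_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qc$replicates, out("qc_replicates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  done("qc")

  if (config$experiment == "autogamy" &&
      all(c("meiosis", "fragmented", "anlagen") %in% names(sheet))) {
    staged <- run_stage("stage", stage_samples(sheet, time_h = sheet$time_h))
    sheet$stage <- staged
    write_sample_sheet(sheet, out("sample_sheet_staged.tsv"))
  }
  done("stage")

  # --- differential expression ---------------------------------------
  de_res <- run_stage("de", de_analysis(gene_matrix, sheet, config$de))
  write_de_result(de_res, out("de_table.tsv"), out("de_summary.json"))
  de_genes <- call_de(de_res)
  write_gene_list(de_genes, out("de_genes.txt"))
  done("de")

  # --- clustering -----------------------------------------------------
  clusters <- NULL
  if (length(de_genes) >= config$k && length(de_genes) >= 2L) {
    cl_genes <- de_genes
    if (!is.null(config$select_n) && config$select_n < length(cl_genes)) {
      cl_genes <- select_variable_genes(gene_matrix[cl_genes, , drop = FALSE],
                                        config$select_n)
    }
    clusters <- run_stage("cluster",
                          cluster_genes(gene_matrix, cl_genes, config$k, sheet,
                                        archetypes = default_archetypes(config$experiment)))
    profiles <- cluster_profiles(clusters, gene_matrix, sheet)
    write_clusters(clusters, profiles, out("clusters.tsv"),
                   out("cluster_profiles.tsv"))
  }
  done("cluster")

  # --- enrichment -----------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$enrichment) && !is.null(config$inputs$subsets)) {
    enrichment <- lapply(names(config$inputs$subsets), function(nm) {
      subset <- read_gene_list(config$inputs$subsets[[nm]])
      ec <- config$enrichment
      ec$seed <- config$seed
      res <- run_stage(paste0("enrich:", nm),
                       permutation_enrichment(subset, rownames(gene_matrix),
                                              gene_matrix, sheet, ec,
                                              de_labels = de_genes,
                                              de_cfg = config$de))
      write_enrichment(res, out(sprintf("enrichment_%s.json", nm)),
                       out(sprintf("enrichment_%s_null.tsv", nm)))
      res
    })
    names(enrichment) <- names(config$inputs$subsets)
  }
  done("enrich")

  # --- ohnolog analysis ----------------------------------------------
  retention <- run_stage("wgd", retention_table(
    list(de = de_genes, genome = rownames(gene_matrix)), families))
  ohno <- NULL
  if (!is.null(clusters)) {
    clustered_de <- intersect(de_genes, names(clusters$assignment))
    ohno <- run_stage("wgd", ohnolog_analysis(clustered_de, clusters, families))
    write_ohnolog_analysis(ohno, retention, out("ohnolog_classification.tsv"),
                           out("retention.tsv"), out("ohnolog_summary.json"))
  } else {
    utils::write.table(retention, out("retention.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  done("wgd")

  manifest <- list(
    package = "wgdexpr",
    version = as.character(utils::packageVersion("wgdexpr")),
    experiment = config$experiment,
    seed = config$seed,
    scale = config$scale,
    de = list(fdr = config$de$fdr, fold_change = config$de$fold_change,
              merge_dev23 = config$de$merge_dev23),
    k = config$k,
    simulated = !is.null(config$simulate),
    inputs = config$inputs,
    stages_completed = stages,
    outputs = list.files(config$outdir)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  done("manifest")

  invisible(list(gene_matrix = gene_matrix, sheet = sheet, qc = qc,
                 de = de_res, clusters = clusters, retention = retention,
                 ohnologs = ohno, enrichment = enrichment,
                 manifest = manifest))
}

#' Validate pipeline input files
#'
#' Schema and cross-reference checks for the pipeline's TSV/FASTA inputs:
#' required columns, probe/gene/family/sample id agreement, morphology
#' fraction ranges and sums. Report-only; nothing is raised.
#'
#' @param paths named list of paths (any of `probe_matrix`, `probes`,
#'   `sample_sheet`, `families`, `transcripts`).
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(paths) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  try_read <- function(name, reader) {
    if (is.null(paths[[name]])) return(NULL)
    tryCatch({
      x <- reader(paths[[name]])
      add(paste0(name, ":readable"), TRUE)
      x
    }, error = function(e) {
      add(paste0(name, ":readable"), FALSE, conditionMessage(e))
      NULL
    })
  }
  pm <- try_read("probe_matrix", read_matrix_tsv)
  pr <- try_read("probes", read_probes)
  sh <- try_read("sample_sheet", read_sample_sheet)
  fam <- try_read("families", read_families)
  tr <- try_read("transcripts", read_transcripts)

  if (!is.null(pm)) {
    add("probe_matrix:finite", all(is.finite(pm)),
        "all signals finite")
  }
  if (!is.null(pm) && !is.null(pr)) {
    missing_pr <- setdiff(rownames(pm), pr$probe_id)
    add("probes:cover_matrix", length(missing_pr) == 0L,
        if (length(missing_pr)) paste("unmapped probes:",
                                      paste(utils::head(missing_pr, 5L), collapse = ", "))
        else "")
  }
  if (!is.null(pr) && !is.null(fam)) {
    missing_g <- setdiff(unique(pr$gene_id), fam$gene_id)
    add("probes:genes_in_families", length(missing_g) == 0L,
        if (length(missing_g)) paste("probe genes missing from families:",
                                     paste(utils::head(missing_g, 5L), collapse = ", "))
        else "")
  }
  if (!is.null(pr) && !is.null(tr)) {
    missing_t <- setdiff(unique(pr$gene_id), names(tr))
    add("probes:genes_have_transcripts", length(missing_t) == 0L,
        if (length(missing_t)) paste("missing transcripts:",
                                     paste(utils::head(missing_t, 5L), collapse = ", "))
        else "")
  }
  if (!is.null(pm) && !is.null(sh)) {
    missing_s <- setdiff(colnames(pm), sh$sample_id)
    add("sheet:covers_samples", length(missing_s) == 0L,
        if (length(missing_s)) paste("samples missing from sheet:",
                                     paste(missing_s, collapse = ", "))
        else "")
  }
  if (!is.null(sh)) {
    morph <- intersect(c("vegetative", "meiosis", "skein", "fragmented",
                         "anlagen", "karyonide"), names(sh))
    if (length(morph)) {
      m <- as.matrix(sh[morph])
      have <- rowSums(!is.na(m)) > 0L
      sums <- rowSums(m, na.rm = TRUE)
      in_range <- all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1)
      ok_sum <- all(sums[have] <= 1.05)
      add("sheet:morphology_range", in_range, "fractions in [0, 1]")
      add("sheet:morphology_sum", ok_sum,
          if (!ok_sum) paste("rows with sum > 1.05:",
                             paste(which(have & sums > 1.05), collapse = ", "))
          else "")
    }
  }
  if (!is.null(fam)) {
    parse_ok <- vapply(fam$wgd_path, function(p) {
      comp <- tryCatch(parse_wgd_path(p), error = function(e) NULL)
      if (is.null(comp)) return(FALSE)
      lv <- as.integer(names(comp))
      all(lv %in% 1:3) && !is.unsorted(rev(lv), strictly = TRUE)
    }, logical(1))
    add("families:paths_parse", all(parse_ok),
        if (!all(parse_ok)) paste("bad paths at rows:",
                                  paste(utils::head(which(!parse_ok), 5L), collapse = ", "))
        else "")
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
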