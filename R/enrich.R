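#' Enrichment test configuration
#'
#' @param n_permutations number of random same-size gene sets (default 1000).
#' @param p_threshold per-gene significance threshold within the subset
#'   analysis (default 0.05).
#' @param adjusted threshold the BH-adjusted (TRUE, default) or raw (FALSE)
#'   gene-level p-values.
#' @param mode `"refit"` re-runs the full DE chain on the subset-only
#'   matrix (retaining maximal power after multiplicity correction);
#'   `"label"` counts members of a precomputed DE label set.
#' @param seed RNG seed for the permutations.
#' @return an `enrichment_config` list.
#' @export
enrichment_config <- function(n_permutations = 1000L, p_threshold = 0.05,
                              adjusted = TRUE, mode = c("refit", "label"),
                              seed = 1L) {
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  structure(list(n_permutations = n_permutations, p_threshold = p_threshold,
                 adjusted = isTRUE(adjusted), mode = match.arg(mode),
                 seed = as.integer(seed)),
            class = "enrichment_config")
}

#' Number of differentially expressed genes in a subset
#'
#' In `refit` mode the expression set is rebuilt from the subset only and
#' the full DE chain (fit, empirical Bayes, moderated tests, BH within the
#' subset) is run, counting genes below the threshold. In `label` mode the
#' subset is intersected with a precomputed DE label set.
#'
#' @param subset character vector of gene ids (non-empty, present in the
#'   matrix).
#' @param matrix gene x sample log2 matrix.
#' @param sheet sample sheet.
#' @param config an [enrichment_config()].
#' @param de_labels precomputed DE gene ids (required for `label` mode).
#' @param de_cfg a [de_config()] used in refit mode (its `fdr`/`tau` are
#'   ignored; the enrichment `p_threshold` applies).
#' @return integer count.
#' @export
subset_de_count <- function(subset, matrix, sheet,
                            config = enrichment_config(),
                            de_labels = NULL, de_cfg = de_config()) {
  if (!length(subset)) stop("subset must be non-empty")
  if (config$mode == "label") {
    if (is.null(de_labels)) stop("label mode requires de_labels")
    return(sum(subset %in% de_labels))
  }
  if (!all(subset %in% rownames(matrix))) {
    stop("subset contains genes absent from the matrix")
  }
  fit <- fit_timecourse(matrix[subset, , drop = FALSE], sheet, de_cfg)
  eb <- estimate_ebayes(fit)
  res <- if (de_cfg$tau > 0) treat_tests(fit, eb, de_cfg)
         else moderated_tests(fit, eb, de_cfg)
  p <- if (config$adjusted) res$table$fdr else res$table$p_value
  sum(p < config$p_threshold)
}

#' Random-gene-set permutation enrichment test
#'
#' Scores the subset of interest, then `n_permutations` random gene sets of
#' the same size drawn (without replacement within a draw) from the
#' analyzed universe, each scored identically. The enrichment is the ratio
#' of the observed DE count to the mean null count; the empirical p-value
#' uses the add-one correction p = (1 + #\{null >= observed\}) /
#' (1 + n_permutations), so p is never 0.
#'
#' @param subset gene ids of interest (subset of `universe`).
#' @param universe gene ids of the analyzed universe.
#' @inheritParams subset_de_count
#' @return an `enrichment_result`: list with `observed`, `null_counts`,
#'   `null_mean`, `ratio`, `p_value`, `n_permutations`, `seed`.
#' @export
permutation_enrichment <- function(subset, universe, matrix = NULL,
                                   sheet = NULL,
                                   config = enrichment_config(),
                                   de_labels = NULL, de_cfg = de_config()) {
  if (!length(subset)) stop("subset must be non-empty")
  if (!all(subset %in% universe)) stop("subset must be contained in universe")
  if (length(subset) > length(universe)) stop("subset larger than universe")
  score <- function(genes) subset_de_count(genes, matrix, sheet, config,
                                           de_labels, de_cfg)
  observed <- score(subset)
  set.seed(config$seed)
  null_counts <- vapply(seq_len(config$n_permutations), function(i) {
    score(sample(universe, length(subset)))
  }, numeric(1))
  null_mean <- mean(null_counts)
  structure(list(
    observed = observed, null_counts = null_counts, null_mean = null_mean,
    ratio = if (null_mean > 0) observed / null_mean else Inf,
    p_value = (1 + sum(null_counts >= observed)) / (1 + config$n_permutations),
    n_permutations = config$n_permutations, seed = config$seed
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: observed %d vs null mean %.2f -> %.1f-fold (p = %.4g, %d permutations)\n",
    x$observed, x$null_mean, x$ratio, x$p_value, x$n_permutations))
  invisible(x)
}

#' Venn partition of differentially expressed gene sets
#'
#' All intersection cardinalities of the Venn partition over 2 or 3 DE gene
#' sets (e.g. per experiment), as used to check the independence of the
#' biological processes.
#'
#' @param sets named list of >= 2 character vectors of gene ids.
#' @return data.frame with one row per Venn region: a membership column per
#'   set and `count` (genes in exactly that combination).
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  combos$count <- apply(combos[names(sets)], 1L, function(cb) {
    if (length(universe) == 0L) return(0L)
    sum(apply(member, 1L, function(mm) all(mm == cb)))
  })
  rownames(combos) <- NULL
  combos
}

#' Write enrichment results
#'
#' JSON summary (observed, null mean, ratio, p, permutations, seed) plus an
#' optional TSV of the null counts.
#'
#' @param result an `enrichment_result`.
#' @param json_path,null_tsv_path output paths (NULL to skip).
#' @export
write_enrichment <- function(result, json_path = NULL, null_tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      observed = result$observed, null_mean = result$null_mean,
      ratio = result$ratio, p_value = result$p_value,
      n_permutations = result$n_permutations, seed = result$seed
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(null_tsv_path)) {
    utils::write.table(data.frame(permutation = seq_along(result$null_counts),
                                  n_de = result$null_counts),
                       null_tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(result)
}
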