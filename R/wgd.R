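#' Classify ohnologs of differentially expressed genes by cluster concordance
#'
#' For each DE gene with at least one present-day ohnolog at the given WGD
#' level, compares the gene's co-expression cluster with its relatives'.
#' Genes with no ohnolog at the level are excluded, not categorized.
#'
#' Categories (mutually exclusive, precedence most-concordant first):
#' \describe{
#'   \item{WGD1}{`same cluster` / `different cluster` / `not in cluster`.}
#'   \item{WGD2}{`both in same cluster` (every relative shares the cluster),
#'     `one in same cluster` (at least one shares), `different cluster`
#'     (none shares but at least one is in another cluster),
#'     `none in cluster`.}
#'   \item{WGD3}{`one or more same cluster`, `different cluster`,
#'     `none in cluster`.}
#' }
#'
#' @param de_genes DE gene ids; every one must be in the cluster set.
#' @param clusters a `cluster_set` (see [cut_clusters()]) over the DE genes,
#'   or a named vector gene -> cluster label.
#' @param families `ohnolog_families` table.
#' @param level WGD level (1 recent .. 3 old).
#' @return an `ohnolog_classification`: list with `category` (named factor
#'   per categorized gene), `level`, `n_with_ohnolog`, `categories` (level's
#'   label set).
#' @export
classify_ohnologs <- function(de_genes, clusters, families, level) {
  stopifnot(level %in% 1:3)
  membership <- if (inherits(clusters, "cluster_set")) {
    cluster_membership(clusters)
  } else clusters
  if (!all(de_genes %in% names(membership))) {
    stop("DE gene(s) absent from the cluster set: ",
         paste(setdiff(de_genes, names(membership)), collapse = ", "))
  }
  rel <- relative_table(de_genes, families)
  labels <- ohnolog_categories(level)
  cats <- character(0)
  for (g in de_genes) {
    relatives <- rel[[g]][[level]]
    if (!length(relatives)) next
    own <- membership[[g]]
    rel_cl <- membership[relatives]          # NA when relative unclustered
    n_same <- sum(!is.na(rel_cl) & rel_cl == own)
    n_other <- sum(!is.na(rel_cl) & rel_cl != own)
    cat_g <- if (level == 1L) {
      if (n_same >= 1L) "same cluster"
      else if (n_other >= 1L) "different cluster"
      else "not in cluster"
    } else if (level == 2L) {
      if (n_same == length(relatives)) "both in same cluster"
      else if (n_same >= 1L) "one in same cluster"
      else if (n_other >= 1L) "different cluster"
      else "none in cluster"
    } else {
      if (n_same >= 1L) "one or more same cluster"
      else if (n_other >= 1L) "different cluster"
      else "none in cluster"
    }
    cats[g] <- cat_g
  }
  category <- factor(cats, levels = labels)
  names(category) <- names(cats)
  structure(list(
    category = category,
    level = level,
    n_with_ohnolog = length(cats),
    categories = labels
  ), class = "ohnolog_classification")
}

# Table-style category labels per WGD level
ohnolog_categories <- function(level) {
  switch(level,
    c("same cluster", "different cluster", "not in cluster"),
    c("both in same cluster", "one in same cluster", "different cluster",
      "none in cluster"),
    c("one or more same cluster", "different cluster", "none in cluster")
  )
}

#' Summarize an ohnolog classification into counts and percentages
#'
#' Counts per category and percentages of the level's categorized genes
#' (the "genes with WGDk ohnolog" denominator), percentages rounded to one
#' decimal. Also accepts a bare named count vector, so printed tables can
#' be re-summarized directly.
#'
#' @param classification an `ohnolog_classification`, or a named integer
#'   vector of category counts.
#' @return data.frame `category`, `count`, `percent`, with the denominator
#'   in `attr(, "n_total")`.
#' @export
summarize_classification <- function(classification) {
  if (inherits(classification, "ohnolog_classification")) {
    counts <- table(classification$category)
  } else {
    if (is.null(names(classification))) stop("counts must be named")
    counts <- classification
  }
  n <- sum(counts)
  if (n == 0L) stop("classification is empty")
  out <- data.frame(category = names(counts), count = as.integer(counts),
                    percent = round(100 * as.integer(counts) / n, 1L),
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- n
  out
}

#' Upper bound on the subfunctionalization rate at a WGD level
#'
#' The percentage of categorized genes whose ohnologs fall in a different
#' co-expression cluster. Because weakly divergent profiles can land in
#' adjacent clusters without true partition of function, this percentage is
#' an upper envelope on the subfunctionalization rate, not an estimate.
#'
#' @param classification an `ohnolog_classification` or named count vector.
#' @return percentage (0-100).
#' @export
subfunctionalization_bound <- function(classification) {
  s <- summarize_classification(classification)
  s$percent[s$category == "different cluster"]
}

#' Retention table for gene sets across WGD levels
#'
#' Per gene set and WGD level, the fraction of genes with at least one
#' retained ohnolog, plus the set size.
#'
#' @param gene_sets named list of character vectors (e.g. DE genes per
#'   experiment, and the whole genome).
#' @param families `ohnolog_families` table.
#' @return data.frame `set`, `WGD1`, `WGD2`, `WGD3` (fractions), `n_genes`.
#' @export
retention_table <- function(gene_sets, families) {
  rows <- lapply(names(gene_sets), function(nm) {
    r <- retention_rate(gene_sets[[nm]], families, 1:3)
    data.frame(set = nm, WGD1 = r[["WGD1"]], WGD2 = r[["WGD2"]],
               WGD3 = r[["WGD3"]], n_genes = length(gene_sets[[nm]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full ohnolog analysis for one experiment
#'
#' Runs [classify_ohnologs()] and [summarize_classification()] at every WGD
#' level and collects the per-level subfunctionalization bounds.
#'
#' @param de_genes DE gene ids (all clustered).
#' @param clusters a `cluster_set` over the DE genes.
#' @param families `ohnolog_families` table.
#' @return list with `summary` (long data.frame `level`, `category`,
#'   `count`, `percent`, `n_with_ohnolog`) and `bounds` (named percentage
#'   per level).
#' @export
ohnolog_analysis <- function(de_genes, clusters, families) {
  per_level <- lapply(1:3, function(lv) {
    cl <- classify_ohnologs(de_genes, clusters, families, lv)
    if (cl$n_with_ohnolog == 0L) {
      return(list(summary = NULL, bound = NA_real_))
    }
    s <- summarize_classification(cl)
    s$level <- paste0("WGD", lv)
    s$n_with_ohnolog <- cl$n_with_ohnolog
    list(summary = s, bound = subfunctionalization_bound(cl))
  })
  summary <- do.call(rbind, lapply(per_level, `[[`, "summary"))
  bounds <- stats::setNames(vapply(per_level, `[[`, numeric(1), "bound"),
                            paste0("WGD", 1:3))
  list(summary = summary, bounds = bounds)
}

#' Write ohnolog analysis outputs
#'
#' Retention-table and classification-summary TSVs plus a JSON summary with
#' the per-level subfunctionalization bounds.
#'
#' @param analysis output of [ohnolog_analysis()].
#' @param retention output of [retention_table()] (optional).
#' @param classification_path,retention_path,json_path output paths.
#' @export
write_ohnolog_analysis <- function(analysis, retention = NULL,
                                   classification_path = NULL,
                                   retention_path = NULL, json_path = NULL) {
  if (!is.null(classification_path) && !is.null(analysis$summary)) {
    utils::write.table(analysis$summary, classification_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(retention_path) && !is.null(retention)) {
    utils::write.table(retention, retention_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(subfunctionalization_bounds =
                                as.list(analysis$bounds)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(analysis)
}
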