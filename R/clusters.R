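#' Select the most variable genes
#'
#' Ranks genes by their expression range (max - min log2 signal) across the
#' designated arrays and returns the top `n`, ties broken by gene id.
#'
#' @param matrix gene x sample log2 matrix.
#' @param n number of genes to select.
#' @param samples optional character vector restricting the arrays used.
#' @return character vector of `n` gene ids.
#' @export
select_variable_genes <- function(matrix, n, samples = NULL) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(matrix)) stop("n exceeds the number of genes")
  if (!is.null(samples)) matrix <- matrix[, samples, drop = FALSE]
  rng <- apply(matrix, 1L, function(x) max(x) - min(x))
  ord <- order(-rng, rownames(matrix))
  rownames(matrix)[ord][seq_len(n)]
}

#' Correlation distance matrix
#'
#' Pairwise dissimilarity 1 - correlation between rows (`axis = "genes"`,
#' Pearson by convention) or columns (`axis = "samples"`, Spearman by
#' convention) of an expression matrix. Zero-variance vectors get distance
#' 1 to every other vector (with a message).
#'
#' @param matrix gene x sample matrix.
#' @param axis cluster `"genes"` (rows) or `"samples"` (columns).
#' @param method `"pearson"` or `"spearman"`.
#' @return symmetric `dist`-convertible matrix with zero diagonal.
#' @export
correlation_distance <- function(matrix, axis = c("genes", "samples"),
                                 method = c("pearson", "spearman")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  x <- if (axis == "genes") t(matrix) else matrix
  if (nrow(x) < 3L) stop("need >= 3 observations per vector")
  sds <- apply(x, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(x, method = method))
  if (any(sds == 0)) {
    message(sum(sds == 0), " zero-variance vector(s): distance set to 1")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  d <- 1 - cc
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum pairwise distance between their members, via [stats::hclust()].
#' Merge heights are non-decreasing (complete linkage is monotone).
#'
#' @param distance symmetric distance matrix (or `dist`).
#' @return an `hclust` object.
#' @export
hclust_complete <- function(distance) {
  if (is.matrix(distance)) {
    if (!isSymmetric(unname(distance), tol = 1e-8)) {
      stop("distance matrix must be symmetric")
    }
    distance <- stats::as.dist(distance)
  }
  stats::hclust(distance, method = "complete")
}

#' Cut a gene dendrogram into named co-expression clusters
#'
#' Cuts the dendrogram into `k` clusters and names each by the archetype
#' template whose profile best matches (highest Pearson correlation with)
#' the cluster's mean replicate-averaged time profile. Each archetype is
#' used at most once (greedy best-match assignment); leftover clusters get
#' ordinal names.
#'
#' @param dendrogram an `hclust` over genes.
#' @param k number of clusters (autogamy 6, reciliation 3, exocytosis 2).
#' @param matrix gene x sample log2 matrix (used for naming profiles).
#' @param sheet sample sheet (timepoint per sample).
#' @param archetypes named list of template profiles per timepoint; NULL
#'   gives ordinal names only.
#' @return a `cluster_set`: list with `assignment` (named cluster id per
#'   gene), `names` (cluster id -> name), `k`.
#' @export
cut_clusters <- function(dendrogram, k, matrix = NULL, sheet = NULL,
                         archetypes = NULL) {
  n_leaves <- length(dendrogram$order)
  if (k < 1L || k > n_leaves) stop("k must be between 1 and the leaf count")
  assignment <- stats::cutree(dendrogram, k = k)
  cluster_names <- stats::setNames(paste("cluster", seq_len(k)), seq_len(k))
  if (!is.null(archetypes) && !is.null(matrix) && !is.null(sheet)) {
    prof <- cluster_profiles(assignment, matrix, sheet)
    tmpl <- do.call(rbind, archetypes)
    tp <- colnames(prof$mean)
    tmpl <- tmpl[, tp, drop = FALSE]
    cors <- matrix(NA_real_, nrow = k, ncol = nrow(tmpl),
                   dimnames = list(rownames(prof$mean), rownames(tmpl)))
    for (i in seq_len(k)) for (j in seq_len(nrow(tmpl))) {
      ci <- prof$mean[i, ]
      cors[i, j] <- if (stats::sd(ci) == 0 || stats::sd(tmpl[j, ]) == 0) -Inf
                    else stats::cor(ci, tmpl[j, ])
    }
    # greedy one-to-one assignment, best correlations first
    taken_c <- taken_a <- character(0)
    ord <- order(-cors)
    for (idx in ord) {
      i <- rownames(cors)[(idx - 1L) %% k + 1L]
      j <- colnames(cors)[(idx - 1L) %/% k + 1L]
      if (i %in% taken_c || j %in% taken_a || !is.finite(cors[i, j])) next
      cluster_names[i] <- j
      taken_c <- c(taken_c, i); taken_a <- c(taken_a, j)
    }
  }
  structure(list(assignment = assignment, names = cluster_names, k = k),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- table(x$assignment)
  cat("cluster_set:", x$k, "clusters over", length(x$assignment), "genes\n")
  for (i in names(sizes)) {
    cat(sprintf("  %s: %d genes\n", x$names[i], sizes[[i]]))
  }
  invisible(x)
}

#' Cluster name lookup for genes
#'
#' @param clusters a `cluster_set`.
#' @param genes gene ids (default: all clustered genes).
#' @return named character vector gene -> cluster name (NA if unclustered).
#' @export
cluster_membership <- function(clusters, genes = names(clusters$assignment)) {
  ids <- clusters$assignment[genes]
  out <- unname(clusters$names[as.character(ids)])
  stats::setNames(out, genes)
}

#' Per-cluster mean and sd time profiles
#'
#' For each cluster and timepoint, the mean and standard deviation over
#' member genes of the replicate-averaged log2 signals.
#'
#' @param clusters a `cluster_set` or a named cluster-id vector.
#' @param matrix gene x sample log2 matrix.
#' @param sheet sample sheet with `sample_id`, `timepoint`.
#' @return list with matrices `mean` and `sd` (cluster x timepoint) and
#'   `n` (genes per cluster); empty clusters are flagged via `n = 0`.
#' @export
cluster_profiles <- function(clusters, matrix, sheet) {
  assignment <- if (inherits(clusters, "cluster_set")) clusters$assignment
                else clusters
  genes <- names(assignment)
  if (!all(genes %in% rownames(matrix))) {
    stop("clustered genes missing from the matrix")
  }
  tp_per_sample <- sheet$timepoint[match(colnames(matrix), sheet$sample_id)]
  tp <- unique(tp_per_sample)
  # replicate-averaged signal per gene and timepoint
  repavg <- vapply(tp, function(t) {
    rowMeans(matrix[genes, tp_per_sample == t, drop = FALSE])
  }, numeric(length(genes)))
  dimnames(repavg) <- list(genes, tp)
  ids <- sort(unique(assignment))
  mean_m <- t(vapply(ids, function(cl) {
    colMeans(repavg[assignment == cl, , drop = FALSE])
  }, numeric(length(tp))))
  sd_m <- t(vapply(ids, function(cl) {
    apply(repavg[assignment == cl, , drop = FALSE], 2L, stats::sd)
  }, numeric(length(tp))))
  sd_m[is.na(sd_m)] <- 0  # single-gene clusters
  n <- vapply(ids, function(cl) sum(assignment == cl), integer(1))
  dimnames(mean_m) <- dimnames(sd_m) <- list(ids, tp)
  list(mean = mean_m, sd = sd_m, n = stats::setNames(n, ids))
}

#' Cluster differentially expressed genes end to end
#'
#' Convenience chain: Pearson correlation distance over the DE genes,
#' complete-linkage dendrogram, cut at `k`, archetype naming.
#'
#' @param matrix gene x sample log2 matrix.
#' @param genes DE gene ids to cluster.
#' @param k cluster count.
#' @param sheet sample sheet.
#' @param archetypes archetype templates for naming (optional).
#' @return a `cluster_set`.
#' @export
cluster_genes <- function(matrix, genes, k, sheet, archetypes = NULL) {
  d <- correlation_distance(matrix[genes, , drop = FALSE], axis = "genes",
                            method = "pearson")
  hc <- hclust_complete(d)
  cut_clusters(hc, k, matrix[genes, , drop = FALSE], sheet, archetypes)
}

#' Write cluster assignments and profiles
#'
#' @param clusters a `cluster_set`.
#' @param profiles output of [cluster_profiles()] (optional).
#' @param assignment_path,profile_path output TSV paths.
#' @export
write_clusters <- function(clusters, profiles = NULL,
                           assignment_path = NULL, profile_path = NULL) {
  if (!is.null(assignment_path)) {
    df <- data.frame(gene_id = names(clusters$assignment),
                     cluster_id = unname(clusters$assignment),
                     cluster_name = unname(clusters$names[as.character(clusters$assignment)]),
                     stringsAsFactors = FALSE)
    utils::write.table(df, assignment_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(profile_path) && !is.null(profiles)) {
    long <- do.call(rbind, lapply(rownames(profiles$mean), function(cl) {
      data.frame(cluster_id = cl,
                 cluster_name = unname(clusters$names[cl]),
                 timepoint = colnames(profiles$mean),
                 mean = profiles$mean[cl, ], sd = profiles$sd[cl, ],
                 n_genes = unname(profiles$n[cl]),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(long, profile_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(clusters)
}
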