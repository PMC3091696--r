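#' Quantile normalization
#'
#' Makes every sample's empirical distribution identical: each sample's
#' sorted values are replaced by the across-sample mean of order statistics;
#' ties within a sample receive the mean of the reference values at their
#' tied ranks. Thin wrapper over [limma::normalizeQuantiles()] that
#' preserves row and column labels and handles the single-sample edge case.
#'
#' @param matrix numeric matrix (probes or genes x samples), log2 scale.
#' @return normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (ncol(matrix) < 2L) {
    warning("quantile normalization with a single sample is the identity")
    return(matrix)
  }
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Summarize probe signals to gene signals
#'
#' The signal of a gene in a sample is the median of its probe signals
#' (6 probes per gene on the full platform; genes with fewer usable probes
#' use the median of those available). Genes with zero probes are excluded
#' with a message.
#'
#' @param matrix probe x sample log2 matrix (rownames = probe ids).
#' @param probe_gene_map data.frame with `probe_id`, `gene_id`, or a named
#'   character vector probe_id -> gene_id.
#' @return gene x sample matrix of median log2 signals.
#' @export
summarize_genes <- function(matrix, probe_gene_map) {
  if (is.data.frame(probe_gene_map)) {
    map <- stats::setNames(probe_gene_map$gene_id, probe_gene_map$probe_id)
  } else {
    map <- probe_gene_map
  }
  probes <- rownames(matrix)
  if (is.null(probes)) stop("probe matrix must have probe ids as rownames")
  if (!all(probes %in% names(map))) {
    stop("probe->gene map must cover all probes in the matrix")
  }
  genes <- map[probes]
  idx <- split(seq_along(probes), genes)
  out <- do.call(rbind, lapply(idx, function(i) {
    apply(matrix[i, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  }))
  mapped_genes <- setdiff(unique(unname(map)), rownames(out))
  if (length(mapped_genes)) {
    message(length(mapped_genes), " gene(s) with zero probes excluded")
  }
  out[order(rownames(out)), , drop = FALSE]
}

#' Sample quality control
#'
#' Estimates each sample's density centre as the histogram mode (0.1 log2
#' unit bins); a sample passes if the centre lies in \[9, 11\] and the
#' distribution is roughly symmetric (|mean - median| <= 0.5). Pearson
#' correlations are computed for every within-replicate-group sample pair.
#'
#' @param matrix gene (or probe) x sample log2 matrix.
#' @param sheet sample sheet with `sample_id` and `replicate_group` (pairs
#'   are formed within groups); NULL skips replicate correlations.
#' @param center_range acceptable density-centre interval.
#' @param symmetry_tol maximum |mean - median|.
#' @return a `qc_report`: list with `samples` (data.frame `sample_id`,
#'   `center`, `symmetry`, `pass`) and `replicates` (data.frame
#'   `sample_a`, `sample_b`, `group`, `r`).
#' @export
qc_samples <- function(matrix, sheet = NULL, center_range = c(9, 11),
                       symmetry_tol = 0.5) {
  centers <- apply(matrix, 2L, density_mode)
  symmetry <- apply(matrix, 2L, function(x) {
    abs(mean(x, na.rm = TRUE) - stats::median(x, na.rm = TRUE))
  })
  samples <- data.frame(
    sample_id = colnames(matrix),
    center = unname(centers),
    symmetry = unname(symmetry),
    pass = unname(centers >= center_range[1] & centers <= center_range[2] &
                  symmetry <= symmetry_tol),
    stringsAsFactors = FALSE
  )
  replicates <- data.frame(sample_a = character(0), sample_b = character(0),
                           group = character(0), r = numeric(0),
                           stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    sheet <- sheet[sheet$sample_id %in% colnames(matrix), ]
    for (grp in split(sheet$sample_id, sheet$replicate_group)) {
      if (length(grp) < 2L) next
      for (pair in utils::combn(grp, 2L, simplify = FALSE)) {
        replicates <- rbind(replicates, data.frame(
          sample_a = pair[1], sample_b = pair[2],
          group = sheet$replicate_group[match(pair[1], sheet$sample_id)],
          r = stats::cor(matrix[, pair[1]], matrix[, pair[2]],
                         use = "complete.obs"),
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(samples = samples, replicates = replicates),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", sum(x$samples$pass), "of", nrow(x$samples),
      "samples pass density QC\n")
  if (nrow(x$replicates)) {
    cat(sprintf("  replicate r: %.3f - %.3f (%d pairs)\n",
                min(x$replicates$r), max(x$replicates$r), nrow(x$replicates)))
  }
  invisible(x)
}

# histogram mode with fixed-width bins (0.1 log2 units)
density_mode <- function(x, binwidth = 0.1) {
  x <- x[is.finite(x)]
  breaks <- seq(floor(min(x) / binwidth) * binwidth,
                ceiling(max(x) / binwidth) * binwidth + binwidth, by = binwidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Assign autogamy samples to developmental stages from nuclear morphology
#'
#' Deterministic staging of autogamy time-course samples from the scored
#' fractions of cells in each nuclear-morphology state. Rules, applied in
#' order: VEG if meiosis + fragmented + anlagen < 5%; MEI if meiosis >= 20%
#' and fragmented < 10%; FRAG if fragmented >= 30% and anlagen < 10%; DEV1
#' if anlagen in \[10%, 70%); DEV2 if anlagen >= 70%. DEV3 cannot be
#' separated from DEV2 by morphology; a sample staged DEV2 is relabelled
#' DEV3 when collection-time metadata (`time_h`) places it >= 10 h after the
#' earliest DEV2-morphology sample. Samples matching no rule are assigned
#' the stage with the nearest canonical morphology centroid, so staging is
#' total on the simplex.
#'
#' @param morphology data.frame with columns `vegetative`, `meiosis`,
#'   `skein`, `fragmented`, `anlagen`, `karyonide` (fractions in \[0, 1\],
#'   row sums <= 1 + tolerance; missing columns are treated as 0).
#' @param time_h optional numeric vector of collection times (hours) used
#'   to resolve DEV3.
#' @param tol tolerance on the fraction sum.
#' @return character vector of stage labels.
#' @export
stage_samples <- function(morphology, time_h = NULL, tol = 0.05) {
  cols <- c("vegetative", "meiosis", "skein", "fragmented", "anlagen",
            "karyonide")
  m <- as.data.frame(morphology)
  for (cc in setdiff(cols, names(m))) m[[cc]] <- 0
  m <- m[cols]
  m[is.na(m)] <- 0
  if (any(m < 0) || any(m > 1)) stop("morphology fractions must be in [0, 1]")
  sums <- rowSums(m)
  if (any(sums > 1 + tol)) {
    stop("morphology fractions sum to more than 1 (rows: ",
         paste(which(sums > 1 + tol), collapse = ", "), ")")
  }
  stage <- vapply(seq_len(nrow(m)), function(i) {
    mei <- m$meiosis[i]; fr <- m$fragmented[i]; an <- m$anlagen[i]
    if (mei + fr + an < 0.05) return("VEG")
    if (mei >= 0.20 && fr < 0.10) return("MEI")
    if (fr >= 0.30 && an < 0.10) return("FRAG")
    if (an >= 0.10 && an < 0.70) return("DEV1")
    if (an >= 0.70) return("DEV2")
    nearest_stage_centroid(as.numeric(m[i, ]))
  }, character(1))
  if (!is.null(time_h) && any(stage == "DEV2")) {
    t0 <- min(time_h[stage == "DEV2"], na.rm = TRUE)
    stage[stage == "DEV2" & !is.na(time_h) & time_h >= t0 + 10] <- "DEV3"
  }
  stage
}

# fallback for morphology mixtures matched by no staging rule: nearest
# canonical stage centroid (midpoints of the generator's stage ranges).
# DEV3 is excluded: morphology alone can never assign it.
nearest_stage_centroid <- function(frac) {
  rng <- morphology_ranges()
  rng <- rng[setdiff(names(rng), "DEV3")]
  cent <- vapply(rng, function(r) vapply(r, mean, numeric(1)), numeric(6))
  d <- colSums((cent - frac)^2)
  names(d)[which.min(d)]
}
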