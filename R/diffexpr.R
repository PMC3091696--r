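#' Differential expression configuration
#'
#' @param fdr Benjamini-Hochberg adjusted p-value threshold (default 0.05).
#' @param fold_change biologically significant fold-change threshold on the
#'   natural scale (e.g. 1.5 or 2), converted to log2 internally; `NULL` or
#'   1 selects the ordinary moderated test.
#' @param merge_dev23 merge the DEV2 and DEV3 autogamy timepoints into a
#'   single level before fitting (the two stages are not separable by
#'   expression).
#' @return a `de_config` list.
#' @export
de_config <- function(fdr = 0.05, fold_change = NULL, merge_dev23 = TRUE) {
  tau <- if (is.null(fold_change)) 0 else log2(fold_change)
  if (is.na(tau) || tau < 0) stop("fold_change must give log2 threshold >= 0")
  structure(list(fdr = fdr, fold_change = fold_change, tau = tau,
                 merge_dev23 = isTRUE(merge_dev23)),
            class = "de_config")
}

#' Fit a one-way timecourse linear model to every gene
#'
#' Ordinary least squares on a cell-means (one coefficient per timepoint
#' level) design, via [limma::lmFit()]. For autogamy data the DEV2 and DEV3
#' timepoints are merged into one level when `config$merge_dev23` is TRUE.
#'
#' @param matrix gene x sample log2 matrix.
#' @param sheet sample sheet with `sample_id` and `timepoint` covering every
#'   column of `matrix`.
#' @param config a [de_config()].
#' @return a `timecourse_fit`: list with `coefficients` (gene x level means),
#'   `sigma2`, `df_residual`, `level_n` (samples per level), `levels`,
#'   `design`, `timepoint` (per-sample level).
#' @export
fit_timecourse <- function(matrix, sheet, config = de_config()) {
  idx <- match(colnames(matrix), sheet$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from sheet: ",
         paste(colnames(matrix)[is.na(idx)], collapse = ", "))
  }
  tp <- sheet$timepoint[idx]
  if (config$merge_dev23) tp[tp %in% c("DEV2", "DEV3")] <- "DEV2-3"
  lev <- unique(tp)
  n_per <- table(factor(tp, levels = lev))
  if (any(n_per == 0L)) {
    stop("singular design: no samples at level ",
         paste(names(n_per)[n_per == 0L], collapse = ", "))
  }
  if (ncol(matrix) - length(lev) < 1L) {
    stop("design leaves no residual degrees of freedom; replicates required")
  }
  design <- stats::model.matrix(~ 0 + factor(tp, levels = lev))
  colnames(design) <- lev
  fit <- limma::lmFit(matrix, design)
  structure(list(
    coefficients = fit$coefficients,
    sigma2 = fit$sigma^2,
    df_residual = fit$df.residual,
    level_n = as.integer(n_per),
    levels = lev,
    design = design,
    timepoint = tp
  ), class = "timecourse_fit")
}

#' Empirical-Bayes variance moderation
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 of the
#' hierarchical variance model by moment matching of log residual variances
#' against the scaled-F distribution (digamma/trigamma inversion, via
#' [limma::squeezeVar()]), and returns the posterior (moderated) variance
#' s~2 = (d0 s0^2 + d_g s2_g) / (d0 + d_g) for every gene. Genes with zero
#' residual variance are offset by 1e-2 times the smallest positive variance
#' before moment matching.
#'
#' @param fit a `timecourse_fit`.
#' @return an `ebayes_params` list: `df_prior`, `var_prior`, `var_post`.
#' @export
estimate_ebayes <- function(fit) {
  v <- fit$sigma2
  if (length(v) < 10L) {
    warning("fewer than 10 genes; prior estimates will be unstable")
  }
  if (all(v == v[1])) {
    return(structure(list(df_prior = Inf, var_prior = v[1],
                          var_post = rep(v[1], length(v))),
                     class = "ebayes_params"))
  }
  if (any(v == 0)) v[v == 0] <- min(v[v > 0]) * 1e-2
  sq <- limma::squeezeVar(v, df = fit$df_residual)
  structure(list(df_prior = sq$df.prior, var_prior = sq$var.prior,
                 var_post = sq$var.post),
            class = "ebayes_params")
}

# all timepoint pairs, and per-contrast unscaled coefficient sd for a
# cell-means design: sd_unscaled = sqrt(1/n_i + 1/n_j)
all_pair_contrasts <- function(fit) {
  pairs <- utils::combn(seq_along(fit$levels), 2L)
  names_ <- paste0(fit$levels[pairs[2L, ]], "-", fit$levels[pairs[1L, ]])
  list(i = pairs[2L, ], j = pairs[1L, ], names = names_,
       sd_unscaled = sqrt(1 / fit$level_n[pairs[2L, ]] +
                          1 / fit$level_n[pairs[1L, ]]))
}

#' Moderated multi-contrast tests of differential expression
#'
#' For every pair of timepoints, computes the moderated t statistic
#' logFC / (sd_unscaled * s~) on d0 + d_g degrees of freedom and its
#' two-sided p-value. The gene-level p-value is the smallest contrast
#' p-value Bonferroni-corrected for the number of contrasts (capped at 1),
#' then Benjamini-Hochberg adjusted across genes. A gene is flagged DE if
#' its adjusted p falls below `config$fdr`.
#'
#' @param fit a `timecourse_fit`.
#' @param ebayes an `ebayes_params` (default: estimated from `fit`).
#' @param config a [de_config()].
#' @return a `de_result`: list with `table` (data.frame `gene_id`,
#'   `p_value`, `fdr`, `de`, `max_abs_logfc`), `logfc`, `t`, `p` (gene x
#'   contrast matrices), `contrasts`, `df_total`, `method`, `config`.
#' @export
moderated_tests <- function(fit, ebayes = estimate_ebayes(fit),
                            config = de_config()) {
  ct <- all_pair_contrasts(fit)
  lfc <- fit$coefficients[, ct$i, drop = FALSE] -
         fit$coefficients[, ct$j, drop = FALSE]
  colnames(lfc) <- ct$names
  df_total <- pmin(ebayes$df_prior + fit$df_residual,
                   sum(fit$df_residual))
  se <- outer(sqrt(ebayes$var_post), ct$sd_unscaled)
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  build_de_result(fit, lfc, tstat, p, df_total, config, method = "ebayes")
}

#' Fold-change-threshold (TREAT) tests of differential expression
#'
#' Tests, per contrast, the null hypothesis |logFC| <= tau against the
#' moderated t reference distribution:
#' p = P(T >= (|logFC| - tau)/se) + P(T >= (|logFC| + tau)/se) on d0 + d_g
#' degrees of freedom. Gene-level combination and BH adjustment as in
#' [moderated_tests()]; the DE flag additionally requires the largest
#' fitted |logFC| to exceed tau (the model fold-change rule). With tau = 0
#' this reduces exactly to the ordinary moderated test.
#'
#' @inheritParams moderated_tests
#' @return a `de_result` (see [moderated_tests()]).
#' @export
treat_tests <- function(fit, ebayes = estimate_ebayes(fit),
                        config = de_config(fold_change = 1.5)) {
  tau <- config$tau
  if (tau == 0) return(moderated_tests(fit, ebayes, config))
  ct <- all_pair_contrasts(fit)
  lfc <- fit$coefficients[, ct$i, drop = FALSE] -
         fit$coefficients[, ct$j, drop = FALSE]
  colnames(lfc) <- ct$names
  df_total <- pmin(ebayes$df_prior + fit$df_residual,
                   sum(fit$df_residual))
  se <- outer(sqrt(ebayes$var_post), ct$sd_unscaled)
  t_right <- (abs(lfc) - tau) / se
  t_left <- (abs(lfc) + tau) / se
  p <- stats::pt(t_right, df = df_total, lower.tail = FALSE) +
       stats::pt(t_left, df = df_total, lower.tail = FALSE)
  tstat <- t_right
  build_de_result(fit, lfc, tstat, p, df_total, config, method = "treat")
}

build_de_result <- function(fit, lfc, tstat, p, df_total, config, method) {
  p <- pmin(p, 1)
  gene_p <- pmin(apply(p, 1L, min) * ncol(p), 1)
  fdr <- adjust_bh(gene_p)
  max_abs <- apply(abs(lfc), 1L, max)
  de <- fdr < config$fdr
  if (method == "treat") de <- de & max_abs > config$tau
  structure(list(
    table = data.frame(gene_id = rownames(fit$coefficients),
                       p_value = unname(gene_p), fdr = unname(fdr),
                       de = unname(de), max_abs_logfc = unname(max_abs),
                       stringsAsFactors = FALSE),
    logfc = lfc, t = tstat, p = p,
    contrasts = colnames(lfc), df_total = df_total,
    method = method, config = config
  ), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result (%s%s): %d of %d genes DE at FDR < %g\n",
              x$method,
              if (x$config$tau > 0) sprintf(", fold-change > %g", x$config$fold_change) else "",
              sum(x$table$de), nrow(x$table), x$config$fdr))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; rejects missing or
#' out-of-range p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, capped at 1).
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Extract the differentially expressed gene set
#'
#' @param result a `de_result`.
#' @return character vector of flagged gene ids.
#' @export
call_de <- function(result) {
  result$table$gene_id[result$table$de]
}

#' Up-regulated members of a DE set
#'
#' A DE gene is called up-regulated when the largest-magnitude fitted
#' contrast against the first (reference) timepoint is positive.
#'
#' @param result a `de_result`.
#' @param fit the `timecourse_fit` the result came from.
#' @return character vector of up-regulated DE gene ids.
#' @export
call_de_up <- function(result, fit) {
  de <- result$table$de
  ref <- fit$coefficients[, 1L]
  dev <- fit$coefficients - ref
  direction <- apply(dev, 1L, function(d) d[which.max(abs(d))])
  result$table$gene_id[de & direction > 0]
}

#' One-call differential expression analysis
#'
#' Chains [fit_timecourse()], [estimate_ebayes()] and the configured test.
#'
#' @param matrix gene x sample log2 matrix.
#' @param sheet sample sheet.
#' @param config a [de_config()]; `fold_change > 1` selects TREAT.
#' @return a `de_result` with the `timecourse_fit` attached as `$fit`.
#' @export
de_analysis <- function(matrix, sheet, config = de_config()) {
  fit <- fit_timecourse(matrix, sheet, config)
  eb <- estimate_ebayes(fit)
  res <- if (config$tau > 0) treat_tests(fit, eb, config)
         else moderated_tests(fit, eb, config)
  res$fit <- fit
  res$ebayes <- eb
  res
}

#' Write a DE result table and run summary
#'
#' @param result a `de_result`.
#' @param tsv_path per-gene table (gene, per-contrast logFC, p, FDR, flag).
#' @param json_path run summary (method, thresholds, counts).
#' @export
write_de_result <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    tab <- cbind(result$table["gene_id"],
                 stats::setNames(as.data.frame(result$logfc),
                                 paste0("logFC.", result$contrasts)),
                 result$table[c("p_value", "fdr", "de", "max_abs_logfc")])
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      method = result$method, fdr = result$config$fdr,
      fold_change = result$config$fold_change,
      n_genes = nrow(result$table), n_de = sum(result$table$de),
      contrasts = result$contrasts
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
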