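#' Platform evaluation configuration
#'
#' @param max_mismatch maximum Hamming distance at which a probe is assumed
#'   to hybridize to a target window (default 5).
#' @param both_strands also match the probe's reverse complement.
#' @return a `platform_config` list.
#' @export
platform_config <- function(max_mismatch = 5L, both_strands = TRUE) {
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L) stop("max_mismatch must be >= 0")
  structure(list(max_mismatch = max_mismatch,
                 both_strands = isTRUE(both_strands)),
            class = "platform_config")
}

#' Transcripts a probe can hybridize to
#'
#' A probe hits a transcript if any 50-nt window of the transcript (on the
#' given sequence or, with `both_strands`, its reverse complement) is within
#' `max_mismatch` Hamming distance of the probe. Ambiguous bases count as
#' mismatches. A transcript is counted once however many windows match.
#'
#' @param probe a 50-nt probe sequence (character).
#' @param transcripts named character vector of transcript sequences.
#' @param config a [platform_config()].
#' @return character vector of matching transcript ids.
#' @export
match_probe_targets <- function(probe, transcripts, config = platform_config()) {
  stopifnot(inherits(config, "platform_config"))
  if (nchar(probe) != 50L) stop("probe length must be exactly 50")
  if (!length(transcripts)) stop("transcripts must be non-empty")
  subj <- Biostrings::DNAStringSet(transcripts)
  hits <- Biostrings::vcountPattern(probe, subj,
                                    max.mismatch = config$max_mismatch,
                                    fixed = TRUE) > 0L
  if (config$both_strands) {
    hits <- hits | Biostrings::vcountPattern(revcomp(probe), subj,
                                             max.mismatch = config$max_mismatch,
                                             fixed = TRUE) > 0L
  }
  names(transcripts)[hits]
}

#' Cross-hybridization report for a probe platform
#'
#' Counts, for every probe, the number of distinct transcripts it can
#' hybridize to under the mismatch model, and summarizes the platform's
#' discriminatory power as the fraction of probes hitting a unique
#' transcript and the fraction hitting no more than two.
#'
#' @param probes probe table with `probe_id`, `gene_id`, `sequence`.
#' @param transcripts named character vector of transcript sequences.
#' @param config a [platform_config()].
#' @return a `crosshyb_report`: list with `per_probe` (data.frame
#'   `probe_id`, `gene_id`, `n_targets`, `self_hit`, `excluded`) and
#'   `summary` (`n_probes`, `frac_unique`, `frac_le2`).
#' @export
platform_uniqueness <- function(probes, transcripts, config = platform_config()) {
  missing_own <- !(probes$gene_id %in% names(transcripts))
  n_targets <- integer(nrow(probes))
  self_hit <- logical(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    if (missing_own[i]) next
    ids <- match_probe_targets(probes$sequence[i], transcripts, config)
    n_targets[i] <- length(ids)
    self_hit[i] <- probes$gene_id[i] %in% ids
  }
  per_probe <- data.frame(probe_id = probes$probe_id, gene_id = probes$gene_id,
                          n_targets = n_targets, self_hit = self_hit,
                          excluded = missing_own, stringsAsFactors = FALSE)
  ok <- !missing_own
  summary <- list(n_probes = sum(ok),
                  frac_unique = mean(n_targets[ok] == 1L),
                  frac_le2 = mean(n_targets[ok] <= 2L))
  structure(list(per_probe = per_probe, summary = summary),
            class = "crosshyb_report")
}

#' @export
print.crosshyb_report <- function(x, ...) {
  cat(sprintf("crosshyb_report: %d probes; %.1f%% unique, %.1f%% <= 2 targets\n",
              x$summary$n_probes, 100 * x$summary$frac_unique,
              100 * x$summary$frac_le2))
  invisible(x)
}

#' Normal+exponential (RMA-style) background correction
#'
#' Models each sample's linear-scale intensities as X = S + B with signal
#' S ~ Exp(alpha) and background B ~ N(mu, sigma^2), and replaces each
#' observation by the posterior expected signal E\[S | X = x\], which is
#' strictly positive and monotone in x. Parameters are estimated per sample
#' with RMA-style heuristics: `mu` as the density mode, `sigma` from the
#' spread of the lower tail below the mode (mirrored), and `1/alpha` as the
#' mean exceedance above the mode. Output is returned on the log2 scale.
#'
#' @param matrix probe x sample matrix.
#' @param scale `"linear"` (default) or `"log2"`; log2 input is converted
#'   to the linear scale internally.
#' @return matrix of log2 background-corrected signals (same dimnames).
#' @export
background_correct <- function(matrix, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  x <- if (scale == "log2") 2^matrix else matrix
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("background correction requires finite, positive linear intensities")
  }
  out <- apply(x, 2L, function(col) {
    par <- normexp_params(col)
    log2(normexp_posterior(col, par$mu, par$sigma, par$alpha))
  })
  dimnames(out) <- dimnames(matrix)
  out
}

# RMA-style heuristic parameter estimates for the normexp model
normexp_params <- function(x) {
  d <- stats::density(x, n = 512)
  mu <- d$x[which.max(d$y)]
  lower <- x[x <= mu]
  sigma <- sqrt(mean((lower - mu)^2))
  if (!is.finite(sigma) || sigma <= 0) sigma <- sqrt(.Machine$double.eps)
  upper <- x[x > mu]
  inv_alpha <- if (length(upper)) mean(upper - mu) else sigma
  alpha <- 1 / max(inv_alpha, sqrt(.Machine$double.eps))
  list(mu = mu, sigma = sigma, alpha = alpha)
}

# E[S | X = x] for X = S + B, S ~ Exp(alpha), B ~ N(mu, sigma^2).
# mu.sf = x - mu - sigma^2 * alpha; E = mu.sf + sigma * h(mu.sf / sigma)
# where h is the inverse Mills ratio dnorm/pnorm, evaluated in log space
# for numerical stability far in the tail.
normexp_posterior <- function(x, mu, sigma, alpha) {
  mu.sf <- x - mu - sigma^2 * alpha
  z <- mu.sf / sigma
  log_h <- stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE)
  out <- mu.sf + sigma * exp(log_h)
  pmax(out, .Machine$double.xmin)
}

#' Write a cross-hybridization report
#'
#' Per-probe target counts as TSV plus a JSON summary of the platform's
#' unique-hit and at-most-two-hit fractions.
#'
#' @param report a `crosshyb_report`.
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @export
write_crosshyb_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$per_probe, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(report)
}
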