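# Independent brute-force oracles used to check the package implementations.

# sliding-window Hamming matcher: all transcript ids containing a window
# within max_mm mismatches of the probe (optionally on either strand)
hamming_match_oracle <- function(probe, transcripts, max_mm, both_strands = TRUE) {
  pats <- c(probe, if (both_strands) revcomp(probe))
  hit <- vapply(transcripts, function(tr) {
    trc <- strsplit(tr, "")[[1]]
    for (p in pats) {
      pc <- strsplit(p, "")[[1]]
      k <- length(pc)
      if (length(trc) < k) next
      for (o in 0:(length(trc) - k)) {
        if (sum(trc[(o + 1):(o + k)] != pc) <= max_mm) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  names(transcripts)[hit]
}

# exhaustive complete-linkage agglomeration; returns sorted merge heights
complete_linkage_heights_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# hand step-up Benjamini-Hochberg
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# sort-based median
median_oracle <- function(x) {
  s <- sort(unname(x))
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# least squares by explicit normal equations
ls_oracle <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(beta = drop(beta), rss = sum(res^2), df = length(y) - ncol(X))
}

# recursive tree walk for ohnolog relatives: rebuild the family tree from
# parent paths and collect the sister-subtree leaves at a level
tree_relatives_oracle <- function(gene, families, level) {
  fam <- families[families$family_id ==
                    families$family_id[match(gene, families$gene_id)], ]
  tokens <- strsplit(fam$wgd_path, "|", fixed = TRUE)
  self <- tokens[[match(gene, fam$gene_id)]]
  lv_tok <- grep(paste0("^", level), self, value = TRUE)
  if (!length(lv_tok)) return(character(0))
  pos <- which(self == lv_tok)
  prefix <- self[seq_len(pos - 1L)]
  sister_side <- if (substr(lv_tok, 2, 2) == "L") "R" else "L"
  want <- c(prefix, paste0(level, sister_side))
  hits <- vapply(tokens, function(tk) {
    length(tk) >= length(want) && all(tk[seq_along(want)] == want)
  }, logical(1))
  sort(fam$gene_id[hits])
}

# precedence oracle for WGD2/WGD3 category assignment given relative
# cluster states ("same", "other", "none")
precedence_oracle <- function(states, level) {
  if (level == 2L) {
    if (all(states == "same")) "both in same cluster"
    else if (any(states == "same")) "one in same cluster"
    else if (any(states == "other")) "different cluster"
    else "none in cluster"
  } else {
    if (any(states == "same")) "one or more same cluster"
    else if (any(states == "other")) "different cluster"
    else "none in cluster"
  }
}

# random DNA of given length / GC
random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small shared synthetic dataset reused across test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_ancestral = 300, seed = 42))
    }
    cache
  }
})

# simple sample sheet for hand-built matrices
toy_sheet <- function(timepoints, reps = 2, experiment = "toy") {
  tp <- rep(timepoints, each = reps)
  data.frame(
    sample_id = paste0(tp, "_r", rep(seq_len(reps), length(timepoints))),
    experiment = experiment, timepoint = tp,
    replicate = rep(seq_len(reps), length(timepoints)),
    replicate_group = tp, stringsAsFactors = FALSE
  )
}
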