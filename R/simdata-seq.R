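#' Simulate transcripts and a probe platform
#'
#' Generates one transcript per gene at the configured GC content
#' (AT-rich by default, GC 30%) and designs 6 non-overlapping 50-mer
#' perfect-match probes per transcript, 3 per strand, preferring windows
#' whose GC is closest to the configured probe GC target (36%). Retained
#' recent-WGD pairs share the configured sequence identity (95% by
#' default) so probe cross-hybridization between near-identical ohnologs
#' is exercisable downstream.
#'
#' @param genome a `wgd_genome` from [simulate_genome()], or an
#'   `ohnolog_families` table.
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{transcripts}{named character vector of transcript sequences.}
#'     \item{probes}{data.frame with columns `probe_id`, `gene_id`,
#'       `strand`, `offset` (0-based on the transcript), `sequence`
#'       (50 nt, reverse-complemented for the minus strand), `gc`.}
#'   }
#' @export
simulate_transcripts_probes <- function(genome, config) {
  validate_sim_config(config)
  families <- if (inherits(genome, "wgd_genome")) genome$families else genome
  genes <- families$gene_id
  L <- config$transcript_length
  if (L < 6L * 50L) stop("transcript too short for 6 non-overlapping probes")
  set.seed(config$seed + 1L)

  base_probs <- c(A = (1 - config$gc_orf) / 2, C = config$gc_orf / 2,
                  G = config$gc_orf / 2, T = (1 - config$gc_orf) / 2)
  bases <- names(base_probs)

  # recent (WGD1) pairs share config$pair_identity: generate the first
  # member, derive the second by point mutation
  partner <- wgd1_partner_map(families)
  transcripts <- stats::setNames(vector("character", length(genes)), genes)
  done <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (g in genes) {
    if (done[[g]]) next
    seq1 <- paste(sample(bases, L, replace = TRUE, prob = base_probs),
                  collapse = "")
    transcripts[[g]] <- seq1
    done[[g]] <- TRUE
    p <- partner[[g]]
    if (!is.na(p) && !done[[p]]) {
      transcripts[[p]] <- mutate_sequence(seq1, 1 - config$pair_identity, bases)
      done[[p]] <- TRUE
    }
  }

  probes <- do.call(rbind, lapply(genes, function(g) {
    design_gene_probes(g, transcripts[[g]], config$gc_probe)
  }))
  rownames(probes) <- NULL
  list(transcripts = transcripts, probes = probes)
}

# point-mutate a fraction of positions, each to a different uniformly
# chosen base
mutate_sequence <- function(seq, frac, bases = c("A", "C", "G", "T")) {
  L <- nchar(seq)
  n_mut <- round(frac * L)
  if (n_mut == 0L) return(seq)
  pos <- sample.int(L, n_mut)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(bases, b), 1L), character(1))
  paste(chars, collapse = "")
}

# 6 non-overlapping 50-mers with GC nearest the target; deterministic
# (ties by offset); strands alternate along the transcript so each strand
# gets 3 probes
design_gene_probes <- function(gene, seq, gc_target, n_probes = 6L, k = 50L) {
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_gc <- cumsum(c(0L, chars %in% c("G", "C")))
  offsets0 <- 0:(L - k)                       # 0-based
  gc <- (is_gc[offsets0 + k + 1L] - is_gc[offsets0 + 1L]) / k
  ord <- order(abs(gc - gc_target), offsets0)
  chosen <- integer(0)
  for (o in offsets0[ord]) {
    if (length(chosen) == n_probes) break
    if (all(abs(o - chosen) >= k)) chosen <- c(chosen, o)
  }
  if (length(chosen) < n_probes) {
    # greedy placement can strand itself on short transcripts; fall back
    # to the fixed non-overlapping grid, taking the windows nearest the
    # GC target
    grid <- seq(0L, L - k, by = k)
    if (length(grid) < n_probes) {
      stop("transcript too short for ", n_probes, " non-overlapping probes")
    }
    gc_grid <- gc[match(grid, offsets0)]
    chosen <- grid[order(abs(gc_grid - gc_target), grid)][seq_len(n_probes)]
  }
  chosen <- sort(chosen)
  strand <- rep(c("+", "-"), length.out = n_probes)
  seqs <- vapply(seq_along(chosen), function(i) {
    s <- substr(seq, chosen[i] + 1L, chosen[i] + k)
    if (strand[i] == "-") s <- revcomp(s)
    s
  }, character(1))
  data.frame(
    probe_id = sprintf("%s_p%d", gene, seq_len(n_probes)),
    gene_id = gene,
    strand = strand,
    offset = chosen,
    sequence = seqs,
    gc = vapply(seqs, gc_fraction, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Reverse complement of a DNA string
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of a sequence
#' @param x a single sequence string.
#' @return numeric in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

# map gene -> its retained WGD1 partner (NA if none). Level tokens are a
# single digit plus L/R, so the level-1 token can be located by regex.
wgd1_partner_map <- function(families) {
  out <- stats::setNames(rep(NA_character_, nrow(families)), families$gene_id)
  m <- regexpr("1[LR]", families$wgd_path)
  has1 <- m > 0L
  if (!any(has1)) return(out)
  side <- substr(regmatches(families$wgd_path, m), 2L, 2L)
  side_all <- rep(NA_character_, nrow(families))
  side_all[has1] <- side
  prefix <- sub("\\|?1[LR]", "", families$wgd_path)
  key <- paste(families$family_id, prefix, sep = "//")
  idx <- which(has1)
  left <- idx[side_all[idx] == "L"]
  right <- idx[side_all[idx] == "R"]
  pos <- match(key[left], key[right])
  ok <- !is.na(pos)
  out[families$gene_id[left[ok]]] <- families$gene_id[right[pos[ok]]]
  out[families$gene_id[right[pos[ok]]]] <- families$gene_id[left[ok]]
  out
}

#' Write/read transcripts as FASTA
#' @param transcripts named character vector of sequences.
#' @param path file path.
#' @export
write_transcripts <- function(transcripts, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(transcripts), path)
  invisible(path)
}

#' @rdname write_transcripts
#' @return `read_transcripts()` returns a named character vector.
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write/read the probe design table
#' @param probes probe data.frame (see [simulate_transcripts_probes()]).
#' @param path file path.
#' @export
write_probes <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_id", "strand", "offset", "sequence")
  if (!all(need %in% names(df))) {
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  }
  df
}
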