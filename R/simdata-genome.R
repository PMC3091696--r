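#' Simulate a paleopolyploid genome
#'
#' Passes every ancestral gene through three successive whole genome
#' duplications, oldest first (WGD3, then WGD2, then WGD1 = most recent).
#' At each WGD every surviving lineage duplicates; the resulting pair is
#' then resolved before the next event: with the per-event both-copy
#' retention probability both copies are kept, otherwise exactly one
#' survives. A family can therefore never be wholly lost, and the
#' configured probability for an event equals the expected fraction of its
#' duplication events still present in two copies.
#'
#' Present-day genes are recorded with a parent-path encoding of their
#' ancestry: the string `"3L|2R|1L"` means the gene descends from the left
#' copy retained at WGD3, the right copy at WGD2 and the left copy at WGD1;
#' levels at which the sister copy was lost do not appear.
#'
#' @param config a [sim_config()]. Only `n_ancestral`, `retention_probs`
#'   and `seed` are used.
#' @return object of class `wgd_genome`: a list with elements
#'   \describe{
#'     \item{families}{data.frame (`ohnolog_families`) with columns
#'       `gene_id`, `family_id`, `wgd_path`, one row per present-day gene.}
#'     \item{genes}{character vector of all gene ids.}
#'     \item{events}{data.frame with per-WGD-level duplication event counts
#'       (`level`, `n_events`, `n_both_kept`, `frac_both_kept`).}
#'   }
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  p <- config$retention_probs  # (recent=1, intermediate=2, old=3)
  set.seed(config$seed)

  fam <- seq_len(config$n_ancestral)
  path <- rep("", length(fam))
  events <- data.frame(level = 3:1, n_events = NA_integer_,
                       n_both_kept = NA_integer_)
  for (lev in 3:1) {
    n <- length(fam)
    keep_both <- stats::rbinom(n, 1L, p[lev]) == 1L
    events$n_events[events$level == lev] <- n
    events$n_both_kept[events$level == lev] <- sum(keep_both)
    tag <- function(side) ifelse(path[keep_both] == "",
                                 paste0(lev, side),
                                 paste0(path[keep_both], "|", lev, side))
    fam <- c(fam[!keep_both], fam[keep_both], fam[keep_both])
    path <- c(path[!keep_both], tag("L"), tag("R"))
  }
  ord <- order(fam, path)
  fam <- fam[ord]; path <- path[ord]
  families <- data.frame(
    gene_id = sprintf("G%06d.%d", fam,
                      as.integer(stats::ave(fam, fam, FUN = seq_along))),
    family_id = sprintf("F%06d", fam),
    wgd_path = path,
    stringsAsFactors = FALSE
  )
  class(families) <- c("ohnolog_families", "data.frame")
  events$frac_both_kept <- events$n_both_kept / events$n_events
  structure(list(families = families, genes = families$gene_id,
                 events = events),
            class = "wgd_genome")
}

#' @export
print.wgd_genome <- function(x, ...) {
  cat("wgd_genome:", length(unique(x$families$family_id)), "families,",
      nrow(x$families), "present-day genes\n")
  print(x$events, row.names = FALSE)
  invisible(x)
}

# Split a parent-path string into a named side vector, e.g.
# "3L|2R" -> c(`3` = "L", `2` = "R"). Empty path -> empty vector.
parse_wgd_path <- function(path) {
  if (is.na(path) || path == "") return(stats::setNames(character(0), character(0)))
  parts <- strsplit(path, "|", fixed = TRUE)[[1]]
  stats::setNames(substr(parts, 2L, 2L), substr(parts, 1L, 1L))
}

# Path prefix strictly above a WGD level (i.e. older levels only).
wgd_path_prefix <- function(path, level) {
  comp <- parse_wgd_path(path)
  keep <- as.integer(names(comp)) > level
  paste(paste0(names(comp)[keep], comp[keep]), collapse = "|")
}

#' Present-day ohnologs of a gene at a given WGD level
#'
#' Returns the present-day genes descending from the sister lineage of the
#' duplication event at `level` on the path from `gene` to the family root.
#' Empty if the sister copy was lost at that event. At most 1 relative at
#' WGD1, 2 at WGD2 and 4 at WGD3.
#'
#' @param gene a gene id.
#' @param families an `ohnolog_families` data.frame (see [simulate_genome()]).
#' @param level WGD level, 1 (recent) to 3 (old).
#' @return character vector of relative gene ids (possibly empty).
#' @export
wgd_relatives <- function(gene, families, level) {
  stopifnot(level %in% 1:3)
  i <- match(gene, families$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene)
  fam_rows <- families[families$family_id == families$family_id[i], ]
  side <- path_side(families$wgd_path[i], level)
  if (is.na(side)) return(character(0))
  prefix <- wgd_path_prefix(families$wgd_path[i], level)
  hits <- vapply(seq_len(nrow(fam_rows)), function(j) {
    s <- path_side(fam_rows$wgd_path[j], level)
    !is.na(s) && s != side &&
      wgd_path_prefix(fam_rows$wgd_path[j], level) == prefix
  }, logical(1))
  fam_rows$gene_id[hits]
}

# side ("L"/"R") taken at a WGD level, NA if the sister copy was lost
path_side <- function(path, level) {
  comp <- parse_wgd_path(path)
  unname(comp[as.character(level)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of a gene set with a retained ohnolog at a WGD level
#'
#' The retention rate of a gene set at a WGD level is the fraction of its
#' genes whose [wgd_relatives()] set at that level is non-empty, matching
#' a per-present-day-gene denominator.
#'
#' @param genes character vector of gene ids.
#' @param families `ohnolog_families` table.
#' @param level WGD level (1..3), or a vector of levels.
#' @return named numeric vector of fractions, one per level.
#' @export
retention_rate <- function(genes, families, level = 1:3) {
  rel <- relative_table(genes, families)
  out <- vapply(level, function(lv) {
    mean(vapply(rel, function(r) length(r[[lv]]) > 0L, logical(1)))
  }, numeric(1))
  stats::setNames(out, paste0("WGD", level))
}

# All-level relatives for a vector of genes: list of list(level1, level2,
# level3) character vectors. Works on precomputed per-level side/prefix
# vectors so large gene sets stay fast.
relative_table <- function(genes, families) {
  i <- match(genes, families$gene_id)
  if (anyNA(i)) stop("unknown gene(s): ", paste(genes[is.na(i)], collapse = ", "))
  path <- families$wgd_path
  side_lv <- lapply(1:3, function(lv) {
    m <- regexpr(paste0(lv, "[LR]"), path)
    out <- rep(NA_character_, length(path))
    out[m > 0L] <- substr(regmatches(path, m), 2L, 2L)
    out
  })
  # prefix above level lv = the level tokens older than lv
  prefix_lv <- lapply(1:3, function(lv) {
    drop <- paste0("(\\|?[1-", lv, "][LR])*$")
    sub(drop, "", path)
  })
  fam <- families$family_id
  fam_rows <- split(seq_along(fam), fam)
  out <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    rows <- fam_rows[[fam[i[k]]]]
    out[[k]] <- lapply(1:3, function(lv) {
      side <- side_lv[[lv]][i[k]]
      if (is.na(side)) return(character(0))
      sides <- side_lv[[lv]][rows]
      hits <- !is.na(sides) & sides != side &
        prefix_lv[[lv]][rows] == prefix_lv[[lv]][i[k]]
      families$gene_id[rows[hits]]
    })
  }
  names(out) <- genes
  out
}

#' Read/write ohnolog family tables
#'
#' Plain TSV with columns `gene_id`, `family_id`, `wgd_path` (parent-path
#' encoding of retained WGD duplications, oldest level first).
#'
#' @param path file path.
#' @return `read_families()` returns an `ohnolog_families` data.frame.
#' @export
read_families <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "family_id", "wgd_path")
  if (!all(need %in% names(df))) {
    stop("family table must have columns: ", paste(need, collapse = ", "))
  }
  df$wgd_path[is.na(df$wgd_path)] <- ""
  class(df) <- c("ohnolog_families", "data.frame")
  df
}

#' @rdname read_families
#' @param families `ohnolog_families` table.
#' @export
write_families <- function(families, path) {
  utils::write.table(as.data.frame(families), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
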