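# hand-built family fixtures -------------------------------------------------

full_family <- function() {
  paths <- c("3L|2L|1L", "3L|2L|1R", "3L|2R|1L", "3L|2R|1R",
             "3R|2L|1L", "3R|2L|1R", "3R|2R|1L", "3R|2R|1R")
  fam <- data.frame(gene_id = paste0("g", 1:8), family_id = "F1",
                    wgd_path = paths, stringsAsFactors = FALSE)
  class(fam) <- c("ohnolog_families", "data.frame")
  fam
}

test_that("a complete 8-leaf family yields 1/2/4 relatives per level", {
  fam <- full_family()
  expect_equal(wgd_relatives("g1", fam, 1), "g2")
  expect_setequal(wgd_relatives("g1", fam, 2), c("g3", "g4"))
  expect_setequal(wgd_relatives("g1", fam, 3), c("g5", "g6", "g7", "g8"))
  # symmetry: g2's WGD1 relative is g1
  expect_equal(wgd_relatives("g2", fam, 1), "g1")
})

test_that("singleton families have no relatives at any level", {
  fam <- data.frame(gene_id = "solo", family_id = "F9", wgd_path = "",
                    stringsAsFactors = FALSE)
  class(fam) <- c("ohnolog_families", "data.frame")
  for (lv in 1:3) expect_length(wgd_relatives("solo", fam, lv), 0L)
  expect_error(wgd_relatives("nope", fam, 1), "unknown")
})

test_that("relatives on random pruned trees equal the tree-walk oracle", {
  g <- simulate_genome(sim_config(n_ancestral = 120, seed = 61))
  fam <- g$families
  set.seed(62)
  for (gene in sample(fam$gene_id, 40)) {
    for (lv in 1:3) {
      expect_equal(sort(wgd_relatives(gene, fam, lv)),
                   tree_relatives_oracle(gene, fam, lv))
    }
  }
  # cardinality bounds: <= 1 at WGD1, <= 2 at WGD2, <= 4 at WGD3
  rel <- wgdexpr:::relative_table(fam$gene_id, fam)
  for (r in rel) {
    expect_lte(length(r[[1]]), 1L)
    expect_lte(length(r[[2]]), 2L)
    expect_lte(length(r[[3]]), 4L)
  }
})

test_that("retention rate counts genes with at least one retained ohnolog", {
  fam <- full_family()
  solo <- data.frame(gene_id = paste0("s", 1:4), family_id = paste0("S", 1:4),
                     wgd_path = "", stringsAsFactors = FALSE)
  both <- rbind(as.data.frame(fam), solo)
  class(both) <- c("ohnolog_families", "data.frame")
  genes <- c(paste0("g", 1:6), paste0("s", 1:4))  # 6 of 10 with WGD1 relative
  expect_equal(unname(retention_rate(genes, both, 1)), 0.6)
  expect_equal(unname(retention_rate(paste0("s", 1:4), both, 1:3)),
               c(0, 0, 0))
})

test_that("WGD1 classification distinguishes same/different/not-in-cluster", {
  fam <- full_family()
  clusters <- c(g1 = "early peak", g2 = "early peak",
                g3 = "early peak", g4 = "late induction")
  de <- c("g1", "g3", "g4")
  cls <- classify_ohnologs(de, clusters, fam, 1)
  expect_equal(unname(as.character(cls$category["g1"])), "same cluster")
  expect_equal(unname(as.character(cls$category["g3"])), "different cluster")
  expect_equal(unname(as.character(cls$category["g4"])), "different cluster")
  expect_equal(cls$n_with_ohnolog, 3L)
  # sole relative not DE -> not in cluster
  cls2 <- classify_ohnologs("g1", c(g1 = "early peak"), fam, 1)
  expect_equal(unname(as.character(cls2$category["g1"])), "not in cluster")
  # genes missing from the cluster set are rejected
  expect_error(classify_ohnologs("g5", clusters, fam, 1), "absent")
})

test_that("WGD1 same-cluster classification is symmetric", {
  fam <- full_family()
  clusters <- c(g1 = "A", g2 = "A", g3 = "B", g4 = "B")
  cls <- classify_ohnologs(c("g1", "g2", "g3", "g4"), clusters, fam, 1)
  expect_equal(unname(as.character(cls$category[c("g1", "g2")])),
               rep("same cluster", 2))
  expect_equal(unname(as.character(cls$category[c("g3", "g4")])),
               rep("same cluster", 2))
})

test_that("WGD2/WGD3 categories follow the concordance-first precedence", {
  fam <- full_family()
  states <- c("same", "other", "none")
  # enumerate every relative-state combination for the 2 WGD2 relatives
  # and the 4 WGD3 relatives of g1
  grid2 <- expand.grid(a = states, b = states, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid2))) {
    st <- unlist(grid2[i, ])
    clusters <- c(g1 = "C",
                  g3 = switch(st[[1]], same = "C", other = "D", none = NA),
                  g4 = switch(st[[2]], same = "C", other = "E", none = NA))
    clusters <- clusters[!is.na(clusters)]
    cls <- classify_ohnologs("g1", clusters, fam, 2)
    expect_equal(unname(as.character(cls$category["g1"])),
                 precedence_oracle(st, 2L), info = paste(st, collapse = "/"))
  }
  set.seed(63)
  for (rep in 1:20) {
    st <- sample(states, 4, replace = TRUE)
    rel <- c("g5", "g6", "g7", "g8")
    cl_rel <- ifelse(st == "same", "C", ifelse(st == "other", "D", NA))
    clusters <- c(C = "C")
    names(clusters) <- "g1"
    clusters <- c(clusters, stats::setNames(cl_rel[!is.na(cl_rel)],
                                            rel[!is.na(cl_rel)]))
    cls <- classify_ohnologs("g1", clusters, fam, 3)
    expect_equal(unname(as.character(cls$category["g1"])),
                 precedence_oracle(st, 3L), info = paste(st, collapse = "/"))
  }
})

test_that("classification summaries reproduce printed-table arithmetic", {
  counts <- c("same cluster" = 956, "different cluster" = 92,
              "not in cluster" = 647)
  s <- summarize_classification(counts)
  expect_equal(attr(s, "n_total"), 1695)
  expect_equal(s$percent[s$category == "same cluster"], 56.4)
  expect_equal(s$percent[s$category == "different cluster"], 5.4)
  expect_equal(s$percent[s$category == "not in cluster"], 38.2)
  expect_equal(subfunctionalization_bound(counts), 5.4)

  expect_equal(summarize_classification(c("same cluster" = 1))$percent, 100)
  expect_error(summarize_classification(c(a = 0, b = 0)), "empty")

  set.seed(64)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    cnt <- stats::setNames(sample(0:50, k), paste0("cat", seq_len(k)))
    cnt[1] <- cnt[1] + 1  # non-empty
    s2 <- summarize_classification(cnt)
    expect_equal(s2$count, unname(as.integer(cnt)))
    expect_equal(s2$percent, unname(round(100 * cnt / sum(cnt), 1)))
    expect_equal(sum(s2$count), attr(s2, "n_total"))
  }
})

test_that("category counts always sum to the with-ohnolog denominator", {
  sim <- shared_sim()
  gm <- summarize_genes(quantile_normalize(sim$matrix), sim$probes)
  res <- de_analysis(gm, sim$sheet, de_config(fold_change = 2))
  de <- call_de(res)
  cl <- cluster_genes(gm, de, 6, sim$sheet, default_archetypes("autogamy"))
  for (lv in 1:3) {
    cls <- classify_ohnologs(de, cl, sim$genome$families, lv)
    if (cls$n_with_ohnolog == 0L) next
    s <- summarize_classification(cls)
    expect_equal(sum(s$count), cls$n_with_ohnolog)
    expect_setequal(s$category, wgdexpr:::ohnolog_categories(lv))
  }
})

test_that("the subfunctionalization bound is zero without divergent pairs", {
  fam <- full_family()
  clusters <- c(g1 = "A", g2 = "A", g3 = "A", g4 = "A")
  cls <- classify_ohnologs(names(clusters), clusters, fam, 1)
  expect_equal(subfunctionalization_bound(cls), 0)
})

test_that("retention tables carry one row per gene set", {
  g <- simulate_genome(sim_config(n_ancestral = 100, seed = 65))
  sets <- list(first = g$genes[1:30], all = g$genes)
  tab <- retention_table(sets, g$families)
  expect_equal(tab$set, c("first", "all"))
  expect_equal(tab$n_genes, c(30L, length(g$genes)))
  expect_true(all(tab$WGD1 >= 0 & tab$WGD1 <= 1))
  expect_true(all(tab$WGD3 <= tab$WGD1 + 0.2))
})
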