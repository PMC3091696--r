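test_that("cell-means fits recover level means and contrasts", {
  m <- matrix(c(1, 3, 5, 7), nrow = 1,
              dimnames = list("g1", c("T0_r1", "T0_r2", "T1_r1", "T1_r2")))
  m <- rbind(g1 = m[1, ], g2 = c(2, 2, 2, 2))
  sheet <- toy_sheet(c("T0", "T1"))
  fit <- fit_timecourse(m, sheet, de_config())
  expect_equal(unname(fit$coefficients["g1", ]), c(2, 6))
  expect_equal(unname(fit$coefficients["g2", ]), c(2, 2))
  ct <- wgdexpr:::all_pair_contrasts(fit)
  lfc <- fit$coefficients[, ct$i] - fit$coefficients[, ct$j]
  expect_equal(unname(lfc["g1"]), 4)
  # identical replicates everywhere -> zero residual variance
  expect_equal(unname(fit$sigma2["g2"]), 0)
  expect_equal(fit$df_residual, c(2, 2), ignore_attr = TRUE)
})

test_that("fits equal the normal-equations least-squares oracle", {
  set.seed(301)
  for (rep in 1:5) {
    n_lev <- sample(3:5, 1)
    reps <- sample(2:3, 1)
    tps <- paste0("T", seq_len(n_lev) - 1)
    sheet <- toy_sheet(tps, reps = reps)
    m <- matrix(rnorm(20 * nrow(sheet), 10), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), sheet$sample_id))
    fit <- fit_timecourse(m, sheet, de_config())
    X <- fit$design
    for (g in sample(rownames(m), 4)) {
      i <- match(g, rownames(m))
      o <- ls_oracle(m[g, ], X)
      expect_equal(unname(fit$coefficients[g, ]), unname(o$beta),
                   tolerance = 1e-10)
      expect_equal(unname(fit$sigma2[g]), o$rss / o$df, tolerance = 1e-10)
      expect_equal(fit$df_residual[i], o$df, ignore_attr = TRUE)
    }
  }
})

test_that("designs without residual degrees of freedom are rejected", {
  m <- matrix(rnorm(4), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  sheet <- data.frame(sample_id = c("a", "b"), experiment = "toy",
                      timepoint = c("T0", "T1"))
  expect_error(fit_timecourse(m, sheet, de_config()), "residual")
  sheet2 <- data.frame(sample_id = c("a", "x"), experiment = "toy",
                       timepoint = c("T0", "T1"))
  expect_error(fit_timecourse(m, sheet2, de_config()), "missing")
})

test_that("DEV2 and DEV3 merge into one autogamy level", {
  sim <- shared_sim()
  gm <- summarize_genes(sim$matrix, sim$probes)
  fit <- fit_timecourse(gm, sim$sheet, de_config(merge_dev23 = TRUE))
  expect_setequal(fit$levels, c("VEG", "MEI", "FRAG", "DEV1", "DEV2-3"))
  fit2 <- fit_timecourse(gm, sim$sheet, de_config(merge_dev23 = FALSE))
  expect_length(fit2$levels, 6L)
})

test_that("identical variances give an infinite prior and no shrinkage", {
  fit <- structure(list(sigma2 = rep(0.04, 50), df_residual = rep(5, 50)),
                   class = "timecourse_fit")
  eb <- estimate_ebayes(fit)
  expect_equal(eb$df_prior, Inf)
  expect_equal(eb$var_prior, 0.04)
  expect_equal(eb$var_post, rep(0.04, 50))
})

test_that("hierarchical variance parameters are recovered by moment matching", {
  set.seed(302)
  d0 <- 4; s02 <- 0.05; dg <- 8
  v <- s02 * stats::rf(5000, dg, d0)
  fit <- structure(list(sigma2 = v, df_residual = rep(dg, 5000)),
                   class = "timecourse_fit")
  eb <- estimate_ebayes(fit)
  expect_lt(abs(eb$df_prior - d0), 1)
  expect_lt(abs(eb$var_prior - s02) / s02, 0.2)
  # posterior lies between the gene variance and the prior
  expect_true(all(eb$var_post >= pmin(v, eb$var_prior) - 1e-12))
  expect_true(all(eb$var_post <= pmax(v, eb$var_prior) + 1e-12))
})

test_that("zero-variance genes are handled through the offset convention", {
  set.seed(303)
  v <- c(rep(0, 5), 0.05 * stats::rchisq(100, 5) / 5)
  fit <- structure(list(sigma2 = v, df_residual = rep(5, length(v))),
                   class = "timecourse_fit")
  eb <- estimate_ebayes(fit)
  expect_true(all(is.finite(eb$var_post)) && all(eb$var_post > 0))
})

test_that("flat genes get p = 1 and are never flagged", {
  m <- rbind(flat = rep(5, 12), de = rep(c(0, 4, 8), each = 4))
  colnames(m) <- toy_sheet(c("T0", "T1", "T2"), reps = 4)$sample_id
  m <- m + matrix(rnorm(24, 0, 0.01), 2)
  m["flat", ] <- 5  # exactly flat
  sheet <- toy_sheet(c("T0", "T1", "T2"), reps = 4)
  fit <- fit_timecourse(m, sheet, de_config())
  eb <- suppressWarnings(estimate_ebayes(fit))
  res <- moderated_tests(fit, eb, de_config())
  expect_equal(res$table$p_value[res$table$gene_id == "flat"], 1)
  expect_false(res$table$de[res$table$gene_id == "flat"])
  expect_true(res$table$de[res$table$gene_id == "de"])
})

test_that("a single-contrast design reduces to a moderated two-sample t-test", {
  set.seed(304)
  sheet <- toy_sheet(c("T0", "T1"), reps = 3)
  m <- matrix(rnorm(50 * 6, 10), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sheet$sample_id))
  fit <- fit_timecourse(m, sheet, de_config())
  eb <- estimate_ebayes(fit)
  res <- moderated_tests(fit, eb, de_config())
  # hand-computed moderated two-sample t on the same shrunken variances
  for (g in sample(rownames(m), 5)) {
    i <- which(rownames(m) == g)
    lfc <- mean(m[g, 4:6]) - mean(m[g, 1:3])
    se <- sqrt(eb$var_post[i] * (1 / 3 + 1 / 3))
    t_ref <- lfc / se
    df_ref <- min(eb$df_prior + 4, sum(fit$df_residual))
    p_ref <- 2 * stats::pt(-abs(t_ref), df = df_ref)
    expect_equal(unname(res$p[g, 1]), min(p_ref, 1), tolerance = 1e-10)
    expect_equal(unname(res$table$p_value[i]), min(1, p_ref), tolerance = 1e-10)
  }
})

test_that("TREAT with tau = 0 equals the ordinary moderated test exactly", {
  set.seed(305)
  sheet <- toy_sheet(c("T0", "T1", "T2"), reps = 3)
  m <- matrix(rnorm(100 * 9, 10), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sheet$sample_id))
  fit <- fit_timecourse(m, sheet, de_config())
  eb <- estimate_ebayes(fit)
  r_mod <- moderated_tests(fit, eb, de_config())
  r_treat <- treat_tests(fit, eb, de_config(fold_change = 1))
  expect_identical(r_treat$table$p_value, r_mod$table$p_value)
  expect_identical(r_treat$p, r_mod$p)
})

test_that("TREAT p tends to 0.5 when |logFC| sits exactly at the threshold", {
  tau <- log2(2)
  fit <- structure(list(
    coefficients = matrix(c(0, tau), 1, dimnames = list("g1", c("A", "B"))),
    sigma2 = c(g1 = 1e-12), df_residual = c(g1 = 4),
    level_n = c(3L, 3L), levels = c("A", "B")), class = "timecourse_fit")
  eb <- structure(list(df_prior = 4, var_prior = 1e-12, var_post = 1e-12),
                  class = "ebayes_params")
  res <- treat_tests(fit, eb, de_config(fold_change = 2))
  expect_equal(res$p[1, 1], 0.5, tolerance = 1e-6)
})

test_that("TREAT is conservative: p never below the ordinary moderated p", {
  set.seed(306)
  sheet <- toy_sheet(c("T0", "T1", "T2"), reps = 3)
  m <- matrix(rnorm(200 * 9, 10, 1), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sheet$sample_id))
  m[1:50, 4:9] <- m[1:50, 4:9] + 1.5
  fit <- fit_timecourse(m, sheet, de_config())
  eb <- estimate_ebayes(fit)
  p_mod <- moderated_tests(fit, eb, de_config())$p
  p_treat <- treat_tests(fit, eb, de_config(fold_change = 1.5))$p
  expect_true(all(p_treat >= p_mod - 1e-12))
})

test_that("BH adjustment equals the hand step-up evaluation", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(adjust_bh(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  set.seed(307)
  for (i in 1:5) {
    p <- stats::runif(sample(5:50, 1))
    expect_equal(adjust_bh(p), bh_oracle(p))
    # invariance under permutation of genes
    perm <- sample(length(p))
    expect_equal(adjust_bh(p[perm]), adjust_bh(p)[perm])
    expect_true(all(adjust_bh(p) >= p))
  }
  expect_error(adjust_bh(c(0.1, NaN)), "finite")
  expect_error(adjust_bh(c(0.1, 1.7)), "\\[0, 1\\]")
})

test_that("DE calls are empty when nothing passes and recover planted genes", {
  set.seed(308)
  sheet <- toy_sheet(c("T0", "T1", "T2"), reps = 3)
  null_m <- matrix(rnorm(100 * 9, 10, 0.3), nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100), sheet$sample_id))
  res_null <- de_analysis(null_m, sheet)
  expect_length(call_de(res_null), sum(res_null$table$de))

  sim <- simulate_dataset(sim_config(n_ancestral = 300, seed = 31,
                                     frac_de = 0.3))
  gm <- summarize_genes(quantile_normalize(sim$matrix), sim$probes)
  res <- de_analysis(gm, sim$sheet)
  truth_de <- sim$truth$gene_id[sim$truth$archetype != "flat"]
  recall <- mean(truth_de %in% call_de(res))
  expect_gte(recall, 0.8)
})

test_that("up-regulated calls point away from the reference timepoint", {
  sheet <- toy_sheet(c("T0", "T1"), reps = 3)
  m <- rbind(up = rep(c(10, 13), each = 3), down = rep(c(10, 7), each = 3))
  colnames(m) <- sheet$sample_id
  m <- m + matrix(rnorm(12, 0, 0.05), 2)
  res <- suppressWarnings(de_analysis(m, sheet))  # 2-gene toy: unstable prior
  up <- call_de_up(res, res$fit)
  expect_true("up" %in% up)
  expect_false("down" %in% up)
})
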