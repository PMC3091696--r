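test_that("exact-substring probes hit exactly their source transcript", {
  set.seed(101)
  transcripts <- stats::setNames(
    vapply(1:5, function(i) random_dna(300), character(1)),
    paste0("t", 1:5))
  probe <- substr(transcripts[["t3"]], 51, 100)
  hits <- match_probe_targets(probe, transcripts, platform_config(max_mismatch = 0))
  expect_identical(hits, "t3")
})

test_that("probes beyond the mismatch budget match nothing", {
  set.seed(102)
  transcripts <- stats::setNames(
    vapply(1:4, function(i) random_dna(200, gc = 0.3), character(1)),
    paste0("t", 1:4))
  # random 50-mers at GC 0.5 are ~25 mismatches from any AT-rich window
  probe <- random_dna(50, gc = 1.0)  # all G/C vs 30% GC background
  expect_length(match_probe_targets(probe, transcripts, platform_config()), 0L)
})

test_that("probe matching equals the exhaustive Hamming oracle", {
  set.seed(103)
  transcripts <- stats::setNames(
    vapply(1:20, function(i) random_dna(300), character(1)), paste0("t", 1:20))
  for (rep in 1:8) {
    src <- sample(names(transcripts), 1)
    off <- sample(0:250, 1)
    probe <- substr(transcripts[[src]], off + 1, off + 50)
    probe <- mutate_sequence(probe, frac = sample(c(0, 0.04, 0.1, 0.2), 1))
    for (mm in c(0L, 3L, 5L)) {
      cfg <- platform_config(max_mismatch = mm)
      expect_setequal(match_probe_targets(probe, transcripts, cfg),
                      hamming_match_oracle(probe, transcripts, mm))
    }
  }
})

test_that("matching is symmetric under reverse complement of both sides", {
  set.seed(104)
  transcripts <- stats::setNames(
    vapply(1:6, function(i) random_dna(250), character(1)), paste0("t", 1:6))
  probe <- mutate_sequence(substr(transcripts[["t2"]], 21, 70), 0.06)
  cfg <- platform_config(max_mismatch = 5)
  rc_transcripts <- stats::setNames(revcomp(transcripts), names(transcripts))
  expect_setequal(match_probe_targets(probe, transcripts, cfg),
                  match_probe_targets(revcomp(probe), rc_transcripts, cfg))
})

test_that("ambiguous bases count as mismatches", {
  tr <- c(t1 = random_dna(120))
  probe <- substr(tr[["t1"]], 11, 60)
  probe_n <- paste0("NNNNNN", substr(probe, 7, 50))
  expect_length(match_probe_targets(probe_n, tr, platform_config(max_mismatch = 5)), 0L)
  expect_identical(match_probe_targets(probe_n, tr, platform_config(max_mismatch = 6)), "t1")
})

test_that("platform uniqueness separates divergent and twin platforms", {
  set.seed(105)
  # mutually unrelated transcripts at zero mismatch: all probes unique
  cfg0 <- sim_config(n_ancestral = 8, seed = 21, retention_probs = c(0, 0, 0))
  sp <- simulate_transcripts_probes(simulate_genome(cfg0), cfg0)
  rep0 <- platform_uniqueness(sp$probes, sp$transcripts,
                              platform_config(max_mismatch = 0))
  expect_equal(rep0$summary$frac_unique, 1.0)
  expect_true(all(rep0$per_probe$self_hit))

  # one identical twin pair: those 12 probes hit exactly 2 transcripts
  cfg1 <- sim_config(n_ancestral = 5, seed = 22, retention_probs = c(0, 0, 0))
  g1 <- simulate_genome(cfg1)
  sp1 <- simulate_transcripts_probes(g1, cfg1)
  twin <- sp1$transcripts[[1]]
  transcripts <- c(sp1$transcripts, twin2 = twin)
  probes <- rbind(sp1$probes,
                  design_probe_rows <- {
                    p <- sp1$probes[sp1$probes$gene_id == names(sp1$transcripts)[1], ]
                    p$gene_id <- "twin2"
                    p$probe_id <- sub("^[^_]+", "twin2", p$probe_id)
                    p
                  })
  rep1 <- platform_uniqueness(probes, transcripts, platform_config())
  twin_probes <- rep1$per_probe$gene_id %in% c(names(sp1$transcripts)[1], "twin2")
  expect_true(all(rep1$per_probe$n_targets[twin_probes] == 2L))
  expect_true(all(rep1$per_probe$n_targets[!twin_probes] == 1L))
})

test_that("uniqueness fraction reflects the share of near-identical pairs", {
  set.seed(106)
  # 40 unrelated genes; 3 of them (15% of 20 pairs... of genes) duplicated
  # at 98% identity -> 6 of 46 transcripts in near-identical pairs
  base <- stats::setNames(vapply(1:40, function(i) random_dna(400, gc = 0.3),
                                 character(1)), sprintf("g%02d", 1:40))
  twins <- stats::setNames(vapply(base[1:3], mutate_sequence, character(1),
                                  frac = 0.02), paste0(names(base)[1:3], "b"))
  transcripts <- c(base, twins)
  probes <- do.call(rbind, lapply(names(transcripts), function(g) {
    wgdexpr:::design_gene_probes(g, transcripts[[g]], gc_target = 0.36)
  }))
  rep <- platform_uniqueness(probes, transcripts, platform_config())
  expected_unique <- (length(transcripts) - 6) / length(transcripts)
  expect_lt(abs(rep$summary$frac_unique - expected_unique), 0.05)
  expect_gt(rep$summary$frac_le2, 0.99)
})

test_that("probes whose transcript is absent are flagged and excluded", {
  set.seed(107)
  tr <- c(t1 = random_dna(200))
  probes <- data.frame(probe_id = c("a", "b"), gene_id = c("t1", "missing"),
                       sequence = c(substr(tr[["t1"]], 1, 50), random_dna(50)),
                       stringsAsFactors = FALSE)
  rep <- platform_uniqueness(probes, tr, platform_config())
  expect_true(rep$per_probe$excluded[2])
  expect_equal(rep$summary$n_probes, 1L)
})

test_that("normexp posterior matches the degenerate constant-background limit", {
  x <- c(110, 150, 300, 1000)
  mu <- 100
  out <- wgdexpr:::normexp_posterior(x, mu = mu, sigma = 1e-6, alpha = 1 / 500)
  expect_equal(out, pmax(x - mu, 1e-300), tolerance = 1e-3)
})

test_that("background correction is monotone and rank-preserving per sample", {
  set.seed(108)
  x <- rexp(600, 1 / 400) + rnorm(600, 150, 25)
  m <- matrix(x, ncol = 2, dimnames = list(paste0("p", 1:300), c("s1", "s2")))
  bc <- background_correct(m)
  expect_identical(dimnames(bc), dimnames(m))
  for (j in 1:2) expect_identical(order(bc[, j]), order(m[, j]))
  # strictly increasing column in, strictly increasing out
  inc <- matrix(sort(x[1:100]), ncol = 1,
                dimnames = list(paste0("p", 1:100), "s"))
  expect_true(all(diff(background_correct(inc)[, 1]) > 0))
})

test_that("background correction rejects non-positive linear intensities", {
  m <- matrix(c(-1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(background_correct(m), "positive")
})

test_that("normexp posterior agrees with the limma evaluation of the model", {
  set.seed(109)
  x <- rexp(3000, 1 / 500) + rnorm(3000, 200, 30)
  p <- wgdexpr:::normexp_params(x)
  mine <- wgdexpr:::normexp_posterior(x, p$mu, p$sigma, p$alpha)
  # limma parameterizes the exponential by its mean (1/rate)
  ref <- limma::normexp.signal(c(p$mu, log(p$sigma), log(1 / p$alpha)), x)
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("correction brings log-signals closer to the simulated truth", {
  set.seed(110)
  s <- rexp(5000, 1 / 300)
  x <- s + rnorm(5000, 200, 30)
  p <- wgdexpr:::normexp_params(x)
  corrected <- wgdexpr:::normexp_posterior(x, p$mu, p$sigma, p$alpha)
  expect_gt(cor(log2(corrected), log2(s)), cor(log2(x), log2(s)))
})
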