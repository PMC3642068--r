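cfg_plain <- function(...) apv_config("A", "B", use_rvm = FALSE, ...)

test_that("the hand-computable ANCOVA toy gene is reproduced exactly", {
  # the fit is exact (zero residual), so the unmoderated p is undefined
  expect_warning(
    fit <- apv_fit_gene(x = c(0, 1, 0, 1), y = c(0, 1, 2, 3),
                        groups = c("A", "A", "B", "B"),
                        config = cfg_plain()),
    "zero residual")
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$delta_pt, 2.0)
  expect_equal(fit$delta_p, 2.0)
  expect_equal(fit$delta_c, 0.0)
  expect_equal(fit$rss, 0.0)
})

test_that("group-identical responses give a null result", {
  # group B is an exact copy of group A: no group effect, but a nonzero
  # residual so the F ratio is defined without moderation
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(1, 3, 2, 1, 3, 2)
  fit <- apv_fit_gene(x, y, c("A", "A", "A", "B", "B", "B"),
                      config = cfg_plain())
  expect_equal(fit$delta_pt, 0)
  expect_equal(fit$fstat, 0)
  expect_equal(fit$p, 1)
  expect_gt(fit$rss, 0)
})

test_that("unmoderated APV matches the lm() ANCOVA oracle to 1e-10", {
  set.seed(31)
  groups <- rep(c("A", "B"), each = 4)
  for (i in 1:100) {
    x <- rnorm(8, 7, 1)
    y <- rnorm(1) + runif(1) * x + rnorm(8, 0, 0.5) +
      (groups == "B") * rnorm(1)
    fit <- apv_fit_gene(x, y, groups, config = cfg_plain())
    orc <- ancova_lm_oracle(x, y, groups)
    expect_equal(fit$p, orc$p, tolerance = 1e-10)
    expect_equal(fit$fstat, orc$fstat, tolerance = 1e-8)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
  }
})

test_that("slope reliability follows the band rule table", {
  cfg <- apv_config("A", "B")
  # inside [0, 1]: p = 1, retained
  r <- slope_reliability(0.5, 0.2, 4, cfg)
  expect_equal(r$slope_p, 1)
  expect_false(r$slope_filtered)
  # beyond maxSlope: filtered regardless of p
  r2 <- slope_reliability(2.0, 1.5, 4, cfg)
  expect_true(r2$slope_filtered)
  # slightly above 1: retained when the band test is insignificant,
  # filtered when it rejects
  se_half <- (1.2 - 1) / qt(0.5, 4, lower.tail = FALSE)   # slope_p = 0.5
  se_001 <- (1.2 - 1) / qt(0.01, 4, lower.tail = FALSE)   # slope_p = 0.01
  expect_false(slope_reliability(1.2, se_half, 4, cfg)$slope_filtered)
  expect_true(slope_reliability(1.2, se_001, 4, cfg)$slope_filtered)
  # below minSlope
  expect_true(slope_reliability(-0.7, 10, 4, cfg)$slope_filtered)
  # tails equal t probabilities
  expect_equal(slope_reliability(1.5, 0.25, 6, cfg)$slope_p,
               pt(2, 6, lower.tail = FALSE))
  expect_equal(slope_reliability(-0.25, 0.25, 6, cfg)$slope_p,
               pt(-1, 6))
})

test_that("bh_adjust matches the independent step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # ties get identical adjusted values
  p <- c(0.02, 0.02, 0.9)
  expect_equal(bh_adjust(p)[1], bh_adjust(p)[2])
  # NA entries stay NA and do not count as tests
  expect_equal(bh_adjust(c(0.05, NA)), c(0.05, NA))
})

test_that("the adjusted-mean identity holds to numerical precision", {
  sim <- simulate_dataset(simulation_params(
    n_genes = 800, n_spiked_up = 60, n_spiked_down = 60,
    n_transcriptional = 40, seed = 12))
  fit <- apv_analysis(sim$dataset, apv_config("reference", "contrast"))
  r <- fit$results
  dev <- abs(r$delta_pt - (r$delta_p - r$slope * r$delta_c))
  expect_lt(max(dev, na.rm = TRUE), 1e-12)
  expect_true(all(r$p >= 0 & r$p <= 1, na.rm = TRUE))
  expect_true(all(r$fdr >= r$p - 1e-12, na.rm = TRUE))
  expect_true(all(r$included ==
                    (!r$slope_filtered & !r$delta_filtered &
                       !is.na(r$fdr) & r$fdr <= fit$config$fdr_threshold)))
})

test_that("results are invariant to sample and gene permutations", {
  sim <- simulate_dataset(simulation_params(
    n_genes = 200, n_spiked_up = 20, n_spiked_down = 20,
    n_transcriptional = 10, seed = 4))
  ds <- sim$dataset
  cfg <- apv_config("reference", "contrast")
  base <- apv_analysis(ds, cfg)$results

  perm_s <- sample(ncol(ds$cytosolic))
  perm_g <- sample(nrow(ds$cytosolic))
  ds2 <- align_paired_dataset(ds$cytosolic[perm_g, perm_s],
                              ds$polysome[perm_g, perm_s],
                              ds$annotation)
  shuffled <- apv_analysis(ds2, cfg)$results
  shuffled <- shuffled[match(base$gene_id, shuffled$gene_id), ]
  expect_equal(shuffled$p, base$p, tolerance = 1e-12)
  expect_equal(shuffled$delta_pt, base$delta_pt, tolerance = 1e-12)
})

test_that("moderation keeps p-values defined in the one-residual-df regime", {
  sim <- simulate_dataset(simulation_params(
    n_genes = 400, n_spiked_up = 30, n_spiked_down = 30,
    n_transcriptional = 20, seed = 9))
  fit <- apv_analysis(sim$dataset, apv_config("reference", "contrast"))
  expect_equal(unique(fit$results$df), 1)
  expect_true(all(is.finite(fit$results$p[!is.na(fit$results$slope)])))
  expect_equal(unique(fit$results$df_mod), 1 + 2 * fit$prior$a)
})

test_that("design violations are rejected", {
  ds <- toy_paired_dataset()
  expect_error(apv_analysis(ds, apv_config("A", "missing")), "missing")
  expect_error(
    apv_fit_gene(c(1, 2, 3), c(1, 2, 3), c("A", "B", "B"),
                 config = cfg_plain()),
    "design error")
})

test_that("de_analysis computes moderated one-way contrasts", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 6, 4, 6))
  colnames(m) <- sprintf("s%d", 1:4)
  de <- de_analysis(m, c("A", "A", "B", "B"), reference = "A",
                    contrast = "B", use_rvm = FALSE)
  expect_equal(de$results$effect, c(2, 0))
  expect_equal(de$results$fstat[2], 0)
  expect_equal(de$results$p[2], 1)

  # unmoderated p equals classic one-way ANOVA
  set.seed(21)
  groups <- rep(c("A", "B", "C"), each = 3)
  mm <- matrix(rnorm(30 * 9, 5, 1), 30, 9,
               dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:9)))
  de2 <- de_analysis(mm, groups, reference = "A", contrast = "B",
                     use_rvm = FALSE)
  for (i in 1:30) {
    a <- anova(lm(mm[i, ] ~ factor(groups)))
    expect_equal(de2$results$p[i], a[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("with a zero slope, APV and polysome-only DE agree on effects", {
  set.seed(77)
  G <- 400; groups <- rep(c("reference", "contrast"), each = 3)
  mu <- rnorm(G, 7, 1)
  X <- matrix(rnorm(G * 6, mu, 0.5), G, 6)
  Y <- matrix(rnorm(G * 6, 2, 0.5), G, 6) +
    outer(c(rep(1, 50), rep(0, G - 50)), as.numeric(groups == "contrast"))
  rownames(X) <- rownames(Y) <- sprintf("g%04d", 1:G)
  colnames(X) <- sprintf("%s_c%d", groups, rep(1:3, 2))
  colnames(Y) <- sprintf("%s_p%d", groups, rep(1:3, 2))
  ann <- data.frame(sample_id = c(colnames(X), colnames(Y)),
                    group = rep(groups, 2),
                    fraction = rep(c("cytosolic", "polysome"), each = 6),
                    replicate = rep(rep(1:3, 2), 2))
  ds <- align_paired_dataset(X, Y, ann)
  apv <- apv_analysis(ds, apv_config("reference", "contrast"))
  de <- de_analysis(ds$polysome, ds$pairing$group,
                    reference = "reference", contrast = "contrast")
  # Monte-Carlo agreement: the cytosolic adjustment is pure noise here, so
  # adjusted and unadjusted effects coincide up to the beta-hat * delta_c
  # sampling error, which averages out and leaves the estimates aligned
  d <- apv$results$delta_pt - de$results$effect
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  expect_gt(cor(apv$results$delta_pt, de$results$effect), 0.8)
  spiked <- 1:50
  expect_lt(abs(mean(apv$results$delta_pt[spiked]) -
                  mean(de$results$effect[spiked])),
            3 * sd(d[spiked]) / sqrt(50))
})
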