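test_that("the generator is bitwise reproducible and validates params", {
  p <- simulation_params(n_genes = 200, n_spiked_up = 20,
                         n_spiked_down = 20, n_transcriptional = 10,
                         seed = 5)
  a <- simulate_dataset(p)
  b <- simulate_dataset(p)
  expect_identical(a$dataset$cytosolic, b$dataset$cytosolic)
  expect_identical(a$dataset$polysome, b$dataset$polysome)
  expect_identical(a$truth$spiked_up, b$truth$spiked_up)

  expect_error(simulation_params(n_genes = 100, n_spiked_up = 90,
                                 n_spiked_down = 90, seed = 1),
               "exceed")
  expect_error(simulation_params(seed = 1, effect_size = -1), ">= 0")
  expect_error(simulation_params(n_genes = 10), "seed")
})

test_that("a null simulation carries no spiked truth", {
  sim <- simulate_dataset(simulation_params(
    n_genes = 300, n_spiked_up = 0, n_spiked_down = 0,
    n_transcriptional = 0, seed = 3))
  expect_length(sim$truth$spiked_up, 0)
  expect_length(sim$truth$spiked_down, 0)
  fit <- apv_analysis(sim$dataset, apv_config("reference", "contrast"))
  expect_true(sum(fit$results$included) <= 3)  # essentially no discoveries
})

test_that("spiked genes realize the requested adjusted-mean effect", {
  sim <- simulate_dataset(simulation_params(n_genes = 5000, seed = 8))
  fit <- apv_analysis(sim$dataset, apv_config("reference", "contrast"))
  r <- fit$results
  up <- r$delta_pt[r$gene_id %in% names(sim$truth$spiked_up)]
  # law of large numbers: mean realized effect ~ Delta within 3 MC se
  mc_se <- sd(up) / sqrt(length(up))
  expect_lt(abs(mean(up) - 2), 3 * mc_se)
  dn <- r$delta_pt[r$gene_id %in% names(sim$truth$spiked_down)]
  expect_lt(abs(mean(dn) + 2), 3 * sd(dn) / sqrt(length(dn)))
  # unspiked, untranscribed genes are centred at zero
  nulls <- setdiff(r$gene_id, c(names(sim$truth$spiked_up),
                                names(sim$truth$spiked_down),
                                names(sim$truth$transcriptional)))
  nv <- r$delta_pt[r$gene_id %in% nulls]
  expect_lt(abs(mean(nv)), 3 * sd(nv) / sqrt(length(nv)))
})

test_that("transcriptional spikes move cytosolic but not adjusted effects", {
  sim <- simulate_dataset(simulation_params(
    n_genes = 3000, n_spiked_up = 0, n_spiked_down = 0,
    n_transcriptional = 500, seed = 13))
  fit <- apv_analysis(sim$dataset, apv_config("reference", "contrast"))
  r <- fit$results
  tr <- r[r$gene_id %in% names(sim$truth$transcriptional), ]
  expect_gt(median(abs(tr$delta_c)), 1.5)        # cytosolic effect present
  # the adjusted effect of a transcriptional gene is centred at zero; its
  # estimator has heavy (t-like) tails, so the median is the stable summary
  expect_lt(abs(median(tr$delta_pt)), 0.1)
  expect_lt(mean(tr$included), 0.02)             # not called translational
})

test_that("residual variances re-estimated from fits recover the prior", {
  sim <- simulate_dataset(simulation_params(
    n_genes = 10000, n_spiked_up = 0, n_spiked_down = 0,
    n_transcriptional = 0, seed = 20))
  fit <- apv_analysis(sim$dataset, apv_config("reference", "contrast"))
  expect_true(fit$prior$converged)
  expect_lt(abs(fit$prior$a - 3) / 3, 0.25)
  expect_lt(abs(fit$prior$b - 2) / 2, 0.25)
})

test_that("secondary effects follow the requested concordance", {
  sim <- simulate_dataset(simulation_params(n_genes = 1000, seed = 6))
  sec <- simulate_secondary_effects(sim$truth, concordance_rate = 1,
                                    seed = 7)
  prim <- c(sim$truth$spiked_up, sim$truth$spiked_down)
  expect_true(all(sign(sec[names(prim)]) == sign(prim)))
  cm <- concordance_module(prim, NULL, sec, secondary_fold = 1.3)
  expect_equal(cm$n_discordant, 0)

  # round-trips through the external-effects TSV reader
  path <- withr::local_tempfile(fileext = ".tsv")
  write_effects_tsv(sec, path)
  expect_equal(read_effects_tsv(path), sec, tolerance = 1e-15)
})

test_that("a 50% concordance rate yields uniform-ish binomial p over seeds", {
  sim <- simulate_dataset(simulation_params(n_genes = 1500, seed = 30))
  prim <- c(sim$truth$spiked_up, sim$truth$spiked_down)
  ps <- vapply(1:40, function(s) {
    sec <- simulate_secondary_effects(sim$truth, concordance_rate = 0.5,
                                      seed = 100 + s)
    concordance_module(prim, NULL, sec, secondary_fold = 1.3)$binomial_p
  }, numeric(1))
  # with ~700 qualifying genes the discrete p is nearly continuous; the KS
  # distance of 40 uniform draws exceeds 0.25 with probability < 0.01
  ks <- suppressWarnings(ks.test(ps, "punif"))$statistic
  expect_lt(ks, 0.25)
})

test_that("linked gene sets are enriched in the spiked genes", {
  sim <- simulate_dataset(simulation_params(
    n_genes = 2000, n_spiked_up = 100, n_spiked_down = 100,
    n_transcriptional = 0, seed = 14))
  col <- simulate_gene_sets(sim$truth, seed = 15)
  spiked <- names(c(sim$truth$spiked_up, sim$truth$spiked_down))
  tab <- enrich(spiked, col, universe = sim$truth$gene_ids)
  linked <- grepl("^LINKED", tab$term_id)
  expect_true(all(tab$fdr[linked] < 0.01))
  expect_gt(min(tab$fold_enrichment[linked]),
            max(2, 0))  # clearly enriched
})
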