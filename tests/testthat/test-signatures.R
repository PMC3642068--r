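test_that("signature membership respects the log2 fold cutoff", {
  eff <- c(a = 1.7, b = 1.5, c = -1.7, d = 0.2, e = 2.5)
  sig <- build_signature(eff, fold_threshold = 3)
  expect_setequal(names(sig$up), c("a", "e"))     # 1.7 >= log2(3) ~ 1.585
  expect_setequal(names(sig$down), c("c"))
  expect_true(all(abs(c(sig$up, sig$down)) >= log2(3)))

  # the included flag gates membership
  sig2 <- build_signature(eff, included = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                          fold_threshold = 3)
  expect_length(sig2$down, 0)

  expect_length(build_signature(numeric(0), fold_threshold = 2)$up, 0)
  expect_error(build_signature(eff, fold_threshold = 0.5), ">= 1")
})

test_that("signature counts match brute-force filtering on random tables", {
  set.seed(9)
  for (i in 1:25) {
    eff <- setNames(rnorm(200, 0, 1.5), sprintf("g%d", 1:200))
    inc <- runif(200) < 0.5
    th <- runif(1, 1, 4)
    sig <- build_signature(eff, inc, th)
    expect_equal(length(sig$up), sum(inc & eff >= log2(th)))
    expect_equal(length(sig$down), sum(inc & eff <= -log2(th)))
    expect_length(intersect(names(sig$up), names(sig$down)), 0)
  }
})

test_that("overlap percentages count mappable and shared genes per direction", {
  up <- setNames(rep(2, 10), sprintf("u%d", 1:10))
  down <- setNames(rep(-2, 4), sprintf("d%d", 1:4))
  sig <- structure(list(up = up, down = down, fold_threshold = 3,
                        label = "t"), class = "signature")
  external <- c(setNames(c(rep(1.7, 5), rep(0.5, 5)), names(up)),
                setNames(rep(-1.7, 4), names(down)))
  ov <- overlap_percent(sig, external, 3, "same_direction")
  expect_equal(ov$percent[ov$direction == "up"], 50)
  expect_equal(ov$percent[ov$direction == "down"], 100)
  expect_equal(ov$n_mappable, c(10, 4))

  # unmappable genes keep n_signature but leave percent undefined
  w <- capture_warnings(ov2 <- overlap_percent(sig, c(z = 3), 3))
  expect_match(w, "percent undefined", all = TRUE)
  expect_length(w, 2)
  expect_true(all(is.na(ov2$percent)))
  expect_equal(ov2$n_signature, c(10, 4))
})

test_that("same-direction overlap never exceeds any-direction overlap", {
  set.seed(33)
  for (i in 1:20) {
    eff <- setNames(rnorm(150, 0, 1.5), sprintf("g%d", 1:150))
    sig <- build_signature(eff, fold_threshold = 2)
    ext <- setNames(rnorm(150, 0, 1.5), sprintf("g%d", 1:150))
    same <- suppressWarnings(overlap_percent(sig, ext, 2, "same_direction"))
    any <- suppressWarnings(overlap_percent(sig, ext, 2, "any_direction"))
    expect_true(all(same$n_shared <= any$n_shared))
  }
})

test_that("self-overlap of a signature is 100% in both directions", {
  set.seed(2)
  eff <- setNames(rnorm(300, 0, 2), sprintf("g%d", 1:300))
  sig <- build_signature(eff, fold_threshold = 3)
  ov <- overlap_percent(sig, eff, 3, "same_direction")
  expect_equal(ov$percent, c(100, 100))
})

test_that("concordance quadrants, counts and binomial tail are exact", {
  prim <- c(a = 2, b = 1.5, c = -2, d = 1.2, e = -1.8, f = 2.2)
  sec <- c(a = 1, b = -0.6, c = -0.9, d = 0.05, e = -1, f = 0.7)
  cm <- concordance_module(prim, NULL, sec, secondary_fold = 1.3)
  # d fails the 1.3-fold secondary filter (|0.05| < log2(1.3))
  expect_equal(sum(cm$quadrants), 5)
  expect_equal(cm$n_concordant, 4)   # a, c, e, f agree in sign
  expect_equal(cm$n_discordant, 1)   # b
  expect_equal(cm$binomial_p, binom_tail_oracle(4, 5))
  expect_setequal(cm$concordant_genes, c("a", "c", "e", "f"))

  # 9 concordant of 10: exact enumeration value 11/1024
  p9 <- pbinom(8, 10, 0.5, lower.tail = FALSE)
  expect_equal(p9, 11 / 1024)
  expect_equal(p9, binom_tail_oracle(9, 10))
  # symmetric null: 5 of 10 leaves p > 0.5
  expect_gt(binom_tail_oracle(5, 10), 0.5)
})

test_that("binomial tail matches choose() enumeration for n up to 200", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    expect_equal(pbinom(k - 1, n, 0.5, lower.tail = FALSE),
                 binom_tail_oracle(k, n), tolerance = 1e-12)
  }
})

test_that("quadrant counts are invariant under a double orientation flip", {
  set.seed(8)
  prim <- setNames(rnorm(100), sprintf("g%d", 1:100))
  sec <- setNames(rnorm(100), sprintf("g%d", 1:100))
  a <- concordance_module(prim, NULL, sec, 1.3, orientation = c(1, 1))
  b <- concordance_module(prim, NULL, sec, 1.3, orientation = c(-1, -1))
  expect_equal(a$n_concordant, b$n_concordant)
  expect_equal(b$quadrants[["down_down"]], a$quadrants[["up_up"]])
  expect_equal(a$binomial_p, b$binomial_p)
})

test_that("an empty concordance intersection warns and returns p = 1", {
  expect_warning(
    cm <- concordance_module(c(a = 2), NULL, c(a = 0.01), 1.3),
    "concordance undefined")
  expect_equal(cm$binomial_p, 1)
  expect_equal(sum(cm$quadrants), 0)
})
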