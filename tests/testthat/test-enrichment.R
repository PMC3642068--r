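test_that("hypergeometric p and fold enrichment match hand combinatorics", {
  col <- gene_set_collection(
    list(T = list(name = "t", genes = sprintf("g%d", 1:5))),
    universe = sprintf("g%d", 1:10))
  tab <- enrich(sprintf("g%d", 1:4), col, min_genes = 1)
  expect_equal(tab$p, 5 / 210)          # C(5,4)*C(5,0)/C(10,4)
  expect_equal(tab$M, 10)
  expect_equal(tab$k, 4)
  expect_equal(tab$fold_enrichment, (4 / 4) / (5 / 10))

  # zero overlap: p = 1 under the upper-tail convention, fails filters
  tab0 <- enrich(sprintf("g%d", 6:9), col)
  expect_equal(tab0$p, 1)
  expect_equal(tab0$fold_enrichment, 0)
  expect_false(tab0$passes_filters)
})

test_that("the stringent reporting filters combine fold, count and FDR", {
  fake <- function(fold, k, fdr)
    !is.na(fold) && fold > 2 && k >= 10 && fdr < 0.01
  expect_true(fake(2.5, 12, 0.005))
  expect_false(fake(2.5, 9, 0.005))    # too few regulated+annotated genes
  expect_false(fake(1.8, 12, 0.005))   # insufficient enrichment
  expect_false(fake(2.5, 12, 0.02))    # FDR above 1%

  # and the same logic through enrich() itself
  set.seed(4)
  uni <- sprintf("g%d", 1:400)
  sel <- sprintf("g%d", 1:40)
  col <- gene_set_collection(
    list(hit = list(name = "h", genes = sprintf("g%d", 1:20)),
         small = list(name = "s", genes = sprintf("g%d", c(1:9, 300))),
         null = list(name = "n", genes = sprintf("g%d", 101:140))),
    universe = uni)
  tab <- enrich(sel, col)
  expect_true(tab$passes_filters[tab$term_id == "hit"])      # k = 20
  expect_false(tab$passes_filters[tab$term_id == "small"])   # k = 9 < 10
  expect_false(tab$passes_filters[tab$term_id == "null"])
})

test_that("hypergeometric pmf sums to one and the tail is monotone in k", {
  set.seed(10)
  for (i in 1:30) {
    M <- sample(20:200, 1)
    K <- sample(1:(M - 1), 1)
    n <- sample(1:(M - 1), 1)
    kk <- max(0, n + K - M):min(K, n)
    expect_equal(sum(dhyper(kk, K, M - K, n)), 1, tolerance = 1e-12)
    tails <- phyper(kk - 1, K, M - K, n, lower.tail = FALSE)
    expect_true(all(diff(tails) <= 1e-12))
    # spot-check against the choose() oracle
    k <- sample(kk, 1)
    expect_equal(phyper(k - 1, K, M - K, n, lower.tail = FALSE),
                 hyper_tail_oracle(k, M, K, n), tolerance = 1e-12)
  }
})

test_that("genes outside the universe are dropped before counting", {
  col <- toy_collection()
  expect_message(tab <- enrich(c("g1", "g2", "nope"), col, min_genes = 1),
                 "outside the universe")
  expect_equal(unique(tab$n), 2)
  expect_warning(out <- enrich("nope", col), "empty selected")
  expect_equal(nrow(out), 0)
})

test_that("the comparison matrix caps -log10 adjusted p at the floor", {
  uni <- sprintf("g%d", 1:2000)
  col <- gene_set_collection(
    list(strong = list(name = "s", genes = sprintf("g%d", 1:50)),
         none = list(name = "n", genes = sprintf("g%d", 1000:1049))),
    universe = uni)
  sets <- list(sel = sprintf("g%d", 1:50))
  hm <- enrichment_compare(sets, col)
  # overlap 50/50 in a 2000-gene universe: p far below 1e-7, capped at 7
  expect_equal(hm["strong", "sel"], 7)
  expect_equal(hm["none", "sel"],
               -log10(enrich(sets$sel, col)[2, "fdr"]))
  # adjusted p of 1 maps to 0
  expect_equal(hm["none", "sel"] >= 0, TRUE)

  # entries equal element-wise recomputation via enrich()
  sets2 <- list(a = sprintf("g%d", 1:30), b = sprintf("g%d", 500:560))
  hm2 <- enrichment_compare(sets2, col)
  for (lab in names(sets2)) {
    tab <- enrich(sets2[[lab]], col)
    for (tid in rownames(hm2))
      expect_equal(hm2[tid, lab],
                   -log10(max(tab$fdr[tab$term_id == tid], 1e-7)))
  }
})
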