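# Small fixtures shared across test files; everything is built in code.

random_expression_matrix <- function(genes = 6, samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples, 8, 1), genes, samples,
              dimnames = list(sprintf("g%d", seq_len(genes)),
                              sprintf("s%d", seq_len(samples))))
  m
}

# 2 groups x 2 replicates x 2 fractions toy dataset with deterministic
# values (gene rows are simple arithmetic patterns).
toy_paired_dataset <- function() {
  groups <- rep(c("A", "B"), each = 2)
  reps <- rep(1:2, 2)
  csam <- sprintf("%s_c%d", groups, reps)
  psam <- sprintf("%s_p%d", groups, reps)
  X <- rbind(g1 = c(0, 1, 0, 1), g2 = c(5, 6, 5, 7), g3 = c(2, 4, 3, 5))
  Y <- rbind(g1 = c(0, 1, 2, 3), g2 = c(5, 7, 6, 8), g3 = c(1, 2, 3, 4))
  colnames(X) <- csam
  colnames(Y) <- psam
  ann <- data.frame(sample_id = c(csam, psam),
                    group = c(groups, groups),
                    fraction = rep(c("cytosolic", "polysome"), each = 4),
                    replicate = c(reps, reps))
  align_paired_dataset(X, Y, ann)
}

toy_collection <- function() {
  gene_set_collection(
    list(T1 = list(name = "term one", genes = c("g1", "g2", "g3")),
         T2 = list(name = "term two", genes = c("g4", "g5"))),
    universe = sprintf("g%d", 1:10))
}

# Independent brute-force oracles -------------------------------------------

# BH step-up by explicit sort / cummin, independent of stats::p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Hypergeometric upper tail by summing choose() terms.
hyper_tail_oracle <- function(k, M, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(M - K, n - kk)) / choose(M, n)
}

# One-sided binomial upper tail at p = 1/2 by summing choose() terms.
binom_tail_oracle <- function(k, n) sum(choose(n, k:n)) / 2^n

# Direct per-gene ANCOVA via lm(), the generic linear-model oracle for the
# unmoderated APV test.
ancova_lm_oracle <- function(x, y, groups) {
  g <- factor(groups)
  full <- lm(y ~ x + g)
  null <- lm(y ~ x)
  a <- anova(null, full)
  list(p = a[["Pr(>F)"]][2L], fstat = a[["F"]][2L],
       slope = coef(full)[["x"]])
}
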