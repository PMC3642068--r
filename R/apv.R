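#' Configuration for an analysis of partial variance
#'
#' Holds the contrast orientation and the reliability/effect filters of the
#' per-gene ANCOVA. Defaults are the filter settings used for stringent
#' gene selection in translatome analysis: slope-test p threshold 0.05,
#' plausible slope band [-0.5, 1.5], and minimum absolute effects of 1 log2
#' unit on both the polysome-level and the cytosol-corrected scale.
#'
#' @param reference,contrast group labels; reported effects are contrast
#'   minus reference.
#' @param slope_p p-value threshold of the slope-reliability test.
#' @param min_slope,max_slope admissible band for the fitted common slope.
#' @param delta_p minimum |polysome-level effect| (log2).
#' @param delta_pt minimum |cytosol-corrected translational effect| (log2).
#' @param fdr_threshold BH FDR cutoff for calling a gene differentially
#'   translated.
#' @param use_rvm moderate residual variances with the random variance
#'   model.
#' @return object of class `apv_config`.
#' @export
apv_config <- function(reference, contrast,
                       slope_p = 0.05, min_slope = -0.5, max_slope = 1.5,
                       delta_p = 1, delta_pt = 1,
                       fdr_threshold = 0.15, use_rvm = TRUE) {
  if (min_slope >= max_slope)
    stop("min_slope must be < max_slope", call. = FALSE)
  if (slope_p < 0 || delta_p < 0 || delta_pt < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must be in (0, 1]", call. = FALSE)
  structure(list(reference = reference, contrast = contrast,
                 slope_p = slope_p, min_slope = min_slope,
                 max_slope = max_slope, delta_p = delta_p,
                 delta_pt = delta_pt, fdr_threshold = fdr_threshold,
                 use_rvm = isTRUE(use_rvm)),
            class = "apv_config")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1. Missing entries stay missing and
#' do not count toward the number of tests.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NA allowed).
#' @return vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Slope reliability test and filter
#'
#' The common cytosolic-to-polysome slope of a reliable ANCOVA fit is
#' expected inside the biologically plausible band [0, 1] (polysome levels
#' track cytosolic levels at most one-to-one). The test p-value is the
#' one-sided t tail for deviation outside that band: upper tail of
#' (b - 1)/se for b > 1, lower tail of b/se for b < 0, and 1 inside the
#' band. A gene is slope-filtered when the fitted slope leaves the
#' configured [min_slope, max_slope] window or the band test rejects at the
#' `slope_p` threshold. The test uses the unmoderated residual variance;
#' it is a model-validity screen, not an inferential claim.
#'
#' @param beta fitted common slope(s).
#' @param se standard error(s) of the slope (> 0).
#' @param m residual degrees of freedom.
#' @param config an [apv_config()].
#' @return list with `slope_p` and logical `slope_filtered` (inestimable
#'   slopes, `NA`, are filtered).
#' @export
slope_reliability <- function(beta, se, m, config) {
  p <- rep(1, length(beta))
  hi <- !is.na(beta) & beta > 1
  lo <- !is.na(beta) & beta < 0
  p[hi] <- stats::pt((beta[hi] - 1) / se[hi], df = m, lower.tail = FALSE)
  p[lo] <- stats::pt(beta[lo] / se[lo], df = m, lower.tail = TRUE)
  p[is.na(beta)] <- NA_real_
  filtered <- is.na(beta) | beta > config$max_slope |
    beta < config$min_slope | (!is.na(p) & p < config$slope_p)
  list(slope_p = p, slope_filtered = filtered)
}

# Vectorized ANCOVA engine shared by apv_fit_gene and apv_analysis.
# X, Y: genes x samples (complete cases); groups: character/factor length
# ncol. Returns the per-gene statistics before FDR and delta filtering.
apv_engine <- function(X, Y, groups, config, prior) {
  groups <- as.character(groups)
  levels <- unique(groups)
  K <- length(levels)
  N <- length(groups)
  gi <- match(groups, levels)
  counts <- tabulate(gi, K)
  if (any(counts < 2L))
    stop("design error: every group needs >=2 replicates (",
         paste(sprintf("%s: %d", levels, counts), collapse = ", "), ")",
         call. = FALSE)
  if (N < K + 2L)
    stop("design error: need at least ", K + 2L, " samples for ", K,
         " groups", call. = FALSE)
  for (lab in c(config$reference, config$contrast))
    if (!lab %in% levels)
      stop("group '", lab, "' absent from the data", call. = FALSE)

  Z <- matrix(0, N, K); Z[cbind(seq_len(N), gi)] <- 1
  Xbar <- (X %*% Z) / rep(counts, each = nrow(X))
  Ybar <- (Y %*% Z) / rep(counts, each = nrow(Y))
  Xc <- X - Xbar[, gi, drop = FALSE]
  Yc <- Y - Ybar[, gi, drop = FALSE]
  sxx <- rowSums(Xc^2)
  sxy <- rowSums(Xc * Yc)
  syy <- rowSums(Yc^2)

  est <- sxx > 1e-12            # slope estimable within groups
  beta <- ifelse(est, sxy / sxx, NA_real_)
  rss1 <- pmax(syy - ifelse(est, beta * sxy, 0), 0)

  Xc0 <- X - rowMeans(X)
  Yc0 <- Y - rowMeans(Y)
  sxx0 <- rowSums(Xc0^2)
  sxy0 <- rowSums(Xc0 * Yc0)
  syy0 <- rowSums(Yc0^2)
  rss0 <- pmax(syy0 - ifelse(sxx0 > 1e-12, sxy0^2 / sxx0, 0), 0)

  m <- N - K - 1L
  s2 <- rss1 / m
  slope_se <- ifelse(est, sqrt(s2 / sxx), NA_real_)

  ic <- match(config$contrast, levels)
  ir <- match(config$reference, levels)
  delta_p <- Ybar[, ic] - Ybar[, ir]
  delta_c <- Xbar[, ic] - Xbar[, ir]
  delta_pt <- delta_p - beta * delta_c

  if (config$use_rvm) {
    mod <- moderate_variance(s2, m, prior)
    denom <- mod$s2_mod
    df2 <- mod$df_mod
  } else {
    denom <- s2
    df2 <- rep(m, length(s2))
  }
  fstat <- ifelse(est & denom > 0, (rss0 - rss1) / (K - 1) / denom,
                  NA_real_)
  if (!config$use_rvm && any(est & denom == 0))
    warning(sum(est & denom == 0), " gene(s) with zero residual variance ",
            "and moderation disabled: p undefined (enable the random ",
            "variance model to resolve)", call. = FALSE)
  p <- ifelse(is.na(fstat), NA_real_,
              stats::pf(fstat, K - 1, df2, lower.tail = FALSE))

  sl <- slope_reliability(beta, slope_se, m, config)
  data.frame(
    gene_id = rownames(Y),
    slope = beta, slope_se = slope_se, slope_p = sl$slope_p,
    slope_filtered = sl$slope_filtered,
    delta_pt = delta_pt, delta_p = delta_p, delta_c = delta_c,
    rss = rss1, s2 = s2, df = m,
    s2_mod = denom, df_mod = df2,
    fstat = fstat, p = p,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene ANCOVA of polysome-associated on cytosolic levels
#'
#' Fits, for one gene, the analysis-of-partial-variance model
#' y = alpha_g + beta * x + e against the null y = alpha + beta * x, where x
#' is the cytosolic and y the polysome-associated log2 level and g indexes
#' sample groups. The group test is F = ((RSS0 - RSS1)/(K - 1)) / s2_mod
#' with the RVM-moderated variance in the denominator (or the raw residual
#' variance when `prior` is `NULL` or moderation is off). The translational
#' effect is the difference of cytosol-adjusted group means,
#' delta_pt = delta_p - beta * delta_c.
#'
#' @param x cytosolic log2 values (length N).
#' @param y polysome-associated log2 values (length N).
#' @param groups group label per sample.
#' @param prior an `rvm_prior`, or `NULL` for no moderation.
#' @param config an [apv_config()].
#' @return one-row data.frame of per-gene APV statistics (slope, slope test,
#'   effects, variances, F, p).
#' @export
apv_fit_gene <- function(x, y, groups, prior = NULL, config) {
  stopifnot(length(x) == length(y), length(y) == length(groups))
  cfg <- config
  if (is.null(prior)) cfg$use_rvm <- FALSE
  X <- matrix(x, nrow = 1, dimnames = list("gene", NULL))
  Y <- matrix(y, nrow = 1, dimnames = list("gene", NULL))
  apv_engine(X, Y, groups, cfg, prior)
}

#' Genome-wide differential translation by analysis of partial variance
#'
#' Runs the per-gene ANCOVA over all complete-case genes of a paired
#' dataset restricted to the configured contrast, fits the random variance
#' model prior on the per-gene residual variances (before any filtering),
#' moderates the group test, applies the slope-reliability and effect-size
#' filters, and controls FDR by Benjamini-Hochberg over the slope-passing
#' genes (filtered genes get missing FDR). A gene is `included` when it
#' passes both filters and its FDR is at or below the configured threshold.
#'
#' @param dataset a `paired_dataset` from [align_paired_dataset()] or
#'   [simulate_dataset()].
#' @param config an [apv_config()] naming reference and contrast groups.
#' @return object of class `apv_result`: list with `results` (per-gene
#'   data.frame), `prior` (fitted `rvm_prior` or `NULL`), `config`, and
#'   `counts` (genes at each pipeline stage).
#' @export
apv_analysis <- function(dataset, config) {
  stopifnot(inherits(dataset, "paired_dataset"),
            inherits(config, "apv_config"))
  ds <- subset_groups(dataset, c(config$reference, config$contrast))
  X <- ds$cytosolic
  Y <- ds$polysome
  groups <- ds$pairing$group

  complete <- stats::complete.cases(X) & stats::complete.cases(Y)
  n_missing <- sum(!complete)
  if (n_missing > 0L)
    message(n_missing, " gene(s) excluded as incomplete cases")
  X <- X[complete, , drop = FALSE]
  Y <- Y[complete, , drop = FALSE]
  if (nrow(Y) == 0L) stop("no complete-case genes", call. = FALSE)

  prior <- NULL
  if (config$use_rvm) {
    cfg0 <- config
    cfg0$use_rvm <- FALSE
    pre <- suppressWarnings(apv_engine(X, Y, groups, cfg0, NULL))
    prior <- fit_rvm_prior(pre$s2, pre$df)
  }
  res <- apv_engine(X, Y, groups, config, prior)

  res$fdr <- NA_real_
  testable <- !res$slope_filtered & !is.na(res$p)
  res$fdr[testable] <- bh_adjust(res$p[testable])
  res$delta_filtered <- (abs(res$delta_p) < config$delta_p) |
    (abs(res$delta_pt) < config$delta_pt)
  res$delta_filtered[is.na(res$delta_pt)] <- TRUE
  res$included <- testable & !res$delta_filtered &
    res$fdr <= config$fdr_threshold
  res$included[is.na(res$included)] <- FALSE

  out <- list(
    results = res, prior = prior, config = config,
    counts = c(n_input = nrow(dataset$cytosolic),
               n_missing_excluded = n_missing,
               n_complete = nrow(res),
               n_slope_filtered = sum(res$slope_filtered),
               n_delta_filtered = sum(res$delta_filtered),
               n_fdr_passed = sum(testable &
                                    res$fdr <= config$fdr_threshold,
                                  na.rm = TRUE),
               n_included = sum(res$included)))
  class(out) <- "apv_result"
  out
}

#' @export
print.apv_result <- function(x, ...) {
  cat(sprintf("APV differential translation: %s vs %s (reference)\n",
              x$config$contrast, x$config$reference))
  cat(sprintf("  %d genes analysed (%d incomplete excluded)\n",
              x$counts[["n_complete"]], x$counts[["n_missing_excluded"]]))
  cat(sprintf("  slope-filtered %d; effect-filtered %d; FDR<=%.2g: %d; included %d\n",
              x$counts[["n_slope_filtered"]], x$counts[["n_delta_filtered"]],
              x$config$fdr_threshold, x$counts[["n_fdr_passed"]],
              x$counts[["n_included"]]))
  if (!is.null(x$prior))
    cat(sprintf("  RVM prior a = %.3g, b = %.3g\n", x$prior$a, x$prior$b))
  invisible(x)
}

#' Differential expression of a single RNA fraction
#'
#' One-way group comparison per gene on a single matrix (polysome-associated
#' or cytosolic), with the same random-variance-model moderation as the APV
#' test: F = ((RSS0 - RSS1)/(K - 1)) / s2_mod on (K - 1, m + 2a) degrees of
#' freedom, m = N - K. The reported effect is the contrast-minus-reference
#' difference of group means (log2).
#'
#' @param mat expression matrix (genes x samples), log2.
#' @param groups group label per sample (column).
#' @param reference,contrast group labels for the reported effect.
#' @param use_rvm moderate variances with the RVM prior.
#' @param fdr_threshold BH FDR cutoff for the `significant` flag.
#' @return list of class `de_result` with `results` (gene_id, effect, s2,
#'   df, fstat, p, fdr, significant), `prior`, `counts`.
#' @export
de_analysis <- function(mat, groups, reference, contrast,
                        use_rvm = TRUE, fdr_threshold = 0.15) {
  validate_expression_matrix(mat)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat))
  levels <- unique(groups)
  K <- length(levels)
  N <- length(groups)
  gi <- match(groups, levels)
  counts <- tabulate(gi, K)
  if (K < 2L || any(counts < 2L))
    stop("design error: >=2 groups with >=2 replicates each required",
         call. = FALSE)
  for (lab in c(reference, contrast))
    if (!lab %in% levels)
      stop("group '", lab, "' absent from the data", call. = FALSE)

  complete <- stats::complete.cases(mat)
  n_missing <- sum(!complete)
  Y <- mat[complete, , drop = FALSE]

  Z <- matrix(0, N, K); Z[cbind(seq_len(N), gi)] <- 1
  Ybar <- (Y %*% Z) / rep(counts, each = nrow(Y))
  rss1 <- rowSums((Y - Ybar[, gi, drop = FALSE])^2)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  m <- N - K
  s2 <- rss1 / m

  prior <- NULL
  if (use_rvm) {
    prior <- fit_rvm_prior(s2, m)
    mod <- moderate_variance(s2, m, prior)
    denom <- mod$s2_mod; df2 <- mod$df_mod
  } else {
    denom <- s2; df2 <- rep(m, length(s2))
  }
  fstat <- ifelse(denom > 0, (rss0 - rss1) / (K - 1) / denom, NA_real_)
  p <- ifelse(is.na(fstat), NA_real_,
              stats::pf(fstat, K - 1, df2, lower.tail = FALSE))
  fdr <- bh_adjust(p)

  res <- data.frame(
    gene_id = rownames(Y),
    effect = Ybar[, match(contrast, levels)] -
      Ybar[, match(reference, levels)],
    s2 = s2, df = m, s2_mod = denom, df_mod = df2,
    fstat = fstat, p = p, fdr = fdr,
    significant = !is.na(fdr) & fdr <= fdr_threshold,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(results = res, prior = prior,
                 counts = c(n_input = nrow(mat),
                            n_missing_excluded = n_missing,
                            n_complete = nrow(res),
                            n_significant = sum(res$significant))),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential expression: %d genes, %d significant\n",
              x$counts[["n_complete"]], x$counts[["n_significant"]]))
  invisible(x)
}

#' Write an APV or DE result table to TSV
#' @param result an `apv_result` or `de_result`.
#' @param path output path.
#' @export
write_result_tsv <- function(result, path) {
  stopifnot(inherits(result, c("apv_result", "de_result")))
  utils::write.table(result$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
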