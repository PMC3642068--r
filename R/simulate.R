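#' Parameters of the paired-translatome simulation
#'
#' The generator emulates a polysome-profiling microarray study: for each
#' gene a baseline cytosolic log2 level, a per-gene residual variance drawn
#' from the inverse-gamma random-variance-model prior (1/sigma^2 ~
#' Gamma(shape a, mean a*b)), and a per-gene cytosolic-to-polysome slope.
#' Polysome-associated levels follow y = alpha + beta * x + spike + noise,
#' so spiked genes carry a pure translational effect (cytosol-corrected),
#' while "transcriptional" genes perturb the cytosolic level only and
#' propagate to polysomes through the slope. The default design is the
#' smallest informative contrast: 2 groups x 2 biological replicates x 2
#' fractions — the one-residual-df regime in which variance moderation is
#' essential.
#'
#' @param n_genes number of genes.
#' @param group_labels group labels; effects are spiked into
#'   `contrast_group`.
#' @param contrast_group label receiving the spiked effects (default: last
#'   label).
#' @param n_replicates biological replicates per group (per fraction).
#' @param baseline_mean,baseline_sd per-gene baseline cytosolic level
#'   (log2), drawn N(mean, sd).
#' @param cytosolic_sd typical between-replicate biological variation of
#'   cytosolic log2 levels (root-mean-square sd). Per-gene cytosolic
#'   variances are drawn from the same inverse-gamma family as the
#'   translational residual (shape `prior_a`, rescaled to mean
#'   `cytosolic_sd^2`), since expression variability is gene-specific.
#'   Cytosolic and polysome fractions derive from the same lysate, so a
#'   gene's cytosolic spread propagates to polysomes through the slope and
#'   the prior-governed residual sigma^2 is the (smaller) purely
#'   translational noise around the regression.
#' @param intercept_sd sd of the per-gene polysome intercept alpha.
#' @param prior_a,prior_b shape/scale of the variance prior.
#' @param slope_min,slope_max uniform slope support (the plausible band).
#' @param out_of_band_fraction fraction of genes given slopes outside the
#'   band (drawn uniformly from [-1.5, -0.6] or [1.6, 2.5]) to exercise the
#'   slope filter.
#' @param n_spiked_up,n_spiked_down counts of translationally
#'   activated/suppressed genes in the contrast group.
#' @param effect_size |translational effect| of spiked genes (log2, >= 0).
#' @param n_transcriptional genes with a cytosolic-only effect.
#' @param transcriptional_effect cytosolic effect magnitude (log2).
#' @param within_group_sd sd of per-(gene, group, fraction) offsets shared
#'   by replicates; > 0 makes replicates of a condition correlate more with
#'   each other than across conditions (QC structure knob).
#' @param seed mandatory integer seed.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_genes = 5000,
                              group_labels = c("reference", "contrast"),
                              contrast_group =
                                group_labels[length(group_labels)],
                              n_replicates = 2,
                              baseline_mean = 7, baseline_sd = 1.5,
                              cytosolic_sd = 0.8,
                              intercept_sd = 1,
                              prior_a = 3, prior_b = 2,
                              slope_min = 0, slope_max = 1,
                              out_of_band_fraction = 0,
                              n_spiked_up = 350, n_spiked_down = 350,
                              effect_size = 2,
                              n_transcriptional = 250,
                              transcriptional_effect = 2,
                              within_group_sd = 0,
                              seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  p <- list(n_genes = as.integer(n_genes), group_labels = group_labels,
            contrast_group = contrast_group,
            n_replicates = as.integer(n_replicates),
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            cytosolic_sd = cytosolic_sd, intercept_sd = intercept_sd,
            prior_a = prior_a, prior_b = prior_b,
            slope_min = slope_min, slope_max = slope_max,
            out_of_band_fraction = out_of_band_fraction,
            n_spiked_up = as.integer(n_spiked_up),
            n_spiked_down = as.integer(n_spiked_down),
            effect_size = effect_size,
            n_transcriptional = as.integer(n_transcriptional),
            transcriptional_effect = transcriptional_effect,
            within_group_sd = within_group_sd,
            seed = as.integer(seed))
  if (p$effect_size < 0 || p$transcriptional_effect < 0)
    stop("effect magnitudes must be >= 0", call. = FALSE)
  if (any(c(p$n_spiked_up, p$n_spiked_down, p$n_transcriptional) < 0))
    stop("spike counts must be >= 0", call. = FALSE)
  if (p$n_spiked_up + p$n_spiked_down + p$n_transcriptional > p$n_genes)
    stop("spiked + transcriptional gene counts exceed n_genes",
         call. = FALSE)
  if (!p$contrast_group %in% p$group_labels)
    stop("contrast_group must be one of group_labels", call. = FALSE)
  if (p$prior_a <= 0 || p$prior_b <= 0)
    stop("prior parameters must be > 0", call. = FALSE)
  class(p) <- "simulation_params"
  p
}

#' Simulate a paired translatome dataset with known ground truth
#'
#' Bitwise reproducible for a given seed. See [simulation_params()] for the
#' generative model.
#'
#' @param params a `simulation_params` object.
#' @return list with `dataset` (a `paired_dataset`) and `truth` (class
#'   `synthetic_truth`: named effect vectors `spiked_up`, `spiked_down`,
#'   `transcriptional`, the full `gene_ids`, the true `slopes` and
#'   `sigma2`, and a `params` echo).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)

  G <- p$n_genes
  genes <- sprintf("g%05d", seq_len(G))
  groups <- rep(p$group_labels, each = p$n_replicates)
  reps <- rep(seq_len(p$n_replicates), times = length(p$group_labels))
  N <- length(groups)

  mu <- stats::rnorm(G, p$baseline_mean, p$baseline_sd)
  alpha <- stats::rnorm(G, 0, p$intercept_sd)
  sigma2 <- rvm_rvariances(G, p$prior_a, p$prior_b)
  sigma <- sqrt(sigma2)

  beta <- stats::runif(G, p$slope_min, p$slope_max)
  n_out <- round(p$out_of_band_fraction * G)
  if (n_out > 0L) {
    idx <- sample.int(G, n_out)
    lo <- stats::runif(n_out) < 0.5
    beta[idx] <- ifelse(lo, stats::runif(n_out, -1.5, -0.6),
                        stats::runif(n_out, 1.6, 2.5))
  }

  pick <- sample.int(G, p$n_spiked_up + p$n_spiked_down + p$n_transcriptional)
  i_up <- pick[seq_len(p$n_spiked_up)]
  i_dn <- pick[p$n_spiked_up + seq_len(p$n_spiked_down)]
  i_tr <- pick[p$n_spiked_up + p$n_spiked_down +
                 seq_len(p$n_transcriptional)]
  spike <- numeric(G)
  spike[i_up] <- p$effect_size
  spike[i_dn] <- -p$effect_size
  trans <- numeric(G)
  trans[i_tr] <- p$transcriptional_effect *
    sample(c(-1, 1), p$n_transcriptional, replace = TRUE)

  b_cyto <- 1 / (p$cytosolic_sd^2 * (p$prior_a - 1))
  sigma_cyto <- sqrt(rvm_rvariances(G, p$prior_a, b_cyto))

  in_contrast <- as.numeric(groups == p$contrast_group)
  X <- mu + outer(trans, in_contrast) +
    matrix(stats::rnorm(G * N, 0, sigma_cyto), G, N)
  Y <- alpha + beta * X + outer(spike, in_contrast) +
    matrix(stats::rnorm(G * N, 0, sigma), G, N)
  if (p$within_group_sd > 0) {
    for (g in p$group_labels) {
      cols <- groups == g
      X[, cols] <- X[, cols] + stats::rnorm(G, 0, p$within_group_sd)
      Y[, cols] <- Y[, cols] + stats::rnorm(G, 0, p$within_group_sd)
    }
  }

  csam <- sprintf("%s_cyto_r%d", groups, reps)
  psam <- sprintf("%s_poly_r%d", groups, reps)
  dimnames(X) <- list(genes, csam)
  dimnames(Y) <- list(genes, psam)
  ann <- data.frame(sample_id = c(csam, psam),
                    group = c(groups, groups),
                    fraction = rep(c("cytosolic", "polysome"), each = N),
                    replicate = c(reps, reps),
                    stringsAsFactors = FALSE)
  dataset <- align_paired_dataset(X, Y, ann)

  truth <- structure(list(
    spiked_up = stats::setNames(rep(p$effect_size, p$n_spiked_up),
                                genes[i_up]),
    spiked_down = stats::setNames(rep(-p$effect_size, p$n_spiked_down),
                                  genes[i_dn]),
    transcriptional = stats::setNames(trans[i_tr], genes[i_tr]),
    gene_ids = genes, slopes = stats::setNames(beta, genes),
    sigma2 = stats::setNames(sigma2, genes),
    params = p), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: %d genes; %d spiked up, %d down (|effect| %g log2); %d transcriptional\n",
    length(x$gene_ids), length(x$spiked_up), length(x$spiked_down),
    x$params$effect_size, length(x$transcriptional)))
  invisible(x)
}

#' Simulate a linked secondary fold-change table
#'
#' Stand-in for an external dataset probing the same biological axis (e.g. a
#' second translatome study with perturbed cap-dependent initiation):
#' spiked genes receive secondary log2 effects whose sign agrees with their
#' primary effect with probability `concordance_rate`; all other genes get
#' null-centred noise.
#'
#' @param truth a `synthetic_truth`.
#' @param concordance_rate probability of sign agreement for spiked genes.
#' @param effect_scale typical |secondary effect| of spiked genes (log2);
#'   magnitudes are drawn uniformly in [0.5, 1.5] x effect_scale.
#' @param noise_sd sd of the null effects of unspiked genes.
#' @param seed integer seed.
#' @return named numeric vector of log2 effects over all genes of `truth`.
#' @export
simulate_secondary_effects <- function(truth, concordance_rate = 0.85,
                                       effect_scale = 1, noise_sd = 0.25,
                                       seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (concordance_rate < 0 || concordance_rate > 1)
    stop("concordance_rate must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  eff <- stats::setNames(stats::rnorm(length(truth$gene_ids), 0, noise_sd),
                         truth$gene_ids)
  spiked <- c(truth$spiked_up, truth$spiked_down)
  if (length(spiked) > 0L) {
    agree <- stats::runif(length(spiked)) < concordance_rate
    s <- sign(spiked) * ifelse(agree, 1, -1)
    mag <- effect_scale * stats::runif(length(spiked), 0.5, 1.5)
    eff[names(spiked)] <- s * mag
  }
  eff
}

#' Simulate a gene-set collection linked to the spiked genes
#'
#' Builds a small synthetic functional annotation: `n_linked` terms sample
#' a `linked_fraction` of their members from the spiked genes of a single
#' regulation direction (functional modules are typically
#' direction-coherent, like a translationally suppressed cell-cycle
#' module), alternating directions across terms; `n_background` terms
#' sample uniformly from all genes.
#'
#' @param truth a `synthetic_truth`.
#' @param n_linked,n_background term counts.
#' @param term_size members per term.
#' @param linked_fraction fraction of a linked term's members drawn from
#'   the spiked genes.
#' @param seed integer seed.
#' @return a `gene_set_collection` with universe = all simulated genes.
#' @export
simulate_gene_sets <- function(truth, n_linked = 5, n_background = 40,
                               term_size = 40, linked_fraction = 0.5,
                               seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  all_genes <- truth$gene_ids
  terms <- list()
  for (i in seq_len(n_linked)) {
    pool <- if (i %% 2 == 1) names(truth$spiked_up)
            else names(truth$spiked_down)
    if (length(pool) == 0L) pool <- names(c(truth$spiked_up,
                                            truth$spiked_down))
    n_sp <- min(round(linked_fraction * term_size), length(pool))
    members <- unique(c(sample(pool, n_sp),
                        sample(all_genes, term_size - n_sp)))
    terms[[sprintf("LINKED:%02d", i)]] <-
      list(name = sprintf("spike-linked module %d (%s)", i,
                          if (i %% 2 == 1) "up" else "down"),
           genes = members)
  }
  for (i in seq_len(n_background)) {
    terms[[sprintf("BG:%02d", i)]] <-
      list(name = sprintf("background set %d", i),
           genes = sample(all_genes, term_size))
  }
  gene_set_collection(terms, universe = all_genes)
}
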