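#' Default pipeline configuration
#'
#' Nested-list configuration for [run_pipeline()], with the stringent
#' defaults used throughout: slope filters slope_p 0.05, band [-0.5, 1.5],
#' effect minima delta_p = delta_pt = 1 log2, FDR 15% (use 30% for low-power
#' ex vivo style contrasts), signature fold 3, secondary concordance fold
#' 1.3, enrichment filters >2-fold / >=10 genes / FDR<1%.
#'
#' @param simulate `NULL`, or a list of [simulation_params()] arguments
#'   (seed may be omitted and supplied via `run_pipeline(seed = )`).
#' @param inputs `NULL`, or list with paths `cytosolic`, `polysome`,
#'   `annotation` (ignored when `simulate` is given).
#' @param contrasts list of lists with `name`, `reference`, `contrast` and
#'   optional `fdr_threshold`.
#' @param apv overrides for [apv_config()] fields.
#' @param qc list with `method` ("pearson"/"spearman") and `linkage`.
#' @param signatures list with `fold_threshold`, `direction_mode`,
#'   `secondary_fold`, optional `external` / `secondary` paths to effect
#'   TSVs (under simulation, a linked secondary table is generated instead).
#' @param enrichment list with `gmt` path (or `NULL` to simulate linked
#'   gene sets under simulation), `min_fold`, `min_genes`, `max_fdr`.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            contrasts = list(list(name = "contrast",
                                                  reference = "reference",
                                                  contrast = "contrast")),
                            apv = list(), qc = list(),
                            signatures = list(), enrichment = list()) {
  defaults <- list(
    apv = list(slope_p = 0.05, min_slope = -0.5, max_slope = 1.5,
               delta_p = 1, delta_pt = 1, fdr_threshold = 0.15,
               use_rvm = TRUE),
    qc = list(method = "pearson", linkage = "average"),
    signatures = list(fold_threshold = 3,
                      direction_mode = "same_direction",
                      secondary_fold = 1.3,
                      concordance_rate = 0.85, effect_scale = 1,
                      noise_sd = 0.25),
    enrichment = list(gmt = NULL, min_fold = 2, min_genes = 10,
                      max_fdr = 0.01))
  cfg <- list(simulate = simulate, inputs = inputs, contrasts = contrasts,
              apv = utils::modifyList(defaults$apv, apv),
              qc = utils::modifyList(defaults$qc, qc),
              signatures = utils::modifyList(defaults$signatures,
                                             signatures),
              enrichment = utils::modifyList(defaults$enrichment,
                                             enrichment))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with blocks simulate / inputs / contrasts / apv /
#'   qc / signatures / enrichment.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

run_stage <- function(out_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(c("INCOMPLETE", paste0("stage=", stage),
                 paste0("error=", conditionMessage(e))),
               file.path(out_dir, "MANIFEST"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full differential-translation pipeline
#'
#' Executes, in order: data load or simulation, correlation-clustering QC,
#' APV differential translation per contrast, single-fraction differential
#' expression (polysome-associated and cytosolic), fold-threshold signatures
#' with overlap and sign-concordance analysis against a secondary effect
#' table, and filtered gene-set enrichment. All result tables are written as
#' TSV under `out_dir`, a prior/fit sidecar and a run summary as JSON. The
#' run is deterministic given the configuration and seed; a failing stage
#' aborts with the stage name and leaves a MANIFEST marking incompleteness.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed used for the simulation blocks when the config
#'   itself does not fix one.
#' @return (invisibly) the summary list, also written to
#'   `out_dir/summary.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config = unclass(config), counts = list())

  ## ---- load / simulate -------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    dataset <- run_stage(out_dir, "simulate", {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      sim <- simulate_dataset(do.call(simulation_params, sim_args))
      truth <- sim$truth
      pipeline_log("simulate", length(sim$truth$gene_ids), " genes, ",
                   nrow(sim$dataset$pairing), " sample pairs")
      write_expression_tsv(sim$dataset$cytosolic,
                           file.path(out_dir, "cytosolic.tsv"))
      write_expression_tsv(sim$dataset$polysome,
                           file.path(out_dir, "polysome.tsv"))
      write_annotation_tsv(sim$dataset$annotation,
                           file.path(out_dir, "annotation.tsv"))
      truth_df <- data.frame(
        gene_id = c(names(sim$truth$spiked_up),
                    names(sim$truth$spiked_down),
                    names(sim$truth$transcriptional)),
        class = rep(c("spiked_up", "spiked_down", "transcriptional"),
                    c(length(sim$truth$spiked_up),
                      length(sim$truth$spiked_down),
                      length(sim$truth$transcriptional))),
        effect = c(sim$truth$spiked_up, sim$truth$spiked_down,
                   sim$truth$transcriptional),
        stringsAsFactors = FALSE)
      utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sim$dataset
    })
  } else {
    dataset <- run_stage(out_dir, "load", {
      inp <- config$inputs
      if (is.null(inp))
        stop("config needs either a simulate or an inputs block")
      align_paired_dataset(read_expression_tsv(inp$cytosolic),
                           read_expression_tsv(inp$polysome),
                           read_annotation_tsv(inp$annotation))
    })
  }
  summary$counts$n_genes <- nrow(dataset$cytosolic)
  summary$counts$n_sample_pairs <- nrow(dataset$pairing)

  ## ---- QC --------------------------------------------------------------
  run_stage(out_dir, "qc", {
    joint <- cbind(dataset$cytosolic, dataset$polysome)
    cc <- correlation_matrix(joint, method = config$qc$method)
    utils::write.table(
      data.frame(sample_id = rownames(cc), cc, check.names = FALSE),
      file.path(out_dir, "qc_correlations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    hc <- hierarchical_cluster(cc, linkage = config$qc$linkage)
    dendrogram_newick(hc, file.path(out_dir, "qc_dendrogram.nwk"))
    pipeline_log("qc", "correlation matrix over ", ncol(joint),
                 " samples (", config$qc$method, ", ",
                 config$qc$linkage, " linkage)")
  })

  ## ---- APV + DE per contrast -------------------------------------------
  apv_fits <- list()
  for (ct in config$contrasts) {
    nm <- ct$name
    fit <- run_stage(out_dir, paste0("apv:", nm), {
      cfg <- apv_config(
        reference = ct$reference, contrast = ct$contrast,
        slope_p = config$apv$slope_p, min_slope = config$apv$min_slope,
        max_slope = config$apv$max_slope, delta_p = config$apv$delta_p,
        delta_pt = config$apv$delta_pt,
        fdr_threshold = if (!is.null(ct$fdr_threshold)) ct$fdr_threshold
        else config$apv$fdr_threshold,
        use_rvm = config$apv$use_rvm)
      fit <- apv_analysis(dataset, cfg)
      write_result_tsv(fit, file.path(out_dir,
                                      paste0("apv_", nm, ".tsv")))
      sidecar <- list(config = unclass(cfg), counts = as.list(fit$counts))
      if (!is.null(fit$prior)) sidecar$prior <- unclass(fit$prior)
      jsonlite::write_json(sidecar,
                           file.path(out_dir, paste0("apv_", nm, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      pipeline_log(paste0("apv:", nm), fit$counts[["n_included"]],
                   " differentially translated genes of ",
                   fit$counts[["n_complete"]])
      fit
    })
    apv_fits[[nm]] <- fit
    summary$counts[[paste0("apv_", nm)]] <- as.list(fit$counts)

    run_stage(out_dir, paste0("de:", nm), {
      for (fr in c("polysome", "cytosolic")) {
        ds <- subset_groups(dataset, c(ct$reference, ct$contrast))
        mat <- ds[[fr]]
        de <- de_analysis(mat, ds$pairing$group,
                          reference = ct$reference, contrast = ct$contrast,
                          use_rvm = config$apv$use_rvm,
                          fdr_threshold = fit$config$fdr_threshold)
        write_result_tsv(de, file.path(out_dir,
                                       paste0("de_", fr, "_", nm, ".tsv")))
        summary$counts[[paste0("de_", fr, "_", nm)]] <- as.list(de$counts)
        pipeline_log(paste0("de:", nm), fr, ": ",
                     de$counts[["n_significant"]], " significant genes")
      }
    })
  }

  ## ---- signatures / overlap / concordance ------------------------------
  sc <- config$signatures
  for (nm in names(apv_fits)) {
    fit <- apv_fits[[nm]]
    run_stage(out_dir, paste0("signatures:", nm), {
      eff <- stats::setNames(fit$results$delta_pt, fit$results$gene_id)
      sig <- build_signature(eff, fit$results$included,
                             fold_threshold = sc$fold_threshold,
                             label = nm)
      writeLines(names(sig$up),
                 file.path(out_dir, paste0("signature_", nm, "_up.txt")))
      writeLines(names(sig$down),
                 file.path(out_dir, paste0("signature_", nm, "_down.txt")))
      summary$counts[[paste0("signature_", nm)]] <-
        list(up = length(sig$up), down = length(sig$down))
      pipeline_log(paste0("signatures:", nm), length(sig$up), " up / ",
                   length(sig$down), " down at >=", sc$fold_threshold,
                   "-fold")

      secondary <- NULL
      if (!is.null(sc[["secondary"]])) {
        secondary <- read_effects_tsv(sc[["secondary"]])
      } else if (!is.null(truth)) {
        secondary <- simulate_secondary_effects(
          truth, concordance_rate = sc$concordance_rate,
          effect_scale = sc$effect_scale, noise_sd = sc$noise_sd,
          seed = seed + 1L)
        write_effects_tsv(secondary,
                          file.path(out_dir, "secondary_effects.tsv"))
      }
      if (!is.null(secondary)) {
        ov <- overlap_percent(sig, secondary,
                              fold_threshold = sc$fold_threshold,
                              direction_mode = sc$direction_mode)
        utils::write.table(ov, file.path(out_dir,
                                         paste0("overlap_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        cm <- concordance_module(eff, fit$results$included, secondary,
                                 secondary_fold = sc$secondary_fold)
        jsonlite::write_json(
          list(quadrants = as.list(cm$quadrants),
               n_concordant = cm$n_concordant,
               n_discordant = cm$n_discordant,
               binomial_p = cm$binomial_p,
               secondary_fold = cm$secondary_fold),
          file.path(out_dir, paste0("concordance_", nm, ".json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        writeLines(cm$concordant_genes,
                   file.path(out_dir,
                             paste0("concordance_", nm,
                                    "_concordant.txt")))
        summary$counts[[paste0("concordance_", nm)]] <-
          list(concordant = cm$n_concordant, discordant = cm$n_discordant,
               binomial_p = cm$binomial_p)
        pipeline_log(paste0("concordance:", nm), cm$n_concordant,
                     " concordant / ", cm$n_discordant,
                     " discordant, binomial p = ",
                     signif(cm$binomial_p, 3))
      }
      invisible(NULL)
    })
  }

  ## ---- enrichment ------------------------------------------------------
  ec <- config$enrichment
  collection <- NULL
  if (!is.null(ec$gmt)) {
    collection <- run_stage(out_dir, "enrichment", read_gmt(ec$gmt))
  } else if (!is.null(truth)) {
    collection <- simulate_gene_sets(truth, seed = seed + 2L)
    write_gmt(collection, file.path(out_dir, "gene_sets.gmt"))
  }
  if (!is.null(collection)) {
    run_stage(out_dir, "enrichment", {
      universe <- rownames(dataset$cytosolic)
      sets <- list()
      for (nm in names(apv_fits)) {
        res <- apv_fits[[nm]]$results
        sets[[paste0(nm, "_up")]] <-
          res$gene_id[res$included & res$delta_pt > 0]
        sets[[paste0(nm, "_down")]] <-
          res$gene_id[res$included & res$delta_pt < 0]
      }
      for (lab in names(sets)) {
        tab <- suppressWarnings(
          enrich(sets[[lab]], collection, universe = universe,
                 min_fold = ec$min_fold, min_genes = ec$min_genes,
                 max_fdr = ec$max_fdr))
        utils::write.table(tab,
                           file.path(out_dir,
                                     paste0("enrichment_", lab, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$counts[[paste0("enrichment_", lab)]] <-
          list(tested = nrow(tab), passing = sum(tab$passes_filters))
      }
      hm <- suppressWarnings(
        enrichment_compare(sets, collection, universe = universe))
      utils::write.table(
        data.frame(term_id = rownames(hm), hm, check.names = FALSE),
        file.path(out_dir, "enrichment_matrix.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      pipeline_log("enrichment", length(sets), " gene lists against ",
                   length(collection$terms), " terms")
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines("COMPLETE", file.path(out_dir, "MANIFEST"))
  invisible(summary)
}
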