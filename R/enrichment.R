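#' Hypergeometric gene-set over-representation
#'
#' Exact one-sided over-representation of a selected gene list in each term
#' of a collection. With universe size M, term size K (within the universe),
#' selection size n (within the universe) and overlap k, the p-value is the
#' hypergeometric upper tail P(X >= k) and the fold enrichment is
#' (k/n)/(K/M). BH FDR is computed across all tested terms. A term passes
#' the stringent reporting filters when fold enrichment > 2, the overlap
#' holds at least 10 genes, and FDR < 1% (all configurable).
#'
#' @param selected character vector of selected genes; genes outside the
#'   universe are dropped with a message.
#' @param collection a `gene_set_collection`.
#' @param universe optional universe overriding the collection's (e.g. the
#'   genes present on the analysed expression matrix); intersected with the
#'   collection's universe.
#' @param min_fold,min_genes,max_fdr the reporting filters.
#' @return data.frame with one row per term: term_id, term_name, M, K, n,
#'   k, fold_enrichment, p, fdr, passes_filters.
#' @export
enrich <- function(selected, collection, universe = NULL,
                   min_fold = 2, min_genes = 10, max_fdr = 0.01) {
  stopifnot(inherits(collection, "gene_set_collection"))
  uni <- collection$universe
  if (!is.null(universe)) uni <- intersect(uni, universe)
  selected <- unique(as.character(selected))
  dropped <- setdiff(selected, uni)
  if (length(dropped) > 0L)
    message(length(dropped), " selected gene(s) outside the universe dropped")
  sel <- intersect(selected, uni)
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      M = integer(0), K = integer(0), n = integer(0),
                      k = integer(0), fold_enrichment = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      passes_filters = logical(0),
                      stringsAsFactors = FALSE)
  if (length(collection$terms) == 0L) return(empty)
  if (length(sel) == 0L) {
    warning("empty selected set after universe intersection", call. = FALSE)
    return(empty)
  }
  M <- length(uni)
  n <- length(sel)
  rows <- lapply(names(collection$terms), function(id) {
    members <- intersect(collection$terms[[id]]$genes, uni)
    K <- length(members)
    k <- length(intersect(members, sel))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = collection$terms[[id]]$name,
               M = M, K = K, n = n, k = k,
               fold_enrichment = if (K == 0L) NA_real_ else
                 (k / n) / (K / M),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$passes_filters <- !is.na(out$fold_enrichment) &
    out$fold_enrichment > min_fold & out$k >= min_genes &
    out$fdr < max_fdr
  out[order(out$p), , drop = FALSE]
}

#' Enrichment heat matrix across labelled gene lists
#'
#' Runs [enrich()] on each labelled gene set and assembles a terms x labels
#' matrix of -log10 adjusted p-values, with very small p-values floored at
#' `floor_p` (default 1e-7, i.e. entries capped at 7) so extreme terms do
#' not dominate a colour scale.
#'
#' @param selected_sets named list of character vectors (label -> genes).
#' @param collection a `gene_set_collection`.
#' @param universe optional universe as in [enrich()].
#' @param floor_p adjusted p-values below this are set to it before the
#'   -log10 transform.
#' @return numeric matrix, rownames term ids, colnames labels.
#' @export
enrichment_compare <- function(selected_sets, collection, universe = NULL,
                               floor_p = 1e-7) {
  stopifnot(is.list(selected_sets), length(selected_sets) >= 1L,
            !is.null(names(selected_sets)))
  per <- lapply(selected_sets, function(genes)
    enrich(genes, collection, universe = universe))
  terms <- names(collection$terms)
  out <- matrix(0, nrow = length(terms), ncol = length(selected_sets),
                dimnames = list(terms, names(selected_sets)))
  for (lab in names(selected_sets)) {
    tab <- per[[lab]]
    if (nrow(tab) == 0L) next
    fdr <- pmax(tab$fdr, floor_p)
    out[tab$term_id, lab] <- -log10(fdr)
  }
  out
}
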