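#' Sample-by-sample correlation matrix
#'
#' Reproducibility QC: correlations between all pairs of samples of an
#' expression matrix, on all genes. Samples with zero variance (constant
#' vectors) yield undefined correlations, reported as `NA` with a warning.
#'
#' @param mat numeric expression matrix (genes x samples).
#' @param method "pearson" or "spearman".
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
correlation_matrix <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  validate_expression_matrix(mat)
  if (ncol(mat) < 2L)
    stop("need >=2 samples for a correlation matrix", call. = FALSE)
  sds <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning("constant sample(s) give undefined correlations: ",
            paste(colnames(mat)[!is.na(sds) & sds == 0], collapse = ", "),
            call. = FALSE)
  cc <- suppressWarnings(
    stats::cor(mat, method = method, use = "pairwise.complete.obs"))
  diag(cc) <- 1
  cc
}

#' Hierarchical clustering of samples from a correlation matrix
#'
#' Agglomerative clustering with distance 1 - r, so sign-discordant samples
#' are maximally distant. Average linkage by default (recorded in the
#' result); overridable.
#'
#' @param corr square correlation matrix with dimnames.
#' @param linkage linkage criterion passed to [stats::hclust()].
#' @return an `hclust` tree over the samples, with the linkage stored in
#'   `$method`.
#' @export
hierarchical_cluster <- function(corr, linkage = "average") {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("corr must be a square correlation matrix", call. = FALSE)
  if (anyNA(corr))
    stop("correlation matrix contains missing values; remove degenerate ",
         "(constant) samples before clustering", call. = FALSE)
  d <- stats::as.dist(1 - corr)
  stats::hclust(d, method = linkage)
}

#' Serialize a sample dendrogram to Newick
#'
#' @param hc an `hclust` tree (e.g. from [hierarchical_cluster()]).
#' @param path optional output path; if `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path))
    return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Indices of sibling leaf pairs in an hclust tree
#'
#' Helper for QC assertions: returns the pairs of observations that are
#' joined directly with each other (both children of a merge are leaves).
#'
#' @param hc an `hclust` object.
#' @return two-column matrix of observation indices.
#' @export
sibling_pairs <- function(hc) {
  m <- hc$merge
  leaf <- m[, 1L] < 0L & m[, 2L] < 0L
  cbind(-m[leaf, 1L], -m[leaf, 2L])
}
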