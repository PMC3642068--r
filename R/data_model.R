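#' Validate a log2 expression matrix
#'
#' Expression matrices are plain numeric matrices with unique gene
#' identifiers as row names and unique sample identifiers as column names,
#' holding log2-scale intensities. Missing values are allowed (`NA`) and are
#' handled per analysis by complete-case exclusion.
#'
#' @param mat numeric matrix, genes x samples, with dimnames.
#' @param what label used in error messages.
#' @return the matrix, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop(what, " must be a numeric matrix", call. = FALSE)
  gid <- rownames(mat)
  sid <- colnames(mat)
  if (is.null(gid) || is.null(sid))
    stop(what, " must have gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(gid))
    stop(what, ": duplicate gene identifier(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop(what, ": duplicate sample identifier(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (any(is.infinite(mat)))
    stop(what, " contains non-finite values that are not NA", call. = FALSE)
  invisible(mat)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers, tab separation, '.' decimal, no quoting. Empty cells and
#' "NA" become missing values.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path))
    stop("expression file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("expression TSV needs a gene column plus >=1 sample column: ",
         path, call. = FALSE)
  gid <- tab[[1L]]
  if (anyDuplicated(gid))
    stop("duplicate gene identifier(s) in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("", "NA")),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell in ", path, " at gene '", gid[bad[1L, 1L]],
         "', sample '", colnames(vals)[bad[1L, 2L]], "': '",
         vals[bad[1L, , drop = FALSE]], "'", call. = FALSE)
  dimnames(num) <- list(gid, colnames(tab)[-1L])
  validate_expression_matrix(num, paste0("matrix from ", path))
  num
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]; full precision (up to 17 significant
#' digits) so that a write/read round-trip is the identity.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  validate_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with columns `sample_id`, `group`, `fraction` (one of "cytosolic",
#' "polysome") and `replicate` (positive integer). Each sample appears once
#' and (group, fraction, replicate) triples are unique.
#'
#' @param path path to the annotation TSV.
#' @return data.frame with the four columns, validated.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  ann <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' @rdname read_annotation_tsv
#' @param ann data.frame to validate in place of reading a file.
#' @export
validate_annotation <- function(ann) {
  need <- c("sample_id", "group", "fraction", "replicate")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L)
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ann <- ann[, need]
  ann$replicate <- as.integer(ann$replicate)
  if (anyDuplicated(ann$sample_id))
    stop("annotation: duplicate sample_id(s): ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
               collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$fraction), c("cytosolic", "polysome"))
  if (length(bad) > 0L)
    stop("annotation: fraction must be 'cytosolic' or 'polysome', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(is.na(ann$replicate)) || any(ann$replicate < 1L))
    stop("annotation: replicate must be a positive integer", call. = FALSE)
  key <- paste(ann$group, ann$fraction, ann$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("annotation: duplicate (group, fraction, replicate) triple(s)",
         call. = FALSE)
  ann
}

#' Write a sample annotation table to TSV
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_annotation_tsv <- function(ann, path) {
  ann <- validate_annotation(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair cytosolic and polysome matrices into one dataset
#'
#' Restricts both matrices to their common genes (in identical order),
#' splits the annotation by fraction and builds the bijective pairing of
#' cytosolic to polysome samples that share a (group, replicate) key. This
#' paired container is the input to the analysis of partial variance, which
#' regresses polysome-associated levels on cytosolic levels per gene.
#'
#' @param cyto,poly numeric expression matrices (genes x samples).
#' @param ann sample annotation covering the samples of both matrices.
#' @return object of class `paired_dataset`: list with elements `cytosolic`,
#'   `polysome` (gene-aligned matrices, columns ordered by the pairing),
#'   `annotation`, and `pairing` (data.frame group / replicate /
#'   cytosolic_sample / polysome_sample).
#' @export
align_paired_dataset <- function(cyto, poly, ann) {
  validate_expression_matrix(cyto, "cytosolic matrix")
  validate_expression_matrix(poly, "polysome matrix")
  ann <- validate_annotation(ann)

  genes <- intersect(rownames(cyto), rownames(poly))
  if (length(genes) == 0L)
    stop("cytosolic and polysome matrices share no genes", call. = FALSE)

  all_samples <- c(colnames(cyto), colnames(poly))
  missing_ann <- setdiff(all_samples, ann$sample_id)
  if (length(missing_ann) > 0L)
    stop("annotation lacks sample(s): ",
         paste(missing_ann, collapse = ", "), call. = FALSE)

  ca <- ann[match(colnames(cyto), ann$sample_id), ]
  pa <- ann[match(colnames(poly), ann$sample_id), ]
  if (any(ca$fraction != "cytosolic"))
    stop("cytosolic matrix contains sample(s) not annotated as cytosolic",
         call. = FALSE)
  if (any(pa$fraction != "polysome"))
    stop("polysome matrix contains sample(s) not annotated as polysome",
         call. = FALSE)

  ckey <- paste(ca$group, ca$replicate, sep = "\r")
  pkey <- paste(pa$group, pa$replicate, sep = "\r")
  unmatched <- c(setdiff(ckey, pkey), setdiff(pkey, ckey))
  if (length(unmatched) > 0L) {
    show <- unique(gsub("\r", ", replicate ", unmatched))
    stop("unpaired (group, replicate) combination(s): (",
         paste(show, collapse = "); ("), ")", call. = FALSE)
  }

  ord <- order(ca$group, ca$replicate)
  pairing <- data.frame(
    group = ca$group[ord],
    replicate = ca$replicate[ord],
    cytosolic_sample = ca$sample_id[ord],
    polysome_sample = pa$sample_id[match(ckey[ord], pkey)],
    stringsAsFactors = FALSE)

  out <- list(
    cytosolic = cyto[genes, pairing$cytosolic_sample, drop = FALSE],
    polysome = poly[genes, pairing$polysome_sample, drop = FALSE],
    annotation = ann[ann$sample_id %in%
                       c(pairing$cytosolic_sample, pairing$polysome_sample), ],
    pairing = pairing)
  class(out) <- "paired_dataset"
  out
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("Paired translatome dataset\n")
  cat("  genes:  ", nrow(x$cytosolic), "\n")
  cat("  pairs:  ", nrow(x$pairing), " (cytosolic + polysome)\n")
  tab <- table(x$pairing$group)
  cat("  groups: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a paired dataset to a subset of groups
#' @param dataset a `paired_dataset`.
#' @param groups character vector of group labels to keep.
#' @return a `paired_dataset` containing only those groups.
#' @export
subset_groups <- function(dataset, groups) {
  stopifnot(inherits(dataset, "paired_dataset"))
  absent <- setdiff(groups, dataset$pairing$group)
  if (length(absent) > 0L)
    stop("group(s) absent from the dataset: ",
         paste(absent, collapse = ", "), call. = FALSE)
  keep <- dataset$pairing$group %in% groups
  if (!any(keep))
    stop("no samples in group(s): ", paste(groups, collapse = ", "),
         call. = FALSE)
  pr <- dataset$pairing[keep, , drop = FALSE]
  out <- list(
    cytosolic = dataset$cytosolic[, pr$cytosolic_sample, drop = FALSE],
    polysome = dataset$polysome[, pr$polysome_sample, drop = FALSE],
    annotation = dataset$annotation[
      dataset$annotation$sample_id %in%
        c(pr$cytosolic_sample, pr$polysome_sample), ],
    pairing = pr)
  class(out) <- "paired_dataset"
  out
}

#' Construct a gene-set collection
#'
#' @param terms named list; each element a list with `name` (description)
#'   and `genes` (character vector of members), names are term ids.
#' @param universe optional character vector of genes eligible for
#'   enrichment; defaults to the union of all members.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, universe = NULL) {
  stopifnot(is.list(terms))
  for (id in names(terms)) {
    tm <- terms[[id]]
    if (is.null(tm$genes) || length(tm$genes) == 0L)
      stop("gene set '", id, "' is empty", call. = FALSE)
    terms[[id]]$genes <- unique(as.character(tm$genes))
    if (is.null(tm$name)) terms[[id]]$name <- id
  }
  if (is.null(universe))
    universe <- unique(unlist(lapply(terms, `[[`, "genes"), use.names = FALSE))
  structure(list(terms = terms, universe = unique(as.character(universe))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection: ", length(x$terms), " terms, universe of ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then member genes, all
#' tab-separated.
#'
#' @param path path to a GMT file.
#' @param universe optional universe passed to [gene_set_collection()].
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path))
    stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(gene_set_collection(stats::setNames(list(), character(0)),
                               universe = character(0)))
  terms <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has ", length(fields),
           " field(s); need term id, description and >=1 gene",
           call. = FALSE)
    terms[[fields[1L]]] <- list(name = fields[2L],
                                genes = fields[-(1:2)][nzchar(fields[-(1:2)])])
  }
  gene_set_collection(terms, universe = universe)
}

#' Write a gene-set collection to GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$terms), function(id) {
    tm <- collection$terms[[id]]
    paste(c(id, tm$name, tm$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an external per-gene effect table
#'
#' TSV with columns `gene_id` and `effect` (log2), e.g. fold changes from a
#' second study used for overlap or concordance analysis.
#'
#' @param path path to the TSV.
#' @return named numeric vector of log2 effects, names are gene ids.
#' @export
read_effects_tsv <- function(path) {
  if (!file.exists(path))
    stop("effect table not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "effect") %in% names(tab)))
    stop("effect table needs columns gene_id and effect: ", path,
         call. = FALSE)
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id(s) in effect table ", path, call. = FALSE)
  stats::setNames(as.numeric(tab$effect), tab$gene_id)
}

#' Write a per-gene effect table
#' @param effects named numeric vector of log2 effects.
#' @param path output path.
#' @export
write_effects_tsv <- function(effects, path) {
  df <- data.frame(gene_id = names(effects),
                   effect = format(unname(effects), digits = 17,
                                   trim = TRUE, scientific = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
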