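#' Build a fold-threshold signature
#'
#' Collects the significantly regulated genes whose log2 effect exceeds a
#' linear fold threshold, split by direction: `up` holds genes with effect
#' >= log2(fold_threshold), `down` those with effect <= -log2(fold_threshold).
#'
#' @param effects named numeric vector of log2 effects (gene ids as names).
#' @param included logical vector (same length/order) flagging the
#'   significant genes eligible for the signature; `NULL` means all.
#' @param fold_threshold linear fold threshold (>= 1); e.g. 3 selects
#'   |log2 effect| >= log2(3).
#' @param label free-text contrast label carried in the result.
#' @return object of class `signature`: list with `up`, `down` (named
#'   effect vectors), `fold_threshold`, `label`.
#' @export
build_signature <- function(effects, included = NULL, fold_threshold,
                            label = "") {
  if (fold_threshold < 1)
    stop("fold_threshold must be >= 1 (linear fold)", call. = FALSE)
  if (is.null(included)) included <- rep(TRUE, length(effects))
  stopifnot(length(included) == length(effects))
  ok <- included & !is.na(effects)
  cut <- log2(fold_threshold)
  up <- effects[ok & effects >= cut & effects > 0]
  down <- effects[ok & effects <= -cut & effects < 0]
  structure(list(up = up[order(-up)], down = down[order(down)],
                 fold_threshold = fold_threshold, label = label),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("Signature '%s' (>=%g-fold): %d up, %d down\n",
              x$label, x$fold_threshold, length(x$up), length(x$down)))
  invisible(x)
}

#' Overlap of a signature with an external fold-change table
#'
#' For each direction of regulation, counts how many signature genes are
#' present in the external table (`n_mappable`) and how many of those also
#' pass the external fold threshold (`n_shared`), reporting the percentage
#' shared. With `direction_mode = "same_direction"` the external effect must
#' have the same sign; `"any_direction"` counts any external effect of
#' sufficient magnitude.
#'
#' @param sig a `signature`.
#' @param external named numeric vector of external log2 effects.
#' @param fold_threshold linear fold threshold applied to the external
#'   effects.
#' @param direction_mode "same_direction" (default) or "any_direction".
#' @return data.frame with one row per direction: direction, n_signature,
#'   n_mappable, n_shared, percent (NA when no signature gene is mappable).
#' @export
overlap_percent <- function(sig, external, fold_threshold,
                            direction_mode = c("same_direction",
                                               "any_direction")) {
  stopifnot(inherits(sig, "signature"))
  direction_mode <- match.arg(direction_mode)
  if (fold_threshold < 1)
    stop("fold_threshold must be >= 1 (linear fold)", call. = FALSE)
  cut <- log2(fold_threshold)
  one <- function(genes, sign_wanted, direction) {
    n_sig <- length(genes)
    ext <- external[names(genes)]
    mappable <- !is.na(ext)
    n_map <- sum(mappable)
    passes <- if (direction_mode == "same_direction")
      mappable & (sign_wanted * ext >= cut) & (sign(ext) == sign_wanted)
    else
      mappable & abs(ext) >= cut
    n_shared <- sum(passes)
    if (n_map == 0L) {
      warning("no ", direction, "-regulated signature gene maps to the ",
              "external table; percent undefined", call. = FALSE)
      pct <- NA_real_
    } else pct <- 100 * n_shared / n_map
    data.frame(direction = direction, n_signature = n_sig,
               n_mappable = n_map, n_shared = n_shared, percent = pct,
               stringsAsFactors = FALSE)
  }
  rbind(one(sig$up, 1, "up"), one(sig$down, -1, "down"))
}

#' Two-dataset sign-concordance module
#'
#' Intersects the differentially translated genes of a primary contrast with
#' the genes showing at least a `secondary_fold` difference in a second
#' fold-change table, cross-tabulates the signs of the two (oriented)
#' effects into quadrants, and tests whether concordant regulation exceeds
#' chance with a one-sided binomial test at p = 1/2. The orientation
#' arguments declare which sign corresponds to the shared biological axis
#' (e.g. "high cap-dependent initiation"), so a convention flip in either
#' dataset is a single sign change.
#'
#' @param primary_effects named numeric vector of log2 effects from the
#'   primary analysis.
#' @param primary_included logical vector flagging the significant genes
#'   (same length/order), or `NULL` for all.
#' @param secondary_effects named numeric vector of log2 effects from the
#'   secondary dataset.
#' @param secondary_fold linear fold threshold applied to the secondary
#'   effects (default 1.3).
#' @param orientation length-2 numeric (+1/-1) for (primary, secondary).
#' @return object of class `concordance_result`: quadrant counts,
#'   n_concordant, n_discordant, binomial_p, and the member gene lists.
#' @export
concordance_module <- function(primary_effects, primary_included = NULL,
                               secondary_effects, secondary_fold = 1.3,
                               orientation = c(1, 1)) {
  if (is.null(primary_included))
    primary_included <- rep(TRUE, length(primary_effects))
  stopifnot(length(primary_included) == length(primary_effects),
            all(orientation %in% c(-1, 1)), length(orientation) == 2L)
  if (secondary_fold < 1)
    stop("secondary_fold must be >= 1 (linear fold)", call. = FALSE)
  prim <- primary_effects[primary_included & !is.na(primary_effects)]
  sec <- secondary_effects[names(prim)]
  keep <- !is.na(sec) & abs(sec) >= log2(secondary_fold)
  prim <- prim[keep] * orientation[1L]
  sec <- sec[keep] * orientation[2L]

  quad <- c(up_up = sum(prim > 0 & sec > 0),
            up_down = sum(prim > 0 & sec < 0),
            down_up = sum(prim < 0 & sec > 0),
            down_down = sum(prim < 0 & sec < 0))
  n_conc <- sum(prim * sec > 0)
  n_disc <- length(prim) - n_conc
  if (length(prim) == 0L) {
    warning("no gene passes both the primary inclusion and the secondary ",
            "fold filter; concordance undefined", call. = FALSE)
    bp <- 1
  } else {
    bp <- stats::pbinom(n_conc - 1L, n_conc + n_disc, 0.5,
                        lower.tail = FALSE)
  }
  structure(list(quadrants = quad, n_concordant = n_conc,
                 n_discordant = n_disc, binomial_p = bp,
                 secondary_fold = secondary_fold,
                 orientation = orientation,
                 concordant_genes = names(prim)[prim * sec > 0],
                 discordant_genes = names(prim)[prim * sec < 0]),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Concordance module (secondary fold >= %g): %d concordant, %d discordant\n",
    x$secondary_fold, x$n_concordant, x$n_discordant))
  cat("  quadrants:",
      paste(sprintf("%s=%d", names(x$quadrants), x$quadrants),
            collapse = " "), "\n")
  cat(sprintf("  one-sided binomial p = %.4g\n", x$binomial_p))
  invisible(x)
}
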