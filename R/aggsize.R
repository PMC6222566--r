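#' Segment bright aggregates in a projected image
#'
#' Binarises a (typically maximum-intensity projected) image with the
#' locally adaptive threshold and returns the physical area of each
#' connected component. Used for the aggregate-size morphology analysis in
#' human cells.
#'
#' @param img A [micrograph()].
#' @param params A [segmentation_params()]; `min_focus_area_px` removes
#'   speckle.
#' @param offset_k Threshold offset (multiples of local sd).
#' @return Numeric vector of aggregate areas in um^2.
#' @export
segment_aggregates <- function(img, params = segmentation_params(),
                               offset_k = 1.5) {
  stopifnot(inherits(img, "micrograph"))
  # aggregates are much larger than yeast puncta: the adaptive window must
  # dwarf the objects, so take a third of the image side
  w <- odd_window(min(dim(img$pixels)) / 3)
  mask <- local_adaptive_threshold(img, w, offset_k, params$min_contrast)
  mask <- EBImage::fillHull(mask * 1L)
  lab <- EBImage::bwlabel(mask)
  tab <- label_table(lab)
  tab <- tab[tab$area_px >= params$min_focus_area_px, , drop = FALSE]
  tab$area_px * img$pixel_size^2
}

#' Bin aggregate sizes at a physical-area cutoff
#'
#' Splits aggregates into "small" and "large" at the cutoff (default
#' 50 um^2); areas exactly at the cutoff count as large. Optionally compares
#' two conditions with the Mann-Whitney rank-sum test.
#'
#' @param areas Numeric vector of aggregate areas (um^2), or an
#'   `aggregate_field` from [render_aggregate_field()] (its true areas), or
#'   a label matrix together with `pixel_size`.
#' @param cutoff Area cutoff in um^2.
#' @param reference Optional second vector of areas; when given, the
#'   rank-sum test between `areas` and `reference` is reported.
#' @param pixel_size Needed only when `areas` is a label matrix.
#' @return List of class `aggregate_sizes` with `areas`, `cutoff`,
#'   `fraction_small`, and (when `reference` is given) `U` and `p_value`.
#' @export
bin_aggregate_sizes <- function(areas, cutoff = 50, reference = NULL,
                                pixel_size = NULL) {
  if (inherits(areas, "aggregate_field")) areas <- areas$areas_um2
  if (is.matrix(areas)) {
    if (is.null(pixel_size)) stop("pixel_size required for a label map")
    counts <- tabulate(areas[areas > 0])
    areas <- counts[counts > 0] * pixel_size^2
  }
  if (length(areas) == 0L) stop("at least one aggregate required")
  out <- list(areas = areas, cutoff = cutoff,
              fraction_small = mean(areas < cutoff))
  if (!is.null(reference)) {
    rs <- rank_sum_test(areas, reference)
    out$U <- rs$U
    out$p_value <- rs$p_value
  }
  structure(out, class = "aggregate_sizes")
}

#' @export
print.aggregate_sizes <- function(x, ...) {
  cat(sprintf("%d aggregates; fraction < %g um^2: %.3f\n",
              length(x$areas), x$cutoff, x$fraction_small))
  if (!is.null(x$p_value))
    cat(sprintf("rank-sum vs reference: U = %g, p = %.4g\n", x$U, x$p_value))
  invisible(x)
}

#' Mann-Whitney rank-sum test
#'
#' U is computed from joint midranks (ties share their average rank). The
#' two-sided p-value is obtained by exhaustive enumeration of all group
#' assignments whenever that is tractable (both samples of size <= 8, and
#' any split of at most choose(16, 8) assignments), counting assignments
#' whose U is at least as far from its null mean as observed; otherwise the
#' normal approximation with tie and continuity corrections is used.
#'
#' @param a,b Numeric samples, both non-empty.
#' @return List with `U` (statistic for `a`), `p_value`, and `method`.
#' @export
rank_sum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= 12870) {
    ids <- combn(n1 + n2, n1)
    Us <- colSums(matrix(r[ids], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(U = U, p_value = p, method = method)
}
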