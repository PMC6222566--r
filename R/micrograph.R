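#' Construct a micrograph
#'
#' A micrograph is a 2-D grid of non-negative intensities together with the
#' physical pixel scale. The scale is what connects segmentation results to
#' physical rules such as the 2 um puncta-diameter cutoff.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities
#'   (rows = y, columns = x).
#' @param pixel_size Physical scale in um per pixel; must be positive.
#' @return An object of class `micrograph`.
#' @examples
#' img <- micrograph(matrix(runif(100), 10, 10), pixel_size = 0.2)
#' img
#' @export
micrograph <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("zero-size image")
  if (!all(is.finite(pixels))) stop("intensities must be finite")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/pixel)")
  structure(list(pixels = pixels, pixel_size = pixel_size), class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph: %d x %d px at %.4g um/px (%.1f x %.1f um), range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              nrow(x$pixels) * x$pixel_size, ncol(x$pixels) * x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

as_micrograph <- function(x, pixel_size) {
  if (inherits(x, "micrograph")) x else micrograph(x, pixel_size)
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a confocal z-stack into one plane by taking, at every pixel
#' position, the maximum intensity across planes.
#'
#' @param zstack List of `micrograph` objects (or matrices) of identical shape.
#' @param pixel_size Pixel scale, required only when plain matrices are given.
#' @return A `micrograph` whose pixels are the per-position maxima.
#' @export
max_project <- function(zstack, pixel_size = NULL) {
  if (length(zstack) == 0L) stop("empty stack")
  mats <- lapply(zstack, function(p) if (inherits(p, "micrograph")) p$pixels else as.matrix(p))
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1L))))
    stop("mismatched plane shapes in z-stack")
  ps <- if (inherits(zstack[[1L]], "micrograph")) zstack[[1L]]$pixel_size else pixel_size
  if (is.null(ps)) stop("pixel_size required when planes are plain matrices")
  micrograph(Reduce(pmax, mats), ps)
}
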