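#' Ground truth for a synthetic micrograph pair
#'
#' Describes a field of ellipsoidal yeast cells, which of them express the
#' fluorescent reporter, and which fluorescent cells carry a punctate focus.
#' [render_field()] turns this description into a DIC/GFP image pair, so every
#' downstream segmentation result can be checked against known truth.
#'
#' @param cells Data frame with columns `cx`, `cy` (centres, px) and
#'   `ax`, `ay` (ellipse semi-axes, px).
#' @param fluorescent Logical flag per cell.
#' @param foci Data frame with columns `cell` (index into `cells`), `x`, `y`
#'   (centre, px) and `diameter_um`. Every focus must sit in a fluorescent
#'   cell and have diameter below 2 um unless `allow_oversize = TRUE`
#'   (used to plant oversize control blobs).
#' @param image_shape Integer c(rows, cols) of the rendered images.
#' @param pixel_size um per pixel.
#' @param background_level,noise_sd Background intensity and additive
#'   Gaussian noise sd (arbitrary detector units).
#' @param dic_amplitude Brightness of a cell above background in the
#'   off-focus DIC proxy channel.
#' @param diffuse_level Diffuse cytoplasmic GFP brightness above background
#'   in fluorescent cells.
#' @param focus_peak Peak amplitude of a rendered focus above the diffuse
#'   signal; `focus_peak / noise_sd` is the field's peak SNR.
#' @param edge_blur_px Gaussian blur applied to the cell/diffuse layers so
#'   object edges are optically soft.
#' @param allow_oversize Permit planted foci with diameter >= 2 um.
#' @return An object of class `field_truth`.
#' @export
field_truth <- function(cells, fluorescent, foci = NULL,
                        image_shape = c(512L, 512L), pixel_size = 0.2,
                        background_level = 100, noise_sd = 0,
                        dic_amplitude = 300, diffuse_level = 150,
                        focus_peak = 600, edge_blur_px = 2,
                        allow_oversize = FALSE) {
  cells <- as.data.frame(cells)
  if (nrow(cells) > 0) stopifnot(all(c("cx", "cy", "ax", "ay") %in% names(cells)))
  stopifnot(length(fluorescent) == nrow(cells))
  if (is.null(foci))
    foci <- data.frame(cell = integer(), x = numeric(), y = numeric(),
                       diameter_um = numeric())
  foci <- as.data.frame(foci)
  if (nrow(foci) > 0) {
    stopifnot(all(c("cell", "x", "y", "diameter_um") %in% names(foci)))
    if (any(!fluorescent[foci$cell]))
      stop("focus planted in a non-fluorescent cell")
    if (!allow_oversize && any(foci$diameter_um >= 2))
      stop("planted focus diameter must be < 2 um (set allow_oversize for control blobs)")
  }
  if (nrow(cells) > 0) {
    inside <- cells$cy - cells$ay >= 1 & cells$cy + cells$ay <= image_shape[1L] &
              cells$cx - cells$ax >= 1 & cells$cx + cells$ax <= image_shape[2L]
    if (!all(inside)) stop("cell ellipses must lie fully inside the image bounds")
  }
  structure(list(cells = cells, fluorescent = as.logical(fluorescent), foci = foci,
                 image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 background_level = background_level, noise_sd = noise_sd,
                 dic_amplitude = dic_amplitude, diffuse_level = diffuse_level,
                 focus_peak = focus_peak, edge_blur_px = edge_blur_px),
            class = "field_truth")
}

#' @export
print.field_truth <- function(x, ...) {
  nf <- sum(x$fluorescent)
  cat(sprintf("field_truth: %d cells (%d fluorescent, %d with foci), %dx%d px at %.3g um/px, noise_sd %.3g\n",
              nrow(x$cells), nf, length(unique(x$foci$cell)),
              x$image_shape[1L], x$image_shape[2L], x$pixel_size, x$noise_sd))
  invisible(x)
}

#' Planted percent-foci of a ground truth
#'
#' The fraction (in percent) of fluorescent cells that carry at least one
#' focus: the statistic the imaging pipeline is meant to recover.
#' @param truth A [field_truth()].
#' @return Percent, or NA when the field has no fluorescent cells.
#' @export
truth_percent_foci <- function(truth) {
  nf <- sum(truth$fluorescent)
  if (nf == 0L) return(NA_real_)
  100 * length(unique(truth$foci$cell)) / nf
}

#' Sample a random field layout
#'
#' Places non-overlapping ellipsoidal cells on a jittered grid (so that
#' arbitrarily dense fields never produce touching cells), marks a fraction
#' fluorescent and gives a fraction of those one punctate focus.
#'
#' @param n_cells Number of cells to place.
#' @param frac_fluorescent Fraction of cells expressing the reporter.
#' @param frac_with_foci Fraction of fluorescent cells bearing one focus.
#' @param image_shape,pixel_size Image geometry (see [field_truth()]).
#' @param cell_diameter_um Mean cell diameter; axes are jittered around it.
#' @param focus_diameter_um Range the focus diameter is drawn from (um).
#' @param seed Integer seed.
#' @param ... Passed to [field_truth()] (levels, noise, blur).
#' @return A [field_truth()].
#' @export
simulate_field_truth <- function(n_cells, frac_fluorescent = 0.8,
                                 frac_with_foci = 0.3,
                                 image_shape = c(512L, 512L), pixel_size = 0.2,
                                 cell_diameter_um = 4,
                                 focus_diameter_um = c(0.8, 1.4),
                                 seed = 1, ...) {
  with_seed(seed, {
    d_px <- cell_diameter_um / pixel_size
    spacing <- ceiling(d_px * 1.6)
    ncol_g <- max(1L, floor((image_shape[2L] - d_px) / spacing))
    nrow_g <- max(1L, floor((image_shape[1L] - d_px) / spacing))
    if (n_cells > nrow_g * ncol_g)
      stop(sprintf("cannot place %d non-touching cells in a %dx%d px field",
                   n_cells, image_shape[1L], image_shape[2L]))
    slots <- sample(nrow_g * ncol_g, n_cells)
    gy <- (slots - 1L) %/% ncol_g
    gx <- (slots - 1L) %% ncol_g
    jit <- max(0, spacing / 2 - 0.6 * d_px - 2)
    cells <- data.frame(
      cx = d_px / 2 + 1 + gx * spacing + spacing / 2 + runif(n_cells, -jit, jit),
      cy = d_px / 2 + 1 + gy * spacing + spacing / 2 + runif(n_cells, -jit, jit),
      ax = d_px / 2 * runif(n_cells, 0.85, 1.1),
      ay = d_px / 2 * runif(n_cells, 0.85, 1.1))
    fluor <- seq_len(n_cells) %in% sample(n_cells, round(frac_fluorescent * n_cells))
    fl_idx <- which(fluor)
    nf <- round(frac_with_foci * length(fl_idx))
    foci_cells <- if (nf > 0) sort(sample(fl_idx, nf)) else integer()
    foci <- data.frame(
      cell = foci_cells,
      x = cells$cx[foci_cells] + runif(nf, -0.3, 0.3) * cells$ax[foci_cells],
      y = cells$cy[foci_cells] + runif(nf, -0.3, 0.3) * cells$ay[foci_cells],
      diameter_um = runif(nf, focus_diameter_um[1L], focus_diameter_um[2L]))
    field_truth(cells, fluor, foci, image_shape = image_shape,
                pixel_size = pixel_size, ...)
  })
}

# Add `value` inside each ellipse of `cells` to matrix `m` (bounding-box loop).
add_ellipses <- function(m, cells, value) {
  if (nrow(cells) == 0L) return(m)
  for (i in seq_len(nrow(cells))) {
    cx <- cells$cx[i]; cy <- cells$cy[i]; ax <- cells$ax[i]; ay <- cells$ay[i]
    ys <- max(1L, floor(cy - ay)):min(nrow(m), ceiling(cy + ay))
    xs <- max(1L, floor(cx - ax)):min(ncol(m), ceiling(cx + ax))
    yy <- (ys - cy) / ay
    xx <- (xs - cx) / ax
    inside <- outer(yy^2, xx^2, `+`) <= 1
    m[ys, xs] <- m[ys, xs] + value * inside
  }
  m
}

# True ellipse mask of a single cell, used by tests for overlap checks.
cell_mask <- function(truth, i) {
  m <- matrix(0, truth$image_shape[1L], truth$image_shape[2L])
  add_ellipses(m, truth$cells[i, , drop = FALSE], 1) > 0
}

#' Render a DIC/GFP micrograph pair from ground truth
#'
#' The DIC proxy shows every cell as a bright smooth blob over a darker
#' background (off-focus DIC makes cells appear bright). The GFP channel
#' shows diffuse cytoplasmic fill in fluorescent cells plus an isotropic
#' Gaussian profile at each planted focus whose full width at half maximum
#' equals the planted diameter. Additive Gaussian noise is applied last.
#'
#' @param truth A [field_truth()].
#' @param image_shape Optional override of the truth's image shape.
#' @param seed Integer seed for the noise.
#' @return List with elements `dic` and `gfp`, both [micrograph()] objects.
#' @export
render_field <- function(truth, image_shape = NULL, seed = 1) {
  stopifnot(inherits(truth, "field_truth"))
  shape <- as.integer(image_shape %||% truth$image_shape)
  if (any(shape < 1L)) stop("zero-size image")
  if (nrow(truth$foci) > 0 && any(!truth$fluorescent[truth$foci$cell]))
    stop("focus planted in a non-fluorescent cell")
  base <- matrix(truth$background_level, shape[1L], shape[2L])

  dic <- add_ellipses(base, truth$cells, truth$dic_amplitude)
  dic <- gauss_smooth(dic, truth$edge_blur_px)

  gfp <- add_ellipses(base, truth$cells[truth$fluorescent, , drop = FALSE],
                      truth$diffuse_level)
  gfp <- gauss_smooth(gfp, truth$edge_blur_px)
  if (nrow(truth$foci) > 0) {
    for (i in seq_len(nrow(truth$foci))) {
      f <- truth$foci[i, ]
      sigma <- (f$diameter_um / truth$pixel_size) / (2 * sqrt(2 * log(2)))
      r <- ceiling(4 * sigma)
      ys <- max(1L, floor(f$y - r)):min(shape[1L], ceiling(f$y + r))
      xs <- max(1L, floor(f$x - r)):min(shape[2L], ceiling(f$x + r))
      g <- truth$focus_peak *
        exp(-outer((ys - f$y)^2, (xs - f$x)^2, `+`) / (2 * sigma^2))
      gfp[ys, xs] <- gfp[ys, xs] + g
    }
  }
  if (truth$noise_sd > 0) {
    with_seed(seed, {
      dic <- dic + rnorm(length(dic), 0, truth$noise_sd)
      gfp <- gfp + rnorm(length(gfp), 0, truth$noise_sd)
    })
  }
  list(dic = micrograph(pmax(dic, 0), truth$pixel_size),
       gfp = micrograph(pmax(gfp, 0), truth$pixel_size))
}

#' Render a field of bright aggregates with a ground-truth label map
#'
#' Places filled circular regions with the requested physical areas at
#' non-overlapping random positions (the stand-in for a projected image of
#' polyQ aggregates in human cells), and returns the true label map alongside
#' the rendered image.
#'
#' @param areas Numeric vector of aggregate areas, um^2 (all positive);
#'   an empty vector renders an empty field.
#' @param image_shape Integer c(rows, cols).
#' @param pixel_size um per pixel.
#' @param seed Integer seed.
#' @param background_level,level,noise_sd Background, aggregate intensity and
#'   noise sd.
#' @param max_tries Placement retries per aggregate before giving up.
#' @return List of class `aggregate_field` with elements `image`
#'   ([micrograph()]), `labels` (integer label matrix) and `areas_um2`
#'   (realised rasterised areas).
#' @export
render_aggregate_field <- function(areas, image_shape = c(512L, 512L),
                                   pixel_size = 0.26, seed = 1,
                                   background_level = 50, level = 500,
                                   noise_sd = 0, max_tries = 500L) {
  if (length(areas) > 0 && any(areas <= 0)) stop("areas must be positive")
  shape <- as.integer(image_shape)
  labels <- matrix(0L, shape[1L], shape[2L])
  realised <- numeric(length(areas))
  with_seed(seed, {
    radii <- sqrt((areas / pixel_size^2) / pi)
    centres <- matrix(numeric(), ncol = 2)
    for (i in seq_along(areas)) {
      r <- radii[i]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- runif(1, r + 2, shape[2L] - r - 1)
        cy <- runif(1, r + 2, shape[1L] - r - 1)
        if (nrow(centres) == 0 ||
            all(sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2) >
                radii[seq_len(nrow(centres))] + r + 3)) {
          ys <- floor(cy - r):ceiling(cy + r)
          xs <- floor(cx - r):ceiling(cx + r)
          disk <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
          labels[ys, xs][disk] <- i
          realised[i] <- sum(disk) * pixel_size^2
          centres <- rbind(centres, c(cx, cy))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("requested aggregates cannot be placed without overlap")
    }
    img <- background_level + level * (labels > 0)
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    structure(list(image = micrograph(pmax(img, 0), pixel_size),
                   labels = labels, areas_um2 = realised),
              class = "aggregate_field")
  })
}
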