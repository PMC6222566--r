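#' Segmentation parameters for the aggregation-quantitation pipeline
#'
#' @param puncta_max_diameter Foci larger than this equivalent diameter (um)
#'   are classified as diffuse fluorescence, not aggregates. Default 2.
#' @param highpass_scale Spatial scale (um) of the high-pass filter used to
#'   amplify punctate objects; features broader than this are attenuated.
#' @param lowpass_scale Spatial scale (um) of the low-pass smoothing used to
#'   decide whether a cell is diffusely fluorescent. Must exceed
#'   `highpass_scale`.
#' @param local_window Side (px, odd, >= 3) of the square window of the
#'   locally adaptive threshold; `NULL` derives it from the pixel size
#'   (about 8 um, roughly two cell diameters).
#' @param cell_offset_k,puncta_offset_k Multiples of the local standard
#'   deviation added to the local mean when binarising the DIC and high-pass
#'   GFP images. `puncta_offset_k` is what [calibrate_thresholds()] tunes.
#' @param min_contrast Small absolute intensity margin added to both local
#'   thresholds so that noise-free flat regions never segment (detector
#'   units).
#' @param min_cell_area,max_cell_area Area bounds (um^2) for accepted cells.
#' @param min_focus_area_px Connected components smaller than this many
#'   pixels are discarded as noise speckle.
#' @param fluor_threshold Low-pass GFP intensity above which a pixel counts
#'   as fluorescent; `NULL` until set directly or by calibration.
#' @param fluor_frac Fraction of a cell's area that must exceed
#'   `fluor_threshold` for the cell to count as fluorescent (default half).
#' @param focus_dilate_px Dilation radius applied to focus masks before they
#'   are excluded from the diffuse-intensity mean.
#' @param exclude_border Drop cells touching the image border (kept by
#'   default; exclusion biases counts in dense fields).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(puncta_max_diameter = 2,
                                highpass_scale = 0.8,
                                lowpass_scale = 1,
                                local_window = NULL,
                                cell_offset_k = 1,
                                puncta_offset_k = 3.5,
                                min_contrast = 2,
                                min_cell_area = 3,
                                max_cell_area = 80,
                                min_focus_area_px = 4L,
                                fluor_threshold = NULL,
                                fluor_frac = 0.5,
                                focus_dilate_px = 2L,
                                exclude_border = FALSE) {
  if (puncta_max_diameter <= 0) stop("puncta_max_diameter must be > 0")
  if (highpass_scale >= lowpass_scale)
    stop("highpass_scale must be smaller than lowpass_scale")
  if (!is.null(local_window)) {
    if (local_window %% 2 == 0 || local_window < 3)
      stop("local_window must be odd and >= 3")
  }
  structure(list(puncta_max_diameter = puncta_max_diameter,
                 highpass_scale = highpass_scale, lowpass_scale = lowpass_scale,
                 local_window = local_window, cell_offset_k = cell_offset_k,
                 puncta_offset_k = puncta_offset_k, min_contrast = min_contrast,
                 min_cell_area = min_cell_area, max_cell_area = max_cell_area,
                 min_focus_area_px = as.integer(min_focus_area_px),
                 fluor_threshold = fluor_threshold, fluor_frac = fluor_frac,
                 focus_dilate_px = as.integer(focus_dilate_px),
                 exclude_border = exclude_border),
            class = "segmentation_params")
}

window_for <- function(params, pixel_size) {
  params$local_window %||% odd_window(8 / pixel_size)
}

#' Locally adaptive threshold
#'
#' A pixel is foreground iff its intensity exceeds the mean over the
#' surrounding square window plus `offset_k` local standard deviations
#' (plus an optional absolute margin). Boundaries are handled by reflected
#' padding. The rule is shift-invariant: adding a constant to the whole
#' image leaves the mask unchanged.
#'
#' @param img A [micrograph()] or numeric matrix.
#' @param window Window side in px; odd, >= 3, no larger than the image.
#' @param offset_k Multiple of the local (population) standard deviation.
#' @param min_contrast Absolute margin added to the threshold (default 0,
#'   the pure local rule).
#' @return Logical matrix of foreground pixels.
#' @export
local_adaptive_threshold <- function(img, window, offset_k, min_contrast = 0) {
  m <- if (inherits(img, "micrograph")) img$pixels else as.matrix(img)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  if (window > nrow(m) || window > ncol(m)) stop("window larger than image")
  ls <- local_stats(m, window)
  m > ls$mean + offset_k * ls$sd + min_contrast
}

#' High-pass filter for punctate objects
#'
#' Difference-of-scales high pass: the image minus a Gaussian-smoothed
#' version of itself at spatial scale `highpass_scale`, negatives clipped to
#' zero. Small punctate objects pass nearly unchanged while features broader
#' than the scale (diffuse fluorescence, background) are attenuated toward
#' zero; a constant image maps to all zeros.
#'
#' @param gfp A [micrograph()].
#' @param params A [segmentation_params()] (uses `highpass_scale`).
#' @return A [micrograph()] with the filtered intensities.
#' @export
highpass_puncta_filter <- function(gfp, params = segmentation_params()) {
  stopifnot(inherits(gfp, "micrograph"))
  if (params$highpass_scale <= 0) stop("highpass_scale must be > 0")
  sigma <- params$highpass_scale / gfp$pixel_size
  micrograph(pmax(gfp$pixels - gauss_smooth(gfp$pixels, sigma), 0),
             gfp$pixel_size)
}

# Otsu two-class split of a sorted numeric vector: the cut minimising the
# within-class sum of squares; returns the midpoint of the two class means.
otsu_split <- function(v) {
  n <- length(v)
  if (n < 2L) return(v[1L] * 0.5)
  best <- Inf; thr <- mean(v)
  for (k in seq_len(n - 1L)) {
    a <- v[seq_len(k)]; b <- v[(k + 1L):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) { best <- ss; thr <- (mean(a) + mean(b)) / 2 }
  }
  thr
}

# Area (px) of the region around component `lb`'s peak where the high-pass
# response stays above half its maximum (connected to the peak, evaluated in
# a bounded neighbourhood). Used for the puncta size rule.
halfmax_area <- function(hp, flab, lb) {
  idx <- which(flab == lb)
  peak <- idx[which.max(hp[idx])]
  nr <- nrow(hp)
  py <- (peak - 1L) %% nr + 1L
  px <- (peak - 1L) %/% nr + 1L
  h <- 15L
  ys <- max(1L, py - h):min(nr, py + h)
  xs <- max(1L, px - h):min(ncol(hp), px + h)
  sub <- hp[ys, xs, drop = FALSE]
  mask <- sub >= hp[peak] / 2
  lab <- EBImage::bwlabel(mask * 1L)
  sum(lab == lab[match(py, ys), match(px, xs)])
}

# Areas and centroids of each positive label; returns a data.frame.
label_table <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), area_px = integer(),
                      cy = numeric(), cx = numeric()))
  l <- lab[idx]
  nr <- nrow(lab)
  ys <- (idx - 1L) %% nr + 1L
  xs <- (idx - 1L) %/% nr + 1L
  area <- tabulate(l)
  keep <- which(area > 0L)
  data.frame(label = keep,
             area_px = area[keep],
             cy = rowsum(ys, l)[, 1L] / area[keep],
             cx = rowsum(xs, l)[, 1L] / area[keep])
}

#' Detect yeast cells in an off-focus DIC image
#'
#' Cells appear as bright objects: the image is binarised with the locally
#' adaptive threshold, holes are filled, and connected components whose
#' areas fall within the configured physical bounds are kept as cell masks.
#' Fluorescence fields are left unset until [detect_foci()] and
#' [detect_diffuse()] annotate them.
#'
#' @param dic A [micrograph()] (slightly off-focus DIC channel).
#' @param params A [segmentation_params()].
#' @return An object of class `cell_set`: disjoint integer cell masks
#'   (`labels`) plus a per-cell table (`cells`).
#' @export
detect_cells <- function(dic, params = segmentation_params()) {
  stopifnot(inherits(dic, "micrograph"))
  ps <- dic$pixel_size
  w <- window_for(params, ps)
  mask <- local_adaptive_threshold(dic, w, params$cell_offset_k,
                                   params$min_contrast)
  mask <- EBImage::fillHull(mask * 1L)
  lab <- EBImage::bwlabel(mask)
  tab <- label_table(lab)
  tab$area_um2 <- tab$area_px * ps^2
  keep <- tab$area_um2 >= params$min_cell_area &
          tab$area_um2 <= params$max_cell_area
  if (params$exclude_border && any(keep)) {
    nr <- nrow(lab); nc <- ncol(lab)
    border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    keep <- keep & !(tab$label %in% border)
  }
  tab <- tab[keep, , drop = FALSE]
  relab <- integer(max(lab, 1L))
  relab[tab$label] <- seq_len(nrow(tab))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  nc <- nrow(tab)
  cells <- data.frame(cell_id = seq_len(nc),
                      area_um2 = tab$area_um2, cx = tab$cx, cy = tab$cy,
                      is_fluorescent = rep(NA, nc),
                      n_foci = rep(NA_integer_, nc),
                      diffuse_mean = rep(NA_real_, nc))
  structure(list(labels = lab, cells = cells,
                 foci = data.frame(cell_id = integer(), cx = numeric(),
                                   cy = numeric(), area_um2 = numeric(),
                                   equiv_diameter_um = numeric()),
                 foci_mask = NULL, pixel_size = ps, params = params),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("cell_set: %d cells", nrow(x$cells)))
  if (!anyNA(x$cells$is_fluorescent))
    cat(sprintf(" (%d fluorescent, %d with foci)",
                sum(x$cells$is_fluorescent), sum(x$cells$n_foci > 0)))
  cat(sprintf("; %d foci\n", nrow(x$foci)))
  invisible(x)
}

#' Detect punctate foci within cells
#'
#' The high-pass-filtered GFP image is binarised with the locally adaptive
#' threshold; connected components are assigned to the cell containing their
#' centroid (a focus straddling two masks goes to the centroid's cell), and
#' components with equivalent diameter above `puncta_max_diameter` are
#' discarded: by the 2 um rule those are diffuse fluorescence, not
#' aggregates.
#'
#' @param gfp GFP-channel [micrograph()].
#' @param cells A `cell_set` from [detect_cells()].
#' @param params A [segmentation_params()].
#' @return The `cell_set` with `foci` table and per-cell `n_foci` filled in.
#' @export
detect_foci <- function(gfp, cells, params = segmentation_params()) {
  stopifnot(inherits(gfp, "micrograph"), inherits(cells, "cell_set"))
  ps <- gfp$pixel_size
  hp <- highpass_puncta_filter(gfp, params)
  w <- window_for(params, ps)
  mask <- local_adaptive_threshold(hp, w, params$puncta_offset_k,
                                   params$min_contrast)
  flab <- EBImage::bwlabel(mask * 1L)
  tab <- label_table(flab)
  keep_mask <- matrix(FALSE, nrow(flab), ncol(flab))
  foci <- data.frame(cell_id = integer(), cx = numeric(), cy = numeric(),
                     area_um2 = numeric(), equiv_diameter_um = numeric())
  if (nrow(tab) > 0) {
    tab <- tab[tab$area_px >= params$min_focus_area_px, , drop = FALSE]
    # size each candidate at half maximum of its high-pass response: the
    # half-max extent is threshold-independent, so a broad blob whose core
    # survives an aggressive threshold is still measured at its true width
    tab$area_px_hm <- vapply(tab$label, function(lb)
      halfmax_area(hp$pixels, flab, lb), numeric(1L))
    tab$area_um2 <- tab$area_px_hm * ps^2
    tab$ed <- 2 * sqrt(tab$area_um2 / pi)
    tab <- tab[tab$ed <= params$puncta_max_diameter, , drop = FALSE]
    if (nrow(tab) > 0) {
      owner <- cells$labels[cbind(pmin(pmax(round(tab$cy), 1), nrow(flab)),
                                  pmin(pmax(round(tab$cx), 1), ncol(flab)))]
      tab <- tab[owner > 0L, , drop = FALSE]
      owner <- owner[owner > 0L]
      if (nrow(tab) > 0) {
        keep_mask <- matrix(flab %in% tab$label, nrow(flab), ncol(flab))
        foci <- data.frame(cell_id = owner, cx = tab$cx, cy = tab$cy,
                           area_um2 = tab$area_um2,
                           equiv_diameter_um = tab$ed)
      }
    }
  }
  cells$foci <- foci[order(foci$cell_id), , drop = FALSE]
  cells$cells$n_foci <- tabulate(foci$cell_id, nbins = nrow(cells$cells))
  cells$foci_mask <- keep_mask
  cells
}

#' Classify cells as fluorescent and measure diffuse intensity
#'
#' A cell is fluorescent iff the low-pass-smoothed GFP signal within its
#' mask exceeds `fluor_threshold` over at least `fluor_frac` of its area, or
#' the cell contains at least one focus. The diffuse mean intensity is the
#' mean of the raw GFP signal over the cell mask with (dilated) focus pixels
#' excluded; a cell whose mask is entirely foci is flagged absent (NA).
#'
#' @param gfp GFP-channel [micrograph()].
#' @param cells A `cell_set` that has been through [detect_foci()].
#' @param params A [segmentation_params()] with `fluor_threshold` set
#'   (directly or via [calibrate_thresholds()]).
#' @return The `cell_set` with `is_fluorescent` and `diffuse_mean` filled in.
#' @export
detect_diffuse <- function(gfp, cells, params = segmentation_params()) {
  stopifnot(inherits(gfp, "micrograph"), inherits(cells, "cell_set"))
  if (anyNA(cells$cells$n_foci))
    stop("run detect_foci() before detect_diffuse()")
  if (is.null(params$fluor_threshold))
    stop("fluor_threshold is unset; call calibrate_thresholds() or set it")
  lp <- gauss_smooth(gfp$pixels, params$lowpass_scale / gfp$pixel_size)
  lab <- cells$labels
  n <- nrow(cells$cells)
  if (n > 0) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    area <- tabulate(l, nbins = n)
    above <- rowsum((lp[idx] > params$fluor_threshold) * 1, l)[, 1L]
    frac <- numeric(n); frac[sort(unique(l))] <- above / area[sort(unique(l))]
    cells$cells$is_fluorescent <- frac >= params$fluor_frac |
      cells$cells$n_foci > 0L
    excl <- cells$foci_mask
    if (!is.null(excl) && any(excl) && params$focus_dilate_px > 0) {
      brush <- EBImage::makeBrush(2L * params$focus_dilate_px + 1L, "disc")
      excl <- EBImage::dilate(excl * 1L, brush) > 0
    }
    if (is.null(excl)) excl <- matrix(FALSE, nrow(lab), ncol(lab))
    keep <- idx[!excl[idx]]
    lk <- lab[keep]
    dsum <- numeric(n); dcount <- numeric(n)
    if (length(keep) > 0) {
      s <- rowsum(gfp$pixels[keep], lk)
      cnt <- tabulate(lk, nbins = n)
      dsum[as.integer(rownames(s))] <- s[, 1L]
      dcount <- cnt
    }
    cells$cells$diffuse_mean <- ifelse(dcount > 0, dsum / pmax(dcount, 1), NA_real_)
  } else {
    cells$cells$is_fluorescent <- logical(0)
  }
  cells$params <- params
  cells
}

#' Calibrate detection sensitivity on a positive control
#'
#' Mirrors the practice of tuning thresholds on a high-aggregating control
#' image. Two parameters are set deterministically from the control:
#' `fluor_threshold` is placed midway between the two classes of an Otsu
#' split of the per-cell median low-pass GFP intensities (separating the
#' background-level cell population from the diffusely fluorescent one;
#' the control should contain both), and the puncta binarisation offset
#' `puncta_offset_k` is the largest value at which the control's foci count
#' stays within 5% of its plateau (the longest stable run of counts over an
#' offset grid).
#'
#' @param control List with elements `dic` and `gfp` ([micrograph()] pair)
#'   such as produced by [render_field()].
#' @param params Starting [segmentation_params()].
#' @param k_grid Candidate puncta offsets to scan.
#' @return A [segmentation_params()] with `fluor_threshold` and
#'   `puncta_offset_k` set.
#' @export
calibrate_thresholds <- function(control, params = segmentation_params(),
                                 k_grid = seq(1.5, 8, by = 0.25)) {
  stopifnot(inherits(control$dic, "micrograph"), inherits(control$gfp, "micrograph"))
  cells <- detect_cells(control$dic, params)
  if (nrow(cells$cells) == 0L) stop("control contains no detectable cells")
  lp <- gauss_smooth(control$gfp$pixels,
                     params$lowpass_scale / control$gfp$pixel_size)
  idx <- which(cells$labels > 0L)
  cell_med <- sort(vapply(split(lp[idx], cells$labels[idx]), median, numeric(1L)))
  thr <- otsu_split(cell_med)
  lo <- cell_med[cell_med <= thr]; hi <- cell_med[cell_med > thr]
  # a genuine fluorescent population must stand clear of the background one;
  # otherwise the split is just carving up noise
  if (length(hi) == 0L || mean(hi) - mean(lo) < 0.2 * mean(lo))
    stop("control contains no fluorescent cells")
  params$fluor_threshold <- thr

  counts <- vapply(k_grid, function(k) {
    p <- params; p$puncta_offset_k <- k
    nrow(detect_foci(control$gfp, cells, p)$foci)
  }, numeric(1L))
  # a 3-point running median removes single-offset count flickers before
  # the plateau search; a larger control (more foci) gives a cleaner curve
  if (length(counts) >= 3L) counts <- runmed(counts, 3L)
  # longest run of offsets whose counts stay within 5% of the run median
  best_len <- 0L; best_end <- 1L
  i <- 1L
  while (i <= length(counts)) {
    j <- i
    while (j < length(counts)) {
      med <- median(counts[i:(j + 1L)])
      if (med == 0 || any(abs(counts[i:(j + 1L)] - med) > 0.05 * med)) break
      j <- j + 1L
    }
    if (j - i + 1L > best_len) { best_len <- j - i + 1L; best_end <- j }
    i <- j + 1L
  }
  params$puncta_offset_k <- k_grid[best_end]
  ann <- detect_diffuse(control$gfp,
                        detect_foci(control$gfp, cells, params), params)
  if (!any(ann$cells$is_fluorescent))
    stop("control contains no fluorescent cells")
  params
}
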