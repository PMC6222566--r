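#' Percent of fluorescent cells with foci
#'
#' The per-field aggregation statistic: 100 times the number of cells
#' containing at least one focus divided by the number of fluorescent cells.
#' Using the fluorescent cells as denominator standardises away variation in
#' reporter expression between fields and strains. With no fluorescent cells
#' the statistic is undefined (NA), never zero.
#'
#' @param cells A fully annotated `cell_set` (through [detect_foci()] and
#'   [detect_diffuse()]).
#' @return List of class `field_phenotype` with `n_cells`, `n_fluorescent`,
#'   `n_with_foci` and `percent_foci` (NA when undefined).
#' @export
percent_foci <- function(cells) {
  stopifnot(inherits(cells, "cell_set"))
  if (anyNA(cells$cells$is_fluorescent) || anyNA(cells$cells$n_foci))
    stop("cells must be fully annotated (detect_foci + detect_diffuse)")
  n_fl <- sum(cells$cells$is_fluorescent)
  n_fo <- sum(cells$cells$is_fluorescent & cells$cells$n_foci > 0L)
  structure(list(n_cells = nrow(cells$cells), n_fluorescent = n_fl,
                 n_with_foci = n_fo,
                 percent_foci = if (n_fl > 0L) 100 * n_fo / n_fl else NA_real_),
            class = "field_phenotype")
}

#' @export
print.field_phenotype <- function(x, ...) {
  cat(sprintf("field: %d cells, %d fluorescent, %d with foci -> percent_foci = %s\n",
              x$n_cells, x$n_fluorescent, x$n_with_foci,
              if (is.na(x$percent_foci)) "undefined" else
                sprintf("%.1f%%", x$percent_foci)))
  invisible(x)
}

#' Quantify one micrograph pair
#'
#' Convenience wrapper running the full per-field pipeline: cell detection
#' in DIC, foci detection in the high-pass GFP image, fluorescence/diffuse
#' annotation, and the percent-foci statistic.
#'
#' @param dic,gfp [micrograph()] pair.
#' @param params A [segmentation_params()] with `fluor_threshold` set.
#' @return Annotated `cell_set` with a `phenotype` element
#'   (see [percent_foci()]).
#' @export
quantify_field <- function(dic, gfp, params) {
  cells <- detect_cells(dic, params)
  cells <- detect_foci(gfp, cells, params)
  cells <- detect_diffuse(gfp, cells, params)
  cells$phenotype <- percent_foci(cells)
  cells
}

#' Aggregate replicate measurements into a strain phenotype
#'
#' The strain phenotype is the unweighted mean of the replicate percentages
#' (each replicate being an independently transformed clone or imaging run).
#' Undefined replicates (fields without fluorescent cells) are excluded from
#' the mean and reported, never treated as zero.
#'
#' @param replicates Numeric vector of replicate percent-foci values (NA for
#'   undefined replicates), or a list of `field_phenotype` objects.
#' @param strain Optional strain identifier.
#' @return List of class `strain_phenotype` with `percent_foci`,
#'   `replicates`, `n_replicates`, `n_undefined`.
#' @export
aggregate_replicates <- function(replicates, strain = NA_character_) {
  if (is.list(replicates) && length(replicates) > 0 &&
      inherits(replicates[[1L]], "field_phenotype"))
    replicates <- vapply(replicates, `[[`, numeric(1L), "percent_foci")
  replicates <- as.numeric(replicates)
  if (length(replicates) == 0L) stop("at least one replicate required")
  ok <- !is.na(replicates)
  structure(list(strain = strain,
                 percent_foci = if (any(ok)) mean(replicates[ok]) else NA_real_,
                 replicates = replicates,
                 n_replicates = length(replicates),
                 n_undefined = sum(!ok)),
            class = "strain_phenotype")
}

#' @export
print.strain_phenotype <- function(x, ...) {
  cat(sprintf("strain %s: percent_foci = %s over %d replicates (%d undefined)\n",
              x$strain,
              if (is.na(x$percent_foci)) "undefined" else sprintf("%.2f%%", x$percent_foci),
              x$n_replicates, x$n_undefined))
  invisible(x)
}

#' Correlation between diffuse intensity and foci propensity
#'
#' Pearson correlation between strain-mean diffuse fluorescence intensity
#' and percent of fluorescent cells with foci. A low correlation indicates
#' that expression-level differences between strains do not drive the
#' aggregation phenotype.
#'
#' @param diffuse Numeric vector of strain-mean diffuse intensities.
#' @param percent_foci Numeric vector of strain percent-foci values.
#' @return Pearson correlation coefficient.
#' @export
diffuse_vs_foci_correlation <- function(diffuse, percent_foci) {
  stopifnot(length(diffuse) == length(percent_foci))
  ok <- !is.na(diffuse) & !is.na(percent_foci)
  if (sum(ok) < 3L) stop("at least 3 strains required")
  if (sd(diffuse[ok]) == 0 || sd(percent_foci[ok]) == 0)
    stop("zero variance in diffuse intensity or percent_foci")
  cor(diffuse[ok], percent_foci[ok])
}
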