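#' Marker quality-control parameters
#'
#' @param r2_max Markers correlated above this squared-Pearson threshold
#'   with a neighbour are redundant; default 0.90.
#' @param max_missing Maximum missing genotype entries per marker; default 1.
#' @param maf_min Minimum minor-allele frequency among non-missing entries;
#'   default 0.25.
#' @return An object of class `prune_params`.
#' @export
prune_params <- function(r2_max = 0.90, max_missing = 1L, maf_min = 0.25) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0, 1]")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  structure(list(r2_max = r2_max, max_missing = as.integer(max_missing),
                 maf_min = maf_min), class = "prune_params")
}

# Squared Pearson correlation of two 0/1 allele vectors over
# pairwise-complete strains; NA when undefined.
marker_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Prune redundant and low-quality markers
#'
#' Two passes, mirroring standard cross-QC. First, correlation pruning
#' within each chromosome: scanning left to right, the squared correlation
#' between the current marker and the next is computed over
#' pairwise-complete strains, and when it exceeds `r2_max` the earlier
#' member of the pair is removed, so a block of correlated markers collapses
#' to its last member and every surviving adjacent pair (under decaying
#' linkage) satisfies R^2 <= r2_max. Second, markers with more than
#' `max_missing` missing entries or minor-allele frequency below `maf_min`
#' are removed. Markers with fewer than two genotyped strains are removed
#' up front. Every removal is logged with its reason.
#'
#' @param geno A [genotype_matrix()] with markers ordered by chromosome and
#'   position.
#' @param params A [prune_params()].
#' @param compare `"adjacent"` (default) compares each marker to its
#'   immediate neighbour and drops the earlier member of a violating pair;
#'   `"last_retained"` compares each candidate to the last retained marker
#'   and drops the candidate.
#' @param filter_order Whether correlation pruning runs before (default) or
#'   after the missingness/frequency filters.
#' @return List of class `marker_prune` with the filtered `geno` and a
#'   `removed` data frame (`name`, `chrom`, `reason`).
#' @export
prune_markers <- function(geno, params = prune_params(),
                          compare = c("adjacent", "last_retained"),
                          filter_order = c("correlation_first", "filters_first")) {
  stopifnot(inherits(geno, "genotype_matrix"))
  compare <- match.arg(compare)
  filter_order <- match.arg(filter_order)
  A <- geno$alleles
  m <- ncol(A)
  reason <- rep(NA_character_, m)

  mark_insufficient <- function(reason) {
    n_ok <- colSums(!is.na(A))
    reason[is.na(reason) & n_ok < 2L] <- "insufficient_data"
    reason
  }
  corr_pass <- function(reason) {
    for (ch in unique(geno$marker_meta$chrom)) {
      idx <- which(geno$marker_meta$chrom == ch & is.na(reason))
      if (length(idx) < 2L) next
      cur <- idx[1L]
      for (j in idx[-1L]) {
        r2 <- marker_r2(A[, cur], A[, j])
        if (!is.na(r2) && r2 > params$r2_max) {
          if (compare == "adjacent") {
            reason[cur] <- "correlated"
            cur <- j
          } else {
            reason[j] <- "correlated"
          }
        } else {
          cur <- j
        }
      }
    }
    reason
  }
  qc_pass <- function(reason) {
    n_miss <- colSums(is.na(A))
    f1 <- colMeans(A, na.rm = TRUE)
    maf <- pmin(f1, 1 - f1)
    reason[is.na(reason) & n_miss > params$max_missing] <- "missing"
    reason[is.na(reason) & (is.nan(maf) | maf < params$maf_min)] <- "maf"
    reason
  }

  reason <- mark_insufficient(reason)
  if (filter_order == "correlation_first") {
    reason <- corr_pass(reason)
    reason <- qc_pass(reason)
  } else {
    reason <- qc_pass(reason)
    reason <- corr_pass(reason)
  }

  keep <- is.na(reason)
  kept <- genotype_matrix(A[, keep, drop = FALSE],
                          geno$marker_meta[keep, , drop = FALSE],
                          geno$strain_ids)
  removed <- data.frame(name = geno$marker_meta$name[!keep],
                        chrom = geno$marker_meta$chrom[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(geno = kept, removed = removed, params = params),
            class = "marker_prune")
}

#' @export
print.marker_prune <- function(x, ...) {
  total <- ncol(x$geno$alleles) + nrow(x$removed)
  cat(sprintf("marker QC: %d of %d markers retained\n",
              ncol(x$geno$alleles), total))
  if (nrow(x$removed) > 0) print(table(x$removed$reason))
  invisible(x)
}

# Vectorised per-marker simple-regression statistics for a 0/1 allele
# matrix X (n x m, NA = missing) against phenotype y. Closed form: for each
# marker, strains missing that genotype are dropped and phenotype is
# regressed on the allele code; p is two-sided from t with n_used - 2 df.
scan_stats <- function(X, y) {
  M <- !is.na(X)
  Xz <- X; Xz[!M] <- 0L
  storage.mode(Xz) <- "double"
  storage.mode(M) <- "double"
  n <- colSums(M)
  Sx <- colSums(Xz)
  Sy <- as.vector(crossprod(M, y))
  Sxy <- as.vector(crossprod(Xz, y))
  Syy <- as.vector(crossprod(M, y * y))
  Sxx_c <- Sx - Sx^2 / n
  Sxy_c <- Sxy - Sx * Sy / n
  Syy_c <- Syy - Sy^2 / n
  defined <- n >= 3 & Sxx_c > 0 & Syy_c > 0
  slope <- ifelse(defined, Sxy_c / Sxx_c, NA_real_)
  sse <- pmax(Syy_c - slope * Sxy_c, 0)
  se <- ifelse(defined, sqrt(sse / (n - 2) / Sxx_c), NA_real_)
  tstat <- ifelse(defined, ifelse(se > 0, slope / se,
                                  sign(slope) * Inf), NA_real_)
  p <- ifelse(defined, 2 * pt(-abs(tstat), n - 2), NA_real_)
  data.frame(slope = slope, se = se, t = tstat, p_value = p,
             n_used = as.integer(n), defined = defined)
}

# Align a phenotype table to a genotype matrix; returns the phenotype
# vector in strain order with undefined strains dropped from both.
align_phenotype <- function(geno, pheno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (inherits(pheno, "phenotype_table") || is.data.frame(pheno)) {
    i <- match(geno$strain_ids, pheno$strain)
    if (anyNA(i)) stop("strain ids do not match between genotypes and phenotypes")
    y <- pheno$percent_foci[i]
  } else {
    y <- as.numeric(pheno)
    if (length(y) != length(geno$strain_ids))
      stop("phenotype length does not match strain count")
  }
  y
}

#' Single-marker regression linkage scan
#'
#' For each marker the parental alleles are coded 0 (laboratory) / 1
#' (vineyard), strains missing that genotype are dropped, and the phenotype
#' is regressed on the allele code by least squares. The reported two-sided
#' p-value tests the hypothesis that the fitted slope between the two
#' allelic groups is zero (equivalent to the pooled two-sample t-test).
#' Markers that are monomorphic among the used strains, or with fewer than
#' three informative strains, are flagged undefined, never silently dropped.
#'
#' @param geno A [genotype_matrix()].
#' @param pheno A `phenotype_table` (strain ids must match) or a numeric
#'   vector in strain order. Strains with NA phenotype are dropped.
#' @return An object of class `linkage_scan`: a data frame with one row per
#'   marker (`marker`, `chrom`, `pos`, `slope`, `se`, `t`, `p_value`,
#'   `n_used`, `defined`).
#' @examples
#' g <- simulate_cross(100, c(20, 20), seed = 1)
#' tr <- cross_truth(data.frame(marker = 5, effect = 8), baseline = 6, noise_sd = 2)
#' ph <- simulate_phenotypes(g, tr, seed = 2)
#' sc <- linkage_scan(g, ph)
#' summary(sc)
#' @export
linkage_scan <- function(geno, pheno) {
  y <- align_phenotype(geno, pheno)
  use <- !is.na(y)
  if (sum(use) < 3L) stop("fewer than 3 strains with phenotype data")
  stats <- scan_stats(geno$alleles[use, , drop = FALSE], y[use])
  out <- cbind(data.frame(marker = geno$marker_meta$name,
                          chrom = geno$marker_meta$chrom,
                          pos = geno$marker_meta$pos,
                          stringsAsFactors = FALSE),
               stats)
  attr(out, "n_strains") <- sum(use)
  class(out) <- c("linkage_scan", "data.frame")
  out
}

#' @export
print.linkage_scan <- function(x, ...) {
  cat(sprintf("linkage scan: %d markers, %d strains; min p = %.3g\n",
              nrow(x), attr(x, "n_strains"), min(x$p_value, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.linkage_scan <- function(object, n = 5L, ...) {
  cat(sprintf("Single-marker regression scan: %d markers (%d undefined), %d strains\n",
              nrow(object), sum(!object$defined), attr(object, "n_strains")))
  ord <- order(object$p_value)
  cat("Top markers:\n")
  print(as.data.frame(object)[head(ord, n),
        c("marker", "chrom", "pos", "slope", "t", "p_value", "n_used")],
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.linkage_scan <- function(object, ...) {
  setNames(object$slope, object$marker)
}

#' Genome-wide plot of linkage signal
#'
#' Plots -log10(p) against cumulative genomic position, alternating colour
#' by chromosome, with an optional horizontal line at the p-value threshold
#' corresponding to an FDR ceiling.
#'
#' @param x A `linkage_scan`.
#' @param fdr_table Optional [permutation_fdr()] result.
#' @param fdr_ceiling FDR level for the threshold line.
#' @param ... Passed to [plot()].
#' @importFrom graphics abline axis points
#' @importFrom grDevices dev.off png
#' @export
plot.linkage_scan <- function(x, fdr_table = NULL, fdr_ceiling = 0.12, ...) {
  chroms <- unique(x$chrom)
  offset <- 0
  xpos <- numeric(nrow(x))
  mids <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    sel <- x$chrom == chroms[i]
    xpos[sel] <- x$pos[sel] + offset
    mids[i] <- offset + mean(range(x$pos[sel]))
    offset <- offset + max(x$pos[sel])
  }
  lp <- -log10(pmax(x$p_value, 1e-300))
  plot(xpos, lp, col = c("grey25", "steelblue")[1 + (match(x$chrom, chroms) %% 2)],
       pch = 16, cex = 0.6, xaxt = "n", xlab = "chromosome",
       ylab = expression(-log[10](p)), ...)
  axis(1, at = mids, labels = sub("^chr", "", chroms))
  if (!is.null(fdr_table)) {
    thr <- fdr_threshold(fdr_table, fdr_ceiling)
    if (!is.na(thr)) abline(h = -log10(thr), lty = 2, col = "firebrick")
  }
  invisible(x)
}

#' Variance explained by named loci
#'
#' Fits phenotype on the coded alleles of the named markers jointly
#' (additive model with intercept, least squares; collinear markers are
#' handled by a rank-revealing fit and the rank is reported) and per marker
#' singly, all on the subset of strains genotyped at every named marker.
#'
#' @param geno A [genotype_matrix()].
#' @param pheno Phenotypes (see [linkage_scan()]).
#' @param markers Marker names or column indices (one or more).
#' @return List of class `variance_report`: `single` (named single-locus
#'   R^2), `joint` (joint-model R^2), `rank`, `n_strains`.
#' @export
variance_explained <- function(geno, pheno, markers) {
  idx <- resolve_markers(geno, markers)
  y <- align_phenotype(geno, pheno)
  X <- geno$alleles[, idx, drop = FALSE]
  use <- !is.na(y) & rowSums(is.na(X)) == 0L
  if (sum(use) < length(idx) + 2L) stop("too few complete strains")
  y <- y[use]; X <- X[use, , drop = FALSE]
  storage.mode(X) <- "double"
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero phenotype variance")
  fit <- lm.fit(cbind(1, X), y)
  joint <- 1 - sum(fit$residuals^2) / sst
  single <- vapply(seq_along(idx), function(k) {
    f <- lm.fit(cbind(1, X[, k]), y)
    1 - sum(f$residuals^2) / sst
  }, numeric(1L))
  structure(list(single = setNames(single, geno$marker_meta$name[idx]),
                 joint = joint, rank = fit$rank - 1L, n_strains = sum(use)),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf("variance explained (n = %d strains):\n", x$n_strains))
  for (nm in names(x$single))
    cat(sprintf("  %s: R^2 = %.3f\n", nm, x$single[[nm]]))
  cat(sprintf("  joint additive model (rank %d): R^2 = %.3f\n", x$rank, x$joint))
  invisible(x)
}
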