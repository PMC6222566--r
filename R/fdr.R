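#' Permutation-based false discovery rate for a linkage scan
#'
#' Phenotype values are shuffled across strains (genotypes fixed, so linkage
#' structure is preserved), the scan is re-run on each shuffled set, and the
#' FDR at a p-value threshold is the ratio of the average number of markers
#' reaching that threshold in permuted data to the number reaching it in the
#' real data. Markers whose test is undefined are excluded from both counts.
#' When the real count at a threshold is zero the ratio is flagged NA.
#'
#' @param geno A [genotype_matrix()].
#' @param pheno Phenotypes (see [linkage_scan()]).
#' @param n_perm Number of permuted data sets (default 100).
#' @param thresholds Decreasing p-value grid; defaults to the sorted
#'   observed p-values, which makes the FDR step function exact.
#' @param seed Integer seed for the permutations.
#' @param perms Optional integer matrix (one permutation of the used strains
#'   per row) overriding `n_perm`/`seed`; used for exhaustive enumeration on
#'   tiny instances.
#' @return An object of class `fdr_table`: a data frame with `threshold`,
#'   `mean_permuted_hits`, `real_hits`, `fdr`.
#' @export
permutation_fdr <- function(geno, pheno, n_perm = 100L, thresholds = NULL,
                            seed = 1, perms = NULL) {
  y <- align_phenotype(geno, pheno)
  use <- !is.na(y)
  if (sum(use) < 3L) stop("fewer than 3 strains with phenotype data")
  X <- geno$alleles[use, , drop = FALSE]
  y <- y[use]
  n <- length(y)
  real <- scan_stats(X, y)
  p_real <- real$p_value[real$defined]
  if (is.null(thresholds))
    thresholds <- sort(unique(p_real), decreasing = TRUE)
  if (length(thresholds) == 0L) stop("empty threshold grid")
  thresholds <- sort(thresholds, decreasing = TRUE)

  # number of p-values at or below each threshold; ties at the threshold
  # (equal in exact arithmetic, e.g. symmetric permutations) are counted,
  # so a 1-ulp rounding difference cannot move a hit across the boundary
  count_hits <- function(p, thr) {
    sp <- sort(p)
    findInterval(thr * (1 + 1e-9), sp)
  }
  real_hits <- count_hits(p_real, thresholds)

  if (is.null(perms)) {
    perms <- with_seed(substream_seed(seed, "permute"), {
      t(replicate(n_perm, sample.int(n)))
    })
  } else {
    perms <- as.matrix(perms)
    if (ncol(perms) != n) stop("permutation rows must have one entry per used strain")
    n_perm <- nrow(perms)
  }
  perm_hits <- matrix(0, n_perm, length(thresholds))
  for (b in seq_len(n_perm)) {
    pb <- scan_stats(X, y[perms[b, ]])
    perm_hits[b, ] <- count_hits(pb$p_value[pb$defined], thresholds)
  }
  mean_perm <- colMeans(perm_hits)
  out <- data.frame(threshold = thresholds,
                    mean_permuted_hits = mean_perm,
                    real_hits = real_hits,
                    fdr = ifelse(real_hits > 0, mean_perm / real_hits, NA_real_))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("fdr_table", "data.frame")
  out
}

#' @export
print.fdr_table <- function(x, ...) {
  cat(sprintf("permutation FDR over %d permutations, %d thresholds\n",
              attr(x, "n_perm"), nrow(x)))
  ok <- !is.na(x$fdr)
  if (any(ok))
    cat(sprintf("min FDR %.3g at p <= %.3g (%d real hits)\n",
                min(x$fdr[ok]), x$threshold[ok][which.min(x$fdr[ok])],
                x$real_hits[ok][which.min(x$fdr[ok])]))
  invisible(x)
}

# Largest p-value threshold whose (defined) FDR is at or below the ceiling.
fdr_threshold <- function(fdr_table, fdr_ceiling) {
  ok <- !is.na(fdr_table$fdr) & fdr_table$fdr <= fdr_ceiling
  if (!any(ok)) return(NA_real_)
  max(fdr_table$threshold[ok])
}

#' Call linkage peaks at an FDR ceiling
#'
#' Markers with p-value at or below the largest threshold whose permutation
#' FDR is defined and does not exceed `fdr_ceiling` are significant; within
#' a chromosome, runs of adjacent significant markers are collapsed to the
#' single best (smallest-p) marker. No threshold meeting the ceiling yields
#' an empty call set, not an error.
#'
#' @param scan A [linkage_scan()] result.
#' @param fdr_table A [permutation_fdr()] result from the same scan.
#' @param fdr_ceiling Acceptable false discovery rate (e.g. 0.12).
#' @return Data frame of class `peak_calls`: `marker`, `chrom`, `pos`,
#'   `p_value`, `fdr`, `n_markers_in_run`.
#' @export
call_peaks <- function(scan, fdr_table, fdr_ceiling = 0.12) {
  stopifnot(inherits(scan, "linkage_scan"), inherits(fdr_table, "fdr_table"))
  empty <- data.frame(marker = character(), chrom = character(),
                      pos = numeric(), p_value = numeric(), fdr = numeric(),
                      n_markers_in_run = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("peak_calls", "data.frame")
  thr <- fdr_threshold(fdr_table, fdr_ceiling)
  if (is.na(thr)) return(empty)
  fdr_at <- fdr_table$fdr[match(thr, fdr_table$threshold)]
  sig <- !is.na(scan$p_value) & scan$defined & scan$p_value <= thr
  if (!any(sig)) return(empty)
  peaks <- list()
  for (ch in unique(scan$chrom)) {
    idx <- which(scan$chrom == ch)
    s <- sig[idx]
    if (!any(s)) next
    runs <- rle(s)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      run_idx <- idx[starts[r]:ends[r]]
      best <- run_idx[which.min(scan$p_value[run_idx])]
      peaks[[length(peaks) + 1L]] <-
        data.frame(marker = scan$marker[best], chrom = ch,
                   pos = scan$pos[best], p_value = scan$p_value[best],
                   fdr = fdr_at, n_markers_in_run = length(run_idx),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, peaks)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_calls", "data.frame")
  out
}

#' @export
print.peak_calls <- function(x, ...) {
  cat(sprintf("%d peak(s) called\n", nrow(x)))
  if (nrow(x) > 0) print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
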