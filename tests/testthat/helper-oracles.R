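# Independent oracles used across the suite. These re-derive expectations
# from first principles (enumeration, lm/t.test, brute-force loops) and must
# stay independent of the package internals they check.

# Two-sided p of the pooled-variance two-sample t-test between allele groups.
oracle_ttest_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  t.test(y[ok][x[ok] == 0], y[ok][x[ok] == 1], var.equal = TRUE)$p.value
}

# Per-marker regression p via lm(), the reference for scan_stats.
oracle_lm_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  summary(lm(y[ok] ~ x[ok]))$coefficients[2, 4]
}

# Exhaustive-enumeration Mann-Whitney: all choose(n1+n2, n1) assignments of
# the joint midranks; two-sided p counts assignments with |U - mu| at least
# the observed distance.
oracle_ranksum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ids <- combn(n1 + n2, n1)
  Us <- apply(ids, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  list(U = U, p = mean(abs(Us - mu) >= abs(U - mu) - 1e-9))
}

# Straightforward re-implementation of the greedy adjacent-pair pruning rule
# on a single chromosome of 0/1 allele columns; returns retained indices.
oracle_prune_chrom <- function(A, r2_max = 0.9) {
  m <- ncol(A)
  removed <- logical(m)
  cur <- 1L
  for (j in seq_len(m)[-1L]) {
    ok <- !is.na(A[, cur]) & !is.na(A[, j])
    r2 <- if (sum(ok) >= 2 && sd(A[ok, cur]) > 0 && sd(A[ok, j]) > 0)
      cor(A[ok, cur], A[ok, j])^2 else NA
    if (!is.na(r2) && r2 > r2_max) {
      removed[cur] <- TRUE
      cur <- j
    } else cur <- j
  }
  which(!removed)
}

# Build a genotype_matrix from an explicit allele matrix on one chromosome.
toy_geno <- function(A, chrom = rep("chr1", ncol(A))) {
  pos <- ave(seq_len(ncol(A)), chrom, FUN = seq_along) * 1000
  genotype_matrix(A,
                  data.frame(chrom = chrom, pos = pos,
                             name = paste0("m", seq_len(ncol(A)))),
                  paste0("s", seq_len(nrow(A))))
}

# Reference segmentation parameters calibrated once on a rendered control
# field (70% fluorescent cells, half of them with foci, assay-level noise);
# cached so multiple test files can reuse the calibration.
calibrated_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulate_field_truth(100, frac_fluorescent = 0.7, frac_with_foci = 0.5,
                                 image_shape = c(640L, 640L), seed = 11,
                                 noise_sd = 120)
      cache <<- calibrate_thresholds(render_field(tr, seed = 11))
    }
    cache
  }
})
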