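#' Construct a genotype matrix for a two-parent haploid cross
#'
#' Alleles are coded `0` (laboratory parent, "L"), `1` (vineyard parent, "V"),
#' or `NA` (missing). Markers carry chromosome/position metadata; positions
#' must increase strictly within a chromosome.
#'
#' @param alleles Integer matrix, strains x markers, values in \{0, 1, NA\}.
#' @param marker_meta Data frame with columns `chrom`, `pos`, `name`
#'   (one row per marker).
#' @param strain_ids Character vector of strain identifiers (one per row).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, marker_meta, strain_ids) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L, NA_integer_)))
    stop("allele codes must be 0 (L), 1 (V) or NA (missing)")
  if (nrow(marker_meta) != ncol(alleles))
    stop("marker_meta rows must match allele columns")
  if (length(strain_ids) != nrow(alleles))
    stop("strain_ids must match allele rows")
  stopifnot(all(c("chrom", "pos", "name") %in% names(marker_meta)))
  for (ch in unique(marker_meta$chrom)) {
    p <- marker_meta$pos[marker_meta$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must increase strictly within a chromosome")
  }
  rownames(alleles) <- strain_ids
  colnames(alleles) <- marker_meta$name
  structure(list(alleles = alleles,
                 marker_meta = as.data.frame(marker_meta, stringsAsFactors = FALSE),
                 strain_ids = as.character(strain_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d markers on %d chromosomes; %.2f%% missing\n",
              nrow(x$alleles), ncol(x$alleles), length(unique(x$marker_meta$chrom)),
              100 * mean(is.na(x$alleles))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$alleles)

#' Simulate meiotic segregant genotypes
#'
#' Each segregant's chromosome is a two-state Markov chain over the parental
#' alleles: the first marker is a fair coin, and the allele switches between
#' adjacent markers with probability `recomb_prob`, which induces the
#' within-chromosome linkage structure of a meiotic cross. Entries are then
#' independently masked as missing.
#'
#' @param n_segregants Number of haploid segregant strains (> 0).
#' @param chrom_lengths Integer vector of marker counts per chromosome (>= 1).
#' @param recomb_prob Switch probability per adjacent-marker interval, in
#'   \[0, 0.5\]; 0 gives fully linked chromosomes, 0.5 free recombination.
#' @param missing_rate Probability an entry is missing.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param marker_spacing Basepair spacing of the integer position grid.
#' @return A [genotype_matrix()].
#' @examples
#' g <- simulate_cross(50, chrom_lengths = c(10, 10), recomb_prob = 0.1, seed = 1)
#' g
#' @export
simulate_cross <- function(n_segregants, chrom_lengths, recomb_prob = 0.1,
                           missing_rate = 0, seed = 1, marker_spacing = 5000L) {
  if (n_segregants < 1) stop("non-positive segregant count")
  if (recomb_prob < 0 || recomb_prob > 0.5) stop("recomb_prob outside [0, 0.5]")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  with_seed(seed, {
    chroms <- lapply(seq_along(chrom_lengths), function(ci) {
      L <- chrom_lengths[ci]
      first <- rbinom(n_segregants, 1L, 0.5)
      if (L == 1L) {
        m <- matrix(first, ncol = 1L)
      } else {
        sw <- matrix(rbinom(n_segregants * (L - 1L), 1L, recomb_prob),
                     nrow = n_segregants)
        cum <- t(apply(sw, 1, cumsum)) %% 2L
        if (L == 2L) cum <- matrix(cum, nrow = n_segregants)
        m <- cbind(first, (first + cum) %% 2L)
      }
      m
    })
    alleles <- do.call(cbind, chroms)
    storage.mode(alleles) <- "integer"
    if (missing_rate > 0) {
      miss <- matrix(runif(length(alleles)) < missing_rate, nrow = n_segregants)
      alleles[miss] <- NA_integer_
    }
    meta <- do.call(rbind, lapply(seq_along(chrom_lengths), function(ci) {
      L <- chrom_lengths[ci]
      data.frame(chrom = paste0("chr", ci),
                 pos = seq_len(L) * as.integer(marker_spacing),
                 name = sprintf("c%02d_m%04d", ci, seq_len(L)),
                 stringsAsFactors = FALSE)
    }))
    genotype_matrix(alleles, meta, sprintf("seg%04d", seq_len(n_segregants)))
  })
}

#' Describe the planted genetic architecture of a simulated cross
#'
#' @param qtl Data frame with columns `marker` (marker name or column index)
#'   and `effect` (additive shift, in phenotype percent units, carried by the
#'   laboratory allele; negative values make the vineyard allele the
#'   increasing one).
#' @param baseline Phenotype (percent of fluorescent cells with foci) of a
#'   strain carrying the vineyard allele at every planted locus.
#' @param noise_sd Residual standard deviation, percent units.
#' @return An object of class `cross_truth`.
#' @export
cross_truth <- function(qtl, baseline = 6, noise_sd = 2) {
  qtl <- as.data.frame(qtl)
  stopifnot(all(c("marker", "effect") %in% names(qtl)))
  if (!all(is.finite(qtl$effect))) stop("effects must be finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (baseline + sum(pmax(qtl$effect, 0)) > 100)
    stop("baseline plus positive effects exceeds 100 percent")
  structure(list(qtl = qtl, baseline = baseline, noise_sd = noise_sd),
            class = "cross_truth")
}

resolve_markers <- function(geno, markers) {
  idx <- if (is.numeric(markers)) as.integer(markers)
         else match(as.character(markers), geno$marker_meta$name)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > ncol(geno$alleles)))
    stop("qtl marker index out of range")
  idx
}

#' Simulate additive QTL phenotypes for a cross
#'
#' Each replicate phenotype is `baseline + sum(effect * [allele == L]) +
#' Gaussian noise`, clamped to \[0, 100\] (the phenotype is a percentage).
#' A strain missing the genotype at a planted locus receives no contribution
#' from that locus. The strain phenotype is the mean of its replicates.
#'
#' @param geno A [genotype_matrix()].
#' @param truth A [cross_truth()].
#' @param n_replicates Replicates per strain (each with independent noise).
#' @param seed Integer seed.
#' @return A `phenotype_table`: data frame with columns `strain`,
#'   `percent_foci`, `n_replicates`, and a `replicates` list-column.
#' @export
simulate_phenotypes <- function(geno, truth, n_replicates = 1L, seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(truth, "cross_truth"))
  idx <- resolve_markers(geno, truth$qtl$marker)
  n <- nrow(geno$alleles)
  genetic <- rep(truth$baseline, n)
  for (k in seq_along(idx)) {
    a <- geno$alleles[, idx[k]]
    contrib <- ifelse(is.na(a), 0, (a == 0L) * truth$qtl$effect[k])
    genetic <- genetic + contrib
  }
  with_seed(seed, {
    reps <- matrix(rep(genetic, n_replicates) +
                     rnorm(n * n_replicates, 0, truth$noise_sd),
                   nrow = n)
    reps <- pmin(pmax(reps, 0), 100)
    phenotype_table(geno$strain_ids, rowMeans(reps),
                    replicates = split(reps, row(reps)))
  })
}

#' Assemble a phenotype table
#'
#' @param strain Strain identifiers.
#' @param percent_foci Percent of fluorescent cells with foci, in \[0, 100\]
#'   (NA allowed for strains where the statistic is undefined).
#' @param replicates Optional list of per-strain replicate values; when
#'   present, `percent_foci` must equal the replicate mean.
#' @return Data frame of class `phenotype_table`.
#' @export
phenotype_table <- function(strain, percent_foci, replicates = NULL) {
  ok <- !is.na(percent_foci)
  if (any(percent_foci[ok] < 0 | percent_foci[ok] > 100))
    stop("percent_foci outside [0, 100]")
  percent_foci <- unname(percent_foci)
  if (is.null(replicates)) replicates <- as.list(percent_foci)
  replicates <- unname(lapply(replicates, unname))
  stopifnot(length(replicates) == length(strain))
  mns <- vapply(replicates, function(r) mean(r[!is.na(r)]), numeric(1L))
  if (any(abs(mns[ok] - percent_foci[ok]) > 1e-8))
    stop("percent_foci must equal the mean of replicate values")
  d <- data.frame(strain = as.character(strain), percent_foci = percent_foci,
                  n_replicates = lengths(replicates), stringsAsFactors = FALSE)
  d$replicates <- replicates
  class(d) <- c("phenotype_table", "data.frame")
  d
}

#' Expected parental phenotypes under a planted architecture
#'
#' Noise-free expectations for the two parents: the laboratory parent carries
#' the L allele at every planted locus, the vineyard parent the V allele.
#'
#' @param truth A [cross_truth()].
#' @return Named numeric vector `c(lab = ..., vineyard = ...)`.
#' @export
parental_phenotypes <- function(truth) {
  stopifnot(inherits(truth, "cross_truth"))
  c(lab = min(max(truth$baseline + sum(truth$qtl$effect), 0), 100),
    vineyard = truth$baseline)
}
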