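# Plain-text table dialect: tab-separated, metadata in leading '#key=value'
# lines so every output records the seed and configuration it came from.

write_meta_tsv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(package = "aggscan",
                 version = as.character(utils::packageVersion("aggscan"))), meta)
  for (k in names(meta))
    writeLines(sprintf("#%s=%s", k, format(meta[[k]])), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_meta_tsv <- function(path, colClasses = NA) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#", "", lines[h])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          sep = "\t", header = TRUE, colClasses = colClasses,
                          stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Write a genotype matrix to tab-separated text
#'
#' One row per marker: `chrom`, `pos`, `name`, then one allele code per
#' strain (`L` laboratory, `V` vineyard, `N` missing). Metadata (seed,
#' version) is carried in leading `#key=value` lines.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output file.
#' @param meta Named list of extra metadata to record.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(geno, path, meta = list()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  codes <- matrix(c("L", "V")[geno$alleles + 1L], nrow = nrow(geno$alleles))
  codes[is.na(geno$alleles)] <- "N"
  df <- cbind(geno$marker_meta[, c("chrom", "pos", "name")],
              as.data.frame(t(codes), stringsAsFactors = FALSE))
  names(df) <- c("chrom", "pos", "name", geno$strain_ids)
  write_meta_tsv(df, path, meta)
}

#' Read a genotype matrix from tab-separated text
#'
#' @param path File written by [write_genotypes()] (or conforming to the
#'   same dialect). Unknown allele codes raise an error naming the marker
#'   row and strain column.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  df <- read_meta_tsv(path, colClasses = "character")
  stopifnot(all(c("chrom", "pos", "name") %in% names(df)))
  strains <- setdiff(names(df), c("chrom", "pos", "name"))
  codes <- as.matrix(df[, strains, drop = FALSE])
  bad <- which(matrix(!(codes %in% c("L", "V", "N")), nrow(codes)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unknown allele code '%s' at marker row %d, strain column '%s'",
                 codes[bad[1, 1], bad[1, 2]], bad[1, 1], strains[bad[1, 2]]))
  alleles <- t(matrix(match(codes, c("L", "V")) - 1L, nrow = nrow(codes)))
  genotype_matrix(alleles,
                  data.frame(chrom = df$chrom, pos = as.numeric(df$pos),
                             name = df$name, stringsAsFactors = FALSE),
                  strains)
}

#' Write a phenotype table to tab-separated text
#'
#' Columns: `strain`, `percent_foci`, `n_replicates`, then one column per
#' replicate (ragged rows padded with NA).
#'
#' @param pheno A `phenotype_table`.
#' @param path Output file.
#' @param meta Named list of extra metadata.
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(pheno, path, meta = list()) {
  stopifnot(inherits(pheno, "phenotype_table"))
  k <- max(pheno$n_replicates)
  reps <- do.call(rbind, lapply(pheno$replicates,
                                function(r) c(r, rep(NA_real_, k - length(r)))))
  df <- data.frame(strain = pheno$strain,
                   percent_foci = pheno$percent_foci,
                   n_replicates = pheno$n_replicates)
  df[paste0("rep", seq_len(k))] <- as.data.frame(reps)
  write_meta_tsv(df, path, meta)
}

#' Read a phenotype table from tab-separated text
#'
#' @param path File written by [write_phenotypes()]. Percent values outside
#'   \[0, 100\] raise a validation error naming the strain.
#' @return A `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  df <- read_meta_tsv(path)
  stopifnot(all(c("strain", "percent_foci") %in% names(df)))
  bad <- which(!is.na(df$percent_foci) &
                 (df$percent_foci < 0 | df$percent_foci > 100))
  if (length(bad) > 0)
    stop(sprintf("percent_foci %g for strain '%s' outside [0, 100]",
                 df$percent_foci[bad[1]], df$strain[bad[1]]))
  repcols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  reps <- if (length(repcols) > 0) {
    lapply(seq_len(nrow(df)), function(i) {
      r <- as.numeric(df[i, repcols])
      r[!is.na(r)]
    })
  } else NULL
  phenotype_table(df$strain, df$percent_foci, replicates = reps)
}

#' Write a linkage scan, FDR table or peak calls to TSV
#'
#' @param x A `linkage_scan`, `fdr_table` or `peak_calls` object.
#' @param path Output file.
#' @param meta Named list of extra metadata.
#' @return The path, invisibly.
#' @export
write_scan <- function(x, path, meta = list()) {
  write_meta_tsv(as.data.frame(x), path, meta)
}

#' Read a table written by [write_scan()]
#'
#' @param path Input file.
#' @param class Class to restore (`"linkage_scan"`, `"fdr_table"`,
#'   `"peak_calls"`, or `NULL` for a plain data frame).
#' @return The table with its class restored.
#' @export
read_scan <- function(path, class = "linkage_scan") {
  df <- read_meta_tsv(path)
  if (!is.null(class)) class(df) <- c(class, "data.frame")
  df
}

#' Write a micrograph as 16-bit grayscale TIFF or PNG
#'
#' Intensities are rounded to integer detector numbers (clipped to
#' \[0, 65535\]); the pixel scale is stored in a JSON sidecar file
#' (`<path>.json`) so that a re-read image keeps its physical calibration.
#'
#' @param img A [micrograph()].
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return The path, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  v <- pmin(pmax(round(img$pixels), 0), 65535) / 65535
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(v, path)
  } else {
    tiff::writeTIFF(v, path, bits.per.sample = 16)
  }
  jsonlite::write_json(list(pixel_size = img$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a micrograph from TIFF or PNG
#'
#' @param path Image path; 8- or 16-bit grayscale.
#' @param pixel_size um/pixel; if `NULL`, taken from the `<path>.json`
#'   sidecar written by [write_micrograph()].
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size = NULL) {
  if (is.null(pixel_size)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("pixel_size missing: give it explicitly or provide the JSON sidecar")
    pixel_size <- jsonlite::read_json(sidecar)$pixel_size
  }
  v <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  micrograph(round(v * 65535), pixel_size)
}

#' Write ground truth or configuration as JSON
#'
#' @param x A `field_truth`, `cross_truth` or plain list.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_truth <- function(x, path) {
  jsonlite::write_json(list(type = class(x)[1L], data = unclass(x)), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null")
  invisible(path)
}

#' Read ground truth written by [write_truth()]
#'
#' @param path Input file.
#' @return The reconstructed object.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$data
  switch(obj$type,
    cross_truth = cross_truth(as.data.frame(d$qtl), d$baseline, d$noise_sd),
    field_truth = field_truth(as.data.frame(d$cells), d$fluorescent,
                              as.data.frame(d$foci), d$image_shape,
                              d$pixel_size, d$background_level, d$noise_sd,
                              d$dic_amplitude, d$diffuse_level, d$focus_peak,
                              d$edge_blur_px),
    d)
}
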