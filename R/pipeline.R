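#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the simulate -> quantify -> scan -> fdr ->
#' peaks pipeline. All randomness flows from the single `seed`, expanded
#' into per-stage substreams so stages are individually reproducible.
#'
#' @param seed Global integer seed.
#' @param n_segregants,chrom_lengths,recomb_prob,missing_rate Cross
#'   simulation (see [simulate_cross()]); ignored when `geno_file` is given.
#' @param qtl,baseline,noise_sd Planted architecture (see [cross_truth()]);
#'   ignored when `pheno_file` is given.
#' @param n_replicates Replicates per strain.
#' @param phenotype_source `"direct"` takes phenotypes straight from the
#'   simulator; `"imaging"` renders micrograph fields per strain whose
#'   planted foci fraction equals the simulated phenotype, quantifies them
#'   with the imaging pipeline, and uses the measured values.
#' @param fields_per_strain,cells_per_field,field_shape,pixel_size,field_noise_sd
#'   Imaging-mode field geometry and noise.
#' @param segmentation A [segmentation_params()].
#' @param prune A [prune_params()].
#' @param n_perm,fdr_ceiling Permutation FDR settings.
#' @param geno_file,pheno_file Optional input tables to ingest instead of
#'   simulating (formats of [write_genotypes()] / [write_phenotypes()]).
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_segregants = 120L,
                            chrom_lengths = rep(10L, 15L),
                            recomb_prob = 0.1,
                            missing_rate = 0.005,
                            qtl = data.frame(marker = c(25, 95), effect = c(6, 4)),
                            baseline = 6,
                            noise_sd = 2,
                            n_replicates = 1L,
                            phenotype_source = c("direct", "imaging"),
                            fields_per_strain = 2L,
                            cells_per_field = 60L,
                            field_shape = c(320L, 320L),
                            pixel_size = 0.2,
                            field_noise_sd = 60,
                            segmentation = segmentation_params(),
                            prune = prune_params(),
                            n_perm = 100L,
                            fdr_ceiling = 0.12,
                            geno_file = NULL,
                            pheno_file = NULL,
                            out_dir = tempfile("aggscan_run_")) {
  structure(list(seed = as.integer(seed), n_segregants = n_segregants,
                 chrom_lengths = chrom_lengths, recomb_prob = recomb_prob,
                 missing_rate = missing_rate, qtl = as.data.frame(qtl),
                 baseline = baseline, noise_sd = noise_sd,
                 n_replicates = n_replicates,
                 phenotype_source = match.arg(phenotype_source),
                 fields_per_strain = fields_per_strain,
                 cells_per_field = cells_per_field,
                 field_shape = field_shape, pixel_size = pixel_size,
                 field_noise_sd = field_noise_sd,
                 segmentation = segmentation, prune = prune,
                 n_perm = n_perm, fdr_ceiling = fdr_ceiling,
                 geno_file = geno_file, pheno_file = pheno_file,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Quantify one strain by rendering and measuring `n_fields` synthetic
# fields whose planted foci fraction equals `target_pct`.
measure_strain_by_imaging <- function(target_pct, config, params, seed) {
  reps <- vapply(seq_len(config$fields_per_strain), function(f) {
    tr <- simulate_field_truth(config$cells_per_field,
                               frac_with_foci = target_pct / 100,
                               image_shape = config$field_shape,
                               pixel_size = config$pixel_size,
                               seed = seed + f,
                               noise_sd = config$field_noise_sd)
    imgs <- render_field(tr, seed = seed + f)
    quantify_field(imgs$dic, imgs$gfp, params)$phenotype$percent_foci
  }, numeric(1L))
  aggregate_replicates(reps)
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> quantify -> marker QC -> scan -> fdr ->
#' peaks, writing every stage's table under `config$out_dir` with seed and
#' config-hash metadata, and returns a run manifest with per-stage wall
#' times and output checksums. Input files are validated before any stage
#' runs; a failing stage aborts with its name, earlier outputs preserved.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$geno_file, config$pheno_file))
    if (!file.exists(f)) stop(sprintf("input file not found: %s", f))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(lapply(unclass(config), unclass), cfg_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  # hash the scientific configuration only (not the output location)
  hcfg <- unclass(config); hcfg$out_dir <- NULL
  htmp <- tempfile()
  jsonlite::write_json(lapply(hcfg, unclass), htmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  cfg_hash <- unname(tools::md5sum(htmp))
  unlink(htmp)
  meta <- list(seed = config$seed, config_md5 = cfg_hash)
  times <- c(); outputs <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    times[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  emit <- function(obj, file, writer) {
    p <- file.path(config$out_dir, file)
    writer(obj, p, meta)
    outputs <<- c(outputs, p)
    p
  }

  geno <- stage("simulate", {
    if (!is.null(config$geno_file)) read_genotypes(config$geno_file)
    else simulate_cross(config$n_segregants, config$chrom_lengths,
                        config$recomb_prob, config$missing_rate,
                        seed = substream_seed(config$seed, "simulate"))
  })
  emit(geno, "genotypes.tsv", write_genotypes)

  pheno <- stage("phenotype", {
    if (!is.null(config$pheno_file)) read_phenotypes(config$pheno_file)
    else {
      truth <- cross_truth(config$qtl, config$baseline, config$noise_sd)
      sim <- simulate_phenotypes(geno, truth, config$n_replicates,
                                 seed = substream_seed(config$seed, "phenotype"))
      if (config$phenotype_source == "imaging") {
        params <- config$segmentation
        if (is.null(params$fluor_threshold)) {
          ctrl_truth <- simulate_field_truth(
            config$cells_per_field, frac_with_foci = 0.5,
            image_shape = config$field_shape, pixel_size = config$pixel_size,
            seed = substream_seed(config$seed, "field"),
            noise_sd = config$field_noise_sd)
          params <- calibrate_thresholds(
            render_field(ctrl_truth, seed = substream_seed(config$seed, "field")),
            params)
        }
        fseed <- substream_seed(config$seed, "field")
        measured <- lapply(seq_len(nrow(sim)), function(i)
          measure_strain_by_imaging(sim$percent_foci[i], config, params,
                                    seed = (fseed + i * 131L) %% 2147483647L))
        phenotype_table(sim$strain,
                        vapply(measured, `[[`, numeric(1L), "percent_foci"),
                        replicates = lapply(measured, `[[`, "replicates"))
      } else sim
    }
  })
  emit(pheno, "phenotypes.tsv", write_phenotypes)

  qc <- stage("prune", prune_markers(geno, config$prune))
  emit(qc$removed, "markers_removed.tsv",
       function(o, p, m) write_meta_tsv(o, p, m))
  emit(qc$geno, "genotypes_pruned.tsv", write_genotypes)

  scan <- stage("scan", linkage_scan(qc$geno, pheno))
  emit(scan, "scan.tsv", write_scan)

  fdr <- stage("fdr", permutation_fdr(qc$geno, pheno, n_perm = config$n_perm,
                                      seed = config$seed))
  emit(fdr, "fdr.tsv", write_scan)

  peaks <- stage("peaks", call_peaks(scan, fdr, config$fdr_ceiling))
  emit(peaks, "peaks.tsv", write_scan)

  manifest <- list(config = cfg_path, config_md5 = cfg_hash,
                   seed = config$seed,
                   version = as.character(utils::packageVersion("aggscan")),
                   outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                                      basename(outputs)),
                   wall_time_s = as.list(times))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(c(manifest, list(scan = scan, fdr = fdr, peaks = peaks,
                             pheno = pheno, geno = qc$geno, removed = qc$removed)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("aggscan run (seed %d, config %s)\n", x$seed, substr(x$config_md5, 1, 8)))
  for (s in names(x$wall_time_s))
    cat(sprintf("  %-10s %6.2fs\n", s, x$wall_time_s[[s]]))
  cat(sprintf("%d peak(s) called\n", nrow(x$peaks)))
  invisible(x)
}

#' Bundled demonstration configuration
#'
#' Two planted QTL on different chromosomes in a 120-segregant, 150-marker
#' cross, matching the package's worked example.
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A [pipeline_config()].
#' @export
demo_config <- function(seed = 1, out_dir = tempfile("aggscan_demo_"), ...) {
  pipeline_config(seed = seed,
                  n_segregants = 120L, chrom_lengths = rep(10L, 15L),
                  qtl = data.frame(marker = c(25, 95), effect = c(6, 4)),
                  baseline = 6, noise_sd = 2, out_dir = out_dir, ...)
}
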