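test_that("simulated cross genotypes have meiotic linkage structure", {
  # no recombination: each chromosome is a single parental block per strain
  g0 <- simulate_cross(50, c(8, 8), recomb_prob = 0, seed = 1)
  for (ch in c("chr1", "chr2")) {
    A <- g0$alleles[, g0$marker_meta$chrom == ch]
    expect_true(all(apply(A, 1, function(r) length(unique(r)) == 1L)))
  }
  # free recombination: adjacent markers uncorrelated
  g5 <- simulate_cross(5000, c(10), recomb_prob = 0.5, seed = 2)
  r2 <- sapply(1:9, function(j) cor(g5$alleles[, j], g5$alleles[, j + 1])^2)
  expect_true(all(r2 < 0.01))
  # allele frequencies near 1/2
  g1 <- simulate_cross(1000, c(20), recomb_prob = 0.1, seed = 3)
  expect_true(all(abs(colMeans(g1$alleles) - 0.5) < 0.05))
  g5k <- simulate_cross(5000, c(20), recomb_prob = 0.1, seed = 4)
  expect_true(all(abs(colMeans(g5k$alleles) - 0.5) < 0.03))
  # Markov property: empirical switch frequency tracks recomb_prob
  sw <- mean(g5k$alleles[, -1] != g5k$alleles[, -20])
  expect_lt(abs(sw - 0.1), 0.02)
})

test_that("cross simulation is seeded and validates its inputs", {
  a <- simulate_cross(30, c(5, 5), missing_rate = 0.1, seed = 9)
  b <- simulate_cross(30, c(5, 5), missing_rate = 0.1, seed = 9)
  expect_identical(a$alleles, b$alleles)
  expect_error(simulate_cross(0, c(5)), "non-positive")
  expect_error(simulate_cross(10, c(5), recomb_prob = 0.7), "0.5")
  expect_error(simulate_cross(10, c(0)), ">= 1")
})

test_that("phenotypes follow the planted additive model", {
  g <- simulate_cross(60, c(10), recomb_prob = 0.2, seed = 5)
  tr <- cross_truth(data.frame(marker = 4, effect = 10), baseline = 5, noise_sd = 0)
  ph <- simulate_phenotypes(g, tr, seed = 1)
  expect_setequal(unique(ph$percent_foci), c(5, 15))
  expect_equal(ph$percent_foci, unname(ifelse(g$alleles[, 4] == 0L, 15, 5)))
  # missing genotype at the QTL contributes nothing
  g2 <- g; g2$alleles[1, 4] <- NA_integer_
  ph2 <- simulate_phenotypes(g2, tr, seed = 1)
  expect_equal(ph2$percent_foci[1], 5)
  expect_error(cross_truth(data.frame(marker = 1, effect = Inf)), "finite")
  expect_error(simulate_phenotypes(g, cross_truth(data.frame(marker = 99, effect = 1))),
               "out of range")
})

test_that("antagonistic planted alleles yield transgressive segregation", {
  # enumerate the four two-locus classes: with one L-increasing and one
  # V-increasing effect, some segregants exceed both parents
  g <- simulate_cross(200, c(10, 10), recomb_prob = 0.3, seed = 6)
  tr <- cross_truth(data.frame(marker = c(3, 14), effect = c(8, -6)),
                    baseline = 12, noise_sd = 0)
  ph <- simulate_phenotypes(g, tr, seed = 1)
  par <- parental_phenotypes(tr)
  expect_equal(unname(par), c(12 + 8 - 6, 12))
  expect_setequal(unique(ph$percent_foci), c(12, 12 + 8, 12 - 6, 12 + 2))
  expect_gt(max(ph$percent_foci), max(par))
  expect_lt(min(ph$percent_foci), min(par))
})

test_that("a planted effect reproduces its expected variance explained", {
  # effect e over a fair Bernoulli allele contributes e^2/4 variance;
  # e and noise chosen so the single-locus R^2 expectation is 0.38
  sd_n <- 2; v_tot <- sd_n^2 / (1 - 0.38)
  e <- 2 * sqrt(0.38 * v_tot)
  g <- simulate_cross(500, c(25, 25), recomb_prob = 0.15, seed = 7)
  tr <- cross_truth(data.frame(marker = 10, effect = e), baseline = 10, noise_sd = sd_n)
  ph <- simulate_phenotypes(g, tr, seed = 8)
  r2 <- cor(g$alleles[, 10], ph$percent_foci)^2
  expect_lt(abs(r2 - 0.38), 0.05)
})

test_that("replicate phenotypes average to the strain value and stay in range", {
  g <- simulate_cross(40, c(6), seed = 10)
  tr <- cross_truth(data.frame(marker = 2, effect = 5), baseline = 3, noise_sd = 4)
  ph <- simulate_phenotypes(g, tr, n_replicates = 5L, seed = 11)
  expect_true(all(ph$n_replicates == 5L))
  means <- vapply(ph$replicates, mean, numeric(1))
  expect_equal(ph$percent_foci, means)
  expect_true(all(unlist(ph$replicates) >= 0 & unlist(ph$replicates) <= 100))
})

test_that("rendered fields match their planted truth", {
  # empty field: pure background plus noise
  tr0 <- field_truth(data.frame(cx = numeric(), cy = numeric(),
                                ax = numeric(), ay = numeric()),
                     logical(), image_shape = c(64L, 64L), noise_sd = 0)
  im0 <- render_field(tr0)
  expect_true(all(im0$dic$pixels == tr0$background_level))
  expect_true(all(im0$gfp$pixels == tr0$background_level))
  # planted 3-of-8 fluorescent-with-foci arithmetic
  tr <- simulate_field_truth(20, frac_fluorescent = 0.4, frac_with_foci = 3 / 8,
                             image_shape = c(340L, 340L), seed = 2)
  expect_equal(truth_percent_foci(tr), 37.5)
  # focus FWHM matches the planted diameter (1 um at 0.2 um/px -> 5 px)
  trf <- field_truth(data.frame(cx = 50, cy = 50, ax = 12, ay = 12), TRUE,
                     data.frame(cell = 1, x = 50, y = 50, diameter_um = 1),
                     image_shape = c(100L, 100L), noise_sd = 0)
  im <- render_field(trf)
  base <- render_field(field_truth(trf$cells, TRUE, NULL,
                                   image_shape = c(100L, 100L), noise_sd = 0))
  spot <- im$gfp$pixels - base$gfp$pixels
  width <- sum(spot[50, ] > max(spot) / 2)
  expect_lt(abs(width - 5), 1.5)
  # determinism
  trn <- simulate_field_truth(10, image_shape = c(200L, 200L), seed = 3, noise_sd = 50)
  expect_identical(render_field(trn, seed = 4), render_field(trn, seed = 4))
})

test_that("field truth enforces its invariants", {
  cells <- data.frame(cx = 30, cy = 30, ax = 10, ay = 10)
  expect_error(field_truth(cells, FALSE,
                           data.frame(cell = 1, x = 30, y = 30, diameter_um = 1),
                           image_shape = c(64L, 64L)),
               "non-fluorescent")
  expect_error(field_truth(cells, TRUE,
                           data.frame(cell = 1, x = 30, y = 30, diameter_um = 3),
                           image_shape = c(64L, 64L)),
               "oversize")
  expect_error(field_truth(data.frame(cx = 5, cy = 5, ax = 10, ay = 10), TRUE,
                           image_shape = c(64L, 64L)),
               "inside")
  expect_error(micrograph(matrix(numeric(), 0, 0), 0.2), "zero-size")
})

test_that("noiseless GFP regions are conserved: one per fluorescent cell, one focus each", {
  tr <- simulate_field_truth(24, frac_fluorescent = 0.5, frac_with_foci = 0.5,
                             image_shape = c(360L, 360L), seed = 12, noise_sd = 0)
  im <- render_field(tr, seed = 12)
  bright <- EBImage::bwlabel((im$gfp$pixels > tr$background_level + 20) * 1L)
  expect_equal(max(bright), sum(tr$fluorescent))
  hp <- highpass_puncta_filter(im$gfp, segmentation_params())
  spots <- EBImage::bwlabel((hp$pixels > tr$focus_peak / 2) * 1L)
  expect_equal(max(spots), nrow(tr$foci))
})

test_that("aggregate fields realise requested areas and densities", {
  f <- render_aggregate_field(50, image_shape = c(128L, 128L), pixel_size = 0.26,
                              seed = 1)
  px <- sum(f$labels == 1L)
  expect_lt(abs(px - 50 / 0.26^2) / (50 / 0.26^2), 0.05)
  f0 <- render_aggregate_field(numeric(), image_shape = c(64L, 64L), seed = 1)
  expect_true(all(f0$labels == 0L))
  f2 <- render_aggregate_field(c(10, 100), image_shape = c(256L, 256L),
                               pixel_size = 0.26, seed = 2)
  expect_equal(bin_aggregate_sizes(f2)$fraction_small, 0.5)
  expect_error(render_aggregate_field(rep(400, 50), image_shape = c(96L, 96L),
                                      pixel_size = 0.26, seed = 3),
               "overlap")
})
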