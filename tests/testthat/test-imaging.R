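test_that("locally adaptive threshold follows the local mean + k*sd rule", {
  flat <- matrix(7, 32, 32)
  expect_false(any(local_adaptive_threshold(flat, 9, offset_k = 1)))
  # single bright pixel: exactly that pixel segments
  m <- matrix(10, 31, 31); m[16, 16] <- 200
  mask <- local_adaptive_threshold(m, 9, offset_k = 1)
  expect_true(mask[16, 16])
  expect_equal(sum(mask), 1L)
  # shift invariance
  r <- matrix(runif(900, 0, 50), 30, 30)
  expect_identical(local_adaptive_threshold(r, 7, 1.5),
                   local_adaptive_threshold(r + 123.4, 7, 1.5))
  expect_error(local_adaptive_threshold(r, 8, 1), "odd")
  expect_error(local_adaptive_threshold(r, 51, 1), "larger than image")
})

test_that("high-pass filter passes puncta and suppresses broad features", {
  p <- segmentation_params()
  const <- micrograph(matrix(40, 64, 64), 0.2)
  expect_true(all(highpass_puncta_filter(const, p)$pixels == 0))
  # 1 um spot vs 4 um blob of equal peak: filtered peak ratio >= 3
  spot_img <- function(fwhm_um) {
    s <- (fwhm_um / 0.2) / (2 * sqrt(2 * log(2)))
    g <- 100 * exp(-outer((1:129 - 65)^2, (1:129 - 65)^2, `+`) / (2 * s^2))
    micrograph(g + 10, 0.2)
  }
  pk1 <- max(highpass_puncta_filter(spot_img(1), p)$pixels)
  pk4 <- max(highpass_puncta_filter(spot_img(4), p)$pixels)
  expect_gte(pk1 / pk4, 3)
  # DC invariance
  r <- micrograph(matrix(runif(4096, 0, 100), 64, 64), 0.2)
  r2 <- micrograph(r$pixels + 55, 0.2)
  expect_equal(highpass_puncta_filter(r2, p)$pixels,
               highpass_puncta_filter(r, p)$pixels, tolerance = 1e-8)
})

test_that("cell detection recovers planted cells and applies size filters", {
  p <- segmentation_params()
  flat <- micrograph(matrix(100, 128, 128), 0.2)
  expect_equal(nrow(detect_cells(flat, p)$cells), 0L)
  tr <- simulate_field_truth(20, image_shape = c(340L, 340L), seed = 21, noise_sd = 0)
  im <- render_field(tr, seed = 21)
  cells <- detect_cells(im$dic, p)
  expect_equal(nrow(cells$cells), 20L)
  for (i in seq_len(20)) {
    truth_mask <- aggscan:::cell_mask(tr, i)
    lab <- cells$labels[round(tr$cells$cy[i]), round(tr$cells$cx[i])]
    expect_gt(lab, 0)
    overlap <- sum(cells$labels == lab & truth_mask) / sum(truth_mask)
    expect_gte(overlap, 0.8)
  }
  # an object below min_cell_area is rejected (1 um blob ~ 0.8 um^2 < 3)
  tiny <- matrix(100, 128, 128)
  tiny[60:62, 60:62] <- 400
  expect_equal(nrow(detect_cells(micrograph(tiny, 0.2), p)$cells), 0L)
})

test_that("foci are assigned to the right cells and obey the 2 um rule", {
  p <- calibrated_params()
  tr <- simulate_field_truth(12, frac_fluorescent = 1, frac_with_foci = 0.25,
                             image_shape = c(280L, 280L), seed = 22, noise_sd = 0)
  im <- render_field(tr, seed = 22)
  cells <- detect_foci(im$gfp, detect_cells(im$dic, p), p)
  expect_equal(nrow(cells$foci), nrow(tr$foci))
  # each detected focus sits on a distinct planted focus, and its assigned
  # cell mask contains that planted focus's cell centre
  nearest <- vapply(seq_len(nrow(cells$foci)), function(i) {
    d <- sqrt((tr$foci$x - cells$foci$cx[i])^2 + (tr$foci$y - cells$foci$cy[i])^2)
    expect_lt(min(d), 3)
    which.min(d)
  }, integer(1))
  expect_setequal(nearest, seq_len(nrow(tr$foci)))
  for (i in seq_len(nrow(cells$foci))) {
    planted_cell <- tr$foci$cell[nearest[i]]
    lab_at_centre <- cells$labels[round(tr$cells$cy[planted_cell]),
                                  round(tr$cells$cx[planted_cell])]
    expect_equal(cells$foci$cell_id[i], lab_at_centre)
  }
  expect_true(all(cells$foci$equiv_diameter_um <= p$puncta_max_diameter))
  # oversize blob is diffuse, never a focus
  tr3 <- field_truth(data.frame(cx = 100, cy = 100, ax = 12, ay = 12), TRUE,
                     data.frame(cell = 1, x = 100, y = 100, diameter_um = 3),
                     image_shape = c(200L, 200L), allow_oversize = TRUE)
  im3 <- render_field(tr3, seed = 1)
  c3 <- detect_foci(im3$gfp, detect_cells(im3$dic, p), p)
  expect_equal(nrow(c3$foci), 0L)
  # blank GFP channel
  blank <- micrograph(matrix(100, 280, 280), 0.2)
  cb <- detect_foci(blank, detect_cells(im$dic, p), p)
  expect_equal(sum(cb$cells$n_foci), 0L)
})

test_that("fluorescence classification and diffuse means follow the contract", {
  # hand-built pair: one disk cell, uniform diffuse level inside
  d <- 240; bg <- 100
  disk <- outer((1:120 - 60)^2, (1:120 - 60)^2, `+`) <= 15^2
  dic <- micrograph(bg + 300 * disk, 0.2)
  gfp <- micrograph(bg + (d - bg) * disk, 0.2)
  p <- segmentation_params(fluor_threshold = 170)
  cells <- detect_diffuse(gfp, detect_foci(gfp, detect_cells(dic, p), p), p)
  expect_equal(nrow(cells$cells), 1L)
  expect_true(cells$cells$is_fluorescent[1])
  expect_identical(cells$cells$diffuse_mean[1], d)
  # non-fluorescent cell
  gfp0 <- micrograph(matrix(bg, 120, 120), 0.2)
  c0 <- detect_diffuse(gfp0, detect_foci(gfp0, detect_cells(dic, p), p), p)
  expect_false(c0$cells$is_fluorescent[1])
  # focus pixels are excluded from the diffuse mean (rendered field)
  trf <- field_truth(data.frame(cx = 60, cy = 60, ax = 14, ay = 14), TRUE,
                     data.frame(cell = 1, x = 60, y = 60, diameter_um = 1),
                     image_shape = c(120L, 120L), noise_sd = 0, edge_blur_px = 0)
  imf <- render_field(trf)
  pf <- calibrated_params()
  cf <- detect_diffuse(imf$gfp, detect_foci(imf$gfp, detect_cells(imf$dic, pf), pf), pf)
  expect_equal(cf$cells$n_foci[1], 1L)
  expected_diffuse <- trf$background_level + trf$diffuse_level
  expect_lt(abs(cf$cells$diffuse_mean[1] - expected_diffuse) / expected_diffuse, 0.05)
  expect_error(detect_diffuse(gfp, detect_cells(dic, p), p), "detect_foci")
  expect_error(detect_diffuse(gfp, detect_foci(gfp, detect_cells(dic, p), p),
                              segmentation_params()),
               "fluor_threshold")
})

test_that("threshold calibration is deterministic and self-consistent", {
  tr <- simulate_field_truth(100, frac_fluorescent = 0.7, frac_with_foci = 0.5,
                             image_shape = c(640L, 640L), seed = 11, noise_sd = 120)
  ctrl <- render_field(tr, seed = 11)
  p1 <- calibrate_thresholds(ctrl)
  p2 <- calibrate_thresholds(ctrl)
  expect_identical(p1, p2)
  meas <- quantify_field(ctrl$dic, ctrl$gfp, p1)$phenotype$percent_foci
  expect_lt(abs(meas - truth_percent_foci(tr)), 5)
  # a control with no fluorescent cells cannot calibrate
  dark <- simulate_field_truth(20, frac_fluorescent = 0, frac_with_foci = 0,
                               image_shape = c(340L, 340L), seed = 13)
  expect_error(calibrate_thresholds(render_field(dark, seed = 13)),
               "no fluorescent cells")
})

test_that("percent_foci and replicate aggregation follow their contracts", {
  fake <- function(is_fl, nf) {
    structure(list(cells = data.frame(cell_id = seq_along(is_fl),
                                      is_fluorescent = is_fl, n_foci = nf)),
              class = "cell_set")
  }
  r <- percent_foci(fake(rep(c(TRUE, FALSE), c(40, 10)),
                         rep(c(1L, 0L), c(10, 40))))
  expect_equal(r$percent_foci, 25)
  expect_equal(percent_foci(fake(rep(TRUE, 5), rep(2L, 5)))$percent_foci, 100)
  expect_true(is.na(percent_foci(fake(rep(FALSE, 6), rep(0L, 6)))$percent_foci))

  expect_equal(aggregate_replicates(c(10, 20, 30))$percent_foci, 20)
  expect_equal(aggregate_replicates(42)$percent_foci, 42)
  withna <- aggregate_replicates(c(10, NA, 20))
  expect_equal(withna$percent_foci, 15)
  expect_equal(withna$n_undefined, 1L)
  expect_error(aggregate_replicates(numeric()), "at least one")
})

test_that("diffuse intensity is uncorrelated with foci status under the null", {
  expect_error(diffuse_vs_foci_correlation(1:10, rep(5, 10)), "zero variance")
  expect_equal(diffuse_vs_foci_correlation(1:10, 1:10), 1)
  set.seed(31)
  r <- replicate(20, diffuse_vs_foci_correlation(rnorm(30, 200, 20),
                                                 runif(30, 0, 40)))
  expect_lt(median(abs(r)), 0.2)
})

test_that("maximum projection equals the per-pixel brute-force maximum", {
  one <- micrograph(matrix(runif(400), 20, 20), 0.26)
  expect_equal(max_project(list(one))$pixels, one$pixels)
  zero <- micrograph(matrix(0, 20, 20), 0.26)
  expect_equal(max_project(list(one, zero))$pixels, one$pixels)
  set.seed(7)
  stack <- lapply(1:14, function(i) micrograph(matrix(runif(400, 0, 1000), 20, 20), 0.26))
  brute <- matrix(0, 20, 20)
  for (y in 1:20) for (x in 1:20)
    brute[y, x] <- max(vapply(stack, function(s) s$pixels[y, x], numeric(1)))
  expect_equal(max_project(stack)$pixels, brute)
  expect_error(max_project(list()), "empty")
  expect_error(max_project(list(one, micrograph(matrix(1, 5, 5), 0.26))),
               "mismatched")
})

test_that("every cell with foci is fluorescent and counts are DC-invariant", {
  p <- calibrated_params()
  tr <- simulate_field_truth(40, frac_fluorescent = 0.6, frac_with_foci = 0.4,
                             image_shape = c(420L, 420L), seed = 23, noise_sd = 120)
  im <- render_field(tr, seed = 23)
  q <- quantify_field(im$dic, im$gfp, p)
  expect_true(all(q$cells$is_fluorescent[q$cells$n_foci > 0]))
  shifted <- quantify_field(micrograph(im$dic$pixels + 75, 0.2),
                            micrograph(im$gfp$pixels + 75, 0.2), p)
  expect_equal(nrow(shifted$cells), nrow(q$cells))
  expect_equal(nrow(shifted$foci), nrow(q$foci))
})
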