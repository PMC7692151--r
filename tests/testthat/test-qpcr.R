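test_that("standard-curve fit recovers exact log-linear standards", {
  std <- data.frame(concentration = c(1e6, 1e5, 1e4),
                    ct = c(15, 18.3219, 21.6438))
  curve <- fit_standard_curve(std, assay = "total_16S")
  expect_equal(curve$slope, -3.3219, tolerance = 1e-4)
  expect_equal(curve$efficiency, 1.00, tolerance = 1e-3)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
  # closed-form agreement on another exact line
  std2 <- data.frame(concentration = 10^(2:8), ct = 40 - 3.5 * (2:8))
  c2 <- fit_standard_curve(std2)
  expect_equal(c2$slope, -3.5, tolerance = 1e-9)
  expect_equal(c2$intercept, 40, tolerance = 1e-9)
})

test_that("standard-curve fit validates input and flags poor efficiency", {
  expect_error(fit_standard_curve(data.frame(concentration = c(1e4, 1e5),
                                             ct = c(20, 17))), "3 distinct")
  expect_error(fit_standard_curve(data.frame(concentration = c(0, 1e4, 1e5),
                                             ct = c(30, 20, 17))), "positive")
  # symmetric duplicate noise leaves the slope unchanged
  base <- data.frame(concentration = 10^(3:6), ct = 38 - 3.4 * (3:6))
  noisy <- rbind(transform(base, ct = ct + 0.4),
                 transform(base, ct = ct - 0.4))
  expect_equal(fit_standard_curve(noisy)$slope, -3.4, tolerance = 1e-9)
  # a shallow slope implies efficiency > 1.2 and warns
  shallow <- data.frame(concentration = 10^(3:6), ct = 30 - 2.0 * (3:6))
  expect_warning(fit_standard_curve(shallow), "efficiency")
})

test_that("quantification follows the anchors of the log-linear model", {
  std <- data.frame(concentration = 10^(2:8), ct = 38 - 3.3219 * (2:8))
  curve <- fit_standard_curve(std, assay = "total_16S")
  # mean Ct at the intercept, 20-fold dilution: 20 units
  r <- quantify(c(curve$intercept, curve$intercept), curve,
                dilution_factor = 20, ct_cutoff = 45)
  expect_equal(r$concentration, 20, tolerance = 1e-9)
  # one log10 step along the slope: 10 units at dilution 1
  r2 <- quantify(rep(curve$intercept + curve$slope, 2), curve,
                 dilution_factor = 1, ct_cutoff = 45)
  expect_equal(r2$concentration, 10, tolerance = 1e-9)
  # both duplicates censored
  r3 <- quantify(c(39.2, NA), curve, ct_cutoff = 38)
  expect_false(r3$detected)
  expect_true(is.na(r3$concentration))
  # discordant duplicates flagged, not dropped
  r4 <- quantify(c(30, 31.5), curve, ct_cutoff = 38)
  expect_true(r4$detected)
  expect_true(r4$discordant)
  # monotonicity: lower Ct, strictly higher concentration
  cts <- seq(35, 20, by = -1)
  concs <- vapply(cts, function(ct)
    quantify(c(ct, ct), curve, ct_cutoff = 38)$concentration, numeric(1))
  expect_true(all(diff(concs) > 0))
})

test_that("quantify inverts the qPCR simulator exactly at zero noise", {
  curve <- fit_standard_curve(
    data.frame(concentration = 10^(2:8), ct = 38 - 3.3219 * (2:8)))
  for (conc in 10^(2:11)) {
    ct <- simulate_qpcr(conc, curve, dilution_factor = 20, noise_sd = 0,
                        ct_cutoff = 38)
    r <- quantify(ct, curve, dilution_factor = 20, ct_cutoff = 38)
    expect_equal(r$concentration, conc, tolerance = 1e-9)
  }
  expect_identical(simulate_qpcr(0, curve), c(NA_real_, NA_real_))
  # tenfold increase moves Ct by exactly the slope at zero noise
  c1 <- simulate_qpcr(1e6, curve, 20, noise_sd = 0)
  c2 <- simulate_qpcr(1e7, curve, 20, noise_sd = 0)
  expect_equal(c2 - c1, rep(curve$slope, 2), tolerance = 1e-9)
})

test_that("load ratios follow their definition and censoring rules", {
  b <- data.frame(sample_id = "S1", assay = "total_16S",
                  concentration = 1e8, detected = TRUE)
  h <- data.frame(sample_id = "S1", assay = "human_cyc1",
                  concentration = 1e6, detected = TRUE)
  expect_equal(load_ratio(b, h)$ratio, 100)
  expect_equal(load_ratio(h, h)$ratio, 1)
  # invariant to common rescaling
  b2 <- transform(b, concentration = concentration * 37)
  h2 <- transform(h, concentration = concentration * 37)
  expect_equal(load_ratio(b2, h2)$ratio, 100)
  bc <- transform(b, detected = FALSE, concentration = NA_real_)
  r <- load_ratio(bc, h)
  expect_equal(r$ratio, 0)
  expect_true(r$below_detection)
  hc <- transform(h, detected = FALSE)
  expect_error(load_ratio(b, hc), "not detected")
})

test_that("group medians honour the non-detect policy", {
  meta <- sample_metadata(data.frame(sample_id = paste0("S", 1:3),
                                     group = "NL"))
  res <- data.frame(sample_id = paste0("S", 1:3),
                    concentration = c(1, NA, 3), detected = c(TRUE, FALSE, TRUE))
  d <- group_median_summary(res, meta, policy = "detected-only")
  expect_equal(d$median, 2)
  expect_equal(d$n_detected, 2)
  z <- group_median_summary(res, meta, policy = "zero-impute")
  expect_equal(z$median, 1)
  res2 <- data.frame(sample_id = paste0("S", 1:3),
                     concentration = c(1, 2, 3), detected = TRUE)
  expect_equal(group_median_summary(res2, meta)$median, 2)
  expect_error(group_median_summary(
    data.frame(sample_id = "X9", concentration = 1, detected = TRUE), meta),
    "missing from metadata")
})

test_that("plate files round-trip and quantify end to end", {
  cc <- generate_cohort(cohort_config(n_per_group = c(AV = 3, BV = 3, NL = 3),
                                      seed = 5))
  plate <- cc$qpcr_plates$total_16S
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qpcr_plate(plate, path)
  back <- read_qpcr_plate(path)
  expect_equal(back$standards$ct, plate$standards$ct, tolerance = 1e-9)
  expect_identical(back$samples$sample_id, plate$samples$sample_id)
  q1 <- quantify_plate(plate)
  q2 <- quantify_plate(back)
  expect_equal(q1$concentration, q2$concentration, tolerance = 1e-9)
  expect_s3_class(attr(q1, "curve"), "standard_curve")
  expect_true(all(q1$concentration[q1$detected] > 0))
})
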