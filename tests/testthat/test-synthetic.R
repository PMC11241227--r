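test_that("the generator is deterministic and respects n_samples", {
  cfg <- small_config(n_samples = 50, n_points = 80)
  a <- generate_dataset(cfg, seed = 12)
  b <- generate_dataset(cfg, seed = 12)
  expect_equal(nrow(a$records), 50L)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(cfg, seed = 13)
  expect_false(identical(a$spectra$absorbance, c$spectra$absorbance))
})

test_that("default composition and trait moments match the emulated study", {
  ds <- generate_dataset(synthetic_config(n_samples = 1736, n_points = 60),
                         seed = 8)
  r <- ds$records
  n <- nrow(r)
  # 3-standard-error stochastic bands around the target moments
  expect_lt(abs(mean(r$fat_pct) - 7.87), 3 * 1.19 / sqrt(n))
  expect_lt(abs(sd(r$fat_pct) - 1.19), 3 * 1.19 / sqrt(2 * n))
  rct <- r$rct_min[!is.na(r$rct_min)]
  expect_lt(abs(mean(rct) - 17.71), 3 * 3.75 / sqrt(length(rct)))
  expect_lt(abs(sd(rct) - 3.75), 3 * 3.75 / sqrt(2 * length(rct)) + 0.08)
})

test_that("composition moments converge to the configured values (LLN)", {
  cfg <- synthetic_config(n_samples = 10000, n_points = 40)
  ds <- generate_dataset(cfg, seed = 14)
  comp <- cfg$composition
  for (i in seq_len(nrow(comp))) {
    v <- ds$records[[comp$name[i]]]
    # slight shrinkage from range truncation is absorbed by the 3 SE + 2% slack
    expect_lt(abs(mean(v) - comp$mean[i]),
              3 * comp$sd[i] / sqrt(10000) + 0.02 * comp$mean[i])
    expect_lt(abs(sd(v) - comp$sd[i]),
              3 * comp$sd[i] / sqrt(20000) + 0.03 * comp$sd[i])
  }
  # protein and casein are correlated as configured
  expect_equal(cor(ds$records$protein_pct, ds$records$casein_pct), 0.8,
               tolerance = 0.05)
})

test_that("censoring is consistent with the latent coagulation time", {
  ds <- generate_dataset(synthetic_config(n_samples = 2000, n_points = 40),
                         seed = 15)
  cens <- ds$records$coagulated == 0L
  expect_true(all(ds$truth$rct_min_signal[cens] > 30))
  expect_true(all(ds$truth$rct_min_signal[!cens] < 30))
  expect_true(all(is.na(ds$records$rct_min[cens])))
  expect_true(all(is.na(ds$records$a30_mm[cens])))
})

test_that("spectra reflect the configured constituent bands", {
  cfg <- synthetic_config(n_samples = 150, noise_sd = 0.0005)
  ds <- generate_dataset(cfg, seed = 16)
  wn <- ds$spectra$wavenumbers
  # absorbance at the lactose 1045 band correlates with lactose content
  j <- which.min(abs(wn - 1045))
  expect_gt(cor(ds$spectra$absorbance[, j], ds$records$lactose_pct), 0.2)
  jf <- which.min(abs(wn - 1743))
  expect_gt(cor(ds$spectra$absorbance[, jf], ds$records$fat_pct), 0.5)
})

test_that("invalid generator configurations are rejected with the offending field", {
  expect_error(synthetic_config(n_samples = 0), "n_samples")
  expect_error(synthetic_config(noise_sd = -1), "SDs")
  expect_error(synthetic_config(censor_rate = 1.2), "censor_rate")
})

test_that("outlier injection is local and validated", {
  ds <- generate_dataset(small_config(n_samples = 60, n_points = 100), seed = 17)
  same <- inject_outliers(ds, 0, 0)
  expect_identical(same$spectra$absorbance, ds$spectra$absorbance)
  expect_identical(same$records, ds$records)

  planted <- inject_outliers(ds, n_spectral = 3, n_chemical = 3,
                             magnitude = 10, seed = 99)
  expect_length(planted$planted$spectral_ids, 3)
  expect_length(planted$planted$chemical_ids, 3)
  untouched <- setdiff(ds$records$sample_id,
                       unlist(planted$planted))
  expect_identical(planted$spectra$absorbance[untouched, ],
                   ds$spectra$absorbance[untouched, ])
  expect_identical(planted$records[match(untouched, planted$records$sample_id), ],
                   ds$records[match(untouched, ds$records$sample_id), ])
  expect_error(inject_outliers(ds, 1, 0, magnitude = 0), "magnitude")
  expect_error(inject_outliers(ds, 40, 40, magnitude = 1), "more planted")
})

test_that("a planted 10-SD chemical outlier exceeds the T threshold", {
  ds <- generate_dataset(small_config(n_samples = 250, n_points = 250), seed = 18)
  ds <- inject_outliers(ds, n_spectral = 0, n_chemical = 1, magnitude = 10,
                        seed = 7)
  id <- ds$planted$chemical_ids
  keep <- filter_noncoagulating(ds$records)$retained
  if (!id %in% keep$sample_id) skip("planted sample was censored")
  sp <- mask_regions(subset_samples(ds$spectra, keep$sample_id))
  res <- t_outlier_rounds(sp$absorbance, keep$a30_mm, seed = 4, max_factors = 8)
  r1 <- res$log[res$log$stage == "T1", ]
  expect_gt(r1$statistic[r1$sample_id == id], 3)
  expect_true(id %in% res$removed_ids)
})

test_that("the noiseless limit is recovered end to end", {
  ds <- generate_dataset(noiseless_config(n_samples = 300), seed = 19)
  for (tr in c("rct_min", "k20_min", "a30_mm")) {
    res <- trait_pipeline(ds$spectra, ds$records, tr,
                          preprocess_spec("none", "0,0,1,1"), seed = 21)
    expect_gt(res$stats$r2_exv, 0.99)
  }
})

test_that("achieved R2 decreases as trait noise grows", {
  r2 <- vapply(c(0, 6, 20), function(ns) {
    cfg <- small_config(n_samples = 220, n_points = 250)
    cfg$trait_model$a30_mm$noise_sd <- ns
    ds <- generate_dataset(cfg, seed = 22)
    trait_pipeline(ds$spectra, ds$records, "a30_mm",
                   preprocess_spec("SNV", "0,0,1,1"), seed = 23,
                   outlier_removal = FALSE, max_factors = 8)$stats$r2_exv
  }, 0)
  expect_true(all(diff(r2) < 0))
})

test_that("noise calibration hits an easy target in the easy limit", {
  cfg <- small_config(n_samples = 220, n_points = 200,
                      mult_sd = 0.005, baseline_offset_sd = 0.001,
                      baseline_slope_sd = 0.001, baseline_curvature_sd = 0.001,
                      noise_sd = 5e-4, water_noise_sd = 0.001)
  out <- calibrate_noise_for_target(cfg, target_r2 = 0.85, trait = "a30_mm",
                                    tol = 0.05, seeds = 1, max_iter = 8,
                                    outlier_removal = FALSE, max_factors = 8)
  expect_lt(attr(out, "noise_sd"), cfg$trait_model$a30_mm$noise_sd)
  expect_equal(attr(out, "achieved_r2"), 0.85, tolerance = 0.06)
  expect_error(
    calibrate_noise_for_target(cfg, target_r2 = 0.999999, trait = "a30_mm",
                               tol = 1e-7, seeds = 1, max_iter = 2,
                               outlier_removal = FALSE, max_factors = 8),
    "unreachable")
})

test_that("scatter correction protects against multiplicative artifacts", {
  seeds <- 1:10
  gain <- vapply(seeds, function(s) {
    cfg <- small_config(n_samples = 200, n_points = 250, mult_sd = 0.25,
                        baseline_offset_sd = 0.08)
    ds <- generate_dataset(cfg, seed = s + 300)
    r2 <- vapply(c("none", "SNV"), function(sc) {
      trait_pipeline(ds$spectra, ds$records, "a30_mm",
                     preprocess_spec(sc, "0,0,1,1"), seed = s,
                     outlier_removal = FALSE, max_factors = 8)$stats$r2_exv
    }, 0)
    r2["SNV"] - r2["none"]
  }, 0)
  # SNV beats raw spectra on average and in a clear majority of replicates
  expect_gt(mean(gain), 0)
  expect_gte(sum(gain > 0), 6L)
})

test_that("synthetic datasets export through the standard tables", {
  ds <- generate_dataset(small_config(n_samples = 20, n_points = 50), seed = 30)
  fs <- tempfile(fileext = ".csv")
  ft <- tempfile(fileext = ".csv")
  write_dataset(ds, fs, ft)
  sp <- read_spectra(fs)
  rec <- read_traits(ft)
  expect_equal(sp$absorbance, ds$spectra$absorbance, tolerance = 1e-12)
  expect_equal(rec$a30_mm, ds$records$a30_mm, tolerance = 1e-12)
  unlink(c(fs, ft))
})
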