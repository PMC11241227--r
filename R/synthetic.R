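#' Configuration for the synthetic milk-spectra generator
#'
#' Default values emulate the statistical structure of a bulk-milk MIR study:
#' composition distributions (truncated normals at the published
#' calibration-set moments: fat 7.87 +/- 1.19, protein 4.64 +/- 0.35, casein
#' 3.68 +/- 0.36, lactose 4.64 +/- 0.18 percent; SCC lognormal with mean
#' 181.54 and SD 274.08 cells/uL), constituent absorption bands at the
#' wavenumbers reported for milk MIR spectra (lactose near 1045/1076/1157/1250
#' cm^-1, protein near 1550, fat near 1390/1454/1743/2862/2927), strong noisy
#' water bands inside the masked regions, per-sample additive/multiplicative
#' scatter artifacts, coagulation traits linear in the latent composition, and
#' a 3.38% noncoagulation rate censored at the 30-min test limit.
#'
#' Trait noise SDs are expressed directly in trait units; the defaults were
#' set with [calibrate_noise_for_target()] so the full pipeline lands in the
#' low-predictability regime typical of coagulation traits.
#'
#' @param n_samples number of samples (default 1736).
#' @param seed default seed used by [generate_dataset()] when none is given.
#' @param n_points,axis_lo,axis_hi wavenumber grid (1060 points, 900-5000
#'   cm^-1).
#' @param composition data.frame(name, mean, sd, min, max) of the truncated
#'   normal composition distributions (percent w/w).
#' @param protein_casein_cor correlation between protein and casein.
#' @param scc_meanlog,scc_sdlog,scc_min,scc_max lognormal SCC parameters.
#' @param bands data.frame(constituent, center, width, amplitude): Gaussian
#'   absorption bands, amplitude in absorbance units per percent constituent.
#' @param water_bands data.frame(center, width, amplitude, jitter_sd):
#'   water-absorption bands with per-sample amplitude jitter.
#' @param water_noise_sd extra absorbance noise inside the default water
#'   regions.
#' @param baseline_offset_sd,baseline_slope_sd,baseline_curvature_sd per-sample
#'   additive baseline artifacts.
#' @param mult_sd SD of the per-sample multiplicative scatter factor.
#' @param noise_sd spectral noise SD (absorbance units).
#' @param trait_model named list per trait: `intercept`, `coef` (named vector
#'   on centred composition), `noise_sd`, `min`, `max`.
#' @param censor_rate fraction of noncoagulating samples (default 0.0338).
#' @param censor_threshold coagulation test limit in minutes (default 30).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_samples = 1736L,
    seed = 1L,
    n_points = 1060L, axis_lo = 900, axis_hi = 5000,
    composition = data.frame(
      name = c("fat_pct", "protein_pct", "casein_pct", "lactose_pct"),
      mean = c(7.87, 4.64, 3.68, 4.64),
      sd   = c(1.19, 0.35, 0.36, 0.18),
      min  = c(3.99, 3.15, 2.54, 3.69),
      max  = c(11.86, 7.53, 4.89, 5.18),
      stringsAsFactors = FALSE),
    protein_casein_cor = 0.8,
    scc_meanlog = 4.6078, scc_sdlog = 1.0898, scc_min = 11, scc_max = 3486,
    bands = data.frame(
      constituent = c(rep("lactose_pct", 4), "protein_pct",
                      rep("casein_pct", 2), rep("fat_pct", 5)),
      center = c(1045, 1076, 1157, 1250, 1550, 975, 1550,
                 1390, 1454, 1743, 2862, 2927),
      width  = c(18, 16, 20, 25, 30, 20, 30, 18, 18, 14, 24, 24),
      amplitude = c(0.060, 0.045, 0.035, 0.025, 0.035, 0.035, 0.050,
                    0.020, 0.022, 0.050, 0.038, 0.042),
      stringsAsFactors = FALSE),
    water_bands = data.frame(
      center = c(1640, 2120, 3350),
      width  = c(55, 130, 160),
      amplitude = c(1.2, 0.45, 1.0),
      jitter_sd = c(0.08, 0.08, 0.08)),
    water_noise_sd = 0.02,
    baseline_offset_sd = 0.02, baseline_slope_sd = 0.010,
    baseline_curvature_sd = 0.010,
    mult_sd = 0.05, noise_sd = 0.002,
    trait_model = list(
      rct_min = list(intercept = 17.71,
                     coef = c(casein_pct = -5.5, fat_pct = 1.5),
                     noise_sd = 2.70, min = 7.37, max = 29.45),
      k20_min = list(intercept = 3.29,
                     coef = c(casein_pct = -1.8, fat_pct = -0.34),
                     noise_sd = 0.846, min = 0.37, max = 7.15),
      a30_mm  = list(intercept = 38.83,
                     coef = c(casein_pct = 25, protein_pct = 8),
                     noise_sd = 8.2, min = 0.98, max = 73.84)),
    censor_rate = 0.0338, censor_threshold = 30) {
  cfg <- list(n_samples = as.integer(n_samples), seed = as.integer(seed),
              n_points = as.integer(n_points), axis_lo = axis_lo,
              axis_hi = axis_hi, composition = composition,
              protein_casein_cor = protein_casein_cor,
              scc_meanlog = scc_meanlog, scc_sdlog = scc_sdlog,
              scc_min = scc_min, scc_max = scc_max,
              bands = bands, water_bands = water_bands,
              water_noise_sd = water_noise_sd,
              baseline_offset_sd = baseline_offset_sd,
              baseline_slope_sd = baseline_slope_sd,
              baseline_curvature_sd = baseline_curvature_sd,
              mult_sd = mult_sd, noise_sd = noise_sd,
              trait_model = trait_model,
              censor_rate = censor_rate,
              censor_threshold = censor_threshold)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  bad <- character(0)
  if (cfg$n_samples < 1L) bad <- c(bad, "n_samples must be >= 1")
  sds <- c(cfg$composition$sd, cfg$water_noise_sd, cfg$baseline_offset_sd,
           cfg$baseline_slope_sd, cfg$baseline_curvature_sd, cfg$mult_sd,
           cfg$noise_sd, vapply(cfg$trait_model, `[[`, 0, "noise_sd"))
  if (any(sds < 0)) bad <- c(bad, "all SDs must be >= 0")
  if (any(cfg$bands$center < cfg$axis_lo | cfg$bands$center > cfg$axis_hi)) {
    bad <- c(bad, "band centers must lie on the axis")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    bad <- c(bad, "censor_rate must be in [0, 1)")
  }
  if (length(bad)) stop("invalid synthetic_config: ", paste(bad, collapse = "; "))
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic_config: n = %d, %d points %.0f-%.0f cm^-1, censor %.2f%%\n",
              x$n_samples, x$n_points, x$axis_lo, x$axis_hi,
              100 * x$censor_rate))
  invisible(x)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Generate a synthetic milk MIR dataset
#'
#' Draws per-sample composition from truncated normals (protein and casein
#' correlated), builds each absorbance spectrum as a Beer-Lambert sum of
#' Gaussian constituent bands scaled by concentration, adds jittered water
#' bands with extra in-band noise, a per-sample quadratic baseline, a
#' multiplicative scatter factor, and white spectral noise. Coagulation traits
#' are linear functions of the latent composition plus Gaussian noise,
#' truncated to the published trait ranges; a configured fraction of samples
#' is noncoagulating (noise-free RCT beyond the 30-min test limit) and carries
#' censored (NA) coagulation traits. Fully reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list of class `synthetic_dataset`: `spectra` ([milk_spectra()]),
#'   `records` (sample-record data.frame, see [validate_records()]), and
#'   `truth` (data.frame of latent composition and noise-free traits).
#' @export
generate_dataset <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  with_local_seed(seed, {
    n <- config$n_samples
    ids <- sprintf("BM%05d", seq_len(n))
    comp <- config$composition
    cvals <- list()
    for (i in seq_len(nrow(comp))) {
      nm <- comp$name[i]
      if (nm == "casein_pct") next
      cvals[[nm]] <- rtruncnorm(n, comp$mean[i], comp$sd[i],
                                comp$min[i], comp$max[i])
    }
    # casein correlated with protein
    pc <- comp[comp$name == "protein_pct", ]
    cc <- comp[comp$name == "casein_pct", ]
    rho <- config$protein_casein_cor
    zc <- rho * (cvals$protein_pct - pc$mean) / pc$sd +
      sqrt(1 - rho^2) * stats::rnorm(n)
    casein <- cc$mean + cc$sd * zc
    casein <- pmin(pmax(casein, cc$min), cc$max)
    cvals$casein_pct <- casein
    scc <- pmin(pmax(stats::rlnorm(n, config$scc_meanlog, config$scc_sdlog),
                     config$scc_min), config$scc_max)

    # spectra
    wn <- default_axis(config$n_points, config$axis_lo, config$axis_hi)
    chem <- matrix(0, n, length(wn))
    for (i in seq_len(nrow(config$bands))) {
      b <- config$bands[i, ]
      prof <- b$amplitude * exp(-0.5 * ((wn - b$center) / b$width)^2)
      chem <- chem + tcrossprod(cvals[[b$constituent]], prof)
    }
    for (i in seq_len(nrow(config$water_bands))) {
      b <- config$water_bands[i, ]
      prof <- b$amplitude * exp(-0.5 * ((wn - b$center) / b$width)^2)
      amp <- 1 + b$jitter_sd * stats::rnorm(n)
      chem <- chem + tcrossprod(amp, prof)
    }
    u <- (wn - mean(range(wn))) / (diff(range(wn)) / 2)   # in [-1, 1]
    baseline <- tcrossprod(stats::rnorm(n, 0, config$baseline_offset_sd),
                           rep(1, length(wn))) +
      tcrossprod(stats::rnorm(n, 0, config$baseline_slope_sd), u) +
      tcrossprod(stats::rnorm(n, 0, config$baseline_curvature_sd), u^2)
    mult <- 1 + stats::rnorm(n, 0, config$mult_sd)
    absorb <- chem * mult + baseline +
      matrix(stats::rnorm(n * length(wn), 0, config$noise_sd), n)
    wr <- water_regions()
    in_water <- rep(FALSE, length(wn))
    for (i in seq_len(nrow(wr))) {
      in_water <- in_water | (wn >= wr[i, "lo"] & wn <= wr[i, "hi"])
    }
    if (any(in_water) && config$water_noise_sd > 0) {
      absorb[, in_water] <- absorb[, in_water] +
        matrix(stats::rnorm(n * sum(in_water), 0, config$water_noise_sd), n)
    }
    spectra <- milk_spectra(absorb, wn, sample_ids = ids)

    # traits: linear in centred composition + noise, truncated to trait range
    comp_means <- stats::setNames(comp$mean, comp$name)
    truth <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    for (nm in names(cvals)) truth[[nm]] <- cvals[[nm]]
    obs <- list()
    for (tr in names(config$trait_model)) {
      tm <- config$trait_model[[tr]]
      signal <- rep(tm$intercept, n)
      for (cn in names(tm$coef)) {
        signal <- signal + tm$coef[[cn]] * (cvals[[cn]] - comp_means[[cn]])
      }
      noisy <- if (tm$noise_sd > 0) {
        vapply(signal, function(s) rtruncnorm(1L, s, tm$noise_sd,
                                              tm$min, tm$max), 0)
      } else {
        pmin(pmax(signal, tm$min), tm$max)
      }
      truth[[paste0(tr, "_signal")]] <- signal
      obs[[tr]] <- noisy
    }

    # noncoagulation: independent regime with noise-free RCT beyond the limit
    nc <- stats::runif(n) < config$censor_rate
    truth$rct_min_signal[nc] <- config$censor_threshold +
      stats::rexp(sum(nc), rate = 1 / 3) + 0.01
    truth$rct_min_signal <- pmin(truth$rct_min_signal,
                                 ifelse(nc, Inf, config$censor_threshold - 0.01))
    for (tr in COAG_TRAITS) obs[[tr]][nc] <- NA_real_
    truth$coagulated <- as.integer(!nc)

    records <- data.frame(
      sample_id = ids,
      rct_min = obs$rct_min, k20_min = obs$k20_min, a30_mm = obs$a30_mm,
      fat_pct = cvals$fat_pct, protein_pct = cvals$protein_pct,
      casein_pct = cvals$casein_pct, lactose_pct = cvals$lactose_pct,
      scc_cells_ul = scc, coagulated = as.integer(!nc),
      stringsAsFactors = FALSE)
    validate_records(records)
    structure(list(spectra = spectra, records = records, truth = truth,
                   config = config, seed = seed),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples (%d noncoagulating), seed %d\n",
              nrow(x$records), sum(x$records$coagulated == 0L), x$seed))
  invisible(x)
}

#' Plant known outliers in a synthetic dataset
#'
#' Spectral outliers receive a gross baseline distortion (offset plus tilt and
#' a broad spurious band); chemical outliers have every observed coagulation
#' trait shifted by `magnitude` trait SDs. All other rows are untouched.
#'
#' @param dataset a [generate_dataset()] result.
#' @param n_spectral,n_chemical how many of each to plant (disjoint sets).
#' @param magnitude distortion size: absorbance offset scale for spectral
#'   outliers, trait-SD multiples for chemical outliers. Must be > 0.
#' @param seed integer seed for choosing the planted samples.
#' @return The dataset with `planted` added: list(`spectral_ids`,
#'   `chemical_ids`).
#' @export
inject_outliers <- function(dataset, n_spectral = 0L, n_chemical = 0L,
                            magnitude = 10, seed = dataset$seed + 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (magnitude <= 0) stop("magnitude must be > 0")
  n <- nrow(dataset$records)
  if (n_spectral + n_chemical > n) stop("more planted outliers than samples")
  if (n_spectral + n_chemical == 0L) {
    dataset$planted <- list(spectral_ids = character(0),
                            chemical_ids = character(0))
    return(dataset)
  }
  with_local_seed(seed, {
    pick <- sample(dataset$records$sample_id, n_spectral + n_chemical)
    sp_ids <- pick[seq_len(n_spectral)]
    ch_ids <- setdiff(pick, sp_ids)
    wn <- dataset$spectra$wavenumbers
    u <- (wn - min(wn)) / diff(range(wn))
    for (id in sp_ids) {
      center <- stats::runif(1, min(wn) + 300, max(wn) - 300)
      distort <- magnitude * 0.05 *
        (1 + u + 2 * exp(-0.5 * ((wn - center) / 150)^2))
      dataset$spectra$absorbance[id, ] <- dataset$spectra$absorbance[id, ] + distort
    }
    for (tr in COAG_TRAITS) {
      sdv <- stats::sd(dataset$records[[tr]], na.rm = TRUE)
      rows <- dataset$records$sample_id %in% ch_ids &
        !is.na(dataset$records[[tr]])
      dataset$records[[tr]][rows] <- dataset$records[[tr]][rows] +
        magnitude * sdv
    }
    dataset$planted <- list(spectral_ids = sp_ids, chemical_ids = ch_ids)
    dataset
  })
}

#' Calibrate trait noise to a target prediction difficulty
#'
#' Bisects the noise SD of one trait until the mean external-validation R2 of
#' the full pipeline (censor filter, water masking, balanced split, scatter
#' correction + math treatment, outlier elimination, cross-validated mPLS,
#' external validation), averaged over several generator seeds, is within
#' `tol` of `target_r2`. Achieved R2 is monotone decreasing in the noise SD,
#' so bisection is well posed.
#'
#' @param config a [synthetic_config()]; its `n_samples` sets the problem size
#'   used during calibration.
#' @param target_r2 target external-validation R2, in (0, 1).
#' @param trait one of `"rct_min"`, `"k20_min"`, `"a30_mm"`.
#' @param tol acceptable |mean R2 - target| (default 0.05).
#' @param seeds generator seeds averaged over (default 1:3).
#' @param spec [preprocess_spec()] used in the evaluation pipeline; defaults
#'   to the identity treatment with SNV.
#' @param max_iter bisection iterations cap.
#' @param upper_mult upper bisection bound as a multiple of the trait's total
#'   SD implied by the config.
#' @param ... further arguments passed to [trait_pipeline()].
#' @return The adjusted `synthetic_config`, with attributes `achieved_r2` and
#'   `noise_sd`.
#' @export
calibrate_noise_for_target <- function(config, target_r2, trait, tol = 0.05,
                                       seeds = 1:3,
                                       spec = preprocess_spec("SNV", "0,0,1,1"),
                                       max_iter = 12L, upper_mult = 3,
                                       ...) {
  stopifnot(target_r2 > 0, target_r2 < 1,
            trait %in% names(config$trait_model))
  eval_r2 <- function(noise_sd) {
    cfg <- config
    cfg$trait_model[[trait]]$noise_sd <- noise_sd
    r2 <- vapply(seeds, function(s) {
      ds <- generate_dataset(cfg, seed = s)
      res <- trait_pipeline(ds$spectra, ds$records, trait, spec,
                            seed = substream_seed(s, paste0("cal_", trait)),
                            ...)
      res$stats$r2_exv
    }, 0)
    mean(r2)
  }
  tm <- config$trait_model[[trait]]
  sd_total <- sqrt(tm$noise_sd^2 +
                     sum(vapply(names(tm$coef), function(cn) {
                       (tm$coef[[cn]] *
                          config$composition$sd[config$composition$name == cn])^2
                     }, 0)))
  lo <- 0
  hi <- upper_mult * sd_total
  r2_lo <- eval_r2(lo)
  if (r2_lo < target_r2 - tol) {
    stop(sprintf(
      "target R2 %.2f unreachable: noiseless pipeline achieves only %.2f",
      target_r2, r2_lo))
  }
  r2_hi <- eval_r2(hi)
  if (r2_hi > target_r2 + tol) {
    stop(sprintf(
      "target R2 %.2f unreachable: bracket [%.3g, %.3g] gives R2 [%.2f, %.2f]",
      target_r2, lo, hi, r2_hi, r2_lo))
  }
  mid <- tm$noise_sd
  achieved <- NA_real_
  for (i in seq_len(max_iter)) {
    achieved <- eval_r2(mid)
    if (abs(achieved - target_r2) <= tol / 2) break
    if (achieved > target_r2) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
  }
  config$trait_model[[trait]]$noise_sd <- mid
  attr(config, "achieved_r2") <- achieved
  attr(config, "noise_sd") <- mid
  config
}

#' Write a synthetic dataset to the standard tables
#'
#' @param dataset a [generate_dataset()] result.
#' @param spectra_path,traits_path output paths for the spectral and trait
#'   tables.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, spectra_path, traits_path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  write_spectra(dataset$spectra, spectra_path)
  write_traits(dataset$records, traits_path)
  invisible(c(spectra = spectra_path, traits = traits_path))
}
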