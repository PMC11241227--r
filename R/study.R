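#' Study configuration
#'
#' Bundles every setting of the full modelling study: the water-region mask,
#' the scatter-correction and math-treatment grids, the traits to model, the
#' split fraction, cross-validation folds, outlier thresholds, and the
#' latent-factor cap. All randomness in a study flows from the single
#' top-level `seed`, split into deterministic per-trait, per-stage substreams,
#' so a study (or any single trait of it) reruns bit-identically.
#'
#' @param traits trait columns to model.
#' @param scatter_grid scatter corrections to sweep.
#' @param math_grid math-treatment codes to sweep.
#' @param regions water regions to mask, see [mask_regions()].
#' @param frac calibration fraction (default 0.75).
#' @param folds cross-validation folds (default 15).
#' @param gh_threshold,t_threshold,t_rounds outlier settings.
#' @param max_factors latent-factor cap (default 16).
#' @param n_candidates candidate splits examined, see
#'   [split_calibration_validation()].
#' @param seed top-level integer seed (required).
#' @return A list of class `study_config`.
#' @export
study_config <- function(traits = COAG_TRAITS,
                         scatter_grid = c("none", "SNV", "D", "SNV+D", "MSC"),
                         math_grid = c("0,0,1,1", "1,4,4,1", "1,8,8,1",
                                       "2,5,5,1", "2,10,10,1"),
                         regions = water_regions(),
                         frac = 0.75, folds = 15L,
                         gh_threshold = 3.0, t_threshold = 3.0, t_rounds = 3L,
                         max_factors = 16L, n_candidates = 200L, seed) {
  if (missing(seed)) stop("a study seed is required")
  if (!length(scatter_grid) || !length(math_grid)) stop("grids must be non-empty")
  if (folds < 2L) stop("folds must be >= 2")
  if (gh_threshold <= 0 || t_threshold <= 0) stop("thresholds must be > 0")
  structure(list(traits = traits, scatter_grid = scatter_grid,
                 math_grid = math_grid, regions = validate_regions(regions),
                 frac = frac, folds = as.integer(folds),
                 gh_threshold = gh_threshold, t_threshold = t_threshold,
                 t_rounds = as.integer(t_rounds),
                 max_factors = as.integer(max_factors),
                 n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run one trait through one preprocessing specification
#'
#' The per-combination unit of [run_study()]: masks the water regions, drops
#' samples without a reference value for the trait, draws the balanced
#' calibration/validation split, applies the scatter correction and math
#' treatment (MSC referenced to the calibration mean spectrum), eliminates
#' Global-H and T-statistic outliers on the calibration set, selects the
#' latent-factor count by 15-fold cross-validation, fits the final mPLS model,
#' and evaluates it on the untouched validation set.
#'
#' @param spectra [milk_spectra()] on the raw axis.
#' @param records sample-record data.frame (noncoagulating samples may still
#'   be present; they are filtered here).
#' @param trait trait column to model.
#' @param spec a [preprocess_spec()].
#' @param seed integer seed governing split, folds, and outlier CV.
#' @param regions water regions (default [water_regions()]).
#' @param frac,folds,n_candidates,gh_threshold,t_threshold,t_rounds,max_factors
#'   as in [study_config()].
#' @param outlier_removal set `FALSE` to skip the outlier stages.
#' @return A list: `stats` ([fit_statistics()]), `cv` ([cross_validate()]
#'   result on the cleaned calibration set), `model` (final [fit_mpls()]),
#'   `outliers` (`outlier_report` or `NULL`), `split`, `spec`, `trait`.
#' @export
trait_pipeline <- function(spectra, records, trait, spec, seed,
                           regions = water_regions(), frac = 0.75,
                           folds = 15L, n_candidates = 200L,
                           gh_threshold = 3.0, t_threshold = 3.0,
                           t_rounds = 3L, max_factors = 16L,
                           outlier_removal = TRUE) {
  keep <- filter_noncoagulating(records)$retained
  keep <- keep[!is.na(keep[[trait]]), , drop = FALSE]
  if (nrow(keep) < 4L * folds) stop("too few samples with '", trait, "' values")
  masked <- mask_regions(subset_samples(spectra, keep$sample_id), regions)

  split <- split_calibration_validation(
    keep, frac = frac, traits = trait,
    seed = substream_seed(seed, paste0("split_", trait)),
    n_candidates = n_candidates)
  cal_sp <- subset_samples(masked, split$cal_ids)
  val_sp <- subset_samples(masked, split$val_ids)
  ref <- if (spec$scatter == "MSC") msc_reference(cal_sp) else NULL
  cal_pp <- apply_preprocess(cal_sp, spec, ref = ref)
  val_pp <- apply_preprocess(val_sp, spec, ref = ref)

  y_cal <- keep[[trait]][match(split$cal_ids, keep$sample_id)]
  y_val <- keep[[trait]][match(split$val_ids, keep$sample_id)]
  X_cal <- cal_pp$absorbance
  X_val <- val_pp$absorbance

  outliers <- NULL
  if (outlier_removal) {
    op <- outlier_pipeline(X_cal, y_cal, gh_threshold = gh_threshold,
                           t_threshold = t_threshold, rounds = t_rounds,
                           folds = folds, max_factors = max_factors,
                           seed = substream_seed(seed, paste0("outl_", trait)))
    X_cal <- op$X
    y_cal <- op$y
    outliers <- op$report
  }

  cv <- cross_validate(X_cal, y_cal, folds = folds, max_factors = max_factors,
                       seed = substream_seed(seed, paste0("cv_", trait)))
  model <- fit_mpls(X_cal, y_cal, n_factors = cv$lf)
  model$axis <- cal_pp$wavenumbers
  model$preprocess <- spec
  y_pred <- predict(model, X_val)
  stats <- fit_statistics(y_val, y_pred, y_ref_cal = y_cal,
                          y_pred_cv = cv$oof[, cv$lf], lf = cv$lf)
  list(stats = stats, cv = cv, model = model, outliers = outliers,
       split = split, spec = spec, trait = trait)
}

#' Run the full modelling study
#'
#' For every trait: censor-filter, balanced 75/25 split, then a sweep over
#' every scatter correction x math treatment combination (outlier
#' elimination, cross-validated mPLS fit, external validation). The winning
#' combination per trait is the one with the lowest cross-validated error
#' (SECV) at its chosen factor count; ties break toward fewer latent factors,
#' then grid order. Choosing on SECV rather than on the validation set keeps
#' the validation statistics honest. A failing combination is logged and
#' skipped; the sweep continues.
#'
#' @param spectra [milk_spectra()] on the raw axis.
#' @param records sample-record data.frame.
#' @param config a [study_config()].
#' @return A list of class `study_report`: per trait a list with `results`
#'   (one row per grid combination: scatter, math, n_cal, lf, sec, secv,
#'   r2_crv, n_val, bias, slope, sep, r2_exv, rpd), `winner` (row index),
#'   `best` (the winning [trait_pipeline()] output), `interpretation`,
#'   `errors`; plus `descriptives` and the `config`.
#' @export
run_study <- function(spectra, records, config) {
  stopifnot(inherits(config, "study_config"))
  grid <- expand.grid(scatter = config$scatter_grid, math = config$math_grid,
                      stringsAsFactors = FALSE)
  traits_out <- list()
  for (trait in config$traits) {
    rows <- list()
    fits <- list()
    errors <- character(0)
    for (g in seq_len(nrow(grid))) {
      spec <- preprocess_spec(grid$scatter[g], grid$math[g])
      res <- tryCatch(
        trait_pipeline(spectra, records, trait, spec,
                       seed = config$seed, regions = config$regions,
                       frac = config$frac, folds = config$folds,
                       n_candidates = config$n_candidates,
                       gh_threshold = config$gh_threshold,
                       t_threshold = config$t_threshold,
                       t_rounds = config$t_rounds,
                       max_factors = config$max_factors),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, sprintf("%s / %s: %s", trait, format(spec),
                                    conditionMessage(res)))
        rows[[g]] <- NULL
        next
      }
      fits[[g]] <- res
      st <- res$stats
      rows[[g]] <- data.frame(
        trait = trait, scatter = grid$scatter[g], math = grid$math[g],
        n_cal = st$n_cal, lf = res$cv$lf, sec = st$sec,
        secv = res$cv$secv[res$cv$lf], r2_crv = st$r2_crv,
        n_val = st$n_val, bias = st$bias, slope = st$slope, sep = st$sep,
        r2_exv = st$r2_exv, rpd = st$rpd, stringsAsFactors = FALSE)
    }
    results <- do.call(rbind, rows)
    if (is.null(results) || !nrow(results)) {
      traits_out[[trait]] <- list(results = NULL, winner = NA_integer_,
                                  best = NULL, interpretation = NULL,
                                  errors = errors)
      next
    }
    ord <- order(results$secv, results$lf, seq_len(nrow(results)))
    winner <- ord[1L]
    best <- fits[[which(!vapply(fits, is.null, TRUE))[winner]]]
    traits_out[[trait]] <- list(
      results = results, winner = winner, best = best,
      interpretation = interpret_model(results$r2_exv[winner],
                                       results$rpd[winner]),
      errors = errors)
  }
  structure(list(traits = traits_out,
                 descriptives = study_descriptives(records, traits_out,
                                                   config),
                 config = config),
            class = "study_report")
}

# Table-1-style descriptive block: per trait per set N, mean, SD, CV, min, max
study_descriptives <- function(records, traits_out, config) {
  out <- list()
  for (trait in names(traits_out)) {
    best <- traits_out[[trait]]$best
    if (is.null(best)) next
    split <- best$split
    for (set in c("calibration", "validation")) {
      ids <- if (set == "calibration") split$cal_ids else split$val_ids
      v <- records[[trait]][match(ids, records$sample_id)]
      v <- v[!is.na(v)]
      out[[paste(trait, set)]] <- data.frame(
        trait = trait, set = set, n = length(v), mean = mean(v),
        sd = stats::sd(v),
        cv = coefficient_of_variation(mean(v), stats::sd(v)),
        min = min(v), max = max(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.study_report <- function(x, ...) {
  for (trait in names(x$traits)) {
    tr <- x$traits[[trait]]
    if (is.null(tr$results)) {
      cat(sprintf("%s: no successful combination\n", trait))
      next
    }
    w <- tr$results[tr$winner, ]
    cat(sprintf(
      "%s: best %s / %s  LF=%d  SEC=%.3g R2CrV=%.2f | SEP=%.3g R2ExV=%.2f RPD=%.2f -> %s\n",
      trait, w$scatter, w$math, w$lf, w$sec, w$r2_crv, w$sep, w$r2_exv,
      w$rpd, tr$interpretation$category))
  }
  invisible(x)
}

#' Write study report tables
#'
#' Emits a descriptive-statistics table (per trait per set: N, mean, SD, CV,
#' min, max), a fitting-statistics table with the conventional 12 columns
#' (trait, N, scatter correction, math treatment, LF, SEC, R2CrV, N_val,
#' bias, slope, SEP, R2ExV, RPD) for the winning model of each trait, a table
#' of every grid combination, and a run log (seed, versions).
#'
#' @param report a [run_study()] result.
#' @param out_dir output directory (created if missing).
#' @param sep field separator (default tab).
#' @return Character vector of the files written, invisibly.
#' @export
report_tables <- function(report, out_dir, sep = "\t") {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  f_desc <- file.path(out_dir, "descriptive_statistics.tsv")
  utils::write.table(report$descriptives, f_desc, sep = sep,
                     row.names = FALSE, quote = FALSE)
  best_rows <- do.call(rbind, lapply(names(report$traits), function(trait) {
    tr <- report$traits[[trait]]
    if (is.null(tr$results)) return(NULL)
    w <- tr$results[tr$winner, ]
    data.frame(trait = trait, n = w$n_cal, scatter_correction = w$scatter,
               mathematical_treatment = w$math, lf = w$lf, sec = w$sec,
               r2_crv = w$r2_crv, n_val = w$n_val, bias = w$bias,
               slope = w$slope, sep = w$sep, r2_exv = w$r2_exv, rpd = w$rpd,
               stringsAsFactors = FALSE)
  }))
  f_fit <- file.path(out_dir, "fitting_statistics.tsv")
  utils::write.table(best_rows, f_fit, sep = sep, row.names = FALSE,
                     quote = FALSE)
  all_rows <- do.call(rbind, lapply(report$traits, `[[`, "results"))
  f_all <- file.path(out_dir, "all_combinations.tsv")
  utils::write.table(all_rows, f_all, sep = sep, row.names = FALSE,
                     quote = FALSE)
  f_log <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("seed: %d", report$config$seed),
    sprintf("traits: %s", paste(report$config$traits, collapse = ", ")),
    sprintf("grid: %d scatter x %d math", length(report$config$scatter_grid),
            length(report$config$math_grid)),
    sprintf("folds: %d; GH > %.1f; T > %.1f (%d rounds); LF cap %d",
            report$config$folds, report$config$gh_threshold,
            report$config$t_threshold, report$config$t_rounds,
            report$config$max_factors),
    sprintf("R version: %s", R.version.string),
    sprintf("coagmir version: %s",
            as.character(utils::packageVersion("coagmir")))),
    f_log)
  invisible(c(f_desc, f_fit, f_all, f_log))
}
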