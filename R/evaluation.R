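#' Balanced calibration/validation split
#'
#' Draws `n_candidates` seeded random splits into a calibration set
#' (`frac` of the samples, 75% by default) and a validation set, and returns
#' the candidate whose per-trait means and standard deviations are most
#' similar between the two sets (summed standardized discrepancy). This is a
#' random selection method that ensures similar mean and SD for each trait
#' across both sets, without imposing strata.
#'
#' @param records sample-record data.frame (see [validate_records()]); rows
#'   with `NA` for a given trait are ignored in that trait's balance term.
#' @param frac calibration fraction (default 0.75).
#' @param traits character vector of trait columns used in the balance
#'   criterion.
#' @param seed integer seed (required; same seed, same split).
#' @param n_candidates random splits examined (default 200).
#' @return A list of class `cv_split`: `cal_ids`, `val_ids`, `score`,
#'   `summary` (per-trait per-set N/mean/SD), `seed`.
#' @export
split_calibration_validation <- function(records, frac = 0.75,
                                         traits = COAG_TRAITS, seed,
                                         n_candidates = 200L) {
  n <- nrow(records)
  if (n < 8L) stop("need at least 8 samples to split")
  if (missing(seed)) stop("a split seed is required")
  n_cal <- round(frac * n)
  traits_ok <- traits[vapply(traits, function(tr) {
    sum(!is.na(records[[tr]])) >= 4L
  }, logical(1))]
  if (length(traits_ok) < length(traits)) {
    warning("trait(s) with too few values excluded from the balance criterion: ",
            paste(setdiff(traits, traits_ok), collapse = ", "))
  }
  if (!length(traits_ok)) stop("no usable trait for the balance criterion")

  score_split <- function(cal_idx) {
    s <- 0
    for (tr in traits_ok) {
      v <- records[[tr]]
      vc <- v[cal_idx]; vv <- v[-cal_idx]
      vc <- vc[!is.na(vc)]; vv <- vv[!is.na(vv)]
      if (length(vc) < 2L || length(vv) < 2L) return(Inf)
      sd_pool <- stats::sd(v[!is.na(v)])
      if (sd_pool < 1e-12) next
      s <- s + abs(mean(vc) - mean(vv)) / sd_pool +
        abs(stats::sd(vc) - stats::sd(vv)) / sd_pool
    }
    s
  }

  best <- NULL
  best_score <- Inf
  with_local_seed(seed, {
    for (i in seq_len(n_candidates)) {
      cal_idx <- sort(sample.int(n, n_cal))
      sc <- score_split(cal_idx)
      if (sc < best_score) {
        best_score <- sc
        best <- cal_idx
      }
    }
  })
  cal_ids <- records$sample_id[best]
  val_ids <- records$sample_id[-best]
  summ <- do.call(rbind, lapply(traits_ok, function(tr) {
    v <- records[[tr]]
    data.frame(
      trait = tr,
      set = c("calibration", "validation"),
      n = c(sum(!is.na(v[best])), sum(!is.na(v[-best]))),
      mean = c(mean(v[best], na.rm = TRUE), mean(v[-best], na.rm = TRUE)),
      sd = c(stats::sd(v[best], na.rm = TRUE), stats::sd(v[-best], na.rm = TRUE)),
      stringsAsFactors = FALSE)
  }))
  structure(list(cal_ids = cal_ids, val_ids = val_ids, score = best_score,
                 summary = summ, seed = seed),
            class = "cv_split")
}

#' @export
print.cv_split <- function(x, ...) {
  cat(sprintf("cv_split: %d calibration / %d validation (balance score %.4f)\n",
              length(x$cal_ids), length(x$val_ids), x$score))
  invisible(x)
}

#' NIRS-convention fitting statistics
#'
#' Computes the standard calibration/validation panel: on the validation set,
#' bias = mean(predicted - reference), slope = OLS slope of the reference
#' regressed on the predictions, SEP = bias-corrected standard error of
#' prediction `sqrt(sum((pred - ref - bias)^2) / (n - 1))`, R2ExV = squared
#' Pearson correlation, and RPD = SD(reference) / SEP; on the
#' calibration/cross-validation side, SEC = `sqrt(RSS_cv / (n - LF - 1))` and
#' R2CrV from the pooled out-of-fold predictions.
#'
#' @param y_ref_val,y_pred_val reference and predicted values on the
#'   validation set.
#' @param y_ref_cal,y_pred_cv reference values and pooled out-of-fold
#'   cross-validation predictions on the calibration set (optional; `NULL`
#'   leaves SEC/R2CrV as `NA`).
#' @param lf number of latent factors of the model (used in the SEC
#'   denominator).
#' @param slope_on `"predicted"` (default, WinISI convention: regress
#'   reference on predicted) or `"reference"` (the reverse).
#' @param r2_method `"pearson"` (default) or `"one_minus_rss"`.
#' @return An object of class `fit_statistics`: `n_cal`, `n_val`, `lf`,
#'   `sec`, `r2_crv`, `bias`, `slope`, `sep`, `r2_exv`, `rpd` (`Inf` when
#'   SEP is 0), `sd_val`.
#' @export
fit_statistics <- function(y_ref_val, y_pred_val, y_ref_cal = NULL,
                           y_pred_cv = NULL, lf = NA_integer_,
                           slope_on = c("predicted", "reference"),
                           r2_method = c("pearson", "one_minus_rss")) {
  slope_on <- match.arg(slope_on)
  r2_method <- match.arg(r2_method)
  y <- as.numeric(y_ref_val)
  yp <- as.numeric(y_pred_val)
  if (length(y) != length(yp)) stop("validation vectors must have equal length")
  n_val <- length(y)
  if (n_val < 3L) stop("need at least 3 validation samples")
  if (stats::sd(y) < 1e-14) stop("zero variance in validation reference values")

  bias <- mean(yp - y)
  sep <- sqrt(sum((yp - y - bias)^2) / (n_val - 1L))
  slope <- if (stats::sd(yp) < 1e-14) {
    NA_real_
  } else if (slope_on == "predicted") {
    stats::cov(yp, y) / stats::var(yp)
  } else {
    stats::cov(yp, y) / stats::var(y)
  }
  r2_exv <- if (stats::sd(yp) < 1e-14) {
    0
  } else if (r2_method == "pearson") {
    stats::cor(yp, y)^2
  } else {
    1 - sum((yp - y)^2) / sum((y - mean(y))^2)
  }
  sd_val <- stats::sd(y)
  rpd <- if (sep > 0) sd_val / sep else Inf

  sec <- r2_crv <- NA_real_
  n_cal <- NA_integer_
  if (!is.null(y_ref_cal) && !is.null(y_pred_cv)) {
    yc <- as.numeric(y_ref_cal)
    ycv <- as.numeric(y_pred_cv)
    if (length(yc) != length(ycv)) stop("calibration vectors must have equal length")
    n_cal <- length(yc)
    sec <- sqrt(sum((ycv - yc)^2) / max(n_cal - (if (is.na(lf)) 1L else lf) - 1L, 1L))
    r2_crv <- if (r2_method == "pearson") {
      if (stats::sd(ycv) < 1e-14) 0 else stats::cor(ycv, yc)^2
    } else {
      1 - sum((ycv - yc)^2) / sum((yc - mean(yc))^2)
    }
  }
  structure(list(n_cal = n_cal, n_val = n_val, lf = lf, sec = sec,
                 r2_crv = r2_crv, bias = bias, slope = slope, sep = sep,
                 r2_exv = r2_exv, rpd = rpd, sd_val = sd_val),
            class = "fit_statistics")
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf(
    "fit_statistics: N_val=%d LF=%s SEC=%.3g R2CrV=%.3g | bias=%.3g slope=%.3g SEP=%.3g R2ExV=%.3g RPD=%.3g\n",
    x$n_val, ifelse(is.na(x$lf), "?", x$lf), x$sec, x$r2_crv, x$bias,
    x$slope, x$sep, x$r2_exv, x$rpd))
  invisible(x)
}

#' Coefficient of variation
#'
#' @param mean,sd trait mean (must be positive) and standard deviation.
#' @return CV as a percentage: `100 * sd / mean`.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(mean <= 0)) stop("CV requires a positive mean")
  100 * sd / mean
}

INTERPRETATION_LEVELS <- c("not recommended", "below screening", "screening",
                           "caution", "most applications", "any application")

band_level_r2 <- function(r2) {
  # upper categories keyed on the published R2ExV bands; values in the gaps
  # between bands take the lower adjacent category
  if (r2 > 0.98) 6L
  else if (r2 >= 0.92) 5L
  else if (r2 >= 0.83) 4L
  else if (r2 >= 0.66) 3L
  else 2L          # below the screening band
}

band_level_rpd <- function(rpd) {
  if (rpd > 5.0) 6L
  else if (rpd >= 3.6) 5L
  else if (rpd >= 2.3) 4L
  else if (rpd >= 1.7) 3L
  else if (rpd >= 0.75) 2L
  else 1L
}

#' Interpret a prediction model by its R2ExV and RPD
#'
#' Maps the external-validation coefficient of determination and the ratio of
#' prediction to deviation onto the conventional NIRS applicability scale:
#' screening (R2ExV 0.66-0.81, RPD 1.7-2.2), caution (0.83-0.90, 2.3-3.5),
#' most applications (0.92-0.96, 3.6-4.9), any application (> 0.98, > 5.0);
#' models with R2ExV < 0.66 and RPD < 0.75 are not recommended. Pairs falling
#' between bands (for example RPD in (0.75, 1.7)) are labelled
#' "below screening", a label this package adds for the gaps the published
#' scale leaves open. When the two metrics disagree, the lower category wins.
#'
#' @param r2_exv coefficient of determination of external validation.
#' @param rpd ratio of prediction to deviation.
#' @return A list of class `interpretation_band`: `category`, `level`
#'   (1 = not recommended ... 6 = any application), and the inputs.
#' @export
interpret_model <- function(r2_exv, rpd) {
  stopifnot(is.finite(r2_exv), !is.na(rpd))   # rpd may be +Inf (perfect SEP)
  level <- if (r2_exv < 0.66 && rpd < 0.75) {
    1L
  } else {
    min(band_level_r2(r2_exv), band_level_rpd(rpd))
  }
  structure(list(category = INTERPRETATION_LEVELS[level], level = level,
                 r2_exv = r2_exv, rpd = rpd),
            class = "interpretation_band")
}

#' @export
print.interpretation_band <- function(x, ...) {
  cat(sprintf("interpretation: %s (R2ExV = %.2f, RPD = %.2f)\n",
              x$category, x$r2_exv, x$rpd))
  invisible(x)
}

#' Classify the regression slope of a prediction model
#'
#' A slope within 0.95-1.05 is adequate; within 0.85-1.15 it is acceptable;
#' outside that the model is considered imprecise at the extreme ends of the
#' trait range.
#'
#' @param slope validation regression slope.
#' @return `"adequate"`, `"acceptable"`, or `"imprecise-at-extremes"`.
#' @export
slope_adequacy <- function(slope) {
  stopifnot(is.finite(slope))
  dev <- abs(slope - 1)
  if (dev <= 0.05) "adequate"
  else if (dev <= 0.15) "acceptable"
  else "imprecise-at-extremes"
}
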