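#' Global H (standardized Mahalanobis distance) in score space
#'
#' GH_i = D^2_i / LF, where D^2_i is the Mahalanobis distance of sample i in
#' the latent-factor score space, computed with the maximum-likelihood
#' covariance of the calibration scores. With that normalization the mean GH
#' of the calibration set is ~1, and GH > 3 is the conventional cutoff for
#' spectral outliers.
#'
#' @param scores numeric matrix of calibration scores (samples x factors),
#'   e.g. the `scores` element of an [fit_mpls()] model.
#' @return Numeric vector of GH values, one per sample.
#' @export
global_h <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  if (n <= k + 1L) stop("need more samples than factors + 1")
  ctr <- sweep(scores, 2L, colMeans(scores), check.margin = FALSE)
  S <- crossprod(ctr) / n                     # ML covariance
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) stop("singular score covariance; cannot compute Global H")
  z <- backsolve(ch, t(ctr), transpose = TRUE)
  colSums(z^2) / k
}

#' Remove spectral outliers by Global H
#'
#' Fits an mPLS decomposition to the calibration data (selecting the factor
#' count by cross-validation unless `n_factors` is given), computes Global H
#' for every sample, and removes those with GH above the threshold in a
#' single pass.
#'
#' @param X calibration spectra matrix (preprocessed).
#' @param y trait values.
#' @param threshold GH cutoff (default 3.0).
#' @param n_factors latent factors for the decomposition; `NULL` (default)
#'   selects by cross-validation.
#' @param folds,max_factors,seed,standardize cross-validation settings, see
#'   [cross_validate()].
#' @return List with `X`, `y` (retained), `removed_ids` (row indices or names
#'   removed), `gh` (all GH values), `lf` used, and `log` (a data.frame with
#'   sample_id, stage, statistic, removed).
#' @export
remove_gh_outliers <- function(X, y, threshold = 3.0, n_factors = NULL,
                               folds = 15L, max_factors = 16L, seed,
                               standardize = TRUE) {
  X <- as.matrix(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  if (is.null(n_factors)) {
    cv <- cross_validate(X, y, folds = folds, max_factors = max_factors,
                         seed = seed, standardize = standardize)
    n_factors <- cv$lf
  }
  fit <- fit_mpls(X, y, n_factors = n_factors, standardize = standardize,
                  compute_coef = FALSE)
  gh <- global_h(fit$scores)
  out <- gh > threshold
  if (mean(out) > 0.5) {
    stop(sprintf("Global-H pass would remove %.0f%% of samples; aborting",
                 100 * mean(out)))
  }
  log <- data.frame(sample_id = ids, stage = "GH", statistic = gh,
                    removed = out, stringsAsFactors = FALSE)
  list(X = X[!out, , drop = FALSE], y = y[!out], removed_ids = ids[out],
       gh = gh, lf = fit$n_factors, log = log)
}

#' Iterative chemical-outlier elimination by T-statistic
#'
#' Runs up to `rounds` rounds. Each round refits the mPLS model (with
#' cross-validated factor selection), computes T_i = |prediction residual| /
#' SEC for every calibration sample, removes those with T above the
#' threshold, and refits; it stops early when a round removes nothing.
#'
#' @inheritParams remove_gh_outliers
#' @param rounds maximum elimination rounds (default 3).
#' @param threshold T cutoff (default 3.0).
#' @param t_denominator `"SEC"` (default, calibration standard error of the
#'   current round's model) or `"SECV"` (the cross-validated error).
#' @return List with retained `X`, `y`, `removed_ids`, per-round `log`
#'   data.frame (sample_id, stage, statistic, removed), and `rounds_run`.
#' @export
t_outlier_rounds <- function(X, y, rounds = 3L, threshold = 3.0, folds = 15L,
                             max_factors = 16L, seed, standardize = TRUE,
                             t_denominator = c("SEC", "SECV")) {
  t_denominator <- match.arg(t_denominator)
  X <- as.matrix(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  logs <- list()
  removed_ids <- character(0)
  rounds_run <- 0L
  for (r in seq_len(rounds)) {
    rounds_run <- r
    cv <- cross_validate(X, y, folds = folds, max_factors = max_factors,
                         seed = substream_seed(seed, paste0("t_round_", r)),
                         standardize = standardize)
    fit <- fit_mpls(X, y, n_factors = cv$lf, standardize = standardize,
                    compute_coef = FALSE)
    resid <- predict_factorwise(fit, X)[, fit$n_factors] - y
    sec <- sqrt(sum(resid^2) / max(nrow(X) - fit$n_factors - 1L, 1L))
    denom <- if (t_denominator == "SEC") sec else cv$secv[cv$lf]
    tstat <- abs(resid) / denom
    out <- tstat > threshold
    logs[[r]] <- data.frame(sample_id = ids, stage = paste0("T", r),
                            statistic = tstat, removed = out,
                            stringsAsFactors = FALSE)
    if (!any(out)) break
    if (mean(out) > 0.5) {
      stop(sprintf("T round %d would remove %.0f%% of samples; aborting",
                   r, 100 * mean(out)))
    }
    removed_ids <- c(removed_ids, ids[out])
    X <- X[!out, , drop = FALSE]
    y <- y[!out]
    ids <- ids[!out]
  }
  list(X = X, y = y, removed_ids = removed_ids,
       log = do.call(rbind, logs), rounds_run = rounds_run)
}

#' Full outlier-elimination pipeline
#'
#' One Global-H spectral-outlier pass followed by up to three rounds of
#' chemical-outlier elimination by the T-statistic, refitting between stages.
#'
#' @inheritParams remove_gh_outliers
#' @param gh_threshold Global H cutoff (default 3.0).
#' @param t_threshold T cutoff (default 3.0).
#' @param rounds maximum T rounds (default 3).
#' @return List with retained `X`, `y`, and `report`: an `outlier_report`
#'   containing the audit `log` (sample_id, stage, statistic, removed),
#'   `removed_gh`, `removed_t`, `n_initial`, `n_removed`, `pct_removed`.
#' @export
outlier_pipeline <- function(X, y, gh_threshold = 3.0, t_threshold = 3.0,
                             rounds = 3L, folds = 15L, max_factors = 16L,
                             seed, standardize = TRUE) {
  n0 <- nrow(X)
  gh <- remove_gh_outliers(X, y, threshold = gh_threshold, folds = folds,
                           max_factors = max_factors,
                           seed = substream_seed(seed, "gh"),
                           standardize = standardize)
  tr <- t_outlier_rounds(gh$X, gh$y, rounds = rounds, threshold = t_threshold,
                         folds = folds, max_factors = max_factors,
                         seed = seed, standardize = standardize)
  n_removed <- length(gh$removed_ids) + length(tr$removed_ids)
  report <- structure(list(
    log = rbind(gh$log, tr$log),
    removed_gh = gh$removed_ids, removed_t = tr$removed_ids,
    n_initial = n0, n_removed = n_removed,
    pct_removed = 100 * n_removed / n0
  ), class = "outlier_report")
  list(X = tr$X, y = tr$y, report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "outlier_report: %d of %d samples removed (%.2f%%): %d Global-H, %d T-statistic\n",
    x$n_removed, x$n_initial, x$pct_removed,
    length(x$removed_gh), length(x$removed_t)))
  invisible(x)
}

#' Write an outlier audit log
#'
#' @param report an `outlier_report` from [outlier_pipeline()].
#' @param path output path for the tabular log (sample_id, stage, statistic,
#'   removed).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_outlier_log <- function(report, path, sep = "\t") {
  stopifnot(inherits(report, "outlier_report"))
  utils::write.table(report$log, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
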