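#' Fit a modified partial least-squares (mPLS) regression
#'
#' PLS1 by NIPALS with the Shenk-Westerhaus modification: after each latent
#' factor is extracted, the X-residuals at each wavelength are divided by the
#' standard deviation of the residuals at that wavelength before the next
#' factor is computed. The y-residuals are not rescaled. With
#' `standardize = FALSE` the fit reduces exactly to conventional PLS1.
#'
#' @param X numeric matrix of preprocessed spectra (samples x points), no
#'   missing values.
#' @param y numeric response (trait values), one per row of `X`.
#' @param n_factors number of latent factors to extract (>= 1). If the data
#'   rank is exhausted earlier, the model is truncated with a warning.
#' @param standardize logical; apply the per-wavelength residual
#'   standardization after each factor (the mPLS modification). Default TRUE.
#' @param compute_coef logical; also compute the composite regression
#'   coefficients for every factor count 1..LF (needed for [coef()] and model
#'   serialization, not for prediction, which uses the factor recursion).
#'
#' @return An object of class `mpls_model`: centering terms `x_mean`,
#'   `y_mean`; per-factor weights `W` (p x LF), X-loadings `P`, y-loadings
#'   `q`, residual-scaling vectors `Dsd` (p x LF, strictly positive; all ones
#'   when `standardize = FALSE`); calibration scores `scores` (n x LF);
#'   `n_factors`; and, when requested, `coefficients` (p x LF, column k =
#'   composite coefficients using k factors).
#' @export
fit_mpls <- function(X, y, n_factors, standardize = TRUE, compute_coef = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (n_factors < 1L) stop("n_factors must be >= 1")
  if (n < n_factors + 2L) stop("need at least n_factors + 2 samples")
  if (stats::sd(y) < 1e-12) stop("constant response y")

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean, check.margin = FALSE)
  f <- y - y_mean

  K <- min(n_factors, n - 1L, p)
  eng <- mpls_engine(E, f, K, standardize)
  k_actual <- eng$k_actual
  if (k_actual == 0L) stop("no latent factor could be extracted (X has no variance)")
  W <- eng$W; P <- eng$P; q <- as.numeric(eng$q); Dsd <- eng$Dsd
  Tm <- eng$scores
  if (k_actual < n_factors) {
    warning(sprintf("rank exhausted: %d factor(s) extracted of %d requested",
                    k_actual, n_factors))
  }
  keep <- seq_len(k_actual)
  model <- structure(list(
    x_mean = x_mean, y_mean = y_mean,
    W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
    q = q[keep], Dsd = Dsd[, keep, drop = FALSE],
    scores = Tm[, keep, drop = FALSE],
    n_factors = k_actual, standardize = standardize,
    axis = NULL, preprocess = NULL
  ), class = "mpls_model")
  if (compute_coef) model$coefficients <- mpls_coefficients(model)
  model
}

# composite regression coefficients for every factor count, by propagating the
# deflation/rescaling recursion through a p x p operator (rank-1 updates)
mpls_coefficients <- function(model) {
  p <- length(model$x_mean)
  K <- model$n_factors
  A <- diag(p)
  B <- matrix(0, p, K)
  b <- numeric(p)
  for (k in seq_len(K)) {
    w <- model$W[, k]
    b <- b + model$q[k] * as.numeric(crossprod(A, w))
    B[, k] <- b
    if (k < K) {
      wA <- as.numeric(crossprod(w, A))          # t(w) %*% A
      A <- (A - tcrossprod(model$P[, k], wA)) / model$Dsd[, k]
    }
  }
  dimnames(B) <- list(names(model$x_mean), NULL)
  B
}

#' @export
coef.mpls_model <- function(object, n_factors = object$n_factors, ...) {
  if (is.null(object$coefficients)) object$coefficients <- mpls_coefficients(object)
  object$coefficients[, n_factors]
}

#' @export
print.mpls_model <- function(x, ...) {
  cat(sprintf("mpls_model: %d latent factor(s), %d wavelengths%s\n",
              x$n_factors, length(x$x_mean),
              if (x$standardize) " (residual standardization on)" else ""))
  invisible(x)
}

# predictions for every factor count 1..K via the factor recursion applied to
# the new spectra; returns an n x K matrix
predict_factorwise <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    stop("axis mismatch: model has ", length(model$x_mean),
         " wavelengths, newdata has ", ncol(X))
  }
  E <- sweep(X, 2L, model$x_mean, check.margin = FALSE)
  mpls_predict_engine(E, model$W, model$P, model$q, model$Dsd, model$y_mean)
}

#' Predict trait values from an mPLS model
#'
#' @param object an [fit_mpls()] model.
#' @param newdata matrix of preprocessed spectra on the same working axis and
#'   preprocessing as the training data, or a [milk_spectra()] object.
#' @param n_factors number of latent factors to use (default: all extracted).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mpls_model <- function(object, newdata, n_factors = object$n_factors,
                               ...) {
  if (inherits(newdata, "milk_spectra")) newdata <- newdata$absorbance
  if (n_factors < 1L || n_factors > object$n_factors) {
    stop("n_factors must be in 1..", object$n_factors)
  }
  predict_factorwise(object, newdata)[, n_factors]
}

#' Select the number of latent factors from a SECV curve
#'
#' Returns the smallest factor count whose cross-validated error is within a
#' relative band (default 2%) of the global minimum SECV, capped at `cap`.
#' Favouring the smallest count inside the band guards against overfitting
#' when the SECV curve is nearly flat past its minimum.
#'
#' @param secv numeric vector, SECV at factor counts 1..length(secv).
#' @param cap maximum factor count returned (default 16).
#' @param band relative band around the minimum (default 0.02).
#' @return Integer factor count.
#' @export
select_latent_factors <- function(secv, cap = 16L, band = 0.02) {
  if (!length(secv)) stop("empty SECV curve")
  lf <- which(secv <= min(secv) * (1 + band))[1L]
  min(as.integer(lf), as.integer(cap))
}

#' Cross-validate an mPLS model
#'
#' Randomly partitions the calibration samples into `folds` folds (seeded;
#' fold sizes differ by at most one), refits the full mPLS model on each
#' training complement, and pools the out-of-fold predictions. SECV at each
#' factor count is `sqrt(sum((pred - y)^2) / n)` over the pooled out-of-fold
#' predictions; the factor count is then chosen by
#' [select_latent_factors()].
#'
#' @param X calibration spectra matrix (preprocessed).
#' @param y trait values.
#' @param folds number of folds (default 15).
#' @param max_factors maximum latent factors examined (default 16).
#' @param seed integer seed for the fold assignment (required).
#' @param standardize passed to [fit_mpls()].
#' @param lf_cap,lf_band passed to [select_latent_factors()].
#' @param r2_method `"pearson"` (squared Pearson correlation of pooled
#'   out-of-fold predictions with the reference; NIRS convention) or
#'   `"one_minus_rss"` (1 - RSS/TSS).
#' @return An object of class `mpls_cv`: `secv` (per factor count), `lf`
#'   (chosen), `oof` (pooled out-of-fold prediction matrix n x K), `fold`
#'   (fold id per sample), `sec` and `r2_crv` at the chosen LF, `n`.
#' @export
cross_validate <- function(X, y, folds = 15L, max_factors = 16L, seed,
                           standardize = TRUE, lf_cap = max_factors,
                           lf_band = 0.02, r2_method = c("pearson", "one_minus_rss")) {
  r2_method <- match.arg(r2_method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > n) stop("more folds than samples")
  if (missing(seed)) stop("a fold-assignment seed is required")
  fold <- with_local_seed(seed, sample(rep_len(seq_len(folds), n)))
  K <- min(max_factors, n - ceiling(n / folds) - 2L, ncol(X))
  if (K < 1L) stop("too few samples for cross-validation")
  oof <- matrix(NA_real_, n, K)
  for (fd in seq_len(folds)) {
    test <- fold == fd
    fit <- suppressWarnings(
      fit_mpls(X[!test, , drop = FALSE], y[!test], n_factors = K,
               standardize = standardize, compute_coef = FALSE))
    pr <- predict_factorwise(fit, X[test, , drop = FALSE])
    if (fit$n_factors < K) {       # rank-exhausted fold: carry last column
      pr <- cbind(pr, matrix(pr[, fit$n_factors], sum(test),
                             K - fit$n_factors))
    }
    oof[test, ] <- pr
  }
  secv <- sqrt(colSums((oof - y)^2) / n)
  lf <- select_latent_factors(secv, cap = lf_cap, band = lf_band)
  rss <- sum((oof[, lf] - y)^2)
  sec <- sqrt(rss / max(n - lf - 1L, 1L))
  r2 <- if (r2_method == "pearson") {
    if (stats::sd(oof[, lf]) < 1e-14) 0 else stats::cor(oof[, lf], y)^2
  } else {
    1 - rss / sum((y - mean(y))^2)
  }
  structure(list(secv = secv, lf = lf, oof = oof, fold = fold,
                 sec = sec, r2_crv = r2, n = n, folds = folds, seed = seed),
            class = "mpls_cv")
}

#' @export
print.mpls_cv <- function(x, ...) {
  cat(sprintf("mpls_cv: %d folds, chosen LF = %d, SECV = %.4g, R2CrV = %.3f\n",
              x$folds, x$lf, x$secv[x$lf], x$r2_crv))
  invisible(x)
}
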