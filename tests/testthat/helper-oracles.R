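# Independent reference implementations used as oracles. Each takes a
# different computational route than the package code it checks.

# Conventional PLS1 by textbook NIPALS; coefficients via the closed form
# b = W (P'W)^{-1} q rather than the package's deflation recursion.
oracle_nipals_pls1 <- function(X, y, n_factors) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  p <- ncol(X)
  W <- P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  for (k in seq_len(n_factors)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    q[k] <- sum(tt * f) / t2
    pk <- drop(crossprod(E, tt)) / t2
    E <- E - outer(tt, pk)
    f <- f - q[k] * tt
    W[, k] <- w
    P[, k] <- pk
  }
  b <- W %*% solve(crossprod(P, W), q)
  list(coef = drop(b), x_mean = x_mean, y_mean = y_mean,
       predict = function(Xn) {
         y_mean + drop(sweep(as.matrix(Xn), 2, x_mean) %*% b)
       })
}

# Degree-2 polynomial residual via lm(); the residual of the projection onto
# span{1, w, w^2} is invariant to rescaling the basis, so a standardized axis
# keeps the normal equations well conditioned without changing the answer.
oracle_detrend_row <- function(x, w) {
  ws <- (w - mean(w)) / stats::sd(w)
  unname(stats::resid(stats::lm(x ~ ws + I(ws^2))))
}

# MSC slope/intercept by the simple-linear-regression closed form.
oracle_msc_coefs <- function(x, ref) {
  b <- sum((ref - mean(ref)) * (x - mean(x))) / sum((ref - mean(ref))^2)
  a <- mean(x) - b * mean(ref)
  c(a = a, b = b)
}

# Gap-segment math treatment by direct per-point loops: centred running mean
# of s points (window one point further right when s is even), centred gap
# difference x[i + ceil(g/2)] - x[i - floor(g/2)] applied d times, second
# smoothing. Returns the treated row; the kept-index bookkeeping is implicit
# in the output length.
oracle_math_row <- function(x, d, gap, s1, s2) {
  smooth <- function(v, s) {
    if (s == 1) return(v)
    lo <- (s - 1) %/% 2
    hi <- s %/% 2
    idx <- seq(1 + lo, length(v) - hi)
    vapply(idx, function(i) mean(v[(i - lo):(i + hi)]), 0)
  }
  deriv <- function(v, g) {
    lo <- g %/% 2
    hi <- g - lo
    idx <- seq(1 + lo, length(v) - hi)
    vapply(idx, function(i) v[i + hi] - v[i - lo], 0)
  }
  v <- smooth(x, s1)
  if (d > 0) for (i in seq_len(d)) v <- deriv(v, gap)
  smooth(v, s2)
}

# Mahalanobis GH by direct covariance solve.
oracle_global_h <- function(scores) {
  scores <- as.matrix(scores)
  mu <- colMeans(scores)
  S <- crossprod(sweep(scores, 2, mu)) / nrow(scores)
  Sinv <- solve(S)
  d2 <- apply(scores, 1, function(r) {
    v <- r - mu
    drop(t(v) %*% Sinv %*% v)
  })
  d2 / ncol(scores)
}

# SECV by an explicit leave-fold-out loop with per-sample prediction.
oracle_secv <- function(X, y, fold, max_factors, standardize = TRUE) {
  n <- nrow(X)
  oof <- matrix(NA_real_, n, max_factors)
  for (fd in unique(fold)) {
    test <- which(fold == fd)
    fit <- fit_mpls(X[-test, , drop = FALSE], y[-test],
                    n_factors = max_factors, standardize = standardize,
                    compute_coef = TRUE)
    for (i in test) {
      for (k in seq_len(max_factors)) {
        b <- fit$coefficients[, k]
        oof[i, k] <- fit$y_mean + sum((X[i, ] - fit$x_mean) * b)
      }
    }
  }
  sqrt(colSums((oof - y)^2) / n)
}
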