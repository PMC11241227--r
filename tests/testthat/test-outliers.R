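test_that("Global H is zero at the centroid and matches the direct oracle", {
  set.seed(50)
  scores <- matrix(rnorm(200 * 5), 200, 5)
  scores <- rbind(scores, colMeans(scores))   # a sample exactly at the centroid
  gh <- global_h(scores)
  oracle <- oracle_global_h(scores)
  expect_equal(gh, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(gh[201], 1e-10)
})

test_that("mean Global H is 1 under the ML covariance normalization", {
  set.seed(51)
  scores <- matrix(rnorm(200 * 5), 200, 5)
  # trace identity: mean Mahalanobis D^2 with the ML covariance equals the
  # dimension, so mean(GH) = 1 exactly up to numerics
  expect_equal(mean(global_h(scores)), 1, tolerance = 1e-10)
})

test_that("a grossly displaced sample is flagged by Global H", {
  set.seed(52)
  scores <- matrix(rnorm(100 * 4), 100, 4)
  scores[13, 1] <- scores[13, 1] + 100 * sd(scores[, 1])
  gh <- global_h(scores)
  expect_gt(gh[13], 3)
  expect_equal(which.max(gh), 13L)
})

test_that("GH removal honours its threshold and removes only true outliers", {
  set.seed(53)
  n <- 150; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p, 0, 0.2)) + rnorm(n, 0, 0.3)
  res_inf <- remove_gh_outliers(X, y, threshold = Inf, n_factors = 5, seed = 1)
  expect_equal(nrow(res_inf$X), n)
  expect_length(res_inf$removed_ids, 0)

  Xo <- X
  Xo[40, ] <- Xo[40, ] + 50       # gross spectral outlier
  rownames(Xo) <- paste0("s", seq_len(n))
  res <- remove_gh_outliers(Xo, y, threshold = 3, n_factors = 5, seed = 1)
  expect_true("s40" %in% res$removed_ids)
  expect_gt(res$gh[40], 3)
})

test_that("the clean-data GH removal rate matches a Monte-Carlo oracle", {
  # brute-force tail probability of GH > 3 for gaussian scores at n=500, k=10
  set.seed(54)
  reps <- 40
  frac_oracle <- mean(vapply(seq_len(reps), function(i) {
    mean(oracle_global_h(matrix(rnorm(500 * 10), 500, 10)) > 3)
  }, 0))
  frac_pkg <- mean(vapply(seq_len(reps), function(i) {
    mean(global_h(matrix(rnorm(500 * 10), 500, 10)) > 3)
  }, 0))
  expect_equal(frac_pkg, frac_oracle, tolerance = 3 * 0.002 + 1e-6)
  expect_lt(frac_pkg, 0.01)   # clean data loses well under 1% to the GH pass
})

test_that("T rounds with an infinite threshold remove nothing", {
  set.seed(55)
  X <- matrix(rnorm(120 * 40), 120, 40)
  y <- drop(X %*% rnorm(40, 0, 0.3)) + rnorm(120, 0, 0.5)
  res <- t_outlier_rounds(X, y, rounds = 3, threshold = Inf, folds = 10,
                          max_factors = 5, seed = 2)
  expect_length(res$removed_ids, 0)
  expect_equal(res$X, X, ignore_attr = TRUE)
  expect_equal(res$rounds_run, 1L)          # early stop: nothing removed
  expect_true(all(res$log$statistic >= 0))
})

test_that("a planted 10-SEC reference error is caught in the first T round", {
  set.seed(56)
  n <- 150; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  rownames(X) <- paste0("s", seq_len(n))
  beta <- rnorm(p, 0, 0.3)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.3)
  # independent estimate of the achievable SEC scale
  fit0 <- fit_mpls(X, y, n_factors = 8)
  sec0 <- sqrt(sum((predict(fit0, X) - y)^2) / (n - 8 - 1))
  y[25] <- y[25] + 10 * sec0
  res <- t_outlier_rounds(X, y, rounds = 3, threshold = 3, folds = 10,
                          max_factors = 8, seed = 3)
  round1 <- res$log[res$log$stage == "T1", ]
  expect_true(round1$removed[round1$sample_id == "s25"])
  expect_true("s25" %in% res$removed_ids)
})

test_that("the outlier pipeline reports exact percentages and spares clean data", {
  set.seed(57)
  ds <- generate_dataset(small_config(n_samples = 300, n_points = 250), seed = 9)
  keep <- filter_noncoagulating(ds$records)$retained
  sp <- mask_regions(subset_samples(ds$spectra, keep$sample_id))
  res <- outlier_pipeline(snv(sp)$absorbance, keep$a30_mm, seed = 5,
                          max_factors = 8)
  rep <- res$report
  expect_equal(rep$pct_removed, 100 * rep$n_removed / rep$n_initial)
  expect_equal(rep$n_initial - rep$n_removed, nrow(res$X))
  expect_lt(rep$pct_removed, 10)
  expect_setequal(c(rownames(res$X), rep$removed_gh, rep$removed_t),
                  rownames(sp$absorbance))
})

test_that("outlier removal is monotone in its thresholds", {
  set.seed(58)
  ds <- generate_dataset(small_config(n_samples = 200, n_points = 200), seed = 4)
  keep <- filter_noncoagulating(ds$records)$retained
  X <- snv(mask_regions(subset_samples(ds$spectra, keep$sample_id)))$absorbance
  y <- keep$rct_min
  loose <- outlier_pipeline(X, y, gh_threshold = 6, t_threshold = 6, seed = 7,
                            max_factors = 8)
  tight <- outlier_pipeline(X, y, gh_threshold = 3, t_threshold = 3, seed = 7,
                            max_factors = 8)
  expect_lte(loose$report$n_removed, tight$report$n_removed)
})

test_that("the pipeline is deterministic given data and seed", {
  set.seed(59)
  ds <- generate_dataset(small_config(n_samples = 150, n_points = 150), seed = 2)
  keep <- filter_noncoagulating(ds$records)$retained
  X <- mask_regions(subset_samples(ds$spectra, keep$sample_id))$absorbance
  y <- keep$k20_min
  a <- outlier_pipeline(X, y, seed = 11, max_factors = 6)
  b <- outlier_pipeline(X, y, seed = 11, max_factors = 6)
  expect_identical(a$report$log, b$report$log)
  expect_identical(a$X, b$X)
})

test_that("planted gross outliers are removed with high sensitivity and rare false alarms", {
  seeds <- 1:20
  sens <- numeric(0)
  false_removed <- 0L
  clean_total <- 0L
  for (s in seeds) {
    ds <- generate_dataset(small_config(n_samples = 400, n_points = 250),
                           seed = s)
    ds <- inject_outliers(ds, n_spectral = 10, n_chemical = 10,
                          magnitude = 10, seed = s + 1000)
    keep <- filter_noncoagulating(ds$records)$retained
    sp <- mask_regions(subset_samples(ds$spectra, keep$sample_id))
    y <- keep$a30_mm
    res <- outlier_pipeline(sp$absorbance, y, seed = s + 2000, max_factors = 8)
    removed <- c(res$report$removed_gh, res$report$removed_t)
    planted <- intersect(c(ds$planted$spectral_ids, ds$planted$chemical_ids),
                         keep$sample_id)
    sens <- c(sens, mean(planted %in% removed))
    clean <- setdiff(keep$sample_id, planted)
    false_removed <- false_removed + sum(removed %in% clean)
    clean_total <- clean_total + length(clean)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(false_removed / clean_total, 0.01)
})

test_that("outlier logs can be written for audit", {
  set.seed(60)
  X <- matrix(rnorm(100 * 30), 100, 30)
  y <- drop(X %*% rnorm(30, 0, 0.3)) + rnorm(100, 0, 0.3)
  res <- outlier_pipeline(X, y, seed = 1, max_factors = 5)
  f <- tempfile(fileext = ".tsv")
  write_outlier_log(res$report, f)
  log <- read.delim(f)
  expect_named(log, c("sample_id", "stage", "statistic", "removed"))
  unlink(f)
})
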