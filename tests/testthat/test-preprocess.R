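# Timeseries cleaning: filters, confound extraction/regression, smoothing.

test_that("initial-volume drop shortens runs as specified", {
  x <- matrix(rnorm(800 * 3), 800, 3)
  expect_equal(nrow(drop_initial_volumes(x, 5)), 795)
  expect_identical(drop_initial_volumes(x, 0), x)
  expect_error(drop_initial_volumes(x[1:4, ], 5), "cannot drop")
  # three runs concatenated after the drop
  total <- sum(rep(795, 3))
  expect_equal(total, 3 * 800 - 15)
  expect_equal(nrow(do.call(rbind, replicate(3, drop_initial_volumes(x, 5),
                                             simplify = FALSE))), 2385)
})

test_that("temporal filter preserves the passband and kills stopbands", {
  tr <- 2; n <- 800
  t <- seq_len(n) * tr
  tone <- function(f) sin(2 * pi * f * t)
  spec <- filter_spec(2000, 10)
  # in-band 0.05 Hz tone within 5 percent (exactly preserved here)
  y <- temporal_filter(tone(0.05), spec, tr)
  expect_equal(max(abs(y)), max(abs(tone(0.05))), tolerance = 0.05)
  expect_equal(as.numeric(y), tone(0.05), tolerance = 1e-8)
  # DC removed by the high-pass
  yc <- temporal_filter(matrix(5, n, 1), spec, tr)
  expect_lt(max(abs(yc)), 1e-8)
  # >= 20 dB attenuation at twice the low-pass cutoff (0.2 Hz)
  ys <- temporal_filter(tone(0.2), spec, tr)
  expect_lt(max(abs(ys[100:700, ])), 0.1)
  # notch centre attenuated >= 90 percent
  yn <- temporal_filter(tone(0.1), filter_spec(Inf, 0, list(c(0.1, 0.01))),
                        tr)
  expect_lt(max(abs(yn[100:700, ])), 0.1)
  expect_error(temporal_filter(tone(0.05), filter_spec(2000, 3), tr),
               "Nyquist")
  expect_error(temporal_filter(tone(0.05),
                               filter_spec(Inf, 0, list(c(0.3, 0.01))),
                               tr),
               "Nyquist")
})

test_that("filtering twice is near-idempotent", {
  set.seed(1)
  x <- matrix(rnorm(795 * 20), 795, 20)
  spec <- filter_spec(2000, 10)
  once <- temporal_filter(x, spec, 2)
  twice <- temporal_filter(once, spec, 2)
  expect_lt(max(abs(twice - once)) / stats::sd(once), 0.01)
})

test_that("dynamic band-stop detection flags planted tones only", {
  set.seed(42)
  tr <- 2; n <- 600; V <- 60
  t <- seq_len(n) * tr
  noise <- matrix(rnorm(n * V), n, V)
  expect_length(detect_bandstop(noise, tr), 0)
  shared <- 3 * sin(2 * pi * 0.2 * t)
  x1 <- noise + outer(shared, rep(1, V))
  bands <- detect_bandstop(x1, tr)
  expect_gte(length(bands), 1)
  hit <- vapply(bands, function(b) abs(b[1] - 0.2) <= b[2] + 1e-9,
                logical(1))
  expect_true(any(hit))
  # two tones give two disjoint bands
  shared2 <- 3 * sin(2 * pi * 0.07 * t)
  x2 <- x1 + outer(shared2, rep(1, V))
  bands2 <- detect_bandstop(x2, tr)
  expect_gte(length(bands2), 2)
  ctrs <- vapply(bands2, `[`, numeric(1), 1)
  expect_true(any(abs(ctrs - 0.07) < 0.02) && any(abs(ctrs - 0.2) < 0.02))
  expect_length(detect_bandstop(matrix(1, 100, 5), tr), 0)
})

test_that("Volterra expansion produces the 27-term degree-2 basis", {
  set.seed(2)
  m <- matrix(rnorm(50 * 6), 50, 6)
  X <- volterra_expand(m)
  expect_equal(ncol(X), 27)   # 6 + 6 squares + 15 products
  expect_equal(max(abs(colMeans(X))), 0, tolerance = 1e-12)
  expect_equal(ncol(volterra_expand(m, lag1 = TRUE)), 33)
  expect_true(all(volterra_expand(matrix(0, 20, 6)) == 0))
  # single active column contributes itself and its square
  m1 <- matrix(0, 50, 6); m1[, 3] <- rnorm(50)
  X1 <- volterra_expand(m1)
  expect_equal(X1[, 3], m1[, 3] - mean(m1[, 3]))
  sq <- m1[, 3]^2
  expect_true(any(apply(X1, 2, function(col)
    isTRUE(all.equal(col, sq - mean(sq))))))
  expect_error(volterra_expand(m[, 1:5]), "6 columns")
  m[2, 2] <- NA
  expect_error(volterra_expand(m), "missing")
})

test_that("compartment PCA recovers planted structure deterministically", {
  set.seed(3)
  n <- 120; V <- 40
  # rank-1 data: PC1 explains everything
  u <- rnorm(n)
  x1 <- outer(u, rnorm(V))
  expect_warning(c1 <- compartment_confounds(x1, rep(TRUE, V), k = 5),
                 "truncated")
  expect_equal(ncol(c1$compartment_pcs), 1)
  expect_gt(abs(cor(c1$compartment_pcs[, 1], u)), 0.999)
  # orthogonality of PCs
  x <- matrix(rnorm(n * V), n, V)
  cc <- compartment_confounds(x, rep(TRUE, V), k = 5)
  G <- crossprod(cc$compartment_pcs)
  expect_equal(G, diag(5), tolerance = 1e-10)
  # planted global sine dominates PC1
  g <- sin(2 * pi * seq_len(n) / 30)
  xg <- x + 5 * outer(g, rep(1, V))
  cg <- compartment_confounds(xg, rep(TRUE, V), k = 5)
  expect_gt(abs(cor(cg$compartment_pcs[, 1], g)), 0.95)
  expect_error(compartment_confounds(x, rep(FALSE, V)), "empty")
})

test_that("confound regression leaves orthogonal residuals, never inflates variance", {
  set.seed(4)
  n <- 150
  mot <- matrix(rnorm(n * 6), n, 6)
  X <- volterra_expand(mot)
  mask_ts <- matrix(rnorm(n * 30), n, 30)
  conf <- compartment_confounds(mask_ts, rep(TRUE, 30), k = 5,
                                motion_expanded = X)
  y <- cbind(conf$compartment_mean,                     # pure regressor
             matrix(rnorm(n * 10), n, 10))
  res <- regress_confounds(y, conf)
  expect_lt(max(abs(res[, 1])), 1e-8)
  # orthogonality: residuals vs all regressors
  R <- cbind(1, conf$compartment_mean, conf$compartment_pcs, X)
  dots <- crossprod(R, res)
  norms <- outer(sqrt(colSums(R^2)), sqrt(colSums(res^2)))
  expect_lt(max(abs(dots) / pmax(norms, 1e-12)), 1e-8)
  # variance never increases
  expect_true(all(apply(res, 2, var) <= apply(y, 2, var) + 1e-12))
  # a series orthogonal to every regressor passes through unchanged
  y_orth <- res[, 5]
  res2 <- regress_confounds(matrix(y_orth), conf)
  expect_equal(as.numeric(res2), y_orth, tolerance = 1e-10)
  expect_warning(
    regress_confounds(y, structure(list(compartment_mean = conf$compartment_mean,
                                        compartment_pcs = cbind(conf$compartment_pcs,
                                                                conf$compartment_mean),
                                        motion_expanded = NULL),
                                   class = "confound_set")),
    "rank-deficient")
})

test_that("Gaussian smoothing has the requested FWHM and conserves mass", {
  dims <- c(21, 21, 21)
  delta <- array(0, dims); delta[11, 11, 11] <- 1
  sm <- smooth_spatial(delta, dims, fwhm = 3, spacing = 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation of the half-maximum crossings
  lo <- min(above); hi <- max(above)
  f_lo <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
  f_hi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_equal(f_hi - f_lo, 3, tolerance = 0.5)
  # constant image unchanged
  const <- array(2, dims)
  expect_equal(smooth_spatial(const, dims, 3, 1), const, tolerance = 1e-12)
  # two deltas 10 mm apart stay resolved
  d2 <- array(0, dims); d2[6, 11, 11] <- 1; d2[16, 11, 11] <- 1
  s2 <- smooth_spatial(d2, dims, 3, 1)
  prof2 <- s2[, 11, 11]
  expect_lt(prof2[11], 0.5 * prof2[6])
  expect_warning(smooth_spatial(delta, dims, fwhm = 0.5, spacing = 1),
                 "under-resolved")
  # matrix form matches the volume form
  xm <- matrix(as.vector(delta), 1, prod(dims))
  expect_equal(as.vector(smooth_spatial(xm, dims, 3, 1)), as.vector(sm),
               tolerance = 1e-12)
})

test_that("explained variance is the exact eigenvalue ratio", {
  set.seed(5)
  n <- 80
  # exact rank 5
  x5 <- matrix(rnorm(n * 5), n, 5) %*% matrix(rnorm(5 * 30), 5, 30)
  expect_equal(explained_variance(x5, 5), 1)
  # independent oracle: eigen decomposition of the sample covariance
  x <- matrix(rnorm(n * 25), n, 25)
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(explained_variance(x, 5), sum(ev[1:5]) / sum(ev),
               tolerance = 1e-10)
  # monotone in planted shared-component strength
  g <- rnorm(n)
  fr <- vapply(c(0, 1, 2, 4), function(s)
    explained_variance(x + s * outer(g, rep(1, 25)), 5), numeric(1))
  expect_true(all(diff(fr) > 0))
  expect_equal(explained_variance(matrix(3, n, 10), 5), 0)
})

test_that("the full per-run pipeline returns demeaned cleaned data", {
  lay <- compact_layout()
  pr <- compact_pair(seed = 9, n_volumes = 120, n_subjects = 1, n_runs = 1)
  r <- pr$control$runs[[1]]
  out <- preprocess_run(r$ts, r$motion, pr$control$compartments,
                        pr$control$dim, pr$control$spacing, pr$control$tr)
  expect_equal(nrow(out), 115)
  expect_equal(ncol(out), prod(pr$control$dim))
  expect_lt(max(abs(colMeans(out))), 1e-10)
  expect_false(any(!is.finite(out)))
})
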