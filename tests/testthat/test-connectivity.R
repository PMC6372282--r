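# ROI construction, coupling maps, fingerprints and permutation inference.

test_that("bilateral ROI construction mirrors across the mid-sagittal plane", {
  dims <- c(20, 20, 20); sp <- 1
  r <- make_roi("test", c(14, 10, 10), dims, sp, radius = 4)
  expect_gt(length(r$right), 0)
  # mirrored member sits at x -> 20 - 14 = 6
  rl <- arrayInd(r$left, dims)
  expect_equal(mean((rl[, 1] - 0.5) * sp), 6, tolerance = 0.3)
  # sphere-volume check within 20 percent
  vol <- 4 / 3 * pi * 4^3
  expect_lt(abs(length(r$right) - vol) / vol, 0.2)
  # midline centre: both members share the same voxels
  rm <- make_roi("mid", c(10, 10, 10), dims, sp, radius = 4)
  expect_setequal(rm$left, rm$right)
  # tiny radius gives a single voxel per side
  r1 <- make_roi("pt", c(14.5, 10.5, 10.5), dims, sp, radius = 0.4)
  expect_length(r1$right, 1)
  expect_error(make_roi("out", c(30, 10, 10), dims, sp), "outside")
  expect_error(make_roi("thin", c(14, 10, 10), dims, sp, radius = 0.2),
               "empty")
})

test_that("seed maps are bounded Fisher z with exact known values", {
  dims <- c(8, 8, 2); sp <- 1
  V <- prod(dims)
  n <- 60
  # exact sample correlations via an orthonormal basis
  w <- matrix(rnorm(n * 3), n, 3)
  w <- sweep(w, 2, colMeans(w))
  E <- qr.Q(qr(w))
  seed_series <- E[, 1]
  corr05 <- 0.5 * E[, 1] + sqrt(0.75) * E[, 2]
  x <- matrix(rep(E[, 3], V), n, V)   # independent filler everywhere
  seed_roi <- make_roi("s", c(2.5, 4.5, 0.5), dims, sp, radius = 0.4)
  expect_length(seed_roi$right, 1); expect_length(seed_roi$left, 1)
  x[, seed_roi$right] <- seed_series
  x[, seed_roi$left] <- seed_series
  tgt_vox <- 12L
  stopifnot(!tgt_vox %in% c(seed_roi$right, seed_roi$left))
  x[, tgt_vox] <- corr05
  m <- seed_map(x, seed_roi)
  expect_equal(m[tgt_vox], atanh(0.5), tolerance = 1e-10)
  expect_equal(m[seed_roi$right], 2)     # clipped self-correlation
  expect_true(all(m >= -2 & m <= 2))
  # sign flip of a voxel's series flips its map value
  x2 <- x; x2[, tgt_vox] <- -x2[, tgt_vox]
  expect_equal(seed_map(x2, seed_roi)[tgt_vox], -atanh(0.5),
               tolerance = 1e-10)
  # invariance to voxel-wise affine rescaling
  x3 <- sweep(x, 2, runif(V, 0.5, 3), "*") + 7
  expect_equal(as.numeric(seed_map(x3, seed_roi)), as.numeric(m),
               tolerance = 1e-8)
})

test_that("fingerprints separate within- from out-of-network targets", {
  lay <- compact_layout()
  st <- seed_and_targets(lay)
  pr <- compact_pair(seed = 21, n_volumes = 300, n_subjects = 1, n_runs = 1,
                     effect = effect_spec(local_gain = 1.3,
                                          distal_loss = 0.6))
  fpc <- fingerprint(pr$control$runs[[1]]$ts, st$seed, st$targets)
  in_net <- names(lay$networks)[lay$networks == "sensorimotor"]
  in_net <- setdiff(in_net, lay$seed)
  expect_gt(min(fpc[in_net]), max(fpc[setdiff(names(fpc), in_net)]))
  # planted sharpening: within-network spokes rise, distal spokes fall
  fps <- fingerprint(pr$stim$runs[[1]]$ts, st$seed, st$targets)
  expect_true(all(fps[in_net] > fpc[in_net]))
  out_net <- setdiff(names(fpc), in_net)
  expect_lt(mean(fps[out_net]), mean(fpc[out_net]))
  # overlapping seed/target is refused
  expect_error(fingerprint(pr$control$runs[[1]]$ts, st$seed,
                           c(st$targets, list(st$seed))), "overlaps")
})

test_that("self-coupling tracks within-ROI homogeneity", {
  dims <- c(8, 8, 2); sp <- 1
  roi <- make_roi("s", c(2.5, 4.5, 0.5), dims, sp, radius = 1.5)
  n <- 50; V <- prod(dims)
  shared <- rnorm(n)
  x <- matrix(rep(shared, V), n, V)
  expect_equal(self_coupling(x, roi), 2)   # identical series clip at 2
  set.seed(6)
  x2 <- matrix(rnorm(n * V), n, V)
  expect_lt(abs(self_coupling(x2, roi)), 0.15)
  # monotone in the shared-signal fraction
  sc <- vapply(c(0.2, 0.5, 0.8), function(a) {
    xs <- sqrt(a) * matrix(rep(shared, V), n, V) + sqrt(1 - a) * x2
    self_coupling(xs, roi)
  }, numeric(1))
  expect_true(all(diff(sc) > 0))
  r1 <- make_roi("pt", c(2.5, 4.5, 0.5), dims, sp, radius = 0.4,
                 mirror = FALSE)
  expect_error(self_coupling(x, r1), "single-voxel")
})

test_that("percentile coupling map matches uniform-correlation closed form", {
  n <- 170; V <- 150
  set.seed(7)
  r0 <- 0.4
  # exactly uniform pairwise sample correlation r0: shared + idiosyncratic
  # components drawn from one orthonormal basis
  w <- matrix(rnorm(n * (V + 1)), n, V + 1)
  w <- sweep(w, 2, colMeans(w))
  E <- qr.Q(qr(w))
  x <- sqrt(r0) * E[, rep(1, V)] + sqrt(1 - r0) * E[, -1]
  m <- percentile_coupling_map(x, q = 98)
  expect_equal(mean(m), atanh(r0), tolerance = 1e-6)
  expect_lt(diff(range(m)), 1e-6)
  expect_true(all(percentile_coupling_map(x, q = 100) <= 2))
  # adding a global component raises the map essentially everywhere
  x2 <- x + 1.5 * outer(rnorm(n), rep(1, V))
  m2 <- percentile_coupling_map(x2, q = 98)
  expect_gt(mean(m2 > m), 0.95)
})

test_that("group reduction preserves coupling at and above the data rank", {
  set.seed(8)
  n <- 90; V <- 60; rank <- 10
  x <- matrix(rnorm(n * rank), n, rank) %*% matrix(rnorm(rank * V), rank, V)
  red <- group_reduce(x, k = 40)   # k above true rank: lossless
  expect_equal(cor(red), cor(x), tolerance = 1e-8)
  full <- group_reduce(x, k = rank)
  expect_equal(cor(full), cor(x), tolerance = 1e-8)
  expect_error(group_reduce(x, k = 200), "below k")
  # truncation below the rank denoises: coupling values inflate uniformly
  # but the fingerprint *shape* is preserved (see vignette)
  lay <- compact_layout()
  st <- seed_and_targets(lay)
  pr <- compact_pair(seed = 23, n_volumes = 300, n_subjects = 1, n_runs = 3)
  xs <- lapply(pr$control$runs, `[[`, "ts")
  red2 <- group_reduce(xs, k = 200)
  fp_red <- fingerprint(red2, st$seed, st$targets)
  fp_full <- fingerprint(do.call(rbind, xs), st$seed, st$targets)
  expect_gt(cosine_similarity(fp_red, fp_full), 0.999)
  expect_equal(order(fp_red), order(fp_full))
  expect_true(all(fp_red >= fp_full - 0.01))
})

test_that("cosine similarity follows the closed form and validates input", {
  f1 <- structure(c(a = 1, b = 1))
  f2 <- structure(c(a = 1, b = 0))
  expect_equal(cosine_similarity(f1, f1), 1)
  expect_equal(cosine_similarity(f1, 3 * f1), 1)
  expect_equal(cosine_similarity(f1, f2), 1 / sqrt(2))
  expect_error(cosine_similarity(f1, c(a = 0, b = 0)), "zero-norm")
  expect_error(cosine_similarity(f1, c(b = 1, a = 1)), "target order")
})

test_that("exhaustive relabelling counts identify complements and drop identity", {
  expect_equal(count_exhaustive(18, 9), 24309)
  expect_equal(count_exhaustive(2, 1), 0)
  expect_equal(count_exhaustive(6, 3), 9)
  expect_error(count_exhaustive(7, 3), "equal groups")
})

test_that("permutation test agrees with hand enumeration on 2 vs 2", {
  fps <- lapply(list(c(1, 0.2), c(0.9, 0.3), c(0.2, 1), c(0.25, 0.9)),
                function(v) stats::setNames(v, c("a", "b")))
  res <- permutation_test(fps, c("x", "x", "y", "y"))
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 2)
  # brute force: all C(4,2)/2 - 1 = 2 non-identity groupings
  cosm <- function(iA) {
    F <- do.call(rbind, fps)
    mA <- colMeans(F[iA, ]); mB <- colMeans(F[-iA, ])
    sum(mA * mB) / sqrt(sum(mA^2) * sum(mB^2))
  }
  null_hand <- sort(c(cosm(c(1, 3)), cosm(c(1, 4))))
  expect_equal(sort(res$null_distribution), null_hand, tolerance = 1e-12)
  expect_equal(res$p_value, mean(null_hand <= res$observed_cosine))
})

test_that("identical-condition fingerprints sit at the top of the null", {
  set.seed(9)
  base <- stats::setNames(runif(8, 0.2, 1), letters[1:8])
  fps <- lapply(1:8, function(i) base + rnorm(8, 0, 1e-4))
  res <- permutation_test(fps, rep(c("x", "y"), each = 4))
  expect_gt(res$p_value, 0.5)
  # unbalanced design falls back to Monte-Carlo with a warning
  expect_warning(
    resu <- permutation_test(fps[1:7], c("x", "x", "x", "x", "y", "y", "y"),
                             n_mc = 200, seed = 3),
    "Monte-Carlo")
  expect_false(resu$exhaustive)
  expect_gte(resu$p_value, 1 / 201)
})
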