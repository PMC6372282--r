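# Seed-based coupling maps, connectional fingerprints, and the
# cosine-similarity permutation test.
#
# Coupling is Pearson r, Fisher z-transformed (atanh) and clipped to [-2, 2]
# per voxel pair before any averaging. Bilateral ROIs are averaged across
# hemispheres, so each map/fingerprint value describes a bilateral region.

Z_BOUND <- 2

fisher_z <- function(r) {
  z <- atanh(pmin(pmax(r, -1), 1))
  pmin(pmax(z, -Z_BOUND), Z_BOUND)
}

#' Build a bilateral spherical ROI
#'
#' A Euclidean ball of `radius` mm around `centre` (mm coordinates) and
#' around its mirror across the mid-sagittal plane of the grid (the plane
#' x = extent_x / 2).
#'
#' @param name ROI name.
#' @param centre mm coordinate triple (voxel centres sit at
#'   `(index - 0.5) * spacing`).
#' @param dims Grid voxel dimensions.
#' @param spacing Voxel size, mm (isotropic).
#' @param radius Ball radius, mm.
#' @param mirror Build the mirrored member too.
#' @return An `roi`: integer voxel indices `left` and `right` (right = the
#'   member containing `centre`), `name`, `centre`, `radius`.
#' @export
make_roi <- function(name, centre, dims, spacing, radius = 4,
                     mirror = TRUE) {
  extent <- dims * spacing
  if (any(centre < 0) || any(centre > extent)) {
    stop("ROI centre lies outside the grid")
  }
  ball <- function(ctr) {
    rng <- lapply(1:3, function(d) {
      lo <- max(1L, floor((ctr[d] - radius) / spacing + 0.5))
      hi <- min(dims[d], ceiling((ctr[d] + radius) / spacing + 0.5))
      lo:hi
    })
    g <- expand.grid(rng[[1]], rng[[2]], rng[[3]])
    mm <- (as.matrix(g) - 0.5) * spacing
    d2 <- rowSums(sweep(mm, 2, ctr)^2)
    keep <- d2 < radius^2
    as.integer(g[keep, 1] + dims[1] * (g[keep, 2] - 1 +
                                         dims[2] * (g[keep, 3] - 1)))
  }
  right <- ball(centre)
  left <- if (mirror) {
    ball(c(extent[1] - centre[1], centre[2], centre[3]))
  } else integer(0)
  if (length(right) == 0) {
    stop("empty ROI ball: radius too small to reach any voxel centre")
  }
  structure(list(name = name, centre = centre, radius = radius,
                 left = left, right = right),
            class = "roi")
}

roi_voxels <- function(roi) unique(c(roi$left, roi$right))

# clipped-z correlation of the seed columns against all columns; NA-safe.
# crossprod of standardized columns (BLAS) rather than stats::cor: the
# latter is an order of magnitude slower at fingerprint problem sizes
seed_z <- function(x, seed_idx) {
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- sqrt(colSums(x^2) / n - mu^2) * sqrt(n / (n - 1))
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero)) {
    warning("zero-variance voxel(s): coupling set to 0")
    sdv[zero] <- Inf
  }
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  r <- crossprod(xs[, seed_idx, drop = FALSE], xs) / (n - 1)
  fisher_z(r)
}

#' Seed-based coupling map
#'
#' For each voxel of each ROI member, Pearson correlation with every voxel,
#' Fisher z-transformed and clipped to \[-2, 2\], averaged over the member's
#' voxels, then averaged across hemispheres.
#'
#' @param x T x V cleaned timeseries matrix.
#' @param roi A [make_roi()] object.
#' @return A numeric map of length V (class `seed_map`).
#' @export
seed_map <- function(x, roi) {
  members <- Filter(length, list(roi$left, roi$right))
  z <- seed_z(x, unlist(members))   # one pass over the data
  splits <- rep(seq_along(members), lengths(members))
  maps <- lapply(seq_along(members), function(i) {
    colMeans(z[splits == i, , drop = FALSE])
  })
  out <- Reduce(`+`, maps) / length(maps)
  structure(out, class = "seed_map", seed = roi$name)
}

#' Connectional fingerprint
#'
#' The seed's bilateral coupling map averaged within each target ROI
#' (hemisphere-averaged per target).
#'
#' @param x T x V cleaned timeseries matrix.
#' @param seed_roi A [make_roi()] seed.
#' @param targets Named list of target [make_roi()]s (order fixed).
#' @param map Optional precomputed [seed_map()] for `seed_roi`.
#' @return A `fingerprint`: named numeric vector of bounded-z couplings
#'   with attributes `seed`.
#' @export
fingerprint <- function(x, seed_roi, targets, map = NULL) {
  sv <- roi_voxels(seed_roi)
  for (tg in targets) {
    if (length(intersect(sv, roi_voxels(tg))) > 0) {
      stop(sprintf("target '%s' overlaps the seed ROI", tg$name))
    }
  }
  if (is.null(map)) map <- seed_map(x, seed_roi)
  vals <- vapply(targets, function(tg) {
    members <- Filter(length, list(tg$left, tg$right))
    mean(vapply(members, function(idx) mean(map[idx]), numeric(1)))
  }, numeric(1))
  names(vals) <- vapply(targets, `[[`, character(1), "name")
  structure(vals, class = "fingerprint", seed = seed_roi$name)
}

#' Within-ROI self-coupling
#'
#' For each ROI voxel, the mean bounded-z coupling to every other ROI voxel;
#' then the mean over voxels. A single homogeneous signal gives the clip
#' bound 2; independent voxels give ~0.
#'
#' @param x T x V cleaned timeseries matrix.
#' @param roi A [make_roi()] object.
#' @return Scalar self-coupling estimate.
#' @export
self_coupling <- function(x, roi) {
  idx <- roi_voxels(roi)
  if (length(idx) < 2) stop("self-coupling undefined for single-voxel ROI")
  z <- seed_z(x[, idx, drop = FALSE], seq_along(idx))
  diag(z) <- NA
  mean(rowMeans(z, na.rm = TRUE))
}

#' Percentile coupling map
#'
#' Per voxel: bounded-z coupling to all other voxels, and the linearly
#' interpolated `q`-th percentile of those values. Captures broad coupling
#' inflation from shared (e.g. meningeal) signal.
#'
#' @param x T x V cleaned timeseries matrix.
#' @param q Percentile (default 98).
#' @param chunk Voxels per block (memory control).
#' @return Numeric map of length V.
#' @export
percentile_coupling_map <- function(x, q = 98, chunk = 1024) {
  x <- as.matrix(x)
  V <- ncol(x)
  if (V < 100) warning("percentile coupling map on fewer than 100 voxels")
  xs <- scale(x)
  xs[!is.finite(xs)] <- 0
  n <- nrow(x)
  out <- numeric(V)
  for (lo in seq(1, V, by = chunk)) {
    hi <- min(lo + chunk - 1, V)
    r <- crossprod(xs[, lo:hi, drop = FALSE], xs) / (n - 1)
    z <- fisher_z(r)
    for (j in seq_len(hi - lo + 1)) {
      out[lo + j - 1] <- stats::quantile(z[j, -(lo + j - 1)], q / 100,
                                         names = FALSE, type = 7)
    }
  }
  out
}

#' Group reduction of concatenated timeseries
#'
#' Stacks run-concatenated datasets across subjects and keeps the top-`k`
#' singular components. The reduced series embeds `diag(d_k) %*% t(v_k)`
#' into `k + 1` zero-column-mean pseudo-volumes (via a normalised Helmert
#' rotation), so downstream Pearson-based coupling operations applied to
#' the reduced series reproduce those of the stacked data exactly once `k`
#' reaches the data rank.
#'
#' @param xs List of T_i x V matrices (or a single matrix).
#' @param k Number of components.
#' @return (k + 1) x V reduced series matrix.
#' @export
group_reduce <- function(xs, k = 200) {
  if (is.matrix(xs)) xs <- list(xs)
  X <- do.call(rbind, xs)
  X <- sweep(X, 2, colMeans(X))
  if (nrow(X) < k) stop("concatenated length below k")
  sv <- svd(X, nu = 0, nv = min(k, min(dim(X))))
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  k_eff <- min(k, rank)
  v <- sv$v[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  # orthonormal columns orthogonal to the constant vector: the embedded
  # series has exactly zero column means and crossprod v d^2 v'
  H <- stats::contr.helmert(k_eff + 1)
  Q <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  Q %*% (sv$d[seq_len(k_eff)] * t(v))
}

#' Cosine similarity between fingerprints
#'
#' `dot(f1, f2) / (||f1|| ||f2||)`: the angle between the two fingerprint
#' vectors, invariant to overall amplitude.
#'
#' @param f1,f2 [fingerprint()]s (or bare named vectors) with identical
#'   target order.
#' @return Scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(f1, f2) {
  v1 <- as.numeric(f1); v2 <- as.numeric(f2)
  if (length(v1) != length(v2) ||
      (!is.null(names(f1)) && !is.null(names(f2)) &&
         !identical(names(f1), names(f2)))) {
    stop("fingerprints must share the same target order")
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for zero-norm fingerprint")
  sum(v1 * v2) / (n1 * n2)
}

# enumeration of balanced relabellings with observation 1 fixed in the
# first group (complementary assignments counted once); cached because the
# same design is re-tested across many datasets
.perm_cache <- new.env(parent = emptyenv())

exhaustive_indicators <- function(n, g) {
  key <- paste(n, g)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  combos <- utils::combn(seq(2, n), g - 1)
  P <- ncol(combos)
  ind <- matrix(0, P, n)
  ind[cbind(rep(seq_len(P), each = g - 1), as.vector(combos))] <- 1
  ind[, 1] <- 1
  .perm_cache[[key]] <- ind
  ind
}

#' Number of distinct exhaustive relabellings
#'
#' Two equal groups of size g from n = 2g observations, complementary
#' assignments identified (the statistic is symmetric in group exchange) and
#' the identity excluded: `choose(n, g) / 2 - 1`. For 18 observations in two
#' groups of 9 this is 24309.
#'
#' @param n_total Total observations (even).
#' @param group_size Size of each group (`n_total / 2`).
#' @return Integer count.
#' @export
count_exhaustive <- function(n_total, group_size) {
  if (n_total != 2 * group_size) {
    stop("exhaustive enumeration requires two equal groups")
  }
  choose(n_total, group_size) / 2 - 1
}

#' Permutation test on fingerprint condition labels
#'
#' The observed statistic is the cosine similarity between the mean
#' fingerprint of each condition. The null distribution relabels
#' observations into two groups of the original sizes; lower similarity
#' means greater fingerprint difference, so `p` is the proportion of null
#' similarities at or below the observed one (one-tailed toward
#' dissimilarity). Exhaustive mode enumerates all distinct non-identity
#' relabellings with complementary assignments counted once (24309 for
#' 9 vs 9) and reports the exact proportion; Monte-Carlo mode samples
#' `n_mc` relabellings and reports `(k + 1) / (n_mc + 1)`.
#'
#' @param fps List of [fingerprint()]s (identical target order).
#' @param conditions Factor/character of condition labels (two levels).
#' @param mode "exhaustive" or "monte_carlo"; unbalanced groups fall back
#'   to Monte-Carlo with a warning.
#' @param n_mc Monte-Carlo relabellings.
#' @param seed RNG seed for Monte-Carlo mode.
#' @return A `permutation_result`: `observed_cosine`, `null_distribution`,
#'   `n_permutations`, `p_value`, `exhaustive`, `seed`.
#' @export
permutation_test <- function(fps, conditions,
                             mode = c("exhaustive", "monte_carlo"),
                             n_mc = 9999, seed = 1) {
  mode <- match.arg(mode)
  Fm <- do.call(rbind, lapply(fps, as.numeric))
  nm <- lapply(fps, names)
  if (length(unique(vapply(nm, paste, character(1), collapse = "|"))) > 1) {
    stop("fingerprints must share the same target order")
  }
  cond <- as.factor(conditions)
  if (nlevels(cond) != 2) stop("exactly two condition levels required")
  gA <- which(cond == levels(cond)[1])
  gB <- which(cond == levels(cond)[2])
  if (length(gA) < 2 || length(gB) < 2) {
    stop("need at least 2 observations per condition")
  }
  n <- nrow(Fm)
  cos_groups <- function(idxA) {
    mA <- colMeans(Fm[idxA, , drop = FALSE])
    mB <- colMeans(Fm[-idxA, , drop = FALSE])
    sum(mA * mB) / sqrt(sum(mA^2) * sum(mB^2))
  }
  observed <- cos_groups(gA)
  if (mode == "exhaustive" && length(gA) != length(gB)) {
    warning("unbalanced groups: falling back to Monte-Carlo relabelling")
    mode <- "monte_carlo"
  }
  if (mode == "exhaustive") {
    g <- length(gA)
    ind <- exhaustive_indicators(n, g)
    obs_ind <- as.numeric(seq_len(n) %in% gA)
    if (obs_ind[1] == 0) obs_ind <- 1 - obs_ind
    keep <- rowSums(abs(sweep(ind, 2, obs_ind)) ) > 0
    ind <- ind[keep, , drop = FALSE]
    mA <- (ind %*% Fm) / g
    mB <- ((1 - ind) %*% Fm) / (n - g)
    null <- rowSums(mA * mB) /
      sqrt(rowSums(mA^2) * rowSums(mB^2))
    p <- mean(null <= observed)
    res_seed <- NA_integer_
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_mc), function(i) {
      cos_groups(sample.int(n, length(gA)))
    }, numeric(1))
    p <- (sum(null <= observed) + 1) / (n_mc + 1)
    res_seed <- seed
  }
  structure(list(observed_cosine = observed, null_distribution = null,
                 n_permutations = length(null), p_value = p,
                 exhaustive = mode == "exhaustive", seed = res_seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Fingerprint permutation test: cos = %.4f, p = %.4g (%s, %d relabellings)\n",
    x$observed_cosine, x$p_value,
    if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_permutations))
  invisible(x)
}

#' Per-run fingerprints for a dataset pair
#'
#' Convenience wrapper: computes the seed fingerprint of every run in one or
#' more datasets, tagging each with its condition.
#'
#' @param datasets List of `bold_dataset`s (e.g. control and stim).
#' @param seed_roi Seed [make_roi()].
#' @param targets Named list of target ROIs.
#' @return List with `fingerprints` (list) and `conditions` (character).
#' @export
run_fingerprints <- function(datasets, seed_roi, targets) {
  fps <- list(); conds <- character(0)
  for (ds in datasets) {
    for (r in ds$runs) {
      fps[[length(fps) + 1]] <- fingerprint(r$ts, seed_roi, targets)
      conds <- c(conds, r$condition)
    }
  }
  list(fingerprints = fps, conditions = conds)
}
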