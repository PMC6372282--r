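# BOLD timeseries cleaning: initial-volume drop, zero-phase temporal
# filtering with dynamically detected band-stop notches, compartment-PCA
# confound regression with Volterra-expanded motion regressors, volumetric
# Gaussian smoothing, and demeaning.
#
# Timeseries are stored as T x V matrices (rows = volumes, columns = voxels
# in array order of the label grid).

#' Temporal filter specification
#'
#' Cutoffs are given in seconds of period, following the convention of the
#' processing narrative: high-pass at 2000 s passes fluctuations slower than
#' 2000 s periods... i.e. removes frequencies below 1/2000 Hz; low-pass at
#' 10 s removes frequencies above 1/10 Hz. Notches are (centre Hz,
#' halfwidth Hz) pairs.
#'
#' @param highpass_s High-pass cutoff period, s (`Inf` disables).
#' @param lowpass_s Low-pass cutoff period, s (`0` disables).
#' @param notches List of numeric pairs `c(centre_hz, halfwidth_hz)`.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(highpass_s = 2000, lowpass_s = 10,
                        notches = list()) {
  stopifnot(highpass_s > lowpass_s)
  structure(list(highpass_s = highpass_s, lowpass_s = lowpass_s,
                 notches = notches),
            class = "filter_spec")
}

#' Discard initial volumes
#'
#' Drops the first `n` rows of a run (RF saturation volumes): 800 volumes
#' become 795.
#'
#' @param x T x V timeseries matrix (or vector).
#' @param n Number of initial volumes to drop.
#' @return The shortened timeseries.
#' @export
drop_initial_volumes <- function(x, n = 5) {
  x <- as.matrix(x)
  if (nrow(x) <= n) {
    stop(sprintf("run has %d volumes; cannot drop %d", nrow(x), n))
  }
  if (n == 0) return(x)
  x[-seq_len(n), , drop = FALSE]
}

# ideal (brick-wall) zero-phase gains: exactly idempotent, unit passband,
# total stopband rejection (see vignette for the design rationale)
edge_gain <- function(f, cutoff_hz, type) {
  if (type == "low") as.numeric(f <= cutoff_hz) else
    as.numeric(f >= cutoff_hz & f > 0)
}

notch_gain <- function(f, centre, halfwidth) {
  as.numeric(abs(f - centre) > halfwidth)
}

#' Zero-phase temporal filtering
#'
#' Applies high-pass, low-pass and band-stop gains in the frequency domain
#' (real symmetric gains, hence exactly zero-phase). Gains are ideal
#' (brick-wall) responses: unit passband, total stopband rejection, and
#' exact idempotence under re-filtering; notch gains are zero within one
#' halfwidth of the notch centre.
#'
#' @param x T x V timeseries matrix (or a single series).
#' @param spec A [filter_spec()].
#' @param tr Repetition time, s.
#' @return Filtered matrix of the same shape.
#' @export
temporal_filter <- function(x, spec = filter_spec(), tr) {
  stopifnot(tr > 0)
  x <- as.matrix(x)
  n <- nrow(x)
  nyq <- 1 / (2 * tr)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) / (n * tr)
  gain <- rep(1, n)
  if (is.finite(spec$highpass_s)) {
    gain <- gain * edge_gain(f, 1 / spec$highpass_s, "high")
  }
  if (spec$lowpass_s > 0) {
    fc <- 1 / spec$lowpass_s
    if (fc >= nyq) stop("low-pass cutoff at or beyond Nyquist frequency")
    gain <- gain * edge_gain(f, fc, "low")
  }
  for (nt in spec$notches) {
    if (nt[1] <= 0 || nt[1] >= nyq) {
      stop("notch centre outside (0, Nyquist)")
    }
    gain <- gain * notch_gain(f, nt[1], nt[2])
  }
  Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / n
}

#' Detect band-stop notches from principal-component spectra
#'
#' Computes the amplitude spectra of the first `n_pcs` principal components
#' of the timeseries, flags frequency bins whose amplitude exceeds
#' `threshold` times a rolling median, and merges adjacent flagged bins into
#' notch bands (each widened by `halfwidth_bins`).
#'
#' @param x T x V timeseries matrix.
#' @param tr Repetition time, s.
#' @param n_pcs Number of principal components to scan.
#' @param threshold Peak threshold relative to the rolling median.
#' @param window Rolling-median window, bins (odd).
#' @param halfwidth_bins Half-width added around each flagged bin.
#' @return List of `c(centre_hz, halfwidth_hz)` pairs (possibly empty).
#' @export
detect_bandstop <- function(x, tr, n_pcs = 3, threshold = 5, window = 21,
                            halfwidth_bins = 2) {
  x <- as.matrix(x)
  if (ncol(x) < n_pcs) stop("need at least n_pcs voxels")
  xc <- sweep(x, 2, colMeans(x))
  if (all(abs(xc) < 1e-12)) return(list())
  sv <- svd(xc, nu = n_pcs, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  n <- nrow(x)
  nbin <- floor(n / 2)
  freqs <- (seq_len(nbin)) / (n * tr)   # exclude DC
  flagged <- rep(FALSE, nbin)
  for (j in seq_len(n_pcs)) {
    amp <- Mod(stats::fft(pcs[, j]))[2:(nbin + 1)]
    med <- stats::runmed(amp, k = min(window, 2 * floor(nbin / 2) - 1))
    flagged <- flagged | (amp > threshold * pmax(med, 1e-12))
  }
  if (!any(flagged)) return(list())
  for (h in seq_len(halfwidth_bins)) {
    flagged <- flagged | c(flagged[-1], FALSE) | c(FALSE, flagged[-nbin])
  }
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  bands <- list()
  df <- 1 / (n * tr)
  for (i in which(runs$values)) {
    lo <- freqs[starts[i]]; hi <- freqs[ends[i]]
    bands[[length(bands) + 1]] <- c((lo + hi) / 2,
                                    max((hi - lo) / 2, df))
  }
  bands
}

#' Second-degree Volterra expansion of motion parameters
#'
#' Expands the 6 motion (B0-confound) parameters into the 6 linear terms
#' plus all 21 degree-2 products (squares and pairwise products): 27
#' demeaned regressors. With `lag1 = TRUE`, the 6 one-volume-lagged linear
#' terms are appended (33 columns).
#'
#' @param motion T x 6 numeric matrix or data.frame.
#' @param lag1 Append lag-1 linear terms.
#' @return T x 27 (or T x 33) demeaned regressor matrix.
#' @export
volterra_expand <- function(motion, lag1 = FALSE) {
  m <- as.matrix(motion)
  if (ncol(m) != 6) stop("motion parameters must have 6 columns")
  if (any(!is.finite(m))) stop("motion parameters contain missing values")
  cols <- list()
  for (i in 1:6) cols[[length(cols) + 1]] <- m[, i]
  for (i in 1:6) for (j in i:6) {
    cols[[length(cols) + 1]] <- m[, i] * m[, j]
  }
  if (lag1) {
    for (i in 1:6) {
      cols[[length(cols) + 1]] <- c(m[1, i], m[-nrow(m), i])
    }
  }
  out <- do.call(cbind, cols)
  sweep(out, 2, colMeans(out))
}

#' Compartment confound extraction
#'
#' Mean time course plus the first `k` temporal principal components (left
#' singular vectors of the demeaned within-mask voxel-time matrix), with a
#' deterministic sign convention (largest-magnitude element positive).
#'
#' @param x T x V timeseries matrix.
#' @param mask Logical vector/array (length V) or integer voxel indices
#'   selecting the compartment.
#' @param k Number of principal components.
#' @param motion_expanded Optional regressor matrix from
#'   [volterra_expand()] to carry along.
#' @return A `confound_set`: `compartment_mean`, `compartment_pcs` (T x k),
#'   `motion_expanded` (possibly NULL).
#' @export
compartment_confounds <- function(x, mask, k = 5, motion_expanded = NULL) {
  x <- as.matrix(x)
  idx <- if (is.logical(mask)) which(as.vector(mask)) else as.integer(mask)
  if (length(idx) == 0) stop("compartment mask is empty")
  xm <- x[, idx, drop = FALSE]
  mu <- rowMeans(xm)
  xc <- sweep(xm, 2, colMeans(xm))
  sv <- svd(xc, nu = min(k, min(dim(xc))), nv = 0)
  rank <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1])
  k_eff <- min(k, rank)
  if (k_eff < k) {
    warning(sprintf("compartment rank %d < requested %d components; truncated",
                    rank, k))
  }
  pcs <- sv$u[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(ncol(pcs))) {
    if (pcs[which.max(abs(pcs[, j])), j] < 0) pcs[, j] <- -pcs[, j]
  }
  structure(list(compartment_mean = mu, compartment_pcs = pcs,
                 motion_expanded = motion_expanded),
            class = "confound_set")
}

#' Regress confounds out of every voxel
#'
#' Ordinary least-squares residuals against an intercept, the compartment
#' mean + principal components (when `include_compartment`), and the
#' expanded motion regressors. Rank-deficient columns are dropped with a
#' warning; residuals are orthogonal to every retained regressor.
#'
#' @param x T x V timeseries matrix.
#' @param confounds A [compartment_confounds()] result.
#' @param include_compartment If `FALSE`, only motion terms are used (the
#'   alternative pipeline that leaves compartment signal in the data).
#' @return Residual matrix of the same shape.
#' @export
regress_confounds <- function(x, confounds, include_compartment = TRUE) {
  x <- as.matrix(x)
  X <- matrix(1, nrow(x), 1)
  if (include_compartment) {
    X <- cbind(X, confounds$compartment_mean, confounds$compartment_pcs)
  }
  if (!is.null(confounds$motion_expanded)) {
    X <- cbind(X, confounds$motion_expanded)
  }
  if (nrow(X) != nrow(x)) stop("confound length does not match timeseries")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning(sprintf("dropped %d rank-deficient confound column(s)",
                    ncol(X) - qx$rank))
  }
  qr.resid(qx, x)
}

#' Volumetric Gaussian smoothing
#'
#' Separable Gaussian convolution per volume with sigma = FWHM / 2.3548 mm,
#' replicate padding at the faces. The kernel is normalised, so interior
#' sums are conserved.
#'
#' @param x T x V timeseries matrix (columns in array order of `dim`), or a
#'   3D array (single volume).
#' @param dims Voxel dimensions of the grid.
#' @param fwhm Kernel full width at half maximum, mm.
#' @param spacing Voxel size, mm.
#' @return Smoothed data of the same shape.
#' @export
smooth_spatial <- function(x, dims, fwhm = 3, spacing) {
  stopifnot(spacing > 0)
  if (fwhm < spacing) {
    warning("FWHM below voxel size: smoothing kernel is under-resolved")
  }
  sigma_vox <- fwhm / 2.3548 / spacing
  rad <- max(1L, ceiling(3 * sigma_vox))
  kern <- exp(-((-rad):rad)^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  single <- is.array(x) && length(dim(x)) == 3
  if (single) {
    arr <- array(x, dim = c(dims, 1))
  } else {
    x <- as.matrix(x)
    arr <- array(t(x), dim = c(dims, nrow(x)))
  }
  for (d in 1:3) {
    if (dims[d] == 1) next
    out <- array(0, dim = dim(arr))
    for (o in (-rad):rad) {
      n <- dims[d]
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- switch(d, arr[idx, , , , drop = FALSE],
                        arr[, idx, , , drop = FALSE],
                        arr[, , idx, , drop = FALSE])
      out <- out + kern[o + rad + 1] * shifted
    }
    arr <- out
  }
  if (single) array(arr, dim = dims) else
    t(matrix(arr, prod(dims), dim(arr)[4]))
}

#' Variance explained by the first k principal components
#'
#' Sum of the first `k` eigenvalues of the covariance matrix of the
#' compartment signals divided by the sum of all eigenvalues.
#'
#' @param x T x V matrix of compartment signals.
#' @param k Number of leading components.
#' @return Fraction in \[0, 1\] (0 for zero-variance data).
#' @export
explained_variance <- function(x, k = 5) {
  x <- as.matrix(x)
  if (ncol(x) < k + 1) stop("need at least k + 1 signals")
  xc <- sweep(x, 2, colMeans(x))
  d2 <- svd(xc, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot <= 0) return(0)
  sum(d2[seq_len(min(k, length(d2)))]) / tot
}

#' Full preprocessing pipeline for one run
#'
#' Order: drop initial volumes, high-pass, dynamic band-stop, compartment +
#' motion confound regression, low-pass, volumetric smoothing, demean.
#'
#' @param ts T x V timeseries matrix of one run.
#' @param motion T x 6 motion-parameter table for the full run (trimmed
#'   along with the data).
#' @param compartments Label array/vector over voxels with values "GM",
#'   "WM", "meningeal" (others ignored).
#' @param dims Grid voxel dimensions.
#' @param spacing Voxel size, mm.
#' @param tr Repetition time, s.
#' @param spec A [filter_spec()] (its `notches` are replaced by detected
#'   bands when `detect_notches`).
#' @param n_drop Initial volumes to discard.
#' @param include_meningeal If `TRUE` (default) confound components come
#'   from the combined WM + meningeal compartment; if `FALSE` from WM alone.
#' @param n_pcs Compartment principal components to regress.
#' @param detect_notches Detect band-stop bands from the data.
#' @param fwhm Smoothing kernel FWHM, mm (0 disables).
#' @return Cleaned T' x V matrix (T' = T - n_drop), demeaned.
#' @export
preprocess_run <- function(ts, motion, compartments, dims, spacing, tr,
                           spec = filter_spec(), n_drop = 5,
                           include_meningeal = TRUE, n_pcs = 5,
                           detect_notches = TRUE, fwhm = 3) {
  comp <- as.vector(compartments)
  x <- drop_initial_volumes(ts, n_drop)
  if (!is.null(motion)) {
    motion <- drop_initial_volumes(as.matrix(motion), n_drop)
  }
  hp_only <- filter_spec(spec$highpass_s, 0)
  x <- temporal_filter(x, hp_only, tr)
  notches <- if (detect_notches) detect_bandstop(x, tr) else spec$notches
  if (length(notches) > 0) {
    x <- temporal_filter(x, filter_spec(Inf, 0, notches), tr)
  }
  mask <- if (include_meningeal) comp %in% c("WM", "meningeal") else
    comp == "WM"
  mot <- if (is.null(motion)) NULL else volterra_expand(motion)
  conf <- compartment_confounds(x, mask, k = n_pcs, motion_expanded = mot)
  x <- regress_confounds(x, conf, include_compartment = TRUE)
  if (spec$lowpass_s > 0) {
    x <- temporal_filter(x, filter_spec(Inf, spec$lowpass_s), tr)
  }
  if (fwhm > 0) {
    x <- smooth_spatial(x, dims, fwhm = fwhm, spacing = spacing)
  }
  sweep(x, 2, colMeans(x))
}

#' Preprocess every run of a BOLD dataset
#'
#' Applies [preprocess_run()] to each run of a [make_bold_dataset()] object,
#' returning a dataset of cleaned runs.
#'
#' @param dataset A `bold_dataset`.
#' @param ... Passed to [preprocess_run()].
#' @return The dataset with cleaned `ts` matrices.
#' @export
preprocess_bold <- function(dataset, ...) {
  dataset$runs <- lapply(dataset$runs, function(r) {
    r$ts <- preprocess_run(r$ts, r$motion, dataset$compartments,
                           dataset$dim, dataset$spacing, dataset$tr, ...)
    r$motion <- NULL
    r
  })
  dataset$preprocessed <- TRUE
  dataset
}
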