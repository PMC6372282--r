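# Synthetic multi-subject, multi-run, two-condition BOLD data with
# block-structured network coupling, a planted "sharpening" effect on the
# seed region's coupling profile, and a shared slow component loaded most
# heavily on the meningeal compartment.
#
# Latent construction: network signals are an orthonormalised white basis
# mixed by the Cholesky factor of the network coupling matrix, so the
# *sample* correlation of the latent network signals equals the requested
# matrix exactly. ROI latents load on their network's signal with weight
# sqrt(w); voxels load on their ROI latent with weight sqrt(v) plus white
# noise. The sharpening effect multiplies the within-network ROI coupling w
# of the stimulated network by local_gain and the stimulated network's
# cross-network couplings by distal_loss (applied as a congruence scaling,
# hence provably positive semidefinite).

#' Planted TUS effect specification
#'
#' @param seed_roi Name of the stimulated ROI (its network is "sharpened").
#' @param local_gain Multiplicative factor >= 1 on within-network coupling.
#' @param distal_loss Multiplicative factor in \[0, 1\] on the stimulated
#'   network's coupling with other networks.
#' @param global_confound_sd Amplitude of the shared slow component
#'   concentrated in the meningeal compartment (0 disables).
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(seed_roi = "SMA", local_gain = 1.3,
                        distal_loss = 0.6, global_confound_sd = 0) {
  stopifnot(local_gain >= 1, distal_loss >= 0, distal_loss <= 1,
            global_confound_sd >= 0)
  structure(list(seed_roi = seed_roi, local_gain = local_gain,
                 distal_loss = distal_loss,
                 global_confound_sd = global_confound_sd),
            class = "effect_spec")
}

#' Default synthetic network layout
#'
#' Twelve bilateral 4 mm ROIs on a 16 x 16 x 10 grid (2 mm voxels),
#' organised into three networks mirroring the fingerprint targets of a
#' dorsomedial-frontal TUS study: a sensorimotor network around the seed
#' (SMA, M1, SPL, MCC), a prefrontal network (FPC, 9m, 9-46d, 11m), and a
#' temporoparietal network (aSTG, midSTS, IPLc, PCC). The top two grid
#' slices form the meningeal compartment; remaining unlabelled voxels are
#' white matter.
#'
#' @param dims Grid voxel dimensions.
#' @param spacing Voxel size, mm.
#' @param radius ROI radius, mm.
#' @return List: `rois` (named list of [make_roi()]), `networks` (named
#'   character vector ROI -> network), `seed` (seed ROI name),
#'   `compartments` (label array: "GM", "WM", "meningeal"), `dims`,
#'   `spacing`.
#' @export
synthetic_network_layout <- function(dims = c(16, 16, 10), spacing = 2,
                                     radius = 4) {
  extent <- dims * spacing
  roi_names <- c("SMA", "M1", "SPL", "MCC",
                 "FPC", "9m", "9-46d", "11m",
                 "aSTG", "midSTS", "IPLc", "PCC")
  networks <- stats::setNames(rep(c("sensorimotor", "prefrontal",
                                    "temporoparietal"), each = 4),
                              roi_names)
  # right-hemisphere centres on a lattice clear of the meningeal slab
  xs <- extent[1] / 2 + extent[1] * c(1 / 8, 3 / 8)  # 20, 28 by default
  ys <- seq(extent[2] / 8, 7 * extent[2] / 8, length.out = 4)
  zs <- extent[3] * c(0.25, 0.55)  # clear of the meningeal top slices
  slots <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  slots <- slots[seq_len(length(roi_names)), , drop = FALSE]
  rois <- list()
  for (i in seq_along(roi_names)) {
    rois[[roi_names[i]]] <- make_roi(roi_names[i], slots[i, ], dims,
                                     spacing, radius = radius)
  }
  comp <- array("WM", dim = dims)
  comp[, , dims[3] - c(1, 0)] <- "meningeal"
  for (r in rois) comp[roi_voxels(r)] <- "GM"
  list(rois = rois, networks = networks, seed = "SMA",
       compartments = comp, dims = dims, spacing = spacing)
}

# orthonormal T x k basis from column-centred white noise; the columns are
# exactly orthonormal and exactly mean-zero, so Cholesky mixtures have
# sample correlation equal to the target matrix to machine precision
orthonormal_basis <- function(T_len, k) {
  w <- matrix(stats::rnorm(T_len * k), T_len, k)
  w <- sweep(w, 2, colMeans(w))
  qr.Q(qr(w))
}

# nearest PSD projection by eigenvalue clipping, unit diagonal restored
nearest_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (all(e$values >= -1e-10)) return(m)
  m2 <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
  d <- sqrt(diag(m2))
  m2 / outer(d, d)
}

# slow shared component: low-pass filtered standardized white noise
slow_component <- function(T_len, tr, cutoff_s = 20) {
  g <- temporal_filter(matrix(stats::rnorm(T_len)),
                       filter_spec(Inf, cutoff_s), tr)
  as.numeric(scale(g))
}

#' Generate a control / stim BOLD dataset pair
#'
#' Multi-subject, multi-run voxel timeseries whose latent network signals
#' have (sample-)exact correlation `base_coupling` in the control condition
#' and the sharpening-modified matrix in the stim condition, plus white
#' voxel noise, plus `global_confound_sd` times a shared slow component
#' loaded most heavily on meningeal voxels. Motion parameters are smooth
#' low-amplitude random walks.
#'
#' @param n_subjects,n_runs,n_volumes Design (default 3 subjects, 3 runs of
#'   800 volumes).
#' @param tr Repetition time, s.
#' @param layout A [synthetic_network_layout()] (ROIs, networks, labels).
#' @param base_coupling K x K symmetric unit-diagonal PSD network coupling
#'   matrix (K = number of networks); default couples the seed network
#'   weakly to prefrontal (0.2) and moderately to temporoparietal (0.45).
#' @param effect An [effect_spec()] applied in the stim condition.
#' @param within_network ROI-level within-network coupling w.
#' @param voxel_coupling Voxel-on-ROI-latent shared-variance fraction v.
#' @param meningeal_loading,tissue_loading Loadings of the shared slow
#'   component on meningeal and GM/WM voxels respectively.
#' @param seed Integer RNG seed; identical seeds give identical datasets.
#' @return List with `control` and `stim`, each a `bold_dataset`: `runs`
#'   (list of `subject`, `run`, `condition`, `ts` T x V matrix, `motion`
#'   T x 6), `dim`, `spacing`, `tr`, `compartments`, `layout`,
#'   `network_signals` (per run, latent K-column matrices).
#' @export
make_bold_dataset <- function(n_subjects = 3, n_runs = 3, n_volumes = 800,
                              tr = 2, layout = synthetic_network_layout(),
                              base_coupling = NULL,
                              effect = effect_spec(), seed = 1,
                              within_network = 0.45, voxel_coupling = 0.5,
                              meningeal_loading = 1, tissue_loading = 0.3) {
  if (n_volumes < 100) stop("need at least 100 volumes per run")
  nets <- unique(layout$networks)
  K <- length(nets)
  if (is.null(base_coupling)) {
    base_coupling <- diag(K)
    rownames(base_coupling) <- colnames(base_coupling) <- nets
    base_coupling["sensorimotor", "prefrontal"] <-
      base_coupling["prefrontal", "sensorimotor"] <- 0.2
    base_coupling["sensorimotor", "temporoparietal"] <-
      base_coupling["temporoparietal", "sensorimotor"] <- 0.45
    base_coupling["prefrontal", "temporoparietal"] <-
      base_coupling["temporoparietal", "prefrontal"] <- 0.45
  }
  if (!isSymmetric(unname(base_coupling)) ||
      any(abs(diag(base_coupling) - 1) > 1e-8) ||
      any(eigen(base_coupling, symmetric = TRUE,
                only.values = TRUE)$values < -1e-10)) {
    stop("base_coupling must be symmetric, unit-diagonal and positive semidefinite")
  }
  seed_net <- layout$networks[[effect$seed_roi]]
  s_idx <- match(seed_net, nets)

  # stim-condition network matrix: congruence scaling of the seed network's
  # row/column by delta plus a rank-one diagonal restore (PSD by
  # construction); nearest_psd() is a safety no-op here
  delta <- effect$distal_loss / sqrt(effect$local_gain)
  C_stim <- base_coupling
  C_stim[s_idx, ] <- C_stim[s_idx, ] * delta
  C_stim[, s_idx] <- C_stim[, s_idx] * delta
  C_stim[s_idx, s_idx] <- 1
  C_stim <- nearest_psd(C_stim)

  M <- length(layout$rois)
  roi_names <- names(layout$rois)
  V <- prod(layout$dims)
  comp <- as.vector(layout$compartments)
  roi_of_voxel <- rep(NA_integer_, V)
  for (i in seq_len(M)) {
    roi_of_voxel[roi_voxels(layout$rois[[i]])] <- i
  }
  gm_idx <- which(!is.na(roi_of_voxel))
  men_idx <- which(comp == "meningeal")
  load <- ifelse(comp == "meningeal", meningeal_loading, tissue_loading)

  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max,
                                 2 * n_subjects * n_runs),
                      ncol = 2)

  make_run <- function(rs, subject, run, condition) {
    set.seed(rs)
    stim <- condition == "stim"
    C <- if (stim) C_stim else base_coupling
    w <- rep(within_network, M)
    if (stim) {
      in_seed_net <- layout$networks[roi_names] == seed_net
      w[in_seed_net] <- pmin(0.95, w[in_seed_net] * effect$local_gain)
    }
    E <- orthonormal_basis(n_volumes, K + M) * sqrt(n_volumes - 1)
    Z <- E[, seq_len(K), drop = FALSE] %*% chol(C)
    U <- sapply(seq_len(M), function(r) {
      k <- match(layout$networks[[roi_names[r]]], nets)
      sqrt(w[r]) * Z[, k] + sqrt(1 - w[r]) * E[, K + r]
    })
    ts <- matrix(stats::rnorm(n_volumes * V), n_volumes, V)
    v <- voxel_coupling
    ts[, gm_idx] <- sqrt(v) * U[, roi_of_voxel[gm_idx]] +
      sqrt(1 - v) * ts[, gm_idx]
    if (effect$global_confound_sd > 0) {
      g <- slow_component(n_volumes, tr)
      ts <- ts + (effect$global_confound_sd * g) %o% load
    }
    motion <- sapply(1:6, function(j) {
      stats::filter(cumsum(stats::rnorm(n_volumes, 0, 2e-3)),
                    rep(1 / 5, 5), sides = 2)
    })
    motion[!is.finite(motion)] <- 0
    list(subject = subject, run = run, condition = condition,
         ts = ts, motion = motion, network_signals = Z / sqrt(n_volumes - 1))
  }

  build <- function(condition, col) {
    runs <- list()
    i <- 0
    for (s in seq_len(n_subjects)) for (r in seq_len(n_runs)) {
      i <- i + 1
      runs[[i]] <- make_run(run_seeds[i, col], s, r, condition)
    }
    structure(list(runs = runs, dim = layout$dims,
                   spacing = layout$spacing, tr = tr,
                   compartments = layout$compartments, layout = layout,
                   effect = effect, seed = seed, condition = condition),
              class = "bold_dataset")
  }
  list(control = build("control", 1), stim = build("stim", 2))
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic BOLD dataset (%s): %d runs of %d volumes, %s grid @ %g mm, TR %g s\n",
    x$condition, length(x$runs), nrow(x$runs[[1]]$ts),
    paste(x$dim, collapse = "x"), x$spacing, x$tr))
  invisible(x)
}

#' Concatenate the runs of one subject (or all runs)
#'
#' @param dataset A `bold_dataset`.
#' @param subject Subject id, or `NULL` for all runs.
#' @return A single T_total x V matrix.
#' @export
concatenate_runs <- function(dataset, subject = NULL) {
  runs <- dataset$runs
  if (!is.null(subject)) {
    runs <- Filter(function(r) r$subject == subject, runs)
  }
  do.call(rbind, lapply(runs, `[[`, "ts"))
}
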