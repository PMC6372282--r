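# Shared fixtures: compact synthetic layout and an independent brute-force
# Rayleigh integral oracle.

compact_layout <- function() {
  synthetic_network_layout(dims = c(12, 12, 8), spacing = 2, radius = 3)
}

compact_pair <- function(seed, n_volumes = 200, n_subjects = 3, n_runs = 3,
                         effect = effect_spec(local_gain = 1,
                                              distal_loss = 1),
                         layout = compact_layout()) {
  make_bold_dataset(n_subjects = n_subjects, n_runs = n_runs,
                    n_volumes = n_volumes, layout = layout,
                    effect = effect, seed = seed)
}

seed_and_targets <- function(layout) {
  list(seed = layout$rois[[layout$seed]],
       targets = layout$rois[setdiff(names(layout$rois), layout$seed)])
}

# Brute-force Rayleigh surface integral over a uniformly driven spherical
# cap, written independently of the package's element discretiser: plain
# double loop over a fine theta/phi quadrature, evaluated at axial points.
brute_force_rayleigh_axis <- function(roc, aperture, f0, z_mm,
                                      n_theta = 400, c_water = 1500) {
  a <- aperture / 2
  theta_max <- asin(a / roc)
  k <- 2 * pi * f0 / c_water * 1e-3    # 1/mm
  dtheta <- theta_max / n_theta
  acc <- complex(length.out = length(z_mm))
  for (it in seq_len(n_theta)) {
    th <- (it - 0.5) * dtheta
    # cap ring: axial depth and radius (apex at z = 0, focus at z = roc);
    # on-axis symmetry collapses the phi integral to the ring area
    zc <- roc * (1 - cos(th))
    rc <- roc * sin(th)
    dS_ring <- 2 * pi * roc^2 * sin(th) * dtheta
    R <- sqrt(rc^2 + (z_mm - zc)^2)
    acc <- acc + exp(1i * k * R) / R * dS_ring
  }
  (k / (2 * pi)) * Mod(acc)   # source pressure 1, mm units cancel
}
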