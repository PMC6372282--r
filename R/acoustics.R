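# Acoustic medium mapping and focused pressure-field estimation.
#
# The transcranial propagation model is deliberately monochromatic: a
# Rayleigh surface integral over the apodized spherical cap gives the
# steady-state pressure amplitude in water, and heterogeneous media attenuate
# each voxel's amplitude by the line integral of the attenuation coefficient
# along the source-to-voxel ray. Absolute amplitude is anchored by the
# free-water calibration of the transducer (1.2 MPa at 130 V), mirroring the
# standard practice of rescaling simulated fields by a hydrophone reference.

DB_TO_NP <- 8.6859  # dB per neper

#' Medium mapping parameters
#'
#' Parameters of the linear Hounsfield-unit (HU) to acoustic-property maps
#' and of the porosity attenuation power law used for skull bone. HU = 0 maps
#' to water/soft tissue (`rho_water`, `c_water`); HU = `hu_ref` maps to
#' compact bone (`rho_max`, `c_max`). Attenuation in bone follows
#' \eqn{\alpha = \alpha_0 f^b \phi^\beta} (dB/cm, f in MHz) where the
#' porosity \eqn{\phi} is the normalised density deficit.
#'
#' @param rho_water Water/soft-tissue density, kg/m^3.
#' @param c_water Water/soft-tissue sound speed, m/s.
#' @param rho_max Compact-bone density, kg/m^3.
#' @param c_max Compact-bone sound speed, m/s.
#' @param beta Porosity exponent of the attenuation power law.
#' @param alpha0 Attenuation prefactor, dB/cm/MHz^b.
#' @param b Frequency exponent.
#' @param hu_ref Hounsfield value mapped to (`rho_max`, `c_max`).
#' @return An object of class `medium_mapping_params`.
#' @export
medium_mapping_params <- function(rho_water = 1000, c_water = 1500,
                                  rho_max = 2200, c_max = 3100,
                                  beta = 0.5, alpha0 = 8, b = 1.1,
                                  hu_ref = 2000) {
  stopifnot(rho_max > rho_water, c_max > c_water, beta > 0, alpha0 >= 0,
            hu_ref > 0)
  structure(list(rho_water = rho_water, c_water = c_water,
                 rho_max = rho_max, c_max = c_max,
                 beta = beta, alpha0 = alpha0, b = b, hu_ref = hu_ref),
            class = "medium_mapping_params")
}

#' Bone porosity from density
#'
#' \eqn{\phi = (\rho_{max} - \rho) / (\rho_{max} - \rho_{water})}, clipped to
#' \[0, 1\]. Densities outside the mapping range are clipped with a warning.
#'
#' @param density Density, kg/m^3 (vector or array).
#' @param params A [medium_mapping_params()] object.
#' @return Porosity, dimensionless in \[0, 1\], same shape as `density`.
#' @export
porosity <- function(density, params = medium_mapping_params()) {
  out_of_range <- density < params$rho_water | density > params$rho_max
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sprintf("%d density value(s) outside [%g, %g] kg/m^3; clipped",
                    sum(out_of_range, na.rm = TRUE),
                    params$rho_water, params$rho_max))
  }
  phi <- (params$rho_max - density) / (params$rho_max - params$rho_water)
  pmin(pmax(phi, 0), 1)
}

#' Attenuation power law
#'
#' Skull attenuation \eqn{\alpha = \alpha_0 (f/\mathrm{MHz})^b \phi^\beta}
#' in dB/cm, converted to Np/m (divide by 8.6859 dB/Np, multiply by 100 cm/m).
#'
#' @param phi Porosity in \[0, 1\].
#' @param f Frequency, Hz.
#' @param params A [medium_mapping_params()] object.
#' @return Attenuation, Np/m, at frequency `f`.
#' @export
attenuation_power_law <- function(phi, f, params = medium_mapping_params()) {
  stopifnot(f > 0)
  if (any(phi < 0 | phi > 1, na.rm = TRUE)) {
    stop("porosity must lie in [0, 1]")
  }
  db_per_cm <- params$alpha0 * (f / 1e6)^params$b * phi^params$beta
  db_per_cm / DB_TO_NP * 100
}

#' Map a head phantom to an acoustic medium
#'
#' Density and sound speed are affine in HU, anchored at HU = 0 (water) and
#' HU = `hu_ref` (compact bone), then clipped to the mapping range.
#' Attenuation is computed from porosity via [attenuation_power_law()] in
#' skull-labelled voxels only; soft tissue is acoustically homogeneous with
#' water values and zero attenuation.
#'
#' @param phantom A [make_head_phantom()] object.
#' @param params A [medium_mapping_params()] object.
#' @param f Carrier frequency, Hz (attenuation is frequency dependent).
#' @return An `acoustic_medium`: grids `density` (kg/m^3), `speed` (m/s),
#'   `attenuation` (Np/m at `f`), `porosity`, plus `spacing` (mm).
#' @export
hu_to_medium <- function(phantom, params = medium_mapping_params(),
                         f = 250e3) {
  hu <- phantom$hu_volume
  if (any(!is.finite(hu))) stop("HU volume contains non-finite values")
  skull <- phantom$compartment_labels == "skull"

  frac <- hu / params$hu_ref
  density <- params$rho_water + (params$rho_max - params$rho_water) * frac
  speed   <- params$c_water   + (params$c_max   - params$c_water)   * frac
  density <- pmin(pmax(density, params$rho_water), params$rho_max)
  speed   <- pmin(pmax(speed,   params$c_water),  params$c_max)

  density[!skull] <- params$rho_water
  speed[!skull]   <- params$c_water

  phi <- porosity(density, params)
  att <- array(0, dim = dim(hu))
  if (any(skull)) {
    att[skull] <- attenuation_power_law(phi[skull], f, params)
  }
  structure(list(density = density, speed = speed, attenuation = att,
                 porosity = phi, spacing = phantom$spacing, f = f),
            class = "acoustic_medium")
}

#' Spherical-cap transducer geometry
#'
#' @param roc Radius of curvature, mm. The geometric focus sits one `roc`
#'   from the cap apex along `axis`.
#' @param aperture Active diameter, mm.
#' @param apodization_r Radial Gaussian amplitude taper: the rim of the cap
#'   is driven at `apodization_r` times the centre amplitude (1 = uniform).
#' @param position Cap apex, mm coordinates on the simulation grid.
#' @param axis Unit propagation axis (normalised internally).
#' @return A `transducer_geometry` object.
#' @export
transducer_geometry <- function(roc = 63, aperture = 64, apodization_r = 0.35,
                                position = c(0, 0, 0), axis = c(0, 0, 1)) {
  stopifnot(aperture <= 2 * roc, apodization_r > 0, apodization_r <= 1,
            length(position) == 3, length(axis) == 3)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(roc = roc, aperture = aperture,
                 apodization_r = apodization_r,
                 position = as.numeric(position), axis = axis),
            class = "transducer_geometry")
}

#' Sonication protocol
#'
#' Pulse schedule and drive of the stimulation train: 30 ms bursts every
#' 100 ms (duty cycle 0.3) for 40 s at a 250 kHz carrier, with the free-water
#' transducer calibration anchoring pressure to drive voltage (1.2 MPa at
#' 130 V, linear in voltage).
#'
#' @param f0 Carrier frequency, Hz.
#' @param burst_duration_ms Burst length, ms.
#' @param burst_period_ms Burst repetition period, ms.
#' @param train_duration_s Sonication train length, s.
#' @param drive_voltage Peak-to-peak drive, V.
#' @param calibration_pressure Free-water peak pressure at
#'   `calibration_voltage`, Pa.
#' @param calibration_voltage Calibration drive, V.
#' @return A `sonication_protocol` object with a `duty_cycle` element.
#' @export
sonication_protocol <- function(f0 = 250e3, burst_duration_ms = 30,
                                burst_period_ms = 100, train_duration_s = 40,
                                drive_voltage = 130,
                                calibration_pressure = 1.2e6,
                                calibration_voltage = 130) {
  stopifnot(burst_duration_ms <= burst_period_ms, burst_duration_ms > 0,
            drive_voltage > 0)
  structure(list(f0 = f0, burst_duration_ms = burst_duration_ms,
                 burst_period_ms = burst_period_ms,
                 train_duration_s = train_duration_s,
                 drive_voltage = drive_voltage,
                 calibration_pressure = calibration_pressure,
                 calibration_voltage = calibration_voltage,
                 duty_cycle = burst_duration_ms / burst_period_ms),
            class = "sonication_protocol")
}

#' Closed-form on-axis pressure of a focused spherical cap
#'
#' The classical uniform-bowl solution in lossless water: with apex at z = 0,
#' radius of curvature A, cap depth h and rim distance
#' \eqn{r_e(z) = \sqrt{a^2 + (z-h)^2}},
#' \deqn{|p(z)| = p_0 \, |e^{ikz} - e^{ik r_e}| / |1 - z/A|,}
#' with the removable singularity at the focus evaluated as its limit
#' \eqn{p_0 k h}. Valid for a uniformly driven cap (`apodization_r = 1`).
#'
#' @param geom A [transducer_geometry()]; apodization is ignored (uniform).
#' @param f0 Frequency, Hz.
#' @param source_pressure Surface pressure amplitude \eqn{p_0 = \rho c u_0},
#'   Pa.
#' @param z_mm Axial evaluation points, mm from the cap apex.
#' @param c_water Sound speed, m/s.
#' @return data.frame with columns `z_mm` and `pressure` (Pa).
#' @export
oneil_onaxis <- function(geom, f0 = 250e3, source_pressure = 1,
                         z_mm = seq(1, 2 * geom$roc, by = 0.25),
                         c_water = 1500) {
  a <- geom$aperture / 2
  A <- geom$roc
  h <- A - sqrt(A^2 - a^2)
  lambda_mm <- c_water / f0 * 1000
  if (geom$aperture < lambda_mm) {
    warning("cap aperture below one wavelength; on-axis solution inaccurate")
  }
  k <- 2 * pi / lambda_mm  # 1/mm
  re <- sqrt(a^2 + (z_mm - h)^2)
  denom <- 1 - z_mm / A
  p <- Mod(exp(1i * k * z_mm) - exp(1i * k * re)) / abs(denom)
  at_focus <- abs(denom) < 1e-6
  p[at_focus] <- k * h
  data.frame(z_mm = z_mm, pressure = source_pressure * p)
}

# Discretize the spherical cap into surface elements.
# Returns mm coordinates on the grid, element areas (mm^2) and the apodized
# amplitude of each element.
cap_elements <- function(geom, f0, c_water = 1500, pitch = NULL) {
  lambda_mm <- c_water / f0 * 1000
  if (is.null(pitch)) pitch <- lambda_mm / 4
  A <- geom$roc
  a <- geom$aperture / 2
  theta_max <- asin(a / A)
  n_theta <- max(4L, ceiling(A * theta_max / pitch))
  dtheta <- theta_max / n_theta
  # orthonormal frame around the axis
  ax <- geom$axis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  focus <- geom$position + A * ax
  xyz <- NULL; amp <- NULL; area <- NULL
  log_r <- log(geom$apodization_r)
  for (i in seq_len(n_theta)) {
    th <- (i - 0.5) * dtheta
    ring_r <- A * sin(th)
    n_phi <- max(6L, ceiling(2 * pi * ring_r / pitch))
    phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
    dS <- A^2 * sin(th) * dtheta * (2 * pi / n_phi)
    pts <- t(focus - A * (cos(th) * matrix(ax, 3, n_phi) +
                            sin(th) * (outer(e1, cos(phi)) +
                                         outer(e2, sin(phi)))))
    xyz <- rbind(xyz, pts)
    amp <- c(amp, rep(exp(log_r * (ring_r / a)^2), n_phi))
    area <- c(area, rep(dS, n_phi))
  }
  list(xyz = xyz, amp = amp, area = area, focus = focus,
       lambda_mm = lambda_mm)
}

# Rayleigh sum at arbitrary mm points (N x 3), lossless water.
rayleigh_at_points <- function(geom, points, f0, source_pressure = 1,
                               c_water = 1500, pitch = NULL) {
  el <- cap_elements(geom, f0, c_water, pitch)
  k_m <- 2 * pi * f0 / c_water            # 1/m
  acc <- complex(length.out = nrow(points))
  for (j in seq_len(nrow(el$xyz))) {
    dx <- points[, 1] - el$xyz[j, 1]
    dy <- points[, 2] - el$xyz[j, 2]
    dz <- points[, 3] - el$xyz[j, 3]
    R_m <- sqrt(dx * dx + dy * dy + dz * dz) * 1e-3
    acc <- acc + (el$amp[j] * el$area[j] * 1e-6) * exp(1i * k_m * R_m) / R_m
  }
  source_pressure * (k_m / (2 * pi)) * Mod(acc)
}

#' Steady-state focused pressure field by Rayleigh integral
#'
#' Discretizes the apodized spherical cap and sums the Rayleigh surface
#' integral at every voxel centre of the grid. In heterogeneous media the
#' amplitude at each voxel is additionally reduced by
#' \eqn{\exp(-\int \alpha\, dl)} along the straight ray from the cap apex to
#' the voxel (ray approximation; refraction is neglected).
#'
#' @param geom A [transducer_geometry()] placed in grid mm coordinates.
#' @param grid_shape Voxel dimensions of the output grid.
#' @param spacing Isotropic voxel size, mm.
#' @param f0 Frequency, Hz.
#' @param medium Optional `acoustic_medium` on the same grid; `NULL` means
#'   free water (no attenuation).
#' @param source_pressure Cap surface pressure, Pa.
#' @param pitch Element pitch, mm (default a quarter wavelength).
#' @return A `pressure_field`: `peak_pressure` array (Pa), `focus_value`,
#'   `focus_index` (voxel triple of the geometric focus), `spacing`.
#' @export
rayleigh_field <- function(geom, grid_shape, spacing, f0 = 250e3,
                           medium = NULL, source_pressure = 1, pitch = NULL) {
  grid_shape <- as.integer(grid_shape)
  c_water <- if (is.null(medium)) 1500 else min(medium$speed)
  focus <- geom$position + geom$roc * geom$axis
  focus_idx <- pmin(pmax(round(focus / spacing + 0.5), 1L), grid_shape)
  if (any(focus < 0) || any(focus > grid_shape * spacing)) {
    stop("grid excludes the focal region; enlarge the grid or move the cap")
  }
  centres <- lapply(seq_along(grid_shape),
                    function(d) (seq_len(grid_shape[d]) - 0.5) * spacing)
  pts <- as.matrix(expand.grid(centres[[1]], centres[[2]], centres[[3]]))
  p <- rayleigh_at_points(geom, pts, f0, source_pressure, c_water, pitch)
  p <- array(p, dim = grid_shape)
  if (!is.null(medium) && any(medium$attenuation > 0)) {
    p <- p * exp(-ray_attenuation(geom$position, grid_shape, spacing,
                                  medium$attenuation))
  }
  structure(list(peak_pressure = p,
                 focus_value = p[focus_idx[1], focus_idx[2], focus_idx[3]],
                 focus_index = focus_idx, spacing = spacing, f0 = f0),
            class = "pressure_field")
}

# Line integral of alpha (Np/m) from `origin` (mm) to every voxel centre;
# returns a grid of dimensionless attenuation exponents.
ray_attenuation <- function(origin, grid_shape, spacing, alpha,
                            step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- spacing / 2
  out <- array(0, dim = grid_shape)
  idx <- which(array(TRUE, grid_shape))
  coord <- arrayInd(idx, grid_shape)
  target <- (coord - 0.5) * spacing
  d <- sweep(target, 2, origin)
  len <- sqrt(rowSums(d^2))
  n_steps <- pmax(1L, ceiling(len / step_mm))
  max_steps <- max(n_steps)
  acc <- numeric(length(idx))
  for (s in seq_len(max_steps)) {
    frac <- pmin((s - 0.5) / n_steps, 1)
    samp <- sweep(d * frac, 2, origin, "+")
    vi <- pmin(pmax(round(samp / spacing + 0.5), 1L),
               matrix(grid_shape, nrow(samp), 3, byrow = TRUE))
    lin <- vi[, 1] + grid_shape[1] * (vi[, 2] - 1L +
                                        grid_shape[2] * (vi[, 3] - 1L))
    active <- s <= n_steps
    acc[active] <- acc[active] +
      alpha[lin[active]] * (len[active] / n_steps[active]) * 1e-3
  }
  out[idx] <- acc
  out
}

#' Rescale a simulated field by the free-water calibration
#'
#' Scales the field so that the free-water reference maximum equals the
#' calibrated pressure at the protocol's drive voltage (linear in voltage):
#' at 130 V the free-water maximum is 1.2 MPa.
#'
#' @param field A `pressure_field`.
#' @param protocol A [sonication_protocol()].
#' @param free_water_max Maximum pressure of the matching free-water
#'   simulation on the same grid, in the field's (arbitrary) source units.
#' @return The rescaled `pressure_field` in Pa.
#' @export
rescale_by_calibration <- function(field, protocol, free_water_max) {
  if (!is.numeric(free_water_max) || length(free_water_max) != 1 ||
      !is.finite(free_water_max) || free_water_max <= 0) {
    stop("free-water reference maximum must be a positive scalar")
  }
  target <- protocol$calibration_pressure *
    protocol$drive_voltage / protocol$calibration_voltage
  s <- target / free_water_max
  field$peak_pressure <- field$peak_pressure * s
  field$focus_value <- field$focus_value * s
  field
}

#' Pulse intensity metrics
#'
#' Spatial-peak pulse-average intensity \eqn{I_{sppa} = p^2 / (2\rho c)} and
#' its temporal average \eqn{I_{spta} = I_{sppa} \times} duty cycle, in
#' W/cm^2.
#'
#' @param p Peak pressure amplitude, Pa (scalar or array).
#' @param rho Density, kg/m^3.
#' @param c Sound speed, m/s.
#' @param duty_cycle Burst on-fraction in \[0, 1\].
#' @return List with `isppa` and `ispta`, W/cm^2.
#' @export
pulse_intensities <- function(p, rho = 1000, c = 1500, duty_cycle = 0.3) {
  stopifnot(all(p >= 0), duty_cycle >= 0, duty_cycle <= 1)
  isppa <- p^2 / (2 * rho * c) / 1e4
  list(isppa = isppa, ispta = isppa * duty_cycle)
}
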