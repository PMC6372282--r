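# Pennes bioheat equation solved by an explicit 3D finite-difference scheme:
#   rho C dT/dt = div(kappa grad T) + q(t) - w rho_b C_b (T - T_a)
# with Dirichlet boundaries fixed at their initial temperatures. The blood
# perfusion term is a *cooling* term driving brain tissue toward arterial
# temperature (standard Pennes form). Perfusion applies in brain tissue only.

#' Thermal material grids
#'
#' Per-voxel thermal conductivity, specific heat, density, sound speed, and
#' acoustic absorption, assembled from a compartment-label grid. Soft tissue:
#' kappa 0.528 W/m/K, C 3600 J/kg/K, absorption 0.21 dB/cm/MHz^b. Skull:
#' kappa 0.4, C 1300, absorption proportional to density with maximum
#' alpha0/3 dB/cm/MHz^b at compact-bone density. Water: kappa 0.6, C 4180,
#' no absorption. Background voxels are treated as soft tissue.
#'
#' @param labels Character array of compartment labels ("brain", "skull",
#'   "water", "background").
#' @param medium Optional `acoustic_medium` supplying density/speed grids;
#'   defaults to water values outside skull and compact-bone interpolation
#'   inside.
#' @param f0 Carrier frequency, Hz (absorption scales with frequency).
#' @param params [medium_mapping_params()] supplying `alpha0`, `b`,
#'   `rho_max`.
#' @param alpha_abs_tissue Soft-tissue absorption prefactor, dB/cm/MHz^b.
#' @return A `thermal_materials` object: grids `kappa`, `C`, `rho`, `speed`,
#'   `alpha_abs` (Np/m at `f0`), plus `labels`, `spacing` and the skull
#'   absorption ceiling `alpha_abs_max_db` (dB/cm/MHz^b).
#' @export
thermal_materials <- function(labels, medium = NULL, f0 = 250e3,
                              params = medium_mapping_params(),
                              alpha_abs_tissue = 0.21) {
  dm <- dim(labels)
  skull <- labels == "skull"
  water <- labels == "water"
  kappa <- array(0.528, dm); kappa[skull] <- 0.4; kappa[water] <- 0.6
  Cp <- array(3600, dm); Cp[skull] <- 1300; Cp[water] <- 4180
  if (is.null(medium)) {
    rho <- array(params$rho_water, dm)
    rho[skull] <- params$rho_max
    speed <- array(params$c_water, dm)
    speed[skull] <- params$c_max
  } else {
    rho <- medium$density
    speed <- medium$speed
  }
  fmhz <- (f0 / 1e6)^params$b
  alpha_max_db <- params$alpha0 / 3
  alpha <- array(alpha_abs_tissue * fmhz / DB_TO_NP * 100, dm)
  alpha[skull] <- alpha_max_db * (rho[skull] / params$rho_max) * fmhz /
    DB_TO_NP * 100
  alpha[water] <- 0
  spacing <- if (!is.null(medium)) medium$spacing else NA_real_
  structure(list(kappa = kappa, C = Cp, rho = rho, speed = speed,
                 alpha_abs = alpha, labels = labels, spacing = spacing,
                 f0 = f0, alpha_abs_max_db = alpha_max_db),
            class = "thermal_materials")
}

#' Blood perfusion parameters
#'
#' @param w Perfusion rate, 1/s.
#' @param rho_b Blood density, kg/m^3.
#' @param C_b Blood specific heat, J/kg/K.
#' @param T_a Arterial temperature, degrees C.
#' @return A `perfusion_params` object.
#' @export
perfusion_params <- function(w = 0.008, rho_b = 1030, C_b = 3620, T_a = 37) {
  stopifnot(w >= 0, rho_b >= 0, C_b >= 0)
  structure(list(w = w, rho_b = rho_b, C_b = C_b, T_a = T_a),
            class = "perfusion_params")
}

#' Simulation timeline
#'
#' Pre-sonication / sonication / post-sonication phases of the thermal run.
#' The solver step `dt` must satisfy the explicit von Neumann bound
#' `dt <= safety * dx^2 / (6 max(kappa / (rho C)))`; if `NULL` it is chosen
#' at that bound (safety 0.9).
#'
#' @param pre,on,post Phase durations, s.
#' @param dt Solver time step, s, or `NULL` for automatic.
#' @param record_stride Steps per recorded frame, or `NULL` (about 40
#'   frames).
#' @return A `thermal_timeline` object.
#' @export
thermal_timeline <- function(pre = 60, on = 40, post = 300, dt = NULL,
                             record_stride = NULL) {
  stopifnot(pre >= 0, on > 0, post >= 0)
  structure(list(pre = pre, on = on, post = post, dt = dt,
                 record_stride = record_stride),
            class = "thermal_timeline")
}

#' Initial temperature state
#'
#' 37 C in brain, skull and tissue-like background; 24 C in the water cone.
#'
#' @param labels Compartment-label array.
#' @param t_tissue,t_water Initial temperatures, degrees C.
#' @return A temperature array congruent with `labels`.
#' @export
initial_temperature <- function(labels, t_tissue = 37, t_water = 24) {
  T0 <- array(t_tissue, dim = dim(labels))
  T0[labels == "water"] <- t_water
  T0
}

#' Acoustic heat production
#'
#' \eqn{q = \alpha_{abs} P^2 / (2 \rho c)} per voxel (W/m^3), optionally
#' multiplied by the protocol duty cycle for time-averaged pulsed heating.
#'
#' @param field A `pressure_field` (Pa) or a bare pressure array.
#' @param materials A [thermal_materials()] object on the same grid.
#' @param protocol A [sonication_protocol()] (supplies the duty cycle).
#' @param pulse_averaged If `TRUE` (default) the duty cycle is folded into
#'   `q`; use `FALSE` with an explicit burst schedule in [solve_pennes()].
#' @return Heat production grid, W/m^3.
#' @export
heat_source <- function(field, materials, protocol = sonication_protocol(),
                        pulse_averaged = TRUE) {
  p <- if (inherits(field, "pressure_field")) field$peak_pressure else field
  if (!all(dim(p) == dim(materials$alpha_abs))) {
    stop("pressure and material grids have mismatched shapes")
  }
  q <- materials$alpha_abs * p^2 / (2 * materials$rho * materials$speed)
  if (pulse_averaged) q <- q * protocol$duty_cycle
  q
}

# edge-replicating shift of a 3D array along axis d by +/-1
shift3 <- function(x, d, dir) {
  n <- dim(x)[d]
  idx <- if (dir > 0) c(seq(2, n), n) else c(1, seq(1, n - 1))
  switch(d, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

#' Explicit finite-difference Pennes solver
#'
#' Forward-Euler update of the bioheat equation over the pre / sonication /
#' post timeline. The source `q` is active during `[pre, pre + on)`,
#' optionally gated by a burst schedule. Dirichlet boundaries hold the grid
#' faces at their initial values; `boundary = "insulated"` uses zero-flux
#' faces instead (useful for closed-form comparisons).
#'
#' @param T0 Initial temperature array (degrees C), e.g. from
#'   [initial_temperature()].
#' @param materials A [thermal_materials()] object.
#' @param perfusion A [perfusion_params()] object; perfusion acts only where
#'   `perfusion_mask` is `TRUE` (default: brain-labelled voxels).
#' @param q Heat-production grid, W/m^3 (zeros allowed).
#' @param timeline A [thermal_timeline()].
#' @param spacing Voxel size, mm (defaults to `materials$spacing`).
#' @param boundary "dirichlet" or "insulated".
#' @param perfusion_mask Logical array; `NULL` = brain voxels.
#' @param burst_schedule Optional function of time-since-sonication-start
#'   (s) returning a 0/1 gate, for explicit pulsed heating (e.g.
#'   [burst_gate()]); `NULL` means the source is constant during the
#'   on-phase.
#' @param focus Optional voxel triple; its temperature is recorded every
#'   step.
#' @return A `temperature_history`: `frames` (4D array x,y,z,frame),
#'   `times` (s, one per frame), `t_max` (per-voxel running maximum),
#'   `focal` (data.frame time/temperature per step, if `focus` given),
#'   `dt`, `T0`.
#' @export
solve_pennes <- function(T0, materials, perfusion = perfusion_params(),
                         q, timeline = thermal_timeline(),
                         spacing = NULL, boundary = c("dirichlet",
                                                      "insulated"),
                         perfusion_mask = NULL, burst_schedule = NULL,
                         focus = NULL) {
  boundary <- match.arg(boundary)
  if (is.null(spacing)) spacing <- materials$spacing
  if (!is.finite(spacing) || spacing <= 0) {
    stop("voxel spacing (mm) is required")
  }
  dm <- dim(T0)
  stopifnot(all(dm == dim(q)), all(dm == dim(materials$kappa)))
  dx <- spacing * 1e-3
  rhoC <- materials$rho * materials$C
  D_max <- max(materials$kappa / rhoC)
  dt_bound <- 0.9 * dx^2 / (6 * D_max)
  dt <- timeline$dt
  if (is.null(dt)) dt <- dt_bound
  if (dt > dt_bound) {
    stop(sprintf(
      "time step %.4g s violates the explicit stability bound %.4g s",
      dt, dt_bound))
  }
  total <- timeline$pre + timeline$on + timeline$post
  n_steps <- ceiling(total / dt)
  stride <- timeline$record_stride
  if (is.null(stride)) stride <- max(1L, floor(n_steps / 40))
  if (is.null(perfusion_mask)) perfusion_mask <- materials$labels == "brain"
  perf_coef <- perfusion$w * perfusion$rho_b * perfusion$C_b
  perf <- array(0, dm)
  perf[perfusion_mask] <- perf_coef

  # face-averaged conductivities (arithmetic mean)
  kap <- materials$kappa
  kxp <- (kap + shift3(kap, 1, +1)) / 2
  kxm <- (kap + shift3(kap, 1, -1)) / 2
  kyp <- (kap + shift3(kap, 2, +1)) / 2
  kym <- (kap + shift3(kap, 2, -1)) / 2
  kzp <- (kap + shift3(kap, 3, +1)) / 2
  kzm <- (kap + shift3(kap, 3, -1)) / 2

  Tarr <- T0
  bmask <- array(FALSE, dm)
  if (boundary == "dirichlet") {
    bmask[c(1, dm[1]), , ] <- TRUE
    bmask[, c(1, dm[2]), ] <- TRUE
    bmask[, , c(1, dm[3])] <- TRUE
  }
  bvals <- T0[bmask]

  frames <- list(); times <- numeric(0)
  t_max <- T0
  focal_t <- numeric(0); focal_T <- numeric(0)
  inv_rhoC_dt <- dt / rhoC
  dx2 <- dx^2
  for (s in seq_len(n_steps)) {
    t_now <- (s - 1) * dt
    lap <- (kxp * (shift3(Tarr, 1, +1) - Tarr) -
              kxm * (Tarr - shift3(Tarr, 1, -1)) +
              kyp * (shift3(Tarr, 2, +1) - Tarr) -
              kym * (Tarr - shift3(Tarr, 2, -1)) +
              kzp * (shift3(Tarr, 3, +1) - Tarr) -
              kzm * (Tarr - shift3(Tarr, 3, -1))) / dx2
    q_t <- 0
    if (t_now >= timeline$pre && t_now < timeline$pre + timeline$on) {
      gate <- if (is.null(burst_schedule)) 1 else
        burst_schedule(t_now - timeline$pre)
      q_t <- q * gate
    }
    Tarr <- Tarr + inv_rhoC_dt *
      (lap + q_t - perf * (Tarr - perfusion$T_a))
    if (boundary == "dirichlet") Tarr[bmask] <- bvals
    t_max <- pmax(t_max, Tarr)
    if (!is.null(focus)) {
      focal_t <- c(focal_t, s * dt)
      focal_T <- c(focal_T, Tarr[focus[1], focus[2], focus[3]])
    }
    if (s %% stride == 0 || s == n_steps) {
      frames[[length(frames) + 1]] <- Tarr
      times <- c(times, s * dt)
    }
  }
  frames4d <- array(unlist(frames), dim = c(dm, length(frames)))
  focal <- if (is.null(focus)) NULL else
    data.frame(time = focal_t, temperature = focal_T)
  structure(list(frames = frames4d, times = times, t_max = t_max,
                 focal = focal, dt = dt, T0 = T0,
                 timeline = timeline, spacing = spacing),
            class = "temperature_history")
}

#' Burst gating function for explicit pulsed heating
#'
#' @param protocol A [sonication_protocol()].
#' @return A function of time since sonication onset (s) returning 1 during
#'   bursts and 0 between them.
#' @export
burst_gate <- function(protocol = sonication_protocol()) {
  period <- protocol$burst_period_ms / 1000
  on <- protocol$burst_duration_ms / 1000
  function(t) as.numeric((t %% period) < on)
}

#' Focal heating benchmark on a homogeneous tissue grid
#'
#' Builds a homogeneous soft-tissue grid carrying a focused pressure
#' distribution (anisotropic Gaussian focal spot: lateral FWHM of one
#' wavelength, axial FWHM of three, the typical elongation of a focused
#' beam) peaking at `peak_pressure` in the grid centre, and runs the Pennes
#' solver over the pre / sonication / post timeline with duty-cycle-averaged
#' heating. Reports the focal temperature rise.
#'
#' @param peak_pressure Focal peak pressure, Pa.
#' @param grid_shape Voxel dimensions.
#' @param spacing Voxel size, mm.
#' @param f0 Carrier frequency, Hz (sets the wavelength).
#' @param protocol A [sonication_protocol()] (duty cycle).
#' @param timeline A [thermal_timeline()].
#' @param perfusion A [perfusion_params()].
#' @return List: `focal_dT` (max rise at the focus, degrees C), `focal`
#'   (timecourse data.frame), `max_dT` (grid-wide max rise), `q_focus`
#'   (W/m^3).
#' @export
simulate_focal_heating <- function(peak_pressure = 0.88e6,
                                   grid_shape = c(64, 64, 64),
                                   spacing = 0.5, f0 = 250e3,
                                   protocol = sonication_protocol(),
                                   timeline = thermal_timeline(),
                                   perfusion = perfusion_params()) {
  grid_shape <- as.integer(grid_shape)
  labels <- array("brain", dim = grid_shape)
  mats <- thermal_materials(labels, f0 = f0)
  mats$spacing <- spacing
  lambda_mm <- 1500 / f0 * 1000
  fwhm <- c(lambda_mm, lambda_mm, 3 * lambda_mm)
  focus <- pmax(1L, grid_shape %/% 2L)  # spot centred on this voxel
  ax <- lapply(1:3, function(d) {
    (seq_len(grid_shape[d]) - focus[d]) * spacing
  })
  ln2_4 <- 4 * log(2)
  g2 <- outer(exp(-ln2_4 * ax[[1]]^2 / fwhm[1]^2),
              exp(-ln2_4 * ax[[2]]^2 / fwhm[2]^2), "*")
  p <- outer(g2, exp(-ln2_4 * ax[[3]]^2 / fwhm[3]^2), "*") * peak_pressure
  q <- heat_source(p, mats, protocol, pulse_averaged = TRUE)
  T0 <- array(37, dim = grid_shape)
  hist <- solve_pennes(T0, mats, perfusion, q, timeline, spacing = spacing,
                       perfusion_mask = array(TRUE, grid_shape),
                       focus = focus)
  list(focal_dT = max(hist$focal$temperature) - 37,
       focal = hist$focal,
       max_dT = max(hist$t_max) - 37,
       q_focus = q[focus[1], focus[2], focus[3]])
}

#' Summarize a thermal run
#'
#' Maximum temperature rise over space and time in each labelled
#' compartment, the maximum absolute brain temperature, and the focal
#' timecourse.
#'
#' @param history A [solve_pennes()] result.
#' @param labels Compartment-label array.
#' @param focus Voxel triple of the geometric focus.
#' @return A `thermal_report`: `max_dT` (named per compartment, degrees C),
#'   `max_brain_T` (absolute, degrees C), `focal_dT`, `focal_timecourse`.
#' @export
summarize_thermal <- function(history, labels, focus) {
  if (length(history$times) == 0) stop("thermal history holds no frames")
  comps <- setdiff(unique(as.vector(labels)), character(0))
  dT <- history$t_max - history$T0
  max_dT <- vapply(comps, function(cc) {
    m <- labels == cc
    if (!any(m)) stop(sprintf("compartment '%s' has an empty mask", cc))
    max(dT[m])
  }, numeric(1))
  tc <- history$focal
  if (is.null(tc)) {
    fv <- history$frames[focus[1], focus[2], focus[3], ]
    tc <- data.frame(time = history$times, temperature = fv)
  }
  structure(list(max_dT = max_dT,
                 max_brain_T = if ("brain" %in% comps)
                   max(history$t_max[labels == "brain"]) else NA_real_,
                 focal_dT = max(tc$temperature) -
                   history$T0[focus[1], focus[2], focus[3]],
                 focal_timecourse = tc),
            class = "thermal_report")
}

#' @export
print.thermal_report <- function(x, ...) {
  cat("Thermal dose summary\n")
  for (nm in names(x$max_dT)) {
    cat(sprintf("  max dT %-11s %.3f C\n", paste0(nm, ":"), x$max_dT[[nm]]))
  }
  cat(sprintf("  focal dT:          %.3f C\n", x$focal_dT))
  if (is.finite(x$max_brain_T)) {
    cat(sprintf("  max brain T:       %.2f C\n", x$max_brain_T))
  }
  invisible(x)
}
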