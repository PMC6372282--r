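# Configuration, NIfTI / table I-O, and the staged pipeline driver tying
# simulation, preprocessing, fingerprinting and permutation inference (or
# the acoustic -> thermal dosimetry chain) into one reproducible call.

#' Default pipeline configuration
#'
#' Nested parameter list with one section per stage. Defaults equal the
#' study protocol values throughout: 250 kHz carrier, 30/100 ms bursts,
#' 40 s train, 130 V drive and 1.2 MPa free-water calibration; 60/40/300 s
#' thermal timeline; 3 subjects x 3 runs x 800 volumes at TR 2 s with the
#' first 5 volumes dropped; 2000 s high-pass, 10 s low-pass, 5 compartment
#' components, 3 mm FWHM smoothing; 4 mm ROIs; exhaustive permutation test.
#'
#' @param output_dir Output directory for artifacts.
#' @param seed Master RNG seed.
#' @param ... Named overrides merged over the defaults (nested lists).
#' @return A `pipeline_config` object (plain nested list).
#' @export
pipeline_config <- function(output_dir = "tusmod-out", seed = 1, ...) {
  cfg <- list(
    output_dir = output_dir,
    seed = seed,
    simulate = list(n_subjects = 3, n_runs = 3, n_volumes = 800, tr = 2,
                    local_gain = 1.3, distal_loss = 0.6,
                    global_confound_sd = 0, write_nifti = FALSE),
    acoustic = list(grid_shape = c(48, 48, 48), spacing = 0.5,
                    skull_hu = 1800, skull_thickness = 2,
                    drive_voltage = 130),
    thermal = list(pre = 60, on = 40, post = 300, pulsed = FALSE),
    preprocess = list(n_drop = 5, highpass_s = 2000, lowpass_s = 10,
                      n_pcs = 5, fwhm = 3, include_meningeal = TRUE,
                      detect_notches = TRUE),
    fingerprint = list(radius = 4),
    permtest = list(mode = "exhaustive", n_mc = 9999)
  )
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration
#'
#' YAML round-trip: `read_config(write_config(cfg, path))` reproduces the
#' configuration.
#'
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the configuration.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers preserving voxel spacing and the time axis.
#'
#' @param path File path (`.nii` / `.nii.gz`).
#' @param data 3D or 4D array.
#' @param spacing Voxel size(s), mm (scalar or length-3).
#' @return `read_nifti` returns a list `data` (array) and `spacing` (mm,
#'   length 3); `write_nifti` returns `path` invisibly.
#' @export
write_nifti <- function(data, path, spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(data)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim = dim(img)),
       spacing = pd[seq_len(min(3, length(pd)))])
}

#' Write a BOLD dataset to disk
#'
#' One 4D NIfTI per run, one 3D label volume, one whitespace-delimited
#' 6-column motion table per run, and a manifest CSV (subject, run,
#' condition, paths).
#'
#' @param dataset A `bold_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The manifest data.frame, invisibly.
#' @export
write_bold_dataset <- function(dataset, dir, prefix = "bold") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- array(match(as.vector(dataset$compartments),
                        c("GM", "WM", "meningeal")),
                  dim = dataset$dim)
  label_path <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  write_nifti(labels, label_path, dataset$spacing)
  rows <- list()
  for (r in dataset$runs) {
    stem <- sprintf("%s_sub%02d_run%02d_%s", prefix, r$subject, r$run,
                    r$condition)
    nii <- file.path(dir, paste0(stem, ".nii.gz"))
    arr <- array(t(r$ts), dim = c(dataset$dim, nrow(r$ts)))
    write_nifti(arr, nii, dataset$spacing)
    mot <- file.path(dir, paste0(stem, "_motion.txt"))
    if (!is.null(r$motion)) {
      utils::write.table(format(r$motion, digits = 8), mot,
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    } else {
      mot <- NA_character_
    }
    rows[[length(rows) + 1]] <- data.frame(
      subject = r$subject, run = r$run, condition = r$condition,
      bold = nii, motion = mot, labels = label_path)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest,
                   file.path(dir, paste0(prefix, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}

write_provenance <- function(dir, cfg, stage_list) {
  cfg_path <- file.path(dir, "config.yaml")
  write_config(cfg, cfg_path)
  prov <- list(config_hash = unname(tools::md5sum(cfg_path)),
               seed = cfg$seed, stages = stage_list,
               package_version = as.character(
                 utils::packageVersion("tusmod")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the staged analysis pipeline
#'
#' Executes the requested stages in dependency order. BOLD stages:
#' `simulate` -> `preprocess` -> `fingerprint` -> `permtest`. Dosimetry
#' stages: `acoustic` -> `thermal`. Requesting a stage whose inputs were
#' not produced raises a dependency error naming the required prior stage.
#' Every invocation writes a provenance sidecar (config hash, seed, stage
#' list); identical configurations and seeds give identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Character vector of stages to run.
#' @return Invisibly, a list of in-memory stage results plus `manifest`
#'   (paths of written artifacts).
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("simulate", "preprocess",
                                    "fingerprint", "permtest")) {
  known <- c("simulate", "preprocess", "fingerprint", "permtest",
             "acoustic", "thermal")
  stopifnot(all(stages %in% known))
  deps <- list(preprocess = "simulate", fingerprint = "preprocess",
               permtest = "fingerprint", thermal = "acoustic")
  for (st in stages) {
    d <- deps[[st]]
    if (!is.null(d) && !(d %in% stages)) {
      stop(sprintf("stage '%s' requires prior stage '%s'", st, d))
    }
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  artifacts <- character(0)

  if ("simulate" %in% stages) {
    sc <- cfg$simulate
    layout <- synthetic_network_layout()
    pair <- make_bold_dataset(
      n_subjects = sc$n_subjects, n_runs = sc$n_runs,
      n_volumes = sc$n_volumes, tr = sc$tr, layout = layout,
      effect = effect_spec(local_gain = sc$local_gain,
                           distal_loss = sc$distal_loss,
                           global_confound_sd = sc$global_confound_sd),
      seed = cfg$seed)
    out$datasets <- pair
    if (isTRUE(sc$write_nifti)) {
      write_bold_dataset(pair$control, cfg$output_dir, "control")
      write_bold_dataset(pair$stim, cfg$output_dir, "stim")
      artifacts <- c(artifacts, file.path(cfg$output_dir,
                                          "control_manifest.csv"))
    }
  }
  if ("preprocess" %in% stages) {
    pc <- cfg$preprocess
    spec <- filter_spec(pc$highpass_s, pc$lowpass_s)
    out$clean <- lapply(out$datasets, preprocess_bold, spec = spec,
                        n_drop = pc$n_drop,
                        include_meningeal = pc$include_meningeal,
                        n_pcs = pc$n_pcs,
                        detect_notches = pc$detect_notches,
                        fwhm = pc$fwhm)
  }
  if ("fingerprint" %in% stages) {
    layout <- out$clean$control$layout
    seed_roi <- layout$rois[[layout$seed]]
    targets <- layout$rois[setdiff(names(layout$rois), layout$seed)]
    rf <- run_fingerprints(out$clean, seed_roi, targets)
    out$fingerprints <- rf
    fp_tab <- cbind(
      data.frame(condition = rf$conditions),
      do.call(rbind, lapply(rf$fingerprints, as.numeric)))
    colnames(fp_tab)[-1] <- names(rf$fingerprints[[1]])
    fp_path <- file.path(cfg$output_dir, "fingerprints.csv")
    utils::write.csv(fp_tab, fp_path, row.names = FALSE)
    artifacts <- c(artifacts, fp_path)
  }
  if ("permtest" %in% stages) {
    tc <- cfg$permtest
    res <- permutation_test(out$fingerprints$fingerprints,
                            out$fingerprints$conditions,
                            mode = tc$mode, n_mc = tc$n_mc,
                            seed = cfg$seed)
    out$permtest <- res
    pt_path <- file.path(cfg$output_dir, "permtest.json")
    jsonlite::write_json(
      list(observed_cosine = res$observed_cosine, p_value = res$p_value,
           n_permutations = res$n_permutations,
           exhaustive = res$exhaustive),
      pt_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- c(artifacts, pt_path)
  }
  if ("acoustic" %in% stages) {
    ac <- cfg$acoustic
    phantom <- make_head_phantom(ac$grid_shape, ac$spacing, ac$skull_hu,
                                 ac$skull_thickness, seed = cfg$seed)
    medium <- hu_to_medium(phantom)
    protocol <- sonication_protocol(drive_voltage = ac$drive_voltage)
    extent <- ac$grid_shape * ac$spacing
    focus_mm <- (phantom$focus_point - 0.5) * ac$spacing
    geom <- transducer_geometry(
      position = focus_mm + c(0, 0, 63), axis = c(0, 0, -1))
    field <- rayleigh_field(geom, ac$grid_shape, ac$spacing,
                            f0 = protocol$f0, medium = medium)
    free <- rayleigh_field(geom, ac$grid_shape, ac$spacing,
                           f0 = protocol$f0, medium = NULL)
    field <- rescale_by_calibration(field, protocol,
                                    max(free$peak_pressure))
    out$phantom <- phantom; out$medium <- medium
    out$protocol <- protocol; out$field <- field
    fp <- file.path(cfg$output_dir, "pressure.nii.gz")
    write_nifti(field$peak_pressure, fp, ac$spacing)
    ints <- pulse_intensities(field$focus_value,
                              duty_cycle = protocol$duty_cycle)
    jsonlite::write_json(
      list(focal_pressure_pa = field$focus_value,
           isppa_wcm2 = ints$isppa, ispta_wcm2 = ints$ispta),
      file.path(cfg$output_dir, "intensities.json"),
      auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, fp)
  }
  if ("thermal" %in% stages) {
    tc <- cfg$thermal
    mats <- thermal_materials(out$phantom$compartment_labels, out$medium)
    q <- heat_source(out$field, mats, out$protocol,
                     pulse_averaged = !isTRUE(tc$pulsed))
    T0 <- initial_temperature(out$phantom$compartment_labels)
    hist <- solve_pennes(
      T0, mats, perfusion_params(), q,
      thermal_timeline(tc$pre, tc$on, tc$post),
      burst_schedule = if (isTRUE(tc$pulsed)) burst_gate(out$protocol)
      else NULL,
      focus = out$phantom$focus_point)
    rep <- summarize_thermal(hist, out$phantom$compartment_labels,
                             out$phantom$focus_point)
    out$thermal <- rep
    tc_path <- file.path(cfg$output_dir, "focal_timecourse.csv")
    utils::write.csv(rep$focal_timecourse, tc_path, row.names = FALSE)
    jsonlite::write_json(
      list(max_dT = as.list(rep$max_dT), focal_dT = rep$focal_dT,
           max_brain_T = rep$max_brain_T),
      file.path(cfg$output_dir, "thermal_report.json"),
      auto_unbox = TRUE, digits = NA)
    write_nifti(hist$frames, file.path(cfg$output_dir,
                                       "temperature.nii.gz"),
                out$medium$spacing)
    artifacts <- c(artifacts, tc_path)
  }
  write_provenance(cfg$output_dir, cfg, stages)
  out$manifest <- artifacts
  invisible(out)
}
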