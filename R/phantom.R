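# Synthetic head phantom: ellipsoidal skull shell, brain interior, and a
# water coupling cone above the focus. Stands in for a CT head volume so the
# acoustic and thermal stages run without external data.

#' Generate a synthetic head phantom
#'
#' Builds a Hounsfield-unit volume with an ellipsoidal skull shell of
#' elevated HU enclosing brain tissue, and a cylindrical water coupling cone
#' descending from the top grid face onto the outer skull surface above the
#' focus. Brain HU is soft-tissue-like (~30) with mild seeded noise; water
#' HU is 0; background is air-like (-1000). The focus point sits inside the
#' brain below the cone.
#'
#' @param grid_shape Voxel dimensions (>= 32 each).
#' @param spacing Isotropic voxel size, mm.
#' @param skull_hu Mean HU of the skull shell.
#' @param skull_thickness Shell thickness, mm (>= 2 voxels).
#' @param seed Integer RNG seed; identical seeds give identical phantoms.
#' @return A `head_phantom`: `hu_volume`, `compartment_labels` (character
#'   array: "brain" | "skull" | "water" | "background"), `spacing`,
#'   `focus_point` (voxel triple).
#' @export
make_head_phantom <- function(grid_shape = c(64, 64, 64), spacing = 0.5,
                              skull_hu = 1800, skull_thickness = 2,
                              seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 32)) {
    stop("grid too small: each dimension must be at least 32 voxels")
  }
  if (skull_thickness < 2 * spacing) {
    stop("skull_thickness must be at least two voxels thick")
  }
  extent <- grid_shape * spacing
  centre <- extent / 2
  semi <- 0.38 * extent            # outer skull ellipsoid semi-axes, mm
  if (any(semi - skull_thickness < 4 * spacing)) {
    stop("grid too small to contain the skull shell and brain interior")
  }
  set.seed(seed)
  ax <- lapply(1:3, function(d) (seq_len(grid_shape[d]) - 0.5) * spacing)
  dx2 <- outer((ax[[1]] - centre[1])^2 / semi[1]^2,
               (ax[[2]] - centre[2])^2 / semi[2]^2, "+")
  d_out <- outer(dx2, (ax[[3]] - centre[3])^2 / semi[3]^2, "+")
  semi_in <- semi - skull_thickness
  dx2i <- outer((ax[[1]] - centre[1])^2 / semi_in[1]^2,
                (ax[[2]] - centre[2])^2 / semi_in[2]^2, "+")
  d_in <- outer(dx2i, (ax[[3]] - centre[3])^2 / semi_in[3]^2, "+")

  labels <- array("background", dim = grid_shape)
  labels[d_out <= 1] <- "skull"
  labels[d_in <= 1] <- "brain"

  # water cone: cylinder along +z from the top face down to the outer shell,
  # above the focus column
  cone_radius <- 0.18 * min(extent[1:2])
  r2 <- outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, "+")
  in_cyl <- r2 <= cone_radius^2
  cyl <- array(rep(in_cyl, grid_shape[3]), dim = grid_shape)
  labels[cyl & labels == "background" &
           d_out > 1 & outer(array(TRUE, grid_shape[1:2]),
                             ax[[3]] > centre[3], "&")] <- "water"

  hu <- array(-1000, dim = grid_shape)
  n_brain <- sum(labels == "brain")
  n_skull <- sum(labels == "skull")
  hu[labels == "brain"] <- 30 + stats::rnorm(n_brain, 0, 5)
  hu[labels == "skull"] <- skull_hu + stats::rnorm(n_skull, 0, abs(skull_hu) * 0.02)
  hu[labels == "water"] <- 0

  # focus: inside the brain, on the cone axis, in the upper brain half
  fz <- centre[3] + 0.4 * semi_in[3]
  focus <- pmin(pmax(round(c(centre[1], centre[2], fz) / spacing + 0.5), 1L),
                grid_shape)
  if (labels[focus[1], focus[2], focus[3]] != "brain") {
    # walk down the axis until inside brain tissue
    zcol <- labels[focus[1], focus[2], ]
    focus[3] <- max(which(zcol == "brain"))
  }
  structure(list(hu_volume = hu, compartment_labels = labels,
                 spacing = spacing, focus_point = as.integer(focus),
                 seed = seed),
            class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  tab <- table(x$compartment_labels)
  cat("Synthetic head phantom:", paste(dim(x$hu_volume), collapse = " x "),
      "voxels @", x$spacing, "mm\n")
  cat("  compartments:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat("  focus voxel:", paste(x$focus_point, collapse = ", "), "\n")
  invisible(x)
}
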