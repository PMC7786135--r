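# Voxel-level phantoms: axis-aligned block parcellations that exercise the
# volumetric half of the pipeline (flip, smooth, normalize, extract) with an
# exactly known ground truth.

#' Phantom construction parameters
#'
#' @param grid Integer vector of 3 positive extents (voxels) for the volume.
#' @param noise_sd Standard deviation of additive Gaussian voxel noise
#'   (uptake units); 0 gives a noiseless phantom.
#' @param reference_uptake Voxel value rendered inside the reference region.
#' @param block Optional `c(by, bz)` in-plane block size in voxels; chosen
#'   automatically when `NULL`.
#' @param seed RNG seed for the voxel noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(24L, 48L, 48L), noise_sd = 0,
                         reference_uptake = 1, block = NULL, seed = NULL) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(!is.finite(grid)) || any(grid < 1L))
    mc_stop("`grid` must be 3 positive integers", "mcnet_validation_error")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    mc_stop("`noise_sd` must be non-negative", "mcnet_validation_error")
  structure(list(grid = grid, noise_sd = noise_sd,
                 reference_uptake = reference_uptake, block = block,
                 seed = seed),
            class = "phantom_spec")
}

# Deterministic block layout. The x axis is the left-right axis: left-hemisphere
# regions occupy x in [1, bx], right-hemisphere regions the mirrored band
# [X - bx + 1, X], and midline regions span the full x extent, so that the
# voxel-space left-right flip maps the layout onto itself with left and right
# labels exchanged. In-plane (y, z) cells are assigned in table order, with
# the k-th left and k-th right region sharing a cell.
phantom_layout <- function(tab, spec) {
  X <- spec$grid[1L]; Y <- spec$grid[2L]; Z <- spec$grid[3L]
  hemi <- tab$hemisphere
  n_mid <- sum(hemi == "midline")
  n_left <- sum(hemi == "left")
  n_right <- sum(hemi == "right")
  cells_needed <- n_mid + max(n_left, n_right)
  if (cells_needed == 0L)
    mc_stop("region table is empty", "mcnet_validation_error")
  bx <- X %/% 2L
  if (bx < 1L) mc_stop("grid too small along x", "mcnet_capacity_error")
  if (is.null(spec$block)) {
    g <- ceiling(sqrt(cells_needed))
    by <- Y %/% g; bz <- Z %/% g
  } else {
    by <- as.integer(spec$block[1L]); bz <- as.integer(spec$block[2L])
  }
  if (by < 1L || bz < 1L)
    mc_stop("grid too small to host all regions as disjoint blocks",
            "mcnet_capacity_error")
  gy <- Y %/% by; gz <- Z %/% bz
  if (gy * gz < cells_needed)
    mc_stop(sprintf(
      "grid capacity %d blocks < %d regions required; blocks would overlap",
      gy * gz, cells_needed), "mcnet_capacity_error")

  cell_of <- integer(nrow(tab))
  mid_counter <- 0L; left_counter <- 0L; right_counter <- 0L
  for (r in seq_len(nrow(tab))) {
    cell_of[r] <- switch(hemi[r],
      midline = { mid_counter <- mid_counter + 1L; mid_counter - 1L },
      left = { left_counter <- left_counter + 1L; n_mid + left_counter - 1L },
      right = { right_counter <- right_counter + 1L; n_mid + right_counter - 1L },
      mc_stop(paste("unknown hemisphere:", hemi[r]), "mcnet_validation_error"))
  }
  lapply(seq_len(nrow(tab)), function(r) {
    cell <- cell_of[r]
    iy <- cell %% gy; iz <- cell %/% gy
    xr <- switch(hemi[r],
                 left = c(1L, bx),
                 right = c(X - bx + 1L, X),
                 midline = c(1L, X))
    list(x = xr[1L]:xr[2L],
         y = (iy * by + 1L):(iy * by + by),
         z = (iz * bz + 1L):(iz * bz + bz))
  })
}

#' Simulate a labelled phantom volume pair
#'
#' Renders each region of `tab` as a contiguous axis-aligned voxel block with
#' the requested regional uptake plus optional Gaussian noise, together with
#' the matching integer label volume. The reference region is rendered at
#' `spec$reference_uptake`. The first voxel axis is the left-right axis and
#' the layout is mirror-symmetric, so flipped phantoms remain valid.
#'
#' @param tab Region table.
#' @param uptake_row Numeric vector of per-region uptake for the network
#'   nodes (length = node count), optionally named by region.
#' @param spec A [phantom_spec()].
#' @return List with elements `image` (3-D numeric array), `labels` (3-D
#'   integer array of region ids, 0 = background), `voxel_mm`, and `tab`.
#' @export
simulate_phantom <- function(tab, uptake_row, spec = phantom_spec()) {
  validate_region_table(tab)
  stopifnot(inherits(spec, "phantom_spec"))
  nodes <- region_nodes(tab)
  if (length(uptake_row) != nrow(nodes))
    mc_stop(sprintf("`uptake_row` must have one value per network node (%d)",
                    nrow(nodes)), "mcnet_validation_error")
  if (!is.null(names(uptake_row))) {
    if (!setequal(names(uptake_row), nodes$name))
      mc_stop("`uptake_row` names do not match the region table",
              "mcnet_validation_error")
    uptake_row <- uptake_row[nodes$name]
  }
  blocks <- phantom_layout(tab, spec)
  labels <- array(0L, dim = spec$grid)
  image <- array(0, dim = spec$grid)
  value_of <- ifelse(tab$is_reference, spec$reference_uptake,
                     NA_real_)
  value_of[!tab$is_reference] <- uptake_row
  for (r in seq_len(nrow(tab))) {
    b <- blocks[[r]]
    labels[b$x, b$y, b$z] <- tab$region_id[r]
    image[b$x, b$y, b$z] <- value_of[r]
  }
  if (spec$noise_sd > 0) {
    image <- image + with_seed(spec$seed,
      array(stats::rnorm(length(image), sd = spec$noise_sd), dim = spec$grid))
  }
  list(image = image, labels = labels, voxel_mm = c(1, 1, 1), tab = tab)
}

#' Write phantom volumes as NIfTI-1 files
#'
#' @param phantom Result of [simulate_phantom()].
#' @param image_path,label_path Output paths (`.nii` / `.nii.gz`).
#' @export
write_phantom <- function(phantom, image_path, label_path) {
  img <- RNifti::asNifti(phantom$image, pixdim = phantom$voxel_mm)
  lab <- RNifti::asNifti(phantom$labels, pixdim = phantom$voxel_mm,
                         datatype = "int32")
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(lab, label_path)
  invisible(c(image_path, label_path))
}
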