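# Regional extraction: per-subject volume -> one normalized uptake value per
# region. Inputs are assumed to live in a common space; the voxel-space
# left-right flip, Gaussian smoothing, and reference-region intensity
# normalization mirror the standard PET preprocessing chain.

#' Per-subject volumetric image
#'
#' A light container for one subject's volume plus the metadata the extraction
#' steps need: voxel size (for FWHM-to-sigma conversion), the epileptogenic
#' focus side (right-sided foci are flipped so analyses run uniformly on the
#' left), and whether the first voxel axis is the left-right axis.
#'
#' @param volume 3-D numeric array of finite values.
#' @param subject_id Subject identifier string.
#' @param focus_side One of `"none"`, `"left"`, `"right"`.
#' @param voxel_mm Voxel edge lengths in mm (length 3).
#' @param lr_first_axis Is the first array axis the left-right axis? Must be
#'   `TRUE` (or `NA` to signal unknown orientation, which makes [flip_lr()]
#'   fail rather than guess).
#' @return An object of class `subject_image`.
#' @export
subject_image <- function(volume, subject_id,
                          focus_side = c("none", "left", "right"),
                          voxel_mm = c(1, 1, 1), lr_first_axis = TRUE) {
  focus_side <- match.arg(focus_side)
  if (!is.array(volume) || length(dim(volume)) != 3L)
    mc_stop("`volume` must be a 3-D array", "mcnet_validation_error")
  if (any(!is.finite(volume)))
    mc_stop("`volume` contains non-finite voxels", "mcnet_validation_error")
  structure(list(volume = volume, subject_id = as.character(subject_id),
                 focus_side = focus_side, voxel_mm = as.numeric(voxel_mm),
                 lr_first_axis = lr_first_axis),
            class = "subject_image")
}

#' Left-right flip for right-focus subjects
#'
#' Mirrors the volume along the first (left-right) voxel axis, so voxel
#' `(i, j, k)` of the output equals voxel `(X - 1 - i, j, k)` of the input.
#' The flip is applied only when `focus_side == "right"`; left- and
#' unlateralized images pass through unchanged. Unknown orientation is an
#' error, never a silent guess.
#'
#' @param image A [subject_image()].
#' @return A `subject_image` with the (possibly) flipped volume.
#' @export
flip_lr <- function(image) {
  stopifnot(inherits(image, "subject_image"))
  if (is.na(image$lr_first_axis) || !isTRUE(image$lr_first_axis))
    mc_stop("image orientation unknown or not left-right-first; conform the volume upstream",
            "mcnet_orientation_error")
  if (image$focus_side != "right") return(image)
  d <- dim(image$volume)
  image$volume <- image$volume[d[1L]:1L, , , drop = FALSE]
  image
}

# 1-D normalized Gaussian convolution along the rows of a matrix, with
# boundary renormalization (the kernel mass falling outside the volume is
# redistributed), so constant images are exact fixed points.
conv_axis <- function(a, w) {
  r <- (length(w) - 1L) %/% 2L
  n <- nrow(a)
  out <- matrix(0, n, ncol(a))
  den <- numeric(n)
  for (j in seq_along(w)) {
    t <- j - r - 1L
    lo <- max(1L, 1L - t); hi <- min(n, n - t)
    if (lo > hi) next
    idx <- lo:hi
    out[idx, ] <- out[idx, ] + w[j] * a[idx + t, , drop = FALSE]
    den[idx] <- den[idx] + w[j]
  }
  out / den
}

#' Isotropic Gaussian smoothing
#'
#' Convolves the volume with a separable Gaussian kernel of the given full
#' width at half maximum, using `sigma = fwhm / (2 * sqrt(2 * log(2)))`
#' converted to voxels per axis. Default 5 mm. The kernel is truncated at
#' 4 sigma and renormalized, so constant volumes are unchanged.
#'
#' @param image A [subject_image()].
#' @param fwhm_mm Kernel FWHM in millimetres (> 0).
#' @return Smoothed `subject_image`.
#' @export
smooth_gaussian <- function(image, fwhm_mm = 5) {
  stopifnot(inherits(image, "subject_image"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    mc_stop("`fwhm_mm` must be a positive number", "mcnet_validation_error")
  if (is.null(image$voxel_mm) || length(image$voxel_mm) != 3L ||
      any(!is.finite(image$voxel_mm)) || any(image$voxel_mm <= 0))
    mc_stop("voxel size metadata missing; cannot convert FWHM to voxels",
            "mcnet_metadata_error")
  vol <- image$volume
  d <- dim(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / image$voxel_mm
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    r <- max(1L, ceiling(4 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(vol, perm), nrow = d[ax])
    m <- conv_axis(m, w)
    vol <- aperm(array(m, dim = d[perm]), order(perm))
  }
  image$volume <- vol
  image
}

#' Reference-region intensity normalization
#'
#' Divides every voxel by the mean value inside the reference region (the
#' cerebellar region in the default table), so uptake is expressed relative
#' to the reference and comparable across subjects.
#'
#' @param image A [subject_image()].
#' @param labels Integer label volume, dimension-matched to the image.
#' @param reference_id Integer label of the reference region.
#' @return Normalized `subject_image`; the reference-region mean of the
#'   output is 1.
#' @export
normalize_to_reference <- function(image, labels, reference_id) {
  stopifnot(inherits(image, "subject_image"))
  if (!identical(dim(image$volume), dim(labels)))
    mc_stop("label volume dimensions do not match the image",
            "mcnet_validation_error")
  sel <- labels == reference_id
  if (!any(sel))
    mc_stop("reference region has no voxels in the label volume",
            "mcnet_normalization_error")
  m <- mean(image$volume[sel])
  if (!is.finite(m) || m <= 0)
    mc_stop(sprintf("reference-region mean is not strictly positive (%.3g)", m),
            "mcnet_normalization_error")
  image$volume <- image$volume / m
  image
}

#' Label-wise regional uptake extraction
#'
#' Averages each subject's voxel values within every network-node region of
#' the label volume, producing the subjects x regions uptake matrix. The
#' reference region is excluded from the columns; column order equals region
#' table order.
#'
#' @param images List of [subject_image()] objects (already preprocessed).
#' @param labels Integer label volume shared by all subjects.
#' @param tab Region table.
#' @return Uptake matrix with subject-id rownames and region-name colnames.
#' @export
extract_uptake <- function(images, labels, tab) {
  validate_region_table(tab)
  nodes <- region_nodes(tab)
  sel_list <- lapply(nodes$region_id, function(id) which(labels == id))
  empty <- lengths(sel_list) == 0L
  if (any(empty))
    mc_stop(paste("regions missing from the label volume:",
                  paste(nodes$name[empty], collapse = ", ")),
            "mcnet_extraction_error")
  out <- matrix(NA_real_, length(images), nrow(nodes),
                dimnames = list(vapply(images, `[[`, "", "subject_id"),
                                nodes$name))
  for (s in seq_along(images)) {
    img <- images[[s]]
    stopifnot(inherits(img, "subject_image"))
    if (!identical(dim(img$volume), dim(labels)))
      mc_stop(sprintf("subject %s: image dimensions do not match label volume",
                      img$subject_id), "mcnet_validation_error")
    v <- img$volume
    out[s, ] <- vapply(sel_list, function(ii) mean(v[ii]), 0)
  }
  out
}

#' One-call preprocessing for a single subject
#'
#' Applies the volumetric chain in pipeline order: left-right flip (right-focus
#' subjects only), optional Gaussian smoothing, then reference-region
#' intensity normalization.
#'
#' @param image A [subject_image()].
#' @param labels Label volume.
#' @param reference_id Reference-region label.
#' @param fwhm_mm Smoothing FWHM in mm, or `NULL` to skip smoothing.
#' @return Preprocessed `subject_image`.
#' @export
preprocess_subject <- function(image, labels, reference_id, fwhm_mm = 5) {
  image <- flip_lr(image)
  if (!is.null(fwhm_mm)) image <- smooth_gaussian(image, fwhm_mm)
  normalize_to_reference(image, labels, reference_id)
}

#' Read a subject manifest
#'
#' Tab-separated with columns `subject_id`, `path`, `focus_side`, `group`.
#'
#' @param path Manifest file path.
#' @return Data frame of the manifest rows.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "focus_side", "group")
  if (!all(need %in% names(df)))
    mc_stop(paste("manifest missing columns:",
                  paste(setdiff(need, names(df)), collapse = ", ")),
            "mcnet_validation_error")
  df
}
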