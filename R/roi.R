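#' Region-of-interest mask on an integer voxel grid
#'
#' A lightweight container for one hemisphere's ROI: unique voxel coordinates
#' on a grid of a given shape plus a voxel-to-millimetre affine. Left and
#' right hemispheres live on separate grids of identical shape; the second
#' grid axis ascending is the anterior direction (the affine's y scaling is
#' positive by construction).
#'
#' @param coords integer matrix (n x 3) of voxel coordinates (1-based)
#' @param shape integer grid dimensions, length 3
#' @param hemisphere `"left"` or `"right"`
#' @param affine 4x4 voxel-to-mm matrix; default 3 mm isotropic with x
#'   mirrored between hemispheres and y ascending toward anterior
#' @return an object of class `roi_mask`
#' @export
roi_mask <- function(coords, shape, hemisphere, affine = NULL) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  dimnames(coords) <- NULL
  stopifnot(ncol(coords) == 3L, length(shape) == 3L)
  shape <- as.integer(shape)
  if (anyDuplicated(coord_key(coords, shape))) {
    stop("duplicate voxel coordinates in mask", call. = FALSE)
  }
  if (any(coords < 1L) || any(coords > matrix(shape, nrow(coords), 3, byrow = TRUE))) {
    stop("voxel coordinates outside grid", call. = FALSE)
  }
  if (is.null(affine)) {
    sx <- if (hemisphere == "left") -3 else 3
    affine <- rbind(
      c(sx, 0, 0, if (hemisphere == "left") -15 else 15),
      c(0, 3, 0, -3 * shape[2L] - 20),
      c(0, 0, 3, 10),
      c(0, 0, 0, 1)
    )
  }
  structure(list(coords = coords, shape = shape, hemisphere = hemisphere,
                 affine = affine),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s hemisphere, %d voxels on %s grid\n",
              x$hemisphere, nrow(x$coords), paste(x$shape, collapse = "x")))
  invisible(x)
}

# voxel coordinates -> mm via the mask affine
voxel_to_mm <- function(mask, coords) {
  h <- cbind(coords, 1)
  mm <- h %*% t(mask$affine)
  mm[, 1:3, drop = FALSE]
}

#' Generate left/right ROI masks with planted anterior/posterior structure
#'
#' Builds one box-shaped grid per hemisphere and splits its voxels into a
#' planted anterior and posterior subregion by a plane perpendicular to the
#' anterior-posterior (second) grid axis: the most anterior
#' `round(anterior_fraction * shape[2])` coordinate planes form the anterior
#' subregion. With `mirrored = TRUE` the right mask and labels are the
#' left-right flip of the left ones; otherwise the right hemisphere is
#' generated independently. `drop_fraction > 0` removes a random voxel subset
#' per hemisphere, producing irregular masks for congruency analyses.
#'
#' @param shape 3-integer grid shape per hemisphere
#' @param anterior_fraction fraction of the anterior-posterior extent assigned
#'   to the anterior subregion (strictly between 0 and 1)
#' @param mirrored should the right hemisphere mirror the left?
#' @param seed integer seed (used only when voxels are dropped or hemispheres
#'   are generated independently)
#' @param drop_fraction fraction of voxels removed at random per hemisphere
#' @return list with elements `left`, `right` ([roi_mask()] objects) and
#'   `labels` (list of integer vectors, 1 = anterior, 2 = posterior, aligned
#'   with each mask's rows)
#' @export
generate_roi <- function(shape, anterior_fraction = 0.5, mirrored = TRUE,
                         seed = 1L, drop_fraction = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  if (!is.numeric(anterior_fraction) || anterior_fraction <= 0 || anterior_fraction >= 1) {
    stop("`anterior_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  n_ant <- round(anterior_fraction * shape[2L])
  if (n_ant < 1L || n_ant >= shape[2L]) {
    stop("`anterior_fraction` leaves an empty subregion on this grid", call. = FALSE)
  }
  set.seed(seed)

  grid <- as.matrix(expand.grid(x = seq_len(shape[1L]),
                                y = seq_len(shape[2L]),
                                z = seq_len(shape[3L])))
  labels_full <- ifelse(grid[, 2L] > shape[2L] - n_ant, 1L, 2L)

  subsample <- function() {
    if (drop_fraction == 0) return(seq_len(nrow(grid)))
    sort(sample(nrow(grid), round((1 - drop_fraction) * nrow(grid))))
  }

  keep_l <- subsample()
  left <- roi_mask(grid[keep_l, , drop = FALSE], shape, "left")
  lab_l <- labels_full[keep_l]

  if (mirrored) {
    rc <- grid[keep_l, , drop = FALSE]
    rc[, 1L] <- shape[1L] + 1L - rc[, 1L]
    ord <- order(coord_key(rc, shape))
    right <- roi_mask(rc[ord, , drop = FALSE], shape, "right")
    lab_r <- lab_l[ord]
  } else {
    keep_r <- subsample()
    right <- roi_mask(grid[keep_r, , drop = FALSE], shape, "right")
    lab_r <- labels_full[keep_r]
  }
  list(left = left, right = right, labels = list(left = lab_l, right = lab_r))
}

#' Write a mask (with optional integer labels) as a NIfTI volume
#'
#' Background voxels are 0; mask voxels carry `labels` (default 1).
#'
#' @param mask an [roi_mask()]
#' @param path output file (`.nii` or `.nii.gz`)
#' @param labels optional integer vector aligned with mask voxels
#' @return `path`, invisibly
#' @export
write_mask_nifti <- function(mask, path, labels = NULL) {
  vol <- array(0L, dim = mask$shape)
  vol[mask$coords] <- if (is.null(labels)) 1L else as.integer(labels)
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label NIfTI volume back into a mask plus labels
#'
#' @param path NIfTI file written by [write_mask_nifti()]
#' @param hemisphere hemisphere tag for the resulting mask
#' @return list with `mask` ([roi_mask()]) and `labels` (integer vector)
#' @export
read_mask_nifti <- function(path, hemisphere) {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  idx <- which(vol != 0, arr.ind = TRUE)
  idx <- idx[order(coord_key(idx, dim(vol))), , drop = FALSE]
  mask <- roi_mask(idx, dim(vol), hemisphere, affine = RNifti::xform(img))
  list(mask = mask, labels = as.integer(vol[idx]))
}
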