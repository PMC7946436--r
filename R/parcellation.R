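#' Build a parcellation directly from known labels
#'
#' Useful for planted-truth analyses and for consuming externally computed
#' label volumes: every voxel is marked stable and cluster codes are taken
#' as given.
#'
#' @param mask an [roi_mask()]
#' @param labels integer labels (1..k) aligned with mask voxels
#' @param names optional character names per cluster code (e.g.
#'   `c("anterior", "posterior")`)
#' @return a `parcellation` with the mask attached
#' @export
parcellation_from_labels <- function(mask, labels, names = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(mask$coords), all(labels >= 1L))
  k <- max(labels)
  out <- structure(list(label = labels, stable = rep(TRUE, length(labels)),
                        agreement = rep(1, length(labels)), k = k),
                   class = "parcellation")
  out$mask <- mask
  if (!is.null(names)) {
    stopifnot(length(names) == k)
    out$names <- names
  }
  out
}

#' Name subregions along the anterior-posterior axis
#'
#' Attaches the ROI mask to the parcellation, computes per-cluster centers of
#' mass (grid and millimetre coordinates via the mask affine) over stable
#' voxels, and names the clusters by anatomical position: for a two-cluster
#' solution the cluster with the greater anterior-posterior center-of-mass
#' coordinate is `"anterior"`, the other `"posterior"`; for k > 2 names are
#' ordinal from anterior to posterior (`"sub1"` most anterior).
#'
#' @param parc a [consensus_labels()] result
#' @param mask the [roi_mask()] the parcellation was computed on
#' @return the parcellation with `mask`, `names`, `centers_vox` and
#'   `centers_mm` fields filled in
#' @export
name_subregions <- function(parc, mask) {
  stopifnot(inherits(parc, "parcellation"), inherits(mask, "roi_mask"))
  stopifnot(length(parc$label) == nrow(mask$coords))
  used <- sort(unique(parc$label[parc$stable]))
  centers_vox <- t(vapply(used, function(j) {
    colMeans(mask$coords[which(parc$stable & parc$label == j), , drop = FALSE])
  }, numeric(3)))
  centers_mm <- voxel_to_mm(mask, centers_vox)
  # anterior direction: ascending second grid axis, flipped if the affine's
  # y scaling is negative
  ap <- centers_vox[, 2L] * sign(mask$affine[2L, 2L])
  if (anyDuplicated(ap)) {
    stop("degenerate parcellation: equal anterior-posterior centers", call. = FALSE)
  }
  ord <- order(ap, decreasing = TRUE) # most anterior first
  names <- character(parc$k)
  if (parc$k == 2L && length(used) == 2L) {
    names[used[ord]] <- c("anterior", "posterior")
  } else {
    names[used[ord]] <- sprintf("sub%d", seq_along(used))
  }
  parc$mask <- mask
  parc$names <- names
  rownames(centers_vox) <- rownames(centers_mm) <- names[used]
  parc$centers_vox <- centers_vox
  parc$centers_mm <- centers_mm
  parc
}

#' Summarize a named parcellation
#'
#' One row per subregion: voxel count, volume in cm^3 (from the affine's
#' voxel volume), center of mass in mm, and stable-voxel counts, mirroring a
#' standard subregion summary table.
#'
#' @param object a named parcellation (see [name_subregions()])
#' @param ... unused
#' @return a data.frame
#' @export
summary.parcellation <- function(object, ...) {
  if (is.null(object$mask) || is.null(object$names)) {
    stop("parcellation must be named first (see name_subregions())", call. = FALSE)
  }
  vox_vol <- abs(det(object$mask$affine[1:3, 1:3])) / 1000 # cm^3
  used <- sort(unique(object$label[object$stable]))
  rows <- lapply(used, function(j) {
    idx <- which(object$stable & object$label == j)
    com <- colMeans(voxel_to_mm(object$mask, object$mask$coords[idx, , drop = FALSE]))
    data.frame(hemisphere = object$mask$hemisphere,
               subregion = object$names[j],
               n_voxels = length(idx),
               volume_cm3 = length(idx) * vox_vol,
               com_x = com[1], com_y = com[2], com_z = com[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n_unstable <- sum(!object$stable)
  rownames(out) <- NULL
  out
}

#' Hemispheric congruency of two parcellations
#'
#' Flips the right parcellation across the left-right (first) grid axis and
#' quantifies (i) the overall spatial overlap: for each hemisphere, the
#' percentage of its ROI voxels whose mirrored position is contained in the
#' other hemisphere's mask, and (ii) subregion concordance over the voxels
#' contained in both masks after flipping: the percentage of shared voxels
#' (stable and labelled on both sides) that carry the same subregion name,
#' overall and per subregion. With no shared voxels the concordance is
#' undefined and reported as `NA`.
#'
#' @param left,right named parcellations on grids of identical shape
#' @return list with `overlap_pct` (named: left, right), `concordance_pct`
#'   (scalar), `per_subregion_pct` (per hemisphere x subregion), `n_shared`
#' @export
hemispheric_congruency <- function(left, right) {
  stopifnot(inherits(left, "parcellation"), inherits(right, "parcellation"))
  if (is.null(left$mask) || is.null(right$mask)) {
    stop("parcellations must carry masks (see name_subregions())", call. = FALSE)
  }
  if (!identical(left$mask$shape, right$mask$shape)) {
    stop("mask shapes differ between hemispheres", call. = FALSE)
  }
  shape <- left$mask$shape
  rc <- right$mask$coords
  rc[, 1L] <- shape[1L] + 1L - rc[, 1L]
  key_l <- coord_key(left$mask$coords, shape)
  key_r <- coord_key(rc, shape)
  shared <- intersect(key_l, key_r)
  overlap <- c(left = 100 * length(shared) / length(key_l),
               right = 100 * length(shared) / length(key_r))
  if (!length(shared)) {
    return(list(overlap_pct = overlap, concordance_pct = NA_real_,
                per_subregion_pct = NULL, n_shared = 0L))
  }
  il <- match(shared, key_l)
  ir <- match(shared, key_r)
  name_of <- function(p, idx) {
    out <- rep(NA_character_, length(idx))
    ok <- p$stable[idx]
    out[ok] <- p$names[p$label[idx[ok]]]
    out
  }
  nl <- name_of(left, il)
  nr <- name_of(right, ir)
  both <- !is.na(nl) & !is.na(nr)
  concordance <- if (any(both)) 100 * mean(nl[both] == nr[both]) else NA_real_
  subregions <- sort(unique(stats::na.omit(c(left$names, right$names))))
  per <- matrix(NA_real_, 2L, length(subregions),
                dimnames = list(c("left", "right"), subregions))
  for (s in subregions) {
    sel_l <- both & nl == s
    if (any(sel_l)) per["left", s] <- 100 * mean(nr[sel_l] == s)
    sel_r <- both & nr == s
    if (any(sel_r)) per["right", s] <- 100 * mean(nl[sel_r] == s)
  }
  list(overlap_pct = overlap, concordance_pct = concordance,
       per_subregion_pct = per, n_shared = length(shared))
}

#' Write a named parcellation as a NIfTI label volume
#'
#' Voxel values: 1 = anterior, 2 = posterior (or ordinal codes for k > 2),
#' 0 = background or unstable/excluded voxels.
#'
#' @param parc a named parcellation
#' @param path output NIfTI path
#' @return `path`, invisibly
#' @export
write_parcellation_nifti <- function(parc, path) {
  if (is.null(parc$mask) || is.null(parc$names)) {
    stop("parcellation must be named first", call. = FALSE)
  }
  # stable codes remapped so 1 = anterior, 2 = posterior (ordinal otherwise)
  name_order <- c("anterior", "posterior",
                  setdiff(sort(unique(parc$names)), c("anterior", "posterior")))
  code <- match(parc$names, name_order)
  lab <- ifelse(parc$stable, code[parc$label], 0L)
  write_mask_nifti(parc$mask, path, labels = lab)
}
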