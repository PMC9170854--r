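#' Sphere region of interest
#'
#' Ties a detected sphere to its nominal diameter, physical center and
#' central axial plane. The central plane is the slice whose plane lies
#' nearest the center's axial coordinate; when the center is exactly
#' equidistant from two slices, the lower index is chosen.
#'
#' @param sphere_id label (by convention the nominal diameter, e.g. "10mm").
#' @param center_mm 3-D physical center (mm).
#' @param nominal_diameter_mm nominal sphere diameter (mm).
#' @param grid a [grid_spec()] used to resolve the central plane.
#' @return an object of class `sphere_roi`.
#' @export
sphere_roi <- function(sphere_id, center_mm, nominal_diameter_mm, grid) {
  if (nominal_diameter_mm <= 0) stop("nominal_diameter_mm must be > 0")
  zs <- axis_coords(grid, 3)
  plane <- which.min(abs(zs - center_mm[3]))  # first match = lower index on ties
  structure(list(sphere_id = sphere_id,
                 center_mm = as.numeric(center_mm),
                 nominal_diameter_mm = nominal_diameter_mm,
                 central_plane_index = plane),
            class = "sphere_roi")
}

#' Voxel mask
#'
#' A set of unique in-bounds voxel indices (1-based, n x 3 integer matrix)
#' on a grid.
#'
#' @param indices n x 3 integer matrix of voxel indices.
#' @param grid a [grid_spec()].
#' @return an object of class `voxel_mask`.
#' @export
voxel_mask <- function(indices, grid) {
  indices <- matrix(as.integer(indices), ncol = 3)
  if (nrow(indices)) {
    if (any(indices < 1L) ||
        any(sweep(indices, 2, grid$matrix_size, ">")))
      stop("mask indices out of grid bounds")
    if (anyDuplicated(indices))
      stop("mask indices must be unique")
  }
  structure(list(indices = indices, grid = grid), class = "voxel_mask")
}

# Values of an image at mask voxels, in the mask's (lexicographic) order.
mask_values <- function(image, mask) image$values[mask$indices]

# Sort mask rows lexicographically by (i, j, k) for deterministic tie-breaks.
sort_mask_indices <- function(idx) {
  idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
}

# Voxel indices whose centers lie within radius_mm of center_mm.
ball_indices <- function(center_mm, radius_mm, grid) {
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  ix <- which(abs(xs - center_mm[1]) <= radius_mm)
  iy <- which(abs(ys - center_mm[2]) <= radius_mm)
  iz <- which(abs(zs - center_mm[3]) <= radius_mm)
  if (!length(ix) || !length(iy) || !length(iz))
    return(matrix(integer(0), ncol = 3))
  box <- as.matrix(expand.grid(i = ix, j = iy, k = iz))
  d2 <- (xs[box[, 1]] - center_mm[1])^2 + (ys[box[, 2]] - center_mm[2])^2 +
    (zs[box[, 3]] - center_mm[3])^2
  sort_mask_indices(box[d2 <= radius_mm^2, , drop = FALSE])
}

#' 3-D sphere mask (center-in rule)
#'
#' A voxel belongs to the mask iff its center lies within
#' `nominal_diameter/2` of the ROI center. No partial weighting is applied.
#'
#' @param roi a [sphere_roi()].
#' @param grid a [grid_spec()].
#' @return a [voxel_mask()].
#' @export
sphere_mask_3d <- function(roi, grid) {
  r <- roi$nominal_diameter_mm / 2
  b <- grid_bounds_mm(grid)
  if (any(roi$center_mm - r < b$lower) || any(roi$center_mm + r > b$upper))
    stop(sprintf("ROI %s extends beyond the grid", roi$sphere_id))
  voxel_mask(ball_indices(roi$center_mm, r, grid), grid)
}

#' Central-plane disk mask
#'
#' The voxels of [sphere_mask_3d()] restricted to the ROI's central axial
#' slice.
#'
#' @inheritParams sphere_mask_3d
#' @return a [voxel_mask()].
#' @export
disk_mask_2d <- function(roi, grid) {
  m <- sphere_mask_3d(roi, grid)
  keep <- m$indices[, 3] == roi$central_plane_index
  voxel_mask(m$indices[keep, , drop = FALSE], grid)
}

#' 1 cm^3 peak mask
#'
#' The spherical neighbourhood used by SUVPeak: voxels whose centers lie
#' within `r = (3 * 1000 / (4*pi))^(1/3) ~ 6.2035` mm of a given voxel's
#' center (a 1 cm^3 ball). If the ball is clipped by the grid boundary a
#' warning is emitted and the clipped mask returned.
#'
#' @param center_voxel 3-D integer voxel index (1-based).
#' @param grid a [grid_spec()].
#' @return a [voxel_mask()].
#' @export
peak_mask <- function(center_voxel, grid) {
  center_voxel <- as.integer(center_voxel)
  if (any(center_voxel < 1L) || any(center_voxel > grid$matrix_size))
    stop("center voxel outside the grid")
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  ctr <- as.numeric(index_to_mm(grid, matrix(center_voxel, ncol = 3)))
  b <- grid_bounds_mm(grid)
  if (any(ctr - r < b$lower) || any(ctr + r > b$upper))
    warning("1 cm^3 peak mask clipped by the grid boundary")
  voxel_mask(ball_indices(ctr, r, grid), grid)
}

#' Locate the six spheres in an image
#'
#' In geometry mode (a phantom geometry hint is supplied) the nominal
#' centers are refined by the intensity center-of-mass within each nominal
#' sphere. In automatic mode the image is lightly smoothed, the six
#' strongest local maxima separated by at least 20 mm are found, each
#' region's equivalent diameter is estimated from the volume of its
#' 50%-of-local-max isocontour, and regions are matched to the expected
#' diameters by nearest size.
#'
#' @param image an [image_volume()] (typically the truth image or a
#'   high-count reference frame).
#' @param geom_hint optional [build_phantom_geometry()] result.
#' @param expected_diameters_mm the nominal diameters to assign (mm).
#' @return list of six [sphere_roi()], sorted by increasing diameter.
#' @export
detect_spheres <- function(image, geom_hint = NULL,
                           expected_diameters_mm = c(10, 13, 17, 22, 28, 37)) {
  grid <- image$grid
  expected <- sort(expected_diameters_mm)
  if (!is.null(geom_hint)) {
    rois <- vector("list", length(geom_hint$sphere_diameters_mm))
    for (s in seq_along(rois)) {
      roi0 <- sphere_roi(geom_hint$sphere_ids[s],
                         geom_hint$sphere_centers_mm[s, ],
                         geom_hint$sphere_diameters_mm[s], grid)
      m <- sphere_mask_3d(roi0, grid)
      w <- pmax(mask_values(image, m), 0)
      ctr <- if (sum(w) > 0)
        colSums(index_to_mm(grid, m$indices) * w) / sum(w)
      else roi0$center_mm
      rois[[s]] <- sphere_roi(roi0$sphere_id, ctr, roi0$nominal_diameter_mm,
                              grid)
    }
    return(rois[order(vapply(rois, function(r) r$nominal_diameter_mm, 0))])
  }

  # automatic mode
  sm <- gaussian_blur3d(image$values, grid$voxel_size_mm, 6)
  med <- stats::median(sm)
  rng <- max(sm) - med
  if (!is.finite(rng) || rng <= 1e-9 * max(abs(sm), 1))
    stop("sphere detection failed: no distinct hot regions in the image")
  # candidate floor: far above background texture, below the smoothed peak
  # of the dimmest sphere even on noisy references
  thr <- med + 0.25 * rng
  cand <- list()
  work <- sm
  # non-maximum suppression: wide enough that the smoothed halo of the
  # largest sphere cannot resurface as a second candidate, and in any case
  # at least the required 20 mm separation
  supp_r <- max(20, max(expected) / 2 + 12)
  while (length(cand) < length(expected)) {
    peak <- which.max(work)
    if (work[peak] < thr) break
    idx <- arrayInd(peak, dim(work))
    ctr <- as.numeric(index_to_mm(grid, idx))
    cand[[length(cand) + 1]] <- list(center = ctr, value = sm[peak])
    supp <- ball_indices(ctr, supp_r, grid)
    work[supp] <- -Inf
  }
  if (length(cand) < length(expected))
    stop(sprintf(
      "sphere detection failed: found %d candidate region(s), expected %d",
      length(cand), length(expected)))

  # equivalent diameter from the 50%-of-local-max isocontour volume
  d_eq <- vapply(cand, function(cn) {
    local <- ball_indices(cn$center, max(expected) / 2 + 2 * grid$voxel_size_mm,
                          grid)
    v <- sm[local]
    n_above <- sum(v >= 0.5 * cn$value)
    (6 * n_above * grid$voxel_size_mm^3 / pi)^(1 / 3)
  }, 0)

  # rank matching: k-th largest estimated region gets the k-th largest
  # expected diameter (optimal 1-D assignment)
  ord <- order(d_eq)
  rois <- vector("list", length(expected))
  for (k in seq_along(expected)) {
    d <- expected[k]
    rois[[k]] <- sphere_roi(sprintf("%dmm", round(d)),
                            cand[[ord[k]]]$center, d, grid)
  }
  # refine by center-of-mass within the nominal sphere
  lapply(rois, function(roi) {
    m <- sphere_mask_3d(roi, grid)
    w <- pmax(mask_values(image, m), 0)
    ctr <- if (sum(w) > 0)
      colSums(index_to_mm(grid, m$indices) * w) / sum(w)
    else roi$center_mm
    sphere_roi(roi$sphere_id, ctr, roi$nominal_diameter_mm, grid)
  })
}

#' ROI table
#'
#' @param rois list of [sphere_roi()].
#' @return data.frame with one row per ROI (id, center, diameter, plane).
#' @export
roi_table <- function(rois) {
  data.frame(
    sphere_id = vapply(rois, function(r) r$sphere_id, ""),
    center_x_mm = vapply(rois, function(r) r$center_mm[1], 0),
    center_y_mm = vapply(rois, function(r) r$center_mm[2], 0),
    center_z_mm = vapply(rois, function(r) r$center_mm[3], 0),
    nominal_diameter_mm = vapply(rois, function(r) r$nominal_diameter_mm, 0),
    central_plane_index = vapply(rois, function(r) r$central_plane_index, 0L),
    stringsAsFactors = FALSE)
}

#' Export masks as a NIfTI label map for visual QC
#'
#' Voxels of the i-th ROI's 3-D sphere mask are labelled `i` (later ROIs
#' overwrite earlier ones where masks touch, which default geometries never
#' do).
#'
#' @param rois list of [sphere_roi()].
#' @param grid a [grid_spec()].
#' @param path output NIfTI file.
#' @export
write_roi_labelmap <- function(rois, grid, path) {
  lab <- array(0L, grid$matrix_size)
  for (i in seq_along(rois))
    lab[sphere_mask_3d(rois[[i]], grid)$indices] <- i
  nii <- RNifti::asNifti(lab)
  nii <- RNifti::`pixdim<-`(nii, rep(grid$voxel_size_mm, 3))
  RNifti::writeNifti(nii, path)
  invisible(path)
}
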