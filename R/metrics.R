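#' SUV metrics for one sphere in one frame
#'
#' The five metrics are computed over fixed masks derived from the ROI:
#' `Max2D`/`Max3D` are the maximum voxel value over the central-plane disk /
#' the full nominal sphere; `Mean2D`/`Mean3D` the arithmetic mean over the
#' same masks, with no thresholding; `Peak` the mean over a 1 cm^3 ball
#' centered on the maximum voxel of the sphere mask (tie broken at the
#' lexicographically lowest index; a ball clipped by the grid edge is used
#' as-is with a warning). Values are activity concentrations (kBq/ml); a
#' phantom has no patient normalization, but an external scale factor can
#' convert to clinical SUV.
#'
#' @param image an [image_volume()].
#' @param roi a [sphere_roi()].
#' @return a single numeric value (kBq/ml).
#' @name suv_metrics
NULL

metric_over_mask <- function(image, mask, fun, what) {
  if (nrow(mask$indices) == 0L)
    stop(sprintf("empty mask for %s", what))
  fun(mask_values(image, mask))
}

#' @rdname suv_metrics
#' @export
suv_max_2d <- function(image, roi) {
  metric_over_mask(image, disk_mask_2d(roi, image$grid), max,
                   paste("Max2D of", roi$sphere_id))
}

#' @rdname suv_metrics
#' @export
suv_max_3d <- function(image, roi) {
  metric_over_mask(image, sphere_mask_3d(roi, image$grid), max,
                   paste("Max3D of", roi$sphere_id))
}

#' @rdname suv_metrics
#' @export
suv_mean_2d <- function(image, roi) {
  metric_over_mask(image, disk_mask_2d(roi, image$grid), mean,
                   paste("Mean2D of", roi$sphere_id))
}

#' @rdname suv_metrics
#' @export
suv_mean_3d <- function(image, roi) {
  metric_over_mask(image, sphere_mask_3d(roi, image$grid), mean,
                   paste("Mean3D of", roi$sphere_id))
}

#' @rdname suv_metrics
#' @export
suv_peak <- function(image, roi) {
  m <- sphere_mask_3d(roi, image$grid)
  if (nrow(m$indices) == 0L)
    stop(sprintf("empty mask for Peak of %s", roi$sphere_id))
  v <- mask_values(image, m)
  argmax <- m$indices[which.max(v), ]  # mask rows are lexicographically sorted
  mean(mask_values(image, peak_mask(argmax, image$grid)))
}

suv_metric_names <- c("Max2D", "Max3D", "Mean2D", "Mean3D", "Peak")

#' Compute all SUV metrics for all spheres and frames
#'
#' Applies the five metrics to every frame of every subset using a single
#' fixed set of ROIs (detected once on a reference image), so that the
#' resulting variation isolates counting statistics rather than ROI
#' placement.
#'
#' @param frames named list mapping reconstruction length to a list of
#'   [image_volume()] frames, as returned by [simulate_subsets()] or
#'   [read_frames()].
#' @param rois list of [sphere_roi()].
#' @return long-format data.frame with columns `sphere_id`, `metric`,
#'   `frame_index`, `rl_s`, `value_kbq_ml`.
#' @export
compute_all_metrics <- function(frames, rois) {
  stopifnot(length(frames) > 0, length(rois) > 0)
  grid <- frames[[1]][[1]]$grid
  # fixed-ROI contract: masks built once and reused across all frames
  prep <- lapply(rois, function(roi) {
    list(roi = roi,
         m3 = sphere_mask_3d(roi, grid),
         m2 = disk_mask_2d(roi, grid))
  })
  rows <- list()
  for (rl_name in names(frames)) {
    fl <- frames[[rl_name]]
    for (k in seq_along(fl)) {
      img <- fl[[k]]
      if (!all(dim(img$values) == grid$matrix_size))
        stop(sprintf("frame %d of RL=%s has a mismatched grid", k, rl_name))
      for (p in prep) {
        v2 <- mask_values(img, p$m2)
        v3 <- mask_values(img, p$m3)
        argmax <- p$m3$indices[which.max(v3), ]
        pk <- mean(mask_values(img, peak_mask(argmax, grid)))
        rows[[length(rows) + 1]] <- data.frame(
          sphere_id = p$roi$sphere_id,
          metric = suv_metric_names,
          frame_index = k,
          rl_s = img$frame_duration_s,
          value_kbq_ml = c(max(v2), max(v3), mean(v2), mean(v3), pk),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
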