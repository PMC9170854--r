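#' Write frames as NIfTI volumes with JSON sidecars
#'
#' One `.nii` file per frame plus a sidecar `<name>.json` carrying
#' `frame_start_s`, `frame_duration_s`, `decay_corrected_to_s`,
#' `voxel_size_mm`, `origin_mm` and, when given, the seed.
#'
#' @param frames named list mapping reconstruction length to a list of
#'   [image_volume()] frames.
#' @param dir output directory (created if needed).
#' @param seed optional master seed recorded in each sidecar.
#' @return invisibly, the vector of NIfTI paths written.
#' @export
write_frames <- function(frames, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (rl_name in names(frames)) {
    fl <- frames[[rl_name]]
    for (k in seq_along(fl)) {
      stem <- file.path(dir, sprintf("rl%s_frame%03d", rl_name, k))
      paths <- c(paths, write_one_frame(fl[[k]], stem, seed))
    }
  }
  invisible(paths)
}

write_one_frame <- function(img, stem, seed = NULL) {
  nii <- RNifti::asNifti(img$values)
  nii <- RNifti::`pixdim<-`(nii, rep(img$grid$voxel_size_mm, 3))
  RNifti::writeNifti(nii, paste0(stem, ".nii"))
  sidecar <- list(frame_start_s = img$frame_start_s,
                  frame_duration_s = img$frame_duration_s,
                  decay_corrected_to_s = img$decay_corrected_to_s,
                  voxel_size_mm = img$grid$voxel_size_mm,
                  origin_mm = img$grid$origin_mm)
  if (!is.null(seed)) sidecar$seed <- seed
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  paste0(stem, ".nii")
}

#' Read a directory of frames
#'
#' Loads every `.nii`/`.nii.gz` volume with its JSON sidecar, validates
#' consistency (one common grid, complete sidecars) and groups the frames by
#' reconstruction length.
#'
#' @param dir directory containing NIfTI frames and sidecars.
#' @return named list mapping reconstruction length to a list of
#'   [image_volume()] frames, ordered by frame start time within each RL.
#' @export
read_frames <- function(dir) {
  niis <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(niis)) stop(sprintf("no NIfTI frames found in %s", dir))
  vols <- list()
  ref_grid <- NULL
  for (f in niis) {
    sidecar_path <- paste0(sub("\\.nii(\\.gz)?$", "", f), ".json")
    if (!file.exists(sidecar_path))
      stop(sprintf("missing JSON sidecar for %s", basename(f)))
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    for (field in c("frame_start_s", "frame_duration_s", "voxel_size_mm"))
      if (is.null(side[[field]]))
        stop(sprintf("sidecar of %s lacks %s", basename(f), field))
    arr <- as.array(RNifti::readNifti(f))
    arr <- array(as.numeric(arr), dim(arr))  # strip NIfTI attributes
    grid <- grid_spec(dim(arr), side$voxel_size_mm,
                      origin_mm = side$origin_mm)
    if (is.null(ref_grid)) {
      ref_grid <- grid
    } else if (!isTRUE(all.equal(ref_grid, grid))) {
      stop(sprintf("frame %s has a different grid than the other frames",
                   basename(f)))
    }
    vols[[length(vols) + 1]] <- image_volume(
      arr, grid, frame_start_s = side$frame_start_s,
      frame_duration_s = side$frame_duration_s,
      decay_corrected_to_s = side$decay_corrected_to_s %||% 0)
  }
  rls <- vapply(vols, function(v) v$frame_duration_s, 0)
  out <- list()
  for (rl in sort(unique(rls))) {
    grp <- vols[rls == rl]
    starts <- vapply(grp, function(v) v$frame_start_s, 0)
    out[[as.character(rl)]] <- grp[order(starts)]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
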