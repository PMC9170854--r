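#' Voxel grid specification
#'
#' Describes the sampling grid of a reconstructed PET volume: matrix size,
#' isotropic voxel size and the physical position of the first voxel center.
#' The voxel-center convention is used throughout: the center of voxel
#' `(i, j, k)` (1-based indices, axial = third index) lies at
#' `origin_mm + (index - 1) * voxel_size_mm`.
#'
#' @param matrix_size integer vector of length 3, voxels per axis
#'   (in-plane x, in-plane y, axial). Default 144 x 144 x 48.
#' @param voxel_size_mm isotropic voxel edge length in mm (default 4).
#' @param origin_mm position (mm) of the center of voxel (1,1,1). Defaults to
#'   centering the grid on the physical origin.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(matrix_size = c(144L, 144L, 48L),
                      voxel_size_mm = 4,
                      origin_mm = NULL) {
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) != 3L || any(matrix_size < 1L))
    stop("matrix_size must be three positive integers")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0)
    stop("voxel_size_mm must be a single positive number")
  if (is.null(origin_mm))
    origin_mm <- -(matrix_size - 1) / 2 * voxel_size_mm
  if (length(origin_mm) != 3L || !all(is.finite(origin_mm)))
    stop("origin_mm must be three finite numbers")
  structure(list(matrix_size = matrix_size,
                 voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3g mm isotropic\n",
              x$matrix_size[1], x$matrix_size[2], x$matrix_size[3],
              x$voxel_size_mm))
  invisible(x)
}

# Physical coordinates (mm) of voxel centers along one axis.
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$matrix_size[axis]) - 1) * grid$voxel_size_mm
}

# Voxel volume in ml (1 ml = 1000 mm^3).
voxel_volume_ml <- function(grid) grid$voxel_size_mm^3 / 1000

# mm position of voxel centers given an n x 3 matrix of 1-based indices.
index_to_mm <- function(grid, idx) {
  sweep(sweep(idx - 1, 2, rep(grid$voxel_size_mm, 3), "*"),
        2, grid$origin_mm, "+")
}

# Outer physical bounds of the grid (faces of the outermost voxels).
grid_bounds_mm <- function(grid) {
  half <- grid$voxel_size_mm / 2
  list(lower = grid$origin_mm - half,
       upper = grid$origin_mm + (grid$matrix_size - 1) * grid$voxel_size_mm + half)
}

#' Reconstructed PET image volume
#'
#' A 3-D array of decay-corrected activity concentration (kBq/ml) together
#' with its grid and frame timing metadata. `frame_duration_s` is the
#' reconstruction length (RL) of the frame; a value of 0 marks a noise-free
#' ground-truth volume.
#'
#' @param values 3-D numeric array of activity concentration (kBq/ml).
#' @param grid a [grid_spec()].
#' @param frame_start_s frame start time relative to acquisition start (s).
#' @param frame_duration_s reconstruction length of the frame (s); 0 for a
#'   ground-truth image.
#' @param decay_corrected_to_s reference time the values are decay-corrected
#'   to (0 = acquisition start).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(values, grid, frame_start_s = 0,
                         frame_duration_s = 0, decay_corrected_to_s = 0) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!all(dim(values) == grid$matrix_size))
    stop("values dimensions do not match the grid")
  if (!all(is.finite(values)))
    stop("image values must all be finite")
  if (frame_duration_s < 0)
    stop("frame_duration_s must be >= 0")
  structure(list(values = values, grid = grid,
                 frame_start_s = unname(frame_start_s),
                 frame_duration_s = unname(frame_duration_s),
                 decay_corrected_to_s = unname(decay_corrected_to_s)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (x$frame_duration_s > 0)
    sprintf("frame [%g, %g) s", x$frame_start_s,
            x$frame_start_s + x$frame_duration_s)
  else "ground truth"
  cat(sprintf("<image_volume> %s, %d x %d x %d voxels, range [%.3g, %.3g] kBq/ml\n",
              kind, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}
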