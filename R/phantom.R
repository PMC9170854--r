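#' NEMA image-quality phantom geometry
#'
#' Builds the geometry of a NEMA IQ phantom: a torso-shaped background
#' compartment, a cold cylindrical insert on the central axis, and six
#' fillable spheres on a ring around the insert, all in one axial plane.
#' Activity concentrations are given at scan start. Defaults follow the
#' standard phantom: sphere diameters 10/13/17/22/28/37 mm, background
#' 2.10 MBq/ml and spheres 20.04 MBq/ml (nominal 10:1, actual ratio ~9.54).
#'
#' @param config named list overriding defaults. Recognised entries:
#'   `sphere_diameters_mm`, `sphere_centers_mm` (6 x 3 matrix),
#'   `background_activity_kbq_ml`, `sphere_activity_kbq_ml`,
#'   `torso_semiaxes_mm` (in-plane half-widths of the elliptical torso
#'   cross-section), `lung_insert_radius_mm`, `ring_radius_mm`.
#' @return an object of class `phantom_geometry`.
#' @export
build_phantom_geometry <- function(config = list()) {
  defaults <- list(
    sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
    sphere_centers_mm = NULL,
    background_activity_kbq_ml = 2.10 * 1000,
    sphere_activity_kbq_ml = 20.04 * 1000,
    torso_semiaxes_mm = c(150, 110),
    lung_insert_radius_mm = 25,
    ring_radius_mm = 57.2
  )
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])

  d <- sort(as.numeric(cfg$sphere_diameters_mm))
  if (length(d) != 6L)
    stop("exactly six sphere diameters are required")
  if (any(diff(d) <= 0))
    stop("sphere diameters must be distinct")
  if (cfg$background_activity_kbq_ml < 0 || cfg$sphere_activity_kbq_ml < 0)
    stop("activity concentrations must be >= 0")

  centers <- cfg$sphere_centers_mm
  if (is.null(centers)) {
    # largest sphere at angle 0, then decreasing diameter every 60 degrees
    ang <- (seq_len(6) - 1) * pi / 3
    centers <- cbind(cfg$ring_radius_mm * cos(ang),
                     cfg$ring_radius_mm * sin(ang), 0)
    centers <- centers[6:1, , drop = FALSE]  # row i pairs with i-th smallest diameter
  }
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (nrow(centers) != 6L)
    stop("sphere_centers_mm must supply six 3-D points")

  r <- d / 2
  ids <- sprintf("%dmm", round(d))
  # pairwise non-overlap
  for (i in 1:5) for (j in (i + 1):6) {
    if (sqrt(sum((centers[i, ] - centers[j, ])^2)) < r[i] + r[j])
      stop(sprintf("spheres %s and %s overlap", ids[i], ids[j]))
  }
  # inside the torso cross-section and clear of the cold insert
  ab <- cfg$torso_semiaxes_mm
  for (i in 1:6) {
    if ((centers[i, 1] / (ab[1] - r[i]))^2 +
        (centers[i, 2] / (ab[2] - r[i]))^2 > 1)
      stop(sprintf("sphere %s extends outside the torso compartment", ids[i]))
    if (sqrt(sum(centers[i, 1:2]^2)) < cfg$lung_insert_radius_mm + r[i])
      stop(sprintf("sphere %s overlaps the central insert", ids[i]))
  }

  structure(list(sphere_ids = ids,
                 sphere_diameters_mm = d,
                 sphere_centers_mm = centers,
                 torso_semiaxes_mm = ab,
                 lung_insert_radius_mm = cfg$lung_insert_radius_mm,
                 background_activity_kbq_ml = cfg$background_activity_kbq_ml,
                 sphere_activity_kbq_ml = cfg$sphere_activity_kbq_ml),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf(paste0("<phantom_geometry> six spheres (%s mm), background %.3g",
                     " kBq/ml, spheres %.3g kBq/ml (ratio %.3g:1)\n"),
              paste(round(x$sphere_diameters_mm), collapse = "/"),
              x$background_activity_kbq_ml, x$sphere_activity_kbq_ml,
              sphere_to_background_ratio(x)))
  invisible(x)
}

#' Computed sphere-to-background activity ratio
#'
#' @param geom a [build_phantom_geometry()] result.
#' @return the ratio of sphere to background activity concentration.
#' @export
sphere_to_background_ratio <- function(geom) {
  geom$sphere_activity_kbq_ml / geom$background_activity_kbq_ml
}

#' Rasterize the phantom onto a voxel grid
#'
#' Produces the noise-free ground-truth activity map. Each voxel takes the
#' value `background + (sphere - background) * f`, where `f` is the fraction
#' of the voxel inside a sphere, computed by `supersample^3` sub-voxel point
#' sampling for voxels straddling a sphere surface. The torso boundary and
#' the cold insert are voxelized with the center-in rule (partial volume at
#' those interfaces is not read by the sphere analysis).
#'
#' @param geom a [build_phantom_geometry()] result.
#' @param grid a [grid_spec()].
#' @param supersample sub-voxel sampling factor per axis (integer >= 1).
#' @return an [image_volume()] with frame metadata zeroed (ground truth).
#' @export
rasterize_activity <- function(geom, grid, supersample = 3L) {
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop("supersample must be >= 1")
  xs <- axis_coords(grid, 1); ys <- axis_coords(grid, 2); zs <- axis_coords(grid, 3)
  nd <- grid$matrix_size
  bg <- geom$background_activity_kbq_ml

  # torso background (center-in, elliptical cylinder along z)
  ab <- geom$torso_semiaxes_mm
  in_torso <- outer((xs / ab[1])^2, (ys / ab[2])^2, "+") <= 1
  vals <- array(0, nd)
  vals[] <- bg * rep(as.numeric(in_torso), nd[3])

  # cold central insert (center-in, cylinder along z); radius 0 disables it
  if (geom$lung_insert_radius_mm > 0) {
    in_lung <- outer(xs^2, ys^2, "+") <= geom$lung_insert_radius_mm^2
    vals[] <- vals * rep(as.numeric(!in_lung), nd[3])
  }

  half_diag <- sqrt(3) / 2 * grid$voxel_size_mm
  delta <- geom$sphere_activity_kbq_ml - bg
  for (s in seq_len(6)) {
    ctr <- geom$sphere_centers_mm[s, ]
    r <- geom$sphere_diameters_mm[s] / 2
    # bounding box of voxels possibly touched by the sphere
    ix <- which(abs(xs - ctr[1]) <= r + half_diag)
    iy <- which(abs(ys - ctr[2]) <= r + half_diag)
    iz <- which(abs(zs - ctr[3]) <= r + half_diag)
    if (!length(ix) || !length(iy) || !length(iz)) next
    box <- as.matrix(expand.grid(i = ix, j = iy, k = iz))
    cmm <- cbind(xs[box[, 1]], ys[box[, 2]], zs[box[, 3]])
    dist <- sqrt((cmm[, 1] - ctr[1])^2 + (cmm[, 2] - ctr[2])^2 +
                 (cmm[, 3] - ctr[3])^2)
    frac <- numeric(nrow(box))
    frac[dist <= r - half_diag] <- 1
    edge <- which(dist > r - half_diag & dist < r + half_diag)
    if (length(edge)) {
      off1 <- (seq_len(supersample) - (supersample + 1) / 2) /
        supersample * grid$voxel_size_mm
      offs <- as.matrix(expand.grid(off1, off1, off1))
      d2 <- outer(cmm[edge, 1] - ctr[1], offs[, 1], "+")^2 +
            outer(cmm[edge, 2] - ctr[2], offs[, 2], "+")^2 +
            outer(cmm[edge, 3] - ctr[3], offs[, 3], "+")^2
      frac[edge] <- rowMeans(d2 <= r^2)
    }
    nz <- frac > 0
    vals[box[nz, , drop = FALSE]] <- vals[box[nz, , drop = FALSE]] +
      delta * frac[nz]
  }
  image_volume(vals, grid)
}
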