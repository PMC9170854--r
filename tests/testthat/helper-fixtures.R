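# Small grids and phantoms used across tests; everything built in code.

# grid wide enough for the default sphere ring (+/-160 mm in-plane)
small_grid <- function(nz = 24L) grid_spec(c(80L, 80L, nz), 4)

uniform_volume <- function(value, n = 20L, voxel = 4) {
  g <- grid_spec(rep(as.integer(n), 3), voxel)
  image_volume(array(value, g$matrix_size), g)
}

# exhaustive lattice enumeration: voxel centers on an integer lattice around
# a center, counted by direct distance test (independent of ball_indices)
enum_ball_count <- function(center_mm, radius_mm, voxel_mm, reach = 10L) {
  n <- 0L
  for (i in -reach:reach) for (j in -reach:reach) for (k in -reach:reach) {
    d <- sqrt(sum((c(i, j, k) * voxel_mm - center_mm)^2))
    if (d <= radius_mm) n <- n + 1L
  }
  n
}

# noise-free default phantom at full resolution, cached per test run
default_truth_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- build_phantom_geometry()
      cache <<- list(geom = geom,
                     grid = grid_spec(),
                     truth = rasterize_activity(geom, grid_spec(), 3))
    }
    cache
  }
})
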