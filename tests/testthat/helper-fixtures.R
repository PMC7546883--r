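# Shared fixtures and independent oracles for the test suite.

unit_grid <- function(n = 20, spacing = 1) {
  make_grid(rep(n, 3), rep(spacing, 3))
}

# Mask from an explicit logical array on a unit grid.
mask_from_array <- function(arr, name = "M", role = "oar", spacing = 1) {
  g <- make_grid(dim(arr), rep(spacing, 3))
  contourdose:::new_structure_mask(g, arr, name, role)
}

# Axis-aligned cuboid mask given 1-based index ranges.
cube_mask <- function(grid, i, j, k, name = "cube", role = "oar") {
  arr <- array(FALSE, grid$shape)
  arr[i, j, k] <- TRUE
  contourdose:::new_structure_mask(grid, arr, name, role)
}

# Random blobby mask: union of a few random spheres, guaranteed non-empty.
random_blob_mask <- function(seed, n = 14, spacing = 1, name = "blob") {
  set.seed(seed)
  g <- make_grid(rep(n, 3), rep(spacing, 3))
  arr <- array(FALSE, g$shape)
  centers <- matrix(runif(9, 3, (n - 3) * spacing), ncol = 3)
  radii <- runif(3, 1.2, 3.5) * spacing
  for (s in 1:3) {
    m <- rasterize_sphere(g, centers[s, ], radii[s], "tmp")
    arr <- arr | m$voxels
  }
  contourdose:::new_structure_mask(g, arr, name, "oar")
}

# Random dose field on the mask's grid, values in [0, max_gy].
random_dose_grid <- function(grid, seed, max_gy = 50) {
  set.seed(seed)
  contourdose:::new_dose_grid(
    grid, array(runif(prod(grid$shape), 0, max_gy), grid$shape))
}

# All-pairs brute-force directed Hausdorff oracle: per source point, the
# nearest-neighbour distance is minimized explicitly over every target point.
brute_directed_hd <- function(A, B) {
  worst <- -Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2 + (A[i, 3] - B[, 3])^2
    worst <- max(worst, min(d2))
  }
  sqrt(worst)
}

brute_hausdorff <- function(mask_a, mask_b) {
  A <- boundary_points(mask_a)
  B <- boundary_points(mask_b)
  max(brute_directed_hd(A, B), brute_directed_hd(B, A))
}

# Direct one-line endpoint computations used as constraint-engine oracles.
direct_endpoint <- function(con, dose, mask) {
  dv <- dose$dose[mask$voxels]
  switch(con$metric,
         V_at_dose = 100 * sum(dv >= con$dose_gy) / length(dv),
         max = max(dv),
         mean = sum(dv) / length(dv))
}

all_constraint_strings <- function() {
  rbind(
    utils::read.csv(system.file("extdata", "constraints_prostate.csv",
                                package = "contourdose"), encoding = "UTF-8"),
    utils::read.csv(system.file("extdata", "constraints_hn.csv",
                                package = "contourdose"), encoding = "UTF-8"))
}
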