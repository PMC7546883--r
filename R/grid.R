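#' Construct a voxel grid
#'
#' A voxel grid is the common spatial frame for all structure masks and dose
#' distributions: a regular 3D lattice with `shape` voxels per axis, physical
#' `spacing` in mm and an `origin` in mm. The physical center of the voxel
#' with 0-based index `(i, j, k)` is `origin + c(i, j, k) * spacing`, and the
#' mapping is exactly invertible.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (all > 0).
#' @param origin numeric vector of length 3, physical coordinate in mm of the
#'   center of voxel (0, 0, 0).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- make_grid(c(10, 10, 10), spacing = c(1, 1, 1))
#' voxel_volume(g)  # 1 mm^3
#' @export
make_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("invalid-argument: 'shape' must be 3 integers >= 1", call. = FALSE)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("invalid-argument: 'spacing' must be 3 positive lengths in mm",
         call. = FALSE)
  if (length(origin) != 3L || anyNA(origin))
    stop("invalid-argument: 'origin' must be 3 finite coordinates in mm",
         call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param grid a `voxel_grid`.
#' @return Volume of one voxel in mm^3.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing)
}

#' Physical coordinates of voxel centers along each axis
#'
#' @param grid a `voxel_grid`.
#' @return List of three numeric vectors (mm), one per axis.
#' @export
axis_coords <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

# Physical extent [min center, max center] per axis.
grid_extent <- function(grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1L) * grid$spacing
  rbind(lo = lo, hi = hi)
}

same_grid <- function(g1, g2) {
  identical(g1$shape, g2$shape) &&
    isTRUE(all.equal(g1$spacing, g2$spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(g1$origin, g2$origin, tolerance = 1e-12))
}

new_structure_mask <- function(grid, voxels, name, role) {
  structure(list(grid = grid, voxels = voxels, name = name, role = role),
            class = "structure_mask")
}

check_mask <- function(mask, arg = "mask") {
  if (!inherits(mask, "structure_mask"))
    stop(sprintf("invalid-argument: '%s' must be a structure_mask", arg),
         call. = FALSE)
  invisible(mask)
}

#' Number of occupied voxels and physical volume of a mask
#'
#' @param mask a `structure_mask`.
#' @return `mask_count`: occupied voxel count. `mask_volume`: volume in mm^3.
#' @export
mask_count <- function(mask) {
  check_mask(mask)
  sum(mask$voxels)
}

#' @rdname mask_count
#' @export
mask_volume <- function(mask) {
  mask_count(mask) * voxel_volume(mask$grid)
}

#' Centroid of a mask in physical coordinates
#'
#' @param mask a `structure_mask`.
#' @return Numeric length-3 vector, mm.
#' @export
mask_centroid <- function(mask) {
  check_mask(mask)
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty-structure: mask has no occupied voxels", call. = FALSE)
  ctr <- (colMeans(idx) - 1) * mask$grid$spacing + mask$grid$origin
  unname(ctr)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s' (%s): %d voxels, %.1f mm^3\n",
              x$name, x$role, mask_count(x), mask_volume(x)))
  invisible(x)
}

# Physical centers (n x 3 matrix, mm) of the TRUE voxels of a logical array.
occupied_centers <- function(grid, voxels) {
  idx <- which(voxels, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

# Exact Euclidean distance (mm) from every voxel center to the nearest TRUE
# voxel center. Returns an array shaped like the grid.
distance_to <- function(grid, voxels) {
  d <- edt3d_cpp(as.logical(voxels), grid$shape, grid$spacing)
  array(d, dim = grid$shape)
}

# Occupied voxels with at least one unoccupied 6-neighbour; the grid boundary
# counts as unoccupied. Returns a logical array.
boundary_voxels <- function(mask) {
  v <- mask$voxels
  dm <- dim(v)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- v
  inner <-
    pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  v & !inner
}

# Unoccupied in-grid voxels 6-adjacent to an occupied voxel.
outer_shell_voxels <- function(mask) {
  v <- mask$voxels
  dm <- dim(v)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- v
  near <-
    pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] |
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] |
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] |
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] |
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] |
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  !v & near
}
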