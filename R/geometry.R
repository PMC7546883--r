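# Geometric agreement metrics between structure masks, in physical units.

#' Dice similarity coefficient between two masks
#'
#' Volumetric overlap 2|A intersect B| / (|A| + |B|) over occupied-voxel
#' counts. Symmetric in its arguments; 1 for identical occupancy, 0 for
#' disjoint masks. If exactly one mask is empty the coefficient is 0 by
#' definition; two empty masks have no defined value.
#'
#' @param mask_a,mask_b `structure_mask`s sharing one grid.
#' @return Dimensionless value in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  check_mask(mask_a, "mask_a"); check_mask(mask_b, "mask_b")
  if (!same_grid(mask_a$grid, mask_b$grid))
    stop("incompatible-grids: masks live on different grids", call. = FALSE)
  na <- sum(mask_a$voxels); nb <- sum(mask_b$voxels)
  if (na == 0L && nb == 0L)
    stop("undefined-metric: Dice is undefined for two empty masks",
         call. = FALSE)
  2 * sum(mask_a$voxels & mask_b$voxels) / (na + nb)
}

#' Boundary point set of a mask
#'
#' The physical centers (mm) of the occupied voxels that have at least one
#' unoccupied 6-neighbour; the grid boundary counts as unoccupied. These are
#' the contour points the Hausdorff distance is evaluated on. Points are
#' ordered by column-major voxel index, so the set is deterministic.
#'
#' @param mask a non-empty `structure_mask`.
#' @return An n x 3 numeric matrix of mm coordinates with attribute
#'   `source_structure`.
#' @export
boundary_points <- function(mask) {
  check_mask(mask)
  if (!any(mask$voxels))
    stop("empty-structure: mask has no occupied voxels", call. = FALSE)
  pts <- occupied_centers(mask$grid, boundary_voxels(mask))
  dimnames(pts) <- NULL
  attr(pts, "source_structure") <- mask$name
  pts
}

#' Directed and symmetric Hausdorff distance
#'
#' `directed_hd(A, B)` is the worst-case nearest-point distance
#' max over a in A of min over b in B of ||a - b||, in mm; it is not symmetric
#' in general. `hausdorff(mask_a, mask_b)` is the symmetric version
#' max(dHD(A, B), dHD(B, A)) over the two masks' boundary point sets; it is 0
#' iff the masks have identical occupancy. Distances are exact (no spatial
#' approximation); large point sets are processed in blocks to bound memory.
#'
#' @param points_a,points_b n x 3 matrices of mm coordinates (e.g. from
#'   [boundary_points()]).
#' @param mask_a,mask_b `structure_mask`s sharing one grid.
#' @return Distance in mm.
#' @examples
#' a <- matrix(c(0, 0, 0), ncol = 3)
#' b <- matrix(c(3, 4, 0), ncol = 3)
#' directed_hd(a, b)  # 5
#' @export
directed_hd <- function(points_a, points_b) {
  if (!is.matrix(points_a) || ncol(points_a) != 3L || nrow(points_a) == 0L ||
      !is.matrix(points_b) || ncol(points_b) != 3L || nrow(points_b) == 0L)
    stop("empty-structure: point sets must be non-empty n x 3 matrices",
         call. = FALSE)
  block <- 2048L
  n <- nrow(points_a)
  worst <- 0
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(points_a[s:e, 1], points_b[, 1], `-`)^2 +
      outer(points_a[s:e, 2], points_b[, 2], `-`)^2 +
      outer(points_a[s:e, 3], points_b[, 3], `-`)^2
    m <- max(apply(d2, 1, min))
    if (m > worst) worst <- m
  }
  sqrt(worst)
}

#' @rdname directed_hd
#' @export
hausdorff <- function(mask_a, mask_b) {
  check_mask(mask_a, "mask_a"); check_mask(mask_b, "mask_b")
  if (!same_grid(mask_a$grid, mask_b$grid))
    stop("incompatible-grids: masks live on different grids", call. = FALSE)
  a <- boundary_points(mask_a)
  b <- boundary_points(mask_b)
  max(directed_hd(a, b), directed_hd(b, a))
}

#' Per-structure geometric comparison of two structure sets
#'
#' Computes Dice and symmetric Hausdorff distance for every structure name
#' present in both sets (typically MS vs AS for one subject). Names present
#' in only one set are skipped with a warning and listed in the result's
#' `skipped` attribute.
#'
#' @param set_ms,set_as `structure_set`s on the same grid.
#' @return A data.frame with columns `subject_id`, `structure`, `dsc`,
#'   `hd_mm`.
#' @export
compare_structures <- function(set_ms, set_as) {
  stopifnot(inherits(set_ms, "structure_set"), inherits(set_as, "structure_set"))
  if (!same_grid(set_ms$grid, set_as$grid))
    stop("incompatible-grids: sets live on different grids", call. = FALSE)
  common <- intersect(names(set_ms$structures), names(set_as$structures))
  skipped <- setdiff(union(names(set_ms$structures), names(set_as$structures)),
                     common)
  if (length(common) == 0L)
    stop("invalid-argument: no structure names in common", call. = FALSE)
  if (length(skipped) > 0L)
    warning("structures present in only one set were skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  res <- data.frame(
    subject_id = set_ms$subject_id,
    structure = common,
    dsc = vapply(common, function(nm)
      dice(set_ms$structures[[nm]], set_as$structures[[nm]]), numeric(1)),
    hd_mm = vapply(common, function(nm)
      hausdorff(set_ms$structures[[nm]], set_as$structures[[nm]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  res
}

#' Cohort-level geometric summary
#'
#' Runs [compare_structures()] over every subject pair of a simulated cohort
#' and summarizes per-structure mean and SD of Dice and Hausdorff distance
#' (the usual box-plot quantities).
#'
#' @param cohort list of subject pairs from [simulate_cohort()].
#' @return List with `per_subject` (stacked comparison rows) and `summary`
#'   (per-structure mean/SD).
#' @export
geometry_summary <- function(cohort) {
  rows <- do.call(rbind, lapply(cohort, function(p)
    compare_structures(p$MS, p$AS)))
  agg <- do.call(rbind, lapply(split(rows, rows$structure), function(d)
    data.frame(structure = d$structure[1],
               n = nrow(d),
               dsc_mean = mean(d$dsc),
               dsc_sd = if (nrow(d) > 1) stats::sd(d$dsc) else NA_real_,
               hd_mean_mm = mean(d$hd_mm),
               hd_sd_mm = if (nrow(d) > 1) stats::sd(d$hd_mm) else NA_real_,
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(per_subject = rows, summary = agg)
}
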