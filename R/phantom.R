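# Synthetic phantom cohorts: paired "manual" (MS) and "auto" (AS) structure
# sets on a shared voxel grid, with controllable geometric discrepancy.

# Evaluate expr with a local RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# n x 3 matrix of all voxel center coordinates (mm), column-major voxel order.
all_centers <- function(grid) {
  ax <- axis_coords(grid)
  cbind(rep(ax[[1]], times = grid$shape[2] * grid$shape[3]),
        rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
        rep(ax[[3]], each = grid$shape[1] * grid$shape[2]))
}

check_center_inside <- function(grid, center) {
  ext <- grid_extent(grid)
  if (any(center < ext["lo", ] - grid$spacing / 2) ||
      any(center > ext["hi", ] + grid$spacing / 2))
    stop("invalid-argument: center lies outside the grid physical extent",
         call. = FALSE)
}

finish_mask <- function(grid, occ, name, role) {
  if (!any(occ))
    stop(sprintf("empty-structure: '%s' rasterized to zero voxels", name),
         call. = FALSE)
  new_structure_mask(grid, array(occ, dim = grid$shape), name, role)
}

#' Rasterize geometric primitives onto a voxel grid
#'
#' A voxel is occupied iff its physical center lies inside the shape
#' (voxel-center rule, no partial volume). All coordinates and sizes are in mm.
#'
#' @param grid a `voxel_grid`.
#' @param center shape center, mm (length 3); must lie inside the grid extent.
#' @param radius sphere/tube radius, mm (> 0).
#' @param semi_axes ellipsoid semi-axes, mm (length 3, all > 0).
#' @param axis tube direction (length 3, need not be normalized but non-zero).
#' @param length tube length, mm (>= 0); the tube is the set of points within
#'   `radius` of the axis segment of this length centered at `center`, so
#'   `length = 0` degenerates to a sphere.
#' @param name structure label (non-empty).
#' @param role `"target"` or `"oar"`.
#' @return A `structure_mask`.
#' @examples
#' g <- make_grid(c(20, 20, 20), c(1, 1, 1))
#' s <- rasterize_sphere(g, center = c(10, 10, 10), radius = 5, name = "CTV",
#'                       role = "target")
#' mask_volume(s)
#' @export
rasterize_sphere <- function(grid, center, radius, name, role = "oar") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("invalid-argument: radius must be a positive length in mm", call. = FALSE)
  check_center_inside(grid, center)
  xyz <- all_centers(grid)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  finish_mask(grid, d2 <= radius^2, name, role)
}

#' @rdname rasterize_sphere
#' @export
rasterize_ellipsoid <- function(grid, center, semi_axes, name, role = "oar") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("invalid-argument: semi_axes must be 3 positive lengths in mm",
         call. = FALSE)
  check_center_inside(grid, center)
  xyz <- all_centers(grid)
  q <- ((xyz[, 1] - center[1]) / semi_axes[1])^2 +
    ((xyz[, 2] - center[2]) / semi_axes[2])^2 +
    ((xyz[, 3] - center[3]) / semi_axes[3])^2
  finish_mask(grid, q <= 1, name, role)
}

#' @rdname rasterize_sphere
#' @export
rasterize_tube <- function(grid, axis = c(0, 0, 1), center, radius, length,
                           name, role = "oar") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("invalid-argument: radius must be a positive length in mm", call. = FALSE)
  if (!is.numeric(length) || base::length(length) != 1L || length < 0)
    stop("invalid-argument: length must be a non-negative length in mm",
         call. = FALSE)
  nrm <- sqrt(sum(axis^2))
  if (base::length(axis) != 3L || nrm == 0)
    stop("invalid-argument: axis must be a non-zero 3-vector", call. = FALSE)
  u <- axis / nrm
  check_center_inside(grid, center)
  xyz <- all_centers(grid)
  rel <- sweep(xyz, 2, center, `-`)
  # distance from each voxel center to the axis segment: project onto the
  # axis, clamp to the half-length, measure the residual
  t <- rel %*% u
  tc <- pmin(pmax(t, -length / 2), length / 2)
  res <- rel - tcrossprod(as.vector(tc), u)
  d2 <- res[, 1]^2 + res[, 2]^2 + res[, 3]^2
  finish_mask(grid, d2 <= radius^2, name, role)
}

#' Specify a geometric perturbation
#'
#' Describes one way an auto-segmented contour may deviate from its manual
#' counterpart: rigid translation, morphological dilation/erosion by a
#' physical radius, superior-inferior (axial) truncation, or seeded random
#' toggling of boundary voxels.
#'
#' @param kind one of `"translate"`, `"dilate"`, `"erode"`, `"truncate_axial"`,
#'   `"surface_noise"`.
#' @param magnitude perturbation size: mm for translate/dilate/erode, mm of
#'   axial length removed for truncate_axial, and the expected fraction of
#'   boundary voxels toggled (in \[0, 1\]) for surface_noise.
#' @param axis translation direction (unit-normalized internally); translate
#'   only.
#' @param seed RNG seed; surface_noise only.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind, magnitude, axis = c(1, 0, 0), seed = 1L) {
  kinds <- c("translate", "dilate", "erode", "truncate_axial", "surface_noise")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop("invalid-argument: unknown perturbation kind '", kind, "'",
         call. = FALSE)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0)
    stop("invalid-argument: magnitude must be >= 0", call. = FALSE)
  if (kind == "surface_noise" && magnitude > 1)
    stop("invalid-argument: surface_noise magnitude is a fraction in [0, 1]",
         call. = FALSE)
  if (kind == "translate") {
    nrm <- sqrt(sum(axis^2))
    if (length(axis) != 3L || nrm == 0)
      stop("invalid-argument: translate needs a non-zero axis", call. = FALSE)
    axis <- axis / nrm
  }
  structure(list(kind = kind, magnitude = magnitude, axis = axis,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Apply a perturbation to a structure mask
#'
#' Translation rounds the mm offset to the nearest whole-voxel offset per axis
#' (masks stay binary, no resampling); the applied voxel offset is recorded in
#' the result's `meta` field. Dilation and erosion are morphological ball
#' operations with physical radius equal to `magnitude`, computed from exact
#' voxel-center distances. Axial truncation removes occupied voxels whose
#' third-axis coordinate lies in the top `magnitude` mm of the structure's
#' occupied axial extent. Surface noise toggles boundary-shell voxels (the
#' occupied boundary and its unoccupied 6-neighbours) independently with
#' probability `magnitude`, under the spec's seed. All perturbations are
#' deterministic given the spec.
#'
#' @param mask a `structure_mask`.
#' @param spec a `perturbation_spec`.
#' @return The perturbed `structure_mask`.
#' @export
perturb <- function(mask, spec) {
  check_mask(mask)
  if (!inherits(spec, "perturbation_spec"))
    stop("invalid-argument: 'spec' must be a perturbation_spec", call. = FALSE)
  g <- mask$grid
  v <- mask$voxels
  out <- switch(spec$kind,
    translate = {
      off <- as.integer(round(spec$magnitude * spec$axis / g$spacing))
      shifted <- shift_array(v, off)
      m <- new_structure_mask(g, shifted, mask$name, mask$role)
      m$meta <- list(voxel_offset = off)
      m
    },
    dilate = {
      if (spec$magnitude == 0) mask
      else {
        d <- distance_to(g, v)
        new_structure_mask(g, v | (d <= spec$magnitude), mask$name, mask$role)
      }
    },
    erode = {
      if (spec$magnitude == 0) mask
      else {
        dbg <- distance_to(g, !v)
        new_structure_mask(g, v & (dbg > spec$magnitude), mask$name, mask$role)
      }
    },
    truncate_axial = {
      if (spec$magnitude == 0) mask
      else {
        zc <- axis_coords(g)[[3]]
        occ_z <- apply(v, 3, any)
        zmax <- max(zc[occ_z])
        keep_z <- zc <= zmax - spec$magnitude
        vv <- v & rep(keep_z, each = g$shape[1] * g$shape[2])
        new_structure_mask(g, array(vv, dim = g$shape), mask$name, mask$role)
      }
    },
    surface_noise = {
      if (spec$magnitude == 0) mask
      else {
        inner <- which(boundary_voxels(mask))
        outer <- which(outer_shell_voxels(mask))
        vv <- v
        with_seed(spec$seed, {
          flip_in <- inner[stats::runif(length(inner)) < spec$magnitude]
          flip_out <- outer[stats::runif(length(outer)) < spec$magnitude]
        })
        vv[flip_in] <- FALSE
        vv[flip_out] <- TRUE
        new_structure_mask(g, vv, mask$name, mask$role)
      }
    })
  if (!any(out$voxels))
    stop(sprintf("empty-structure: perturbation '%s' emptied '%s'",
                 spec$kind, mask$name), call. = FALSE)
  out
}

# Shift a logical 3D array by whole-voxel offsets, clipping at the boundary.
shift_array <- function(v, off) {
  dm <- dim(v)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= dm[a]) return(out)
    if (o >= 0) {
      src[[a]] <- 1:(dm[a] - o)
      dst[[a]] <- (1 + o):dm[a]
    } else {
      src[[a]] <- (1 - o):dm[a]
      dst[[a]] <- 1:(dm[a] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}

#' Bundle structure masks into a structure set
#'
#' @param subject_id subject label.
#' @param source `"MS"` (manual) or `"AS"` (auto).
#' @param structures list of `structure_mask` objects sharing one grid.
#' @return An object of class `structure_set`; masks are accessible by name
#'   via `x$structures[[name]]`.
#' @export
structure_set <- function(subject_id, source, structures) {
  if (!source %in% c("MS", "AS"))
    stop("invalid-argument: source must be 'MS' or 'AS'", call. = FALSE)
  if (length(structures) == 0L)
    stop("invalid-argument: empty structure list", call. = FALSE)
  lapply(structures, check_mask)
  nms <- vapply(structures, function(m) m$name, character(1))
  if (anyDuplicated(nms))
    stop("invalid-argument: duplicate structure names in set", call. = FALSE)
  g <- structures[[1]]$grid
  for (m in structures)
    if (!same_grid(g, m$grid))
      stop("incompatible-grids: all masks in a set must share one grid",
           call. = FALSE)
  names(structures) <- nms
  structure(list(subject_id = subject_id, source = source, grid = g,
                 structures = structures),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> subject '%s' (%s): %d structures [%s]\n",
              x$subject_id, x$source, length(x$structures),
              paste(names(x$structures), collapse = ", ")))
  invisible(x)
}

#' Define a structure template for the phantom
#'
#' Templates place primitive shapes relative to the physical center of the
#' grid; per-subject jitter is applied to the offset and size at simulation
#' time.
#'
#' @param name structure label.
#' @param role `"target"` or `"oar"`.
#' @param shape `"sphere"`, `"ellipsoid"` or `"tube"`.
#' @param center_offset mm offset of the shape center from the grid's physical
#'   center.
#' @param radius sphere/tube radius, mm.
#' @param semi_axes ellipsoid semi-axes, mm.
#' @param length tube length, mm.
#' @param axis tube direction.
#' @return A `structure_template` list.
#' @export
structure_template <- function(name, role, shape, center_offset = c(0, 0, 0),
                               radius = NULL, semi_axes = NULL, length = NULL,
                               axis = c(0, 0, 1)) {
  if (!shape %in% c("sphere", "ellipsoid", "tube"))
    stop("invalid-argument: unknown template shape '", shape, "'", call. = FALSE)
  structure(list(name = name, role = role, shape = shape,
                 center_offset = center_offset, radius = radius,
                 semi_axes = semi_axes, length = length, axis = axis),
            class = "structure_template")
}

#' Specify a synthetic cohort
#'
#' @param n_subjects number of simulated subjects (>= 1).
#' @param grid the shared `voxel_grid`.
#' @param templates list of `structure_template`s.
#' @param perturbations named list mapping structure names to
#'   `perturbation_spec`s (names must match templates); structures without an
#'   entry are copied unperturbed into the AS set.
#' @param seed integer master seed; subject `i` draws from seed `seed + i`.
#' @param center_jitter_mm half-width of the uniform per-axis jitter applied
#'   to template centers per subject (mm).
#' @param size_jitter relative half-width of the uniform size jitter (e.g.
#'   0.05 scales sizes by U(0.95, 1.05)).
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, grid, templates, perturbations = list(),
                        seed = 1L, center_jitter_mm = 2, size_jitter = 0.05) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("invalid-argument: n_subjects must be >= 1", call. = FALSE)
  stopifnot(inherits(grid, "voxel_grid"))
  tnames <- vapply(templates, function(t) t$name, character(1))
  if (anyDuplicated(tnames))
    stop("invalid-argument: duplicate template names", call. = FALSE)
  bad <- setdiff(names(perturbations), tnames)
  if (length(bad) > 0)
    stop("invalid-argument: perturbation keys name no template: ",
         paste(bad, collapse = ", "), call. = FALSE)
  names(templates) <- tnames
  structure(list(n_subjects = as.integer(n_subjects), grid = grid,
                 templates = templates, perturbations = perturbations,
                 seed = as.integer(seed), center_jitter_mm = center_jitter_mm,
                 size_jitter = size_jitter),
            class = "cohort_spec")
}

rasterize_template <- function(grid, tpl, center, scale) {
  switch(tpl$shape,
    sphere = rasterize_sphere(grid, center, tpl$radius * scale, tpl$name,
                              tpl$role),
    ellipsoid = rasterize_ellipsoid(grid, center, tpl$semi_axes * scale,
                                    tpl$name, tpl$role),
    tube = rasterize_tube(grid, tpl$axis, center, tpl$radius * scale,
                          tpl$length * scale, tpl$name, tpl$role))
}

#' Simulate one subject's paired MS/AS structure sets
#'
#' The MS ("truth") set is built from the cohort templates with seeded
#' per-subject jitter of centers and sizes; the AS set applies each
#' structure's perturbation to its MS mask. Fully reproducible from
#' `(spec$seed, subject_index)`; the caller's RNG state is untouched.
#'
#' @param spec a `cohort_spec`.
#' @param subject_index subject number in `1:n_subjects`.
#' @return List with elements `MS` and `AS`, both `structure_set`s on the
#'   spec's grid.
#' @export
simulate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (subject_index < 1 || subject_index > spec$n_subjects)
    stop("invalid-argument: subject_index out of range", call. = FALSE)
  g <- spec$grid
  gcenter <- (grid_extent(g)["lo", ] + grid_extent(g)["hi", ]) / 2
  subj_seed <- spec$seed + as.integer(subject_index)
  ntpl <- length(spec$templates)
  jit <- with_seed(subj_seed, list(
    centers = matrix(stats::runif(3 * ntpl, -spec$center_jitter_mm,
                                  spec$center_jitter_mm), ncol = 3),
    scales = stats::runif(ntpl, 1 - spec$size_jitter, 1 + spec$size_jitter)))
  ms <- vector("list", ntpl)
  for (i in seq_len(ntpl)) {
    tpl <- spec$templates[[i]]
    ctr <- gcenter + tpl$center_offset + jit$centers[i, ]
    ms[[i]] <- tryCatch(
      rasterize_template(g, tpl, ctr, jit$scales[i]),
      error = function(e) stop(sprintf("structure '%s': %s", tpl$name,
                                       conditionMessage(e)), call. = FALSE))
  }
  names(ms) <- names(spec$templates)
  as <- lapply(ms, function(m) {
    p <- spec$perturbations[[m$name]]
    if (is.null(p)) return(m)
    # derive the noise seed from the subject so realizations differ per subject
    if (p$kind == "surface_noise")
      p$seed <- p$seed + 7919L * subj_seed
    tryCatch(perturb(m, p),
             error = function(e) stop(sprintf("structure '%s': %s", m$name,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  id <- sprintf("S%02d", subject_index)
  list(MS = structure_set(id, "MS", ms), AS = structure_set(id, "AS", as))
}

#' Simulate a full cohort of paired MS/AS structure sets
#'
#' @param spec a `cohort_spec`.
#' @return List of `spec$n_subjects` elements, each as returned by
#'   [simulate_subject()].
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_subjects), function(i) simulate_subject(spec, i))
}

#' Built-in phantom cohorts
#'
#' `prostate_cohort_spec()` lays out a prostate-like geometry (spherical CTV,
#' bladder, tubular rectum and femoral shafts) on a 96^3 grid at 2 mm spacing
#' with a default prescription-study perturbation pattern: CTV translation,
#' bladder dilation, rectum surface noise, and superior-inferior truncation of
#' the femurs. `hn_cohort_spec()` lays out a head-and-neck-like geometry with
#' three nested SIB targets and the constraint-table organs at risk, with
#' truncation of the elongated cord/esophagus and noise on the pharynx.
#'
#' @param n_subjects cohort size (default 5).
#' @param seed master seed.
#' @param perturbations overrides the default perturbation map; pass
#'   `list()` for a zero-discrepancy cohort (AS identical to MS).
#' @return A `cohort_spec`.
#' @export
prostate_cohort_spec <- function(n_subjects = 5, seed = 1L,
                                 perturbations = NULL) {
  grid <- make_grid(c(96, 96, 96), spacing = c(2, 2, 2))
  templates <- list(
    structure_template("CTV", "target", "sphere", c(0, 0, 0), radius = 25),
    structure_template("Bladder", "oar", "sphere", c(0, 60, 10), radius = 25),
    structure_template("Rectum", "oar", "tube", c(0, -42, 0), radius = 12,
                       length = 70),
    structure_template("Femur L", "oar", "tube", c(-65, 0, 0), radius = 14,
                       length = 80),
    structure_template("Femur R", "oar", "tube", c(65, 0, 0), radius = 14,
                       length = 80))
  if (is.null(perturbations))
    perturbations <- list(
      "CTV" = perturbation_spec("translate", 3, axis = c(1, 0, 0)),
      "Bladder" = perturbation_spec("dilate", 2),
      "Rectum" = perturbation_spec("surface_noise", 0.3, seed = 11L),
      "Femur L" = perturbation_spec("truncate_axial", 15),
      "Femur R" = perturbation_spec("truncate_axial", 15))
  cohort_spec(n_subjects, grid, templates, perturbations, seed = seed)
}

#' @rdname prostate_cohort_spec
#' @export
hn_cohort_spec <- function(n_subjects = 5, seed = 1L, perturbations = NULL) {
  grid <- make_grid(c(96, 96, 96), spacing = c(2, 2, 2))
  templates <- list(
    structure_template("PTV70", "target", "sphere", c(0, 0, 0), radius = 20),
    structure_template("PTV60", "target", "sphere", c(0, 0, 0), radius = 28),
    structure_template("PTV54", "target", "sphere", c(0, 0, 0), radius = 35),
    structure_template("Brain", "oar", "sphere", c(0, 0, 64), radius = 28),
    structure_template("Brainstem", "oar", "tube", c(0, -48, 30), radius = 8,
                       length = 30),
    structure_template("Chiasm", "oar", "sphere", c(0, -20, 55), radius = 4),
    structure_template("Cord", "oar", "tube", c(0, -55, 0), radius = 5,
                       length = 120),
    structure_template("Esophagus", "oar", "tube", c(10, -45, -30), radius = 6,
                       length = 90),
    structure_template("Larynx", "oar", "sphere", c(0, 48, -10), radius = 12),
    structure_template("Lips", "oar", "sphere", c(0, 60, 20), radius = 8),
    structure_template("Mandible", "oar", "tube", c(0, 50, 5), radius = 10,
                       length = 70, axis = c(1, 0, 0)),
    structure_template("optic nerve L", "oar", "tube", c(-18, -25, 55),
                       radius = 2.5, length = 25, axis = c(1, 0, 0)),
    structure_template("optic nerve R", "oar", "tube", c(18, -25, 55),
                       radius = 2.5, length = 25, axis = c(1, 0, 0)),
    structure_template("orbit L", "oar", "sphere", c(-28, -15, 58), radius = 11),
    structure_template("orbit R", "oar", "sphere", c(28, -15, 58), radius = 11),
    structure_template("parotid contralateral", "oar", "sphere",
                       c(-52, 10, 10), radius = 14),
    structure_template("Pharynx", "oar", "tube", c(0, 30, 0), radius = 7,
                       length = 80))
  if (is.null(perturbations))
    perturbations <- list(
      "Cord" = perturbation_spec("truncate_axial", 20),
      "Esophagus" = perturbation_spec("truncate_axial", 15),
      "Pharynx" = perturbation_spec("surface_noise", 0.3, seed = 13L),
      "Chiasm" = perturbation_spec("translate", 3, axis = c(0, 1, 0)),
      "optic nerve L" = perturbation_spec("translate", 2, axis = c(1, 0, 0)),
      "optic nerve R" = perturbation_spec("translate", 2, axis = c(-1, 0, 0)),
      "parotid contralateral" = perturbation_spec("dilate", 3))
  cohort_spec(n_subjects, grid, templates, perturbations, seed = seed,
              center_jitter_mm = 1.5, size_jitter = 0.04)
}
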