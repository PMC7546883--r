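# Volume IO: structure masks and dose grids as NIfTI volumes with physical
# spacing/origin in the header, plus a JSON manifest per structure set.

grid_affine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(grid$spacing)
  aff[1:3, 4] <- grid$origin
  aff
}

write_volume <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(grid_affine(grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4]
  # NIfTI xforms are RAS-signed; a negated axis keeps its spacing magnitude
  # and the translation still names the center of voxel (0,0,0)
  grid <- make_grid(dim(img), spacing, origin)
  list(data = array(as.numeric(img), dim = dim(img)), grid = grid)
}

sanitize_filename <- function(name) gsub("[^A-Za-z0-9_.-]", "_", name)

#' Write and read structure sets as NIfTI volumes
#'
#' Each mask is written as one NIfTI volume of 0/1 values with spacing and
#' origin in the header, alongside a `manifest.json` recording the subject,
#' source (MS/AS), structure names, roles and file names. `read_structure_set`
#' reconstructs the set from the manifest.
#'
#' @param set a `structure_set`.
#' @param dir output directory (created if needed).
#' @return `write_structure_set`: the manifest path, invisibly.
#'   `read_structure_set`: a `structure_set`.
#' @export
write_structure_set <- function(set, dir) {
  stopifnot(inherits(set, "structure_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(set$structures))
  for (i in seq_along(set$structures)) {
    m <- set$structures[[i]]
    files[i] <- paste0(sanitize_filename(m$name), ".nii.gz")
    write_volume(array(as.integer(m$voxels), dim = m$grid$shape), m$grid,
                 file.path(dir, files[i]))
  }
  manifest <- list(
    subject_id = set$subject_id, source = set$source,
    structures = data.frame(
      name = names(set$structures),
      role = vapply(set$structures, function(m) m$role, character(1)),
      file = files, stringsAsFactors = FALSE),
    grid = list(shape = set$grid$shape, spacing_mm = set$grid$spacing,
                origin_mm = set$grid$origin))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_structure_set
#' @param manifest path to a `manifest.json` (or its directory).
#' @export
read_structure_set <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  grid <- make_grid(mf$grid$shape, mf$grid$spacing_mm, mf$grid$origin_mm)
  masks <- lapply(seq_len(nrow(mf$structures)), function(i) {
    vol <- read_volume(file.path(dir, mf$structures$file[i]))
    if (!same_grid(vol$grid, grid))
      stop("incompatible-grids: volume header disagrees with manifest for '",
           mf$structures$name[i], "'", call. = FALSE)
    new_structure_mask(grid, array(vol$data != 0, dim = grid$shape),
                       mf$structures$name[i], mf$structures$role[i])
  })
  structure_set(mf$subject_id, mf$source, masks)
}

#' Write and read dose grids as NIfTI volumes
#'
#' Dose is stored in Gy with grid spacing/origin in the header. Reading
#' checks grid congruence against `reference_grid` when one is supplied and
#' refuses to resample on mismatch.
#'
#' @param dose a `dose_grid`.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param reference_grid optional `voxel_grid` the dose must match.
#' @return `write_dose`: `path`, invisibly. `read_dose`: a `dose_grid`.
#' @export
write_dose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  write_volume(dose$dose, dose$grid, path)
  invisible(path)
}

#' @rdname write_dose
#' @export
read_dose <- function(path, reference_grid = NULL) {
  vol <- read_volume(path)
  if (!is.null(reference_grid) && !same_grid(vol$grid, reference_grid))
    stop("incompatible-grids: dose grid does not match the reference grid; ",
         "no resampling is performed", call. = FALSE)
  new_dose_grid(vol$grid, vol$data)
}
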