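# Parametric dose surrogate: a closed-form, prescription-conformal dose field
# shaped by a structure set, standing in for inverse-optimized VMAT dose. The
# surrogate is deliberately not a delivery model; its one physical dial is the
# falloff half-distance, which controls the dose gradient outside the target.

#' Dose surrogate parameters
#'
#' Each prescribed target T contributes a field equal to its prescription
#' Rx_T inside T and Rx_T * 2^(-d/h) outside, where d is the exact Euclidean
#' distance (mm) from a voxel center to the nearest occupied voxel center of
#' T and h is the falloff half-distance (the dose halves every h mm). The raw
#' dose is the voxelwise maximum over target fields, so simultaneous
#' integrated boost (SIB) prescriptions compose naturally. Voxels inside a
#' spared OAR and outside every target are multiplied by (1 - w) for that
#' OAR's sparing weight w (a hard in-mask multiplier, no feathering); the
#' final dose is floored at `background_floor`.
#'
#' @param prescriptions named numeric vector: target structure name -> Rx in
#'   Gy (all > 0).
#' @param falloff_half_distance h in mm (> 0). Presets: 5 mm emulates a steep
#'   SBRT-like gradient, 10 mm a conventional one.
#' @param oar_sparing named numeric vector: OAR name -> sparing weight in
#'   \[0, 1).
#' @param background_floor minimum dose anywhere, Gy (>= 0).
#' @return An object of class `dose_params`.
#' @examples
#' dose_params(c(CTV = 40), falloff_half_distance = 5)
#' dose_params(c(PTV70 = 70, PTV60 = 60, PTV54 = 54), 10)
#' @export
dose_params <- function(prescriptions, falloff_half_distance = 5,
                        oar_sparing = numeric(0), background_floor = 0) {
  if (length(prescriptions) == 0L || is.null(names(prescriptions)) ||
      any(!nzchar(names(prescriptions))) || any(prescriptions <= 0))
    stop("invalid-argument: prescriptions must be a named vector of Rx > 0 Gy",
         call. = FALSE)
  if (falloff_half_distance <= 0)
    stop("invalid-argument: falloff_half_distance must be > 0 mm", call. = FALSE)
  if (length(oar_sparing) > 0 &&
      (is.null(names(oar_sparing)) || any(oar_sparing < 0) ||
       any(oar_sparing >= 1)))
    stop("invalid-argument: sparing weights must be named and in [0, 1)",
         call. = FALSE)
  if (background_floor < 0)
    stop("invalid-argument: background_floor must be >= 0 Gy", call. = FALSE)
  structure(list(prescriptions = prescriptions,
                 falloff_half_distance = falloff_half_distance,
                 oar_sparing = oar_sparing,
                 background_floor = background_floor),
            class = "dose_params")
}

new_dose_grid <- function(grid, dose, meta = list()) {
  structure(list(grid = grid, dose = dose, meta = meta), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels, dose range [%.2f, %.2f] Gy\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$dose), max(x$dose)))
  invisible(x)
}

#' Synthesize a dose distribution from a planning structure set
#'
#' Evaluates the parametric surrogate of [dose_params()] on the set's grid.
#' Deterministic; the dose depends only on which contours are in
#' `planning_set`, so plans built on different contour sets genuinely differ.
#'
#' @param planning_set a `structure_set` containing every structure named in
#'   `params` (targets non-empty).
#' @param params a `dose_params`.
#' @return A `dose_grid` (per-voxel dose in Gy).
#' @export
synthesize_dose <- function(planning_set, params) {
  stopifnot(inherits(planning_set, "structure_set"),
            inherits(params, "dose_params"))
  g <- planning_set$grid
  need <- c(names(params$prescriptions), names(params$oar_sparing))
  missing <- setdiff(need, names(planning_set$structures))
  if (length(missing) > 0)
    stop("invalid-argument: planning set lacks structures: ",
         paste(missing, collapse = ", "), call. = FALSE)
  h <- params$falloff_half_distance
  raw <- array(0, dim = g$shape)
  in_any_target <- array(FALSE, dim = g$shape)
  for (nm in names(params$prescriptions)) {
    tmask <- planning_set$structures[[nm]]
    if (!any(tmask$voxels))
      stop(sprintf("empty-structure: target '%s' has no voxels", nm),
           call. = FALSE)
    rx <- params$prescriptions[[nm]]
    d <- distance_to(g, tmask$voxels)  # 0 inside the target
    raw <- pmax(raw, rx * 2^(-d / h))
    in_any_target <- in_any_target | tmask$voxels
  }
  for (nm in names(params$oar_sparing)) {
    w <- params$oar_sparing[[nm]]
    sel <- planning_set$structures[[nm]]$voxels & !in_any_target
    raw[sel] <- raw[sel] * (1 - w)
  }
  dose <- pmax(raw, params$background_floor)
  new_dose_grid(g, dose, meta = list(params = params,
                                     source = planning_set$source))
}

#' Build the plan for one evaluation arm of a subject pair
#'
#' Assembles the planning structure set per the target policy, then calls
#' [synthesize_dose()]. With `target_policy = "same_source"` both targets and
#' OARs come from `mode_source` (the prostate-style arrangement); with
#' `"always_MS_target"` targets always come from the MS set and only the OARs
#' from `mode_source` (the head-and-neck-style arrangement, where clinical
#' target contours are kept). The policy and source are recorded in the dose
#' grid's `meta`.
#'
#' @param subject_pair list with `MS` and `AS` `structure_set`s (as from
#'   [simulate_subject()]).
#' @param mode_source `"AS"` or `"MS"`: which contour set drives the plan.
#' @param params a `dose_params`.
#' @param target_policy `"same_source"` or `"always_MS_target"`.
#' @return A `dose_grid`.
#' @export
plan_for <- function(subject_pair, mode_source, params,
                     target_policy = c("same_source", "always_MS_target")) {
  target_policy <- match.arg(target_policy)
  if (!mode_source %in% c("AS", "MS"))
    stop("invalid-argument: mode_source must be 'AS' or 'MS'", call. = FALSE)
  src <- subject_pair[[mode_source]]
  need <- c(names(params$prescriptions), names(params$oar_sparing))
  structures <- lapply(need, function(nm) {
    from <- if (target_policy == "always_MS_target" &&
                nm %in% names(params$prescriptions)) subject_pair$MS else src
    m <- from$structures[[nm]]
    if (is.null(m))
      stop(sprintf("invalid-argument: structure '%s' missing from %s set",
                   nm, from$source), call. = FALSE)
    m
  })
  pset <- structure_set(src$subject_id, mode_source, structures)
  dg <- synthesize_dose(pset, params)
  dg$meta$target_policy <- target_policy
  dg$meta$mode_source <- mode_source
  dg
}
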