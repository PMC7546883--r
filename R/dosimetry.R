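# Cumulative DVHs, dosimetric endpoints (VxGy / Max / Mean) and clinical
# constraint evaluation.

in_mask_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"))
  check_mask(mask)
  if (!same_grid(dose$grid, mask$grid))
    stop("incompatible-grids: dose and mask live on different grids",
         call. = FALSE)
  if (!any(mask$voxels))
    stop(sprintf("empty-structure: mask '%s' has no occupied voxels",
                 mask$name), call. = FALSE)
  dose$dose[mask$voxels]
}

#' Cumulative dose-volume histogram
#'
#' Bin edges run 0, w, 2w, ... up to the first edge strictly above the
#' in-mask maximum dose; the value at edge e is the percentage of the
#' structure's occupied voxels receiving at least e Gy (closed superlevel
#' convention, uniform voxel volume). The curve therefore starts at 100%, is
#' non-increasing, and ends at 0%.
#'
#' @param dose a `dose_grid`.
#' @param mask a non-empty `structure_mask` on the same grid.
#' @param bin_width bin width w in Gy (default 0.1).
#' @param mode optional label for the evaluation mode (kept in the object).
#' @return An object of class `dvh` with fields `edges` (Gy) and
#'   `volume_pct`; `as.data.frame()` and `plot()` methods are provided.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.1, mode = NA_character_) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("invalid-argument: bin_width must be > 0 Gy", call. = FALSE)
  dv <- in_mask_dose(dose, mask)
  dmax <- max(dv)
  k <- floor(dmax / bin_width) + 1L
  edges <- (0:k) * bin_width
  # exact survival counts with the closed (dose >= edge) convention, so the
  # curve agrees with the bin-free volume_at_dose at every edge
  iv <- findInterval(dv, edges)
  n_lt <- c(0, cumsum(tabulate(iv, nbins = length(edges))))[seq_along(edges)]
  vol <- 100 * (length(dv) - n_lt) / length(dv)
  structure(list(edges = edges, volume_pct = vol, structure = mask$name,
                 mode = mode, bin_width = bin_width),
            class = "dvh")
}

#' @export
as.data.frame.dvh <- function(x, ...) {
  data.frame(dose_gy = x$edges, volume_pct = x$volume_pct,
             structure = x$structure, mode = x$mode,
             stringsAsFactors = FALSE)
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> '%s'%s: %d edges at %g Gy, D0 = %.1f%%, max edge %.1f Gy\n",
              x$structure, if (is.na(x$mode)) "" else paste0(" [", x$mode, "]"),
              length(x$edges), x$bin_width, x$volume_pct[1], max(x$edges)))
  invisible(x)
}

#' @export
plot.dvh <- function(x, ..., col = "steelblue", lwd = 2) {
  plot(x$edges, x$volume_pct, type = "s", col = col, lwd = lwd,
       xlab = "Dose (Gy)", ylab = "Volume (%)",
       main = paste("Cumulative DVH:", x$structure), ylim = c(0, 100), ...)
  invisible(x)
}

#' Mean dose implied by a cumulative DVH
#'
#' Trapezoid integral of the cumulative curve divided by 100; agrees with the
#' direct voxel mean to within one bin width.
#'
#' @param x a `dvh`.
#' @return Mean dose in Gy.
#' @export
dvh_mean <- function(x) {
  stopifnot(inherits(x, "dvh"))
  v <- x$volume_pct / 100
  sum(diff(x$edges) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Dosimetric endpoints over a structure
#'
#' `volume_at_dose` is the percentage of occupied voxels receiving at least
#' `d` Gy (the VxGy endpoint), computed directly from voxels (bin-free) so
#' constraint evaluation never depends on DVH binning. `dose_max` and
#' `dose_mean` are the hottest-voxel dose and the arithmetic mean dose.
#'
#' @param dose a `dose_grid`.
#' @param mask a non-empty `structure_mask` on the same grid.
#' @param d dose threshold in Gy.
#' @return Percent volume (`volume_at_dose`) or Gy (`dose_max`, `dose_mean`).
#' @export
volume_at_dose <- function(dose, mask, d) {
  dv <- in_mask_dose(dose, mask)
  # integer superlevel count over voxel count: exact, so pass/fail decisions
  # never hinge on accumulation order
  100 * sum(dv >= d) / length(dv)
}

#' @rdname volume_at_dose
#' @export
dose_max <- function(dose, mask) max(in_mask_dose(dose, mask))

#' @rdname volume_at_dose
#' @export
dose_mean <- function(dose, mask) mean(in_mask_dose(dose, mask))

#' Parse a clinical dose-constraint string
#'
#' Accepts the usual constraint grammar: `V<d>Gy <rel> <p>%` for volume
#' constraints, and `Max <rel> <d>Gy` / `Mean <rel> <d>Gy` for point and mean
#' dose limits, with `rel` one of `<`, `<=`, `>=` (Unicode `≤`/`≥`
#' typography is accepted and normalized; strictness is preserved as parsed).
#' Spacing is tolerated anywhere, e.g. `"Mean <40 Gy"`.
#'
#' @param text constraint string.
#' @param structure optional structure name to attach.
#' @return An object of class `dose_constraint` with fields `metric`
#'   (`"V_at_dose"`, `"max"` or `"mean"`), `dose_gy` (volume constraints
#'   only), `limit` (% or Gy), `relation`, `structure` and `source_text`.
#' @examples
#' parse_constraint("V40Gy ≥ 95%")
#' parse_constraint("Max <52Gy")
#' @export
parse_constraint <- function(text, structure = NA_character_) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("parse error: constraint text must be a single non-empty string",
         call. = FALSE)
  norm <- gsub("≤", "<=", gsub("≥", ">=", text))
  norm <- gsub("\\s+", "", norm)
  m <- regmatches(norm, regexec("^[Vv]([0-9.]+)Gy(<=|>=|<)([0-9.]+)%$", norm))[[1]]
  if (length(m) == 4L) {
    con <- list(structure = structure, metric = "V_at_dose",
                dose_gy = as.numeric(m[2]), limit = as.numeric(m[4]),
                relation = m[3], source_text = text)
  } else {
    m <- regmatches(norm, regexec("^(Max|Mean|max|mean)(<=|>=|<)([0-9.]+)Gy$",
                                  norm))[[1]]
    if (length(m) != 4L)
      stop("parse error: cannot parse constraint '", text, "'", call. = FALSE)
    con <- list(structure = structure, metric = tolower(m[2]), dose_gy = NA_real_,
                limit = as.numeric(m[4]), relation = m[3], source_text = text)
  }
  if (is.na(con$limit) || con$limit <= 0)
    stop("parse error: constraint limit must be > 0 in '", text, "'",
         call. = FALSE)
  structure(con, class = "dose_constraint")
}

#' @export
format.dose_constraint <- function(x, ...) {
  rel <- c("<" = "<", "<=" = "≤", ">=" = "≥")[[x$relation]]
  if (x$metric == "V_at_dose")
    sprintf("V%gGy %s %g%%", x$dose_gy, rel, x$limit)
  else
    sprintf("%s %s %gGy", if (x$metric == "max") "Max" else "Mean", rel,
            x$limit)
}

#' @export
print.dose_constraint <- function(x, ...) {
  cat(sprintf("<dose_constraint>%s %s\n",
              if (is.na(x$structure)) "" else paste0(" ", x$structure, ":"),
              format(x)))
  invisible(x)
}

relation_holds <- function(achieved, relation, limit) {
  switch(relation,
         "<" = achieved < limit,
         "<=" = achieved <= limit,
         ">=" = achieved >= limit,
         stop("invalid-argument: unknown relation '", relation, "'",
              call. = FALSE))
}

#' Evaluate a constraint against a dose distribution
#'
#' Computes the achieved endpoint value (percent volume for VxGy, Gy for
#' Max/Mean) by the matching bin-free endpoint operation and tests it against
#' the limit; a strict `<` is evaluated strictly. The signed `margin` is
#' positive when the constraint is met (limit - achieved for upper limits,
#' achieved - limit for coverage).
#'
#' @param con a `dose_constraint`.
#' @param dose a `dose_grid`.
#' @param mask the `structure_mask` to evaluate on (the caller chooses the
#'   contour source, so cross-evaluations are possible).
#' @return A one-row data.frame: `structure`, `constraint`, `metric`,
#'   `achieved`, `limit`, `passed`, `margin`.
#' @export
evaluate_constraint <- function(con, dose, mask) {
  stopifnot(inherits(con, "dose_constraint"))
  achieved <- switch(con$metric,
                     V_at_dose = volume_at_dose(dose, mask, con$dose_gy),
                     max = dose_max(dose, mask),
                     mean = dose_mean(dose, mask))
  passed <- relation_holds(achieved, con$relation, con$limit)
  margin <- if (con$relation == ">=") achieved - con$limit else
    con$limit - achieved
  data.frame(structure = if (is.na(con$structure)) mask$name else con$structure,
             constraint = con$source_text,
             metric = con$metric,
             achieved = achieved,
             limit = con$limit,
             passed = passed,
             margin = margin,
             stringsAsFactors = FALSE)
}

#' Clinical constraint tables
#'
#' `read_constraint_table()` reads a two-column CSV (`structure`,
#' `constraint_text`) into a list of parsed `dose_constraint`s.
#' `constraint_table()` loads one of the tables shipped with the package:
#' `"prostate"` (9 rows, a 40 Gy SBRT-style prescription) or `"hn"` (16 rows,
#' a 70/60/54 Gy SIB head-and-neck prescription).
#'
#' @param path CSV file path.
#' @param site `"prostate"` or `"hn"`.
#' @return List of `dose_constraint` objects.
#' @export
read_constraint_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("structure", "constraint_text") %in% names(df)))
    stop("invalid-argument: constraint CSV needs columns 'structure', ",
         "'constraint_text'", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    parse_constraint(df$constraint_text[i], structure = df$structure[i]))
}

#' @rdname read_constraint_table
#' @export
constraint_table <- function(site = c("prostate", "hn")) {
  site <- match.arg(site)
  path <- system.file("extdata", paste0("constraints_", site, ".csv"),
                      package = "contourdose", mustWork = TRUE)
  read_constraint_table(path)
}
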