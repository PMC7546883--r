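# Three-mode plan/contour cross-evaluation and study orchestration.
#
# The three evaluation modes follow the three-DVH design: PlanAEvalA (plan
# optimized on AS contours, evaluated on AS contours), PlanMEvalM (the
# clinical reference: MS plan on MS contours) and PlanAEvalM (the controlled
# observation: AS plan evaluated on the MS contours). The fourth combination
# (MS plan on AS contours) is intentionally never produced.

EVAL_MODES <- c("PlanAEvalA", "PlanMEvalM", "PlanAEvalM")

#' Cross-evaluate one subject pair under a constraint list
#'
#' Builds the AS-driven and MS-driven plans with [plan_for()], then evaluates
#' every constraint in the three modes: plan A on AS contours, plan M on MS
#' contours, and plan A on MS contours. One record per (constraint, mode).
#'
#' @param subject_pair list with `MS` and `AS` `structure_set`s.
#' @param constraints list of `dose_constraint`s (with `structure` set).
#' @param params a `dose_params`.
#' @param target_policy passed to [plan_for()].
#' @return A data.frame with columns `subject_id`, `structure`, `constraint`,
#'   `mode`, `achieved`, `passed`.
#' @export
cross_evaluate <- function(subject_pair, constraints, params,
                           target_policy = c("same_source", "always_MS_target")) {
  target_policy <- match.arg(target_policy)
  need <- unique(vapply(constraints, function(con) con$structure, character(1)))
  for (src in c("MS", "AS")) {
    missing <- setdiff(need, names(subject_pair[[src]]$structures))
    if (length(missing) > 0)
      stop(sprintf("invalid-argument: %s set of subject '%s' lacks: %s", src,
                   subject_pair[[src]]$subject_id,
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  plan_A <- plan_for(subject_pair, "AS", params, target_policy)
  plan_M <- plan_for(subject_pair, "MS", params, target_policy)
  arms <- list(PlanAEvalA = list(plan = plan_A, eval_set = subject_pair$AS),
               PlanMEvalM = list(plan = plan_M, eval_set = subject_pair$MS),
               PlanAEvalM = list(plan = plan_A, eval_set = subject_pair$MS))
  out <- vector("list", length(constraints) * 3L)
  i <- 0L
  for (con in constraints)
    for (mode in EVAL_MODES) {
      arm <- arms[[mode]]
      mask <- arm$eval_set$structures[[con$structure]]
      r <- tryCatch(evaluate_constraint(con, arm$plan, mask),
                    error = function(e)
                      stop(sprintf("subject '%s', structure '%s': %s",
                                   subject_pair$MS$subject_id, con$structure,
                                   conditionMessage(e)), call. = FALSE))
      i <- i + 1L
      out[[i]] <- data.frame(subject_id = subject_pair$MS$subject_id,
                             structure = con$structure,
                             constraint = con$source_text,
                             mode = mode,
                             achieved = r$achieved,
                             passed = r$passed,
                             stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}

#' Paired t-test on aligned per-subject endpoints
#'
#' Classical paired t-test: with differences d_i = x_i - y_i, the statistic
#' is t = mean(d) / (sd(d) / sqrt(n)) with sample SD (n - 1 denominator) and
#' a two-sided p-value from the Student t distribution with n - 1 degrees of
#' freedom. Zero-variance differences are flagged degenerate rather than
#' producing a spurious statistic: p = 1 when the mean difference is also 0,
#' p = 0 otherwise.
#'
#' @param values_x,values_y equal-length numeric vectors (n >= 2), aligned by
#'   subject.
#' @param alpha two-sided significance level (default 0.05).
#' @return An object of class `paired_t` with fields `n`, `mean_diff`,
#'   `sd_diff`, `t_statistic`, `df`, `p_value`, `significant`, `degenerate`.
#' @examples
#' paired_t(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))  # d = 1..5, t ~ 4.243
#' @export
paired_t <- function(values_x, values_y, alpha = 0.05) {
  if (length(values_x) != length(values_y))
    stop("invalid-argument: paired vectors must have equal length",
         call. = FALSE)
  n <- length(values_x)
  if (n < 2L)
    stop("invalid-argument: paired t-test needs n >= 2", call. = FALSE)
  d <- values_x - values_y
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    res <- list(n = n, mean_diff = md, sd_diff = 0, t_statistic = NA_real_,
                df = n - 1L, p_value = if (md == 0) 1 else 0,
                significant = if (md == 0) FALSE else TRUE, degenerate = TRUE)
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
    res <- list(n = n, mean_diff = md, sd_diff = sdd, t_statistic = t_stat,
                df = n - 1L, p_value = p, significant = p < alpha,
                degenerate = FALSE)
  }
  structure(res, class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("<paired_t> n = %d, mean diff = %g, zero-variance differences (degenerate), p = %g\n",
                x$n, x$mean_diff, x$p_value))
  else
    cat(sprintf("<paired_t> n = %d, mean diff = %.4g (SD %.4g), t(%d) = %.4f, p = %.4g%s\n",
                x$n, x$mean_diff, x$sd_diff, x$df, x$t_statistic, x$p_value,
                if (x$significant) " *" else ""))
  invisible(x)
}

record_key <- function(records)
  paste(records$structure, records$constraint, sep = " | ")

check_complete_records <- function(records) {
  subjects <- sort(unique(records$subject_id))
  cellkey <- paste(record_key(records), records$mode, records$subject_id,
                   sep = " | ")
  if (anyDuplicated(cellkey))
    stop("invalid-argument: duplicate cross-evaluation record(s): ",
         paste(utils::head(cellkey[duplicated(cellkey)], 3), collapse = "; "),
         call. = FALSE)
  cons <- unique(record_key(records))
  expected <- length(subjects) * length(cons) * length(EVAL_MODES)
  if (nrow(records) != expected) {
    want <- as.vector(outer(as.vector(outer(cons, EVAL_MODES, paste,
                                            sep = " | ")),
                            subjects, paste, sep = " | "))
    stop("invalid-argument: incomplete record set; missing cells: ",
         paste(utils::head(setdiff(want, cellkey), 5), collapse = "; "),
         call. = FALSE)
  }
  invisible(records)
}

#' Count constraint exceedances per (constraint, mode)
#'
#' Number of subjects whose achieved value violates the constraint, for every
#' constraint and evaluation mode; zero rows are included. The record set
#' must be complete (every subject x constraint x mode exactly once).
#'
#' @param records stacked output of [cross_evaluate()] over a cohort.
#' @return A data.frame with columns `structure`, `constraint`, `mode`,
#'   `n_subjects`, `n_exceed`.
#' @export
count_exceedances <- function(records) {
  check_complete_records(records)
  key <- paste(record_key(records), records$mode, sep = " | ")
  out <- do.call(rbind, lapply(split(records, key), function(d)
    data.frame(structure = d$structure[1], constraint = d$constraint[1],
               mode = d$mode[1], n_subjects = nrow(d),
               n_exceed = sum(!d$passed), stringsAsFactors = FALSE)))
  out <- out[order(out$structure, out$constraint,
                   match(out$mode, EVAL_MODES)), ]
  rownames(out) <- NULL
  out
}

#' Mean and SD of achieved values per (constraint, mode)
#'
#' The achieved-value summary that mirrors a clinical plan-evaluation table:
#' per constraint and evaluation mode, the mean and sample SD of the achieved
#' endpoint over subjects (SD is `NA` for a single subject).
#'
#' @param records stacked output of [cross_evaluate()] over a cohort.
#' @return A data.frame with columns `structure`, `constraint`, `mode`, `n`,
#'   `mean`, `sd`.
#' @export
summarize_modes <- function(records) {
  if (nrow(records) == 0L)
    stop("invalid-argument: no records to summarize", call. = FALSE)
  key <- paste(record_key(records), records$mode, sep = " | ")
  out <- do.call(rbind, lapply(split(records, key), function(d)
    data.frame(structure = d$structure[1], constraint = d$constraint[1],
               mode = d$mode[1], n = nrow(d), mean = mean(d$achieved),
               sd = if (nrow(d) > 1) stats::sd(d$achieved) else NA_real_,
               stringsAsFactors = FALSE)))
  out <- out[order(out$structure, out$constraint,
                   match(out$mode, EVAL_MODES)), ]
  rownames(out) <- NULL
  out
}

#' Paired t-tests per constraint between evaluation modes
#'
#' For every constraint, compares the per-subject achieved values of two mode
#' pairs: the AS arm against the clinical reference (PlanAEvalA vs
#' PlanMEvalM) and against the controlled observation (PlanAEvalA vs
#' PlanAEvalM). No multiple-testing correction is applied by default,
#' matching routine per-endpoint plan comparison practice; pass
#' `correct = "holm"` to adjust.
#'
#' @param records stacked output of [cross_evaluate()] over a cohort.
#' @param alpha two-sided significance level.
#' @param correct `"none"` (default) or `"holm"`.
#' @return A data.frame with one row per (constraint, mode pair).
#' @export
paired_tests <- function(records, alpha = 0.05, correct = c("none", "holm")) {
  correct <- match.arg(correct)
  check_complete_records(records)
  pairs <- list(c("PlanAEvalA", "PlanMEvalM"), c("PlanAEvalA", "PlanAEvalM"))
  out <- list()
  for (k in split(records, record_key(records))) {
    k <- k[order(k$subject_id), ]
    for (pr in pairs) {
      x <- k$achieved[k$mode == pr[1]]
      y <- k$achieved[k$mode == pr[2]]
      tt <- paired_t(x, y, alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(
        structure = k$structure[1], constraint = k$constraint[1],
        mode_pair = paste(pr, collapse = " vs "), n = tt$n,
        mean_diff = tt$mean_diff, sd_diff = tt$sd_diff,
        t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value,
        significant = tt$significant, degenerate = tt$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (correct == "holm") {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
    out$significant <- out$p_value < alpha & !out$degenerate
  }
  out <- out[order(out$structure, out$constraint, out$mode_pair), ]
  rownames(out) <- NULL
  out
}

#' Geometric-versus-dosimetric discordance sweep
#'
#' Simulates, for each cell of a (distance-to-target x perturbation
#' magnitude) sweep at a fixed dose falloff, cohorts in which a spherical OAR
#' sits at a given surface-to-surface distance from a spherical target and
#' its AS contour is rigidly shifted by the given magnitude. Each subject is
#' cross-evaluated on the OAR mean dose and compared geometrically, yielding
#' joined records of (DSC, HD) and dosimetric deltas. Because the geometric
#' error is identical across distances while the local dose level decays
#' exponentially, the sweep exhibits the discordance between geometric and
#' dosimetric agreement: equal-DSC cells can differ many-fold in dose impact.
#'
#' @param distances_mm surface-to-surface distances from target to OAR.
#' @param magnitudes_mm rigid shift magnitudes applied to the AS OAR.
#' @param falloff_mm dose falloff half-distance h (5 mm = steep).
#' @param n_per_cell subjects per sweep cell.
#' @param seed master seed.
#' @param grid the voxel grid (default 96^3 at 2 mm).
#' @param target_radius,oar_radius sphere radii, mm.
#' @param oar_sparing sparing weight applied to the OAR in planning.
#' @return A data.frame with one row per (cell, subject): `distance_mm`,
#'   `magnitude_mm`, `subject`, `dsc`, `hd_mm`, `mean_dose_aa`,
#'   `mean_dose_mm`, `mean_dose_am`, `delta_aa_am`, `delta_aa_mm` (Gy).
#' @export
discrepancy_experiment <- function(distances_mm = c(10, 25, 40),
                                   magnitudes_mm = c(2, 4, 6),
                                   falloff_mm = 5, n_per_cell = 5, seed = 1L,
                                   grid = make_grid(c(96, 96, 96), c(2, 2, 2)),
                                   target_radius = 15, oar_radius = 10,
                                   oar_sparing = 0.15) {
  if (length(distances_mm) == 0L || length(magnitudes_mm) == 0L ||
      any(distances_mm < 0) || any(magnitudes_mm < 0) || n_per_cell < 1)
    stop("invalid-argument: invalid sweep configuration", call. = FALSE)
  params <- dose_params(c(Target = 40),
                        falloff_half_distance = falloff_mm,
                        oar_sparing = c(OAR = oar_sparing))
  con <- parse_constraint("Mean <1000Gy", structure = "OAR")
  cells <- expand.grid(distance_mm = distances_mm,
                       magnitude_mm = magnitudes_mm)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    d <- cells$distance_mm[ci]
    m <- cells$magnitude_mm[ci]
    templates <- list(
      structure_template("Target", "target", "sphere", c(-35, 0, 0),
                         radius = target_radius),
      structure_template("OAR", "oar", "sphere",
                         c(-35 + target_radius + d + oar_radius, 0, 0),
                         radius = oar_radius))
    perts <- if (m > 0)
      list(OAR = perturbation_spec("translate", m, axis = c(1, 0, 0)))
    else list()
    spec <- cohort_spec(n_per_cell, grid, templates, perts,
                        seed = seed + 1000L * ci, center_jitter_mm = 1,
                        size_jitter = 0.03)
    rows <- vector("list", n_per_cell)
    for (si in seq_len(n_per_cell)) {
      pair <- simulate_subject(spec, si)
      geom <- compare_structures(pair$MS, pair$AS)
      geom <- geom[geom$structure == "OAR", ]
      rec <- cross_evaluate(pair, list(con), params, "same_source")
      ach <- stats::setNames(rec$achieved, rec$mode)
      rows[[si]] <- data.frame(
        distance_mm = d, magnitude_mm = m, subject = si,
        dsc = geom$dsc, hd_mm = geom$hd_mm,
        mean_dose_aa = ach[["PlanAEvalA"]],
        mean_dose_mm = ach[["PlanMEvalM"]],
        mean_dose_am = ach[["PlanAEvalM"]],
        delta_aa_am = ach[["PlanAEvalA"]] - ach[["PlanAEvalM"]],
        delta_aa_mm = ach[["PlanAEvalA"]] - ach[["PlanMEvalM"]],
        stringsAsFactors = FALSE)
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Configure and run a full contour-evaluation study
#'
#' `study_config()` assembles a self-contained configuration: a phantom
#' cohort, a constraint table, dose-surrogate parameters and the target
#' policy. The built-in sites are `"prostate"` (single 40 Gy target, target
#' and OARs both taken from the planning contour source) and `"hn"` (SIB
#' 70/60/54 Gy, targets always from MS contours). `run_study()` executes the
#' whole workflow — simulate, geometric comparison, three-mode
#' cross-evaluation, mode summaries, exceedance counts and paired t-tests —
#' and optionally writes the result tables as CSV plus a JSON run manifest.
#'
#' @param site `"prostate"` or `"hn"`.
#' @param n_subjects cohort size.
#' @param seed master seed (drives all randomness in the study).
#' @param cohort optional `cohort_spec` overriding the site default.
#' @param constraints optional list of `dose_constraint`s overriding the
#'   shipped table.
#' @param params optional `dose_params` overriding the site default.
#' @param target_policy optional policy overriding the site default.
#' @param bin_width DVH bin width, Gy.
#' @return `study_config()`: a `study_config` list. `run_study()`: a
#'   `contour_study` object bundling `geometry` (per-subject and summary),
#'   `records`, `mode_summary`, `exceedances`, `tests` and the config.
#' @export
study_config <- function(site = c("prostate", "hn"), n_subjects = 5,
                         seed = 1L, cohort = NULL, constraints = NULL,
                         params = NULL, target_policy = NULL,
                         bin_width = 0.1) {
  site <- match.arg(site)
  if (is.null(cohort))
    cohort <- switch(site,
                     prostate = prostate_cohort_spec(n_subjects, seed),
                     hn = hn_cohort_spec(n_subjects, seed))
  if (is.null(constraints)) constraints <- constraint_table(site)
  if (is.null(params))
    params <- switch(site,
      prostate = dose_params(c(CTV = 40), falloff_half_distance = 5,
                             oar_sparing = c(Bladder = 0.2, Rectum = 0.3)),
      hn = dose_params(c(PTV70 = 70, PTV60 = 60, PTV54 = 54),
                       falloff_half_distance = 10,
                       oar_sparing = c(Cord = 0.2, Brainstem = 0.2,
                                       "parotid contralateral" = 0.3)))
  if (is.null(target_policy))
    target_policy <- switch(site, prostate = "same_source",
                            hn = "always_MS_target")
  structure(list(site = site, cohort = cohort, constraints = constraints,
                 params = params, target_policy = target_policy,
                 bin_width = bin_width, seed = as.integer(seed)),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param out_dir optional directory for CSV/JSON outputs
#'   (`geometry_metrics.csv`, `geometry_summary.csv`, `mode_summary.csv`,
#'   `exceedance_counts.csv`, `paired_tests.csv`, `run_manifest.json`).
#' @export
run_study <- function(config, out_dir = NULL) {
  if (!inherits(config, "study_config"))
    stop("invalid-argument: 'config' must come from study_config()",
         call. = FALSE)
  if (length(config$constraints) == 0L)
    stop("invalid-argument: study has no constraints", call. = FALSE)
  cohort <- simulate_cohort(config$cohort)
  geom <- geometry_summary(cohort)
  records <- do.call(rbind, lapply(cohort, function(pair)
    cross_evaluate(pair, config$constraints, config$params,
                   config$target_policy)))
  res <- structure(list(config = config,
                        geometry = geom,
                        records = records,
                        mode_summary = summarize_modes(records),
                        exceedances = count_exceedances(records),
                        tests = paired_tests(records)),
                   class = "contour_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, file)
      utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
    wr(geom$per_subject, "geometry_metrics.csv")
    wr(geom$summary, "geometry_summary.csv")
    wr(res$mode_summary, "mode_summary.csv")
    wr(res$exceedances, "exceedance_counts.csv")
    wr(res$tests, "paired_tests.csv")
    manifest <- list(
      package = "contourdose",
      version = as.character(utils::packageVersion("contourdose")),
      site = config$site, seed = config$seed,
      n_subjects = config$cohort$n_subjects,
      grid_shape = config$cohort$grid$shape,
      grid_spacing_mm = config$cohort$grid$spacing,
      target_policy = config$target_policy,
      falloff_half_distance_mm = config$params$falloff_half_distance,
      prescriptions_gy = as.list(config$params$prescriptions),
      oar_sparing = as.list(config$params$oar_sparing),
      constraints = vapply(config$constraints, function(con)
        paste(con$structure, con$source_text, sep = ": "), character(1)))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.contour_study <- function(x, ...) {
  cat(sprintf("<contour_study> site '%s', %d subjects, %d constraints, seed %d\n",
              x$config$site, x$config$cohort$n_subjects,
              length(x$config$constraints), x$config$seed))
  cat(sprintf("  structures: %s\n",
              paste(x$geometry$summary$structure, collapse = ", ")))
  cat(sprintf("  exceedances: %d of %d evaluations; significant paired tests: %d of %d\n",
              sum(x$exceedances$n_exceed),
              sum(x$exceedances$n_subjects),
              sum(x$tests$significant), nrow(x$tests)))
  invisible(x)
}

#' @export
summary.contour_study <- function(object, ...) {
  cat("Geometric agreement (per structure):\n")
  print(object$geometry$summary, digits = 3)
  cat("\nAchieved endpoint values (mean over subjects, by mode):\n")
  print(object$mode_summary, digits = 3)
  cat("\nExceedance counts:\n")
  print(object$exceedances)
  cat("\nPaired t-tests:\n")
  print(object$tests, digits = 3)
  invisible(object)
}
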