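#' Cohort CSV input and output
#'
#' The tabular interchange format is one CSV row per child with a sidecar
#' JSON file (same path with extension `.units.json`) declaring the unit
#' system of the glucose and HbA1c columns. On ingest, values are
#' converted to the package's internal units (glucose mg/dl, HbA1c %).
#' Malformed rows (non-positive glucose, negative titre, negative
#' follow-up time) are collected into an error report attached as the
#' `"row_errors"` attribute, not silently dropped.
#'
#' @param path CSV path.
#' @param cohort Cohort data.frame.
#' @param units Named list: `glucose` (`"mgdl"` or `"mmoll"`), `hba1c`
#'   (`"pct"` or `"mmolmol"`).
#' @param visits Optional long-format visit data.frame written to a
#'   companion `*_visits.csv`.
#' @return `read_cohort()` returns the cohort data.frame (internal
#'   units); `write_cohort()` returns the path invisibly.
#' @name cohort_io
NULL

.REQUIRED_COLS <- c("child_id", "hba1c_pct",
                    paste0("glucose_", c(0, 30, 60, 90, 120)),
                    "ia2a_titre")

.units_path <- function(path) sub("\\.csv$", "", path) |> paste0(".units.json")

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path,
                         units = list(glucose = "mgdl", hba1c = "pct"),
                         visits = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE)
  jsonlite::write_json(units, .units_path(path), auto_unbox = TRUE)
  if (!is.null(visits)) {
    utils::write.csv(visits, sub("\\.csv$", "_visits.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.REQUIRED_COLS, names(cohort))
  if (length(missing_cols)) {
    stop("cohort schema error; missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  upath <- .units_path(path)
  units <- if (file.exists(upath)) {
    jsonlite::read_json(upath, simplifyVector = TRUE)
  } else list(glucose = "mgdl", hba1c = "pct")
  gcols <- paste0("glucose_", c(0, 30, 60, 90, 120))
  if (identical(units$glucose, "mmoll")) {
    cohort[gcols] <- lapply(cohort[gcols], glucose_mmoll_to_mgdl)
  }
  if (identical(units$hba1c, "mmolmol")) {
    cohort$hba1c_pct <- hba1c_mmolmol_to_pct(cohort$hba1c_pct)
  }
  errs <- list()
  note <- function(rows, msg) {
    if (length(rows)) errs[[length(errs) + 1]] <<-
        data.frame(row = rows, problem = msg)
  }
  staged <- which(!is.na(cohort$hba1c_pct))
  gl <- as.matrix(cohort[staged, gcols])
  note(staged[rowSums(gl <= 0, na.rm = TRUE) > 0], "non-positive glucose")
  note(which(!is.na(cohort$ia2a_titre) & cohort$ia2a_titre < 0),
       "negative IA-2A titre")
  if ("event_time_years" %in% names(cohort)) {
    note(which(!is.na(cohort$event_time_years) & cohort$event_time_years < 0),
         "negative follow-up time")
  }
  attr(cohort, "row_errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(0), problem = character(0))
  cohort
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the whole analysis end to end on a synthetic cohort: simulate
#' the screened population, stage the multiple-autoantibody children,
#' score the stage 1 children and substage them, estimate progression
#' risk by stratum, evaluate the score against the 2-year outcome, and
#' compute the screening/recruitment cost plan implied by the simulated
#' frequencies. Returns all results plus a participant-flow summary whose
#' counts are internally consistent (staged = stage 1 + stage 2 +
#' stage 3) and a reproducibility manifest.
#'
#' @param config A [cohort_config()].
#' @param horizon Risk horizon in years (must be positive).
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV/JSON files.
#' @return A list of class `"pipeline_result"`.
#' @export
run_pipeline <- function(config = cohort_config(), horizon = 2,
                         out_dir = NULL) {
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("horizon must be a positive number of years", call. = FALSE)
  }
  pop <- simulate_screened_population(config)
  staged <- pop[pop$multi_aab, , drop = FALSE]
  staged <- simulate_progression(staged, config)
  visits <- simulate_followup_visits(staged, config)

  flow <- list(
    screened = nrow(pop),
    multi_aab = nrow(staged),
    stage1 = sum(staged$stage_at_staging == 1L),
    stage2 = sum(staged$stage_at_staging == 2L),
    stage3_at_screen = sum(staged$stage_at_staging == 3L)
  )

  s1 <- staged[staged$stage_at_staging == 1L, , drop = FALSE]
  s1$cph_score <- cph_score(s1$hba1c_pct, s1$glucose_90, s1$ia2a_cat)
  s1$lr_score <- lr_score(s1$hba1c_pct, s1$glucose_90, s1$ia2a_titre)
  sub <- assign_substage(s1$cph_score, mode = "fixed_threshold", form = "cph")
  s1$substage <- as.character(sub$substage)

  strata <- list()
  for (st in c(1L, 2L)) {
    idx <- staged$stage_at_staging == st
    if (sum(idx) > 0 && any(staged$event[idx])) {
      cur <- km_fit(staged$event_time_years[idx], staged$event[idx])
      strata[[paste0("stage", st)]] <- risk_at(cur, horizon)
    }
  }

  eval_cohort <- restrict_to_outcome(s1, horizon)
  diagnostics <- NULL; deciles <- NULL
  if (nrow(eval_cohort) > 0 && any(eval_cohort$outcome_2y)) {
    diagnostics <- threshold_diagnostics(eval_cohort$cph_score,
                                         eval_cohort$outcome_2y,
                                         score_coefficients()$cph_threshold)
    deciles <- decile_curve(s1$cph_score, s1$event_time_years, s1$event,
                            horizon)
  }

  elig_freq <- (sum(s1$substage == "1b") + flow$stage2) / max(flow$screened, 1)
  plan <- if (elig_freq > 0) {
    trial_plan(n_enrol = sample_size(power_spec()),
               eligible_frequency = elig_freq,
               stage3_rate = flow$stage3_at_screen / max(flow$screened, 1))
  } else NULL

  result <- structure(list(
    flow = flow, staged = staged, stage1_scored = s1, visits = visits,
    strata_risk = strata, diagnostics = diagnostics, deciles = deciles,
    trial_plan = plan,
    manifest = list(seed = config$seed, horizon = horizon,
                    timestamp = NA, package_version =
                      as.character(utils::packageVersion("t1dstage")))
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(staged, file.path(out_dir, "staged_cohort.csv"),
                 visits = visits)
    utils::write.csv(s1, file.path(out_dir, "stage1_scored.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(flow = flow, strata_risk = strata, manifest = result$manifest),
      file.path(out_dir, "pipeline_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  result
}
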