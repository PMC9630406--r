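#' Glycaemic thresholds for metabolic staging
#'
#' Threshold set used by [classify_stage()]. All glucose bounds are in
#' mg/dl and HbA1c bounds in mmol/mol; comparisons are performed on those
#' scales after unit conversion, with a small numeric tolerance so that
#' values sitting exactly on a printed bound are classified consistently
#' regardless of the unit system they arrived in.
#'
#' Dysglycaemia (stage 2) under the 2015 consensus criteria requires, in a
#' child with confirmed multiple islet autoantibodies, fasting plasma
#' glucose 110-125 mg/dl, or 2 h glucose 140-199 mg/dl, or glucose >= 200
#' mg/dl at 30, 60 or 90 min. The revised ADA criteria lower the fasting
#' band to 100-125 mg/dl and add HbA1c 39-47 mmol/mol (5.7-6.4%) or a
#' >= 10% relative rise in HbA1c. Stage 3 uses the ADA diabetes criteria
#' (fasting >= 126, 2 h >= 200, HbA1c > 48 mmol/mol, or symptoms with
#' random glucose > 200).
#'
#' @param criteria_set `"consensus2015"` or `"ada_revised"`.
#' @return A list of named numeric bounds, class `"glucose_thresholds"`.
#' @export
glucose_thresholds <- function(criteria_set = c("consensus2015", "ada_revised")) {
  criteria_set <- match.arg(criteria_set)
  th <- list(
    criteria_set = criteria_set,
    fasting_dysglycaemia = if (criteria_set == "consensus2015") c(110, 125) else c(100, 125),
    two_hour_impaired = c(140, 199),
    intermediate_diabetic = 200,   # >= at 30/60/90 min
    fasting_diabetic = 126,        # >=
    two_hour_diabetic = 200,       # >=
    random_diabetic = 200,         # >  (with symptoms)
    hba1c_diabetic_mmolmol = 48,   # >
    hba1c_dysglycaemia_mmolmol = c(39, 47),  # revised ADA only
    hba1c_rise_fraction = 0.10,    # revised ADA only, relative to earliest
    tol = 1e-9
  )
  class(th) <- "glucose_thresholds"
  th
}

#' Classify a staged child as stage 1, 2 or 3 presymptomatic type 1 diabetes
#'
#' Applies the staging rules to one child with confirmed multiple islet
#' autoantibodies. Stage 3 (clinical diabetes) takes precedence: fasting
#' glucose >= 126 mg/dl, 2 h glucose >= 200 mg/dl, HbA1c > 48 mmol/mol
#' (each requiring confirmation by repeat testing unless `confirmed`), or
#' classic symptoms with a random glucose > 200 mg/dl. Otherwise stage 2
#' if any dysglycaemia rule of the active criteria set fires, else
#' stage 1.
#'
#' @param ogtt_glucose_mgdl Named or positional numeric vector of length 5:
#'   plasma glucose at 0, 30, 60, 90, 120 min, mg/dl.
#' @param hba1c_pct HbA1c in %. Required for the stage 3 HbA1c rule and for
#'   the revised ADA criteria.
#' @param criteria_set `"consensus2015"` (default) or `"ada_revised"`.
#' @param confirmed Logical; has a confirmatory repeat test been performed
#'   for any glycaemic stage 3 criterion that fires?
#' @param symptoms Logical; classic symptoms of hyperglycaemia present?
#' @param random_glucose_mgdl Optional random plasma glucose, mg/dl.
#' @param earliest_hba1c_pct Optional earliest available HbA1c (%), used by
#'   the revised ADA >= 10% relative-rise rule.
#' @return A list of class `"staging_result"` with elements `stage`
#'   (integer 1, 2 or 3), `criteria_met` (character vector of rule names),
#'   `requires_confirmation` (logical) and `criteria_set`.
#' @examples
#' classify_stage(c(120, 150, 170, 160, 150), hba1c_pct = 5.4)$stage # 2
#' @export
classify_stage <- function(ogtt_glucose_mgdl,
                           hba1c_pct = NA_real_,
                           criteria_set = c("consensus2015", "ada_revised"),
                           confirmed = FALSE,
                           symptoms = FALSE,
                           random_glucose_mgdl = NA_real_,
                           earliest_hba1c_pct = NA_real_) {
  criteria_set <- match.arg(criteria_set)
  th <- glucose_thresholds(criteria_set)
  eps <- th$tol

  if (length(ogtt_glucose_mgdl) != 5 || anyNA(ogtt_glucose_mgdl)) {
    stop("missing measurement: ogtt_glucose_mgdl must supply all five ",
         "time points (0, 30, 60, 90, 120 min)", call. = FALSE)
  }
  if (any(ogtt_glucose_mgdl <= 0)) {
    stop("glucose values must be positive", call. = FALSE)
  }
  g <- as.numeric(ogtt_glucose_mgdl)
  g0 <- g[1]; g2h <- g[5]; g_mid <- g[2:4]

  need_hba1c <- criteria_set == "ada_revised"
  hba1c_mmolmol <- NA_real_
  if (!is.na(hba1c_pct)) hba1c_mmolmol <- hba1c_pct_to_mmolmol(hba1c_pct)
  if (need_hba1c && is.na(hba1c_pct)) {
    stop("missing measurement: hba1c_pct is required for the ada_revised ",
         "criteria", call. = FALSE)
  }

  ge <- function(x, bound) x >= bound - eps
  gt <- function(x, bound) x > bound + eps
  in_band <- function(x, band) x >= band[1] - eps & x <= band[2] + eps

  # --- stage 3 ----------------------------------------------------------
  crit3 <- character(0)
  if (ge(g0, th$fasting_diabetic)) crit3 <- c(crit3, "fasting_glucose_ge_126")
  if (ge(g2h, th$two_hour_diabetic)) crit3 <- c(crit3, "two_hour_glucose_ge_200")
  if (!is.na(hba1c_mmolmol) && gt(hba1c_mmolmol, th$hba1c_diabetic_mmolmol)) {
    crit3 <- c(crit3, "hba1c_gt_48_mmolmol")
  }
  symptomatic <- isTRUE(symptoms) && !is.na(random_glucose_mgdl) &&
    gt(random_glucose_mgdl, th$random_diabetic)
  if (symptomatic) crit3 <- c(crit3, "symptoms_random_glucose_gt_200")
  if (length(crit3) > 0) {
    # the glycaemic criteria (not the symptomatic one) require repeat testing
    needs_conf <- !isTRUE(confirmed) && !symptomatic
    return(structure(
      list(stage = 3L, criteria_met = crit3,
           requires_confirmation = needs_conf, criteria_set = criteria_set),
      class = "staging_result"))
  }

  # --- stage 2 ----------------------------------------------------------
  crit2 <- character(0)
  if (in_band(g0, th$fasting_dysglycaemia)) {
    crit2 <- c(crit2, "impaired_fasting_glucose")
  }
  if (in_band(g2h, th$two_hour_impaired)) {
    crit2 <- c(crit2, "impaired_two_hour_glucose")
  }
  if (any(ge(g_mid, th$intermediate_diabetic))) {
    crit2 <- c(crit2, "intermediate_glucose_ge_200")
  }
  if (criteria_set == "ada_revised") {
    if (in_band(hba1c_mmolmol, th$hba1c_dysglycaemia_mmolmol)) {
      crit2 <- c(crit2, "hba1c_39_47_mmolmol")
    }
    if (!is.na(earliest_hba1c_pct) && earliest_hba1c_pct > 0 &&
        (hba1c_pct - earliest_hba1c_pct) / earliest_hba1c_pct >=
          th$hba1c_rise_fraction - eps) {
      crit2 <- c(crit2, "hba1c_rise_ge_10pct")
    }
  }
  if (length(crit2) > 0) {
    return(structure(
      list(stage = 2L, criteria_met = crit2, requires_confirmation = FALSE,
           criteria_set = criteria_set),
      class = "staging_result"))
  }

  structure(
    list(stage = 1L, criteria_met = character(0),
         requires_confirmation = FALSE, criteria_set = criteria_set),
    class = "staging_result")
}

#' Stage every child in a cohort data frame
#'
#' Vectorised wrapper over [classify_stage()].
#'
#' @param cohort Data frame with columns `glucose_0`, `glucose_30`,
#'   `glucose_60`, `glucose_90`, `glucose_120` (mg/dl) and `hba1c_pct`.
#' @inheritParams classify_stage
#' @return Integer vector of stages, one per row.
#' @export
stage_cohort <- function(cohort, criteria_set = "consensus2015",
                         confirmed = TRUE) {
  cols <- paste0("glucose_", c(0, 30, 60, 90, 120))
  missing_cols <- setdiff(c(cols, "hba1c_pct"), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  vapply(seq_len(nrow(cohort)), function(i) {
    classify_stage(as.numeric(cohort[i, cols]),
                   hba1c_pct = cohort$hba1c_pct[i],
                   criteria_set = criteria_set,
                   confirmed = confirmed)$stage
  }, integer(1))
}

#' Weight status from the BMI standard-deviation score
#'
#' WHO convention: overweight is a standardised BMI of 1-2 SD (both ends
#' inclusive), obesity is above 2 SD.
#'
#' @param bmi_sds Numeric vector of BMI SD scores.
#' @return Character vector: `"normal"`, `"overweight"` or `"obese"`.
#' @export
classify_weight_status <- function(bmi_sds) {
  if (any(!is.finite(bmi_sds))) stop("bmi_sds must be finite", call. = FALSE)
  out <- rep("normal", length(bmi_sds))
  out[bmi_sds >= 1 & bmi_sds <= 2] <- "overweight"
  out[bmi_sds > 2] <- "obese"
  out
}
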