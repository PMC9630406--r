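#' Published coefficients of the progression likelihood score
#'
#' The score exists in two forms. The Cox proportional-hazards (CPH) form
#' is the exponentiated centered linear predictor
#' \deqn{\exp[(HbA1c - 5.233) \times 1.125 + (OGTT90 - 107.6) \times 0.0195
#'       + (IA2Acat - 1.27) \times 0.662]}
#' with HbA1c in %, the 90 min OGTT glucose in mg/dl and IA-2A as an
#' ordinal titre category 0-3. The logistic-regression (LR) form is the
#' linear combination \eqn{2.048 \times HbA1c + 0.034 \times OGTT90 +
#' 0.006 \times IA2A} with IA-2A as the raw titre in arbitrary units.
#' Children above the cohort's 90th score centile (fixed thresholds: CPH
#' > 4.0, LR > 17.1) are substaged 1b; the 30th centile further splits
#' stage 1a.
#'
#' @return A list of class `"score_coefficients"`.
#' @export
score_coefficients <- function() {
  structure(list(
    cph = list(
      center = c(hba1c = 5.233, ogtt90 = 107.6, ia2a_cat = 1.27),
      weight = c(hba1c = 1.125, ogtt90 = 0.0195, ia2a_cat = 0.662)
    ),
    lr = list(
      weight = c(hba1c = 2.048, ogtt90 = 0.034, ia2a_titre = 0.006)
    ),
    cph_threshold = 4.0,
    lr_threshold = 17.1,
    centile_bounds = c(lower = 30, upper = 90)
  ), class = "score_coefficients")
}

#' IA-2A titre category
#'
#' Maps an IA-2A titre in arbitrary units (AU) onto the ordinal category
#' used by the CPH score: 0 for negative (titre below the 3 AU positivity
#' bound), then tertiles of positive titres at 3-100 AU (1), 100-290 AU
#' (2) and above 290 AU (3). The printed tertile ranges overlap at 100 AU;
#' here 100 AU falls in category 2 and 290 AU in category 2 (the upper
#' bound is strict, ">290").
#'
#' @param titre Numeric vector of titres, AU; must be non-negative.
#' @param bounds Numeric: positivity bound and two tertile cuts.
#' @return Integer vector of categories in 0:3.
#' @export
ia2a_category <- function(titre, bounds = c(positivity = 3, t1 = 100, t2 = 290)) {
  if (any(!is.na(titre) & titre < 0)) {
    stop("IA-2A titre must be non-negative", call. = FALSE)
  }
  cat <- ifelse(titre < bounds[1], 0L,
         ifelse(titre < bounds[2], 1L,
         ifelse(titre <= bounds[3], 2L, 3L)))
  as.integer(cat)
}

.check_score_inputs <- function(hba1c, ogtt90, third, third_name) {
  bad <- is.na(hba1c) | is.na(ogtt90) | is.na(third)
  if (any(bad)) {
    stop("missing data for scoring (", sum(bad), " record(s) lack HbA1c, ",
         "OGTT90 or ", third_name, "); no imputation is performed",
         call. = FALSE)
  }
}

#' Progression likelihood score, CPH form
#'
#' @param hba1c HbA1c in %.
#' @param ogtt90 90 min OGTT plasma glucose in mg/dl.
#' @param ia2a_cat IA-2A ordinal category (see [ia2a_category()]).
#' @param coeffs A [score_coefficients()] object.
#' @return Positive numeric score; the log of the score is exactly the
#'   centered linear predictor.
#' @examples
#' cph_score(5.233, 107.6, 1.27) # exactly 1
#' @export
cph_score <- function(hba1c, ogtt90, ia2a_cat, coeffs = score_coefficients()) {
  .check_score_inputs(hba1c, ogtt90, ia2a_cat, "IA-2A category")
  ctr <- coeffs$cph$center; w <- coeffs$cph$weight
  lp <- (hba1c - ctr["hba1c"]) * w["hba1c"] +
        (ogtt90 - ctr["ogtt90"]) * w["ogtt90"] +
        (ia2a_cat - ctr["ia2a_cat"]) * w["ia2a_cat"]
  unname(exp(lp))
}

#' Progression likelihood score, LR form
#'
#' @inheritParams cph_score
#' @param ia2a_titre IA-2A titre in arbitrary units (raw, not category).
#' @return Numeric score.
#' @export
lr_score <- function(hba1c, ogtt90, ia2a_titre, coeffs = score_coefficients()) {
  .check_score_inputs(hba1c, ogtt90, ia2a_titre, "IA-2A titre")
  w <- coeffs$lr$weight
  unname(w["hba1c"] * hba1c + w["ogtt90"] * ogtt90 + w["ia2a_titre"] * ia2a_titre)
}

#' Substage stage 1 children from their progression likelihood scores
#'
#' Splits a stage 1 cohort into `1a_low` (below the 30th centile),
#' `1a_mid` (30th to 90th centile inclusive) and `1b` (above the 90th
#' centile). In `"fixed_threshold"` mode the published thresholds stand in
#' for the 90th centile (CPH > 4.0 or LR > 17.1, strict); there is no
#' fixed 30th-centile threshold, so the 30th-centile split still comes
#' from the supplied score distribution. In `"cohort_centile"` mode both
#' cuts are the empirical 30th/90th centiles (type 7 quantiles, linear
#' interpolation of order statistics); scores exactly equal to a centile
#' bound fall in `1a_mid` (ties are kept below the strict ">" cut).
#'
#' @param scores Numeric vector of scores for stage 1 children.
#' @param mode `"fixed_threshold"` or `"cohort_centile"`.
#' @param form `"cph"` or `"lr"`; selects the fixed threshold.
#' @param coeffs A [score_coefficients()] object.
#' @return A data.frame with columns `score` and `substage` (factor with
#'   levels `1a_low`, `1a_mid`, `1b`).
#' @export
assign_substage <- function(scores,
                            mode = c("fixed_threshold", "cohort_centile"),
                            form = c("cph", "lr"),
                            coeffs = score_coefficients()) {
  mode <- match.arg(mode)
  form <- match.arg(form)
  if (length(scores) == 0) {
    stop("cannot assign substages to an empty score collection", call. = FALSE)
  }
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  q30 <- stats::quantile(scores, coeffs$centile_bounds["lower"] / 100,
                         names = FALSE, type = 7)
  if (mode == "fixed_threshold") {
    hi <- if (form == "cph") coeffs$cph_threshold else coeffs$lr_threshold
  } else {
    hi <- stats::quantile(scores, coeffs$centile_bounds["upper"] / 100,
                          names = FALSE, type = 7)
  }
  substage <- ifelse(scores > hi, "1b",
              ifelse(scores < q30, "1a_low", "1a_mid"))
  data.frame(score = scores,
             substage = factor(substage, levels = c("1a_low", "1a_mid", "1b")))
}

#' First follow-up visit at which the CPH score crosses the 1b threshold
#'
#' Scans a child's follow-up visits in time order, recomputing the CPH
#' form of the progression likelihood score at each visit, and returns the
#' earliest time at which it exceeds the stage 1b threshold (first-crossing
#' semantics: later visits falling back below the threshold are ignored).
#'
#' @param visits Data frame with columns `time_years`, `hba1c_pct`,
#'   `glucose_90` (mg/dl) and `ia2a_titre` (AU), including the baseline
#'   visit at time 0 if it should be eligible.
#' @param coeffs A [score_coefficients()] object.
#' @return The crossing time in years, or `NA_real_` if the score never
#'   exceeds the threshold.
#' @export
longitudinal_rescore <- function(visits, coeffs = score_coefficients()) {
  if (is.null(visits) || nrow(visits) == 0) return(NA_real_)
  o <- order(visits$time_years)
  v <- visits[o, , drop = FALSE]
  s <- cph_score(v$hba1c_pct, v$glucose_90, ia2a_category(v$ia2a_titre),
                 coeffs = coeffs)
  idx <- which(s > coeffs$cph_threshold)
  if (length(idx) == 0) return(NA_real_)
  v$time_years[idx[1]]
}
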