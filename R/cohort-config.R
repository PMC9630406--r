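#' Configuration for the synthetic screening cohort generator
#'
#' Bundles every parameter of the generator with defaults that emulate the
#' statistical structure of a childhood public-health islet-autoantibody
#' screening programme: roughly 0.29% of screened children confirmed
#' positive for two or more islet autoantibodies, a 293/30/41 split (out
#' of 364 staged) between stage 1, stage 2 and undiagnosed stage 3 at
#' initial staging, correlated metabolic covariates, and
#' proportional-hazards progression to clinical diabetes whose true
#' log-hazard is the published score linear predictor with weights
#' (1.125 per % HbA1c, 0.0195 per mg/dl OGTT90, 0.662 per IA-2A
#' category).
#'
#' Covariates (HbA1c %, OGTT glucose at 0/30/60/90/120 min mg/dl, log
#' IA-2A titre, BMI SDS) are drawn from a multivariate normal with
#' stage-specific mean shifts, then constrained by rejection sampling so
#' that each child's OGTT/HbA1c pattern is consistent with the stage label
#' it was assigned (a stage 1 child is normoglycaemic under the active
#' criteria, and so on). Event times are exponential given the linear
#' predictor; censoring is the minimum of an independent exponential
#' dropout time and the administrative follow-up horizon.
#'
#' @param n_screened Number of children screened.
#' @param prevalence_multi_aab Probability a screened child has confirmed
#'   multiple islet autoantibodies (default 0.0029).
#' @param stage_split Probabilities of stage 1 / stage 2 / stage 3 at the
#'   initial staging among staged children (defaults 293/364, 30/364,
#'   41/364).
#' @param covariate_means Named list with elements `stage1`, `stage2`,
#'   `stage3`: mean vectors for (hba1c, glucose_0, glucose_30, glucose_60,
#'   glucose_90, glucose_120, log_titre, bmi_sds).
#' @param covariate_sds Standard deviations, same 8 components.
#' @param covariate_corr 8 x 8 correlation matrix (symmetric PSD).
#' @param frac_iaa,frac_gada,frac_ia2a,frac_znt8a Marginal positivity
#'   probabilities of the four autoantibodies among multi-autoantibody
#'   children (conditioned on at least two positives).
#' @param hla_dr3dr4_freq Frequency of the HLA DR3/DR4-DQ8 genotype.
#' @param true_log_hazard_coeffs Generator-truth log-hazard weights for
#'   (HbA1c %, OGTT90 mg/dl, IA-2A category).
#' @param baseline_hazard_rate Events/year at the centering covariate
#'   values (HbA1c 5.233%, OGTT90 107.6 mg/dl, IA-2A category 1.27).
#' @param followup_years_max Administrative censoring horizon, years.
#' @param visit_interval_months Range of follow-up visit spacing, months.
#' @param dropout_hazard Independent exponential dropout rate, per year.
#' @param visit_drift Named per-year drifts of HbA1c (%) and OGTT90
#'   (mg/dl) in children on a progression trajectory.
#' @param visit_noise Named visit-to-visit measurement SDs for HbA1c (%),
#'   OGTT90 (mg/dl) and log titre.
#' @param seed Master seed; each sub-generator uses a documented offset of
#'   it so that the population, progression and visit draws are
#'   independently reproducible.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_screened = 154462,
                          prevalence_multi_aab = 0.0029,
                          stage_split = c(stage1 = 293, stage2 = 30, stage3 = 41) / 364,
                          covariate_means = NULL,
                          covariate_sds = NULL,
                          covariate_corr = NULL,
                          frac_iaa = 0.50,
                          frac_gada = 0.80,
                          frac_ia2a = 0.64,
                          frac_znt8a = 0.50,
                          hla_dr3dr4_freq = 0.25,
                          true_log_hazard_coeffs = c(hba1c = 1.125,
                                                     ogtt90 = 0.0195,
                                                     ia2a_cat = 0.662),
                          baseline_hazard_rate = 0.032,
                          followup_years_max = 6,
                          visit_interval_months = c(2, 6),
                          dropout_hazard = 0.25,
                          visit_drift = c(hba1c = 0.30, ogtt90 = 15),
                          visit_noise = c(hba1c = 0.15, ogtt90 = 8, log_titre = 0.2),
                          seed = 20150201L) {
  covnames <- c("hba1c", "glucose_0", "glucose_30", "glucose_60",
                "glucose_90", "glucose_120", "log_titre", "bmi_sds")
  if (is.null(covariate_means)) {
    covariate_means <- list(
      stage1 = c(5.20,  88, 138, 125, 106, 104, log(90), 0.2),
      stage2 = c(6.00, 105, 178, 178, 175, 160, log(280), 0.3),
      stage3 = c(7.00, 135, 230, 250, 245, 235, log(160), 0.1)
    )
    covariate_means <- lapply(covariate_means, stats::setNames, covnames)
  }
  if (is.null(covariate_sds)) {
    covariate_sds <- stats::setNames(c(0.30, 7, 22, 22, 18, 16, 1.6, 1.0),
                                     covnames)
  }
  if (is.null(covariate_corr)) {
    R <- diag(8)
    gl <- 2:6
    R[gl, gl] <- 0.45; diag(R)[] <- 1
    R[1, gl] <- R[gl, 1] <- 0.25   # HbA1c correlates with glucose
    dimnames(R) <- list(covnames, covnames)
    covariate_corr <- R
  }

  cfg <- list(
    n_screened = n_screened,
    prevalence_multi_aab = prevalence_multi_aab,
    stage_split = stage_split,
    covariate_means = covariate_means,
    covariate_sds = covariate_sds,
    covariate_corr = covariate_corr,
    frac_iaa = frac_iaa, frac_gada = frac_gada,
    frac_ia2a = frac_ia2a, frac_znt8a = frac_znt8a,
    hla_dr3dr4_freq = hla_dr3dr4_freq,
    true_log_hazard_coeffs = true_log_hazard_coeffs,
    baseline_hazard_rate = baseline_hazard_rate,
    followup_years_max = followup_years_max,
    visit_interval_months = visit_interval_months,
    dropout_hazard = dropout_hazard,
    visit_drift = visit_drift,
    visit_noise = visit_noise,
    seed = as.integer(seed),
    covnames = covnames
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$prevalence_multi_aab, cfg$stage_split,
             cfg$frac_iaa, cfg$frac_gada, cfg$frac_ia2a, cfg$frac_znt8a,
             cfg$hla_dr3dr4_freq)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: all probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(cfg$stage_split) - 1) > 1e-8) {
    stop("configuration error: stage_split must sum to 1", call. = FALSE)
  }
  if (cfg$n_screened < 0) {
    stop("configuration error: n_screened must be non-negative", call. = FALSE)
  }
  R <- cfg$covariate_corr
  if (!isSymmetric(unname(R))) {
    stop("configuration error: covariance must be symmetric", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("configuration error: covariance must be positive semi-definite",
         call. = FALSE)
  }
  if (cfg$baseline_hazard_rate < 0 || cfg$dropout_hazard < 0) {
    stop("configuration error: hazard rates must be non-negative",
         call. = FALSE)
  }
  invisible(cfg)
}
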