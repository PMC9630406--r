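#' Specification of the score-(re)building procedure
#'
#' Mirrors the published model-building workflow: every candidate
#' predictor is screened in a univariable Cox model; predictors with
#' two-sided p below `alpha_enter` enter a multivariable Cox model that is
#' reduced by backward elimination (largest p first, refit after each
#' removal) until all remaining predictors have p below `alpha_retain`.
#' Independently, a penalised logistic regression and a random forest are
#' fitted to the binary 2-year-progression outcome and their shared most
#' important variables refitted in an unpenalised logistic model.
#'
#' @param candidate_variables Character vector of cohort column names.
#' @param alpha_enter,alpha_retain Two-sided significance levels.
#' @param cv_folds Cross-validation folds for the penalised model.
#' @param outcome_horizon Years defining the binary progression outcome.
#' @param seed Seed for fold assignment and the forest.
#' @return A list of class `"fit_spec"`.
#' @export
fit_spec <- function(candidate_variables = c("hba1c_pct", "glucose_0",
                                             "glucose_30", "glucose_60",
                                             "glucose_90", "glucose_120",
                                             "bmi_sds", "hla_dr3dr4",
                                             "ia2a_cat", "aab_3or4",
                                             "grs", "age_years"),
                     alpha_enter = 0.05, alpha_retain = 0.05,
                     cv_folds = 10, outcome_horizon = 2,
                     seed = 1L) {
  stopifnot(cv_folds >= 2, alpha_enter > 0, alpha_enter < 1,
            alpha_retain > 0, alpha_retain < 1)
  structure(list(candidate_variables = candidate_variables,
                 alpha_enter = alpha_enter, alpha_retain = alpha_retain,
                 cv_folds = cv_folds, outcome_horizon = outcome_horizon,
                 seed = as.integer(seed)),
            class = "fit_spec")
}

# add derived candidate columns (3-or-4 autoantibody positivity) if absent
.prepare_candidates <- function(cohort) {
  if (!"aab_3or4" %in% names(cohort) &&
      all(c("iaa_pos", "gada_pos", "ia2a_pos", "znt8a_pos") %in% names(cohort))) {
    cohort$aab_3or4 <- (cohort$iaa_pos + cohort$gada_pos + cohort$ia2a_pos +
                          cohort$znt8a_pos) >= 3
  }
  cohort
}

#' Univariable Cox screen of candidate predictors
#'
#' One proportional-hazards fit (Efron ties) per candidate variable;
#' constant variables are skipped with a recorded reason.
#'
#' @param cohort Staged cohort with `event_time_years` and `event`.
#' @param spec A [fit_spec()].
#' @return A data.frame with one row per candidate: `variable`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `entered`, `skipped`, `reason`.
#' @export
univariable_screen <- function(cohort, spec = fit_spec()) {
  cohort <- .prepare_candidates(cohort)
  keep <- !is.na(cohort$event_time_years) & !is.na(cohort$event)
  cohort <- cohort[keep, , drop = FALSE]
  if (sum(cohort$event) == 0) {
    stop("no events in cohort; cannot fit survival models", call. = FALSE)
  }
  rows <- lapply(spec$candidate_variables, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) {
      return(data.frame(variable = v, hr = NA, ci_low = NA, ci_high = NA,
                        p = NA, entered = FALSE, skipped = TRUE,
                        reason = "column absent"))
    }
    x <- as.numeric(x)
    if (length(unique(x[!is.na(x)])) < 2) {
      return(data.frame(variable = v, hr = NA, ci_low = NA, ci_high = NA,
                        p = NA, entered = FALSE, skipped = TRUE,
                        reason = "constant variable"))
    }
    fit <- survival::coxph(
      survival::Surv(cohort$event_time_years, as.integer(cohort$event)) ~ x,
      ties = "efron")
    s <- summary(fit)
    p <- s$coefficients[1, "Pr(>|z|)"]
    data.frame(variable = v, hr = unname(s$conf.int[1, "exp(coef)"]),
               ci_low = unname(s$conf.int[1, "lower .95"]),
               ci_high = unname(s$conf.int[1, "upper .95"]),
               p = p, entered = p < spec$alpha_enter, skipped = FALSE,
               reason = "")
  })
  do.call(rbind, rows)
}

#' Multivariable Cox model with backward elimination
#'
#' Fits all entered variables jointly (Efron ties) and removes, one at a
#' time, the variable with the largest p at or above `alpha_retain`,
#' refitting after each removal. Ties in p are broken by the pre-declared
#' candidate order. The final coefficients, together with the cohort means
#' of the retained variables, form a candidate set of score coefficients.
#'
#' @param cohort Staged cohort with follow-up columns.
#' @param entered_variables Character vector (typically the `entered`
#'   rows of [univariable_screen()]).
#' @param spec A [fit_spec()].
#' @return A list of class `"cox_fit_result"`: `selected` (variables
#'   retained), `coefficients`, `hr_table` (HR, CI, p per retained
#'   variable), `centering` (cohort means), `fit` (the final `coxph`
#'   object), `eliminated` (removal order).
#' @export
multivariable_select <- function(cohort, entered_variables, spec = fit_spec()) {
  cohort <- .prepare_candidates(cohort)
  keep <- !is.na(cohort$event_time_years) & !is.na(cohort$event)
  cohort <- cohort[keep, , drop = FALSE]
  if (length(entered_variables) < 1) {
    stop("at least one entered variable is required", call. = FALSE)
  }
  vars <- entered_variables
  eliminated <- character(0)
  repeat {
    dat <- cohort[, vars, drop = FALSE]
    dat[] <- lapply(dat, as.numeric)
    dat$..time <- cohort$event_time_years
    dat$..event <- as.integer(cohort$event)
    fml <- stats::as.formula(paste(
      "survival::Surv(..time, ..event) ~",
      paste(sprintf("`%s`", vars), collapse = " + ")))
    fit <- survival::coxph(fml, data = dat, ties = "efron")
    if (any(is.na(stats::coef(fit)))) {
      dropped <- vars[which(is.na(stats::coef(fit)))[1]]
      warning("collinear variable dropped: ", dropped, call. = FALSE)
      eliminated <- c(eliminated, dropped)
      vars <- setdiff(vars, dropped)
      next
    }
    pv <- summary(fit)$coefficients[, "Pr(>|z|)"]
    if (length(vars) == 1 || max(pv) < spec$alpha_retain) break
    worst <- which(pv == max(pv))[1]   # candidate order breaks exact ties
    eliminated <- c(eliminated, vars[worst])
    vars <- vars[-worst]
  }
  s <- summary(fit)
  structure(list(
    selected = vars,
    coefficients = stats::setNames(as.numeric(stats::coef(fit)), vars),
    hr_table = data.frame(variable = vars,
                          hr = unname(s$conf.int[, "exp(coef)"]),
                          ci_low = unname(s$conf.int[, "lower .95"]),
                          ci_high = unname(s$conf.int[, "upper .95"]),
                          p = unname(s$coefficients[, "Pr(>|z|)"])),
    centering = vapply(vars, function(v) mean(as.numeric(cohort[[v]]),
                                              na.rm = TRUE), numeric(1)),
    eliminated = eliminated,
    fit = fit
  ), class = "cox_fit_result")
}

#' Restrict a cohort to children with a defined 2-year outcome
#'
#' A child contributes to the binary outcome analysis iff followed for at
#' least `horizon` years or progressing within `horizon` years.
#'
#' @param cohort Cohort with `event_time_years` and `event`.
#' @param horizon Outcome horizon in years (default 2).
#' @return The restricted cohort with a logical `outcome_2y` column.
#' @export
restrict_to_outcome <- function(cohort, horizon = 2) {
  ok <- !is.na(cohort$event_time_years) &
    (cohort$event_time_years >= horizon |
       (cohort$event & cohort$event_time_years < horizon))
  out <- cohort[ok, , drop = FALSE]
  out$outcome_2y <- out$event & out$event_time_years < horizon
  # a child whose event falls exactly on the horizon has, by the rule
  # above, completed the horizon event-free
  out$outcome_2y[out$event_time_years >= horizon] <- FALSE
  out
}

#' Penalised logistic regression and random-forest importance
#'
#' On the outcome-restricted cohort, fits (i) an elastic-net logistic
#' regression whose penalty is chosen by `cv_folds`-fold cross-validation
#' and (ii) a 500-tree random forest (permutation importance, which is
#' unbiased with respect to predictor cardinality). The top-k
#' variables of each ranking are intersected, with k equal to the number
#' of variables with non-zero penalised coefficients; variables in both
#' top sets are refitted in an unpenalised logistic model whose
#' coefficients are the LR-form score weights.
#'
#' @param cohort Cohort already carrying follow-up columns; it is
#'   restricted internally via [restrict_to_outcome()].
#' @param spec A [fit_spec()].
#' @param alpha Elastic-net mixing parameter (1 = lasso).
#' @return A list of class `"lr_fit_result"`: `selected`,
#'   `lr_coefficients` (including intercept), `glmnet_rank`,
#'   `forest_rank`, `top_k`, `stable` (logical: is the intersection
#'   non-empty), `n_used`.
#' @export
lr_importance_fit <- function(cohort, spec = fit_spec(), alpha = 0.5) {
  cohort <- .prepare_candidates(cohort)
  dat <- restrict_to_outcome(cohort, spec$outcome_horizon)
  vars <- intersect(spec$candidate_variables, names(dat))
  vars <- vars[vapply(vars, function(v)
    length(unique(dat[[v]][!is.na(dat[[v]])])) > 1, logical(1))]
  y <- dat$outcome_2y
  if (length(unique(y)) < 2) {
    stop("outcome is single-class in the restricted cohort", call. = FALSE)
  }
  X <- as.matrix(as.data.frame(lapply(dat[, vars, drop = FALSE], as.numeric)))
  set.seed(spec$seed)
  foldid <- sample(rep_len(seq_len(spec$cv_folds), nrow(X)))
  cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                             foldid = foldid, standardize = TRUE)
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1]
  names(beta) <- vars
  # importance = |coefficient on the standardised scale|
  sds <- apply(X, 2, stats::sd)
  glmnet_imp <- abs(beta) * sds
  glmnet_rank <- names(sort(glmnet_imp, decreasing = TRUE))
  k <- max(sum(abs(beta) > 0), 1L)

  rf <- ranger::ranger(x = as.data.frame(X), y = factor(y),
                       num.trees = 500, importance = "permutation",
                       seed = spec$seed)
  forest_rank <- names(sort(rf$variable.importance, decreasing = TRUE))

  top_glmnet <- glmnet_rank[seq_len(min(k, length(glmnet_rank)))]
  top_forest <- forest_rank[seq_len(min(k, length(forest_rank)))]
  selected <- intersect(top_glmnet, top_forest)
  stable <- length(selected) > 0
  lr_coefficients <- NULL
  if (stable) {
    gdat <- data.frame(y = y, X[, selected, drop = FALSE])
    gfit <- stats::glm(y ~ ., data = gdat, family = stats::binomial())
    lr_coefficients <- stats::coef(gfit)
  }
  structure(list(selected = selected, lr_coefficients = lr_coefficients,
                 glmnet_rank = glmnet_rank, forest_rank = forest_rank,
                 glmnet_nonzero = sum(abs(beta) > 0),
                 top_k = k, stable = stable, n_used = nrow(X)),
            class = "lr_fit_result")
}
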