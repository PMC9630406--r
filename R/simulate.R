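#' @title Synthetic screening-cohort generator
#' @description Internal helpers plus the exported simulation surface:
#'   [simulate_screened_population()], [simulate_staged_cohort()],
#'   [simulate_progression()] and [simulate_followup_visits()].
#' @name simulate
NULL

# deterministic sub-stream seeds derived from the master seed; offsets are
# fixed so each operation is independently reproducible
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 10007) %% (.Machine$integer.max - 1L))
}

.IA2A_POSITIVITY_AU <- 3

# draw stage-consistent metabolic covariates for n children of one stage.
# MVN draw with stage-specific means, physiologic floors, then rejection
# until classify_stage() agrees with the assigned stage; after max_rounds
# the few remaining draws are clamped into the stage-consistent region.
.draw_covariates_stage <- function(n, stage, cfg, max_rounds = 50) {
  covn <- cfg$covnames
  mu <- cfg$covariate_means[[paste0("stage", stage)]]
  D <- diag(cfg$covariate_sds)
  Sigma <- D %*% cfg$covariate_corr %*% D
  draw <- function(m) {
    x <- MASS::mvrnorm(m, mu = mu, Sigma = Sigma)
    if (m == 1) x <- matrix(x, nrow = 1)
    colnames(x) <- covn
    x[, "hba1c"] <- pmax(x[, "hba1c"], 3.8)
    gl <- paste0("glucose_", c(0, 30, 60, 90, 120))
    x[, gl] <- pmax(x[, gl], 45)
    x
  }
  X <- draw(n)
  gl <- paste0("glucose_", c(0, 30, 60, 90, 120))
  stage_of <- function(x) {
    vapply(seq_len(nrow(x)), function(i) {
      classify_stage(x[i, gl], hba1c_pct = x[i, "hba1c"],
                     criteria_set = "consensus2015", confirmed = TRUE)$stage
    }, integer(1))
  }
  bad <- which(stage_of(X) != stage)
  round <- 0
  while (length(bad) > 0 && round < max_rounds) {
    X[bad, ] <- draw(length(bad))
    bad <- bad[stage_of(X[bad, , drop = FALSE]) != stage]
    round <- round + 1
  }
  if (length(bad) > 0) {
    # clamp the stragglers rather than loop forever
    if (stage == 1) {
      X[bad, "glucose_0"] <- pmin(X[bad, "glucose_0"], 109)
      X[bad, c("glucose_30", "glucose_60", "glucose_90")] <-
        pmin(X[bad, c("glucose_30", "glucose_60", "glucose_90")], 199)
      X[bad, "glucose_120"] <- pmin(X[bad, "glucose_120"], 139)
      X[bad, "hba1c"] <- pmin(X[bad, "hba1c"], 6.4)
    } else if (stage == 2) {
      X[bad, "glucose_0"] <- pmin(X[bad, "glucose_0"], 125)
      X[bad, "glucose_120"] <- pmin(pmax(X[bad, "glucose_120"], 140), 199)
      X[bad, "hba1c"] <- pmin(X[bad, "hba1c"], 6.4)
    } else {
      X[bad, "glucose_120"] <- pmax(X[bad, "glucose_120"], 205)
    }
  }
  X
}

# autoantibody panel with >= 2 positives, conditioning by rejection;
# IA-2A positivity is drawn first because it feeds the titre
.draw_aab_panel <- function(n, cfg) {
  if (n == 0) {
    return(matrix(logical(0), ncol = 4,
                  dimnames = list(NULL, c("iaa", "gada", "ia2a", "znt8a"))))
  }
  draw <- function(m) {
    cbind(iaa = stats::runif(m) < cfg$frac_iaa,
          gada = stats::runif(m) < cfg$frac_gada,
          ia2a = stats::runif(m) < cfg$frac_ia2a,
          znt8a = stats::runif(m) < cfg$frac_znt8a)
  }
  P <- draw(n)
  bad <- which(rowSums(P) < 2)
  while (length(bad) > 0) {
    P[bad, ] <- draw(length(bad))
    bad <- bad[rowSums(P[bad, , drop = FALSE]) < 2]
  }
  P
}

# assemble full baseline records for n staged children with given stages
.build_staged_records <- function(stages, cfg, id_offset = 0L) {
  n <- length(stages)
  if (n == 0) return(.empty_cohort())
  X <- matrix(NA_real_, n, length(cfg$covnames),
              dimnames = list(NULL, cfg$covnames))
  for (s in sort(unique(stages))) {
    idx <- which(stages == s)
    X[idx, ] <- .draw_covariates_stage(length(idx), s, cfg)
  }
  panel <- .draw_aab_panel(n, cfg)
  titre <- ifelse(panel[, "ia2a"],
                  pmax(exp(X[, "log_titre"]), .IA2A_POSITIVITY_AU), 0)
  data.frame(
    child_id = sprintf("C%06d", id_offset + seq_len(n)),
    age_years = pmin(pmax(stats::rlnorm(n, log(3.6), 0.45), 1.75), 10.99),
    multi_aab = TRUE,
    iaa_pos = panel[, "iaa"], gada_pos = panel[, "gada"],
    ia2a_pos = panel[, "ia2a"], znt8a_pos = panel[, "znt8a"],
    stage_at_staging = as.integer(stages),
    hba1c_pct = X[, "hba1c"],
    glucose_0 = X[, "glucose_0"], glucose_30 = X[, "glucose_30"],
    glucose_60 = X[, "glucose_60"], glucose_90 = X[, "glucose_90"],
    glucose_120 = X[, "glucose_120"],
    ia2a_titre = titre,
    ia2a_cat = ia2a_category(titre),
    bmi_sds = X[, "bmi_sds"],
    hla_dr3dr4 = stats::runif(n) < cfg$hla_dr3dr4_freq,
    grs = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
}

.empty_cohort <- function() {
  data.frame(child_id = character(0), age_years = numeric(0),
             multi_aab = logical(0), iaa_pos = logical(0),
             gada_pos = logical(0), ia2a_pos = logical(0),
             znt8a_pos = logical(0), stage_at_staging = integer(0),
             hba1c_pct = numeric(0), glucose_0 = numeric(0),
             glucose_30 = numeric(0), glucose_60 = numeric(0),
             glucose_90 = numeric(0), glucose_120 = numeric(0),
             ia2a_titre = numeric(0), ia2a_cat = integer(0),
             bmi_sds = numeric(0), hla_dr3dr4 = logical(0),
             grs = numeric(0), stringsAsFactors = FALSE)
}

#' Simulate a screened population
#'
#' Draws `n_screened` children; each is confirmed multiple-autoantibody
#' positive with probability `prevalence_multi_aab`. Multi-autoantibody
#' children receive a stage label from `stage_split` and full baseline
#' covariates; autoantibody-negative children carry only identifiers (their
#' metabolic covariates are never measured by the screening programme and
#' are returned as `NA`).
#'
#' @param config A [cohort_config()].
#' @return A data.frame, one row per screened child.
#' @export
simulate_screened_population <- function(config) {
  validate_cohort_config(config)
  n <- config$n_screened
  if (n == 0) return(.empty_cohort())
  set.seed(.sub_seed(config$seed, 1))
  multi <- stats::runif(n) < config$prevalence_multi_aab
  n_multi <- sum(multi)
  stages <- if (n_multi > 0) {
    sample(1:3, n_multi, replace = TRUE, prob = config$stage_split)
  } else integer(0)
  staged <- .build_staged_records(stages, config)
  out <- .empty_cohort()[rep(1L, n), ]
  rownames(out) <- NULL
  out$child_id <- sprintf("C%06d", seq_len(n))
  out$multi_aab <- FALSE
  out$age_years <- NA_real_
  if (n_multi > 0) {
    idx <- which(multi)
    staged$child_id <- out$child_id[idx]
    out[idx, ] <- staged
  }
  out
}

#' Simulate a staged sub-cohort directly
#'
#' Draws `n_staged` multiple-autoantibody-positive children with stage
#' labels from `stage_split` and full baseline covariates, without
#' materialising the (much larger) autoantibody-negative screening
#' population. Used for large parameter-recovery experiments.
#'
#' @param n_staged Number of staged children.
#' @param config A [cohort_config()].
#' @return A data.frame, one row per staged child.
#' @export
simulate_staged_cohort <- function(n_staged, config) {
  validate_cohort_config(config)
  if (n_staged == 0) return(.empty_cohort())
  set.seed(.sub_seed(config$seed, 4))
  stages <- sample(1:3, n_staged, replace = TRUE, prob = config$stage_split)
  .build_staged_records(stages, config)
}

#' Generator-truth linear predictor of progression
#'
#' The centered log-hazard used as simulation truth: weights from
#' `config$true_log_hazard_coeffs` applied to (HbA1c - 5.233,
#' OGTT90 - 107.6, IA-2A category - 1.27).
#'
#' @param cohort Staged cohort data.frame.
#' @param config A [cohort_config()].
#' @return Numeric vector, one value per row.
#' @export
true_linear_predictor <- function(cohort, config) {
  b <- config$true_log_hazard_coeffs
  ctr <- score_coefficients()$cph$center
  (cohort$hba1c_pct - ctr["hba1c"]) * b[["hba1c"]] +
    (cohort$glucose_90 - ctr["ogtt90"]) * b[["ogtt90"]] +
    (cohort$ia2a_cat - ctr["ia2a_cat"]) * b[["ia2a_cat"]]
}

#' Simulate progression to stage 3 under proportional hazards
#'
#' For every staged stage 1 or stage 2 child, draws an exponential event
#' time with hazard `baseline_hazard_rate * exp(linear predictor)` and an
#' independent exponential dropout time; follow-up is censored at the
#' earlier of dropout and the administrative horizon. Children already at
#' stage 3 when staged get an event at time zero. Adds columns
#' `event_time_years` and `event`.
#'
#' @param cohort Staged cohort data.frame (from [simulate_staged_cohort()]
#'   or the multi-autoantibody rows of [simulate_screened_population()]).
#' @param config A [cohort_config()].
#' @return The cohort with follow-up columns added.
#' @export
simulate_progression <- function(cohort, config) {
  validate_cohort_config(config)
  n <- nrow(cohort)
  cohort$event_time_years <- NA_real_
  cohort$event <- NA
  if (n == 0) return(cohort)
  set.seed(.sub_seed(config$seed, 2))
  at_risk <- which(cohort$multi_aab & cohort$stage_at_staging %in% c(1L, 2L))
  if (length(at_risk) > 0) {
    lp <- true_linear_predictor(cohort[at_risk, , drop = FALSE], config)
    haz <- config$baseline_hazard_rate * exp(lp)
    t_event <- ifelse(haz > 0, stats::rexp(length(at_risk), rate = 1) / haz, Inf)
    t_drop <- if (config$dropout_hazard > 0) {
      stats::rexp(length(at_risk), rate = config$dropout_hazard)
    } else rep(Inf, length(at_risk))
    t_cens <- pmin(t_drop, config$followup_years_max)
    cohort$event_time_years[at_risk] <- pmin(t_event, t_cens)
    cohort$event[at_risk] <- t_event <= t_cens
  }
  at_stage3 <- which(cohort$multi_aab & cohort$stage_at_staging == 3L)
  cohort$event_time_years[at_stage3] <- 0
  cohort$event[at_stage3] <- TRUE
  cohort
}

#' Simulate 2-6-monthly follow-up visits
#'
#' Generates monitoring visits for every staged stage 1/2 child: the
#' baseline visit at time zero, then visits spaced uniformly within the
#' configured interval (default 2-6 months) strictly before the child's
#' event/censoring time. Visit HbA1c and OGTT90 follow the baseline value
#' plus, in progressors, a linear upward drift, plus measurement noise;
#' the IA-2A titre of IA-2A-positive children wobbles on the log scale.
#'
#' @param cohort Cohort with follow-up columns (see
#'   [simulate_progression()]).
#' @param config A [cohort_config()].
#' @return A long-format data.frame: `child_id`, `visit`, `time_years`,
#'   `hba1c_pct`, `glucose_90`, `ia2a_titre`.
#' @export
simulate_followup_visits <- function(cohort, config) {
  validate_cohort_config(config)
  set.seed(.sub_seed(config$seed, 3))
  rows <- which(cohort$multi_aab & cohort$stage_at_staging %in% c(1L, 2L) &
                  !is.na(cohort$event_time_years))
  out <- vector("list", length(rows))
  lo <- config$visit_interval_months[1] / 12
  hi <- config$visit_interval_months[2] / 12
  for (j in seq_along(rows)) {
    i <- rows[j]
    t_end <- cohort$event_time_years[i]
    if (t_end <= 0) next   # no follow-up window, no visits
    times <- 0
    t <- if (hi > 0) stats::runif(1, lo, hi) else Inf
    while (t < t_end) {
      times <- c(times, t)
      t <- t + stats::runif(1, lo, hi)
    }
    k <- length(times)
    progressing <- isTRUE(cohort$event[i])
    drift_h <- if (progressing) config$visit_drift[["hba1c"]] else 0
    drift_g <- if (progressing) config$visit_drift[["ogtt90"]] else 0
    noise_h <- c(0, stats::rnorm(k - 1, 0, config$visit_noise[["hba1c"]]))
    noise_g <- c(0, stats::rnorm(k - 1, 0, config$visit_noise[["ogtt90"]]))
    titre0 <- cohort$ia2a_titre[i]
    titre <- if (titre0 > 0) {
      titre0 * exp(c(0, stats::rnorm(k - 1, 0, config$visit_noise[["log_titre"]])))
    } else rep(0, k)
    out[[j]] <- data.frame(
      child_id = cohort$child_id[i],
      visit = seq_len(k),
      time_years = times,
      hba1c_pct = pmax(cohort$hba1c_pct[i] + drift_h * times + noise_h, 3.8),
      glucose_90 = pmax(cohort$glucose_90[i] + drift_g * times + noise_g, 45),
      ia2a_titre = titre,
      stringsAsFactors = FALSE
    )
  }
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) {
    return(data.frame(child_id = character(0), visit = integer(0),
                      time_years = numeric(0), hba1c_pct = numeric(0),
                      glucose_90 = numeric(0), ia2a_titre = numeric(0)))
  }
  do.call(rbind, out)
}
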