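#' Prevalence with a binomial confidence interval
#'
#' Point estimate and 95% CI for a screening detection frequency, e.g.
#' 447 multiple-autoantibody-positive children among 154,462 screened.
#'
#' @param x Number of positives.
#' @param n Number screened.
#' @param method `"wilson"` (default) or `"wald"`.
#' @param conf Confidence level.
#' @return List with `estimate`, `ci_low`, `ci_high` (proportions).
#' @export
prevalence_ci <- function(x, n, method = c("wilson", "wald"), conf = 0.95) {
  method <- match.arg(method)
  stopifnot(x >= 0, n >= 1, x <= n)
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    hw <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - hw); hi <- min(1, p + hw)
  } else {
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- ctr - hw; hi <- ctr + hw
  }
  list(estimate = p, ci_low = lo, ci_high = hi)
}

#' Power specification for a two-arm prevention trial
#'
#' Defaults mirror a 1:1 randomised trial powered to detect a 50%
#' reduction in the 2-year progression risk at two-tailed alpha 0.05 and
#' 80% power with 15% dropout.
#'
#' @param effect Relative risk/hazard reduction in the treated arm.
#' @param alpha Two-tailed type I error.
#' @param power Target power.
#' @param dropout Anticipated dropout fraction; enrolment is inflated by
#'   1/(1 - dropout).
#' @param control_2y_risk 2-year progression risk in the control arm.
#' @param method `"proportions"` (two-sample binomial) or
#'   `"logrank_events"` (event-count formula
#'   4 (z_a + z_b)^2 / log(HR)^2 converted through the average event
#'   probability).
#' @return A list of class `"power_spec"`.
#' @export
power_spec <- function(effect = 0.5, alpha = 0.05, power = 0.80,
                       dropout = 0.15, control_2y_risk = 0.5,
                       method = c("proportions", "logrank_events")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            dropout >= 0, dropout < 1,
            control_2y_risk > 0, control_2y_risk < 1,
            effect >= 0, effect <= 1)
  structure(list(effect = effect, alpha = alpha, power = power,
                 dropout = dropout, control_2y_risk = control_2y_risk,
                 method = method),
            class = "power_spec")
}

#' Trial enrolment sample size
#'
#' Two-sample sample size for the comparison of the control 2-year risk
#' p1 against the treated risk p1 (1 - effect), inflated for dropout and
#' rounded up to an even total (1:1 allocation).
#'
#' @param spec A [power_spec()].
#' @return Total children to enrol (integer).
#' @export
sample_size <- function(spec = power_spec()) {
  if (spec$effect <= 0) {
    stop("a null treatment effect requires an infinite sample size",
         call. = FALSE)
  }
  z_a <- stats::qnorm(1 - spec$alpha / 2)
  z_b <- stats::qnorm(spec$power)
  p1 <- spec$control_2y_risk
  p2 <- p1 * (1 - spec$effect)
  if (spec$method == "proportions") {
    n_arm <- (z_a + z_b)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2
    total <- 2 * n_arm
  } else {
    hr <- log(1 - p2) / log(1 - p1)   # HR implied by the 2-year risks
    d <- 4 * (z_a + z_b)^2 / log(hr)^2
    total <- d / ((p1 + p2) / 2)
  }
  total <- total / (1 - spec$dropout)
  n <- ceiling(total)
  n + (n %% 2)   # even total for 1:1 allocation
}

#' Screening requirement for a target enrolment
#'
#' Eligible children needed = ceiling(n_enrol / participation_rate);
#' children to screen = eligible needed / eligible_frequency, rounded to
#' the nearest `round_to` (default 10,000).
#'
#' @param n_enrol Children to enrol.
#' @param participation_rate Fraction of eligible families enrolling.
#' @param eligible_frequency Population frequency of eligibility (e.g.
#'   59/154462 for stage 1b or stage 2 at initial staging).
#' @param round_to Rounding grain for the screening figure.
#' @return List with `n_eligible_needed`, `n_screen_exact`, `n_screen`.
#' @export
screening_requirement <- function(n_enrol, participation_rate = 0.5,
                                  eligible_frequency = 59 / 154462,
                                  round_to = 10000) {
  if (participation_rate <= 0 || eligible_frequency <= 0) {
    stop("participation_rate and eligible_frequency must be positive",
         call. = FALSE)
  }
  n_eligible <- ceiling(n_enrol / participation_rate)
  exact <- n_eligible / eligible_frequency
  list(n_eligible_needed = n_eligible,
       n_screen_exact = exact,
       n_screen = round(exact / round_to) * round_to)
}

#' Screening cost and case yield
#'
#' Cost arithmetic is carried in integer euro cents and rounded only for
#' reporting: total cost = children screened x cost per screen; expected
#' undiagnosed stage 3 detections = children screened x detection rate
#' (rounded to the nearest child); cost per identified high-risk or
#' stage 3 child = total cost / (eligible + stage 3 detections), rounded
#' to the nearest 100 euros.
#'
#' @param n_screen Children screened.
#' @param n_eligible Eligible (stage 1b or stage 2) children identified.
#' @param cost_per_screen Euros per screened child (default 21.73).
#' @param stage3_rate Frequency of undiagnosed stage 3 among screened
#'   (default 0.00027).
#' @return A list of class `"trial_plan"` with the cost breakdown.
#' @export
cost_and_yield <- function(n_screen, n_eligible, cost_per_screen = 21.73,
                           stage3_rate = 0.00027) {
  cost_cents <- round(cost_per_screen * 100)
  total_cents <- as.numeric(n_screen) * cost_cents
  stage3 <- round(n_screen * stage3_rate)
  per_identified <- total_cents / 100 / (n_eligible + stage3)
  structure(list(
    n_screen = n_screen,
    n_eligible = n_eligible,
    cost_per_screen = cost_cents / 100,
    total_cost = total_cents / 100,
    total_cost_millions = round(total_cents / 100 / 1e6, 1),
    expected_stage3_detected = stage3,
    cost_per_identified_exact = per_identified,
    cost_per_identified = round(per_identified / 100) * 100
  ), class = "trial_plan")
}

#' Full recruitment-and-cost plan
#'
#' Chains [screening_requirement()] and [cost_and_yield()] for a given
#' enrolment target.
#'
#' @inheritParams screening_requirement
#' @inheritParams cost_and_yield
#' @return A `"trial_plan"` list including the screening requirement.
#' @export
trial_plan <- function(n_enrol, participation_rate = 0.5,
                       eligible_frequency = 59 / 154462,
                       cost_per_screen = 21.73, stage3_rate = 0.00027) {
  req <- screening_requirement(n_enrol, participation_rate,
                               eligible_frequency)
  plan <- cost_and_yield(req$n_screen, req$n_eligible_needed,
                         cost_per_screen, stage3_rate)
  plan$n_enrol <- n_enrol
  plan$n_eligible_needed <- req$n_eligible_needed
  plan$participation_rate <- participation_rate
  plan$eligible_frequency <- eligible_frequency
  plan$n_screen_exact <- req$n_screen_exact
  plan
}
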