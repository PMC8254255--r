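#' Logistic survival model for critical patients
#'
#' Survival probability of the most critical patients (cardiac arrest,
#' unconsciousness) as a logistic function of the EMS response time in
#' minutes:
#' \deqn{s(t) = \frac{1}{1 + \exp(\beta_0 + \beta_1 t)}}
#' with defaults \eqn{\beta_0 = -2.04492} and \eqn{\beta_1 = 0.045427}
#' per minute, fitted on historical trip data. With \eqn{\beta_1 > 0}
#' the curve is strictly decreasing: every minute of delay lowers the
#' chance of survival.
#'
#' @param beta0 intercept of the logit (dimensionless).
#' @param beta1 slope of the logit per minute of response time.
#' @return An object of class `ems_survival_model`.
#' @examples
#' m <- survival_model()
#' survival_probability(11.37, m)
#' @export
survival_model <- function(beta0 = -2.04492, beta1 = 0.045427) {
  check_number(beta0, "beta0")
  check_number(beta1, "beta1")
  structure(list(beta0 = beta0, beta1 = beta1), class = "ems_survival_model")
}

#' Survival probability at a given response time
#'
#' @param t response time in minutes (non-negative).
#' @param model an [survival_model()] object.
#' @return Probability in (0, 1).
#' @export
survival_probability <- function(t, model = survival_model()) {
  if (any(!is.finite(t)) || any(t < 0))
    ems_stop("response time 't' must be finite and >= 0",
             "emsloc_validation_error")
  1 / (1 + exp(model$beta0 + model$beta1 * t))
}

#' Survival gain from a response-time reduction
#'
#' Percentage-point increase in survival probability when an average
#' response time of `t0` minutes is reduced by `reduction_s` seconds.
#'
#' @param t0 baseline response time in minutes.
#' @param reduction_s reduction in seconds (non-negative, at most `60 * t0`).
#' @param model an [survival_model()] object.
#' @return Gain in percentage points.
#' @examples
#' survival_gain(11.37, 56) # ~0.61 percentage points
#' @export
survival_gain <- function(t0, reduction_s, model = survival_model()) {
  check_number(t0, "t0", lower = 0)
  check_number(reduction_s, "reduction_s", lower = 0)
  if (reduction_s > 60 * t0)
    ems_stop("'reduction_s' exceeds the whole response time",
             "emsloc_validation_error")
  100 * (survival_probability(t0 - reduction_s / 60, model) -
           survival_probability(t0, model))
}

#' Expected additional survivors from a response-time reduction
#'
#' Scales the per-patient survival gain by the annual number of critical
#' patients: `n_patients * survival_gain / 100`.
#'
#' @param n_patients annual count of most-critical patients.
#' @inheritParams survival_gain
#' @return Expected additional survivors per year (not rounded).
#' @export
expected_additional_survivors <- function(n_patients, t0, reduction_s,
                                          model = survival_model()) {
  check_number(n_patients, "n_patients", lower = 0)
  n_patients * survival_gain(t0, reduction_s, model) / 100
}
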