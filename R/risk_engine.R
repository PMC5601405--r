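#' Apply an odds ratio to a probability
#'
#' Converts to odds, multiplies, and converts back. Used to derive the
#' lipegfilgrastim baseline FN risk from the pegfilgrastim risk.
#'
#' @param p Baseline probability in \[0, 1).
#' @param or_value Odds ratio, > 0.
#' @return Adjusted probability in \[0, 1).
#' @examples
#' apply_odds_ratio(0.032, 0.981)
#' @export
apply_odds_ratio <- function(p, or_value) {
  stopifnot(or_value > 0)
  if (any(p < 0 | p >= 1))
    stop("apply_odds_ratio requires p in [0, 1): odds are infinite at p = 1",
         call. = FALSE)
  odds <- p / (1 - p) * or_value
  odds / (1 + odds)
}

#' Apply a relative risk to a probability
#'
#' Multiplicative on the probability scale, capped at 1.
#'
#' @param p Baseline probability in \[0, 1\].
#' @param rr Relative risk, >= 0.
#' @return `min(1, p * rr)`.
#' @export
apply_relative_risk <- function(p, rr) {
  stopifnot(p >= 0, p <= 1, rr >= 0)
  pmin(1, p * rr)
}

#' Apportion an overall FN risk to chemotherapy cycle 1
#'
#' The overall per-course FN risk is split across cycles assuming cycles
#' 2+ carry `rr_subsequent` times the cycle-1 risk. The default linear
#' (first-order) form solves
#' `p1 * (1 + (n_cycles - 1) * rr_subsequent) = total_risk`, which is
#' the form consistent with the published per-cycle values at 3-decimal
#' truncation; `exact = TRUE` instead solves the compounding form
#' `1 - (1 - p1) * (1 - p1 * rr)^(n - 1) = total_risk` by root finding.
#'
#' @param total_risk Overall risk across the course, in (0, 1).
#' @param rr_subsequent Relative risk of cycles 2+ vs cycle 1, > 0.
#' @param n_cycles Number of cycles, >= 1.
#' @param exact Use the compounding form (default `FALSE`).
#' @return Cycle-1 risk (not truncated; see [truncate3()] for the
#'   display convention).
#' @examples
#' truncate3(apportion_cycle1_fn_risk(0.032, 0.213, 4))  # 0.019
#' @export
apportion_cycle1_fn_risk <- function(total_risk, rr_subsequent, n_cycles,
                                     exact = FALSE) {
  stopifnot(total_risk >= 0, total_risk < 1, rr_subsequent > 0, n_cycles >= 1)
  if (total_risk == 0 || n_cycles == 1) return(total_risk)
  if (!exact) return(total_risk / (1 + (n_cycles - 1) * rr_subsequent))
  f <- function(p1) 1 - (1 - p1) * (1 - p1 * rr_subsequent)^(n_cycles - 1) - total_risk
  stats::uniroot(f, c(0, total_risk), tol = 1e-12)$root
}

#' Truncate to three decimals (display convention)
#'
#' The published per-cycle risks truncate (do not round) derived values
#' to three decimals.
#' @param x Numeric.
#' @return `floor(x * 1000) / 1000`.
#' @export
truncate3 <- function(x) floor(x * 1000) / 1000

#' Posterior event probability given a chemotherapy delay
#'
#' Bayes' rule on the odds scale: posterior odds of the event given
#' delay equal the likelihood ratio
#' `p_delay_given_event / p_delay_given_no_event` times the prior odds.
#'
#' @param p_delay_given_event P(delay | event).
#' @param p_delay_given_no_event P(delay | no event).
#' @param p_event Prior event probability.
#' @return P(event | delay). Degenerate case: a zero likelihood under
#'   "no event" with a non-trivial prior returns 1.
#' @examples
#' bayes_event_given_delay(0.42, 0.32, 0.5)
#' @export
bayes_event_given_delay <- function(p_delay_given_event, p_delay_given_no_event,
                                    p_event) {
  stopifnot(p_delay_given_event >= 0, p_delay_given_event <= 1,
            p_delay_given_no_event >= 0, p_delay_given_no_event <= 1,
            p_event >= 0, p_event <= 1)
  if (p_event == 0) return(0)
  if (p_event == 1) return(1)
  if (p_delay_given_no_event == 0) return(1)
  if (p_delay_given_event == 0) return(0)
  odds <- (p_delay_given_event / p_delay_given_no_event) * p_event / (1 - p_event)
  odds / (1 + odds)
}

#' Event risk derived from a gamma-distributed neutrophil count
#'
#' The published model assigns a gamma distribution to the absolute
#' neutrophil count (ANC) and converts granulocyte levels to an
#' infection/FN risk through a correlation mapping. The mapping is
#' user-supplied (piecewise constant or any vectorised function of the
#' ANC returning risks in \[0, 1\]); no numeric mapping is shipped
#' because none is published. With the default `mapping = NULL`
#' pass-through, the configured per-cycle risk is returned unchanged.
#'
#' @param spec List with `shape`, `scale` (gamma, scale
#'   parameterisation), optional `threshold` (10^9 cells/L), optional
#'   `configured_risk` (pass-through value) and optional `mapping`.
#' @param n_draws Monte-Carlo sample size (default 1000).
#' @param seed Integer seed; the estimate is deterministic given the
#'   seed.
#' @return Expected event risk under the mapping.
#' @export
anc_derived_event_risk <- function(spec, n_draws = 1000, seed = 1L) {
  stopifnot(n_draws >= 1)
  if (is.null(spec$mapping)) {
    if (is.null(spec$configured_risk))
      stop("no ANC-to-risk mapping and no configured risk supplied", call. = FALSE)
    return(spec$configured_risk)
  }
  stopifnot(spec$shape > 0, spec$scale > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  anc <- stats::rgamma(n_draws, shape = spec$shape, scale = spec$scale)
  risk <- spec$mapping(anc)
  if (any(risk < 0 | risk > 1))
    stop("ANC mapping produced risks outside [0, 1]", call. = FALSE)
  mean(risk)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Risk of relative dose intensity below 85% for a cohort stratum
#'
#' The six stratum-level risks are direct published inputs (their
#' derivation from the underlying age/FN/SN ingredients is not
#' reproducible from the printed values); strata are indexed by age
#' band and neutropenic-event history.
#'
#' @param age_band `"lt65"` or `"ge65"`.
#' @param fn_history `"naive"` (no severe/febrile neutropenia),
#'   `"history"` (febrile neutropenia) or `"sn"` (severe neutropenia
#'   without FN).
#' @param params The `rdi` component of a [base_case_config()].
#' @return Probability of RDI < 85%.
#' @examples
#' rdi_low_risk("ge65", "history", base_case_config()$rdi)  # 0.079
#' @export
rdi_low_risk <- function(age_band, fn_history, params) {
  if (!age_band %in% c("lt65", "ge65"))
    stop("unknown age band: ", age_band, call. = FALSE)
  if (!fn_history %in% c("naive", "history", "sn"))
    stop("unknown FN-history stratum: ", fn_history, call. = FALSE)
  unname(params$strata[[age_band]][[fn_history]])
}

#' Annual death probability under the low-RDI survival hazard ratio
#'
#' The hazard ratio acts on the cumulative-hazard scale (standard
#' survival semantics), keeping probabilities in \[0, 1\]:
#' `1 - (1 - p)^hr`.
#'
#' @param annual_death_prob Annual death probability in \[0, 1).
#' @param hr Hazard ratio, > 0.
#' @return Adjusted annual death probability.
#' @examples
#' mortality_with_low_rdi(0.10, 1.32)
#' @export
mortality_with_low_rdi <- function(annual_death_prob, hr) {
  stopifnot(annual_death_prob >= 0, annual_death_prob < 1, hr > 0)
  1 - (1 - annual_death_prob)^hr
}

#' FN risk in subsequent cycles given FN history
#'
#' Patients with a previous FN episode carry a multiplied base FN risk
#' in later cycles (capped at 1); FN-naive patients keep the base risk.
#'
#' @param base_cycle_risk Base per-cycle FN risk.
#' @param has_fn_history Logical.
#' @param multiplier Risk multiplier for FN-history patients.
#' @return Adjusted probability.
#' @export
subsequent_fn_risk <- function(base_cycle_risk, has_fn_history, multiplier) {
  stopifnot(base_cycle_risk >= 0, base_cycle_risk <= 1, multiplier > 0)
  if (has_fn_history) pmin(1, base_cycle_risk * multiplier) else base_cycle_risk
}

#' Per-cycle baseline FN risks for one arm
#'
#' Apportions the overall pegfilgrastim FN risk to cycle 1 via
#' [apportion_cycle1_fn_risk()], scales cycles 2+ by the subsequent-
#' cycle relative risk, and for the lipegfilgrastim arm applies either
#' the odds ratio (odds scale) or the relative risk (probability
#' scale), per `config$fn_risk_estimate_source`.
#'
#' @param arm `"lipegfilgrastim"` or `"pegfilgrastim"`.
#' @param config A `cua_config`.
#' @return Numeric vector of length `n_chemo_cycles`.
#' @export
base_fn_cycle_risks <- function(arm, config) {
  r <- config$risks
  n <- config$cohort$n_chemo_cycles
  p1 <- apportion_cycle1_fn_risk(r$baseline_fn_total, r$rr_fn_cycle2plus, n)
  p <- c(p1, rep(apply_relative_risk(p1, r$rr_fn_cycle2plus), max(0, n - 1)))
  if (arm == "lipegfilgrastim") {
    p <- if (config$fn_risk_estimate_source == "direct_or")
      apply_odds_ratio(p, r$or_fn)
    else apply_relative_risk(p, r$rr_fn)
  }
  p
}
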