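#' Annual discount factor
#'
#' @param t_years Elapsed time in years, >= 0.
#' @param rate Annual discount rate, >= 0.
#' @return `(1 + rate)^(-t_years)`.
#' @examples
#' discount_factor(5, 0.015)
#' @export
discount_factor <- function(t_years, rate) {
  stopifnot(all(t_years >= 0), rate >= 0)
  (1 + rate)^(-t_years)
}

#' Combined lifetime outcome for one treatment arm
#'
#' Runs the on-chemotherapy model and feeds its exit cohort into the
#' lifetime post-chemotherapy model, summing discounted costs (3%),
#' discounted QALYs (1.5%) and undiscounted life-years.
#'
#' @param arm `"lipegfilgrastim"` or `"pegfilgrastim"`.
#' @param config A `cua_config`.
#' @param life_table A `life_table`.
#' @param bc_table A `bc_mortality` table.
#' @return An object of class `arm_outcome`.
#' @export
arm_outcome <- function(arm, config, life_table, bc_table) {
  chemo <- run_chemo_model(arm, config)
  post <- run_post_model(chemo$exit_cohort, life_table, bc_table, config)
  structure(list(
    arm = arm,
    cost = chemo$total_cost + post$cost,
    qalys = chemo$qalys + post$qalys,
    ly = chemo$ly + post$ly,
    cost_components = chemo$cost,
    chemo = chemo, post = post
  ), class = "arm_outcome")
}

#' Incremental cost-effectiveness of strategy a versus strategy b
#'
#' Differences are `a - b`. Classification follows the cost-
#' effectiveness plane: `dominant` (cheaper and more effective),
#' `dominated` (dearer and less effective), `tradeoff_ne` (dearer,
#' more effective) or `tradeoff_sw` (cheaper, less effective). The
#' ICER is defined only in the trade-off quadrants.
#'
#' @param a,b `arm_outcome` objects (or lists with `cost`, `qalys`,
#'   `ly`).
#' @param wtp Willingness-to-pay per QALY used for the reported net
#'   monetary benefit (default 30000).
#' @return An object of class `incremental_result` with `delta_cost`,
#'   `delta_qalys`, `delta_ly`, `classification`, `icer` (NA under
#'   dominance or zero QALY difference) and `nmb`.
#' @export
incremental <- function(a, b, wtp = 30000) {
  dc <- a$cost - b$cost
  dq <- a$qalys - b$qalys
  dl <- (a$ly %||% NA_real_) - (b$ly %||% NA_real_)
  cls <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else if (dc >= 0 && dq >= 0) "tradeoff_ne"
    else "tradeoff_sw"
  icer <- if (cls %in% c("tradeoff_ne", "tradeoff_sw") && dq != 0) dc / dq
    else NA_real_
  res <- structure(list(delta_cost = dc, delta_qalys = dq, delta_ly = dl,
                        classification = cls, icer = icer, wtp = wtp),
                   class = "incremental_result")
  res$nmb <- net_monetary_benefit(res, wtp)
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `wtp * delta_QALYs - delta_cost`; positive values indicate
#' cost-effectiveness at that threshold.
#'
#' @param inc An `incremental_result` (or list with `delta_cost`,
#'   `delta_qalys`).
#' @param wtp Willingness-to-pay per QALY, >= 0 (vectorised).
#' @return Net monetary benefit in euro.
#' @export
net_monetary_benefit <- function(inc, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * inc$delta_qalys - inc$delta_cost
}

#' Run the base-case analysis for both arms
#'
#' @param config A `cua_config` (default the built-in base case).
#' @param life_table,bc_table Mortality inputs; defaults are the
#'   package's synthetic tables.
#' @param wtp Willingness-to-pay used for the reported NMB.
#' @return List of class `base_case_result` with per-arm outcomes and
#'   the incremental comparison (lipegfilgrastim minus pegfilgrastim).
#' @examples
#' res <- run_base_case()
#' res$incremental$delta_cost
#' @export
run_base_case <- function(config = base_case_config(),
                          life_table = generate_life_table(),
                          bc_table = generate_bc_mortality(),
                          wtp = 30000) {
  out <- lapply(ARMS, arm_outcome, config = config,
                life_table = life_table, bc_table = bc_table)
  names(out) <- ARMS
  structure(list(
    lipegfilgrastim = out$lipegfilgrastim,
    pegfilgrastim = out$pegfilgrastim,
    incremental = incremental(out$lipegfilgrastim, out$pegfilgrastim, wtp),
    fn_risk_estimate_source = config$fn_risk_estimate_source
  ), class = "base_case_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> dCost %.2f, dQALY %.4f, dLY %s, %s",
              x$delta_cost, x$delta_qalys,
              ifelse(is.na(x$delta_ly), "NA", sprintf("%.4f", x$delta_ly)),
              x$classification))
  if (!is.na(x$icer)) cat(sprintf(", ICER %.0f", x$icer))
  cat(sprintf(", NMB(%.0f) %.0f\n", x$wtp, x$nmb))
  invisible(x)
}

#' @export
print.base_case_result <- function(x, ...) {
  cat("Cost-effectiveness results (per patient, FN risk source:",
      x$fn_risk_estimate_source, ")\n")
  fmt <- function(o) sprintf("  %-16s %10.0f %10.3f %10.3f\n",
                             o$arm, o$cost, o$qalys, o$ly)
  cat(sprintf("  %-16s %10s %10s %10s\n", "", "Costs (EUR)", "QALYs", "LY"))
  cat(fmt(x$lipegfilgrastim)); cat(fmt(x$pegfilgrastim))
  inc <- x$incremental
  cat(sprintf("  %-16s %10.0f %10.3f %10.3f   [%s]\n", "Difference",
              inc$delta_cost, inc$delta_qalys, inc$delta_ly,
              inc$classification))
  invisible(x)
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome> %s: cost %.2f, QALYs %.4f, LY %.4f\n",
              x$arm, x$cost, x$qalys, x$ly))
  invisible(x)
}
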