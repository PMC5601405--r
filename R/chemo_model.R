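#' Initial cohort state for the on-chemotherapy model
#'
#' Occupancy is carried as fractions of the initial cohort, split by
#' neutropenic-event history (`naive`, `sn` = severe neutropenia
#' without FN, `fn` = any febrile-neutropenia episode) plus an
#' absorbing `dead` mass.
#' @return A list with components `strata` (named numeric) and `dead`.
#' @export
chemo_initial_state <- function() {
  list(strata = c(naive = 1, sn = 0, fn = 0), dead = 0)
}

# disjoint within-cycle event groups for one history stratum
# m: stratum mass; returns named masses
.cycle_groups <- function(m, p_sn, p_fn_sn, p_inf_sn, p_base_fn, p_inf_fn) {
  s <- m * p_sn
  fn_sn <- s * p_fn_sn
  inf_sn <- (s - fn_sn) * p_inf_sn
  sn_only <- s - fn_sn - inf_sn
  fn_base <- (m - s) * p_base_fn
  fn_base_inf <- fn_base * p_inf_fn
  c(fn_sn = fn_sn, inf_sn = inf_sn, sn_only = sn_only,
    fn_base = fn_base - fn_base_inf, fn_base_inf = fn_base_inf,
    none = m - s - fn_base)
}

#' Run one cycle of the on-chemotherapy Markov model
#'
#' Applies the within-cycle event cascade to each history stratum:
#' severe-neutropenia (SN) incidence; among SN patients, FN-if-SN then
#' infection-if-SN for the non-FN remainder (the two risks share their
#' neutrophil-count derivation, so they act as exclusive branches of
#' the SN mass); among non-SN patients, the apportioned base FN risk
#' (multiplied for FN-history patients) with the infection-if-FN risk
#' on that pathway; hospitalisation split of all FN; chemotherapy delay
#' (cycles 2+) for SN and infection patients; and cause-specific deaths
#' at cycle end. Events are tunnel episodes: all survivors return to
#' the chemotherapy state, with their history stratum updated.
#'
#' @param state A state as returned by [chemo_initial_state()] or a
#'   previous cycle.
#' @param cycle_index Cycle number, 1-based.
#' @param arm `"lipegfilgrastim"` or `"pegfilgrastim"`.
#' @param config A `cua_config`.
#' @return List with `state` (next state) and `accrual` (event masses,
#'   cost components, QALY and life-year increments for the cycle).
#' @export
run_chemo_cycle <- function(state, cycle_index, arm, config) {
  r <- config$risks; cs <- config$costs; u <- config$utilities
  du <- config$durations
  k <- cycle_index
  base_fn <- base_fn_cycle_risks(arm, config)
  probs <- c(base_fn, r$sn[[arm]], r$fn_if_sn[[arm]], r$infection_if_sn[[arm]],
             r$delay_if_sn[[arm]], r$delay_if_infection[[arm]],
             r$infection_if_fn, r$hospitalization_if_fn,
             r$death_fn, r$death_sn, r$death_infection, r$death_delay)
  if (any(probs < 0 | probs > 1))
    stop("configuration drives a transition probability outside [0, 1]",
         call. = FALSE)

  alive0 <- sum(state$strata)
  cd <- config$cohort$chemo_cycle_days
  t_years <- (k - 1) * cd / 365.25
  disc_c <- discount_factor(floor(t_years), config$discount$costs)
  disc_q <- discount_factor(floor(t_years), config$discount$qalys)

  h <- r$hospitalization_if_fn
  p_dsn <- if (k >= 2) r$delay_if_sn[[arm]][k] else 0
  p_dinf <- if (k >= 2) r$delay_if_infection[[arm]][k] else 0

  ev <- c(sn = 0, fn = 0, fn_inpatient = 0, fn_outpatient = 0, infection = 0,
          delay = 0, death_fn = 0, death_sn = 0, death_infection = 0,
          death_delay = 0)
  cost <- c(chemo = 0, fn_inpatient = 0, fn_outpatient = 0, infection = 0,
            sn = 0, delay = 0)
  qaly <- 0
  new <- c(naive = 0, sn = 0, fn = 0)

  cost[["chemo"]] <- alive0 * cs$chemo_cycle[[arm]]

  # per-group attributes: event-death risk, delay risk, episode utility-days
  u_fn_mix <- h * (du$fn_inpatient * u$fn_inpatient +
                     (cd - du$fn_inpatient) * u$chemo) +
    (1 - h) * (du$fn_outpatient * u$fn_outpatient +
                 (cd - du$fn_outpatient) * u$chemo)
  udays <- c(fn_sn = u_fn_mix,
             inf_sn = du$infection * u$infection + (cd - du$infection) * u$chemo,
             sn_only = du$sn * u$sn + (cd - du$sn) * u$chemo,
             fn_base = u_fn_mix, fn_base_inf = u_fn_mix,
             none = cd * u$chemo)
  d_event <- c(fn_sn = r$death_fn, inf_sn = r$death_infection,
               sn_only = r$death_sn, fn_base = r$death_fn,
               fn_base_inf = r$death_fn, none = 0)
  p_delay <- c(fn_sn = p_dsn, inf_sn = p_dinf, sn_only = p_dsn,
               fn_base = 0, fn_base_inf = p_dinf, none = 0)

  for (g in names(state$strata)) {
    m <- state$strata[[g]]
    if (m == 0) next
    pb <- subsequent_fn_risk(base_fn[k], g == "fn", r$rr_additional_fn)
    gm <- .cycle_groups(m, r$sn[[arm]][k], r$fn_if_sn[[arm]][k],
                        r$infection_if_sn[[arm]][k], pb, r$infection_if_fn)

    fn_tot <- gm[["fn_sn"]] + gm[["fn_base"]] + gm[["fn_base_inf"]]
    sn_tot <- gm[["fn_sn"]] + gm[["inf_sn"]] + gm[["sn_only"]]
    inf_tot <- gm[["inf_sn"]] + gm[["fn_base_inf"]]
    delay_mass <- sum(gm * p_delay)

    ev[["sn"]] <- ev[["sn"]] + sn_tot
    ev[["fn"]] <- ev[["fn"]] + fn_tot
    ev[["fn_inpatient"]] <- ev[["fn_inpatient"]] + fn_tot * h
    ev[["fn_outpatient"]] <- ev[["fn_outpatient"]] + fn_tot * (1 - h)
    ev[["infection"]] <- ev[["infection"]] + inf_tot
    ev[["delay"]] <- ev[["delay"]] + delay_mass

    cost[["fn_inpatient"]] <- cost[["fn_inpatient"]] +
      fn_tot * h * cs$fn_inpatient_episode
    cost[["fn_outpatient"]] <- cost[["fn_outpatient"]] +
      fn_tot * (1 - h) * cs$fn_outpatient_episode
    cost[["infection"]] <- cost[["infection"]] +
      (gm[["inf_sn"]] * cs$infection_if_sn_per_day[[arm]][k] +
         gm[["fn_base_inf"]] * cs$infection_if_fn_per_day[[arm]][k]) *
      cs$infection_days
    cost[["sn"]] <- cost[["sn"]] + gm[["sn_only"]] * cs$sn_outpatient
    cost[["delay"]] <- cost[["delay"]] + delay_mass * cs$delay

    # utilities: episode days at event utility, remainder on chemotherapy;
    # delayed patients trade delay-days of chemotherapy time for the
    # delay disutility; deaths occur at cycle end (full-cycle accrual)
    qaly_g <- sum(gm * udays) -
      delay_mass * du$delay * u$chemo * (1 - u$delay_factor)
    qaly <- qaly + qaly_g / 365.25

    d_eff_event <- gm * d_event
    d_eff_delay <- gm * (1 - d_event) * p_delay * r$death_delay
    ev[["death_fn"]] <- ev[["death_fn"]] +
      d_eff_event[["fn_sn"]] + d_eff_event[["fn_base"]] + d_eff_event[["fn_base_inf"]]
    ev[["death_sn"]] <- ev[["death_sn"]] + d_eff_event[["sn_only"]]
    ev[["death_infection"]] <- ev[["death_infection"]] + d_eff_event[["inf_sn"]]
    ev[["death_delay"]] <- ev[["death_delay"]] + sum(d_eff_delay)

    surv <- gm - d_eff_event - d_eff_delay
    new[["fn"]] <- new[["fn"]] +
      surv[["fn_sn"]] + surv[["fn_base"]] + surv[["fn_base_inf"]]
    sn_new <- surv[["inf_sn"]] + surv[["sn_only"]]
    if (g == "fn") {
      new[["fn"]] <- new[["fn"]] + sn_new + surv[["none"]]
    } else if (g == "sn") {
      new[["sn"]] <- new[["sn"]] + sn_new + surv[["none"]]
    } else {
      new[["sn"]] <- new[["sn"]] + sn_new
      new[["naive"]] <- new[["naive"]] + surv[["none"]]
    }
  }

  died <- alive0 - sum(new)
  list(
    state = list(strata = new, dead = state$dead + died),
    accrual = list(
      events = ev,
      cost = cost * disc_c,
      cost_undiscounted = cost,
      qaly = qaly * disc_q,
      ly = alive0 * cd / 365.25
    )
  )
}

#' QALYs accrued in one on-chemotherapy cycle
#'
#' Convenience accessor computing the utility-weighted, discounted time
#' for a cycle from its state and event accrual: each event mass spends
#' its episode duration at the event utility (FN inpatient at the
#' inpatient utility for the length of stay, FN outpatient, infection
#' and severe neutropenia likewise), delayed patients trade part of
#' their chemotherapy time for the delay disutility, and the remaining
#' time is valued at the on-chemotherapy utility.
#'
#' @param state State at cycle start.
#' @param cycle_index Cycle number.
#' @param arm Treatment arm.
#' @param config A `cua_config`.
#' @return Discounted QALY increment for the cycle.
#' @export
accrue_cycle_qalys <- function(state, cycle_index, arm, config) {
  run_chemo_cycle(state, cycle_index, arm, config)$accrual$qaly
}

#' Run the on-chemotherapy Markov model for one arm
#'
#' Iterates [run_chemo_cycle()] over the chemotherapy course from a
#' unit cohort, accrues discounted costs and QALYs and undiscounted
#' life-years, and stratifies the surviving mass at exit by relative
#' dose intensity via [rdi_low_risk()] applied to the FN/SN/naive
#' history strata and the cohort age band.
#'
#' @param arm `"lipegfilgrastim"` or `"pegfilgrastim"`.
#' @param config A `cua_config`.
#' @return An object of class `chemo_result`: per-cycle `trace`,
#'   expected event `counts`, `cost` components (discounted), `qalys`,
#'   `ly`, and the `exit_cohort`.
#' @export
run_chemo_model <- function(arm, config) {
  arm <- match.arg(arm, ARMS)
  state <- chemo_initial_state()
  n <- config$cohort$n_chemo_cycles
  counts <- NULL; cost <- NULL; qalys <- 0; ly <- 0
  trace <- vector("list", n)
  for (k in seq_len(n)) {
    step <- run_chemo_cycle(state, k, arm, config)
    a <- step$accrual
    counts <- if (is.null(counts)) a$events else counts + a$events
    cost <- if (is.null(cost)) a$cost else cost + a$cost
    qalys <- qalys + a$qaly
    ly <- ly + a$ly
    trace[[k]] <- data.frame(
      cycle = k, on_chemo = sum(state$strata), t(a$events),
      dead = step$state$dead, check.names = FALSE)
    state <- step$state
  }
  age_band <- if (config$cohort$age_start < 65) "lt65" else "ge65"
  strata <- state$strata
  p_low <- vapply(c(naive = "naive", sn = "sn", fn = "history"),
                  function(s) rdi_low_risk(age_band, s, config$rdi), numeric(1))
  names(p_low) <- names(strata)
  exit <- list(
    age_band = age_band,
    strata = strata,
    rdi_low_by_stratum = strata * p_low,
    rdi_low = sum(strata * p_low),
    rdi_ok = sum(strata * (1 - p_low))
  )
  structure(list(
    arm = arm,
    trace = do.call(rbind, trace),
    counts = counts,
    cost = cost,
    total_cost = sum(cost),
    qalys = qalys,
    ly = ly,
    exit_cohort = exit,
    final_state = state
  ), class = "chemo_result")
}

#' @export
print.chemo_result <- function(x, ...) {
  cat(sprintf("<chemo_result> %s: cost %.2f, QALYs %.4f, LY %.4f, surviving %.4f\n",
              x$arm, x$total_cost, x$qalys, x$ly, sum(x$final_state$strata)))
  invisible(x)
}
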