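# Independent path-enumeration oracle for one on-chemotherapy cycle.
#
# Enumerates every within-cycle event path (SN / FN / infection /
# hospitalisation / delay / death) for each history stratum explicitly,
# with one row per path, and accumulates expected occupancy, costs and
# utility-weighted time from the path probabilities. Deliberately
# written as a brute-force tree walk, independent of the package's
# grouped-expectation arithmetic.
oracle_cycle <- function(state, k, arm, config) {
  r <- config$risks; cs <- config$costs; u <- config$utilities
  du <- config$durations
  cd <- config$cohort$chemo_cycle_days
  base_fn <- gcsfcea::base_fn_cycle_risks(arm, config)
  h <- r$hospitalization_if_fn

  new <- c(naive = 0, sn = 0, fn = 0)
  cost <- c(chemo = 0, fn_inpatient = 0, fn_outpatient = 0, infection = 0,
            sn = 0, delay = 0)
  qaly_days <- 0
  dead <- 0

  for (g in names(state$strata)) {
    m <- state$strata[[g]]
    if (m == 0) next
    pb <- if (g == "fn") min(1, base_fn[k] * r$rr_additional_fn) else base_fn[k]
    p_dsn <- if (k >= 2) r$delay_if_sn[[arm]][k] else 0
    p_dinf <- if (k >= 2) r$delay_if_infection[[arm]][k] else 0

    # event groups: list(prob, had_sn, had_fn, had_inf, inf_cost_kind,
    #                    death_risk, delay_prob)
    ps <- r$sn[[arm]][k]; pf <- r$fn_if_sn[[arm]][k]
    pi_sn <- r$infection_if_sn[[arm]][k]; pi_fn <- r$infection_if_fn
    groups <- list(
      list(p = ps * pf,                    sn = TRUE,  fn = TRUE,  inf = FALSE,
           inf_kind = NA, d = r$death_fn, pdel = p_dsn),
      list(p = ps * (1 - pf) * pi_sn,      sn = TRUE,  fn = FALSE, inf = TRUE,
           inf_kind = "sn", d = r$death_infection, pdel = p_dinf),
      list(p = ps * (1 - pf) * (1 - pi_sn), sn = TRUE, fn = FALSE, inf = FALSE,
           inf_kind = NA, d = r$death_sn, pdel = p_dsn),
      list(p = (1 - ps) * pb * (1 - pi_fn), sn = FALSE, fn = TRUE, inf = FALSE,
           inf_kind = NA, d = r$death_fn, pdel = 0),
      list(p = (1 - ps) * pb * pi_fn,      sn = FALSE, fn = TRUE,  inf = TRUE,
           inf_kind = "fn", d = r$death_fn, pdel = p_dinf),
      list(p = (1 - ps) * (1 - pb),        sn = FALSE, fn = FALSE, inf = FALSE,
           inf_kind = NA, d = 0, pdel = 0)
    )
    for (gr in groups) {
      mass <- m * gr$p
      if (mass == 0) next
      # costs (unaffected by end-of-cycle death)
      if (gr$fn) {
        cost[["fn_inpatient"]] <- cost[["fn_inpatient"]] +
          mass * h * cs$fn_inpatient_episode
        cost[["fn_outpatient"]] <- cost[["fn_outpatient"]] +
          mass * (1 - h) * cs$fn_outpatient_episode
      }
      if (gr$inf) {
        cpd <- if (gr$inf_kind == "sn") cs$infection_if_sn_per_day[[arm]][k]
               else cs$infection_if_fn_per_day[[arm]][k]
        cost[["infection"]] <- cost[["infection"]] + mass * cpd * cs$infection_days
      }
      if (gr$sn && !gr$fn && !gr$inf)
        cost[["sn"]] <- cost[["sn"]] + mass * cs$sn_outpatient
      cost[["delay"]] <- cost[["delay"]] + mass * gr$pdel * cs$delay
      # utility-weighted days: priority FN > infection > SN, remainder chemo
      ud <- if (gr$fn) {
        h * (du$fn_inpatient * u$fn_inpatient + (cd - du$fn_inpatient) * u$chemo) +
          (1 - h) * (du$fn_outpatient * u$fn_outpatient +
                       (cd - du$fn_outpatient) * u$chemo)
      } else if (gr$inf) {
        du$infection * u$infection + (cd - du$infection) * u$chemo
      } else if (gr$sn) {
        du$sn * u$sn + (cd - du$sn) * u$chemo
      } else cd * u$chemo
      ud <- ud - gr$pdel * du$delay * u$chemo * (1 - u$delay_factor)
      qaly_days <- qaly_days + mass * ud
      # death: event risk, then delay risk among delayed survivors
      for (delayed in c(FALSE, TRUE)) {
        pm <- mass * (if (delayed) gr$pdel else 1 - gr$pdel)
        if (pm == 0) next
        d_tot <- 1 - (1 - gr$d) * (1 - (if (delayed) r$death_delay else 0))
        dead <- dead + pm * d_tot
        sv <- pm * (1 - d_tot)
        dest <- if (gr$fn || g == "fn") "fn"
                else if (gr$sn || gr$inf || g == "sn") "sn"
                else "naive"
        new[[dest]] <- new[[dest]] + sv
      }
    }
    cost[["chemo"]] <- cost[["chemo"]] + m * cs$chemo_cycle[[arm]]
  }
  t_years <- (k - 1) * cd / 365.25
  list(state = list(strata = new, dead = state$dead + dead),
       cost = cost * gcsfcea::discount_factor(floor(t_years), config$discount$costs),
       qaly = qaly_days / 365.25 *
         gcsfcea::discount_factor(floor(t_years), config$discount$qalys),
       ly = sum(state$strata) * cd / 365.25)
}

oracle_chemo_model <- function(arm, config) {
  state <- list(strata = c(naive = 1, sn = 0, fn = 0), dead = 0)
  cost <- NULL; qaly <- 0; ly <- 0
  for (k in seq_len(config$cohort$n_chemo_cycles)) {
    step <- oracle_cycle(state, k, arm, config)
    cost <- if (is.null(cost)) step$cost else cost + step$cost
    qaly <- qaly + step$qaly; ly <- ly + step$ly
    state <- step$state
  }
  list(state = state, cost = cost, qaly = qaly, ly = ly)
}
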