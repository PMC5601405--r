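#' Combine independent competing annual death probabilities
#'
#' `1 - (1 - p_allcause) * (1 - p_bc)`.
#' @param p_allcause,p_bc Annual death probabilities in \[0, 1\].
#' @return Combined probability.
#' @export
combine_death_probs <- function(p_allcause, p_bc) {
  stopifnot(all(p_allcause >= 0 & p_allcause <= 1), all(p_bc >= 0 & p_bc <= 1))
  1 - (1 - p_allcause) * (1 - p_bc)
}

#' Run the lifetime post-chemotherapy Markov model
#'
#' Annual cycles from chemotherapy exit to `max_age`. In
#' post-chemotherapy years 1-5, each surviving stratum faces the
#' combination of all-cause mortality (life table) and stage-mixed
#' breast-cancer mortality; the breast-cancer component is adjusted on
#' the cumulative-hazard scale by the low-RDI survival hazard ratio for
#' the `rdi_low` mass. Patients surviving five years are considered
#' cured: only all-cause mortality applies thereafter. Survivors accrue
#' the year-1-5 utility for the first five years and the long-term
#' survivor utility afterwards; QALYs are discounted annually from
#' model start (the chemotherapy phase occupies year 0), life-years are
#' not discounted.
#'
#' @param exit_cohort Exit cohort of [run_chemo_model()] (uses
#'   `rdi_low` / `rdi_ok` masses), or a list with those two fields.
#' @param life_table A `life_table` covering
#'   `[age_start, max_age]`.
#' @param bc_table A `bc_mortality` table.
#' @param config A `cua_config`.
#' @return An object of class `post_result` with the annual `trace`,
#'   discounted `qalys` and undiscounted `ly`.
#' @export
run_post_model <- function(exit_cohort, life_table, bc_table, config) {
  ch <- config$cohort
  n_years <- ch$max_age - ch$age_start
  q_ac <- life_table_q(life_table, ch$age_start, ch$max_age)
  hr <- config$rdi$hr_survival_rdi_low
  r_q <- config$discount$qalys
  r_c <- config$discount$costs
  cure_horizon <- max(bc_table$year)

  alive <- c(rdi_low = exit_cohort$rdi_low, rdi_ok = exit_cohort$rdi_ok)
  qalys <- 0; ly <- 0; cost <- 0
  trace <- data.frame(year = seq_len(n_years), age = ch$age_start + seq_len(n_years) - 1,
                      rdi_low = NA_real_, rdi_ok = NA_real_, dead = NA_real_)

  for (t in seq_len(n_years)) {
    q_bc <- if (t <= cure_horizon) bc_mix_q(bc_table, t, ch$stage_mix) else 0
    q <- c(
      rdi_low = combine_death_probs(q_ac[t], if (q_bc > 0)
        mortality_with_low_rdi(q_bc, hr) else 0),
      rdi_ok = combine_death_probs(q_ac[t], q_bc)
    )
    alive <- alive * (1 - q)
    u <- if (t <= cure_horizon) config$utilities$survivor_y1_5
         else config$utilities$survivor_gt5
    # survivors at the end of each year accrue that year
    ly <- ly + sum(alive)
    qalys <- qalys + sum(alive) * u * discount_factor(t, r_q)
    cost <- cost + sum(alive) * config$costs$post_chemo_annual *
      discount_factor(t, r_c)
    trace$rdi_low[t] <- alive[["rdi_low"]]
    trace$rdi_ok[t] <- alive[["rdi_ok"]]
  }
  trace$dead <- 1 - trace$rdi_low - trace$rdi_ok
  structure(list(trace = trace, qalys = qalys, ly = ly, cost = cost,
                 years = n_years), class = "post_result")
}

#' @export
print.post_result <- function(x, ...) {
  cat(sprintf("<post_result> %d years: QALYs %.4f (discounted), LY %.4f\n",
              x$years, x$qalys, x$ly))
  invisible(x)
}
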