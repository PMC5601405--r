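#' Set a model parameter, propagating tied quantities
#'
#' Wrapper around [config_set()] used by the sensitivity analyses.
#' Handles the parameters that are not plain scalar slots: stage-mix
#' shares (`cohort.stage_II/III/IV`, other shares renormalised), the
#' infection utility (tied to the FN inpatient utility), and the FN
#' inpatient episode cost, which scales multiplicatively with the ward
#' per-day cost and the length of stay.
#'
#' @param config A `cua_config`.
#' @param name Parameter path.
#' @param value New value.
#' @return Modified configuration.
#' @export
set_model_param <- function(config, name, value) {
  if (grepl("^cohort\\.stage_(II|III|IV)$", name)) {
    stage <- sub("^cohort\\.stage_", "", name)
    mix <- config$cohort$stage_mix
    value <- min(max(value, 0), 1)
    rest <- setdiff(names(mix), stage)
    mix[rest] <- mix[rest] / sum(mix[rest]) * (1 - value)
    mix[stage] <- value
    config$cohort$stage_mix <- mix
    return(config)
  }
  if (grepl("^costs\\.infection_if_(fn|sn)_per_day\\.[a-z]+$", name)) {
    vec <- config_get(config, name)
    return(config_set(config, name, vec * value / vec[1]))
  }
  if (name %in% c("costs.fn_ward_per_day", "costs.fn_los_days")) {
    base <- config_get(config, name)
    config <- config_set(config, name, value)
    config$costs$fn_inpatient_episode <-
      config$costs$fn_inpatient_episode * value / base
    return(config)
  }
  config <- config_set(config, name, value)
  if (name == "utilities.fn_inpatient")
    config$utilities$infection <- value
  config
}

#' Sample a configuration for probabilistic sensitivity analysis
#'
#' Draws one joint sample of every non-fixed parameter distribution.
#' Parameters printed per arm (severe-neutropenia risks, chemotherapy/
#' G-CSF cycle cost, infection per-day costs) are drawn independently
#' per arm; single-row parameters are shared between arms. The FN
#' inpatient episode cost scales with the sampled ward cost and length
#' of stay; the infection utility follows the FN inpatient utility; the
#' six RDI stratum risks are scaled by the ratios of the sampled RDI
#' ingredients (baseline risks, age relative risk, FN-history odds
#' ratio) to their base values. Out-of-range values are clipped
#' (probabilities to \[0, 1\], costs to non-negative) and clip events
#' counted.
#'
#' @param config A `cua_config`.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A `cua_config` with sampled point values, carrying
#'   attributes `psa_seed` and `n_clipped`.
#' @export
sample_config <- function(config, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- config
  n_clipped <- 0L
  base_rdi <- config$rdi
  for (nm in names(config$distributions)) {
    spec <- config$distributions[[nm]]
    if (spec$family == "fixed") next
    v <- dist_sample(spec, 1)
    if (startsWith(nm, "costs.")) {
      if (nm == "costs.fn_outpatient_episode") {
        # beta-distributed cost row sampled verbatim (published as is)
      } else if (v < 0) { v <- 0; n_clipped <- n_clipped + 1L }
    } else if (spec$family == "beta" || startsWith(nm, "utilities.")) {
      if (v < 0 || v > 1) { v <- min(max(v, 0), 1); n_clipped <- n_clipped + 1L }
    }
    if (nm %in% c("costs.fn_ward_per_day", "costs.fn_los_days")) {
      out <- set_model_param(out, nm, v)  # scales the episode cost
    } else if (grepl("^costs\\.infection_if_(fn|sn)_per_day\\.", nm)) {
      # one draw per arm, applied to the whole per-cycle cost vector
      # (the printed per-cycle values differ only marginally)
      vec <- config_get(out, nm)
      out <- config_set(out, nm, vec * v / vec[1])
    } else {
      out <- config_set(out, nm, v)
    }
  }
  out$utilities$infection <- out$utilities$fn_inpatient
  # propagate RDI ingredient uncertainty onto the stratum-level risks
  f_naive <- out$rdi$risk_low_lt65_no_fn / base_rdi$risk_low_lt65_no_fn
  f_sn <- out$rdi$risk_low_if_sn / base_rdi$risk_low_if_sn
  f_age <- out$rdi$rr_age_ge65 / base_rdi$rr_age_ge65
  f_fnh <- out$rdi$or_fn_history / base_rdi$or_fn_history
  for (band in c("lt65", "ge65")) {
    fb <- if (band == "ge65") f_age else 1
    s <- base_rdi$strata[[band]]
    s[["naive"]] <- s[["naive"]] * f_naive * fb
    s[["history"]] <- s[["history"]] * f_naive * f_fnh * fb
    s[["sn"]] <- s[["sn"]] * f_sn * fb
    clip <- s < 0 | s > 1
    n_clipped <- n_clipped + sum(clip)
    out$rdi$strata[[band]] <- pmin(pmax(s, 0), 1)
  }
  attr(out, "psa_seed") <- seed
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Probabilistic sensitivity analysis
#'
#' Runs the full two-model pipeline for both arms under `n_draws` joint
#' parameter samples (one master seed expanded into per-draw
#' substreams) and records the per-draw incremental cost and QALYs.
#'
#' @param config A `cua_config`.
#' @param n_draws Number of draws (base case uses 5000).
#' @param seed Master integer seed.
#' @param life_table,bc_table Mortality inputs (defaults synthetic).
#' @return An object of class `psa_result`: per-draw data.frame
#'   `draws` (`delta_cost`, `delta_qalys`, substream seed), quadrant
#'   shares on the cost-effectiveness plane, the probability that the
#'   lipegfilgrastim arm is cost-saving, and clip counts.
#' @export
run_psa <- function(config, n_draws = config$psa$n_draws, seed = 1L,
                    life_table = generate_life_table(),
                    bc_table = generate_bc_mortality()) {
  stopifnot(n_draws >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_draws)
  dc <- dq <- numeric(n_draws)
  clipped <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    cfg_i <- sample_config(config, sub_seeds[i])
    a <- arm_outcome("lipegfilgrastim", cfg_i, life_table, bc_table)
    b <- arm_outcome("pegfilgrastim", cfg_i, life_table, bc_table)
    dc[i] <- a$cost - b$cost
    dq[i] <- a$qalys - b$qalys
    clipped[i] <- attr(cfg_i, "n_clipped")
  }
  quadrants <- c(
    ne = mean(dq > 0 & dc > 0), se = mean(dq > 0 & dc <= 0),
    nw = mean(dq <= 0 & dc > 0), sw = mean(dq <= 0 & dc <= 0))
  structure(list(
    draws = data.frame(draw = seq_len(n_draws), seed = sub_seeds,
                       delta_cost = dc, delta_qalys = dq),
    n_draws = n_draws, seed = seed,
    quadrant_shares = quadrants,
    p_cost_saving = mean(dc < 0),
    n_clipped_total = sum(clipped)
  ), class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the strategy is cost-effective (net monetary
#' benefit > 0) at each willingness-to-pay value, across PSA draws.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Non-empty numeric vector of WTP values.
#' @return data.frame with columns `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1)
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$delta_qalys - psa$draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' One-way (deterministic) sensitivity analysis
#'
#' Re-runs the full model with each parameter set in turn to the bounds
#' of its 95% interval (from its assigned distribution) or +/-30% of
#' the base value where no distribution is available, all other
#' parameters held at base. Entries are returned sorted by the spread
#' in incremental cost; re-sort by `spread_qalys` for the QALY panel of
#' a tornado diagram.
#'
#' @param config A `cua_config`.
#' @param params Character vector of parameter paths; defaults to every
#'   distributed parameter plus the direct-input risks, cohort age and
#'   stage-mix shares.
#' @param life_table,bc_table Mortality inputs.
#' @return data.frame of class `owsa_result`, one row per parameter.
#' @export
owsa <- function(config, params = NULL,
                 life_table = generate_life_table(),
                 bc_table = generate_bc_mortality()) {
  if (is.null(params)) params <- owsa_default_params(config)
  base <- run_base_case(config, life_table, bc_table)
  rows <- lapply(params, function(nm) {
    bounds <- owsa_bounds(config, nm)
    res <- lapply(bounds, function(v) {
      cfg <- set_model_param(config, nm, v)
      inc <- run_base_case(cfg, life_table, bc_table)$incremental
      c(inc$delta_cost, inc$delta_qalys)
    })
    data.frame(parameter = nm, low = bounds[1], high = bounds[2],
               dcost_low = res[[1]][1], dcost_high = res[[2]][1],
               dqalys_low = res[[1]][2], dqalys_high = res[[2]][2],
               spread_cost = abs(res[[2]][1] - res[[1]][1]),
               spread_qalys = abs(res[[2]][2] - res[[1]][2]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread_cost), ]
  rownames(out) <- NULL
  attr(out, "base_incremental") <- base$incremental
  class(out) <- c("owsa_result", "data.frame")
  out
}

owsa_bounds <- function(config, nm) {
  spec <- config$distributions[[nm]]
  if (!is.null(spec) && spec$family != "fixed") return(dist_ci95(spec))
  v <- if (grepl("^cohort\\.stage_", nm))
    config$cohort$stage_mix[[sub("^cohort\\.stage_", "", nm)]]
  else config_get(config, nm)
  v * c(0.7, 1.3)
}

#' @rdname owsa
#' @export
owsa_default_params <- function(config) {
  direct <- c(
    sprintf("risks.fn_if_sn.%s.%d", rep(ARMS, each = 4), 1:4),
    sprintf("risks.delay_if_sn.%s.%d", rep(ARMS, each = 3), 2:4),
    sprintf("risks.delay_if_infection.%s.%d", rep(ARMS, each = 3), 2:4),
    "risks.death_delay", "cohort.age_start",
    "cohort.stage_II", "cohort.stage_III", "cohort.stage_IV")
  c(names(config$distributions), direct)
}

#' Net-monetary-benefit price threshold analysis
#'
#' Deterministic model re-runs across breast-cancer stages, age bands
#' and a grid of lipegfilgrastim prices. Each cell fixes the cohort to
#' one stage and one age band, overrides the lipegfilgrastim unit price
#' (the chemotherapy-cycle cost moves euro for euro) and records the
#' incremental net monetary benefit at the willingness-to-pay
#' threshold. The reported grid threshold is the largest grid price
#' with non-negative NMB in every cell; since NMB is linear in price,
#' the closed-form per-cell threshold
#' `price + NMB(price) / units` (with `units` the discounted number of
#' doses administered per patient) is also returned.
#'
#' @param config A `cua_config`.
#' @param price_grid Candidate lipegfilgrastim prices (default 1000 to
#'   2500 euro by 50).
#' @param wtp Willingness-to-pay per QALY (default 30000).
#' @param stages Stages to run (default II, III, IV).
#' @param age_bands Named vector mapping band labels to representative
#'   ages.
#' @param life_table,bc_table Mortality inputs.
#' @return List of class `threshold_result`: `cells` data.frame (one
#'   row per stage x band x price), `threshold_grid`,
#'   `threshold_closed_form`.
#' @export
price_threshold <- function(config,
                            price_grid = seq(1000, 2500, by = 50),
                            wtp = 30000,
                            stages = c("II", "III", "IV"),
                            age_bands = c("35-45" = 40, "45-55" = 50,
                                          "55-65" = 60, "65-75" = 70,
                                          "75+" = 80),
                            life_table = generate_life_table(),
                            bc_table = generate_bc_mortality()) {
  stopifnot(length(price_grid) >= 1)
  base_price <- config$costs$gcsf_unit_price[["lipegfilgrastim"]]
  cells <- list()
  closed <- c()
  for (stage in stages) for (band in names(age_bands)) {
    cfg <- config
    mix <- c(II = 0, III = 0, IV = 0); mix[stage] <- 1
    cfg$cohort$stage_mix <- mix
    cfg$cohort$age_start <- age_bands[[band]]
    ref <- run_base_case(cfg, life_table, bc_table, wtp = wtp)
    # full deterministic re-run at every candidate price
    nmb <- vapply(price_grid, function(price) {
      cfg_p <- cfg
      cfg_p$costs$gcsf_unit_price[["lipegfilgrastim"]] <- price
      cfg_p$costs$chemo_cycle[["lipegfilgrastim"]] <-
        cfg$costs$chemo_cycle[["lipegfilgrastim"]] - base_price + price
      run_base_case(cfg_p, life_table, bc_table, wtp = wtp)$incremental$nmb
    }, numeric(1))
    cells[[paste(stage, band)]] <- data.frame(
      stage = stage, age_band = band, price = price_grid, nmb = nmb)
    # independent closed form: NMB is linear in price with slope equal
    # to the (discounted) number of doses administered per patient
    units <- sum(ref$lipegfilgrastim$chemo$trace$on_chemo)
    closed[paste(stage, band)] <- base_price + ref$incremental$nmb / units
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  ok <- tapply(cells$nmb >= 0, cells$price, all)
  feasible <- as.numeric(names(ok))[ok]
  structure(list(
    cells = cells,
    wtp = wtp,
    threshold_grid = if (length(feasible)) max(feasible) else NA_real_,
    threshold_closed_form = min(closed),
    closed_form_by_cell = closed
  ), class = "threshold_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d): P(cost-saving) = %.1f%%\n",
              x$n_draws, x$seed, 100 * x$p_cost_saving))
  cat(sprintf("  CE-plane quadrants NE/SE/NW/SW: %.1f / %.1f / %.1f / %.1f %%\n",
              100 * x$quadrant_shares[["ne"]], 100 * x$quadrant_shares[["se"]],
              100 * x$quadrant_shares[["nw"]], 100 * x$quadrant_shares[["sw"]]))
  invisible(x)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> WTP %.0f: grid threshold %.0f, closed form %.1f\n",
              x$wtp, x$threshold_grid, x$threshold_closed_form))
  invisible(x)
}
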