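test_that("zero-risk cohort accrues only chemotherapy costs", {
  cfg <- zero_risk_config()
  for (arm in c("lipegfilgrastim", "pegfilgrastim")) {
    res <- run_chemo_model(arm, cfg)
    expect_equal(res$total_cost, 4 * 2098)
    expect_equal(unname(res$counts[c("sn", "fn", "infection", "delay")]),
                 rep(0, 4))
    expect_equal(res$final_state$dead, 0)
    expect_equal(res$exit_cohort$strata[["naive"]], 1)
    expect_equal(res$exit_cohort$rdi_ok, 1)
    expect_equal(res$exit_cohort$rdi_low, 0)
    expect_equal(res$ly, 4 * 21 / 365.25)
  }
})

test_that("an all-dead state is absorbing with zero accruals", {
  cfg <- base_case_config()
  state <- list(strata = c(naive = 0, sn = 0, fn = 0), dead = 1)
  step <- run_chemo_cycle(state, 2, "pegfilgrastim", cfg)
  expect_equal(step$state$strata, state$strata)
  expect_equal(step$state$dead, 1)
  expect_equal(sum(step$accrual$cost), 0)
  expect_equal(step$accrual$qaly, 0)
  expect_equal(step$accrual$ly, 0)
})

test_that("cohort mass is conserved at every cycle", {
  for (seed in 1:5) {
    cfg <- random_config(seed)
    for (arm in c("lipegfilgrastim", "pegfilgrastim")) {
      res <- run_chemo_model(arm, cfg)
      state <- list(strata = c(naive = 1, sn = 0, fn = 0), dead = 0)
      for (k in 1:4) {
        step <- run_chemo_cycle(state, k, arm, cfg)
        expect_lt(abs(sum(step$state$strata) + step$state$dead - 1), 1e-9)
        state <- step$state
      }
      expect_lt(abs(sum(res$final_state$strata) + res$final_state$dead - 1),
                1e-9)
      expect_lt(abs(res$exit_cohort$rdi_low + res$exit_cohort$rdi_ok -
                      sum(res$final_state$strata)), 1e-12)
    }
  }
})

test_that("cascade agrees with the path-enumeration oracle on random configs", {
  for (seed in 1:20) {
    cfg <- random_config(seed)
    for (arm in c("lipegfilgrastim", "pegfilgrastim")) {
      got <- run_chemo_model(arm, cfg)
      want <- oracle_chemo_model(arm, cfg)
      expect_equal(got$final_state$strata, want$state$strata,
                   tolerance = 1e-9, label = sprintf("strata seed %d", seed))
      expect_lt(abs(got$final_state$dead - want$state$dead), 1e-9)
      expect_equal(got$cost, want$cost, tolerance = 1e-9,
                   label = sprintf("cost seed %d", seed))
      expect_lt(abs(got$qalys - want$qaly), 1e-9)
      expect_lt(abs(got$ly - want$ly), 1e-9)
    }
  }
})

test_that("published cycle risks enter the trace as printed", {
  cfg <- base_case_config()
  state <- list(strata = c(naive = 1, sn = 0, fn = 0), dead = 0)
  s1 <- run_chemo_cycle(state, 1, "pegfilgrastim", cfg)
  expect_equal(s1$accrual$events[["sn"]], 0.511)
  # cycle-2 SN incidence is 0.215 x mass still on chemotherapy
  s2 <- run_chemo_cycle(s1$state, 2, "pegfilgrastim", cfg)
  expect_equal(s2$accrual$events[["sn"]], 0.215 * sum(s1$state$strata))
  expect_equal(s2$accrual$cost[["chemo"]], 2098 * sum(s1$state$strata))
})

test_that("lipegfilgrastim is cheaper than pegfilgrastim in the base case", {
  cfg <- base_case_config("direct_or")
  li <- run_chemo_model("lipegfilgrastim", cfg)
  pe <- run_chemo_model("pegfilgrastim", cfg)
  expect_lt(li$total_cost, pe$total_cost)
  expect_lt(li$final_state$dead, pe$final_state$dead)
})

test_that("identical arm inputs give exactly identical results", {
  cfg <- base_case_config()
  for (f in c("sn", "fn_if_sn", "infection_if_sn", "delay_if_sn",
              "delay_if_infection"))
    cfg$risks[[f]]$lipegfilgrastim <- cfg$risks[[f]]$pegfilgrastim
  cfg$risks$or_fn <- 1.0
  li <- run_chemo_model("lipegfilgrastim", cfg)
  pe <- run_chemo_model("pegfilgrastim", cfg)
  expect_identical(li$total_cost, pe$total_cost)
  expect_identical(li$qalys, pe$qalys)
  expect_identical(li$final_state, pe$final_state)
})

test_that("events and deaths are monotone in their driving risks", {
  cfg <- base_case_config()
  base <- run_chemo_model("pegfilgrastim", cfg)
  up <- cfg
  up$risks$sn$pegfilgrastim <- pmin(1, 2 * cfg$risks$sn$pegfilgrastim)
  res <- run_chemo_model("pegfilgrastim", up)
  for (ev in c("sn", "fn", "infection", "delay"))
    expect_gte(res$counts[[ev]], base$counts[[ev]])
  for (dr in c("death_fn", "death_sn", "death_infection", "death_delay")) {
    more <- base_case_config()
    more$risks[[dr]] <- min(1, cfg$risks[[dr]] * 5 + 0.01)
    resd <- run_chemo_model("pegfilgrastim", more)
    expect_gt(resd$final_state$dead, base$final_state$dead, label = dr)
  }
})

test_that("cycle QALY accrual matches hand arithmetic in simple cases", {
  cfg <- zero_risk_config()
  state <- list(strata = c(naive = 1, sn = 0, fn = 0), dead = 0)
  expect_equal(accrue_cycle_qalys(state, 1, "pegfilgrastim", cfg),
               0.700 * 21 / 365.25)
  # utilities 1 everywhere, no discounting: increment equals time lived
  cfg$utilities[c("chemo", "sn", "fn_inpatient", "fn_outpatient",
                  "infection")] <- list(1, 1, 1, 1, 1)
  cfg$utilities$delay_factor <- 1
  cfg$discount$qalys <- 0
  expect_equal(accrue_cycle_qalys(state, 1, "pegfilgrastim", cfg), 21 / 365.25)
})
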