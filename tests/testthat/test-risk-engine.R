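test_that("odds-ratio adjustment works on the odds scale", {
  # odds(0.032) = 0.0330579; x 0.981 = 0.0324298; back-transform
  expect_equal(apply_odds_ratio(0.032, 0.981), 0.0314111, tolerance = 1e-6)
  p <- c(0, 0.01, 0.3, 0.9)
  expect_equal(apply_odds_ratio(p, 1.0), p)
  expect_equal(apply_odds_ratio(0, 5), 0)
  expect_error(apply_odds_ratio(1, 2), "odds")
})

test_that("relative-risk adjustment is multiplicative and capped", {
  expect_equal(apply_relative_risk(0.032, 0.34), 0.01088)
  expect_equal(apply_relative_risk(0.5, 3.0), 1.0)
  p1 <- apportion_cycle1_fn_risk(0.032, 0.213, 4)
  expect_equal(truncate3(apply_relative_risk(p1, 0.213)), 0.004)
})

test_that("cycle-1 FN apportionment solves the linear split", {
  p1 <- apportion_cycle1_fn_risk(0.032, 0.213, 4)
  expect_equal(p1, 0.032 / (1 + 3 * 0.213), tolerance = 1e-12)
  expect_equal(truncate3(p1), 0.019)
  expect_equal(apportion_cycle1_fn_risk(0.04, 1.0, 4), 0.01)
  expect_equal(apportion_cycle1_fn_risk(0.032, 0.213, 1), 0.032)
  # exact compounding variant reproduces the total risk when composed
  p1e <- apportion_cycle1_fn_risk(0.032, 0.213, 4, exact = TRUE)
  expect_equal(1 - (1 - p1e) * (1 - p1e * 0.213)^3, 0.032, tolerance = 1e-9)
})

test_that("Bayes delay inversion multiplies prior odds by the likelihood ratio", {
  # odds 1 x (0.42/0.32) = 1.3125 -> 1.3125/2.3125
  expect_equal(bayes_event_given_delay(0.42, 0.32, 0.5), 0.5675676,
               tolerance = 1e-6)
  for (p in c(0.1, 0.5, 0.9))
    expect_equal(bayes_event_given_delay(0.3, 0.3, p), p)
  expect_equal(bayes_event_given_delay(0.42, 0.32, 0), 0)
  expect_equal(bayes_event_given_delay(0.42, 0, 0.5), 1)
})

test_that("Bayes posterior is monotone in the prior and the likelihood ratio", {
  priors <- seq(0.05, 0.95, by = 0.05)
  post <- vapply(priors, function(p) bayes_event_given_delay(0.42, 0.32, p),
                 numeric(1))
  expect_true(all(diff(post) > 0))
  lrs <- seq(0.1, 0.9, by = 0.1)
  post2 <- vapply(lrs, function(l) bayes_event_given_delay(l, 0.32, 0.4),
                  numeric(1))
  expect_true(all(diff(post2) > 0))
})

test_that("ANC-derived risk defaults to the configured pass-through", {
  cfg <- base_case_config()
  spec <- list(shape = cfg$anc$lipegfilgrastim$shape[1],
               scale = cfg$anc$lipegfilgrastim$scale[1],
               configured_risk = cfg$risks$fn_if_sn$lipegfilgrastim[1])
  expect_equal(anc_derived_event_risk(spec), 0.363)
  expect_error(anc_derived_event_risk(list(shape = 1, scale = 1)), "mapping")
})

test_that("ANC Monte-Carlo estimate converges to the analytic expectation", {
  const <- list(shape = 2, scale = 1.3, mapping = function(x) rep(0.25, length(x)))
  expect_equal(anc_derived_event_risk(const, n_draws = 100, seed = 7), 0.25)
  # step mapping: risk r below the threshold, 0 above -> r * P(X < thr)
  r <- 0.4; thr <- 0.5; shape <- 0.9; scale <- 1.4
  step <- list(shape = shape, scale = scale,
               mapping = function(x) ifelse(x < thr, r, 0))
  n <- 2e5
  est <- anc_derived_event_risk(step, n_draws = n, seed = 11)
  truth <- r * pgamma(thr, shape, scale = scale)
  se <- sqrt(truth * (r - truth) / n)  # binomial-style MC standard error
  expect_lt(abs(est - truth), 3 * max(se, 1e-4))
  # deterministic given seed, unchanged global RNG state
  expect_identical(est, anc_derived_event_risk(step, n_draws = n, seed = 11))
})

test_that("RDI stratum risks return the published direct inputs", {
  rdi <- base_case_config()$rdi
  expect_equal(rdi_low_risk("ge65", "history", rdi), 0.079)
  expect_equal(rdi_low_risk("lt65", "sn", rdi), 0.118)
  expect_equal(rdi_low_risk("lt65", "naive", rdi), 0.044)
  # age gradient of the printed values is consistent with the age RR
  ratio <- rdi_low_risk("ge65", "naive", rdi) / rdi_low_risk("lt65", "naive", rdi)
  expect_lt(abs(ratio - rdi$rr_age_ge65), 0.05)
  expect_error(rdi_low_risk("lt65", "unknown", rdi), "stratum")
  expect_error(rdi_low_risk("young", "naive", rdi), "age band")
})

test_that("low-RDI mortality adjustment acts on the cumulative hazard", {
  expect_equal(mortality_with_low_rdi(0.10, 1.32), 1 - 0.9^1.32)
  expect_equal(mortality_with_low_rdi(0.10, 1.32), 0.1298380, tolerance = 1e-6)
  expect_equal(mortality_with_low_rdi(0.07, 1.0), 0.07)
  expect_equal(mortality_with_low_rdi(0, 2.5), 0)
  for (p in c(0.01, 0.2, 0.6)) {
    expect_gte(mortality_with_low_rdi(p, 1.32), p)
    expect_lte(mortality_with_low_rdi(p, 0.8), p)
    expect_lt(mortality_with_low_rdi(p, 5), 1)
  }
})

test_that("FN-history multiplier applies only with history and is capped", {
  expect_equal(subsequent_fn_risk(0.004, TRUE, 9.089), 0.036356)
  expect_equal(subsequent_fn_risk(0.004, FALSE, 9.089), 0.004)
  expect_equal(subsequent_fn_risk(0.2, TRUE, 9.089), 1.0)
})

test_that("OR and RR agree for rare events", {
  # exact relative gap: p|f-1| / (1 + p(f-1)); tends to 0 as p -> 0
  for (p in c(0.005, 0.02, 0.05)) for (f in c(0.34, 0.8, 1.2, 2)) {
    por <- apply_odds_ratio(p, f)
    prr <- apply_relative_risk(p, f)
    rel <- abs(por - prr) / prr
    expect_lt(rel, p * abs(f - 1) / (1 + p * (f - 1)) + 1e-12,
              label = sprintf("p=%g factor=%g", p, f))
    if (p * abs(f - 1) <= 0.02) expect_lt(rel, 0.02)
  }
})

test_that("per-cycle base FN risks match the published derived values", {
  cfg <- base_case_config("direct_or")
  for (arm in c("lipegfilgrastim", "pegfilgrastim")) {
    p <- base_fn_cycle_risks(arm, cfg)
    expect_equal(truncate3(p), c(0.019, 0.004, 0.004, 0.004),
                 label = arm)
  }
  # RR source scales the whole lipegfilgrastim profile by 0.34
  cfg_rr <- base_case_config("direct_rr")
  p_li <- base_fn_cycle_risks("lipegfilgrastim", cfg_rr)
  p_pe <- base_fn_cycle_risks("pegfilgrastim", cfg_rr)
  expect_equal(p_li, p_pe * 0.34)
})
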