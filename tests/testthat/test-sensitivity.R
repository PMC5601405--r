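lt <- generate_life_table()
bc <- generate_bc_mortality()

test_that("sample_config is deterministic and respects fixed specs", {
  cfg <- base_case_config()
  s1 <- sample_config(cfg, 123)
  s2 <- sample_config(cfg, 123)
  expect_equal(unclass(s1)[names(s1) != "distributions"],
               unclass(s2)[names(s2) != "distributions"])
  s3 <- sample_config(cfg, 124)
  expect_false(identical(s1$costs$chemo_cycle, s3$costs$chemo_cycle))

  fixed <- cfg
  fixed$distributions <- lapply(fixed$distributions, function(s)
    dist_spec("fixed", point = s$point))
  sf <- sample_config(fixed, 99)
  expect_equal(sf$risks, cfg$risks)
  expect_equal(sf$costs, cfg$costs)
  expect_equal(sf$rdi$strata, cfg$rdi$strata)
})

test_that("sampled chemotherapy cost reproduces its gamma mean", {
  cfg <- base_case_config()
  spec <- cfg$distributions[["costs.chemo_cycle.lipegfilgrastim"]]
  set.seed(7)
  draws <- dist_sample(spec, 50000)
  se <- sqrt(spec$p1) * spec$p2 / sqrt(50000)
  expect_lt(abs(mean(draws) - 2098), 3 * se)
  # and the full joint draw places the sampled value into the config
  s <- sample_config(cfg, 5)
  expect_false(s$costs$chemo_cycle[["lipegfilgrastim"]] ==
                 cfg$costs$chemo_cycle[["lipegfilgrastim"]])
  expect_equal(s$utilities$infection, s$utilities$fn_inpatient)
})

test_that("arm-specific parameters are sampled independently per arm", {
  cfg <- base_case_config()
  s <- sample_config(cfg, 31)
  expect_false(s$costs$chemo_cycle[["lipegfilgrastim"]] ==
                 s$costs$chemo_cycle[["pegfilgrastim"]])
  expect_false(s$risks$sn$lipegfilgrastim[1] == s$risks$sn$pegfilgrastim[1])
  # shared single-row parameters equal across arms by construction
  expect_equal(s$costs$infection_if_fn_per_day$lipegfilgrastim /
                 cfg$costs$infection_if_fn_per_day$lipegfilgrastim,
               rep(s$costs$infection_if_fn_per_day$lipegfilgrastim[1] / 3284, 4))
})

test_that("PSA with all-fixed distributions reproduces the base case", {
  cfg <- base_case_config()
  cfg$distributions <- lapply(cfg$distributions, function(s)
    dist_spec("fixed", point = s$point))
  base <- run_base_case(cfg, lt, bc)
  psa <- run_psa(cfg, n_draws = 3, seed = 1, life_table = lt, bc_table = bc)
  expect_equal(psa$draws$delta_cost,
               rep(base$incremental$delta_cost, 3), tolerance = 1e-12)
  expect_equal(psa$draws$delta_qalys,
               rep(base$incremental$delta_qalys, 3), tolerance = 1e-12)
})

test_that("PSA quadrant shares sum to one and CEAC anchors at cost-saving", {
  psa <- run_psa(base_case_config(), n_draws = 60, seed = 11,
                 life_table = lt, bc_table = bc)
  expect_equal(sum(psa$quadrant_shares), 1)
  cc <- ceac(psa, c(0, 10000, 30000))
  expect_identical(cc$probability[cc$wtp == 0], psa$p_cost_saving)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # identical seed reruns identically
  psa2 <- run_psa(base_case_config(), n_draws = 60, seed = 11,
                  life_table = lt, bc_table = bc)
  expect_identical(psa$draws, psa2$draws)
})

test_that("CEAC is non-decreasing when every draw gains QALYs", {
  fake <- structure(list(draws = data.frame(
    draw = 1:4, seed = 1:4,
    delta_cost = c(-200, -50, 100, 400),
    delta_qalys = c(0.01, 0.05, 0.002, 0.08))), class = "psa_result")
  cc <- ceac(fake, seq(0, 1e5, 5e3))
  expect_true(all(diff(cc$probability) >= 0))
  alldom <- structure(list(draws = data.frame(
    draw = 1:3, seed = 1:3, delta_cost = c(-10, -5, -1),
    delta_qalys = c(0.1, 0.2, 0.3))), class = "psa_result")
  expect_true(all(ceac(alldom, c(0, 2e4))$probability == 1))
})

test_that("one-way sensitivity keeps base results at base values", {
  cfg <- base_case_config()
  base <- run_base_case(cfg, lt, bc)$incremental
  for (nm in c("costs.chemo_cycle.lipegfilgrastim", "utilities.survivor_gt5",
               "cohort.stage_III")) {
    v <- if (nm == "cohort.stage_III") cfg$cohort$stage_mix[["III"]]
         else config_get(cfg, nm)
    cfg2 <- set_model_param(cfg, nm, v)
    inc <- run_base_case(cfg2, lt, bc)$incremental
    expect_equal(inc$delta_cost, base$delta_cost, tolerance = 1e-12, label = nm)
    expect_equal(inc$delta_qalys, base$delta_qalys, tolerance = 1e-12)
  }
})

test_that("tornado ranks the lipegfilgrastim drug cost first for costs", {
  cfg <- base_case_config()
  params <- c("costs.chemo_cycle.lipegfilgrastim",
              "risks.sn.lipegfilgrastim.1", "risks.fn_if_sn.lipegfilgrastim.1",
              "utilities.survivor_gt5", "risks.infection_if_fn")
  tor <- owsa(cfg, params = params, life_table = lt, bc_table = bc)
  expect_identical(tor$parameter[1], "costs.chemo_cycle.lipegfilgrastim")
  # raising the lipegfilgrastim drug cost by 30% flips the cost saving
  row <- tor[tor$parameter == "costs.chemo_cycle.lipegfilgrastim", ]
  hi <- set_model_param(cfg, "costs.chemo_cycle.lipegfilgrastim", 2098 * 1.3)
  expect_gt(run_base_case(hi, lt, bc)$incremental$delta_cost, 0)
  expect_true(all(tor$spread_cost >= 0))
  # a zero-width range (zero-valued base parameter) yields zero spread
  tor0 <- owsa(cfg, params = "costs.delay", life_table = lt, bc_table = bc)
  expect_equal(tor0$spread_cost, 0)
  expect_equal(tor0$spread_qalys, 0)
  b <- owsa_bounds(cfg, "risks.death_delay")
  expect_equal(b, 0.001 * c(0.7, 1.3))
})

test_that("price threshold NMB decreases in price and matches the closed form", {
  cfg <- base_case_config()
  grid <- seq(1100, 2000, by = 100)
  th <- price_threshold(cfg, price_grid = grid, wtp = 30000,
                        stages = c("II", "IV"),
                        age_bands = c("55-65" = 60, "75+" = 80),
                        life_table = lt, bc_table = bc)
  for (key in split(th$cells, interaction(th$cells$stage, th$cells$age_band))) {
    if (!nrow(key)) next
    expect_true(all(diff(key$nmb) < 0))
  }
  at_current <- th$cells[th$cells$price == 1200, ]
  expect_true(all(at_current$nmb > 0))
  expect_lte(abs(th$threshold_grid - th$threshold_closed_form), 100)
  expect_gte(th$threshold_closed_form, th$threshold_grid)
})
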