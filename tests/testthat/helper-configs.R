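# Configuration fixtures built in code.

# all event risks zero: patients glide through chemotherapy untouched
zero_risk_config <- function() {
  cfg <- base_case_config()
  z4 <- list(lipegfilgrastim = rep(0, 4), pegfilgrastim = rep(0, 4))
  cfg$risks[c("sn", "fn_if_sn", "infection_if_sn",
              "delay_if_sn", "delay_if_infection")] <-
    list(z4, z4, z4, z4, z4)
  cfg$risks$baseline_fn_total <- 0
  cfg$risks$death_fn <- cfg$risks$death_sn <- 0
  cfg$risks$death_infection <- cfg$risks$death_delay <- 0
  cfg$rdi$strata <- list(lt65 = c(naive = 0, history = 0, sn = 0),
                         ge65 = c(naive = 0, history = 0, sn = 0))
  cfg
}

# randomly perturbed but valid configuration for oracle comparisons
random_config <- function(seed) {
  set.seed(seed)
  cfg <- base_case_config()
  r4 <- function(lo, hi) list(lipegfilgrastim = runif(4, lo, hi),
                              pegfilgrastim = runif(4, lo, hi))
  cfg$risks$sn <- r4(0.02, 0.6)
  cfg$risks$fn_if_sn <- r4(0, 0.5)
  cfg$risks$infection_if_sn <- r4(0, 0.5)
  d4 <- function() lapply(r4(0, 0.4), function(v) { v[1] <- 0; v })
  cfg$risks$delay_if_sn <- d4()
  cfg$risks$delay_if_infection <- d4()
  cfg$risks$baseline_fn_total <- runif(1, 0.005, 0.15)
  cfg$risks$or_fn <- runif(1, 0.3, 2)
  cfg$risks$rr_fn_cycle2plus <- runif(1, 0.1, 1.5)
  cfg$risks$rr_additional_fn <- runif(1, 1, 10)
  cfg$risks$infection_if_fn <- runif(1, 0, 0.6)
  cfg$risks$death_fn <- runif(1, 0, 0.1)
  cfg$risks$death_sn <- runif(1, 0, 0.05)
  cfg$risks$death_infection <- runif(1, 0, 0.1)
  cfg$risks$death_delay <- runif(1, 0, 0.02)
  cfg$risks$hospitalization_if_fn <- runif(1)
  cfg$costs$infection_days <- sample(1:5, 1)
  cfg
}

# minimal flat mortality fixtures
flat_life_table <- function(q, age_start = 35, max_age = 100) {
  structure(data.frame(age = age_start:max_age, qx = q),
            class = c("life_table", "data.frame"))
}
zero_bc_table <- function() generate_bc_mortality(
  stage_base = c(II = 0, III = 0, IV = 0))
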