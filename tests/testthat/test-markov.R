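test_that("transition matrices are row-stochastic with an absorbing dead state", {
  lt <- generate_gompertz_life_table()
  set.seed(13)
  for (i in 1:30) {
    arm <- random_arm()
    age <- sample(65:105, 1)
    P <- build_transition_matrix(age, sample(c("female", "male"), 1), arm, lt)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(rowSums(P)), c(1, 1, 1), tolerance = 1e-12)
    expect_equal(P["dead", "dead"], 1)
    if (arm$recovery == 0) expect_equal(P["deteriorated", "baseline"], 0)
  }
})

test_that("neutral and degenerate parameters give the expected matrices", {
  lt <- generate_gompertz_life_table()
  neutral <- arm_parameters(0, 0, 1, 1, 0, 0, 0, 0, 0.7, 0.3)
  P <- build_transition_matrix(80, "female", neutral, lt)
  q <- qx_at(lt, 80, "female")
  expect_equal(P["baseline", "dead"], q)
  expect_equal(P["deteriorated", "dead"], q)
  expect_equal(P["baseline", "deteriorated"], 0)
  expect_equal(P["deteriorated", "baseline"], 0)

  # zero mortality: incidence applies in full
  lt0 <- constant_life_table(0)
  arm <- arm_parameters(0.4, 0.1, 1, 1.51, 0, 0, 0, 0, 0.7, 0.27)
  P0 <- build_transition_matrix(70, "male", arm, lt0)
  expect_equal(P0["baseline", "dead"], 0)
  expect_equal(P0["deteriorated", "dead"], 0)
  expect_equal(P0["baseline", "deteriorated"], 0.4)

  # extreme RR is capped at probability 1
  lt_hi <- constant_life_table(0.9)
  P_hi <- build_transition_matrix(70, "male", arm, lt_hi)
  expect_equal(P_hi["deteriorated", "dead"], 1)
})

test_that("deteriorated-state death probability orders with the arm RRs at every age", {
  lt <- generate_gompertz_life_table()
  arms <- build_paper_arms()
  for (age in 65:105) {
    for (sex in c("female", "male")) {
      Pc <- build_transition_matrix(age, sex, arms$control, lt)
      Pi <- build_transition_matrix(age, sex, arms$intervention, lt)
      expect_gte(Pc["deteriorated", "dead"], Pi["deteriorated", "dead"])
      expect_equal(Pc["baseline", "dead"], Pi["baseline", "dead"])
    }
  }
})

test_that("cohort simulation matches exhaustive path enumeration on short horizons", {
  lt <- generate_gompertz_life_table()
  set.seed(99)
  for (i in 1:40) {
    arm <- random_arm()
    h <- sample(1:3, 1)
    age <- sample(65:100, 1)
    pb <- runif(1)
    cfg <- model_config(horizon_cycles = h,
                        initial_state_distribution = c(baseline = pb,
                                                       deteriorated = 1 - pb))
    sex <- sample(c("female", "male"), 1)
    traj <- simulate_cohort(age, sex, arm, cfg, lt)
    mats <- lapply(0:(h - 1), function(t)
      build_transition_matrix(age + t, sex, arm, lt))
    oracle <- enumerate_occupancy(c(pb, 1 - pb, 0), mats)
    expect_equal(traj$p_baseline, oracle[, 1], tolerance = 1e-12)
    expect_equal(traj$p_deteriorated, oracle[, 2], tolerance = 1e-12)
    expect_equal(traj$p_dead, oracle[, 3], tolerance = 1e-12)
  }
})

test_that("trajectories conserve probability and respect state monotonicity", {
  lt <- generate_gompertz_life_table()
  set.seed(21)
  for (i in 1:25) {
    arm <- random_arm()
    cfg <- model_config(horizon_cycles = sample(1:30, 1))
    traj <- simulate_cohort(sample(65:75, 1), "female", arm, cfg, lt)
    total <- traj$p_baseline + traj$p_deteriorated + traj$p_dead
    expect_true(all(abs(total - 1) < 1e-10))
    expect_true(all(diff(traj$p_dead) >= -1e-12))
  }
  # without recovery the baseline state only drains
  no_rec <- arm_parameters(0.4, 0, 1, 1.51, 0, 0, 0, 0, 0.7, 0.27)
  cfg <- model_config(horizon_cycles = 20,
                      initial_state_distribution = c(baseline = 0.6,
                                                     deteriorated = 0.4))
  traj <- simulate_cohort(70, "male", no_rec, cfg, lt)
  expect_true(all(diff(traj$p_baseline) <= 1e-12))
})

test_that("horizon zero returns the initial distribution and range errors propagate", {
  lt <- generate_gompertz_life_table(age_min = 65, age_max = 90)
  arm <- build_paper_arms()$control
  cfg0 <- model_config(horizon_cycles = 0,
                       initial_state_distribution = c(baseline = 0.3,
                                                      deteriorated = 0.7))
  traj <- simulate_cohort(80, "female", arm, cfg0, lt)
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$p_baseline, 0.3)
  expect_equal(traj$p_deteriorated, 0.7)
  expect_equal(traj$p_dead, 0)

  cfg_long <- model_config(horizon_cycles = 30)
  expect_error(simulate_cohort(80, "female", arm, cfg_long, lt), "outside")
})

test_that("outcome accumulation matches hand arithmetic", {
  # one cycle, everyone starts deteriorated, death probability exactly 0.5
  lt <- constant_life_table(0.5)
  arm <- arm_parameters(0.4, 0, 1, 1, 0, 2265.68, 0, 0, 0.70, 0.27,
                        label = "control")
  cfg <- model_config(horizon_cycles = 1)
  out <- accumulate_outcomes(simulate_cohort(70, "female", arm, cfg, lt),
                             arm, cfg)
  expect_equal(out$total_cost, 0.5 * 2265.68, tolerance = 1e-12)
  expect_equal(out$total_qalys, 0.5 * 0.27, tolerance = 1e-12)

  # full health, no deaths, H cycles, no discounting -> H QALYs
  lt0 <- constant_life_table(0)
  full <- arm_parameters(0, 0, 1, 1, 0, 0, 0, 0, 1, 1)
  H <- 7
  cfgH <- model_config(horizon_cycles = H,
                       initial_state_distribution = c(baseline = 1,
                                                      deteriorated = 0))
  outH <- accumulate_outcomes(simulate_cohort(70, "male", full, cfgH, lt0),
                              full, cfgH)
  expect_equal(outH$total_qalys, H, tolerance = 1e-12)
  expect_equal(outH$total_cost, 0)
})

test_that("discounting, one-off costs and the recurrent-cost scope enter as specified", {
  lt0 <- constant_life_table(0)
  arm <- arm_parameters(0, 0, 1, 1, 100, 0, 10, 50, 1, 0.5)
  cfg <- model_config(horizon_cycles = 3, discount_rate_costs = 0.1,
                      discount_rate_effects = 0.05,
                      initial_state_distribution = c(baseline = 1,
                                                     deteriorated = 0))
  out <- accumulate_outcomes(simulate_cohort(70, "female", arm, cfg, lt0),
                             arm, cfg)
  # cost: 50 one-off at t=0, then (100 + 10)/1.1^(t-1) for t = 1..3
  expect_equal(out$total_cost, 50 + 110 * sum(1 / 1.1^(0:2)),
               tolerance = 1e-12)
  expect_equal(out$total_qalys, sum(1 / 1.05^(0:2)), tolerance = 1e-12)

  # recurrent cost restricted to the deteriorated state
  cfg_det <- model_config(horizon_cycles = 3, recurrent_cost_scope = "deteriorated",
                          initial_state_distribution = c(baseline = 1,
                                                         deteriorated = 0))
  out_det <- accumulate_outcomes(simulate_cohort(70, "female", arm, cfg_det,
                                                 lt0), arm, cfg_det)
  expect_equal(out_det$total_cost, 50 + 3 * 100, tolerance = 1e-12)
})

test_that("half-cycle correction averages start- and end-of-cycle occupancy", {
  lt <- constant_life_table(0.5)
  arm <- arm_parameters(0, 0, 1, 1, 0, 1000, 0, 0, 0.7, 0.5)
  cfg <- model_config(horizon_cycles = 1, half_cycle_correction = TRUE)
  out <- accumulate_outcomes(simulate_cohort(70, "female", arm, cfg, lt),
                             arm, cfg)
  # deteriorated occupancy: 1 at cycle 0, 0.5 at cycle 1 -> valued at 0.75
  expect_equal(out$total_cost, 750, tolerance = 1e-12)
  expect_equal(out$total_qalys, 0.75 * 0.5, tolerance = 1e-12)
})

test_that("totals are monotone in utilities and costs", {
  lt <- generate_gompertz_life_table()
  cfg <- model_config(horizon_cycles = 10)
  set.seed(31)
  for (i in 1:10) {
    arm <- random_arm()
    bump_u <- arm
    bump_u$utility_deteriorated <- min(1, arm$utility_deteriorated + 0.1)
    bump_c <- arm
    bump_c$cost_deteriorated <- arm$cost_deteriorated + 100
    base <- accumulate_outcomes(simulate_cohort(70, "female", arm, cfg, lt),
                                arm, cfg)
    up_u <- accumulate_outcomes(simulate_cohort(70, "female", bump_u, cfg, lt),
                                bump_u, cfg)
    up_c <- accumulate_outcomes(simulate_cohort(70, "female", bump_c, cfg, lt),
                                bump_c, cfg)
    expect_gte(up_u$total_qalys, base$total_qalys)
    expect_gte(up_c$total_cost, base$total_cost)
  }
})

test_that("sex-mixed outcomes interpolate the per-sex outcomes", {
  lt <- generate_gompertz_life_table(a = c(female = 2e-5, male = 4e-5),
                                     b = 0.095)
  arms <- build_paper_arms()
  cfg <- model_config(horizon_cycles = 5, sex_mix = 0.75)
  mixed <- mixed_arm_outcome(70, arms$control, cfg, lt)
  f <- accumulate_outcomes(simulate_cohort(70, "female", arms$control, cfg, lt),
                           arms$control, cfg)
  m <- accumulate_outcomes(simulate_cohort(70, "male", arms$control, cfg, lt),
                           arms$control, cfg)
  expect_equal(mixed$total_cost, 0.75 * f$total_cost + 0.25 * m$total_cost,
               tolerance = 1e-12)
  expect_equal(mixed$total_qalys, 0.75 * f$total_qalys + 0.25 * m$total_qalys,
               tolerance = 1e-12)
})

test_that("trajectory CSV export round-trips numerically at 6 decimals", {
  lt <- generate_gompertz_life_table()
  arm <- build_paper_arms()$control
  cfg <- model_config(horizon_cycles = 10)
  traj <- simulate_cohort(75, "female", arm, cfg, lt)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- utils::read.csv(path)
  expect_equal(back$p_dead, traj$p_dead, tolerance = 1e-6)
  expect_identical(names(back),
                   c("cycle", "age", "p_baseline", "p_deteriorated", "p_dead"))
})
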