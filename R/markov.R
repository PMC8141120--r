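STATES <- c("baseline", "deteriorated", "dead")

#' Per-cycle transition matrix at one age
#'
#' Builds the 3x3 transition matrix over the states baseline health,
#' deteriorated health and dead, at a given age. Death is resolved first:
#' the per-cycle death probability of each alive state is the life-table
#' annual death probability multiplied by that state's mortality relative
#' risk, capped at 1. Incidence (baseline -> deteriorated) and recovery
#' (deteriorated -> baseline) then apply among survivors, so an incidence
#' of 0.40 means 40% of the cycle's survivors of the baseline state
#' deteriorate. The dead state is absorbing.
#'
#' @param age Integer age within the life-table range.
#' @param sex `"female"` or `"male"`.
#' @param arm An `arm_parameters`.
#' @param lt A `life_table`.
#' @return A 3x3 row-stochastic matrix with dimnames
#'   `c("baseline", "deteriorated", "dead")`.
#' @export
build_transition_matrix <- function(age, sex, arm, lt) {
  q <- qx_at(lt, age, sex)
  p_death_base <- min(1, arm$rr_baseline * q)
  p_death_det <- min(1, arm$rr_deteriorated * q)
  m <- matrix(0, 3, 3, dimnames = list(STATES, STATES))
  m["baseline", "dead"] <- p_death_base
  m["baseline", "deteriorated"] <- (1 - p_death_base) * arm$incidence
  m["baseline", "baseline"] <- (1 - p_death_base) * (1 - arm$incidence)
  m["deteriorated", "dead"] <- p_death_det
  m["deteriorated", "baseline"] <- (1 - p_death_det) * arm$recovery
  m["deteriorated", "deteriorated"] <- (1 - p_death_det) * (1 - arm$recovery)
  m["dead", "dead"] <- 1
  m
}

#' Simulate a cohort through the three-state model
#'
#' Propagates the cohort's state-occupancy distribution over annual cycles:
#' `occupancy(t + 1) = occupancy(t) %*% P(start_age + t)`, with the
#' transition matrix rebuilt each cycle at the cohort's current age so that
#' mortality tracks the life table. Cycle 0 is the initial distribution
#' (nobody starts dead).
#'
#' @param start_age Integer starting age; `start_age + horizon` must stay
#'   within the life-table range.
#' @param sex `"female"` or `"male"`.
#' @param arm An `arm_parameters`.
#' @param cfg A `model_config` (supplies the horizon and initial
#'   distribution).
#' @param lt A `life_table`.
#' @return An `occupancy_trajectory`: a data frame with columns `cycle`,
#'   `age`, `p_baseline`, `p_deteriorated`, `p_dead` and attributes
#'   `start_age`, `sex`, `arm`.
#' @export
simulate_cohort <- function(start_age, sex, arm, cfg, lt) {
  h <- cfg$horizon_cycles
  ages_needed <- if (h > 0) start_age + 0:(h - 1) else integer(0)
  if (h > 0) qx_at(lt, ages_needed, sex)  # range check up front
  occ <- matrix(0, nrow = h + 1, ncol = 3, dimnames = list(NULL, STATES))
  occ[1, ] <- c(cfg$initial_state_distribution[["baseline"]],
                cfg$initial_state_distribution[["deteriorated"]], 0)
  if (h > 0) {
    for (t in seq_len(h)) {
      P <- build_transition_matrix(start_age + t - 1, sex, arm, lt)
      occ[t + 1, ] <- occ[t, , drop = FALSE] %*% P
    }
  }
  out <- data.frame(cycle = 0:h, age = start_age + 0:h,
                    p_baseline = occ[, "baseline"],
                    p_deteriorated = occ[, "deteriorated"],
                    p_dead = occ[, "dead"])
  structure(out, class = c("occupancy_trajectory", "data.frame"),
            start_age = start_age, sex = sex, arm = arm$label)
}

#' Accumulate discounted costs and QALYs over a trajectory
#'
#' State membership is valued at end of cycle: for each cycle t >= 1 the
#' cost contribution is occupancy-weighted annual state costs (plus the
#' recurrent intervention cost over the configured scope), and the QALY
#' contribution is occupancy-weighted state utilities, each discounted by
#' `(1 + r)^(t - 1)`. The dead state contributes nothing. The one-off
#' intervention cost is charged undiscounted at cycle 0 to the whole
#' starting cohort. With `half_cycle_correction = TRUE` the cycle-t
#' occupancy is replaced by the average of the occupancies at t - 1 and t.
#'
#' @param traj An `occupancy_trajectory` produced under the same config.
#' @param arm The `arm_parameters` used to produce it.
#' @param cfg The `model_config` used to produce it.
#' @return An `arm_outcome`: list with `total_cost`, `total_qalys`,
#'   `cost_by_cycle`, `qaly_by_cycle` (each length `horizon + 1`, cycle 0
#'   first) and `trajectory`.
#' @export
accumulate_outcomes <- function(traj, arm, cfg) {
  h <- cfg$horizon_cycles
  if (nrow(traj) != h + 1) {
    stop("trajectory has ", nrow(traj) - 1, " cycles but config expects ", h,
         call. = FALSE)
  }
  cost_by_cycle <- numeric(h + 1)
  qaly_by_cycle <- numeric(h + 1)
  cost_by_cycle[1] <- arm$intervention_oneoff_cost  # whole cohort alive at t=0
  if (h > 0) {
    for (t in seq_len(h)) {
      pb <- traj$p_baseline[t + 1]
      pd <- traj$p_deteriorated[t + 1]
      if (cfg$half_cycle_correction) {
        pb <- (traj$p_baseline[t] + pb) / 2
        pd <- (traj$p_deteriorated[t] + pd) / 2
      }
      recurrent_pop <- if (cfg$recurrent_cost_scope == "alive") pb + pd else pd
      cost <- pb * arm$cost_baseline + pd * arm$cost_deteriorated +
        recurrent_pop * arm$intervention_recurrent_cost
      qaly <- pb * arm$utility_baseline + pd * arm$utility_deteriorated
      cost_by_cycle[t + 1] <- cost / (1 + cfg$discount_rate_costs)^(t - 1)
      qaly_by_cycle[t + 1] <- qaly / (1 + cfg$discount_rate_effects)^(t - 1)
    }
  }
  structure(list(total_cost = sum(cost_by_cycle),
                 total_qalys = sum(qaly_by_cycle),
                 cost_by_cycle = cost_by_cycle,
                 qaly_by_cycle = qaly_by_cycle,
                 trajectory = traj),
            class = "arm_outcome")
}

#' Sex-mixed arm outcome at one starting age
#'
#' Simulates the female and male cohorts separately and mixes their
#' discounted totals (and per-cycle contributions) by the configured
#' fraction of women (default 0.75).
#'
#' @inheritParams simulate_cohort
#' @return An `arm_outcome` whose `trajectory` is a list with elements
#'   `female` and `male`.
#' @export
mixed_arm_outcome <- function(start_age, arm, cfg, lt) {
  w <- cfg$sex_mix
  out_f <- accumulate_outcomes(
    simulate_cohort(start_age, "female", arm, cfg, lt), arm, cfg)
  out_m <- accumulate_outcomes(
    simulate_cohort(start_age, "male", arm, cfg, lt), arm, cfg)
  structure(list(
    total_cost = w * out_f$total_cost + (1 - w) * out_m$total_cost,
    total_qalys = w * out_f$total_qalys + (1 - w) * out_m$total_qalys,
    cost_by_cycle = w * out_f$cost_by_cycle + (1 - w) * out_m$cost_by_cycle,
    qaly_by_cycle = w * out_f$qaly_by_cycle + (1 - w) * out_m$qaly_by_cycle,
    trajectory = list(female = out_f$trajectory, male = out_m$trajectory)
  ), class = "arm_outcome")
}

#' Write an occupancy trajectory as CSV
#'
#' Columns `cycle,age,p_baseline,p_deteriorated,p_dead`.
#'
#' @param traj An `occupancy_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(format_floats(as.data.frame(traj)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_floats <- function(df, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf(paste0("%.", digits, "f"), x))
  df
}
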