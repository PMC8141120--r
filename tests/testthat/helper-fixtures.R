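# Shared fixtures and independent oracles.

# Life table with the same constant qx at every age, both sexes.
constant_life_table <- function(qx, age_min = 65, age_max = 110) {
  ages <- age_min:age_max
  df <- rbind(
    data.frame(age = ages, sex = "female", qx = qx),
    data.frame(age = ages, sex = "male", qx = qx)
  )
  validate_life_table(df)
}

# Random arm parameters for property-style tests.
random_arm <- function(label = "arm") {
  arm_parameters(
    incidence = runif(1), recovery = runif(1),
    rr_baseline = runif(1, 0, 2), rr_deteriorated = runif(1, 0, 2),
    cost_baseline = runif(1, 0, 5000), cost_deteriorated = runif(1, 0, 5000),
    intervention_recurrent_cost = runif(1, 0, 100),
    intervention_oneoff_cost = runif(1, 0, 100),
    utility_baseline = runif(1), utility_deteriorated = runif(1),
    label = label)
}

# Independent oracle: cohort occupancy by exhaustive enumeration of all
# state paths, multiplying scalar transition probabilities along each path.
# `mats` is a list of per-cycle 3x3 matrices (cycle 1 first).
enumerate_occupancy <- function(start_dist, mats) {
  states <- 1:3
  h <- length(mats)
  occ <- matrix(0, nrow = h + 1, ncol = 3)
  occ[1, ] <- start_dist
  if (h == 0) return(occ)
  paths <- expand.grid(rep(list(states), h + 1))
  for (r in seq_len(nrow(paths))) {
    p <- start_dist[paths[r, 1]]
    for (t in seq_len(h)) {
      p <- p * mats[[t]][paths[r, t], paths[r, t + 1]]
    }
    for (t in seq_len(h)) {
      occ[t + 1, paths[r, t + 1]] <- occ[t + 1, paths[r, t + 1]] + p
    }
  }
  occ
}

# Independent oracle: boxes by day-by-day unit accumulation.
boxes_brute_force <- function(u, a, upb, days) {
  units <- 0
  for (d in seq_len(min(days, 365))) units <- units + u * a
  ceiling(units / upb)
}
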