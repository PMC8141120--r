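#' Read / write a full model configuration (YAML)
#'
#' A configuration file has three top-level blocks: `model` (the
#' [model_config()] fields), `control` and `intervention` (each an
#' [arm_parameters()] block with keys named exactly as the constructor
#' arguments). The packaged base case,
#' `system.file("extdata", "paper_base_case.yaml", package = "demcua")`,
#' reproduces the published parameter table.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `cfg` (a `model_config`), `control` and
#'   `intervention` (each `arm_parameters`).
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (block in c("model", "control", "intervention")) {
    if (is.null(raw[[block]])) {
      stop(path, ": missing '", block, "' block", call. = FALSE)
    }
  }
  m <- raw$model
  dist <- m$initial_state_distribution
  cfg <- model_config(
    age_min = m$age_min %||% 65L,
    age_max = m$age_max %||% 90L,
    horizon_cycles = m$horizon_cycles %||% 1L,
    discount_rate_costs = m$discount_rate_costs %||% 0,
    discount_rate_effects = m$discount_rate_effects %||% 0,
    initial_state_distribution = if (is.null(dist)) {
      c(baseline = 0, deteriorated = 1)
    } else unlist(dist),
    sex_mix = m$sex_mix %||% 0.75,
    population_size = m$population_size %||% 200L,
    wtp_threshold = m$wtp_threshold %||% 15000,
    half_cycle_correction = m$half_cycle_correction %||% FALSE,
    recurrent_cost_scope = m$recurrent_cost_scope %||% "alive",
    population_start_age = m$population_start_age %||% 87L
  )
  arm_from <- function(block, label) {
    arm_parameters(
      incidence = block$incidence, recovery = block$recovery,
      rr_baseline = block$rr_baseline,
      rr_deteriorated = block$rr_deteriorated,
      cost_baseline = block$cost_baseline,
      cost_deteriorated = block$cost_deteriorated,
      intervention_recurrent_cost = block$intervention_recurrent_cost %||% 0,
      intervention_oneoff_cost = block$intervention_oneoff_cost %||% 0,
      utility_baseline = block$utility_baseline,
      utility_deteriorated = block$utility_deteriorated,
      label = label)
  }
  list(cfg = cfg,
       control = arm_from(raw$control, "control"),
       intervention = arm_from(raw$intervention, "intervention"))
}

#' @rdname read_model_config
#' @param cfg A `model_config`.
#' @param control,intervention `arm_parameters` for the two arms.
#' @export
write_model_config <- function(cfg, control, intervention, path) {
  arm_list <- function(a) {
    a <- unclass(a)
    a$label <- NULL
    a
  }
  model <- unclass(cfg)
  model$initial_state_distribution <- as.list(model$initial_state_distribution)
  yaml::write_yaml(list(model = model,
                        control = arm_list(control),
                        intervention = arm_list(intervention)), path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
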