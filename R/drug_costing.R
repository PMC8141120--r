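#' Construct a prescription record
#'
#' One drug line of a patient's therapeutic plan, carrying what the boxes
#' algorithm needs: dose (units per administration), frequency
#' (administrations per day), pack size, pack price and treatment length.
#' Treatment length is capped at 365 days when costing: a course longer than
#' a year is costed as one year.
#'
#' @param drug_name Character label.
#' @param units_per_administration Positive number of units taken each time.
#' @param administrations_per_day Positive number of administrations per day.
#' @param units_per_box Positive integer pack size (>= 1).
#' @param price_per_box Price in euros, >= 0.
#' @param treatment_days Positive integer length of treatment in days.
#' @return A one-row data frame of class `prescription_record`.
#' @export
prescription_record <- function(drug_name, units_per_administration,
                                administrations_per_day, units_per_box,
                                price_per_box, treatment_days) {
  rec <- data.frame(
    drug_name = as.character(drug_name),
    units_per_administration = units_per_administration,
    administrations_per_day = administrations_per_day,
    units_per_box = units_per_box,
    price_per_box = price_per_box,
    treatment_days = treatment_days,
    stringsAsFactors = FALSE
  )
  validate_prescriptions(rec)
  structure(rec, class = c("prescription_record", "data.frame"))
}

validate_prescriptions <- function(p, source = "prescriptions") {
  required <- c("units_per_administration", "administrations_per_day",
                "units_per_box", "price_per_box", "treatment_days")
  missing_cols <- setdiff(required, names(p))
  if (length(missing_cols) > 0) {
    stop(source, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(p$units_per_administration <= 0) || any(p$administrations_per_day <= 0)) {
    stop(source, ": dose and frequency must be positive", call. = FALSE)
  }
  if (any(p$units_per_box < 1)) {
    stop(source, ": units_per_box must be a positive integer >= 1", call. = FALSE)
  }
  if (any(p$price_per_box < 0)) {
    stop(source, ": price_per_box must be >= 0", call. = FALSE)
  }
  if (any(p$treatment_days <= 0)) {
    stop(source, ": treatment_days must be positive", call. = FALSE)
  }
  invisible(p)
}

#' Number of boxes required by a prescription
#'
#' Total units over the (capped) treatment period divided by pack size,
#' rounded up to whole boxes:
#' `ceil(units_per_administration * administrations_per_day *
#' min(treatment_days, 365) / units_per_box)`. Whole boxes are used because
#' fractional boxes cannot be dispensed.
#'
#' @param p A `prescription_record` or a data frame of prescription rows.
#' @return Integer vector, one count per row.
#' @examples
#' boxes_required(prescription_record("haloperidol", 2, 1, 28, 10, 365)) # 27
#' @export
boxes_required <- function(p) {
  validate_prescriptions(p)
  days <- pmin(p$treatment_days, 365)
  units <- p$units_per_administration * p$administrations_per_day * days
  as.integer(ceiling(units / p$units_per_box))
}

#' Annual drug cost of a therapeutic plan
#'
#' Sum over prescriptions of boxes required times price per box. An empty
#' plan costs zero.
#'
#' @param plan A data frame of prescription rows (possibly zero rows).
#' @return Cost in euros.
#' @export
annual_drug_cost <- function(plan) {
  if (is.null(plan) || nrow(plan) == 0) return(0)
  sum(boxes_required(plan) * plan$price_per_box)
}

#' Staff-time intervention cost inputs
#'
#' The medication-review intervention cost is staff time: minutes spent per
#' patient at an hourly staff rate, over a cohort of patients.
#'
#' @param minutes_per_patient Positive minutes of staff time per patient.
#' @param staff_rate_per_hour Staff rate in euros/hour, >= 0.
#' @param n_patients Positive integer cohort size.
#' @return A list of class `staff_time_cost`.
#' @export
staff_time_cost <- function(minutes_per_patient, staff_rate_per_hour,
                            n_patients) {
  if (minutes_per_patient <= 0) {
    stop("minutes_per_patient must be positive", call. = FALSE)
  }
  if (staff_rate_per_hour < 0) {
    stop("staff_rate_per_hour must be >= 0", call. = FALSE)
  }
  if (n_patients < 1 || n_patients != round(n_patients)) {
    stop("n_patients must be a positive integer", call. = FALSE)
  }
  structure(list(minutes_per_patient = minutes_per_patient,
                 staff_rate_per_hour = staff_rate_per_hour,
                 n_patients = as.integer(n_patients)),
            class = "staff_time_cost")
}

#' Per-patient and total intervention cost
#'
#' Per patient: `(minutes_per_patient / 60) * staff_rate_per_hour`.
#' Total: per-patient cost times the number of patients. At the documented
#' rate of EUR 97.12/hour, 30 minutes per patient costs EUR 48.56 and a
#' 240-patient cohort EUR 11,654.40.
#'
#' @param s A `staff_time_cost`.
#' @return Cost in euros.
#' @export
per_patient_intervention_cost <- function(s) {
  stopifnot(inherits(s, "staff_time_cost"))
  (s$minutes_per_patient / 60) * s$staff_rate_per_hour
}

#' @rdname per_patient_intervention_cost
#' @export
total_intervention_cost <- function(s) {
  per_patient_intervention_cost(s) * s$n_patients
}

#' Generate synthetic therapeutic plans
#'
#' Reproducible fixture generator for the drug-cost calculator. Per-patient
#' drug counts are Poisson with the given mean (default 8.04, the observed
#' baseline mean number of drugs per patient in the deprescribing cohort);
#' doses, frequencies, pack sizes, prices and treatment lengths are drawn
#' from ranges typical of psychotropic and comedication prescribing:
#' 0.5-2 units per administration, 1-3 administrations/day, packs of
#' 14-60 units, EUR 2-60 per box, 30-540 treatment days (lengths beyond a
#' year exercise the 365-day cap).
#'
#' @param n_patients Number of patients, >= 1.
#' @param mean_drugs Mean number of drugs per patient, > 0.
#' @param seed Integer seed; the same seed yields identical plans.
#' @return A data frame with columns `patient_id`, `drug_name`,
#'   `units_per_administration`, `administrations_per_day`, `units_per_box`,
#'   `price_per_box`, `treatment_days`.
#' @export
generate_synthetic_plans <- function(n_patients, mean_drugs = 8.04, seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (mean_drugs <= 0) stop("mean_drugs must be positive", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  counts <- stats::rpois(n_patients, lambda = mean_drugs)
  n_rows <- sum(counts)
  if (n_rows == 0) {
    return(data.frame(patient_id = integer(0), drug_name = character(0),
                      units_per_administration = numeric(0),
                      administrations_per_day = numeric(0),
                      units_per_box = integer(0), price_per_box = numeric(0),
                      treatment_days = integer(0), stringsAsFactors = FALSE))
  }
  plans <- data.frame(
    patient_id = rep(seq_len(n_patients), counts),
    drug_name = sprintf("drug_%03d", unlist(lapply(counts, seq_len))),
    units_per_administration = sample(c(0.5, 1, 1, 2), n_rows, replace = TRUE),
    administrations_per_day = sample(1:3, n_rows, replace = TRUE),
    units_per_box = sample(c(14L, 28L, 30L, 56L, 60L), n_rows, replace = TRUE),
    price_per_box = round(stats::runif(n_rows, 2, 60), 2),
    treatment_days = sample(30:540, n_rows, replace = TRUE),
    stringsAsFactors = FALSE
  )
  plans
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read / write prescriptions as CSV
#'
#' Columns: `patient_id,drug_name,units_per_administration,
#' administrations_per_day,units_per_box,price_per_box,treatment_days`.
#'
#' @param path File path.
#' @return `read_prescriptions` returns a validated data frame;
#'   `write_prescriptions` returns `path` invisibly.
#' @export
read_prescriptions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_prescriptions(df, source = path)
  df
}

#' @rdname read_prescriptions
#' @param plans Data frame of prescription rows.
#' @export
write_prescriptions <- function(plans, path) {
  validate_prescriptions(plans)
  utils::write.csv(plans, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
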