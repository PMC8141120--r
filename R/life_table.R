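#' Generate a synthetic Gompertz-Makeham life table
#'
#' Builds an age- and sex-indexed table of annual death probabilities `qx`
#' following a Gompertz-Makeham hazard, as a synthetic stand-in for a national
#' all-cause mortality schedule. The annual probability of death at integer
#' age \eqn{x} is
#' \deqn{q_x = 1 - \exp\{-(c + a e^{b x})\},}
#' capped at 1, where `a` is the baseline (Gompertz) hazard, `b` the
#' senescence rate and `c` the age-independent Makeham constant.
#'
#' Each parameter may be a single number (same schedule for both sexes) or a
#' named vector `c(female = ..., male = ...)` for sex-specific schedules.
#' The defaults give a schedule that rises from roughly 1% per year at age 65
#' to about 13% at age 90, qualitatively matching a Southern-European
#' old-age mortality profile.
#'
#' @param a Baseline hazard, > 0 (or 0 for a zero-hazard table when `c = 0`).
#' @param b Senescence rate, > 0.
#' @param c Makeham (age-independent) hazard, >= 0.
#' @param age_min,age_max Integer age range (inclusive); `age_min < age_max`.
#' @return A `life_table`: a data frame with columns `age`, `sex`
#'   (`"female"`/`"male"`) and `qx`, one row per (age, sex).
#' @examples
#' lt <- generate_gompertz_life_table()
#' head(lt)
#' @export
generate_gompertz_life_table <- function(a = 2.7e-5, b = 0.095, c = 0,
                                         age_min = 65L, age_max = 110L) {
  age_min <- as.integer(age_min)
  age_max <- as.integer(age_max)
  if (age_min >= age_max) {
    stop("`age_min` must be less than `age_max`", call. = FALSE)
  }
  sexes <- c("female", "male")
  par_for <- function(p, name, sex) {
    v <- if (length(p) == 1L) unname(p) else {
      if (is.null(names(p)) || !all(sexes %in% names(p))) {
        stop("sex-specific `", name,
             "` must be a named vector with entries 'female' and 'male'",
             call. = FALSE)
      }
      unname(p[[sex]])
    }
    v
  }
  rows <- lapply(sexes, function(sex) {
    a_s <- par_for(a, "a", sex)
    b_s <- par_for(b, "b", sex)
    c_s <- par_for(c, "c", sex)
    if (a_s < 0) stop("`a` must be non-negative", call. = FALSE)
    if (b_s <= 0) stop("`b` must be positive", call. = FALSE)
    if (c_s < 0) stop("`c` must be non-negative", call. = FALSE)
    ages <- age_min:age_max
    hazard <- c_s + a_s * exp(b_s * ages)
    qx <- pmin(1, 1 - exp(-hazard))
    data.frame(age = ages, sex = sex, qx = qx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new_life_table(out)
}

new_life_table <- function(df) {
  structure(df, class = c("life_table", "data.frame"))
}

#' Validate a life table, returning it invisibly
#'
#' Checks the structural invariants: columns `age`, `sex`, `qx`; every
#' `qx` in \[0, 1\]; contiguous integer ages per sex. A decrease of `qx`
#' with age (between 65 and 105) raises a warning, not an error, since
#' real schedules occasionally show local dips.
#'
#' @param lt A data frame with columns `age`, `sex`, `qx`.
#' @param source Label used in error messages (e.g. a file path).
#' @return The validated `life_table`, invisibly.
#' @export
validate_life_table <- function(lt, source = "life table") {
  required <- c("age", "sex", "qx")
  missing_cols <- setdiff(required, names(lt))
  if (length(missing_cols) > 0) {
    stop(source, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(lt$qx) | lt$qx < 0 | lt$qx > 1)
  if (length(bad) > 0) {
    stop(source, ": qx out of [0,1] at row ", bad[1],
         " (age ", lt$age[bad[1]], ", sex ", lt$sex[bad[1]],
         ", qx ", lt$qx[bad[1]], ")", call. = FALSE)
  }
  bad_sex <- which(!lt$sex %in% c("female", "male"))
  if (length(bad_sex) > 0) {
    stop(source, ": invalid sex at row ", bad_sex[1],
         " ('", lt$sex[bad_sex[1]], "')", call. = FALSE)
  }
  for (s in unique(lt$sex)) {
    ages <- sort(lt$age[lt$sex == s])
    if (any(diff(ages) != 1L)) {
      gap <- which(diff(ages) != 1L)[1]
      stop(source, ": non-contiguous ages for sex ", s,
           " (gap after age ", ages[gap], ")", call. = FALSE)
    }
    sub <- lt[lt$sex == s, ]
    sub <- sub[order(sub$age), ]
    win <- sub$age >= 65 & sub$age <= 105
    if (sum(win) > 1 && any(diff(sub$qx[win]) < 0)) {
      warning(source, ": qx decreases with age for sex ", s,
              " within ages 65-105", call. = FALSE)
    }
  }
  invisible(new_life_table(as.data.frame(lt)))
}

#' Look up the annual death probability at an age
#'
#' @param lt A `life_table`.
#' @param age Integer age (may be a vector).
#' @param sex `"female"` or `"male"`.
#' @return Numeric vector of `qx` values.
#' @export
qx_at <- function(lt, age, sex) {
  sub <- lt[lt$sex == sex, ]
  idx <- match(age, sub$age)
  if (anyNA(idx)) {
    miss <- age[is.na(idx)][1]
    stop("age ", miss, " (sex ", sex, ") outside life-table range [",
         min(sub$age), ", ", max(sub$age), "]", call. = FALSE)
  }
  sub$qx[idx]
}

#' Read / write a life table as CSV
#'
#' The CSV has header columns `age,sex,qx` (UTF-8, decimal point). Reading
#' validates all life-table invariants; a `qx` outside \[0, 1\] or a gap in
#' the age sequence is a format error naming the first offending row, while
#' a non-monotone schedule only warns.
#'
#' @param path File path.
#' @return `read_life_table` returns a `life_table`; `write_life_table`
#'   returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lt <- validate_life_table(df, source = path)
  lt
}

#' @rdname read_life_table
#' @param lt A `life_table` to write.
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  utils::write.csv(as.data.frame(lt)[, c("age", "sex", "qx")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
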