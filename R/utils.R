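# Internal helpers shared across modules.

#' Canonical diary count columns
#'
#' Column names used for the per-setting contact counts of a one-day diary:
#' four travel modes, seven locations and four meals.
#'
#' @return Named list with character vectors `travel`, `location`, `eating`.
#' @export
diary_columns <- function() {
  list(
    travel = c("travel_mass_transit", "travel_bus", "travel_car_taxi",
               "travel_motorbike"),
    location = c("loc_home", "loc_work", "loc_school_university",
                 "loc_restaurant_coffee", "loc_sport_leisure", "loc_concert",
                 "loc_other"),
    eating = c("eat_breakfast", "eat_lunch", "eat_dinner", "eat_snack")
  )
}

# All count-valued columns subject to zero-filling.
count_columns <- function() {
  c(unlist(diary_columns(), use.names = FALSE),
    "household_size", "household_symptomatic")
}

recognised_channels <- function() {
  c("facebook", "direct_email", "forwarded_email", "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Fisher z confidence interval for a correlation estimate.
fisher_ci <- function(r, n, level = 0.95) {
  if (is.na(r) || n <= 3 || abs(r) >= 1) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = tanh(z - q * se), upper = tanh(z + q * se))
}
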