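# Derived diary measures: degree, eating totals, censoring, log transforms,
# symptom indicators and per-stratum summaries.
#
# Degree is the number of close contacts reported for one day, defined as
# the sum of contacts while travelling plus contacts at the different
# locations. Extreme reports are censored (defaults: 500 for degree, 75 for
# contacts while eating) as the highest values considered plausible.
# Household members are asked on a separate roster question and do not enter
# degree (home contacts do, through the home location).

#' Zero-fill missing diary counts for completers
#'
#' Survey convention: respondents leave fields empty when not applicable, so
#' for everyone who reached the final page (completed), an empty count means
#' zero. Non-completers keep their missing values and should be excluded
#' from count-based analyses.
#'
#' @param records An `rds_participants` data frame with a `completed` flag.
#' @return The records with missing counts of completers replaced by 0.
#' @export
zero_fill <- function(records) {
  if (!inherits(records, "rds_participants")) records <- as_participants(records)
  done <- which(records$completed %in% TRUE)
  for (col in intersect(count_columns(), names(records))) {
    v <- records[[col]]
    v[done][is.na(v[done])] <- 0
    records[[col]] <- v
  }
  if ("symptoms" %in% names(records)) {
    records$symptoms[done][is.na(records$symptoms[done])] <- ""
  }
  records
}

default_flu_symptoms <- c("fever", "headache", "muscle_pain")
default_cold_symptoms <- c("runny_nose", "sore_throat", "cough")

#' Derive analysis measures from diary counts
#'
#' Adds per-respondent derived columns: `travel_total`, `location_total`,
#' censored `degree` and `eating_total`, log-transformed versions,
#' `symptom_count`, the `two_plus_symptoms` indicator, and flu-like /
#' cold-like symptom-combination indicators.
#'
#' @param records Zero-filled `rds_participants` (see [zero_fill()]); rows
#'   with `completed == FALSE` get `NA` measures.
#' @param degree_cap,eating_cap Censoring maxima for degree and contacts
#'   while eating (defaults 500 and 75 contacts/day).
#' @param log_convention `"log1p"` (default) transforms counts as
#'   `log(x + 1)` so zero counts stay in the analysis; `"log_positive"`
#'   takes `log(x)` and leaves zeros as `NA` (excluded listwise later).
#' @param flu_symptoms,cold_symptoms Symptom-name sets defining the
#'   flu-like and common-cold-like combinations (all required).
#' @return The records with derived columns appended.
#' @export
derive_measures <- function(records, degree_cap = 500, eating_cap = 75,
                            log_convention = c("log1p", "log_positive"),
                            flu_symptoms = default_flu_symptoms,
                            cold_symptoms = default_cold_symptoms) {
  if (!inherits(records, "rds_participants")) records <- as_participants(records)
  log_convention <- match.arg(log_convention)
  cols <- diary_columns()

  row_total <- function(group) {
    present <- intersect(group, names(records))
    if (!length(present)) return(rep(0, nrow(records)))
    m <- as.matrix(records[present])
    if (any(m < 0, na.rm = TRUE)) stopf("negative diary counts")
    rowSums(m)  # NA propagates for non-completers
  }
  records$travel_total <- row_total(cols$travel)
  records$location_total <- row_total(cols$location)
  records$degree <- pmin(records$travel_total + records$location_total,
                         degree_cap)
  records$eating_total <- pmin(row_total(cols$eating), eating_cap)

  tr <- function(x) {
    if (log_convention == "log1p") log1p(x) else ifelse(x > 0, log(x), NA_real_)
  }
  records$log_degree <- tr(records$degree)
  records$log_eating <- tr(records$eating_total)
  if ("household_size" %in% names(records)) {
    records$log_household <- tr(records$household_size)
  }

  if ("symptoms" %in% names(records)) {
    sets <- parse_symptoms(records$symptoms)
    records$symptom_count <- vapply(sets, length, integer(1))
    records$symptom_count[is.na(records$symptoms)] <- NA_integer_
    records$two_plus_symptoms <- records$symptom_count >= 2L
    records$flu_like <- vapply(sets, function(s) all(flu_symptoms %in% s),
                               logical(1))
    records$cold_like <- vapply(sets, function(s) all(cold_symptoms %in% s),
                                logical(1))
    records$log_symptoms <- tr(records$symptom_count)
  }
  incomplete <- !(records$completed %in% TRUE)
  derived <- intersect(c("travel_total", "location_total", "degree",
                         "eating_total", "log_degree", "log_eating",
                         "log_household", "symptom_count", "log_symptoms"),
                       names(records))
  for (col in derived) records[[col]][incomplete] <- NA
  records
}

parse_symptoms <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(s) trimws(s[nzchar(trimws(s))]))
}

#' Summarise contact counts by respondent stratum
#'
#' Mean, median and SD of contacts while travelling, at locations, and of
#' degree, per stratum of a respondent characteristic. Strata with no
#' completed records are omitted.
#'
#' @param records Records with derived measures (see [derive_measures()]).
#' @param group_by One of `"age_class"` (14-19 / 20-29 / 30-39 / 40+),
#'   `"gender"`, `"education"`, `"household_size"`, `"weekday"`.
#' @return Data frame with one row per stratum: `stratum`, `n`, then
#'   mean/median/sd of `travel_total`, `location_total` and `degree`.
#' @export
setting_summaries <- function(records,
                              group_by = c("age_class", "gender", "education",
                                           "household_size", "weekday")) {
  group_by <- match.arg(group_by)
  if (!"degree" %in% names(records)) {
    stopf("run derive_measures() before setting_summaries()")
  }
  records <- records[records$completed %in% TRUE, , drop = FALSE]
  key <- switch(group_by,
    age_class = cut(records$age, c(14, 19, 29, 39, Inf),
                    labels = c("14-19", "20-29", "30-39", "40+"),
                    include.lowest = TRUE),
    gender = records$gender,
    education = records$education,
    household_size = ifelse(records$household_size >= 7, "7+",
                            as.character(records$household_size)),
    weekday = records$diary_weekday)
  keep <- !is.na(key)
  records <- records[keep, , drop = FALSE]
  key <- as.character(key[keep])

  out <- do.call(rbind, lapply(sort(unique(key)), function(s) {
    sub <- records[key == s, , drop = FALSE]
    row <- data.frame(stratum = s, n = nrow(sub), stringsAsFactors = FALSE)
    for (v in c("travel_total", "location_total", "degree")) {
      row[[paste0(v, "_mean")]] <- mean(sub[[v]], na.rm = TRUE)
      row[[paste0(v, "_median")]] <- stats::median(sub[[v]], na.rm = TRUE)
      row[[paste0(v, "_sd")]] <-
        if (sum(!is.na(sub[[v]])) < 2) 0 else stats::sd(sub[[v]], na.rm = TRUE)
    }
    row
  }))
  rownames(out) <- NULL
  out
}
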