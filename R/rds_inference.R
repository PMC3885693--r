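# Volz-Heckathorn (RDS-II) estimation and equilibrium diagnostics.
#
# RDS oversamples well-connected individuals: the chance of being reached
# grows with network degree. The Volz-Heckathorn estimator corrects this by
# weighting each sampled individual by the reciprocal of their degree, so
# for category A the population proportion is
# (sum over i in A of 1/d_i) / (sum over all i of 1/d_i). The diary degree
# is the only network-size measure collected here and serves as d_i by
# default. Composition curves over waves and over accumulating sample size
# show whether the sample composition stabilises (approaches equilibrium)
# or still reflects the choice of seeds.

#' Volz-Heckathorn population proportion estimate
#'
#' @param records Records with derived measures (for the default
#'   `degree_source = "degree"`).
#' @param attribute Categorical column to estimate proportions for.
#' @param degree_source Column holding the RDS weighting degree.
#' @param include_seeds Seeds are included by default; set `FALSE` to
#'   restrict to recruited participants.
#' @return A `vh_estimate`: list with `variable`, `categories`,
#'   `raw_proportions`, `vh_proportions`, `weights` (named, normalised,
#'   sum 1), `n_used`, `excluded`, `degree_source`.
#'
#' @details Individuals with a missing attribute or a missing/non-positive
#'   degree are excluded and counted in `excluded`. Estimates are invariant
#'   to rescaling all degrees by a constant; with equal degrees they reduce
#'   to the raw sample proportions.
#' @export
vh_estimate <- function(records, attribute, degree_source = "degree",
                        include_seeds = TRUE) {
  if (!degree_source %in% names(records)) {
    stopf("degree column '%s' not found (run derive_measures()?)",
          degree_source)
  }
  if (!include_seeds) {
    records <- records[!is.na(records$recruiter_pid), , drop = FALSE]
  }
  d <- records[[degree_source]]
  v <- records[[attribute]]
  keep <- !is.na(v) & !is.na(d) & d > 0
  if (!any(keep)) stopf("no individuals with positive degree and observed '%s'",
                        attribute)
  d <- d[keep]; v <- as.character(v[keep])
  w <- (1 / d) / sum(1 / d)
  cats <- sort(unique(v))
  vh <- vapply(cats, function(a) sum(w[v == a]), numeric(1))
  raw <- vapply(cats, function(a) mean(v == a), numeric(1))
  structure(list(variable = attribute, categories = cats,
                 raw_proportions = raw, vh_proportions = vh,
                 weights = stats::setNames(w, records$pid[keep]),
                 n_used = sum(keep), excluded = sum(!keep),
                 degree_source = degree_source),
            class = "vh_estimate")
}

#' @export
print.vh_estimate <- function(x, ...) {
  cat(sprintf("Volz-Heckathorn estimate for '%s' (n = %d, excluded %d; weights = 1/%s)\n",
              x$variable, x$n_used, x$excluded, x$degree_source))
  print(data.frame(category = x$categories, raw = round(x$raw_proportions, 4),
                   vh = round(x$vh_proportions, 4), row.names = NULL))
  invisible(x)
}

#' Sample composition over waves and over accumulating sample size
#'
#' Diagnostics for RDS equilibrium: per-wave composition, cumulative
#' composition up to each wave, and cumulative raw and Volz-Heckathorn
#' weighted composition in deterministic recruitment order (wave-major,
#' then pid — the order recruits accumulate absent timestamps).
#'
#' @inheritParams vh_estimate
#' @param forest The matching `recruitment_forest` (supplies waves).
#' @return List of data frames: `per_wave` (`wave`, `category`/`mean`,
#'   `value`, `n`), `cumulative_wave` (same by increasing wave) and
#'   `by_sample_size` (`n`, raw and VH-weighted running estimates). Numeric
#'   attributes are summarised by means, categorical ones by proportions
#'   per category.
#' @export
composition_curves <- function(records, forest, attribute,
                               degree_source = "degree") {
  wave <- stats::setNames(forest$nodes$wave, forest$nodes$pid)
  records <- records[order(wave[records$pid], records$pid), , drop = FALSE]
  w <- wave[records$pid]
  v <- records[[attribute]]
  numeric_attr <- is.numeric(v)
  d <- if (degree_source %in% names(records)) records[[degree_source]]
       else rep(NA_real_, nrow(records))

  summarise <- function(vals) {
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NULL)
    if (numeric_attr) {
      data.frame(category = "mean", value = mean(vals), n = length(vals),
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(vals) / length(vals)
      data.frame(category = names(tab), value = as.numeric(tab),
                 n = length(vals), stringsAsFactors = FALSE)
    }
  }
  waves <- sort(unique(w))
  per_wave <- do.call(rbind, lapply(waves, function(wv) {
    s <- summarise(v[w == wv])
    if (is.null(s)) return(NULL)
    cbind(wave = wv, s)
  }))
  cumulative_wave <- do.call(rbind, lapply(waves, function(wv) {
    s <- summarise(v[w <= wv])
    if (is.null(s)) return(NULL)
    cbind(wave = wv, s)
  }))

  # Running raw and VH-weighted estimates in recruitment order.
  ok <- !is.na(v)
  vv <- v[ok]; dd <- d[ok]
  n_run <- seq_along(vv)
  if (numeric_attr) {
    raw <- cumsum(vv) / n_run
    inv <- ifelse(!is.na(dd) & dd > 0, 1 / dd, NA)
    vh <- cumsum(ifelse(is.na(inv), 0, inv * vv)) /
      cumsum(ifelse(is.na(inv), 0, inv))
    by_n <- data.frame(n = n_run, category = "mean", raw = raw, vh = vh,
                       stringsAsFactors = FALSE)
  } else {
    inv <- ifelse(!is.na(dd) & dd > 0, 1 / dd, NA)
    cats <- sort(unique(as.character(vv)))
    by_n <- do.call(rbind, lapply(cats, function(a) {
      ind <- as.numeric(vv == a)
      raw <- cumsum(ind) / n_run
      vh <- cumsum(ifelse(is.na(inv), 0, inv * ind)) /
        cumsum(ifelse(is.na(inv), 0, inv))
      data.frame(n = n_run, category = a, raw = raw, vh = vh,
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_wave = per_wave, cumulative_wave = cumulative_wave,
       by_sample_size = by_n)
}
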