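# Assortativity between participants at tree distance d.
#
# Mixing within recruitment trees is measured by correlating attribute
# values over pairs of participants in the same component. Directly linked
# pairs (distance 1) are recruiter versus recruit; longer distances follow
# the unique undirected path through the tree. Pearson's r serves integer
# variables, the phi coefficient binary ones (Pearson on 0/1 codes) and
# Spearman's rank correlation ordinal ones. Under first-order (Markov)
# recruitment dependence these correlations decay geometrically with
# distance.

#' Enumerate participant pairs at a given tree distance
#'
#' @param forest A `recruitment_forest`.
#' @param d Tree distance (>= 1), or the string `"5+"` style lump handled by
#'   [distance_profile()]; here `d` must be a single integer.
#' @param mode `"symmetrized"` (default): every unordered pair of
#'   participants in the same component whose undirected path has length
#'   `d`, listed once per orientation (so each appears twice).
#'   `"directed"`: ordered (ancestor, descendant) pairs exactly `d`
#'   recruitment steps apart; at `d = 1` these are the (recruiter,
#'   recruited) pairs.
#' @param min_d If `TRUE`, return pairs at distance `>= d` (the lump used
#'   for the tail of a distance profile).
#' @return A `distance_pairs` data frame with columns `i`, `j` (pids) and
#'   attributes `distance` and `mode`.
#' @export
pairs_at_distance <- function(forest, d, mode = c("symmetrized", "directed"),
                              min_d = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(d) == 1, d >= 1)
  dm <- component_distances(forest)
  sel <- if (min_d) which(dm$d >= d) else which(dm$d == d)
  out <- data.frame(i = dm$i[sel], j = dm$j[sel], stringsAsFactors = FALSE)
  if (mode == "directed") {
    wave <- stats::setNames(forest$nodes$wave, forest$nodes$pid)
    anc <- wave[out$j] - wave[out$i] == (if (min_d) dm$d[sel] else d)
    out <- out[anc, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, distance = if (min_d) paste0(d, "+") else d, mode = mode,
            class = c("distance_pairs", "data.frame"))
}

# Ordered within-component pairs with undirected tree distance.
# Returns parallel vectors i, j, d covering every ordered pair (both
# orientations) of distinct nodes sharing a component.
component_distances <- function(forest) {
  cache <- attr(forest, ".dist_cache")
  if (!is.null(cache)) return(cache)
  nodes <- forest$nodes
  res_i <- res_j <- character(0); res_d <- integer(0)
  for (comp in split(nodes$pid, nodes$component_id)) {
    if (length(comp) < 2) next
    sub_edges <- forest$edges[forest$edges$to %in% comp, , drop = FALSE]
    g <- igraph::graph_from_data_frame(sub_edges, directed = FALSE,
                                       vertices = data.frame(name = comp))
    D <- igraph::distances(g)
    idx <- which(D >= 1 & is.finite(D), arr.ind = TRUE)
    res_i <- c(res_i, rownames(D)[idx[, 1]])
    res_j <- c(res_j, colnames(D)[idx[, 2]])
    res_d <- c(res_d, as.integer(D[idx]))
  }
  list(i = res_i, j = res_j, d = res_d)
}

#' Correlation between paired participants
#'
#' Computes the assortativity coefficient for an attribute over a pair set:
#' Pearson's r, the phi coefficient (Pearson on 0/1 indicator codes) or
#' Spearman's rank correlation, with a Fisher-z confidence interval and a
#' classical test (t for Pearson/Spearman, chi-square for phi). Pairs with
#' a missing value on either side are dropped and counted.
#'
#' In symmetrized mode the estimate uses both orientations of every pair
#' (making it invariant to orientation), while the confidence interval and
#' degrees of freedom are based on the number of unordered pairs.
#'
#' @param pairs A `distance_pairs` object.
#' @param records Participant records carrying the attribute.
#' @param attribute Column name in `records`. Numeric or logical; for
#'   `"phi"` a two-level character/factor is also accepted; for
#'   `"spearman"` a factor's level order defines the ranking.
#' @param statistic `"pearson"`, `"phi"` or `"spearman"`.
#' @param level Confidence level (default 0.95).
#' @return A `correlation_result`: list with `statistic`, `estimate`,
#'   `ci_low`, `ci_high`, `n_pairs`, `n_dropped`, `df`, `p`, `mode`,
#'   `distance`.
#' @export
pair_correlation <- function(pairs, records, attribute,
                             statistic = c("pearson", "phi", "spearman"),
                             level = 0.95) {
  statistic <- match.arg(statistic)
  vals <- stats::setNames(code_attribute(records[[attribute]], statistic),
                          records$pid)
  xi <- vals[pairs$i]; xj <- vals[pairs$j]
  keep <- !is.na(xi) & !is.na(xj)
  n_dropped <- sum(!keep)
  xi <- xi[keep]; xj <- xj[keep]
  mode <- attr(pairs, "mode") %||% "directed"
  n_pairs <- length(xi)
  n_eff <- if (mode == "symmetrized") n_pairs / 2 else n_pairs
  if (n_eff < 3) stopf("fewer than 3 complete pairs for '%s'", attribute)
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
    stopf("zero variance on a pair margin for '%s': correlation undefined",
          attribute)
  }
  if (statistic == "spearman") {
    # Rank over the pooled margins so both sides share one ranking scale.
    r <- stats::cor(rank(xi), rank(xj))
  } else {
    r <- stats::cor(xi, xj)
  }
  df <- n_eff - 2
  p <- if (statistic == "phi") {
    stats::pchisq(n_eff * r^2, df = 1, lower.tail = FALSE)
  } else {
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tstat), df)
  }
  ci <- fisher_ci(r, n_eff, level)
  structure(list(statistic = statistic, estimate = r,
                 ci_low = unname(ci["lower"]), ci_high = unname(ci["upper"]),
                 n_pairs = n_pairs, n_dropped = n_dropped, df = df, p = p,
                 mode = mode, distance = attr(pairs, "distance")),
            class = "correlation_result")
}

# Numeric coding for correlation input. phi: any two-level variable -> 0/1;
# spearman: factor levels (or sorted unique values) -> integer ranks.
code_attribute <- function(v, statistic) {
  if (is.logical(v)) return(as.numeric(v))
  if (is.numeric(v)) return(as.numeric(v))
  f <- if (is.factor(v)) v else factor(v)
  if (statistic == "phi" && nlevels(f) > 2) {
    stopf("phi requires a binary variable (got %d levels)", nlevels(f))
  }
  as.numeric(f) - (statistic == "phi")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s = %.3f [%.3f - %.3f], df = %g, p = %.3g (%s mode, d = %s, n = %d)\n",
              x$statistic, x$estimate, x$ci_low, x$ci_high, x$df, x$p,
              x$mode, as.character(x$distance %||% "?"), x$n_pairs))
  invisible(x)
}

#' Correlation profile over tree distance
#'
#' One correlation per distance `1 .. max_d - 1` plus a lumped `>= max_d`
#' tail (distances of five or more are lumped by default). Distances with
#' fewer than 3 complete pairs, or degenerate margins, are reported as
#' undefined (`NA` estimate).
#'
#' @inheritParams pair_correlation
#' @param forest A `recruitment_forest`.
#' @param max_d Lump threshold; distances `>= max_d` form one class.
#' @param mode Pair orientation mode, see [pairs_at_distance()].
#' @return Data frame with one row per distance class: `distance`,
#'   `estimate`, `ci_low`, `ci_high`, `n_pairs`, `df`, `p`.
#' @export
distance_profile <- function(forest, records, attribute,
                             statistic = c("pearson", "phi", "spearman"),
                             max_d = 5, mode = c("symmetrized", "directed"),
                             level = 0.95) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  stopifnot(max_d >= 1)
  attr(forest, ".dist_cache") <- component_distances(forest)
  dists <- if (max_d > 1) seq_len(max_d - 1) else integer(0)
  rows <- lapply(seq_len(max_d), function(k) {
    lump <- k == max_d
    pr <- pairs_at_distance(forest, k, mode = mode, min_d = lump)
    label <- if (lump) paste0(k, "+") else as.character(k)
    res <- tryCatch(pair_correlation(pr, records, attribute, statistic, level),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(distance = label, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, n_pairs = nrow(pr), df = NA_real_,
                 p = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(distance = label, estimate = res$estimate,
                 ci_low = res$ci_low, ci_high = res$ci_high,
                 n_pairs = res$n_pairs, df = res$df, p = res$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "statistic") <- statistic
  attr(out, "attribute") <- attribute
  out
}

#' Assortativity of directly linked pairs for the standard variable set
#'
#' The recruiter-versus-recruit correlation table: age (Pearson), gender
#' (phi), education (Spearman), log degree, log household size, log
#' contacts while eating, log symptom count (Pearson) and the two-or-more
#' symptoms indicator (phi), computed over directed distance-1 pairs.
#'
#' @param records Records with derived measures ([derive_measures()]).
#' @param forest The matching `recruitment_forest`.
#' @param household_cap Respondents reporting more household contacts than
#'   this are excluded from the household-size row (the deposited survey
#'   held one implausible report above 500); `Inf` disables the filter.
#' @param level Confidence level.
#' @return Data frame with `variable`, `statistic`, `estimate`, `ci_low`,
#'   `ci_high`, `df`, `p`, `n_pairs`, `n_dropped`.
#' @export
linked_pair_table <- function(records, forest, household_cap = 500,
                              level = 0.95) {
  pr <- pairs_at_distance(forest, 1, mode = "directed")
  spec <- list(
    age = c("age", "pearson"),
    gender = c("gender", "phi"),
    education = c("education", "spearman"),
    degree_log = c("log_degree", "pearson"),
    household_size_log = c("log_household", "pearson"),
    food_with_log = c("log_eating", "pearson"),
    symptoms_log = c("log_symptoms", "pearson"),
    two_plus_symptoms = c("two_plus_symptoms", "phi")
  )
  edu_levels <- c("below_bachelor", "bachelor", "master_or_higher")
  if ("education" %in% names(records) && is.character(records$education) &&
      all(records$education %in% c(edu_levels, NA))) {
    records$education <- factor(records$education, levels = edu_levels,
                                ordered = TRUE)
  }
  rows <- lapply(names(spec), function(nm) {
    col <- spec[[nm]][1]; st <- spec[[nm]][2]
    rec <- records
    if (nm == "household_size_log" && "household_size" %in% names(rec)) {
      rec[[col]][!is.na(rec$household_size) &
                   rec$household_size > household_cap] <- NA
    }
    res <- tryCatch(pair_correlation(pr, rec, col, st, level),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(variable = nm, statistic = st, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, df = NA_real_,
                        p = NA_real_, n_pairs = NA_integer_,
                        n_dropped = NA_integer_, stringsAsFactors = FALSE))
    }
    data.frame(variable = nm, statistic = st, estimate = res$estimate,
               ci_low = res$ci_low, ci_high = res$ci_high, df = res$df,
               p = res$p, n_pairs = res$n_pairs, n_dropped = res$n_dropped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
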