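# Intraclass correlation from an intercept-only two-level model.
#
# Participants recruited into the same component resemble each other, which
# inflates the standard errors of naive survey estimates. The intraclass
# correlation (ICC) quantifies this: the variance between components
# divided by the total variance (between plus within), i.e. the expected
# correlation between two randomly chosen members of one component. The
# variance components come from an intercept-only one-way random-effects
# model fitted by restricted maximum likelihood (REML); for the unbalanced
# one-way layout the REML criterion has a cheap exact profile in the
# variance ratio, which is what is optimised here.

#' Intraclass correlation from variance components
#'
#' Pure arithmetic: `sigma2_between / (sigma2_between + sigma2_within)`.
#' An ICC of 0 means members of a component are as unalike as strangers
#' (observations independent); 1 means members of a component respond
#' identically.
#'
#' @param sigma2_between Variance at the component level (>= 0).
#' @param sigma2_within Residual variance at the respondent level (>= 0).
#' @return The ICC, in `[0, 1]`.
#' @export
icc_from_components <- function(sigma2_between, sigma2_within) {
  if (sigma2_between < 0 || sigma2_within < 0) {
    stopf("variance components must be non-negative")
  }
  total <- sigma2_between + sigma2_within
  if (total == 0) stopf("both variance components zero: ICC undefined")
  sigma2_between / total
}

#' Fit variance components for a one-way random-effects model
#'
#' Intercept-only two-level model `y_ij = mu + u_i + e_ij` with
#' `u_i ~ N(0, sigma2_between)` per component and residual
#' `e_ij ~ N(0, sigma2_within)`, for unbalanced component sizes.
#'
#' @param values Numeric response (binary/ordinal variables entered as
#'   numeric codes).
#' @param component_ids Component label per value.
#' @param method `"reml"` (default) profiles the REML criterion in the
#'   variance ratio `theta = sigma2_between / sigma2_within`;
#'   `"anova_mom"` is the ANOVA method-of-moments estimator (expected mean
#'   squares, unbalanced-design coefficient), offered as a cross-check.
#' @param tol Convergence tolerance of the profile optimisation.
#' @return A `variance_components` object: `sigma2_between`,
#'   `sigma2_within`, `icc`, `mu`, `method`, `converged`, `n_components`,
#'   `n_individuals`, `loglik` (restricted, REML only).
#'
#' @details A negative between-component estimate is truncated to zero (ICC
#'   reported 0). Rows with missing values are dropped. At least two
#'   components are required; when no component has two or more members the
#'   between-variance is unidentifiable and reported at the zero boundary.
#' @export
fit_variance_components <- function(values, component_ids,
                                    method = c("reml", "anova_mom"),
                                    tol = 1e-8) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(component_ids)
  y <- as.numeric(values[keep])
  g <- as.character(component_ids[keep])
  groups <- split(y, g)
  a <- length(groups)
  N <- length(y)
  if (a < 2) stopf("need at least 2 components to separate variances")
  n_i <- lengths(groups)
  ybar_i <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))

  if (all(n_i == 1L)) {
    # No replication within any component: between-variance unidentifiable,
    # report the zero boundary.
    s2w <- stats::var(y)
    out <- vc_result(0, s2w, mean(y), method, TRUE, a, N, NA_real_)
    return(out)
  }

  if (method == "anova_mom") {
    gm <- mean(y)
    ssb <- sum(n_i * (ybar_i - gm)^2)
    msw <- ssw / (N - a)
    msb <- ssb / (a - 1)
    n0 <- (N - sum(n_i^2) / N) / (a - 1)
    s2b <- max((msb - msw) / n0, 0)
    return(vc_result(s2b, msw, gm, method, TRUE, a, N, NA_real_))
  }

  # REML profile in theta = s2b / s2w. For given theta the GLS mean and the
  # profiled residual variance are closed-form; the remaining 1-D criterion
  # is minimised over log(theta) with a boundary check at theta = 0.
  neg2reml <- function(theta) {
    w <- n_i / (1 + theta * n_i)
    mu <- sum(w * ybar_i) / sum(w)
    q <- ssw + sum(w * (ybar_i - mu)^2)
    s2 <- q / (N - 1)
    (N - 1) * log(s2) + sum(log(1 + theta * n_i)) + log(sum(w)) + (N - 1)
  }
  opt <- stats::optimize(function(lt) neg2reml(exp(lt)),
                         interval = c(-30, 15), tol = tol)
  theta <- exp(opt$minimum)
  crit <- opt$objective
  if (neg2reml(0) <= crit + tol) { # boundary wins
    theta <- 0
    crit <- neg2reml(0)
  }
  w <- n_i / (1 + theta * n_i)
  mu <- sum(w * ybar_i) / sum(w)
  s2w <- (ssw + sum(w * (ybar_i - mu)^2)) / (N - 1)
  s2b <- theta * s2w
  converged <- is.finite(crit)
  loglik <- -0.5 * (crit + (N - 1) * log(2 * pi))
  vc_result(s2b, s2w, mu, method, converged, a, N, loglik)
}

vc_result <- function(s2b, s2w, mu, method, converged, a, N, loglik) {
  structure(list(sigma2_between = s2b, sigma2_within = s2w,
                 icc = icc_from_components(s2b, s2w), mu = mu,
                 method = method, converged = converged,
                 n_components = a, n_individuals = N, loglik = loglik),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("Variance components (%s): between = %.4f,",
                     " within = %.4f, ICC = %.3f\n",
                     "  %d individuals in %d components\n"),
              x$method, x$sigma2_between, x$sigma2_within, x$icc,
              x$n_individuals, x$n_components))
  invisible(x)
}

#' ICC table for the standard variable set
#'
#' Fits the intercept-only two-level model per variable and reports ICC
#' with its variance components, for: age, gender, education (numeric
#' codes), log degree, log contacts while eating, log household size, log
#' symptom count and the two-or-more-symptoms indicator.
#'
#' @param records Records with derived measures ([derive_measures()]).
#' @param forest The matching `recruitment_forest` supplying component
#'   labels.
#' @param method Passed to [fit_variance_components()].
#' @return Data frame `variable`, `icc`, `sigma2_between`, `sigma2_within`,
#'   `n`.
#' @export
icc_table <- function(records, forest, method = "reml") {
  comp <- stats::setNames(forest$nodes$component_id, forest$nodes$pid)
  cid <- comp[records$pid]
  vars <- list(age = "age", gender = "gender", education = "education",
               degree_log = "log_degree", food_with_log = "log_eating",
               household_size_log = "log_household",
               symptoms_log = "log_symptoms",
               two_plus_symptoms = "two_plus_symptoms")
  rows <- lapply(names(vars), function(nm) {
    col <- vars[[nm]]
    if (!col %in% names(records)) return(NULL)
    v <- records[[col]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) # indicator/ordinal codes
    fit <- tryCatch(fit_variance_components(v, cid, method = method),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(variable = nm, icc = fit$icc,
               sigma2_between = fit$sigma2_between,
               sigma2_within = fit$sigma2_within,
               n = fit$n_individuals, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
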