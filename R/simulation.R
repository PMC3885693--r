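# Synthetic recruitment data and the Markov-assumption simulation.
#
# Two jobs live here. First, a Monte-Carlo check of the first-order Markov
# assumption: simulate a first-order autoregressive (AR(1)) trait along a
# *fixed* recruitment forest and compare its distance-correlation decay
# (rho^d under the assumption) against an observed profile. Second, a full
# synthetic-data generator — coupon-limited branching recruitment from
# seeds, attributes whose assortativity decays along edges, negative
# binomial diary degrees split over settings, household sizes and symptoms
# — emulating the webRDS pilot study conditions so that every analysis
# stage can be validated by parameter recovery without the deposited data.

#' Configuration of the synthetic generative model
#'
#' Defaults emulate the pilot survey: 80 completed seed respondents, four
#' coupons each, a per-coupon completion probability of 0.16 (140 completed
#' recruits from 880 coupons of 220 completers), recruitment chains up to
#' six waves deep, an age-like trait with edge correlation 0.555 (mean 26.7
#' years, SD 6.73), a two-level gender trait (61.6% / 38.4%, edge copy
#' probability 0.205), a three-level ordinal education trait (16.1% /
#' 63.0% / 20.9%, copy probability 0.52) and negative binomial diary
#' degrees with mean 88.2 and dispersion 0.57, mixed at random with respect
#' to degree.
#'
#' Categorical traits follow a "copy-or-draw" Markov kernel along edges:
#' with probability `copy_prob` the recruit takes the recruiter's value,
#' otherwise a fresh draw from the stationary distribution — a kernel whose
#' lag-1 correlation equals `copy_prob` under any numeric coding.
#'
#' @param n_seeds Number of seed respondents.
#' @param coupons Invitations handed to each respondent.
#' @param participation_prob Probability a single coupon yields a completed
#'   recruit.
#' @param max_waves Recruitment depth cap (nodes at this wave recruit no
#'   further).
#' @param rho Lag-1 edge correlation of the continuous (age-like) trait.
#' @param age_mean,age_sd Scale of the age-like trait.
#' @param categorical List per categorical trait: `levels`, `stationary`,
#'   `copy_prob`.
#' @param nb_mu,nb_k Negative binomial degree parameters (variance
#'   `mu + mu^2/k`).
#' @param degree_rho Edge correlation of degree on a latent Gaussian scale
#'   (0: random mixing by degree, as observed).
#' @param eating_mu,eating_k Negative binomial law of contacts while eating.
#' @param household_probs Distribution over household sizes 1..7 (the last
#'   class is open-ended: 7 plus a Poisson(1) excess).
#' @param symptom_rate Mean number of reported symptoms per person (out of
#'   8 named symptoms, drawn independently).
#' @param channel_probs Invitation-channel distribution for recruits.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @return A validated `simulation_config` (list).
#' @export
simulation_config <- function(n_seeds = 80L,
                              coupons = 4L,
                              participation_prob = 0.16,
                              max_waves = 6L,
                              rho = 0.555,
                              age_mean = 26.7, age_sd = 6.73,
                              categorical = list(
                                gender = list(
                                  levels = c("female", "male"),
                                  stationary = c(0.616, 0.384),
                                  copy_prob = 0.205),
                                education = list(
                                  levels = c("below_bachelor", "bachelor",
                                             "master_or_higher"),
                                  stationary = c(0.161, 0.630, 0.209),
                                  copy_prob = 0.52)),
                              nb_mu = 88.2, nb_k = 0.57,
                              degree_rho = 0,
                              eating_mu = 10, eating_k = 1,
                              household_probs = c(45, 21, 36, 45, 32, 15, 27) / 221,
                              symptom_rate = 1.8,
                              channel_probs = c(facebook = 0.836,
                                                direct_email = 0.114,
                                                forwarded_email = 0.05),
                              rng_seed = 1L) {
  stopifnot(n_seeds >= 1, coupons >= 1,
            participation_prob >= 0, participation_prob <= 1,
            max_waves >= 0, abs(rho) <= 1, abs(degree_rho) <= 1,
            nb_mu > 0, nb_k > 0, age_sd > 0)
  for (tr in categorical) {
    stopifnot(length(tr$levels) == length(tr$stationary),
              abs(sum(tr$stationary) - 1) < 1e-6,
              tr$copy_prob >= 0, tr$copy_prob <= 1)
  }
  stopifnot(abs(sum(household_probs) - 1) < 1e-6)
  structure(list(n_seeds = as.integer(n_seeds), coupons = as.integer(coupons),
                 participation_prob = participation_prob,
                 max_waves = as.integer(max_waves), rho = rho,
                 age_mean = age_mean, age_sd = age_sd,
                 categorical = categorical, nb_mu = nb_mu, nb_k = nb_k,
                 degree_rho = degree_rho, eating_mu = eating_mu,
                 eating_k = eating_k, household_probs = household_probs,
                 symptom_rate = symptom_rate, channel_probs = channel_probs,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Generate a recruitment forest by a coupon-limited branching process
#'
#' Starts `n_seeds` completed seeds; every completed respondent issues
#' `coupons` invitations, each independently yielding a completed recruit
#' with probability `participation_prob`; recruitment stops after
#' `max_waves` waves. Node identifiers are zero-padded so the seed is
#' always the smallest pid of its tree.
#'
#' @param config A `simulation_config`.
#' @param reseed Set the RNG from `config$rng_seed` first (default); the
#'   generator dataset builder passes `FALSE` to keep one stream.
#' @return A `recruitment_forest`.
#' @export
generate_forest <- function(config, reseed = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  if (reseed) set.seed(config$rng_seed)
  fmt <- function(i) sprintf("p%07d", i)
  pid <- fmt(seq_len(config$n_seeds))
  recruiter <- rep(NA_character_, config$n_seeds)
  current <- pid
  next_id <- config$n_seeds + 1L
  wave <- 0L
  while (length(current) > 0 && wave < config$max_waves) {
    n_child <- stats::rbinom(length(current), config$coupons,
                             config$participation_prob)
    total <- sum(n_child)
    if (total == 0) break
    child <- fmt(seq.int(next_id, length.out = total))
    parent <- rep(current, n_child)
    pid <- c(pid, child)
    recruiter <- c(recruiter, parent)
    current <- child
    next_id <- next_id + total
    wave <- wave + 1L
  }
  build_forest(data.frame(pid = pid, recruiter_pid = recruiter,
                          stringsAsFactors = FALSE),
               max_coupons = config$coupons)
}

# Propagate an AR(1) standard-normal trait down the forest, vectorised over
# replicates: seeds ~ N(0,1); child = rho * parent + sqrt(1-rho^2) * noise.
# Returns an n_nodes x n_reps matrix (rows in forest$nodes order).
ar1_traits <- function(forest, rho, n_reps) {
  nodes <- forest$nodes
  n <- nrow(nodes)
  parent <- match(nodes$recruiter_pid, nodes$pid)
  X <- matrix(NA_real_, n, n_reps)
  seeds <- which(nodes$is_seed)
  X[seeds, ] <- stats::rnorm(length(seeds) * n_reps)
  sd_innov <- sqrt(1 - rho^2)
  for (w in seq_len(max(nodes$wave))) {
    idx <- which(nodes$wave == w)
    X[idx, ] <- rho * X[parent[idx], , drop = FALSE] +
      sd_innov * stats::rnorm(length(idx) * n_reps)
  }
  X
}

#' Monte-Carlo AR(1) simulation on a fixed recruitment forest
#'
#' Tests the first-order Markov assumption: if attribute dependence along a
#' recruitment chain extends only one link with edge correlation `rho`, the
#' correlation between individuals at tree distance `d` decays as `rho^d`.
#' Each replicate draws standard-normal seed values and propagates
#' `child = rho * parent + sqrt(1 - rho^2) * noise` down the forest, then
#' records the symmetrized distance-`d` correlations. The replicate
#' distribution (median and central 95% envelope) is the null band against
#' which an observed distance profile is compared.
#'
#' @param forest A `recruitment_forest`.
#' @param rho Edge correlation, `|rho| <= 1`.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param rng_seed Integer seed.
#' @param max_d Distance lump threshold (distances `>= max_d` pooled).
#' @return An `ar1_simulation`: list with `summary` (data frame `distance`,
#'   `theoretical` = rho^d, `mean`, `median`, `q025`, `q975`, `n_pairs`)
#'   and `replicates` (matrix, one column per distance class).
#' @export
simulate_ar1_on_forest <- function(forest, rho, n_reps = 2000,
                                   rng_seed = 1L, max_d = 5) {
  stopifnot(abs(rho) <= 1, n_reps >= 1)
  set.seed(rng_seed)
  attr(forest, ".dist_cache") <- component_distances(forest)
  X <- ar1_traits(forest, rho, n_reps)
  pid_row <- stats::setNames(seq_len(nrow(forest$nodes)), forest$nodes$pid)

  classes <- c(as.list(seq_len(max_d - 1)), list(paste0(max_d, "+")))
  reps <- matrix(NA_real_, n_reps, length(classes))
  labels <- character(length(classes))
  n_pairs <- integer(length(classes))
  for (ci in seq_along(classes)) {
    lump <- is.character(classes[[ci]])
    dd <- if (lump) max_d else classes[[ci]]
    pr <- pairs_at_distance(forest, dd, mode = "symmetrized", min_d = lump)
    labels[ci] <- if (lump) paste0(max_d, "+") else as.character(dd)
    n_pairs[ci] <- nrow(pr)
    if (nrow(pr) < 3) next
    A <- X[pid_row[pr$i], , drop = FALSE]
    B <- X[pid_row[pr$j], , drop = FALSE]
    mA <- colMeans(A); mB <- colMeans(B)
    cov <- colMeans(A * B) - mA * mB
    sA <- sqrt(pmax(colMeans(A^2) - mA^2, 0))
    sB <- sqrt(pmax(colMeans(B^2) - mB^2, 0))
    reps[, ci] <- ifelse(sA > 0 & sB > 0, cov / (sA * sB), NA_real_)
  }
  colnames(reps) <- labels
  summary <- data.frame(
    distance = labels,
    theoretical = rho^c(seq_len(max_d - 1), max_d),
    mean = colMeans(reps, na.rm = TRUE),
    median = apply(reps, 2, stats::median, na.rm = TRUE),
    q025 = apply(reps, 2, stats::quantile, probs = 0.025, na.rm = TRUE),
    q975 = apply(reps, 2, stats::quantile, probs = 0.975, na.rm = TRUE),
    n_pairs = n_pairs, stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary, replicates = reps, rho = rho,
                 n_reps = n_reps), class = "ar1_simulation")
}

#' @export
print.ar1_simulation <- function(x, ...) {
  cat(sprintf("AR(1)-on-forest simulation: rho = %.3f, %d replicates\n",
              x$rho, x$n_reps))
  print(x$summary, digits = 3)
  invisible(x)
}

# Draw one categorical trait along the forest with the copy-or-draw kernel.
markov_categorical <- function(forest, levels, stationary, copy_prob) {
  nodes <- forest$nodes
  n <- nrow(nodes)
  parent <- match(nodes$recruiter_pid, nodes$pid)
  out <- character(n)
  seeds <- which(nodes$is_seed)
  out[seeds] <- sample(levels, length(seeds), replace = TRUE,
                       prob = stationary)
  for (w in seq_len(max(nodes$wave))) {
    idx <- which(nodes$wave == w)
    copy <- stats::runif(length(idx)) < copy_prob
    out[idx[copy]] <- out[parent[idx[copy]]]
    out[idx[!copy]] <- sample(levels, sum(!copy), replace = TRUE,
                              prob = stationary)
  }
  out
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

# Mean per-setting composition of degree (4 travel modes then 7 locations):
# travel roughly 30% of contacts, spread over modes and locations in line
# with a student diary (most contacts at school/work/home).
degree_composition_means <- c(
  travel_mass_transit = 3.6, travel_bus = 7.1, travel_car_taxi = 4.8,
  travel_motorbike = 3.7,
  loc_home = 8, loc_work = 10, loc_school_university = 12,
  loc_restaurant_coffee = 6, loc_sport_leisure = 4, loc_concert = 2,
  loc_other = 3.1)

#' Generate a full synthetic participant table
#'
#' Builds a recruitment forest with [generate_forest()], then attaches:
#' an age-like AR(1) trait rescaled to the target mean/SD; gender and
#' education via the copy-or-draw Markov kernel along edges; negative
#' binomial diary degrees (independent of topology unless `degree_rho` is
#' set, via a latent Gaussian AR(1) copula) split across the 4 travel and
#' 7 location settings by a per-respondent Dirichlet composition; contacts
#' while eating split over 4 meals; household sizes; independent symptom
#' draws; invitation channels and diary weekdays. The result is a standard
#' participant table ready for [build_forest()] and the analysis pipeline.
#'
#' @param config A `simulation_config`.
#' @return An `rds_participants` data frame (all rows completed).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  forest <- generate_forest(config, reseed = FALSE)
  nodes <- forest$nodes
  n <- nrow(nodes)

  z_age <- ar1_traits(forest, config$rho, 1)[, 1]
  age <- round(config$age_mean + config$age_sd * z_age)

  cats <- lapply(config$categorical, function(tr) {
    markov_categorical(forest, tr$levels, tr$stationary, tr$copy_prob)
  })

  if (config$degree_rho != 0) {
    zd <- ar1_traits(forest, config$degree_rho, 1)[, 1]
    degree <- stats::qnbinom(stats::pnorm(zd), size = config$nb_k,
                             mu = config$nb_mu)
  } else {
    degree <- stats::rnbinom(n, size = config$nb_k, mu = config$nb_mu)
  }

  comp <- rdirichlet1(n, degree_composition_means / 2) # concentration ~ sum/2
  setting <- matrix(0L, n, length(degree_composition_means),
                    dimnames = list(NULL, names(degree_composition_means)))
  pos <- degree > 0
  if (any(pos)) {
    setting[pos, ] <- t(vapply(which(pos), function(i) {
      stats::rmultinom(1, degree[i], comp[i, ])[, 1]
    }, integer(length(degree_composition_means))))
  }

  eating <- stats::rnbinom(n, size = config$eating_k, mu = config$eating_mu)
  meal_probs <- c(breakfast = 0.15, lunch = 0.35, dinner = 0.35, snack = 0.15)
  meals <- matrix(0L, n, 4, dimnames = list(NULL, paste0("eat_", names(meal_probs))))
  pos <- eating > 0
  if (any(pos)) {
    meals[pos, ] <- t(vapply(which(pos), function(i) {
      stats::rmultinom(1, eating[i], meal_probs)[, 1]
    }, integer(4)))
  }

  hh <- sample(seq_along(config$household_probs), n, replace = TRUE,
               prob = config$household_probs)
  open_class <- hh == length(config$household_probs)
  hh[open_class] <- hh[open_class] + stats::rpois(sum(open_class), 1)

  symptom_names <- c("fever", "headache", "muscle_pain", "runny_nose",
                     "sore_throat", "cough", "sneezing", "fatigue")
  p_sym <- config$symptom_rate / length(symptom_names)
  sym_mat <- matrix(stats::runif(n * length(symptom_names)) < p_sym, n)
  symptoms <- apply(sym_mat, 1, function(row) {
    if (!any(row)) NA_character_ else paste(symptom_names[row], collapse = ";")
  })

  channel <- rep(NA_character_, n)
  rec <- !nodes$is_seed
  channel[rec] <- sample(names(config$channel_probs), sum(rec),
                         replace = TRUE, prob = config$channel_probs)

  out <- data.frame(
    pid = nodes$pid, recruiter_pid = nodes$recruiter_pid,
    channel = channel, completed = TRUE,
    age = age, stringsAsFactors = FALSE)
  for (nm in names(cats)) out[[nm]] <- cats[[nm]]
  out$region_code <- sample(c("10200", "11000", "30000", "50000", NA),
                            n, replace = TRUE,
                            prob = c(0.25, 0.12, 0.28, 0.195, 0.155))
  out$household_size <- hh
  out <- cbind(out, as.data.frame(setting), as.data.frame(meals))
  out$symptoms <- symptoms
  out$household_symptomatic <- stats::rpois(n, 0.41)
  out$diary_weekday <- sample(c("mon", "tue", "wed", "thu", "fri", "sat",
                                "sun"), n, replace = TRUE)
  as_participants(out)
}
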