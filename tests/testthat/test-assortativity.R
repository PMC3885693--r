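test_that("a three-node path has exactly the grandparent pair at distance 2", {
  f <- build_forest(data.frame(pid = c("a", "b", "c"),
                               recruiter_pid = c(NA, "a", "b")))
  pr <- pairs_at_distance(f, 2, mode = "symmetrized")
  expect_equal(sort_pairs(pr), data.frame(i = c("a", "c"), j = c("c", "a")))
  dir <- pairs_at_distance(f, 2, mode = "directed")
  expect_equal(sort_pairs(dir), data.frame(i = "a", j = "c"))
})

test_that("a seed with four children yields 12 ordered sibling pairs at distance 2", {
  f <- build_forest(star_records(4))
  pr <- pairs_at_distance(f, 2, mode = "symmetrized")
  expect_equal(nrow(pr), 12) # C(4,2) unordered pairs, both orientations
  expect_true(all(pr$i != "s00") && all(pr$j != "s00"))
})

test_that("directed distance-1 pairs are exactly the recruiter-recruit edges", {
  set.seed(41)
  rec <- random_forest_records(50, n_seeds = 4)
  f <- build_forest(rec)
  pr <- pairs_at_distance(f, 1, mode = "directed")
  expect_equal(sort_pairs(data.frame(i = pr$i, j = pr$j)),
               sort_pairs(data.frame(i = f$edges$from, j = f$edges$to)))
})

test_that("pair sets at every distance match the all-pairs BFS oracle on a random forest", {
  set.seed(43)
  rec <- random_forest_records(60, n_seeds = 5)
  f <- build_forest(rec)
  D <- oracle_distances(rec)
  for (d in 1:max(D[is.finite(D)])) {
    got <- sort_pairs(pairs_at_distance(f, d, mode = "symmetrized"))
    want <- sort_pairs(oracle_pairs_at(rec, d))
    expect_equal(got, want, info = paste("distance", d))
  }
})

test_that("distance classes partition all within-component ordered pairs", {
  set.seed(47)
  rec <- random_forest_records(70, n_seeds = 6)
  f <- build_forest(rec)
  all_pairs <- do.call(rbind, lapply(1:70, function(d) {
    p <- pairs_at_distance(f, d, mode = "symmetrized")
    if (nrow(p)) as.data.frame(p[c("i", "j")]) else NULL
  }))
  expect_equal(anyDuplicated(all_pairs), 0)
  comp <- stats::setNames(f$nodes$component_id, f$nodes$pid)
  sizes <- table(f$nodes$component_id)
  expect_equal(nrow(all_pairs), sum(sizes * (sizes - 1)))
  expect_true(all(comp[all_pairs$i] == comp[all_pairs$j]))
})

test_that("identical values within every pair give estimate 1; zero variance errors", {
  f <- build_forest(chain_records(5))
  rec <- as_participants(data.frame(pid = f$nodes$pid, completed = TRUE))
  rec$trait <- seq_len(nrow(rec)) # value identical within self-pairs below
  self <- structure(data.frame(i = rec$pid, j = rec$pid),
                    distance = 0, mode = "directed",
                    class = c("distance_pairs", "data.frame"))
  for (st in c("pearson", "spearman")) {
    expect_equal(pair_correlation(self, rec, "trait", st)$estimate, 1)
  }
  rec$flat <- 1
  pr <- pairs_at_distance(f, 1)
  expect_error(pair_correlation(pr, rec, "flat", "pearson"), "zero variance")
})

test_that("phi equals Pearson on 0/1 indicator coding", {
  set.seed(53)
  rec <- random_forest_records(120, n_seeds = 6)
  rec$grp <- sample(c("yes", "no"), 120, TRUE)
  rec <- as_participants(rec)
  f <- build_forest(rec)
  pr <- pairs_at_distance(f, 1, mode = "directed")
  phi <- pair_correlation(pr, rec, "grp", "phi")
  ind <- as.numeric(factor(rec$grp, c("no", "yes"))) - 1
  names(ind) <- rec$pid
  expect_equal(phi$estimate, stats::cor(ind[pr$i], ind[pr$j]))
  expect_error(pair_correlation(pr, transform(rec, g3 = sample(letters[1:3],
    120, TRUE)), "g3", "phi"), "binary")
})

test_that("symmetrized estimates are invariant to pair orientation and CIs bracket them", {
  set.seed(59)
  rec <- random_forest_records(150, n_seeds = 5)
  rec$age <- round(stats::rnorm(150, 27, 7))
  rec <- as_participants(rec)
  f <- build_forest(rec)
  pr <- pairs_at_distance(f, 2, mode = "symmetrized")
  res <- pair_correlation(pr, rec, "age", "pearson")
  flipped <- structure(data.frame(i = pr$j, j = pr$i),
                       distance = 2, mode = "symmetrized",
                       class = c("distance_pairs", "data.frame"))
  expect_equal(pair_correlation(flipped, rec, "age", "pearson")$estimate,
               res$estimate)
  expect_lte(res$ci_low, res$estimate)
  expect_gte(res$ci_high, res$estimate)
  expect_lte(abs(res$estimate), 1)
})

test_that("missing-attribute pairs are dropped listwise and counted", {
  f <- build_forest(chain_records(9))
  rec <- as_participants(data.frame(pid = f$nodes$pid, completed = TRUE))
  set.seed(61)
  rec$v <- stats::rnorm(10)
  rec$v[3] <- NA
  res <- pair_correlation(pairs_at_distance(f, 1, mode = "directed"),
                          rec, "v", "pearson")
  expect_equal(res$n_dropped, 2) # the NA node sits in two edges
  expect_equal(res$n_pairs, 7)
  expect_equal(res$df, 5)
})

test_that("a constant attribute is undefined at every distance in the profile", {
  f <- build_forest(chain_records(8))
  rec <- as_participants(data.frame(pid = f$nodes$pid, completed = TRUE,
                                    c0 = 3))
  prof <- distance_profile(f, rec, "c0", "pearson", max_d = 4)
  expect_equal(prof$distance, c("1", "2", "3", "4+"))
  expect_true(all(is.na(prof$estimate)))
})

test_that("profile on AR(1) traits decays like rho^d on a deep synthetic forest", {
  set.seed(67)
  cfg <- simulation_config(n_seeds = 60, coupons = 2,
                           participation_prob = 0.6, max_waves = 12,
                           rng_seed = 67)
  f <- generate_forest(cfg)
  # one draw of the AR(1) trait, correlated rho = 0.5 along edges
  rho <- 0.5
  nodes <- f$nodes
  parent <- match(nodes$recruiter_pid, nodes$pid)
  z <- numeric(nrow(nodes))
  z[nodes$is_seed] <- stats::rnorm(sum(nodes$is_seed))
  for (w in seq_len(max(nodes$wave))) {
    idx <- which(nodes$wave == w)
    z[idx] <- rho * z[parent[idx]] + sqrt(1 - rho^2) * stats::rnorm(length(idx))
  }
  rec <- as_participants(data.frame(pid = nodes$pid, completed = TRUE,
                                    trait = z))
  prof <- distance_profile(f, rec, "trait", "pearson", max_d = 4)
  for (d in 1:3) {
    n_eff <- prof$n_pairs[d] / 2
    tol <- 3 / sqrt(n_eff - 3) + 0.02
    expect_lt(abs(prof$estimate[d] - rho^d), tol)
  }
})

test_that("the linked-pair table reports the standard variable set with sane rows", {
  rec <- derive_measures(zero_fill(synthetic_diary_records(200, seed = 71)))
  f <- build_forest(rec)
  tab <- linked_pair_table(rec, f)
  expect_equal(tab$variable,
               c("age", "gender", "education", "degree_log",
                 "household_size_log", "food_with_log", "symptoms_log",
                 "two_plus_symptoms"))
  expect_true(all(abs(tab$estimate) <= 1, na.rm = TRUE))
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high,
                  na.rm = TRUE))
  # the household filter blanks implausible reports
  rec$household_size[1] <- 900
  rec <- derive_measures(rec)
  tab2 <- linked_pair_table(rec, f, household_cap = 500)
  hh <- tab2[tab2$variable == "household_size_log", ]
  expect_true(hh$n_dropped >= 1 || hh$n_pairs < tab$n_pairs[5])
})
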