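vh_fixture <- function(pid, degree, cat, recruiter = NULL) {
  as_participants(data.frame(
    pid = pid, recruiter_pid = recruiter %||% c(NA, pid[-length(pid)]),
    completed = TRUE, degree = degree, cat = cat,
    stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("equal degrees make VH proportions coincide with raw shares exactly", {
  rec <- vh_fixture(sprintf("p%02d", 1:20), degree = rep(7, 20),
                    cat = rep(c("A", "B", "B", "B"), 5))
  est <- vh_estimate(rec, "cat")
  expect_equal(est$vh_proportions, est$raw_proportions)
  expect_equal(unname(est$vh_proportions), c(0.25, 0.75))
})

test_that("two individuals with degrees 1 and 3 split as 0.75 / 0.25", {
  rec <- vh_fixture(c("a", "b"), degree = c(1, 3), cat = c("A", "B"),
                    recruiter = c(NA, "a"))
  est <- vh_estimate(rec, "cat")
  expect_equal(unname(est$vh_proportions), c(0.75, 0.25))
})

test_that("VH proportions and weights always sum to 1 and survive degree rescaling", {
  set.seed(29)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    rec <- vh_fixture(sprintf("q%03d", seq_len(n)),
                      degree = sample(1:200, n, TRUE),
                      cat = sample(letters[1:4], n, TRUE))
    est <- vh_estimate(rec, "cat")
    expect_equal(sum(est$vh_proportions), 1)
    expect_equal(sum(est$weights), 1)
    expect_true(all(est$weights > 0))
    rec2 <- rec; rec2$degree <- rec2$degree * 17
    expect_equal(vh_estimate(rec2, "cat")$vh_proportions,
                 est$vh_proportions)
  }
})

test_that("zero or missing degrees are excluded and counted; empty input errors", {
  rec <- vh_fixture(c("a", "b", "c", "d"), degree = c(2, 0, NA, 5),
                    cat = c("A", "A", "B", "B"))
  est <- vh_estimate(rec, "cat")
  expect_equal(est$n_used, 2)
  expect_equal(est$excluded, 2)
  rec$degree <- 0
  expect_error(vh_estimate(rec, "cat"), "positive degree")
})

test_that("VH corrects degree-biased sampling better than the raw share", {
  set.seed(33)
  N <- 3000
  true_prop <- 0.3
  pop_cat <- rep(c("A", "B"), round(N * c(true_prop, 1 - true_prop)))
  pop_deg <- ifelse(pop_cat == "A", # degree differs by group -> raw is biased
                    stats::rnbinom(N, size = 2, mu = 30),
                    stats::rnbinom(N, size = 2, mu = 10)) + 1
  errs <- t(replicate(100, {
    take <- sample(N, 300, prob = pop_deg)
    rec <- vh_fixture(sprintf("s%04d", seq_len(300)),
                      degree = pop_deg[take], cat = pop_cat[take])
    est <- vh_estimate(rec, "cat")
    c(raw = abs(est$raw_proportions[["A"]] - true_prop),
      vh = abs(est$vh_proportions[["A"]] - true_prop))
  }))
  expect_lt(mean(errs[, "vh"]), mean(errs[, "raw"]))
})

test_that("a constant attribute yields flat composition curves at 1", {
  rec <- derive_measures(zero_fill(synthetic_diary_records(60, seed = 37)))
  rec$const <- "only"
  f <- build_forest(rec)
  cc <- composition_curves(rec, f, "const")
  expect_true(all(cc$per_wave$value == 1))
  expect_true(all(cc$by_sample_size$raw == 1))
  expect_true(all(cc$by_sample_size$vh == 1))
})

test_that("cumulative wave composition is the weighted average of the waves so far", {
  rec <- as_participants(data.frame(
    pid = c("s1", "s2", "r1", "r2", "r3"),
    recruiter_pid = c(NA, NA, "s1", "s1", "s2"),
    completed = TRUE, degree = 10,
    grp = c("A", "A", "B", "B", "A"), stringsAsFactors = FALSE))
  f <- build_forest(rec)
  cc <- composition_curves(rec, f, "grp")
  w1 <- cc$cumulative_wave[cc$cumulative_wave$wave == 1, ]
  expect_equal(w1$value[w1$category == "A"], 3 / 5) # (2*1 + 3*(1/3)) / 5
  expect_equal(w1$value[w1$category == "B"], 2 / 5)
})

test_that("the running estimate at full sample equals the overall proportion", {
  rec <- derive_measures(zero_fill(synthetic_diary_records(120, seed = 39)))
  f <- build_forest(rec)
  cc <- composition_curves(rec, f, "gender")
  last <- cc$by_sample_size[cc$by_sample_size$n == max(cc$by_sample_size$n), ]
  overall <- prop.table(table(rec$gender))
  for (g in last$category) {
    expect_equal(last$raw[last$category == g], unname(overall[g]))
  }
  est <- vh_estimate(rec, "gender")
  for (g in last$category) {
    expect_equal(last$vh[last$category == g],
                 unname(est$vh_proportions[g]), tolerance = 1e-10)
  }
})

test_that("a wave-drifting attribute is tracked by the per-wave curve", {
  set.seed(49)
  cfg <- simulation_config(n_seeds = 120, participation_prob = 0.45,
                           max_waves = 4, rng_seed = 49)
  f <- generate_forest(cfg)
  # drift: probability of "A" falls linearly with wave
  p_by_wave <- c(0.9, 0.7, 0.5, 0.3, 0.2)
  drift <- rbinom(nrow(f$nodes), 1, p_by_wave[f$nodes$wave + 1])
  rec <- as_participants(data.frame(pid = f$nodes$pid, completed = TRUE,
                                    degree = 10,
                                    grp = ifelse(drift == 1, "A", "B")))
  cc <- composition_curves(rec, f, "grp")
  pw <- cc$per_wave[cc$per_wave$category == "A", ]
  for (w in pw$wave) {
    n_w <- pw$n[pw$wave == w]
    expect_lt(abs(pw$value[pw$wave == w] - p_by_wave[w + 1]),
              3 * sqrt(0.25 / n_w) + 0.05)
  }
})
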