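test_that("a lone seed forms one component at wave 0", {
  f <- build_forest(data.frame(pid = "s", recruiter_pid = NA))
  expect_equal(f$nodes$wave, 0L)
  expect_equal(f$nodes$component_id, "s")
  expect_equal(nrow(f$edges), 0)
})

test_that("a six-link chain reaches wave six", {
  f <- build_forest(chain_records(6))
  expect_equal(max(f$nodes$wave), 6L)
  expect_equal(sort(f$nodes$wave), 0:6)
})

test_that("waves on a 200-node random forest equal BFS depth from seeds", {
  set.seed(101)
  rec <- random_forest_records(200, n_seeds = 12)
  f <- build_forest(rec)
  D <- oracle_distances(rec)
  seeds <- rec$pid[is.na(rec$recruiter_pid)]
  bfs_wave <- apply(D[, seeds, drop = FALSE], 1, min)
  expect_equal(f$nodes$wave, unname(bfs_wave[f$nodes$pid]))
})

test_that("forest construction is order-independent and idempotent", {
  set.seed(7)
  rec <- random_forest_records(80, n_seeds = 5)
  f1 <- build_forest(rec)
  f2 <- build_forest(rec[sample(nrow(rec)), ])
  expect_identical(f1$nodes, f2$nodes)
  expect_identical(f1$edges, f2$edges)
  expect_identical(build_forest(rec)$nodes, f1$nodes)
})

test_that("component sizes and the wave histogram partition the nodes", {
  set.seed(11)
  rec <- random_forest_records(150, n_seeds = 9)
  f <- build_forest(rec)
  expect_equal(sum(table(f$nodes$component_id)), nrow(f$nodes))
  expect_equal(sum(table(f$nodes$wave)), nrow(f$nodes))
  # every component is labelled by its smallest member pid
  labs <- tapply(f$nodes$pid, f$nodes$component_id, min)
  expect_identical(as.character(labs), names(labs))
})

test_that("cycles and coupon violations are hard errors", {
  cyc <- data.frame(pid = c("a", "b", "c"), recruiter_pid = c("c", "a", "b"))
  expect_error(build_forest(cyc), "cycle")
  fan <- data.frame(pid = c("s", paste0("k", 1:5)),
                    recruiter_pid = c(NA, rep("s", 5)))
  expect_error(build_forest(fan), "coupon limit: s")
})

test_that("DOT export of a 3-node tree carries two directed edges", {
  f <- build_forest(data.frame(pid = c("s", "a", "b"),
                               recruiter_pid = c(NA, "s", "a")))
  path <- withr::local_tempfile(fileext = ".dot")
  export_forest(f, path, format = "dot")
  txt <- readLines(path)
  expect_length(grep("->", txt), 2)
})

test_that("GraphML export round-trips to an isomorphic graph with intact components", {
  set.seed(13)
  rec <- random_forest_records(60, n_seeds = 6)
  f <- build_forest(rec)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_forest(f, path, format = "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 60)
  expect_equal(igraph::ecount(g), nrow(f$edges))
  expect_equal(igraph::count_components(g),
               length(unique(f$nodes$component_id)))
  expect_true(igraph::isomorphic(g, forest_to_igraph(f)))
  expect_error(export_forest(f, path, format = "gexf"))
})

test_that("one recruiter with four coupons and one completion returns 25%", {
  rec <- as_participants(data.frame(
    pid = c("s", "a"), recruiter_pid = c(NA, "s"),
    channel = c(NA, "facebook"), channel_used = c("facebook", NA),
    completed = TRUE))
  s <- recruitment_summary(rec, build_forest(rec))
  expect_equal(s$totals$coupons_issued, 4)
  expect_equal(s$totals$successful_recruitments, 1)
  expect_equal(s$totals$return_rate_pct, 25)
})

test_that("a channel row with recruiter histogram 53/35/10/10/8 totals 117 successes", {
  hist <- c(53, 35, 10, 10, 8)
  seeds <- sprintf("s%03d", seq_len(sum(hist)))
  n_kids <- rep(0:4, hist)
  kids <- sprintf("r%03d", seq_len(sum(n_kids)))
  rec <- as_participants(data.frame(
    pid = c(seeds, kids),
    recruiter_pid = c(rep(NA, length(seeds)), rep(seeds, n_kids)),
    channel = c(rep(NA, length(seeds)), rep("facebook", length(kids))),
    channel_used = c(rep("facebook", length(seeds)), rep(NA, length(kids))),
    completed = TRUE))
  s <- recruitment_summary(rec, build_forest(rec))
  fb <- s$by_channel[s$by_channel$channel == "facebook", ]
  expect_equal(fb$successes, 117)
  expect_equal(unlist(fb[paste0("recruiters_with_", 0:4)], use.names = FALSE),
               hist)
  expect_equal(fb$pct_successes, 100)
})

test_that("per-channel totals equal a brute-force tally on a random forest", {
  set.seed(23)
  rec <- random_forest_records(120, n_seeds = 8)
  rec$channel <- ifelse(is.na(rec$recruiter_pid), NA,
                        sample(c("facebook", "direct_email"), 120, TRUE))
  rec$completed <- sample(c(TRUE, FALSE), 120, TRUE, prob = c(0.8, 0.2))
  rec <- as_participants(rec)
  s <- recruitment_summary(rec, build_forest(rec))
  for (ch in c("facebook", "direct_email")) {
    brute <- sum(!is.na(rec$recruiter_pid) & rec$channel == ch &
                   rec$completed)
    expect_equal(s$by_channel$successes[s$by_channel$channel == ch], brute)
  }
})
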