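# Independent oracles and fixture builders. These deliberately avoid the
# package's own graph code paths: distances come from a hand-rolled BFS on
# an adjacency list, tallies from brute-force loops.

# All-pairs shortest-path distances on the undirected recruitment graph,
# by breadth-first search from every node. Rows/cols named by pid.
oracle_distances <- function(records) {
  pids <- records$pid
  n <- length(pids)
  adj <- vector("list", n)
  names(adj) <- pids
  for (r in seq_len(n)) {
    p <- records$recruiter_pid[r]
    if (!is.na(p)) {
      adj[[records$pid[r]]] <- c(adj[[records$pid[r]]], p)
      adj[[p]] <- c(adj[[p]], records$pid[r])
    }
  }
  D <- matrix(Inf, n, n, dimnames = list(pids, pids))
  for (s in pids) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(D[s, v])) {
            D[s, v] <- d
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- nxt
    }
  }
  D
}

# Random recruitment records: each non-seed picks a uniformly random parent
# among earlier nodes that still have coupons left. Independent of the
# package's branching-process generator.
random_forest_records <- function(n, n_seeds = max(1L, n %/% 20L),
                                  max_coupons = 4L) {
  pid <- sprintf("n%04d", seq_len(n))
  recruiter <- rep(NA_character_, n)
  out_deg <- integer(n)
  for (i in seq_len(n)[-seq_len(n_seeds)]) {
    open <- which(out_deg[seq_len(i - 1)] < max_coupons)
    p <- if (length(open) == 1) open else sample(open, 1)
    recruiter[i] <- pid[p]
    out_deg[p] <- out_deg[p] + 1L
  }
  data.frame(pid = pid, recruiter_pid = recruiter, completed = TRUE,
             stringsAsFactors = FALSE)
}

# A single chain s -> a -> b -> ... with `links` edges.
chain_records <- function(links) {
  pid <- sprintf("c%02d", 0:links)
  data.frame(pid = pid,
             recruiter_pid = c(NA, pid[-(links + 1)]),
             completed = TRUE, stringsAsFactors = FALSE)
}

# One seed with `k` direct recruits.
star_records <- function(k = 4) {
  data.frame(pid = c("s00", sprintf("k%02d", seq_len(k))),
             recruiter_pid = c(NA, rep("s00", k)),
             completed = TRUE, stringsAsFactors = FALSE)
}

# Small complete diary table for IO round-trips and derivations.
synthetic_diary_records <- function(n = 50, seed = 42) {
  set.seed(seed)
  cfg <- simulation_config(n_seeds = max(2L, n %/% 10L),
                           participation_prob = 0.45, rng_seed = seed)
  rec <- generate_dataset(cfg)
  rec[seq_len(min(n, nrow(rec))), , drop = FALSE]
}

# Hand-rolled distance pairs for a fixed distance, from the BFS oracle.
oracle_pairs_at <- function(records, d, min_d = FALSE) {
  D <- oracle_distances(records)
  sel <- if (min_d) which(D >= d & is.finite(D), arr.ind = TRUE)
         else which(D == d, arr.ind = TRUE)
  data.frame(i = rownames(D)[sel[, 1]], j = colnames(D)[sel[, 2]],
             stringsAsFactors = FALSE)
}

sort_pairs <- function(df) {
  df <- df[order(df$i, df$j), c("i", "j"), drop = FALSE]
  rownames(df) <- NULL
  as.data.frame(df)
}

# Closed-form balanced one-way ANOVA variance-component estimator.
balanced_anova_components <- function(y, g) {
  groups <- split(y, g)
  n <- unique(lengths(groups))
  stopifnot(length(n) == 1)
  a <- length(groups)
  gm <- mean(y)
  msb <- n * sum((vapply(groups, mean, numeric(1)) - gm)^2) / (a - 1)
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                    numeric(1))) / (a * (n - 1))
  c(s2b = (msb - msw) / n, s2w = msw)
}
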