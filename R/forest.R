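# Recruitment forest reconstruction and graph export.
#
# Recruitment in RDS produces a directed forest: each participant has at
# most one recruiter, seeds have none, and nobody hands out more coupons
# than the study allows (four here). Waves count recruitment steps from the
# seed; components are the recruitment trees.

#' Reconstruct the recruitment forest from participant records
#'
#' Builds the directed recruiter-to-recruit forest, assigns each participant
#' a wave (0 for seeds, parent wave + 1 otherwise) and labels each weakly
#' connected component by its smallest member pid so component identifiers
#' are deterministic regardless of input order.
#'
#' @param records An `rds_participants` data frame (or anything
#'   [as_participants()] accepts).
#' @param max_coupons Maximum recruits allowed per participant; the study
#'   design hands every respondent four coupons.
#' @return A `recruitment_forest`: list with `nodes` (data frame `pid`,
#'   `recruiter_pid`, `is_seed`, `wave`, `component_id`, sorted by pid) and
#'   `edges` (data frame `from`, `to`).
#'
#' @details Errors on recruitment cycles (the offending cycle is listed) and
#'   on any recruiter exceeding `max_coupons` recruits.
#' @export
build_forest <- function(records, max_coupons = 4L) {
  if (!inherits(records, "rds_participants")) records <- as_participants(records)
  nodes <- data.frame(pid = records$pid,
                      recruiter_pid = records$recruiter_pid,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$pid), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$is_seed <- is.na(nodes$recruiter_pid)

  outdeg <- table(nodes$recruiter_pid[!nodes$is_seed])
  over <- names(outdeg)[outdeg > max_coupons]
  if (length(over)) {
    stopf("recruiter(s) exceed the %d-coupon limit: %s", max_coupons,
          paste(over, collapse = ", "))
  }

  n <- nrow(nodes)
  parent <- match(nodes$recruiter_pid, nodes$pid)  # NA for seeds
  wave <- rep.int(NA_integer_, n)
  wave[nodes$is_seed] <- 0L
  # Peel waves breadth-first; if no progress is made while unassigned nodes
  # remain, the remainder must sit on a cycle.
  repeat {
    ready <- which(is.na(wave) & !is.na(wave[parent]))
    if (!length(ready)) break
    wave[ready] <- wave[parent[ready]] + 1L
  }
  if (anyNA(wave)) {
    cyc <- nodes$pid[cycle_members(parent, which(is.na(wave))[1L])]
    stopf("recruitment cycle detected: %s", paste(cyc, collapse = " -> "))
  }
  nodes$wave <- wave

  # Component = root seed's subtree; label by smallest member pid.
  root <- seq_len(n)
  while (any(!is.na(parent[root]))) {
    step <- !is.na(parent[root])
    root[step] <- parent[root[step]]
  }
  comp_label <- vapply(split(nodes$pid, root), min, character(1))
  nodes$component_id <- unname(comp_label[as.character(root)])

  edges <- data.frame(from = nodes$recruiter_pid[!nodes$is_seed],
                      to = nodes$pid[!nodes$is_seed],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes, edges = edges), class = "recruitment_forest")
}

# Walk parent pointers from `start` until a node repeats; return the cycle.
cycle_members <- function(parent, start) {
  seen <- integer(0)
  i <- start
  while (!(i %in% seen)) {
    seen <- c(seen, i)
    i <- parent[i]
  }
  cyc <- seen[which(seen == i):length(seen)]
  c(cyc, i)
}

#' @export
print.recruitment_forest <- function(x, ...) {
  comp_sizes <- table(x$nodes$component_id)
  cat(sprintf(paste0("<recruitment_forest> %d participants, %d components",
                     " (largest %d), max wave %d\n"),
              nrow(x$nodes), length(comp_sizes), max(comp_sizes),
              max(x$nodes$wave)))
  invisible(x)
}

#' Convert a recruitment forest to an igraph object
#'
#' @param forest A `recruitment_forest`.
#' @param records Optional participant records supplying node attributes
#'   (`age`, `gender`, `education`) for visualisation.
#' @return A directed `igraph` graph with an `is_seed` vertex attribute.
#' @export
forest_to_igraph <- function(forest, records = NULL) {
  g <- igraph::graph_from_data_frame(forest$edges, directed = TRUE,
                                     vertices = forest$nodes["pid"])
  ord <- match(igraph::V(g)$name, forest$nodes$pid)
  g <- igraph::set_vertex_attr(g, "is_seed",
                               value = as.integer(forest$nodes$is_seed[ord]))
  g <- igraph::set_vertex_attr(g, "wave", value = forest$nodes$wave[ord])
  if (!is.null(records)) {
    ridx <- match(igraph::V(g)$name, records$pid)
    for (attr in intersect(c("age", "gender", "education"), names(records))) {
      v <- records[[attr]][ridx]
      if (is.numeric(v)) v[is.na(v)] <- -1 else v[is.na(v)] <- "missing"
      g <- igraph::set_vertex_attr(g, attr, value = v)
    }
  }
  g
}

#' Export a recruitment forest for graph tooling
#'
#' Serialises the forest as GraphML or DOT, with node attributes attached
#' when participant records are supplied, so trees can be rendered by
#' standard graph software.
#'
#' @inheritParams forest_to_igraph
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_forest <- function(forest, path, format = c("graphml", "dot"),
                          records = NULL) {
  format <- match.arg(format)
  g <- forest_to_igraph(forest, records)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Tabulate recruitment success by invitation channel
#'
#' Summarises how recruitment went: for each invitation channel, how many
#' inviters achieved 0 to `max_coupons` completed recruits, the channel's
#' total successful recruitments with percentages, and overall totals —
#' coupons issued (`max_coupons` per inviter), survey entries, completions,
#' and the coupon return rate.
#'
#' A recruit's `channel` column records how they were invited, so successful
#' recruitments are attributed through it. Inviters whose coupons all went
#' unanswered are only visible when the table carries a `channel_used`
#' column (the channel a respondent chose when sending invitations, missing
#' if they never invited anyone); without it the zero-success row is `NA`
#' and coupons are counted over observed recruiters only.
#'
#' @param records An `rds_participants` data frame with `channel` and
#'   `completed` columns, optionally `channel_used`.
#' @param forest The matching `recruitment_forest`.
#' @param max_coupons Coupons handed to each respondent (4).
#' @return List with `by_channel` (data frame `channel`,
#'   `recruiters_with_0`..`recruiters_with_4`, `successes`, `pct_successes`)
#'   and `totals` (named list).
#' @export
recruitment_summary <- function(records, forest, max_coupons = 4L) {
  if (!inherits(records, "rds_participants")) records <- as_participants(records)
  recruits <- forest$nodes[!forest$nodes$is_seed, , drop = FALSE]
  ridx <- match(recruits$pid, records$pid)
  ch <- if ("channel" %in% names(records)) records$channel[ridx]
        else rep("unknown", nrow(recruits))
  ch[is.na(ch)] <- "unknown"
  ok <- records$completed[ridx]
  ok[is.na(ok)] <- FALSE
  succ <- data.frame(recruiter = recruits$recruiter_pid[ok],
                     channel = ch[ok], stringsAsFactors = FALSE)

  has_used <- "channel_used" %in% names(records)
  if (has_used) {
    inviter <- records[records$completed & !is.na(records$channel_used), ,
                       drop = FALSE]
    n_inviters <- nrow(inviter)
  } else {
    inviter <- NULL
    n_inviters <- length(unique(succ$recruiter))
  }

  channels <- sort(unique(c(succ$channel,
                            if (has_used) inviter$channel_used)))
  by_channel <- do.call(rbind, lapply(channels, function(cc) {
    per_recruiter <- table(succ$recruiter[succ$channel == cc])
    hist <- vapply(seq_len(max_coupons),
                   function(k) sum(per_recruiter == k), integer(1))
    zero <- if (has_used) {
      sum(inviter$channel_used == cc &
            !(inviter$pid %in% names(per_recruiter)))
    } else NA_integer_
    data.frame(channel = cc, t(stats::setNames(
      c(zero, hist), paste0("recruiters_with_", 0:max_coupons))),
      successes = sum(succ$channel == cc), stringsAsFactors = FALSE)
  }))
  total_success <- sum(by_channel$successes)
  by_channel$pct_successes <-
    if (total_success > 0) 100 * by_channel$successes / total_success else 0

  coupons <- max_coupons * n_inviters
  totals <- list(
    entries = nrow(records),
    completions = sum(records$completed, na.rm = TRUE),
    inviters = n_inviters,
    coupons_issued = coupons,
    successful_recruitments = total_success,
    return_rate_pct = if (coupons > 0) 100 * total_success / coupons else NA_real_
  )
  list(by_channel = by_channel, totals = totals)
}
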