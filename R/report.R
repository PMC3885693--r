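# One-call pipeline: read -> zero-fill -> derive -> forest -> all analyses,
# with a deterministic file bundle for downstream plotting and archiving.

#' Run the full analysis pipeline and write a report bundle
#'
#' Chains every stage on one participant table: validation, zero-filling,
#' derived measures, forest reconstruction, recruitment summary, negative
#' binomial degree fit, linked-pair assortativity table, distance profiles,
#' ICC table, Volz-Heckathorn estimates and composition curves, plus a
#' GraphML export of the forest. All outputs are plain delimited tables or
#' JSON and are byte-identical across repeated runs on the same input.
#'
#' @param input Path to a participant table, or an `rds_participants` data
#'   frame.
#' @param out_dir Output directory (created if needed). `NULL` skips file
#'   output and just returns the results.
#' @param degree_cap,eating_cap Censoring caps, see [derive_measures()].
#' @param max_d Distance lump threshold for profiles.
#' @param profile_attributes Named character vector
#'   `c(column = statistic, ...)` of distance profiles to compute.
#' @param vh_attributes Columns for Volz-Heckathorn estimation.
#' @param col_map,lenient_orphans Passed to [read_participants()] when
#'   `input` is a path.
#' @return List with `records`, `forest`, `recruitment`, `nb_fit`,
#'   `linked_pairs`, `profiles`, `icc`, `vh`, `composition`, invisibly when
#'   writing files.
#' @export
run_report <- function(input, out_dir = NULL, degree_cap = 500,
                       eating_cap = 75, max_d = 5,
                       profile_attributes = c(age = "pearson",
                                              gender = "phi",
                                              education = "spearman",
                                              log_degree = "pearson"),
                       vh_attributes = c("gender", "education"),
                       col_map = NULL, lenient_orphans = FALSE) {
  records <- if (is.character(input)) {
    read_participants(input, col_map = col_map,
                      lenient_orphans = lenient_orphans)
  } else {
    as_participants(input, lenient_orphans = lenient_orphans)
  }
  records <- zero_fill(records)
  records <- derive_measures(records, degree_cap = degree_cap,
                             eating_cap = eating_cap)
  forest <- build_forest(records)

  done <- records[records$completed %in% TRUE, , drop = FALSE]
  nb <- tryCatch(fit_negative_binomial(done$degree), error = function(e) NULL)
  profiles <- lapply(names(profile_attributes), function(a) {
    if (!a %in% names(records)) return(NULL)
    tryCatch(distance_profile(forest, records, a,
                              statistic = profile_attributes[[a]],
                              max_d = max_d),
             error = function(e) NULL)
  })
  names(profiles) <- names(profile_attributes)
  vh <- lapply(intersect(vh_attributes, names(records)), function(a) {
    tryCatch(vh_estimate(records, a), error = function(e) NULL)
  })
  names(vh) <- intersect(vh_attributes, names(records))
  comp <- lapply(names(vh), function(a) {
    tryCatch(composition_curves(records, forest, a), error = function(e) NULL)
  })
  names(comp) <- names(vh)

  res <- list(records = records, forest = forest,
              recruitment = recruitment_summary(records, forest),
              nb_fit = nb,
              linked_pairs = linked_pair_table(records, forest),
              profiles = profiles,
              icc = icc_table(records, forest),
              vh = vh, composition = comp)
  if (is.null(out_dir)) return(res)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "")
  }
  wt(res$linked_pairs, "linked_pair_correlations.tsv")
  wt(res$icc, "icc_table.tsv")
  wt(res$recruitment$by_channel, "recruitment_by_channel.tsv")
  for (a in names(profiles)) {
    if (!is.null(profiles[[a]])) wt(profiles[[a]],
                                    paste0("distance_profile_", a, ".tsv"))
  }
  if (!is.null(nb)) {
    jsonlite::write_json(
      list(mu = nb$mu, k = nb$k, se_mu = nb$se_mu, se_k = nb$se_k,
           loglik = nb$loglik, n = nb$n, converged = nb$converged),
      file.path(out_dir, "degree_fit.json"), auto_unbox = TRUE, digits = NA)
    wt(degree_histogram(done$degree, nb), "degree_histogram.tsv")
  }
  vh_json <- lapply(vh, function(e) {
    if (is.null(e)) return(NULL)
    list(categories = e$categories, raw = e$raw_proportions,
         vh = e$vh_proportions, n_used = e$n_used, excluded = e$excluded)
  })
  jsonlite::write_json(vh_json, file.path(out_dir, "vh_estimates.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$recruitment$totals,
                       file.path(out_dir, "recruitment_totals.json"),
                       auto_unbox = TRUE, digits = NA)
  export_forest(forest, file.path(out_dir, "forest.graphml"),
                format = "graphml", records = records)
  invisible(res)
}
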