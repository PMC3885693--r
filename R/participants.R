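# Reading, validating and writing participant tables.
#
# A participant table has one row per respondent who entered the survey:
# identity, recruitment link (empty recruiter for seeds), invitation channel,
# completion flag, demographics, household information, per-setting diary
# counts and self-reported symptoms. Missing values stay missing on read;
# zero-filling is an explicit, separate step (see zero_fill()).

#' Read a participant table
#'
#' Reads a delimited text file with one row per respondent and validates the
#' identifier structure. The file must have a header naming at least `pid`;
#' every other column is optional and unknown columns are preserved
#' untouched. Missing values (`""` or `NA`) are kept missing — use
#' [zero_fill()] for the completers-only missing-as-zero rule.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator. `NULL` (default) chooses between comma and tab
#'   by inspecting the header line.
#' @param col_map Optional named character vector mapping file headers to
#'   canonical column names, e.g. `c(id = "pid", inviter = "recruiter_pid")`,
#'   so externally deposited tables can be adapted without editing them.
#' @param lenient_orphans If `TRUE`, a `recruiter_pid` that does not match
#'   any `pid` demotes the row to a seed with a warning instead of failing.
#' @return A `data.frame` of class `rds_participants`.
#'
#' @details Hard validation errors: a missing `pid` column, empty or
#'   duplicated `pid` values (all duplicates are listed), and — unless
#'   `lenient_orphans` — recruiter references to unknown participants.
#'   Count columns that fail to parse as numbers are reported with their row
#'   numbers.
#' @export
read_participants <- function(path, sep = NULL, col_map = NULL,
                              lenient_orphans = FALSE) {
  if (!file.exists(path)) stopf("participant table not found: %s", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, quote = "\"",
                           stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- unname(col_map[names(raw)[hit]])
  }
  as_participants(raw, lenient_orphans = lenient_orphans)
}

#' Coerce a data frame to a validated participant table
#'
#' @param x A data frame with at least a `pid` column; counts may be
#'   character (as read from text) or numeric.
#' @inheritParams read_participants
#' @return A `data.frame` of class `rds_participants`.
#' @export
as_participants <- function(x, lenient_orphans = FALSE) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"pid" %in% names(x)) stopf("participant table lacks a 'pid' column")
  pid <- as.character(x$pid)
  if (anyNA(pid) || any(!nzchar(pid))) {
    stopf("rows with empty pid: %s",
          paste(which(is.na(pid) | !nzchar(pid)), collapse = ", "))
  }
  dup <- unique(pid[duplicated(pid)])
  if (length(dup)) stopf("duplicated pid(s): %s", paste(dup, collapse = ", "))
  x$pid <- pid

  if (!"recruiter_pid" %in% names(x)) x$recruiter_pid <- NA_character_
  x$recruiter_pid <- as.character(x$recruiter_pid)
  x$recruiter_pid[!is.na(x$recruiter_pid) & !nzchar(x$recruiter_pid)] <-
    NA_character_
  orphan <- !is.na(x$recruiter_pid) & !(x$recruiter_pid %in% pid)
  if (any(orphan)) {
    who <- unique(x$recruiter_pid[orphan])
    if (lenient_orphans) {
      warnf("recruiter pid(s) not in table, rows demoted to seeds: %s",
            paste(who, collapse = ", "))
      x$recruiter_pid[orphan] <- NA_character_
    } else {
      stopf("recruiter pid(s) reference missing participants: %s",
            paste(who, collapse = ", "))
    }
  }

  if ("completed" %in% names(x) && !is.logical(x$completed)) {
    x$completed <- tolower(as.character(x$completed)) %in%
      c("true", "t", "1", "yes", "y")
  }
  if (!"completed" %in% names(x)) x$completed <- TRUE
  if ("channel" %in% names(x)) {
    x$channel <- as.character(x$channel)
    x$channel[is.na(x$channel)] <- "unknown"
  }

  numeric_cols <- intersect(c(count_columns(), "age"), names(x))
  bad <- character(0)
  for (col in numeric_cols) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      broken <- which(!is.na(v) & is.na(parsed))
      if (length(broken)) {
        bad <- c(bad, sprintf("%s (rows %s)", col,
                              paste(broken, collapse = ",")))
      }
      v <- parsed
    }
    if (any(v < 0, na.rm = TRUE) && col != "age") {
      stopf("negative counts in column '%s'", col)
    }
    x[[col]] <- v
  }
  if (length(bad)) stopf("malformed counts: %s", paste(bad, collapse = "; "))

  class(x) <- c("rds_participants", "data.frame")
  x
}

#' Write a participant table
#'
#' Writes the canonical delimited-text representation (comma separated,
#' header row, missing values as empty fields) that [read_participants()]
#' reads back field-identically.
#'
#' @param records An `rds_participants` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(records, path) {
  utils::write.table(records, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, na = "", qmethod = "double")
  invisible(path)
}

#' @export
print.rds_participants <- function(x, ...) {
  n_seed <- sum(is.na(x$recruiter_pid))
  cat(sprintf("<rds_participants> %d respondents (%d seeds, %d recruited)\n",
              nrow(x), n_seed, nrow(x) - n_seed))
  NextMethod()
}
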