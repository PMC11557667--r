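# Trial-table I/O with schema validation, and report serialization.
#
# All trial files are plain CSV (header row, '.' decimal separator).  The
# three schemas mirror the simulator's output so that written cohorts can be
# read back and analysed without further bookkeeping.

trial_schemas <- list(
  dyadic = list(
    columns = c(observer_id = "numeric", trial = "numeric",
                gaze_deg = "numeric", response = "numeric"),
    check = function(df) {
      bad <- which(!df$response %in% c(0, 1))
      if (length(bad)) {
        sprintf("response must be 0 or 1 (line %d)", bad[1] + 1L)
      } else NULL
    }
  ),
  adjustment = list(
    columns = c(observer_id = "numeric", trial = "numeric",
                series = "character", side = "character",
                stop_deg = "numeric"),
    check = function(df) {
      bad <- which(!df$series %in% c("ascending", "descending"))
      if (length(bad)) {
        return(sprintf("unknown series label '%s' (line %d)",
                       df$series[bad[1]], bad[1] + 1L))
      }
      bad <- which(!df$side %in% c("left", "right"))
      if (length(bad)) {
        return(sprintf("unknown side label '%s' (line %d)",
                       df$side[bad[1]], bad[1] + 1L))
      }
      NULL
    }
  ),
  triadic = list(
    columns = c(observer_id = "numeric", trial = "numeric",
                true_deg = "numeric", reported_cm = "numeric"),
    check = function(df) {
      bad <- which(df$reported_cm != round(df$reported_cm))
      if (length(bad)) {
        sprintf("reported_cm must be whole centimetres (line %d)",
                bad[1] + 1L)
      } else NULL
    }
  )
)

#' Read a trial-level CSV with schema validation
#'
#' Validates the header against the task schema, coerces column types, and
#' reports the first malformed row with its line number (header = line 1).
#' Duplicate (observer, trial) keys are rejected.  An empty file with a
#' valid header yields an empty record set.
#'
#' @param path Path to a CSV file.
#' @param type `"dyadic"`, `"adjustment"`, or `"triadic"`.
#' @return A validated data.frame.
#' @export
read_trials <- function(path, type = c("dyadic", "adjustment", "triadic")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    stop("validation error: file not found: ", path, call. = FALSE)
  }
  schema <- trial_schemas[[type]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(names(schema$columns), names(df))
  if (length(missing_cols)) {
    stop("validation error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(df), names(schema$columns))
  if (length(unknown)) {
    stop("validation error: unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  df <- df[, names(schema$columns), drop = FALSE]
  for (col in names(schema$columns)) {
    if (schema$columns[[col]] == "numeric") {
      converted <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(converted) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad)) {
        stop(sprintf(
          "validation error: non-numeric value '%s' in column %s (line %d)",
          df[[col]][bad[1]], col, bad[1] + 1L), call. = FALSE)
      }
      if (anyNA(converted) && nrow(df) > 0) {
        stop(sprintf("validation error: missing value in column %s", col),
             call. = FALSE)
      }
      df[[col]] <- converted
    }
  }
  if (nrow(df) > 0) {
    msg <- schema$check(df)
    if (!is.null(msg)) stop("validation error: ", msg, call. = FALSE)
    key <- paste(df$observer_id, df$trial)
    if (anyDuplicated(key)) {
      stop(sprintf("validation error: duplicate (observer_id, trial) key: %s",
                   key[anyDuplicated(key)]), call. = FALSE)
    }
  }
  df
}

#' Write a comparison report to CSV and JSON
#'
#' Writes `per_observer.csv` (threshold table rounded to 2 decimals for
#' degrees) and `report.json` (full precision) into `dir`.
#'
#' @param report A `comparison_report` from [compare_methods()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "comparison_report")) {
    stop("data error: expected a `comparison_report` object", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, "per_observer.csv")
  json_path <- file.path(dir, "report.json")
  per <- report$per_observer
  num <- vapply(per, is.numeric, logical(1))
  per_rounded <- per
  per_rounded[num] <- lapply(per[num], round, digits = 2)
  utils::write.csv(per_rounded, csv_path, row.names = FALSE)

  flatten_stat <- function(s) {
    if (is.null(s)) return(NULL)
    list(statistic = s$statistic, df = s$df, p_value = s$p_value,
         effect_size = s$effect_size, effect_label = s$effect_label,
         method = s$method)
  }
  flatten_block <- function(b) {
    if (is.null(b)) return(NULL)
    list(mean_cs = b$mean_cs, mean_adj = b$mean_adj, sd_cs = b$sd_cs,
         sd_adj = b$sd_adj, ratio = b$ratio, t = flatten_stat(b$t),
         correlation = flatten_stat(b$correlation))
  }
  jsonlite::write_json(
    list(per_observer = per,
         uncorrected = flatten_block(report$uncorrected),
         corrected = flatten_block(report$corrected)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
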