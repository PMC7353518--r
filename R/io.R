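#' Read a tidy trajectory table from CSV
#'
#' Expects the schema written by [write_trajectories_csv()]: UTF-8,
#' comma-separated, dot decimal, header row with columns `batch_label`,
#' `oil_pv`, `temperature_C`, `time_days`, `intensity_mean`,
#' `intensity_sd`, `n`, `censored`.
#'
#' @param path file path.
#' @return data frame in the trajectory schema.
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("batch_label", "oil_pv", "temperature_C", "time_days",
                "intensity_mean")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("trajectory CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("censored" %in% names(df)) df$censored <- as.logical(df$censored)
  df
}

#' Write trajectories to the tidy CSV schema
#'
#' @param trajectories list of `sensory_trajectory` objects or a tidy
#'   trajectory data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  df <- if (is.data.frame(trajectories)) trajectories else trajectories_to_df(trajectories)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a tidy trajectory table
#'
#' Schema and plausibility checks run before fitting: required columns,
#' non-negative times, intensities within the sensory scale, positive panel
#' sizes, non-negative SDs, and no duplicated (batch, temperature, time)
#' keys. Violations are returned as data, not raised as errors.
#'
#' @param data candidate trajectory data frame.
#' @param scale_min,scale_max sensory scale bounds used for the intensity
#'   check (default 1 and 7).
#' @return data frame with columns `row` (offending row index, NA for
#'   table-level problems), `field` and `violation`; zero rows when the
#'   table is well-formed.
#' @export
validate_inputs <- function(data, scale_min = 1, scale_max = 7) {
  violations <- list()
  add <- function(row, field, msg) {
    violations[[length(violations) + 1L]] <<-
      data.frame(row = row, field = field, violation = msg)
  }

  required <- c("batch_label", "oil_pv", "temperature_C", "time_days",
                "intensity_mean")
  for (col in setdiff(required, names(data))) {
    add(NA_integer_, col, "required column missing")
  }
  if (length(violations) > 0L) {
    return(do.call(rbind, violations))
  }

  for (i in seq_len(nrow(data))) {
    if (is.na(data$time_days[i]) || data$time_days[i] < 0) {
      add(i, "time_days", "negative or missing time")
    }
    im <- data$intensity_mean[i]
    if (is.na(im) || im < scale_min || im > scale_max) {
      add(i, "intensity_mean",
          sprintf("intensity outside sensory scale [%g, %g]", scale_min, scale_max))
    }
    if ("n" %in% names(data) && (is.na(data$n[i]) || data$n[i] < 1)) {
      add(i, "n", "panel size below 1")
    }
    if ("intensity_sd" %in% names(data) && !is.na(data$intensity_sd[i]) &&
        data$intensity_sd[i] < 0) {
      add(i, "intensity_sd", "negative standard deviation")
    }
  }

  key <- paste(data$batch_label, data$temperature_C, data$time_days, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup) {
    add(i, "batch_label/temperature_C/time_days",
        "duplicated (batch, temperature, time) key")
  }

  if (length(violations) == 0L) {
    return(data.frame(row = integer(0), field = character(0),
                      violation = character(0)))
  }
  out <- do.call(rbind, violations)
  rownames(out) <- NULL
  out
}
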