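#' Read and write event logs
#'
#' Event logs are plain CSV with columns `day`, `time_s` (float seconds
#' from session start, preserving the 1/30 s recording resolution),
#' `kind`, `sender`, `receiver` (empty where not applicable). The column
#' order is stable and a header is required. Reading enforces
#' non-decreasing times within a day (reporting the offending row) and the
#' tie-break ordering of simultaneous events.
#'
#' @param events a [lek_events()] history.
#' @param path file path.
#' @return `read_events` returns a `lek_events`; `write_events` returns the
#'   path invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)[, c("day", "time_s", "kind", "sender",
                                  "receiver")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("IO error: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("day", "time_s", "kind", "sender", "receiver"),
                          names(df))
  if (length(missing_cols))
    stop("event log error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$day <- as.integer(df$day)
  df$time_s <- as.numeric(df$time_s)
  df$kind <- as.character(df$kind)
  df$sender <- as.character(df$sender)
  df$receiver <- as.character(df$receiver)
  df$sender[!is.na(df$sender) & df$sender == ""] <- NA_character_
  df$receiver[!is.na(df$receiver) & df$receiver == ""] <- NA_character_
  key <- paste(df$day, df$time_s, df$kind, df$sender, df$receiver)
  dup <- duplicated(key) & !df$kind %in% c("clock")
  if (any(dup))
    stop("event log error: duplicated (day, time, type) at row ",
         which(dup)[1])
  ooo <- which(diff(df$time_s) < 0 & diff(df$day) == 0)
  if (length(ooo))
    stop("event log error: times out of order within day at row ",
         ooo[1] + 1)
  lek_events(df)
}

#' Read and write rosters
#'
#' Rosters are stored long-form: one CSV row per actor-day with columns
#' `id`, `category`, `day`, `present`, `territory`, `centroid_x_m`,
#' `centroid_y_m`. Coordinates are metric with the origin at grid stake
#' (0, 0).
#'
#' @param roster a [lek_roster()].
#' @param path file path.
#' @export
write_roster <- function(roster, path) {
  df <- roster$days
  df$category <- roster$actors$category[match(df$id, roster$actors$id)]
  names(df)[names(df) == "x"] <- "centroid_x_m"
  names(df)[names(df) == "y"] <- "centroid_y_m"
  utils::write.csv(df[, c("id", "category", "day", "present", "territory",
                          "centroid_x_m", "centroid_y_m")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "category", "day", "present", "territory",
            "centroid_x_m", "centroid_y_m")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("roster error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  actors <- unique(df[, c("id", "category")])
  days <- data.frame(id = df$id, day = df$day, present = df$present,
                     territory = df$territory, x = df$centroid_x_m,
                     y = df$centroid_y_m)
  lek_roster(actors, days)
}

#' Read and write scaffolds (JSON)
#' @param scaffold a [lek_scaffold()].
#' @param path file path.
#' @export
write_scaffold <- function(scaffold, path) {
  ev <- scaffold$events[scaffold$events$kind != "clock", ]
  jsonlite::write_json(
    list(days = scaffold$days, events = ev,
         return_delay_mean = as.list(scaffold$return_delay_mean),
         clock_period = scaffold$clock_period),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_scaffold
#' @export
read_scaffold <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(x$events)
  if (!nrow(ev)) ev <- data.frame(day = integer(0), time_s = numeric(0),
                                  kind = character(0),
                                  actor = character(0))
  lek_scaffold(as.data.frame(x$days), ev,
               return_delay_mean = unlist(x$return_delay_mean) %||2%
                 numeric(0),
               clock_period = x$clock_period)
}

#' Read and write parameter vectors
#'
#' Coefficient CSVs have columns `name`, `value` (for generating vectors)
#' or `name`, `estimate`, `posterior_se` (for fits via [coef_table()]).
#'
#' @param theta named numeric vector.
#' @param path file path.
#' @export
write_theta <- function(theta, path) {
  utils::write.csv(data.frame(name = names(theta), value = unname(theta)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_theta
#' @export
read_theta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$name)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `roster.csv`, `scaffold.json`, `events.csv`, `theta_truth.csv`
#' and `config.json` so the dataset round-trips losslessly.
#'
#' @param dataset a `lek_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roster(dataset$roster, file.path(dir, "roster.csv"))
  write_scaffold(dataset$scaffold, file.path(dir, "scaffold.json"))
  write_events(dataset$events, file.path(dir, "events.csv"))
  write_theta(dataset$theta_truth, file.path(dir, "theta_truth.csv"))
  cfg <- dataset$config
  cfg$model$statistics <- cfg$model$statistics
  jsonlite::write_json(list(config = unclass(cfg), seed = dataset$seed),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}
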