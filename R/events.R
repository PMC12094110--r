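#' Event kinds of the lek event taxonomy
#'
#' The behavioural stream is categorised into a fixed set of event kinds.
#' Attacks are dyadic (sender and receiver); responses, disengagements,
#' solicitations, copulation ends, departures and arrivals are actor-specific;
#' female entry/exit, clock ticks, disturbances and day ends are global.
#' Attacks, responses, disengagements, solicitations, copulation ends and
#' departures are endogenous (their hazards are modelled); everything else is
#' exogenous and enters only through the scheduled scaffold.
#'
#' @return Named list of character vectors: `all`, `endogenous`, `exogenous`,
#'   `global`, `response`.
#' @export
event_kinds <- function() {
  response <- c("response_face_off", "response_short_fight", "response_chase")
  endo <- c("attack", response, "disengage", "solicit", "copulation_end",
            "depart")
  glob <- c("female_enter", "female_exit", "clock", "disturbance", "day_end")
  exo <- c("arrive", glob)
  list(all = c(endo, exo), endogenous = endo, exogenous = exo,
       global = glob, response = response)
}

.ek <- event_kinds()

#' Construct and validate an actor roster
#'
#' A roster names every male on the lek: identified individuals, unknown
#' "U" males (present a single day or unidentifiable that day), and a single
#' bulk "X" actor standing in for transient unidentified males, which, unlike
#' the others, may hold several simultaneous engagements. Per-day rows give
#' presence, territory-holder status (present on at least the two previous
#' consecutive days) and the movement centroid in metres.
#'
#' @param actors data.frame with columns `id` (unique character) and
#'   `category` (one of `"identified"`, `"U"`, `"X_bulk"`).
#' @param days data.frame with columns `id`, `day` (integer), `present`
#'   (logical), `territory` (logical), `x`, `y` (centroid, metres). One row
#'   per actor-day the actor appears.
#' @return An object of class `lek_roster`.
#' @export
lek_roster <- function(actors, days) {
  stopifnot(is.data.frame(actors), all(c("id", "category") %in% names(actors)))
  actors$id <- as.character(actors$id)
  if (anyDuplicated(actors$id))
    stop("roster error: duplicate actor ids: ",
         paste(unique(actors$id[duplicated(actors$id)]), collapse = ", "))
  if (!all(actors$category %in% c("identified", "U", "X_bulk")))
    stop("roster error: unknown actor category")
  if (sum(actors$category == "X_bulk") > 1)
    stop("roster error: at most one X_bulk actor is allowed")
  if (nrow(actors) < 2) stop("roster error: need at least two actors")
  need <- c("id", "day", "present", "territory", "x", "y")
  stopifnot(is.data.frame(days), all(need %in% names(days)))
  days$id <- as.character(days$id)
  if (!all(days$id %in% actors$id))
    stop("roster error: day rows refer to unknown actor ids")
  miss <- days$present & (is.na(days$x) | is.na(days$y))
  if (any(miss))
    stop("roster error: centroid missing for a present actor-day")
  r <- list(actors = actors[, c("id", "category")],
            days = days[order(days$day, match(days$id, actors$id)), need])
  class(r) <- "lek_roster"
  r
}

#' @export
print.lek_roster <- function(x, ...) {
  tab <- table(x$actors$category)
  cat("lek_roster:", nrow(x$actors), "actors (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "),",
      length(unique(x$days$day)), "days\n")
  invisible(x)
}

#' Enumerate the full event-type taxonomy for a roster
#'
#' For n actors the taxonomy comprises n(n-1) dyadic attack types, 3n
#' response types (face-off, short fight, chase, keyed by the attacked male),
#' n each of disengage, solicit, copulation end, depart and arrive, and 5
#' global types (female entry, female exit, clock, disturbance, day end):
#' n(n-1) + 8n + 5 types in total. A 30-actor roster (29 named males plus
#' the X bulk actor) yields 870 attack types and 1115 types overall.
#'
#' @param roster a [lek_roster()].
#' @param require_bulk if `TRUE` (default) the roster must contain exactly
#'   one X bulk actor; experiment configurations restricted to territory
#'   holders may waive this.
#' @return data.frame with columns `kind`, `sender`, `receiver` (NA where not
#'   applicable), one row per event type.
#' @export
enumerate_event_types <- function(roster, require_bulk = TRUE) {
  stopifnot(inherits(roster, "lek_roster"))
  ids <- roster$actors$id
  if (require_bulk && !any(roster$actors$category == "X_bulk"))
    stop("roster error: no X_bulk actor (set require_bulk = FALSE to waive)")
  n <- length(ids)
  pairs <- expand.grid(sender = ids, receiver = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$sender != pairs$receiver, ]
  out <- rbind(
    data.frame(kind = "attack", sender = pairs$sender,
               receiver = pairs$receiver),
    data.frame(kind = rep(.ek$response, each = n), sender = NA_character_,
               receiver = rep(ids, times = 3)),
    data.frame(kind = rep(c("disengage", "solicit", "copulation_end",
                            "depart", "arrive"), each = n),
               sender = rep(ids, times = 5), receiver = NA_character_),
    data.frame(kind = .ek$global, sender = NA_character_,
               receiver = NA_character_)
  )
  rownames(out) <- NULL
  out
}

#' Construct an event record
#'
#' @param kind event kind, see [event_kinds()].
#' @param time time in seconds from session start.
#' @param day day index (integer).
#' @param sender,receiver actor ids where applicable.
#' @return list of class `lek_event`.
#' @export
lek_event <- function(kind, time, day = 1L, sender = NA_character_,
                      receiver = NA_character_) {
  if (!kind %in% .ek$all) stop("unknown event kind: ", kind)
  if (time < 0) stop("event time must be non-negative")
  structure(list(kind = kind, time = as.numeric(time), day = as.integer(day),
                 sender = sender, receiver = receiver),
            class = "lek_event")
}

#' Assemble an event history
#'
#' An event history is a data.frame (class `lek_events`) with columns `day`,
#' `time_s`, `kind`, `sender`, `receiver`, ordered by day then time. Ties at
#' the 1/30 s recording resolution are ordered attack < response <
#' disengage < copulation_end < other kinds so cycle validity is preserved.
#'
#' @param df data.frame with the five columns above.
#' @return `lek_events` object.
#' @export
lek_events <- function(df) {
  need <- c("day", "time_s", "kind", "sender", "receiver")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("event log error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(df$kind %in% .ek$all))
    stop("event log error: unknown kind(s): ",
         paste(setdiff(unique(df$kind), .ek$all), collapse = ", "))
  df <- df[, need]
  df$day <- as.integer(df$day)
  df$time_s <- as.numeric(df$time_s)
  df$sender <- as.character(df$sender)
  df$receiver <- as.character(df$receiver)
  ord <- order(df$day, df$time_s, .kind_tie_rank(df$kind),
               seq_len(nrow(df)))
  df <- df[ord, ]
  bad <- which(diff(df$time_s) < 0 & diff(df$day) == 0)
  if (length(bad))
    stop("event log error: times out of order within day at row ", bad[1] + 1)
  rownames(df) <- NULL
  class(df) <- c("lek_events", "data.frame")
  df
}

# tie-break rank at equal timestamps: attack < response < disengage <
# copulation_end < everything else, then input order
.kind_tie_rank <- function(kind) {
  r <- match(kind, c("attack", .ek$response, "disengage", "copulation_end"))
  r[is.na(r)] <- 99L
  r
}

#' @export
print.lek_events <- function(x, ...) {
  cat("lek_events:", nrow(x), "events over", length(unique(x$day)),
      "day(s)\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
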