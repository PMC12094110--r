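# Small rosters and hand-built histories used across the suite.

fixture_roster <- function(n_named = 2, bulk = TRUE, n_days = 2,
                           territory = FALSE) {
  ids <- sprintf("m%02d", seq_len(n_named))
  cats <- rep("identified", n_named)
  if (bulk) {
    ids <- c(ids, "X")
    cats <- c(cats, "X_bulk")
  }
  n <- length(ids)
  days <- do.call(rbind, lapply(seq_len(n_days), function(d)
    data.frame(id = ids, day = d, present = TRUE, territory = territory,
               x = 10 * ((seq_len(n) - 1) %% 3),
               y = 10 * ((seq_len(n) - 1) %/% 3))))
  lek_roster(data.frame(id = ids, category = cats), days)
}

# apply a sequence of compact event tuples to a fresh state
play <- function(roster, ..., day = 1L, state = NULL, check = TRUE) {
  evs <- list(...)
  if (is.null(state)) state <- lek_state(roster, day = day)
  for (e in evs)
    state <- apply_event(state, list(kind = e[[1]], time = as.numeric(e[[2]]),
                                     day = day,
                                     sender = if (length(e) > 2) e[[3]] else
                                       NA_character_,
                                     receiver = if (length(e) > 3) e[[4]] else
                                       NA_character_),
                         check = check)
  state
}

events_df <- function(rows) {
  lek_events(do.call(rbind, lapply(rows, function(e)
    data.frame(day = e$day %||0% 1L, time_s = e$time, kind = e$kind,
               sender = e$sender %||0% NA_character_,
               receiver = e$receiver %||0% NA_character_))))
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

ev <- function(kind, time, sender = NULL, receiver = NULL, day = 1L) {
  list(kind = kind, time = time, sender = sender, receiver = receiver,
       day = day)
}

# a minimal complete one-day history: arrival, one short fight, day end
fixture_fight_history <- function() {
  events_df(list(
    ev("arrive", 0, "m01"), ev("arrive", 5, "m02"),
    ev("attack", 60, "m01", "m02"),
    ev("response_short_fight", 60, "m02", "m01"),
    ev("disengage", 95, "m02", "m01"),
    ev("day_end", 3600)))
}
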