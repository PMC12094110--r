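#' Initialise the lek state for a roster
#'
#' The state is the piecewise-constant description of the system between
#' events: who is present, whether females are on the lek, ongoing attack
#' and copulation cycles, the pending (zero-duration) response window, the
#' clock, and the interaction counters that feed the predictor statistics.
#' Counters are kept per ordered pair and per window (today / yesterday /
#' older), each in two context channels: all events, and events that
#' occurred with females present (the latter feed solicitation statistics).
#'
#' @param roster a [lek_roster()].
#' @param day starting day index.
#' @return object of class `lek_state`.
#' @export
lek_state <- function(roster, day = 1L) {
  ids <- roster$actors$id
  n <- length(ids)
  bulk <- which(roster$actors$category == "X_bulk")
  if (!length(bulk)) bulk <- 0L
  s <- list(
    ids = ids, n = n, bulk = bulk,
    category = roster$actors$category,
    day = as.integer(day), time = 0,
    present = rep(FALSE, n), females = FALSE,
    clock_time = 0, last_disturbance = NA_real_,
    fights = list(attacker = integer(0), receiver = integer(0),
                  kind = character(0), start = numeric(0)),
    cops = list(male = integer(0), start = numeric(0)),
    pending = NULL,
    pc = array(0, dim = c(n, n, 4, 3, 2),
               dimnames = list(NULL, NULL,
                               c("att_win", "att_lose", "recv_win",
                                 "recv_lose"),
                               c("today", "yesterday", "older"),
                               c("all", "fem"))),
    intp = array(0, dim = c(n, 3, 2),
                 dimnames = list(NULL, c("today", "yesterday", "older"),
                                 c("all", "fem"))),
    cop_succ = array(0, dim = c(n, 3, 2),
                     dimnames = list(NULL, c("today", "yesterday", "older"),
                                     c("all", "fem"))),
    last_win = rep(NA_real_, n),
    last_lose_chase = rep(NA_real_, n),
    terr = rep(FALSE, n),
    dist = NULL
  )
  class(s) <- "lek_state"
  .state_set_day_covariates(s, roster, day)
}

# per-day covariates: territory flags and the raw pairwise centroid
# distance matrix in metres (standardisation happens at evaluation time)
.state_set_day_covariates <- function(state, roster, day) {
  d <- roster$days[roster$days$day == day, ]
  state$terr <- rep(FALSE, state$n)
  xy <- matrix(NA_real_, state$n, 2)
  if (nrow(d)) {
    i <- match(d$id, state$ids)
    state$terr[i] <- as.logical(d$territory)
    xy[i, 1] <- d$x
    xy[i, 2] <- d$y
  }
  dm <- as.matrix(stats::dist(xy))
  dm[is.na(dm)] <- 0
  diag(dm) <- 0
  state$dist <- dm
  state
}

#' Begin a new observation day
#'
#' Sets the day index and per-day covariates. If the new day does not have a
#' true consecutive predecessor (a gap in the recording), yesterday-window
#' counters are reset to their base value (zero).
#'
#' @param state a `lek_state` (typically carried over a `day_end` event).
#' @param roster the roster.
#' @param day the new day index.
#' @return updated state.
#' @export
state_begin_day <- function(state, roster, day) {
  gap <- day > state$day + 1L || is.na(state$day)
  state$day <- as.integer(day)
  state$time <- 0
  state$clock_time <- 0
  if (gap) {
    state$pc[, , , "yesterday", ] <- 0
    state$intp[, "yesterday", ] <- 0
    state$cop_succ[, "yesterday", ] <- 0
  }
  .state_set_day_covariates(state, roster, day)
}

# availability: present, not in a fight, not copulating; the bulk actor is
# available for new engagements whenever present
.in_fight <- function(state) {
  v <- rep(FALSE, state$n)
  v[c(state$fights$attacker, state$fights$receiver)] <- TRUE
  if (!is.null(state$pending))
    v[c(state$pending$attacker, state$pending$receiver)] <- TRUE
  v
}

.copulating <- function(state) {
  v <- rep(FALSE, state$n)
  v[state$cops$male] <- TRUE
  v
}

.available <- function(state) {
  a <- state$present & !.in_fight(state) & !.copulating(state)
  if (state$bulk > 0L && state$present[state$bulk]) a[state$bulk] <- TRUE
  a
}

# internal candidate table: the supported endogenous event types, by index.
# If an attack is pending, support is exactly the three response types for
# the attacked male.
.candidate_table <- function(state) {
  if (!is.null(state$pending)) {
    return(list(kind = .ek$response,
                sender = rep(state$pending$receiver, 3L),
                receiver = rep(state$pending$attacker, 3L)))
  }
  avail <- .available(state)
  cop <- .copulating(state)
  att_s <- which(avail)
  # a male may be attacked when available, when copulating (interruption),
  # or, for the bulk actor, whenever present
  recv_ok <- avail | cop
  if (state$bulk > 0L && state$present[state$bulk])
    recv_ok[state$bulk] <- TRUE
  att_r <- which(recv_ok)
  kind <- character(0); sender <- integer(0); receiver <- integer(0)
  if (length(att_s) && length(att_r)) {
    gs <- rep(att_s, times = length(att_r))
    gr <- rep(att_r, each = length(att_s))
    keep <- gs != gr
    if (any(keep)) {
      kind <- rep("attack", sum(keep))
      sender <- gs[keep]
      receiver <- gr[keep]
    }
  }
  f <- state$fights
  if (length(f$attacker)) {
    nc <- f$kind != "response_chase"
    ds <- c(f$attacker, f$receiver[nc])
    dr <- c(f$receiver, f$attacker[nc])
    kind <- c(kind, rep("disengage", length(ds)))
    sender <- c(sender, ds)
    receiver <- c(receiver, dr)
  }
  if (state$females) {
    sol <- which(avail)
    if (state$bulk > 0L) sol <- setdiff(sol, state$bulk)
    if (length(sol)) {
      kind <- c(kind, rep("solicit", length(sol)))
      sender <- c(sender, sol)
      receiver <- c(receiver, rep(NA_integer_, length(sol)))
    }
  }
  if (length(state$cops$male)) {
    kind <- c(kind, rep("copulation_end", length(state$cops$male)))
    sender <- c(sender, state$cops$male)
    receiver <- c(receiver, rep(NA_integer_, length(state$cops$male)))
  }
  dep <- which(avail)
  if (state$bulk > 0L && length(f$attacker) &&
      state$bulk %in% c(f$attacker, f$receiver))
    dep <- setdiff(dep, state$bulk)
  if (length(dep)) {
    kind <- c(kind, rep("depart", length(dep)))
    sender <- c(sender, dep)
    receiver <- c(receiver, rep(NA_integer_, length(dep)))
  }
  list(kind = kind, sender = sender, receiver = receiver)
}

#' Support set: the endogenous event types possible right now
#'
#' Encodes the model's hard constraints: only present males interact or
#' depart; solicitations are impossible with females absent; males engaged
#' in an attack or copulation cycle neither attack, receive, solicit nor
#' depart; both parties may disengage from a face-off or short fight but
#' only the attacker may disengage from (and thereby win) a chase; an attack
#' on a copulating male is supported (an interruption); the X bulk actor is
#' available for new fights even while engaged; and in the zero-duration
#' window after an attack the support set is exactly the three response
#' types for the attacked male.
#'
#' @param state a `lek_state`.
#' @return data.frame with columns `kind`, `sender`, `receiver` (actor ids).
#' @export
support_set <- function(state) {
  stopifnot(inherits(state, "lek_state"))
  ct <- .candidate_table(state)
  data.frame(kind = ct$kind %||2% character(0),
             sender = ifelse(is.na(ct$sender), NA_character_,
                             state$ids[ct$sender]),
             receiver = ifelse(is.na(ct$receiver), NA_character_,
                               state$ids[ct$receiver]),
             stringsAsFactors = FALSE)
}

.bump_pair <- function(state, f, p, outcome) {
  state$pc[f, p, outcome, "today", "all"] <-
    state$pc[f, p, outcome, "today", "all"] + 1
  if (state$females)
    state$pc[f, p, outcome, "today", "fem"] <-
      state$pc[f, p, outcome, "today", "fem"] + 1
  state
}

.resolve_idx <- function(state, id) {
  if (is.null(id) || length(id) == 0 || is.na(id)) return(NA_integer_)
  i <- match(id, state$ids)
  if (is.na(i)) stop("unknown actor id: ", id)
  i
}

#' Apply an event to the lek state
#'
#' Deterministic state transition. An attack opens the zero-duration
#' response window (closing any copulation by the receiver as an
#' interruption); the response establishes the fight of the chosen kind; a
#' disengagement removes the pair, crediting the disengager with the win and
#' the partner with the loss (plus a lost-chase mark when the fight was a
#' chase); a solicitation opens and a copulation-end closes a copulation; a
#' disturbance flushes all birds and clears every cycle without assigning
#' outcomes; `day_end` rolls today-counters into yesterday; a clock tick
#' refreshes the time marker used by recency statistics.
#'
#' @param state a `lek_state`.
#' @param event a [lek_event()] (or list with `kind`, `time`, `sender`,
#'   `receiver`).
#' @param check verify endogenous events against [support_set()] (default
#'   `TRUE`).
#' @return the updated state.
#' @export
apply_event <- function(state, event, check = TRUE) {
  kind <- event$kind
  t <- event$time
  s <- .resolve_idx(state, event$sender)
  r <- .resolve_idx(state, event$receiver)
  if (check && kind %in% .ek$endogenous) {
    ct <- .candidate_table(state)
    hit <- ct$kind == kind &
      (is.na(ct$sender) | (!is.na(s) & ct$sender == s)) &
      (is.na(ct$receiver) | is.na(r) | ct$receiver == r)
    # disengage/response receiver may be omitted in the record
    if (kind == "disengage" && is.na(r)) hit <- ct$kind == kind & ct$sender == s
    if (!any(hit))
      stop("support violation at day ", event$day %||% state$day, " t=", t,
           ": ", kind, " ", event$sender %||% "", "->",
           event$receiver %||% "", " is not in the support set")
  }
  state$time <- t
  switch(kind,
    attack = {
      if (!is.null(state$pending)) stop("attack while a response is pending")
      ci <- which(state$cops$male == r)
      if (length(ci)) {               # interruption: supplants copulation end
        state$cops <- lapply(state$cops, function(v) v[-ci])
        state$intp[s, "today", "all"] <- state$intp[s, "today", "all"] + 1
        if (state$females)
          state$intp[s, "today", "fem"] <- state$intp[s, "today", "fem"] + 1
      }
      state$pending <- list(attacker = s, receiver = r, time = t)
    },
    response_face_off = ,
    response_short_fight = ,
    response_chase = {
      p <- state$pending
      if (is.null(p)) stop("response with no pending attack")
      if (!is.na(s) && s != p$receiver)
        stop("response by a male other than the attacked male")
      state$fights$attacker <- c(state$fights$attacker, p$attacker)
      state$fights$receiver <- c(state$fights$receiver, p$receiver)
      state$fights$kind <- c(state$fights$kind, kind)
      state$fights$start <- c(state$fights$start, t)
      state$pending <- NULL
    },
    disengage = {
      fi <- which(state$fights$attacker == s | state$fights$receiver == s)
      if (!is.na(r))
        fi <- fi[state$fights$attacker[fi] == r | state$fights$receiver[fi] == r]
      if (!length(fi)) stop("disengage by a male not in a fight")
      fi <- fi[1]
      f <- list(attacker = state$fights$attacker[fi],
                receiver = state$fights$receiver[fi],
                kind = state$fights$kind[fi])
      partner <- if (f$attacker == s) f$receiver else f$attacker
      if (f$kind == "response_chase" && s != f$attacker)
        stop("only the attacker may disengage from a chase")
      if (s == f$attacker) {
        state <- .bump_pair(state, s, partner, "att_win")
        state <- .bump_pair(state, partner, s, "recv_lose")
      } else {
        state <- .bump_pair(state, s, partner, "recv_win")
        state <- .bump_pair(state, partner, s, "att_lose")
      }
      if (f$kind == "response_chase")
        state$last_lose_chase[partner] <- t
      state$last_win[s] <- t
      state$fights <- lapply(state$fights, function(v) v[-fi])
    },
    solicit = {
      state$cops$male <- c(state$cops$male, s)
      state$cops$start <- c(state$cops$start, t)
    },
    copulation_end = {
      ci <- which(state$cops$male == s)
      if (!length(ci)) stop("copulation_end by a male not copulating")
      state$cops <- lapply(state$cops, function(v) v[-ci[1]])
      state$cop_succ[s, "today", "all"] <- state$cop_succ[s, "today", "all"] + 1
      if (state$females)
        state$cop_succ[s, "today", "fem"] <-
          state$cop_succ[s, "today", "fem"] + 1
    },
    depart = {
      state$present[s] <- FALSE
    },
    arrive = {
      state$present[s] <- TRUE
    },
    female_enter = {
      state$females <- TRUE
    },
    female_exit = {
      state$females <- FALSE
    },
    clock = {
      state$clock_time <- t
    },
    disturbance = {
      state$fights <- lapply(state$fights, function(v) v[0])
      state$cops <- lapply(state$cops, function(v) v[0])
      state$pending <- NULL
      state$present[] <- FALSE
      state$last_disturbance <- t
    },
    day_end = {
      state$pc[, , , "older", ] <-
        state$pc[, , , "older", ] + state$pc[, , , "yesterday", ]
      state$pc[, , , "yesterday", ] <- state$pc[, , , "today", ]
      state$pc[, , , "today", ] <- 0
      state$intp[, "older", ] <- state$intp[, "older", ] +
        state$intp[, "yesterday", ]
      state$intp[, "yesterday", ] <- state$intp[, "today", ]
      state$intp[, "today", ] <- 0
      state$cop_succ[, "older", ] <- state$cop_succ[, "older", ] +
        state$cop_succ[, "yesterday", ]
      state$cop_succ[, "yesterday", ] <- state$cop_succ[, "today", ]
      state$cop_succ[, "today", ] <- 0
      state$fights <- lapply(state$fights, function(v) v[0])
      state$cops <- lapply(state$cops, function(v) v[0])
      state$pending <- NULL
      state$present[] <- FALSE
      state$females <- FALSE
      state$last_win[] <- NA_real_
      state$last_lose_chase[] <- NA_real_
      state$last_disturbance <- NA_real_
    },
    stop("unknown event kind: ", kind)
  )
  state
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Replay and validate an event history
#'
#' Replays the history through [apply_event()], checking every endogenous
#' event against the support set at its time. Violations are collected (with
#' the row and constraint breached) rather than thrown.
#'
#' @param events a [lek_events()] history (including exogenous events).
#' @param roster the roster.
#' @return list with `ok` (logical), `violations` (data.frame row/message),
#'   and `counts` (events per kind).
#' @export
validate_history <- function(events, roster) {
  events <- lek_events(as.data.frame(events))
  state <- lek_state(roster, day = if (nrow(events)) events$day[1] else 1L)
  violations <- list()
  prev_day <- state$day
  for (i in seq_len(nrow(events))) {
    ev <- list(kind = events$kind[i], time = events$time_s[i],
               day = events$day[i], sender = events$sender[i],
               receiver = events$receiver[i])
    if (ev$day != prev_day) {
      state <- state_begin_day(state, roster, ev$day)
      prev_day <- ev$day
    }
    res <- tryCatch({ state <- apply_event(state, ev); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      violations[[length(violations) + 1L]] <-
        data.frame(row = i, message = res)
      # resynchronise: apply without checks so later events stay meaningful
      state <- tryCatch(apply_event(state, ev, check = FALSE),
                        error = function(e) state)
    }
  }
  viol <- if (length(violations)) do.call(rbind, violations) else
    data.frame(row = integer(0), message = character(0))
  list(ok = nrow(viol) == 0L, violations = viol,
       counts = table(factor(events$kind, levels = .ek$all)))
}
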