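#' Construct an exogenous event scaffold
#'
#' The scaffold holds the scheduled exogenous events that drive a
#' simulation: per-day male arrival times, female entry/exit, disturbances,
#' the observation end, and the 15-minute clock grid (materialised as clock
#' rows at multiples of `clock_period` up to each day's end). Departing
#' males may return after an exponential delay with a per-male mean.
#'
#' @param days data.frame with columns `day`, `t_end` (observation end,
#'   seconds from session start).
#' @param events data.frame with columns `day`, `time_s`, `kind` (one of
#'   arrive, female_enter, female_exit, disturbance), `actor` (id, NA for
#'   global kinds).
#' @param return_delay_mean named numeric: mean absence interval (seconds)
#'   per male; names are actor ids. Males absent from the vector never
#'   return after departing.
#' @param clock_period clock tick spacing in seconds (default 900).
#' @return object of class `lek_scaffold`.
#' @export
lek_scaffold <- function(days, events, return_delay_mean = numeric(0),
                         clock_period = 900) {
  stopifnot(all(c("day", "t_end") %in% names(days)),
            all(c("day", "time_s", "kind", "actor") %in% names(events)))
  ok_kinds <- c("arrive", "female_enter", "female_exit", "disturbance")
  if (!all(events$kind %in% ok_kinds))
    stop("scaffold error: unknown scheduled kind(s): ",
         paste(setdiff(unique(events$kind), ok_kinds), collapse = ", "))
  te <- days$t_end[match(events$day, days$day)]
  if (any(is.na(te)) || any(events$time_s < 0 | events$time_s > te))
    stop("scaffold error: scheduled time outside day bounds")
  # one contiguous female window per day at most: entries/exits must alternate
  clocks <- do.call(rbind, lapply(seq_len(nrow(days)), function(i) {
    k <- floor(days$t_end[i] / clock_period)
    if (k < 1) return(NULL)
    data.frame(day = days$day[i], time_s = clock_period * seq_len(k),
               kind = "clock", actor = NA_character_)
  }))
  ev <- rbind(events[, c("day", "time_s", "kind", "actor")], clocks)
  ev <- ev[order(ev$day, ev$time_s), ]
  rownames(ev) <- NULL
  structure(list(days = days[order(days$day), c("day", "t_end")],
                 events = ev, return_delay_mean = return_delay_mean,
                 clock_period = clock_period),
            class = "lek_scaffold")
}

#' @export
print.lek_scaffold <- function(x, ...) {
  cat("lek_scaffold:", nrow(x$days), "day(s),", nrow(x$events),
      "scheduled events (incl. clock)\n")
  invisible(x)
}

# one simulation step: either the next sampled endogenous event (an attack
# is resolved through its instantaneous response) or the next scheduled
# exogenous event, whichever comes first.
.sim_step <- function(state, model, theta, sched_kind, sched_time,
                      sched_actor, day) {
  des <- candidate_design(state, model)
  lam <- exp(as.numeric(des$X %*% theta))
  Lam <- sum(lam)
  t_cand <- if (Lam > 0 && length(des$ct$kind))
    state$time + stats::rexp(1, Lam) else Inf
  if (t_cand >= sched_time) {
    ev <- list(kind = sched_kind, time = sched_time, day = day,
               sender = sched_actor, receiver = NA_character_)
    state <- apply_event(state, ev, check = FALSE)
    return(list(events = list(ev), state = state, scheduled = TRUE))
  }
  i <- sample.int(length(des$ct$kind), 1L, prob = lam)
  ev <- list(kind = des$ct$kind[i], time = t_cand, day = day,
             sender = if (is.na(des$ct$sender[i])) NA_character_ else
               state$ids[des$ct$sender[i]],
             receiver = if (is.na(des$ct$receiver[i])) NA_character_ else
               state$ids[des$ct$receiver[i]])
  state <- apply_event(state, ev)
  evs <- list(ev)
  if (ev$kind == "attack") {        # instantaneous competing-risks response
    des2 <- candidate_design(state, model)
    eta <- as.numeric(des2$X %*% theta)
    p <- exp(eta - max(eta)); p <- p / sum(p)
    j <- sample.int(3L, 1L, prob = p)
    rev <- list(kind = des2$ct$kind[j], time = t_cand, day = day,
                sender = state$ids[des2$ct$sender[j]],
                receiver = state$ids[des2$ct$receiver[j]])
    state <- apply_event(state, rev)
    evs <- c(evs, list(rev))
  }
  list(events = evs, state = state, scheduled = FALSE)
}

#' Draw the next event of the simulated process
#'
#' Samples the waiting time to the next endogenous event from an
#' exponential distribution with rate equal to the total hazard of all
#' supported events, and its identity as a categorical draw weighted by
#' each event's share of the total hazard. If a scheduled exogenous event
#' precedes the sampled time, that event fires instead. An attack is
#' immediately followed by its zero-duration response draw.
#'
#' @param state a `lek_state`.
#' @param model,theta the model and parameter vector.
#' @param next_scheduled list with `kind`, `time`, `actor` of the next
#'   scheduled exogenous event (use kind `"day_end"` at the observation end).
#' @return list with `events` (one or two event records) and `state`.
#' @export
draw_next_event <- function(state, model, theta, next_scheduled) {
  theta <- .align_theta(theta, model)
  .sim_step(state, model, theta, next_scheduled$kind, next_scheduled$time,
            next_scheduled$actor %||% NA_character_, state$day)
}

#' Simulate a single day of lek activity
#'
#' Runs the generative process over one scaffold day from a prepared state
#' (see [state_begin_day()]); the carried-over state supplies the
#' yesterday-window counters. Departing males are scheduled to potentially
#' return after an exponential delay with their scaffold mean absence
#' interval.
#'
#' @param state a `lek_state` begun on `day`.
#' @param model,theta the model and generating parameters.
#' @param scaffold a [lek_scaffold()] containing `day`.
#' @param day the day index to simulate.
#' @return list with `events` (data.frame for that day, `day_end`
#'   included) and the final `state`.
#' @export
simulate_day <- function(state, model, theta, scaffold, day) {
  theta <- .align_theta(theta, model)
  .simulate_day(state, model, theta, scaffold, day)
}

# internal core; returns list(events df, state)
.simulate_day <- function(state, model, theta, scaffold, day) {
  sd_rows <- scaffold$events[scaffold$events$day == day, ]
  t_end <- scaffold$days$t_end[scaffold$days$day == day]
  sched <- rbind(sd_rows,
                 data.frame(day = day, time_s = t_end, kind = "day_end",
                            actor = NA_character_))
  sched <- sched[order(sched$time_s), ]
  out <- list()
  nout <- 0L
  repeat {
    step <- .sim_step(state, model, theta, sched$kind[1], sched$time_s[1],
                      sched$actor[1], day)
    state <- step$state
    for (ev in step$events) {
      nout <- nout + 1L
      out[[nout]] <- ev
    }
    if (step$scheduled) {
      done <- sched$kind[1] == "day_end"
      sched <- sched[-1, , drop = FALSE]
      if (done) break
    } else {
      last <- step$events[[length(step$events)]]
      if (last$kind == "depart") {
        mu <- scaffold$return_delay_mean[last$sender]
        if (length(mu) == 1 && !is.na(mu) && mu > 0) {
          rt <- last$time + stats::rexp(1, 1 / mu)
          if (rt < t_end) {
            sched <- rbind(sched,
                           data.frame(day = day, time_s = rt,
                                      kind = "arrive", actor = last$sender))
            sched <- sched[order(sched$time_s), ]
          }
        }
      }
    }
  }
  ev <- out[seq_len(nout)]
  df <- data.frame(day = day,
                   time_s = vapply(ev, `[[`, numeric(1), "time"),
                   kind = vapply(ev, `[[`, character(1), "kind"),
                   sender = vapply(ev, function(e)
                     e$sender %||% NA_character_, character(1)),
                   receiver = vapply(ev, function(e)
                     e$receiver %||% NA_character_, character(1)))
  list(events = df, state = state)
}

#' Forward-simulate event histories over the scaffold's days
#'
#' Runs the generative process day by day: the state is carried across days
#' (today's counters become yesterday's at each day end), scheduled
#' exogenous events fire at their scaffold times, and endogenous events are
#' drawn by [draw_next_event()]'s law. Fixing the seed reproduces the
#' stream exactly.
#'
#' @param model,theta model specification and generating parameters.
#' @param roster a [lek_roster()].
#' @param scaffold a [lek_scaffold()].
#' @param seed integer seed (optional; the caller may manage the RNG).
#' @param carryover_state optional `lek_state` supplying yesterday-counters
#'   (e.g. the final state of a previous run).
#' @return object of class `lek_sim`: list with `events` (a
#'   [lek_events()]), `seed`, `final_state`.
#' @export
simulate_lek <- function(model, theta, roster, scaffold, seed = NULL,
                         carryover_state = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- .align_theta(theta, model)
  days <- scaffold$days$day
  state <- carryover_state %||2% lek_state(roster, day = days[1])
  parts <- vector("list", length(days))
  for (i in seq_along(days)) {
    state <- state_begin_day(state, roster, days[i])
    res <- .simulate_day(state, model, theta, scaffold, days[i])
    state <- res$state
    parts[[i]] <- res$events
  }
  run <- list(events = lek_events(do.call(rbind, parts)), seed = seed,
              final_state = state)
  class(run) <- "lek_sim"
  run
}

`%||2%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lek_sim <- function(x, ...) {
  cat("lek_sim:", nrow(x$events), "events over",
      length(unique(x$events$day)), "day(s), seed =",
      x$seed %||% NA, "\n")
  invisible(x)
}

#' Per-male summary metrics of a run
#'
#' Replays an event history and computes, per male: total fights (attack
#' cycles entered), wins, losses, win rate (wins / fights with an outcome;
#' `NA` when the male fought no fight to a decision), seconds available to
#' mate (present, females on the lek, and not engaged in any cycle),
#' solicitations received, successful (uninterrupted) copulations,
#' interrupted copulations, and the interruption rate
#' (interrupted / (interrupted + successful); `NA` with no copulations).
#'
#' @param events a [lek_events()] history or `lek_sim` run.
#' @param roster the roster.
#' @return data.frame, one row per actor.
#' @export
summarize_run <- function(events, roster) {
  if (inherits(events, "lek_sim")) events <- events$events
  events <- lek_events(as.data.frame(events))
  state <- lek_state(roster, day = if (nrow(events)) events$day[1] else 1L)
  n <- state$n
  fights <- wins <- losses <- avail_s <- solicits <- cop_ok <-
    cop_int <- rep(0, n)
  t_prev <- 0
  prev_day <- state$day
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]; t <- events$time_s[i]; day <- events$day[i]
    if (day != prev_day) {
      state <- state_begin_day(state, roster, day)
      prev_day <- day
      t_prev <- 0
    }
    dt <- t - t_prev
    if (dt > 0 && state$females) {
      free <- state$present & !.in_fight(state) & !.copulating(state)
      avail_s[free] <- avail_s[free] + dt
    }
    s <- match(events$sender[i], state$ids)
    r <- match(events$receiver[i], state$ids)
    if (kind %in% .ek$response) {
      fights[s] <- fights[s] + 1
      if (!is.na(r)) fights[r] <- fights[r] + 1
    } else if (kind == "disengage") {
      p <- state$fights
      row <- which(p$attacker == s | p$receiver == s)
      if (!is.na(r)) row <- row[p$attacker[row] == r | p$receiver[row] == r]
      if (length(row)) {
        partner <- if (p$attacker[row[1]] == s) p$receiver[row[1]] else
          p$attacker[row[1]]
        wins[s] <- wins[s] + 1
        losses[partner] <- losses[partner] + 1
      }
    } else if (kind == "solicit") {
      solicits[s] <- solicits[s] + 1
    } else if (kind == "copulation_end") {
      cop_ok[s] <- cop_ok[s] + 1
    } else if (kind == "attack" && !is.na(r) && r %in% state$cops$male) {
      cop_int[r] <- cop_int[r] + 1
    }
    state <- apply_event(state, list(kind = kind, time = t, day = day,
                                     sender = events$sender[i],
                                     receiver = events$receiver[i]),
                         check = FALSE)
    t_prev <- t
  }
  decided <- wins + losses
  copul <- cop_ok + cop_int
  data.frame(id = state$ids,
             fights = fights, wins = wins, losses = losses,
             win_rate = ifelse(decided > 0, wins / decided, NA_real_),
             avail_to_mate_s = avail_s,
             solicitations = solicits,
             copulations = cop_ok,
             interrupted = cop_int,
             interruption_rate = ifelse(copul > 0, cop_int / copul,
                                        NA_real_))
}

#' Treatment experiments on a simulated lek
#'
#' Simulates a simplified lek of six territory-holding males over seven
#' consecutive days plus a one-day burn-in (discarded from all metrics).
#' Treatments raise the focal male's intrinsic attack rate, disengagement
#' rate, or both, by one standard deviation (on the log-hazard scale) above
#' the shared mean; two scenarios set the focal male's intrinsic
#' susceptibility to being attacked at the mean or one SD above it.
#' Interruption-rate summaries exclude replicates with three or fewer
#' solicitations; all other metrics use every replicate. Treatment effects
#' are reported as z-scores against the control replicates (difference from
#' the control mean in units of the replicate-level control SD).
#'
#' @param treatments subset of `c("control", "attack", "disengage",
#'   "both")`; control is always run.
#' @param susceptibility `"average"` or `"high"`.
#' @param n_reps replicates per condition.
#' @param seed base seed; replicate r of every condition uses
#'   `seed + r` so conditions share seed streams.
#' @param setup optional list from [experiment_setup()]; built from the
#'   experiment preset when `NULL`.
#' @param focal focal male id (default the setup's first male).
#' @return object of class `lek_experiment`: `metrics` (per replicate x
#'   condition, focal male), `z` (z-score table vs control), `setup`.
#' @export
run_experiment <- function(treatments = c("control", "attack", "disengage",
                                          "both"),
                           susceptibility = c("average", "high"),
                           n_reps = 200, seed = 1, setup = NULL,
                           focal = NULL) {
  susceptibility <- match.arg(susceptibility)
  treatments <- match.arg(treatments, several.ok = TRUE)
  if (!"control" %in% treatments) treatments <- c("control", treatments)
  if (is.null(setup)) setup <- experiment_setup(susceptibility)
  focal <- focal %||2% setup$roster$actors$id[1]
  burn_day <- setup$scaffold$days$day[1]
  res <- list()
  for (tr in treatments) {
    theta <- setup$theta
    if (tr %in% c("attack", "both"))
      theta[paste0("attack:", focal)] <-
        theta[paste0("attack:", focal)] + setup$treat_sd
    if (tr %in% c("disengage", "both"))
      theta[paste0("disengage:", focal)] <-
        theta[paste0("disengage:", focal)] + setup$treat_sd
    for (r in seq_len(n_reps)) {
      run <- simulate_lek(setup$model, theta, setup$roster, setup$scaffold,
                          seed = seed + r)
      keep <- run$events$day != burn_day
      met <- summarize_run(lek_events(as.data.frame(run$events)[keep, ]),
                           setup$roster)
      met <- met[met$id == focal, ]
      res[[length(res) + 1L]] <-
        data.frame(treatment = tr, rep = r, met, row.names = NULL)
    }
  }
  metrics <- do.call(rbind, res)
  num_cols <- c("fights", "wins", "losses", "win_rate", "avail_to_mate_s",
                "solicitations", "copulations", "interrupted",
                "interruption_rate")
  ctl <- metrics[metrics$treatment == "control", ]
  zrow <- function(tr) {
    tm <- metrics[metrics$treatment == tr, ]
    vapply(num_cols, function(cn) {
      use_c <- ctl[[cn]]; use_t <- tm[[cn]]
      if (cn == "interruption_rate") {
        use_c <- use_c[ctl$solicitations > 3]
        use_t <- use_t[tm$solicitations > 3]
      }
      sdc <- stats::sd(use_c, na.rm = TRUE)
      if (!is.finite(sdc) || sdc == 0) return(NA_real_)
      (mean(use_t, na.rm = TRUE) - mean(use_c, na.rm = TRUE)) / sdc
    }, numeric(1))
  }
  z <- t(vapply(setdiff(treatments, "control"), zrow,
                numeric(length(num_cols))))
  out <- list(metrics = metrics, z = z, susceptibility = susceptibility,
              setup = setup, focal = focal, n_reps = n_reps, seed = seed)
  class(out) <- "lek_experiment"
  out
}

#' @export
print.lek_experiment <- function(x, ...) {
  cat("lek_experiment: focal", x$focal, "susceptibility",
      x$susceptibility, ",", x$n_reps, "reps/condition\n")
  cat("z-scores vs control:\n")
  print(round(x$z, 3))
  invisible(x)
}
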