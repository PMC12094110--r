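# Brute-force per-interval likelihood: replays the history event by event,
# enumerates the support set explicitly, evaluates every candidate's hazard
# one at a time through the public hazard/statistics API, and accumulates
# survival and event terms directly. Deliberately independent of the
# package's stacked design-matrix likelihood path.

oracle_fixed_u <- function(model, kind, sender, receiver, ids) {
  u <- numeric(0)
  if (kind == "attack") {
    u[if ("attack" %in% model$per_male) paste0("attack:", sender) else
      "attack"] <- 1
    if ("receive" %in% model$per_male && receiver != ids[1])
      u[paste0("receive:", receiver)] <- 1
  } else if (kind == "response_short_fight") {
    if (model$response_effects) u["resp.short_fight"] <- 1
  } else if (kind == "response_chase") {
    if (model$response_effects) u["resp.chase"] <- 1
  } else if (kind == "response_face_off") {
    u <- numeric(0)
  } else if (kind == "disengage") {
    u[if ("disengage" %in% model$per_male) paste0("disengage:", sender) else
      "disengage"] <- 1
  } else if (kind == "depart") {
    u["depart"] <- 1
  } else if (kind == "copulation_end") {
    u["cop_end"] <- 1
  } else if (kind == "solicit") {
    u[if (model$solicitation == "per_male" &&
          sender %in% (model$solicit_ids %||0% character(0)))
      paste0("solicit:", sender) else "solicit"] <- 1
  }
  u
}

oracle_hazard <- function(state, model, theta, cand) {
  u <- oracle_fixed_u(model, cand$kind, cand$sender, cand$receiver,
                      model$ids)
  su <- evaluate_statistics(state, cand, model$statistics)
  uu <- c(u, su[su != 0])
  if (!length(uu)) return(exp(0))  # reference response category
  rem_hazard(theta, uu)
}

oracle_supported <- function(state, model) {
  ss <- support_set(state)
  keep <- rep(TRUE, nrow(ss))
  if (!model$include_depart) keep <- keep & ss$kind != "depart"
  if (model$solicitation == "none")
    keep <- keep & !ss$kind %in% c("solicit", "copulation_end")
  ss[keep, , drop = FALSE]
}

oracle_loglik <- function(events, model, theta, roster) {
  events <- lek_events(as.data.frame(events))
  theta <- theta[model$par_names]
  state <- lek_state(roster, day = events$day[1])
  ll <- 0
  t_prev <- 0
  prev_day <- events$day[1]
  responses <- c("response_face_off", "response_short_fight",
                 "response_chase")
  endo <- c("attack", responses, "disengage", "solicit", "copulation_end",
            "depart")
  for (i in seq_len(nrow(events))) {
    kind <- events$kind[i]; t <- events$time_s[i]; day <- events$day[i]
    if (day != prev_day) {
      state <- state_begin_day(state, roster, day)
      prev_day <- day
      t_prev <- 0
    }
    dt <- t - t_prev
    ss <- oracle_supported(state, model)
    if (dt > 0 && nrow(ss) && !ss$kind[1] %in% responses) {
      lam_tot <- 0
      for (j in seq_len(nrow(ss)))
        lam_tot <- lam_tot + oracle_hazard(state, model, theta, ss[j, ])
      ll <- ll - dt * lam_tot
    }
    if (kind %in% responses) {
      h <- vapply(responses, function(kk)
        oracle_hazard(state, model, theta,
                      list(kind = kk, sender = events$sender[i],
                           receiver = events$receiver[i])), numeric(1))
      ll <- ll + log(h[[kind]] / sum(h))
    } else if (kind %in% endo) {
      ll <- ll + log(oracle_hazard(state, model, theta,
                                   list(kind = kind,
                                        sender = events$sender[i],
                                        receiver = events$receiver[i])))
    }
    state <- apply_event(state, list(kind = kind, time = t, day = day,
                                     sender = events$sender[i],
                                     receiver = events$receiver[i]),
                         check = FALSE)
    t_prev <- t
  }
  ll
}
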