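#' Specify a relational event model
#'
#' A model specification lays out the fixed effects (intercepts on the
#' log-hazard scale for each endogenous event category, optionally per
#' male) and the predictor-statistic set. Two solicitation schemes mirror
#' the competing hypotheses: `"single"` fits one solicitation intercept
#' common to all males (the "Aggression" formulation, which forces fighting
#' statistics to explain variation in solicitation), while `"per_male"`
#' fits a separate intercept for every male ever solicited, with
#' never-solicited males sharing the base hazard (the "Differential
#' Attractiveness" formulation).
#'
#' @param roster a [lek_roster()]; fixes the actor set and the distance
#'   standardisation (session mean/SD of pairwise centroid distances).
#' @param solicitation `"single"`, `"per_male"`, or `"none"` (no
#'   solicitation/copulation channel, for datasets without females).
#' @param statistics a [stat_catalog()] of predictor statistics.
#' @param per_male subset of `c("attack", "receive", "disengage")` to fit
#'   with individual-level intercepts. Receive effects are offsets with the
#'   first roster actor as reference.
#' @param response_effects fit intercepts for the response multinomial
#'   (short fight and chase, face-off as reference)?
#' @param include_depart model lek departures (if `FALSE` departures never
#'   occur under the model; used by the treatment experiments)?
#' @param solicit_ids ids of ever-solicited males for the `"per_male"`
#'   scheme; if `NULL` they are derived from the data at fit time.
#' @param standardize_distance centre/scale the distance covariate by the
#'   roster-wide mean/SD of pairwise distances?
#' @return object of class `lek_model` with element `par_names` giving the
#'   design columns.
#' @export
lek_model <- function(roster,
                      solicitation = c("single", "per_male", "none"),
                      statistics = default_stat_catalog(),
                      per_male = character(0),
                      response_effects = TRUE,
                      include_depart = TRUE,
                      solicit_ids = NULL,
                      standardize_distance = TRUE) {
  solicitation <- match.arg(solicitation)
  stopifnot(all(per_male %in% c("attack", "receive", "disengage")))
  ids <- roster$actors$id
  bulk_id <- ids[roster$actors$category == "X_bulk"]
  if (standardize_distance && any(statistics$pattern == "pair.dist")) {
    ds <- .roster_dist_moments(roster)
    attr(statistics, "dist_center") <- ds[1]
    attr(statistics, "dist_scale") <- ds[2]
  }
  m <- list(ids = ids, bulk_id = if (length(bulk_id)) bulk_id else NA,
            solicitation = solicitation, statistics = statistics,
            per_male = per_male, response_effects = response_effects,
            include_depart = include_depart, solicit_ids = solicit_ids)
  class(m) <- "lek_model"
  .refresh_model(m)
}

# recompute the cached design-column names and the per-spec list after any
# change to the statistic set or solicitation ids
.refresh_model <- function(m) {
  m$par_names <- .par_names(m)
  m$stat_list <- lapply(seq_len(nrow(m$statistics)), function(i)
    list(name = m$statistics$name[i], pattern = m$statistics$pattern[i],
         scope = m$statistics$scope[i], window = m$statistics$window[i],
         channel = m$statistics$channel[i]))
  m
}

.roster_dist_moments <- function(roster) {
  d <- roster$days[roster$days$present, ]
  vals <- unlist(lapply(split(d, d$day), function(dd) {
    if (nrow(dd) < 2) return(numeric(0))
    as.numeric(stats::dist(cbind(dd$x, dd$y)))
  }))
  if (length(vals) < 2) return(c(0, 1))
  c(mean(vals), max(stats::sd(vals), 1e-8))
}

.par_names <- function(m) {
  ids <- m$ids
  pn <- character(0)
  pn <- c(pn, if ("attack" %in% m$per_male) paste0("attack:", ids) else
    "attack")
  if ("receive" %in% m$per_male) pn <- c(pn, paste0("receive:", ids[-1]))
  if (m$response_effects) pn <- c(pn, "resp.short_fight", "resp.chase")
  pn <- c(pn, if ("disengage" %in% m$per_male)
    paste0("disengage:", ids) else "disengage")
  if (m$include_depart) pn <- c(pn, "depart")
  if (m$solicitation == "single") {
    pn <- c(pn, "solicit")
  } else if (m$solicitation == "per_male") {
    sol <- m$solicit_ids %||% character(0)
    non_bulk <- setdiff(ids, m$bulk_id)
    if (length(setdiff(non_bulk, sol))) pn <- c(pn, "solicit")
    if (length(sol)) pn <- c(pn, paste0("solicit:", sol))
  }
  if (m$solicitation != "none") pn <- c(pn, "cop_end")
  c(pn, m$statistics$name)
}

#' @export
print.lek_model <- function(x, ...) {
  cat("lek_model:", length(x$par_names), "parameters; solicitation scheme:",
      x$solicitation, "\n  fixed effects:",
      paste(setdiff(x$par_names, x$statistics$name), collapse = ", "),
      "\n  statistics:", nrow(x$statistics), "\n")
  invisible(x)
}

#' Zero parameter vector matching a model's design columns
#' @param model a [lek_model()].
#' @return named numeric vector of zeros.
#' @export
par_template <- function(model) {
  stats::setNames(numeric(length(model$par_names)), model$par_names)
}

# resolve ever-solicited males from data for the per-male scheme
.with_solicit_ids <- function(model, events) {
  if (model$solicitation != "per_male" || !is.null(model$solicit_ids))
    return(model)
  sol <- sort(unique(events$sender[events$kind == "solicit"]))
  model$solicit_ids <- sol
  .refresh_model(model)
}

# vectorised statistic values for a block of attack candidates s[k] -> r[k]
.stat_attack_vec <- function(state, spec, s, r, dc, ds) {
  gate <- rep(1, length(s))
  if (spec$channel == "interrupt") gate <- as.numeric(.copulating(state)[r])
  roles_f <- switch(spec$channel, attack_received = r, interrupt = r,
                    attack_initiated = s, NULL)
  if (is.null(roles_f)) return(rep(0, length(s)))
  roles_p <- if (identical(roles_f, r)) s else r
  ctx <- if (spec$channel == "solicit") "fem" else "all"
  w <- .win_idx(spec$window)
  cntm <- function(outcome) {
    M <- state$pc[, , outcome, w[1], ctx]
    for (ww in w[-1]) M <- M + state$pc[, , outcome, ww, ctx]
    M
  }
  val <- switch(spec$pattern,
    att.win = , att.lose = , recv.win = , recv.lose = {
      M <- cntm(c(att.win = "att_win", att.lose = "att_lose",
                  recv.win = "recv_win",
                  recv.lose = "recv_lose")[[spec$pattern]])
      if (spec$scope == "pairwise") M[cbind(roles_f, roles_p)] else
        rowSums(M)[roles_f]
    },
    winloss = , wl.diff.abs = {
      M <- cntm("att_win") + cntm("recv_win") - cntm("att_lose") -
        cntm("recv_lose")
      v <- if (spec$scope == "pairwise") M[cbind(roles_f, roles_p)] else
        rowSums(M)[roles_f]
      if (spec$pattern == "wl.diff.abs") abs(v) else v
    },
    lose.chase = .rec_vec(state, state$last_lose_chase)[roles_f],
    win.any = .rec_vec(state, state$last_win)[roles_f],
    interrupt.perp = rowSums(state$intp[, w, ctx, drop = FALSE])[roles_f],
    cops = rowSums(state$cop_succ[, w, ctx, drop = FALSE])[roles_f],
    fem.pres = rep(as.numeric(state$females), length(s)),
    pair.dist = (state$dist[cbind(roles_f, roles_p)] - dc) / ds,
    time.of.day = rep(state$clock_time / 3600, length(s)),
    disturb = rep(if (is.na(state$last_disturbance)) 0 else
      recency(max(state$time - state$last_disturbance, 1)), length(s)),
    terr.holder = as.numeric(state$terr[roles_p]),
    copulating = rep(1, length(s)),
    stop("unknown pattern: ", spec$pattern))
  val * gate
}

.rec_vec <- function(state, marker) {
  v <- rep(0, state$n)
  ok <- !is.na(marker)
  v[ok] <- 1 / sqrt(pmax(state$time - marker[ok], 1))
  v
}

# design matrix over the current support set (responses when pending).
# Returns list(ct = candidate table by index, X = candidates x parameters).
candidate_design <- function(state, model) {
  pn <- model$par_names
  k <- length(pn)
  col <- stats::setNames(seq_len(k), pn)
  sl <- model$stat_list
  dc <- attr(model$statistics, "dist_center") %||% 0
  ds <- attr(model$statistics, "dist_scale") %||% 1
  if (!is.null(state$pending)) {
    X <- matrix(0, 3, k)
    if (model$response_effects) {
      X[2, col[["resp.short_fight"]]] <- 1
      X[3, col[["resp.chase"]]] <- 1
    }
    return(list(ct = list(kind = .ek$response,
                          sender = rep(state$pending$receiver, 3L),
                          receiver = rep(state$pending$attacker, 3L)),
                X = X))
  }
  ct <- .candidate_table(state)
  if (!model$include_depart && any(drop_ <- ct$kind == "depart"))
    ct <- lapply(ct, function(v) v[!drop_])
  if (model$solicitation == "none" &&
      any(drop_ <- ct$kind %in% c("solicit", "copulation_end")))
    ct <- lapply(ct, function(v) v[!drop_])
  m <- length(ct$kind)
  X <- matrix(0, m, k)
  if (!m) return(list(ct = ct, X = X))
  ids <- state$ids
  # attacks (vectorised)
  ai <- which(ct$kind == "attack")
  if (length(ai)) {
    s <- ct$sender[ai]; r <- ct$receiver[ai]
    if ("attack" %in% model$per_male) {
      X[cbind(ai, col[paste0("attack:", ids[s])])] <- 1
    } else X[ai, col[["attack"]]] <- 1
    if ("receive" %in% model$per_male) {
      off <- r != 1L
      if (any(off))
        X[cbind(ai[off], col[paste0("receive:", ids[r[off]])])] <- 1
    }
    for (spec in sl) {
      if (!spec$channel %in% c("attack_received", "attack_initiated",
                               "interrupt")) next
      X[ai, col[[spec$name]]] <- .stat_attack_vec(state, spec, s, r, dc, ds)
    }
  }
  # remaining kinds (few rows; scalar evaluation)
  for (i in which(ct$kind != "attack")) {
    kind <- ct$kind[i]; s <- ct$sender[i]; r <- ct$receiver[i]
    fx <- switch(kind,
      disengage = if ("disengage" %in% model$per_male)
        paste0("disengage:", ids[s]) else "disengage",
      depart = "depart",
      copulation_end = "cop_end",
      solicit = {
        if (model$solicitation == "per_male" &&
            ids[s] %in% (model$solicit_ids %||% character(0)))
          paste0("solicit:", ids[s]) else "solicit"
      })
    X[i, col[[fx]]] <- 1
    for (spec in sl) {
      if (.channel_kind[[spec$channel]] != kind) next
      X[i, col[[spec$name]]] <-
        .eval_stat_idx(state, kind, s, r, spec, dc, ds)
    }
  }
  list(ct = ct, X = X)
}

#' Event hazard from parameters and a statistic vector
#'
#' The hazard of a supported event is exp of the inner product of the
#' parameter vector with its predictor vector, in events per second;
#' unsupported events have hazard zero.
#'
#' @param theta named parameter vector.
#' @param u named predictor vector aligned to `theta` (names must match
#'   one-to-one; entries of `theta` absent from `u` are treated as inactive
#'   only if `u` is a strict named subset).
#' @param supported is the event in the support set?
#' @return non-negative hazard (per second).
#' @examples
#' rem_hazard(c(depart = -8.54), c(depart = 1))            # 0.0002 / s
#' rem_hazard(c(depart = -8.54, fem = -1.37), c(depart = 1, fem = 1))
#' @export
rem_hazard <- function(theta, u, supported = TRUE) {
  if (!supported) return(0)
  if (is.null(names(theta)) || is.null(names(u)) ||
      !all(names(u) %in% names(theta)))
    stop("alignment error: u names must match theta names")
  unname(exp(sum(theta[names(u)] * u)))
}
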