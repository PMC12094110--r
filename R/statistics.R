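#' Reciprocal-square-root recency transform
#'
#' History effects that decay with elapsed time enter the model as
#' 1/sqrt(seconds since the qualifying event). Under the piecewise-constant
#' contract the value refreshes only at events and scheduled clock ticks
#' (every 15 minutes), so between refreshes the stale value is used.
#'
#' @param delta_seconds positive elapsed time in seconds.
#' @return 1/sqrt(delta_seconds), in (0, 1] for delta >= 1 s.
#' @examples
#' recency(9)   # 1/3
#' recency(400) # 0.05
#' @export
recency <- function(delta_seconds) {
  if (any(delta_seconds <= 0)) stop("delta_seconds must be positive")
  1 / sqrt(delta_seconds)
}

# pattern registry: allowed scopes / windows / channels per base pattern.
# windows: "cumulative","yesterday","today","recency","now" ("now" =
# instantaneous covariates with no history window).
.stat_patterns <- function() {
  count_w <- c("cumulative", "yesterday", "today")
  all_ch <- c("attack_received", "attack_initiated", "disengage",
              "solicit", "interrupt", "depart")
  both <- c("general", "pairwise")
  reg <- list(
    att.win      = list(scopes = both, windows = count_w, channels = all_ch),
    att.lose     = list(scopes = both, windows = count_w, channels = all_ch),
    recv.win     = list(scopes = both, windows = count_w, channels = all_ch),
    recv.lose    = list(scopes = both, windows = count_w, channels = all_ch),
    winloss      = list(scopes = both, windows = count_w, channels = all_ch),
    wl.diff.abs  = list(scopes = "pairwise", windows = count_w,
                        channels = all_ch),
    lose.chase   = list(scopes = "general", windows = "recency",
                        channels = all_ch),
    win.any      = list(scopes = "general", windows = "recency",
                        channels = all_ch),
    interrupt.perp = list(scopes = "general", windows = count_w,
                          channels = all_ch),
    cops         = list(scopes = "general", windows = count_w,
                        channels = all_ch),
    fem.pres     = list(scopes = "general", windows = "now",
                        channels = all_ch),
    pair.dist    = list(scopes = "pairwise", windows = "now",
                        channels = c("attack_received", "attack_initiated",
                                     "interrupt")),
    time.of.day  = list(scopes = "general", windows = "now",
                        channels = all_ch),
    disturb      = list(scopes = "general", windows = "recency",
                        channels = all_ch),
    terr.holder  = list(scopes = "pairwise", windows = "now",
                        channels = c("attack_received", "interrupt")),
    copulating   = list(scopes = "general", windows = "now",
                        channels = "interrupt")
  )
  reg
}

.window_tok <- c(cumulative = "cum", yesterday = "yest", today = "today",
                 recency = "rec", now = "")
.channel_tok <- c(attack_received = "attacked", attack_initiated = "attacker",
                  disengage = "disengage", solicit = "solicit",
                  interrupt = "interrupt", depart = "depart")
.channel_kind <- c(attack_received = "attack", attack_initiated = "attack",
                   interrupt = "attack", disengage = "disengage",
                   solicit = "solicit", depart = "depart")

.spec_name <- function(pattern, scope, window, channel) {
  scope_tok <- c(general = "gen", pairwise = "pair")[scope]
  w <- .window_tok[window]
  mapply(function(s, p, ww, ch)
    paste(c(s, p, if (nzchar(ww)) ww, ch), collapse = "."),
    scope_tok, pattern, w, .channel_tok[channel], USE.NAMES = FALSE)
}

#' Build a catalog of predictor-statistic specifications
#'
#' Crosses base patterns over scopes of effect (general, or pairwise with
#' respect to the interaction partner), history windows (cumulative,
#' yesterday, so-far-today, or reciprocal-square-root recency) and response
#' channels (the event category whose hazard the statistic modifies),
#' dropping combinations a pattern does not admit. The win-loss record
#' pattern crossed over both scopes, the three count windows and the four
#' fight-relevant channels yields the 24 win-loss predictors of the full
#' model. Names are deterministic, e.g. `gen.lose.chase.rec.depart`.
#'
#' Interrupt-channel statistics evaluate only while the candidate's receiver
#' is copulating; solicit-channel statistics draw on counters restricted to
#' events that occurred with females present.
#'
#' @param patterns character vector of base patterns (see Details).
#' @param scopes,windows,channels character vectors restricting the cross.
#' @return data.frame of class `lek_stat_catalog` with columns `name`,
#'   `pattern`, `scope`, `window`, `channel`.
#' @details Patterns: `att.win`, `att.lose`, `recv.win`, `recv.lose`
#'   (fight-role-by-outcome counts), `winloss` (wins minus losses),
#'   `wl.diff.abs` (absolute pairwise win-loss difference), `lose.chase`
#'   and `win.any` (recency of last chase lost / last win),
#'   `interrupt.perp` (interruptions perpetrated), `cops` (successful
#'   copulations), `fem.pres` (female presence 0/1), `pair.dist` (pairwise
#'   centroid distance, metres, optionally standardised), `time.of.day`
#'   (hours since session start at the last clock tick), `disturb`
#'   (disturbance recency), `terr.holder` (attacker is a territory holder),
#'   `copulating` (receiver is copulating; with the interrupt channel this
#'   is the copulation-start attack-risk indicator).
#' @export
stat_catalog <- function(patterns,
                         scopes = c("general", "pairwise"),
                         windows = c("cumulative", "yesterday", "today",
                                     "recency", "now"),
                         channels = names(.channel_tok)) {
  reg <- .stat_patterns()
  unknown <- setdiff(patterns, names(reg))
  if (length(unknown))
    stop("catalog error: unknown pattern(s): ",
         paste(unknown, collapse = ", "))
  bad_ch <- setdiff(channels, names(.channel_tok))
  if (length(bad_ch))
    stop("catalog error: unknown channel(s): ", paste(bad_ch, collapse = ", "))
  rows <- list()
  for (p in patterns) {
    r <- reg[[p]]
    g <- expand.grid(scope = intersect(scopes, r$scopes),
                     window = intersect(windows, r$windows),
                     channel = intersect(channels, r$channels),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (nrow(g))
      rows[[p]] <- data.frame(pattern = p, g)
  }
  if (!length(rows) && length(patterns))
    stop("catalog error: requested combination is empty for pattern(s): ",
         paste(patterns, collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pattern = character(0), scope = character(0),
               window = character(0), channel = character(0))
  out <- out[order(match(out$pattern, patterns), out$scope,
                   match(out$window, names(.window_tok)),
                   match(out$channel, names(.channel_tok))), ]
  out <- data.frame(name = .spec_name(out$pattern, out$scope, out$window,
                                      out$channel), out)
  rownames(out) <- NULL
  class(out) <- c("lek_stat_catalog", "data.frame")
  out
}

#' A single predictor-statistic specification
#' @inheritParams stat_catalog
#' @param pattern,scope,window,channel scalars.
#' @return one-row `lek_stat_catalog`.
#' @export
stat_spec <- function(pattern, scope, window, channel) {
  out <- stat_catalog(pattern, scope, window, channel)
  if (nrow(out) != 1)
    stop("catalog error: invalid combination ",
         paste(pattern, scope, window, channel, sep = "/"))
  out
}

#' The shipped default statistic set
#'
#' A compact analogue of the best-fitting model's predictor set: female
#' presence suppressing attacks and departures and hastening disengagement;
#' pairwise centroid distance and today's absolute pairwise win-loss
#' difference on incoming attacks; win recency as an initiator effect; the
#' copulation-start indicator, yesterday's pairwise receive-and-lose count
#' and the territory-holder indicator on interruptions; today's pairwise
#' win-loss record on disengagement; and lost-chase recency on departure.
#'
#' @return `lek_stat_catalog`.
#' @export
default_stat_catalog <- function() {
  rbind(
    stat_spec("fem.pres", "general", "now", "attack_received"),
    stat_spec("pair.dist", "pairwise", "now", "attack_received"),
    stat_spec("wl.diff.abs", "pairwise", "today", "attack_received"),
    stat_spec("win.any", "general", "recency", "attack_initiated"),
    stat_spec("copulating", "general", "now", "interrupt"),
    stat_spec("recv.lose", "pairwise", "yesterday", "interrupt"),
    stat_spec("terr.holder", "pairwise", "now", "interrupt"),
    stat_spec("fem.pres", "general", "now", "disengage"),
    stat_spec("winloss", "pairwise", "today", "disengage"),
    stat_spec("cops", "general", "today", "solicit"),
    stat_spec("time.of.day", "general", "now", "solicit"),
    stat_spec("fem.pres", "general", "now", "depart"),
    stat_spec("lose.chase", "general", "recency", "depart")
  )
}

# focal / partner resolution for a candidate under a channel; returns NULL
# when the statistic does not apply to this candidate kind
.stat_roles <- function(kind, s, r, channel) {
  if (.channel_kind[[channel]] != kind) return(NULL)
  switch(channel,
    attack_received = list(f = r, p = s),
    interrupt = list(f = r, p = s),
    attack_initiated = list(f = s, p = r),
    disengage = list(f = s, p = r),
    solicit = list(f = s, p = NA_integer_),
    depart = list(f = s, p = NA_integer_))
}

.win_idx <- function(window) switch(window,
  today = "today", yesterday = "yesterday",
  cumulative = c("today", "yesterday", "older"), character(0))

# core evaluator by index; `now` is the state's last refresh time
.eval_stat_idx <- function(state, kind, s, r, spec, dist_center = 0,
                           dist_scale = 1) {
  roles <- .stat_roles(kind, s, r, spec$channel)
  if (is.null(roles)) return(0)
  if (spec$channel == "interrupt" && !(r %in% state$cops$male)) return(0)
  ctx <- if (spec$channel == "solicit") "fem" else "all"
  f <- roles$f; p <- roles$p
  w <- .win_idx(spec$window)
  cnt <- function(outcome) {
    if (spec$scope == "pairwise") {
      if (is.na(p)) return(0)
      sum(state$pc[f, p, outcome, w, ctx])
    } else sum(state$pc[f, , outcome, w, ctx])
  }
  rec <- function(marker) {
    if (is.na(marker)) return(0)
    recency(max(state$time - marker, 1))
  }
  switch(spec$pattern,
    att.win = cnt("att_win"), att.lose = cnt("att_lose"),
    recv.win = cnt("recv_win"), recv.lose = cnt("recv_lose"),
    winloss = cnt("att_win") + cnt("recv_win") -
              cnt("att_lose") - cnt("recv_lose"),
    wl.diff.abs = abs(cnt("att_win") + cnt("recv_win") -
                      cnt("att_lose") - cnt("recv_lose")),
    lose.chase = rec(state$last_lose_chase[f]),
    win.any = rec(state$last_win[f]),
    interrupt.perp = sum(state$intp[f, w, ctx]),
    cops = sum(state$cop_succ[f, w, ctx]),
    fem.pres = as.numeric(state$females),
    pair.dist = if (is.na(p)) 0 else
      (state$dist[f, p] - dist_center) / dist_scale,
    time.of.day = state$clock_time / 3600,
    disturb = rec(state$last_disturbance),
    terr.holder = if (is.na(p)) 0 else as.numeric(state$terr[p]),
    copulating = 1,
    stop("unknown pattern: ", spec$pattern))
}

#' Evaluate a statistic vector for a candidate event
#'
#' Computes the predictor vector u for one candidate event type given the
#' current state. Statistics whose channel does not match the candidate's
#' event category evaluate to 0, as do interrupt-channel statistics when the
#' candidate's receiver is not copulating. Values are piecewise constant:
#' they change only when an event (including a clock tick) updates the
#' state.
#'
#' @param state a `lek_state`.
#' @param candidate list or one-row data.frame with `kind`, `sender`,
#'   `receiver` (actor ids, NA where not applicable).
#' @param catalog a [stat_catalog()].
#' @return named numeric vector aligned to `catalog$name`.
#' @export
evaluate_statistics <- function(state, candidate, catalog) {
  stopifnot(inherits(state, "lek_state"))
  s <- .resolve_idx(state, candidate$sender %||% NA_character_)
  r <- .resolve_idx(state, candidate$receiver %||% NA_character_)
  dc <- attr(catalog, "dist_center") %||% 0
  ds <- attr(catalog, "dist_scale") %||% 1
  vals <- vapply(seq_len(nrow(catalog)), function(i)
    .eval_stat_idx(state, candidate$kind, s, r, catalog[i, ], dc, ds),
    numeric(1))
  stats::setNames(vals, catalog$name)
}

#' Write / read a statistic catalog as CSV
#' @param catalog a [stat_catalog()].
#' @param path file path.
#' @return `read_stat_catalog` returns a `lek_stat_catalog`.
#' @export
write_stat_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stat_catalog
#' @export
read_stat_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    stat_spec(df$pattern[i], df$scope[i], df$window[i], df$channel[i])))
  out
}
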