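#' Synthetic-data configuration presets
#'
#' Builds the configuration for the synthetic-data generator. Three presets
#' are shipped:
#'
#' * `"toy"` — two identified males, no females, five 2-hour days, and a
#'   three-parameter model (attack, disengage and depart intercepts); the
#'   workhorse for parameter-recovery studies.
#' * `"paper_scale"` — 14 identified males, 15 single-day "U" males and the
#'   X bulk actor over 18 four-hour days, with one female window per day,
#'   rare disturbances, and a generating parameter vector anchored on the
#'   worked-example magnitudes (departure intercept -8.54,
#'   female-presence effect on departure -1.37, lost-chase recency 2.84,
#'   copulation-start attack indicator 3.8); event density is calibrated to
#'   roughly 290 events per day.
#' * `"experiment"` — six territory-holding males with individual-level
#'   attack, receive, disengage and solicitation intercepts, no departures,
#'   a fixed 2-hour female window inside a 4-hour session, eight days (one
#'   burn-in plus seven); the substrate of the treatment experiments.
#'
#' @param preset preset name.
#' @param ... named overrides of any config field (e.g. `n_days = 2`).
#' @return list of class `lek_synth_config`.
#' @export
synth_config <- function(preset = c("toy", "paper_scale", "experiment"),
                         ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    toy = list(
      preset = "toy", n_identified = 2, n_U = 0, include_X_bulk = FALSE,
      n_days = 5, session_length_s = 7200, female_window = NULL,
      identified_presence_prob = 1, disturbance_rate = 0,
      grid_spacing = 10, centroid_jitter_sd = 1.5,
      arrival_window_s = 300, return_delay_mean_s = 600,
      model = list(solicitation = "none", per_male = character(0),
                   response_effects = FALSE, include_depart = TRUE,
                   statistics = "none"),
      theta = c(attack = -4.8, disengage = -3.0, depart = -7.5)),
    paper_scale = list(
      preset = "paper_scale", n_identified = 14, n_U = 15,
      include_X_bulk = TRUE, n_days = 18, session_length_s = 14400,
      female_window = list(start_mean = 4000, start_sd = 600,
                           len_mean = 6000, len_sd = 900),
      identified_presence_prob = 0.55, disturbance_rate = 4 / 18,
      grid_spacing = 10, centroid_jitter_sd = 1.5,
      arrival_window_s = 1800, return_delay_mean_s = 900,
      model = list(solicitation = "per_male",
                   solicit_ids = sprintf("m%02d", 1:5),
                   per_male = character(0), response_effects = TRUE,
                   include_depart = TRUE, statistics = "default"),
      theta = c(attack = -10.1, resp.short_fight = 0.3, resp.chase = -0.3,
                disengage = -3.4, depart = -8.54, solicit = -11,
                "solicit:m01" = -8.4, "solicit:m02" = -8.7,
                "solicit:m03" = -9.0, "solicit:m04" = -9.2,
                "solicit:m05" = -9.4, cop_end = -1.7,
                gen.fem.pres.attacked = -0.6,
                pair.pair.dist.attacked = -1.0,
                pair.wl.diff.abs.today.attacked = 0.1,
                gen.win.any.rec.attacker = 1.0,
                gen.copulating.interrupt = 3.8,
                pair.recv.lose.yest.interrupt = 0.3,
                pair.terr.holder.interrupt = 0.7,
                gen.fem.pres.disengage = 0.5,
                pair.winloss.today.disengage = 0.2,
                gen.cops.today.solicit = 0.15,
                gen.time.of.day.solicit = -0.15,
                gen.fem.pres.depart = -1.37,
                gen.lose.chase.rec.depart = 2.84)),
    experiment = list(
      preset = "experiment", n_identified = 6, n_U = 0,
      include_X_bulk = FALSE, n_days = 8, session_length_s = 14400,
      female_window = list(start_mean = 3600, start_sd = 0,
                           len_mean = 7200, len_sd = 0),
      identified_presence_prob = 1, disturbance_rate = 0,
      grid_spacing = 10, centroid_jitter_sd = 0,
      arrival_window_s = 0, return_delay_mean_s = NA,
      treat_sd = 0.5,
      model = list(solicitation = "per_male",
                   solicit_ids = sprintf("m%02d", 1:6),
                   per_male = c("attack", "receive", "disengage"),
                   response_effects = TRUE, include_depart = FALSE,
                   statistics = "default"),
      theta = c(stats::setNames(rep(-10.0, 6),
                                paste0("attack:", sprintf("m%02d", 1:6))),
                resp.short_fight = 0.3, resp.chase = -0.3,
                stats::setNames(rep(-3.4, 6),
                                paste0("disengage:", sprintf("m%02d", 1:6))),
                stats::setNames(rep(-9.0, 6),
                                paste0("solicit:", sprintf("m%02d", 1:6))),
                cop_end = -2.2,
                gen.fem.pres.attacked = -0.6,
                pair.pair.dist.attacked = -1.0,
                pair.wl.diff.abs.today.attacked = 0.1,
                gen.win.any.rec.attacker = 1.0,
                gen.copulating.interrupt = 3.8,
                pair.recv.lose.yest.interrupt = 0.3,
                pair.terr.holder.interrupt = 0.7,
                gen.fem.pres.disengage = 0.5,
                pair.winloss.today.disengage = 0.2,
                gen.cops.today.solicit = 0.4,
                gen.time.of.day.solicit = -0.15)))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "lek_synth_config"
  cfg
}

.config_catalog <- function(cfg) {
  switch(cfg$model$statistics,
         none = stat_catalog(character(0)),
         default = default_stat_catalog(),
         stop("unknown statistics preset: ", cfg$model$statistics))
}

#' Generate a synthetic actor roster
#'
#' Identified males are present on each day independently with the
#' configured probability, each "U" male appears on exactly one random day,
#' and the bulk actor is present on roughly half the days. Territory-holder
#' flags follow the two-consecutive-previous-days rule. Centroids sit on a
#' jittered grid with the configured stake spacing (10 m by default).
#'
#' @param config a [synth_config()].
#' @param seed optional seed (omit to use the current RNG stream).
#' @return a [lek_roster()].
#' @export
make_roster <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("m%02d", seq_len(config$n_identified))
  cats <- rep("identified", config$n_identified)
  if (config$n_U > 0) {
    ids <- c(ids, sprintf("u%02d", seq_len(config$n_U)))
    cats <- c(cats, rep("U", config$n_U))
  }
  if (config$include_X_bulk) {
    ids <- c(ids, "X")
    cats <- c(cats, "X_bulk")
  }
  n <- length(ids)
  nd <- config$n_days
  pres <- matrix(FALSE, n, nd)
  pres[seq_len(config$n_identified), ] <-
    stats::runif(config$n_identified * nd) < config$identified_presence_prob
  if (config$n_U > 0) {
    udays <- sample.int(nd, config$n_U, replace = TRUE)
    for (u in seq_len(config$n_U))
      pres[config$n_identified + u, udays[u]] <- TRUE
  }
  if (config$include_X_bulk) pres[n, ] <- stats::runif(nd) < 0.5
  terr <- matrix(FALSE, n, nd)
  if (nd >= 3)
    for (d in 3:nd) terr[, d] <- pres[, d - 1] & pres[, d - 2]
  side <- ceiling(sqrt(n))
  gx <- config$grid_spacing * ((seq_len(n) - 1) %% side)
  gy <- config$grid_spacing * ((seq_len(n) - 1) %/% side)
  days <- do.call(rbind, lapply(seq_len(nd), function(d) {
    data.frame(id = ids, day = d, present = pres[, d],
               territory = terr[, d],
               x = gx + stats::rnorm(n, 0, config$centroid_jitter_sd),
               y = gy + stats::rnorm(n, 0, config$centroid_jitter_sd))
  }))
  lek_roster(data.frame(id = ids, category = cats), days)
}

#' Generate an exogenous scaffold for a synthetic roster
#'
#' Per day: staggered arrivals for every male present (before the female
#' window opens), one contiguous female-presence window with configurable
#' start/length jitter, Poisson-count disturbances (each followed by
#' re-arrivals of that day's males a few minutes later), the 15-minute
#' clock grid and the observation end.
#'
#' @param config a [synth_config()].
#' @param roster a roster from [make_roster()].
#' @param seed optional seed.
#' @return a [lek_scaffold()].
#' @export
make_scaffold <- function(config, roster, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  te <- config$session_length_s
  rows <- list()
  for (d in seq_len(config$n_days)) {
    pd <- roster$days[roster$days$day == d & roster$days$present, ]
    if (nrow(pd)) {
      at <- if (config$arrival_window_s > 0)
        stats::runif(nrow(pd), 0, config$arrival_window_s) else
          rep(0, nrow(pd))
      rows[[length(rows) + 1L]] <-
        data.frame(day = d, time_s = at, kind = "arrive", actor = pd$id)
    }
    fw <- config$female_window
    if (!is.null(fw)) {
      fs <- max(0, stats::rnorm(1, fw$start_mean, fw$start_sd))
      fl <- max(600, stats::rnorm(1, fw$len_mean, fw$len_sd))
      fe <- min(te - 1, fs + fl)
      if (fs < fe)
        rows[[length(rows) + 1L]] <-
          data.frame(day = d, time_s = c(fs, fe),
                     kind = c("female_enter", "female_exit"),
                     actor = NA_character_)
    }
    ndist <- stats::rpois(1, config$disturbance_rate)
    if (ndist > 0) {
      dt <- sort(stats::runif(ndist, 600, te - 1200))
      rows[[length(rows) + 1L]] <-
        data.frame(day = d, time_s = dt, kind = "disturbance",
                   actor = NA_character_)
      for (tdist in dt) {
        if (nrow(pd))
          rows[[length(rows) + 1L]] <-
            data.frame(day = d,
                       time_s = tdist + stats::runif(nrow(pd), 300, 900),
                       kind = "arrive", actor = pd$id)
      }
    }
  }
  ev <- do.call(rbind, rows)
  ev <- ev[ev$time_s < te, ]
  ret <- if (is.na(config$return_delay_mean_s)) numeric(0) else
    stats::setNames(rep(config$return_delay_mean_s,
                        nrow(roster$actors)), roster$actors$id)
  lek_scaffold(days = data.frame(day = seq_len(config$n_days), t_end = te),
               events = ev, return_delay_mean = ret)
}

# model implied by a config, bound to a roster
.config_model <- function(config, roster) {
  lek_model(roster,
            solicitation = config$model$solicitation,
            statistics = .config_catalog(config),
            per_male = config$model$per_male,
            response_effects = config$model$response_effects,
            include_depart = config$model$include_depart,
            solicit_ids = config$model$solicit_ids %||2% NULL)
}

# full generating parameter vector: template zeros overlaid with the
# config's named values (unknown names are an error)
.config_theta <- function(config, model) {
  th <- par_template(model)
  unknown <- setdiff(names(config$theta), names(th))
  if (length(unknown))
    stop("config error: theta name(s) not in model: ",
         paste(unknown, collapse = ", "))
  th[names(config$theta)] <- config$theta
  th
}

#' Generate a complete synthetic dataset
#'
#' Draws a roster and scaffold from the configuration, then
#' forward-simulates the event history under the configuration's
#' ground-truth parameter vector. Bit-identical regeneration is guaranteed
#' for a fixed config and seed.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return object of class `lek_dataset`: `roster`, `scaffold`, `events`,
#'   `theta_truth`, `model`, `config`, `seed`.
#' @export
generate_dataset <- function(config, seed = 1) {
  set.seed(seed)
  roster <- make_roster(config)
  scaffold <- make_scaffold(config, roster)
  model <- .config_model(config, roster)
  theta <- .config_theta(config, model)
  run <- simulate_lek(model, theta, roster, scaffold)
  out <- list(roster = roster, scaffold = scaffold, events = run$events,
              theta_truth = theta, model = model, config = config,
              seed = seed)
  class(out) <- "lek_dataset"
  out
}

#' @export
print.lek_dataset <- function(x, ...) {
  cat("lek_dataset (preset ", x$config$preset, "): ", nrow(x$events),
      " events, ", nrow(x$roster$actors), " actors, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Deterministic setup for the treatment experiments
#'
#' Six territory-holding males, all present every day with equal mean
#' intrinsic attack, disengagement and solicitation intercepts; fixed
#' centroid grid; a fixed 2 h female window in a 4 h session; no
#' departures or disturbances. The high-susceptibility scenario raises the
#' focal male's intrinsic receive (incoming-attack) effect by one SD.
#'
#' @param susceptibility `"average"` or `"high"`.
#' @return list with `roster`, `scaffold`, `model`, `theta`, `treat_sd`,
#'   `focal`.
#' @export
experiment_setup <- function(susceptibility = c("average", "high")) {
  susceptibility <- match.arg(susceptibility)
  cfg <- synth_config("experiment")
  ids <- sprintf("m%02d", 1:6)
  gx <- cfg$grid_spacing * ((0:5) %% 3)
  gy <- cfg$grid_spacing * ((0:5) %/% 3)
  days <- do.call(rbind, lapply(seq_len(cfg$n_days), function(d)
    data.frame(id = ids, day = d, present = TRUE, territory = TRUE,
               x = gx, y = gy)))
  roster <- lek_roster(data.frame(id = ids, category = "identified"), days)
  te <- cfg$session_length_s
  fw <- cfg$female_window
  ev <- do.call(rbind, lapply(seq_len(cfg$n_days), function(d) rbind(
    data.frame(day = d, time_s = 0, kind = "arrive", actor = ids),
    data.frame(day = d, time_s = c(fw$start_mean,
                                   fw$start_mean + fw$len_mean),
               kind = c("female_enter", "female_exit"),
               actor = NA_character_))))
  scaffold <- lek_scaffold(days = data.frame(day = seq_len(cfg$n_days),
                                             t_end = te), events = ev)
  model <- .config_model(cfg, roster)
  theta <- .config_theta(cfg, model)
  # focal male: second actor, so a receive offset column exists for him
  focal <- ids[2]
  if (susceptibility == "high")
    theta[paste0("receive:", focal)] <-
      theta[paste0("receive:", focal)] + cfg$treat_sd
  list(roster = roster, scaffold = scaffold, model = model, theta = theta,
       treat_sd = cfg$treat_sd, focal = focal,
       susceptibility = susceptibility)
}

#' Parameter-recovery experiment
#'
#' Generates `n_datasets` independent synthetic datasets from a config,
#' fits the generating model to each, and reports per-coefficient bias,
#' RMSE and the coverage of +/-2 posterior-SE intervals around the
#' estimates. Failed fits are recorded and skipped, not fatal.
#'
#' @param config a [synth_config()].
#' @param n_datasets number of datasets.
#' @param seed base seed; dataset i uses `seed + i`.
#' @param prior_sd prior SD for [fit_rem()].
#' @return list with `estimates` (long data.frame: dataset, name, truth,
#'   estimate, se, covered), `summary` (per-coefficient bias, rmse,
#'   coverage), `n_failed`.
#' @export
recovery_experiment <- function(config, n_datasets = 50, seed = 1,
                                prior_sd = 10) {
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(n_datasets)) {
    ds <- generate_dataset(config, seed = seed + i)
    fit <- tryCatch(
      fit_rem(ds$events, ds$model, ds$roster, prior_sd = prior_sd),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    truth <- ds$theta_truth[names(fit$theta)]
    rows[[length(rows) + 1L]] <-
      data.frame(dataset = i, name = names(fit$theta),
                 truth = unname(truth), estimate = unname(fit$theta),
                 se = unname(fit$se),
                 covered = abs(fit$theta - truth) <= 2 * fit$se,
                 n_events = fit$n_events, row.names = NULL)
  }
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(est, est$name), function(g)
    data.frame(name = g$name[1], truth = g$truth[1],
               bias = mean(g$estimate - g$truth),
               rmse = sqrt(mean((g$estimate - g$truth)^2)),
               coverage = mean(g$covered), n = nrow(g))))
  rownames(summ) <- NULL
  list(estimates = est, summary = summ, n_failed = n_failed)
}
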