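test_that("hazards reproduce the worked departure examples", {
  theta <- c(depart = -8.54, gen.fem.pres.depart = -1.37,
             gen.lose.chase.rec.depart = 2.84)
  expect_equal(signif(rem_hazard(theta, c(depart = 1)), 1), 2e-4)
  expect_equal(signif(rem_hazard(theta, c(depart = 1,
                                          gen.fem.pres.depart = 1)), 1),
               5e-5)
  h3 <- rem_hazard(theta, c(depart = 1, gen.fem.pres.depart = 1,
                            gen.lose.chase.rec.depart = recency(9)))
  expect_equal(signif(h3, 2), 1.3e-4)
  # expected waiting time at the baseline hazard is about 5000 s
  expect_equal(1 / rem_hazard(theta, c(depart = 1)), 5000, tolerance = 0.03)

  expect_equal(rem_hazard(theta, c(depart = 1), supported = FALSE), 0)
  expect_error(rem_hazard(theta, c(nonesuch = 1)), "alignment")
})

test_that("starting a copulation multiplies attack hazard about 45-fold", {
  theta <- c(attack = -9, gen.copulating.interrupt = 3.8)
  base <- rem_hazard(theta, c(attack = 1))
  onset <- rem_hazard(theta, c(attack = 1, gen.copulating.interrupt = 1))
  expect_equal(onset / base, exp(3.8))
  expect_equal(round(onset / base), 45)
})

test_that("log-likelihood matches closed forms on degenerate histories", {
  r <- fixture_roster(n_named = 2, bulk = FALSE)
  model <- lek_model(r, solicitation = "none",
                     statistics = stat_catalog(character(0)),
                     response_effects = FALSE)
  theta <- c(attack = -5, disengage = -3, depart = -8)

  # pure survival: two males available for T seconds, no endogenous event;
  # total hazard = 2 attacks + 2 departures
  ev0 <- events_df(list(ev("arrive", 0, "m01"), ev("arrive", 0, "m02"),
                        ev("day_end", 1000)))
  Lam <- 2 * exp(-5) + 2 * exp(-8)
  expect_equal(rem_loglik(ev0, model, theta, r), -1000 * Lam,
               tolerance = 1e-12)

  # single observed event: log(lambda) - Lambda * dt over its interval,
  # then survival of the post-event state to day end
  ev1 <- events_df(list(ev("arrive", 0, "m01"), ev("arrive", 0, "m02"),
                        ev("depart", 400, "m02"), ev("day_end", 1000)))
  Lam2 <- exp(-8)  # only m01 left: nobody to attack, he may still depart
  expect_equal(rem_loglik(ev1, model, theta, r),
               (-8) - 400 * Lam - 600 * Lam2, tolerance = 1e-12)
})

test_that("likelihood equals the brute-force per-interval oracle", {
  # rich model: statistics, females, interruptions, chases, the bulk actor
  r <- fixture_roster(n_named = 3, bulk = TRUE, territory = TRUE)
  model <- lek_model(r, solicitation = "single",
                     statistics = default_stat_catalog(),
                     response_effects = TRUE)
  theta <- par_template(model)
  theta[] <- c(-6, 0.2, -0.2, -3.2, -7.5, -8.5, -2,
               -0.4, -0.3, 0.1, 0.8, 3.8, 0.2, 0.5, 0.4, 0.15, 0.3,
               -0.1, -1.37, 2.84)[seq_along(theta)]
  h <- events_df(list(
    ev("arrive", 0, "m01"), ev("arrive", 2, "m02"),
    ev("arrive", 3, "m03"), ev("arrive", 4, "X"),
    ev("female_enter", 60),
    ev("attack", 100, "m01", "m02"),
    ev("response_chase", 100, "m02", "m01"),
    ev("disengage", 160, "m01", "m02"),
    ev("solicit", 300, "m03"),
    ev("attack", 305, "m01", "m03"),
    ev("response_short_fight", 305, "m03", "m01"),
    ev("disengage", 330, "m03", "m01"),
    ev("clock", 900),
    ev("solicit", 950, "m03"),
    ev("copulation_end", 957, "m03"),
    ev("female_exit", 1500),
    ev("depart", 1700, "m02"),
    ev("day_end", 1800)))
  expect_equal(rem_loglik(h, model, theta, r),
               oracle_loglik(h, model, theta, r), tolerance = 1e-9)

  # and across random simulated toy prefixes
  cfg <- synth_config("toy", n_days = 1, session_length_s = 1200)
  for (seed in c(3, 14)) {
    ds <- generate_dataset(cfg, seed = seed)
    evs <- lek_events(as.data.frame(ds$events)[1:min(20, nrow(ds$events)), ])
    th <- ds$theta_truth
    expect_equal(rem_loglik(evs, ds$model, th, ds$roster),
                 oracle_loglik(evs, ds$model, th, ds$roster),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to a uniform time-origin shift", {
  r <- fixture_roster(n_named = 2, bulk = FALSE)
  model <- lek_model(r, solicitation = "none",
                     statistics = stat_catalog(character(0)),
                     response_effects = FALSE)
  theta <- c(attack = -5, disengage = -3, depart = -8)
  base <- fixture_fight_history()
  shifted <- as.data.frame(base)
  shifted$time_s <- shifted$time_s + 37.5
  expect_equal(rem_loglik(base, model, theta, r),
               rem_loglik(lek_events(shifted), model, theta, r),
               tolerance = 1e-10)
})

test_that("BIC follows k log n - 2 logL and models nest", {
  fake <- structure(list(bic = 3 * log(100) + 500), class = "lek_fit")
  expect_equal(rem_bic(fake), 513.8155, tolerance = 1e-4)

  # per-male solicitation nests the single intercept: logLik can only gain
  cfg <- synth_config("experiment", n_days = 2)
  set.seed(31)
  su <- experiment_setup("average")
  sc <- su$scaffold
  sc$days <- sc$days[1:2, ]
  sc$events <- sc$events[sc$events$day <= 2, ]
  run <- simulate_lek(su$model, su$theta, su$roster, sc, seed = 31)
  r <- su$roster
  m_single <- lek_model(r, solicitation = "single",
                        statistics = stat_catalog(character(0)),
                        response_effects = TRUE, include_depart = FALSE)
  m_per <- lek_model(r, solicitation = "per_male",
                     statistics = stat_catalog(character(0)),
                     response_effects = TRUE, include_depart = FALSE)
  f1 <- fit_rem(run$events, m_single, r, prior_sd = 100)
  f2 <- fit_rem(run$events, m_per, r, prior_sd = 100)
  expect_gte(f2$logLik, f1$logLik - 1e-6)
  expect_equal(f1$bic, f1$k * log(f1$n_events) - 2 * f1$logLik)
})

test_that("posterior mode beats the truth in likelihood and is regular", {
  ds <- generate_dataset(synth_config("toy", n_days = 2), seed = 8)
  fit <- fit_rem(ds$events, ds$model, ds$roster)
  expect_equal(fit$convergence$code, 0L)
  expect_lt(fit$convergence$grad_norm, 1e-3)
  expect_gte(fit$logLik,
             rem_loglik(ds$events, ds$model, ds$theta_truth, ds$roster))
  expect_true(all(fit$se > 0))

  # an unidentifiable column is reported by name
  m_sol <- lek_model(ds$roster, solicitation = "single",
                     statistics = stat_catalog(character(0)),
                     response_effects = FALSE)
  expect_error(fit_rem(ds$events, m_sol, ds$roster),
               "identifiability.*solicit")
})

test_that("the prior keeps never-observed channels finite", {
  # no departure is ever observed: the depart intercept has no finite MLE
  # (the likelihood pushes it to -Inf) but the Gaussian prior bounds it
  r <- fixture_roster(n_named = 2, bulk = FALSE)
  model <- lek_model(r, solicitation = "none",
                     statistics = stat_catalog(character(0)),
                     response_effects = FALSE)
  fit <- fit_rem(fixture_fight_history(), model, r, prior_sd = 5)
  expect_true(all(is.finite(fit$theta)))
  expect_true(all(is.finite(fit$se)))
  expect_lt(fit$theta[["depart"]], -2)
  expect_gt(fit$theta[["depart"]], -25)
})

test_that("greedy BIC selection rejects junk columns and is reproducible", {
  ds <- generate_dataset(synth_config("toy"), seed = 4)
  base <- lek_model(ds$roster, solicitation = "none",
                    statistics = stat_catalog(character(0)),
                    response_effects = FALSE)
  junk <- stat_spec("disturb", "general", "recency", "attack_received")
  sel <- select_rem(ds$events, ds$roster, base, candidate_stats = junk)
  expect_equal(nrow(sel$model$statistics), 0)
  expect_equal(sel$trace$action[1], "base")

  # single candidate model comes back unchanged
  sel2 <- select_rem(ds$events, ds$roster, base)
  expect_equal(sel2$model$par_names, base$par_names)
  sel3 <- select_rem(ds$events, ds$roster, base)
  expect_identical(sel2$trace, sel3$trace)
})
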