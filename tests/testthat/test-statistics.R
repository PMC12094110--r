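test_that("recency is the reciprocal square root of elapsed seconds", {
  expect_equal(recency(9), 1 / 3)
  expect_equal(recency(1), 1)
  expect_equal(recency(400), 0.05)
  expect_error(recency(0), "positive")
  expect_error(recency(-3), "positive")
})

test_that("the catalog factory crosses patterns over scopes, windows, channels", {
  # win-loss record: 2 scopes x 3 count windows x 4 response channels = 24
  c24 <- stat_catalog("winloss", c("general", "pairwise"),
                      c("cumulative", "yesterday", "today"),
                      c("solicit", "interrupt", "attack_received",
                        "disengage"))
  expect_equal(nrow(c24), 24)
  expect_false(anyDuplicated(c24$name) > 0)

  one <- stat_spec("lose.chase", "general", "recency", "depart")
  expect_equal(one$name, "gen.lose.chase.rec.depart")

  expect_equal(nrow(stat_catalog(character(0))), 0)
  expect_error(stat_catalog("no.such.pattern"), "unknown pattern")
  expect_error(stat_spec("lose.chase", "pairwise", "recency", "depart"),
               "combination")

  # deterministic ordering and names across invocations
  a <- stat_catalog(c("att.win", "fem.pres"))
  b <- stat_catalog(c("att.win", "fem.pres"))
  expect_identical(a, b)
})

test_that("statistic evaluation matches the worked recency example", {
  r <- fixture_roster(n_named = 2, bulk = FALSE)
  cat_ <- rbind(stat_spec("fem.pres", "general", "now", "depart"),
                stat_spec("lose.chase", "general", "recency", "depart"))
  # empty history, females present: female-presence 1, history entries 0
  s0 <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
             list("female_enter", 1))
  u0 <- evaluate_statistics(s0, list(kind = "depart", sender = "m01",
                                     receiver = NA), cat_)
  expect_equal(unname(u0), c(1, 0))

  # m01 lost a chase 9 s before the evaluation point: recency = 1/3
  s1 <- play(r, list("attack", 100, "m02", "m01"),
             list("response_chase", 100, "m01", "m02"),
             list("disengage", 191, "m02", "m01"),
             list("clock", 200), state = s0)
  u1 <- evaluate_statistics(s1, list(kind = "depart", sender = "m01",
                                     receiver = NA), cat_)
  expect_equal(unname(u1[["gen.lose.chase.rec.depart"]]), 1 / 3)
})

test_that("pairwise win-loss tallies match a hand count", {
  r <- fixture_roster(n_named = 2, bulk = FALSE)
  # m01 beats m02 twice (as attacker), loses once today
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("attack", 10, "m01", "m02"),
            list("response_short_fight", 10, "m02", "m01"),
            list("disengage", 20, "m01", "m02"),
            list("attack", 30, "m01", "m02"),
            list("response_short_fight", 30, "m02", "m01"),
            list("disengage", 40, "m01", "m02"),
            list("attack", 50, "m01", "m02"),
            list("response_short_fight", 50, "m02", "m01"),
            list("disengage", 60, "m02", "m01"))
  cat_ <- rbind(
    stat_spec("wl.diff.abs", "pairwise", "today", "attack_received"),
    stat_spec("att.win", "pairwise", "today", "attack_initiated"))
  u <- evaluate_statistics(s, list(kind = "attack", sender = "m01",
                                   receiver = "m02"), cat_)
  # |(+2) + (-1)| = 1 from the receiver m02's perspective as well
  expect_equal(unname(u[["pair.wl.diff.abs.today.attacked"]]), 1)
  expect_equal(unname(u[["pair.att.win.today.attacker"]]), 2)
})

test_that("context gating: interruption and solicitation statistics", {
  r <- fixture_roster(n_named = 3, bulk = FALSE)
  cat_ <- rbind(stat_spec("copulating", "general", "now", "interrupt"),
                stat_spec("recv.lose", "pairwise", "today", "interrupt"),
                stat_spec("winloss", "general", "today", "solicit"))
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("arrive", 0, "m03"),
            # a fight m02 loses, with females ABSENT
            list("attack", 10, "m03", "m02"),
            list("response_short_fight", 10, "m02", "m03"),
            list("disengage", 30, "m03", "m02"),
            list("female_enter", 50))
  # m02 not copulating: all interrupt-channel entries are 0
  u <- evaluate_statistics(s, list(kind = "attack", sender = "m03",
                                   receiver = "m02"), cat_)
  expect_equal(unname(u[1:2]), c(0, 0))
  # solicitation statistics ignore the fight because females were absent
  u2 <- evaluate_statistics(s, list(kind = "solicit", sender = "m03",
                                    receiver = NA), cat_)
  expect_equal(unname(u2[["gen.winloss.today.solicit"]]), 0)

  # once m02 copulates the same entries switch on
  s2 <- play(r, list("solicit", 60, "m02"), state = s)
  u3 <- evaluate_statistics(s2, list(kind = "attack", sender = "m03",
                                     receiver = "m02"), cat_)
  expect_equal(unname(u3[["gen.copulating.interrupt"]]), 1)
  expect_equal(unname(u3[["pair.recv.lose.today.interrupt"]]), 1)
})

test_that("recency decays monotonically across clock ticks", {
  r <- fixture_roster(n_named = 2, bulk = FALSE)
  cat_ <- stat_spec("win.any", "general", "recency", "attack_initiated")
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("attack", 10, "m01", "m02"),
            list("response_face_off", 10, "m02", "m01"),
            list("disengage", 20, "m01", "m02"))
  vals <- numeric(0)
  for (tick in c(900, 1800, 2700)) {
    s <- apply_event(s, list(kind = "clock", time = tick))
    vals <- c(vals, unname(evaluate_statistics(
      s, list(kind = "attack", sender = "m01", receiver = "m02"), cat_)))
  }
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 1 / sqrt(880))
})

test_that("vectorised design rows equal per-candidate statistic evaluation", {
  # dual route: the attack-block vectorisation in the design builder against
  # the scalar evaluator, over a state with rich history
  r <- fixture_roster(n_named = 3, bulk = TRUE, territory = TRUE)
  model <- lek_model(r, solicitation = "single",
                     statistics = default_stat_catalog())
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("arrive", 0, "m03"), list("arrive", 0, "X"),
            list("female_enter", 100),
            list("attack", 110, "m01", "m02"),
            list("response_chase", 110, "m02", "m01"),
            list("disengage", 150, "m01", "m02"),
            list("attack", 160, "m02", "m03"),
            list("response_short_fight", 160, "m03", "m02"),
            list("disengage", 200, "m03", "m02"),
            list("solicit", 220, "m01"),
            list("clock", 900))
  des <- lekrem:::candidate_design(s, model)
  ss <- support_set(s)
  stat_names <- model$statistics$name
  idx <- match(stat_names, model$par_names)
  for (i in seq_along(ss$kind)) {
    u <- evaluate_statistics(s, list(kind = ss$kind[i],
                                     sender = ss$sender[i],
                                     receiver = ss$receiver[i]),
                             model$statistics)
    expect_equal(unname(des$X[i, idx]), unname(u),
                 tolerance = 1e-12,
                 label = paste("design row", ss$kind[i], i))
  }
})
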