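test_that("support set enforces presence, female and cycle constraints", {
  r <- fixture_roster(n_named = 3, bulk = FALSE)
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("arrive", 0, "m03"))

  # females absent: no solicitations anywhere in the support set
  expect_false("solicit" %in% support_set(s)$kind)

  # m01 and m02 in a short fight: they can neither attack, receive nor
  # depart; both may disengage; available m03 may still solicit
  s2 <- play(r, list("female_enter", 10),
             list("attack", 20, "m01", "m02"),
             list("response_short_fight", 20, "m02", "m01"),
             state = s)
  ss <- support_set(s2)
  atk <- ss[ss$kind == "attack", ]
  expect_equal(nrow(atk), 0)  # only m03 is free and has no free partner
  expect_setequal(ss$sender[ss$kind == "disengage"], c("m01", "m02"))
  expect_equal(ss$sender[ss$kind == "solicit"], "m03")
  expect_false("m01" %in% ss$sender[ss$kind == "depart"])
  expect_true("m03" %in% ss$sender[ss$kind == "depart"])

  # chase: only the attacker may disengage
  s3 <- play(r, list("attack", 30, "m01", "m02"),
             list("response_chase", 30, "m02", "m01"), state = s)
  dis <- support_set(s3)
  dis <- dis[dis$kind == "disengage", ]
  expect_equal(dis$sender, "m01")

  # pending response window: support is exactly the three response types
  s4 <- play(r, list("attack", 40, "m01", "m02"), state = s)
  ss4 <- support_set(s4)
  expect_equal(sort(ss4$kind),
               sort(c("response_face_off", "response_short_fight",
                      "response_chase")))
  expect_equal(unique(ss4$sender), "m02")
})

test_that("copulating males can be attacked (interruption) but do nothing else", {
  r <- fixture_roster(n_named = 3, bulk = FALSE)
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("arrive", 0, "m03"), list("female_enter", 5),
            list("solicit", 10, "m01"))
  ss <- support_set(s)
  expect_true(any(ss$kind == "attack" & ss$receiver == "m01"))
  expect_false(any(ss$kind == "attack" & ss$sender == "m01"))
  expect_false(any(ss$kind == "solicit" & ss$sender == "m01"))
  expect_false(any(ss$kind == "depart" & ss$sender == "m01"))
  expect_true(any(ss$kind == "copulation_end" & ss$sender == "m01"))

  # the interrupting attack closes the copulation and opens a fight window
  s2 <- apply_event(s, list(kind = "attack", time = 20, sender = "m03",
                            receiver = "m01"))
  expect_length(s2$cops$male, 0)
  expect_equal(s2$intp[3, "today", "all"], 1)
  expect_equal(support_set(s2)$kind[1], "response_face_off")
})

test_that("the bulk actor may hold several simultaneous fights", {
  r <- fixture_roster(n_named = 3, bulk = TRUE)
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("arrive", 0, "m03"), list("arrive", 0, "X"),
            list("attack", 10, "m01", "X"),
            list("response_short_fight", 10, "X", "m01"))
  ss <- support_set(s)
  # X engaged with m01 yet still attackable / able to attack
  expect_true(any(ss$kind == "attack" & ss$sender == "X"))
  expect_true(any(ss$kind == "attack" & ss$receiver == "X"))
  s2 <- play(r, list("attack", 20, "m02", "X"),
             list("response_face_off", 20, "X", "m02"), state = s)
  expect_length(s2$fights$attacker, 2)
  # but X cannot depart while engaged
  expect_false("X" %in%
                 support_set(s2)$sender[support_set(s2)$kind == "depart"])
})

test_that("disengagement records the winner and a chase marks the loser", {
  r <- fixture_roster(n_named = 2, bulk = FALSE)
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("attack", 10, "m01", "m02"),
            list("response_face_off", 10, "m02", "m01"),
            list("disengage", 40, "m02", "m01"))
  # receiver m02 disengaged first: receive+win for m02, attack+lose for m01
  expect_equal(s$pc[2, 1, "recv_win", "today", "all"], 1)
  expect_equal(s$pc[1, 2, "att_lose", "today", "all"], 1)
  expect_equal(s$last_win[2], 40)
  expect_true(is.na(s$last_lose_chase[1]))
  expect_length(s$fights$attacker, 0)

  # chase: receiver cannot disengage; attacker's disengage marks lose-chase
  s2 <- play(r, list("attack", 60, "m01", "m02"),
             list("response_chase", 60, "m02", "m01"), state = s)
  expect_error(apply_event(s2, list(kind = "disengage", time = 70,
                                    sender = "m02", receiver = "m01")),
               "support violation")
  s3 <- apply_event(s2, list(kind = "disengage", time = 70, sender = "m01",
                             receiver = "m02"))
  expect_equal(s3$last_lose_chase[2], 70)
  expect_equal(s3$pc[1, 2, "att_win", "today", "all"], 1)
})

test_that("disturbances flush the lek and day ends roll the windows", {
  r <- fixture_roster(n_named = 3, bulk = FALSE, n_days = 4)
  s <- play(r, list("arrive", 0, "m01"), list("arrive", 0, "m02"),
            list("attack", 10, "m01", "m02"),
            list("response_short_fight", 10, "m02", "m01"),
            list("disengage", 30, "m01", "m02"),
            list("attack", 50, "m01", "m02"),
            list("response_face_off", 50, "m02", "m01"))
  s2 <- apply_event(s, list(kind = "disturbance", time = 60))
  expect_length(s2$fights$attacker, 0)
  expect_false(any(s2$present))
  # the interrupted fight assigned no winner: totals still one win, one loss
  expect_equal(sum(s2$pc[, , c("att_win", "recv_win"), "today", "all"]), 1)
  expect_equal(sum(s2$pc[, , c("att_lose", "recv_lose"), "today", "all"]), 1)

  s3 <- apply_event(s2, list(kind = "day_end", time = 100))
  expect_equal(sum(s3$pc[, , , "today", "all"]), 0)
  expect_equal(s3$pc[1, 2, "att_win", "yesterday", "all"], 1)
  # consecutive next day keeps yesterday; a gapped day resets it to base
  s4 <- state_begin_day(s3, r, 2)
  expect_equal(s4$pc[1, 2, "att_win", "yesterday", "all"], 1)
  s5 <- state_begin_day(s3, r, 4)
  expect_equal(sum(s5$pc[, , , "yesterday", "all"]), 0)
})

test_that("validate_history passes clean histories and names violations", {
  r <- fixture_roster(n_named = 2, bulk = FALSE)
  rep <- validate_history(fixture_fight_history(), r)
  expect_true(rep$ok)
  expect_equal(unname(rep$counts["attack"]), 1L)

  bad <- events_df(list(ev("arrive", 0, "m01"), ev("arrive", 0, "m02"),
                        ev("solicit", 10, "m01"), ev("day_end", 3600)))
  rep2 <- validate_history(bad, r)
  expect_false(rep2$ok)
  expect_match(rep2$violations$message[1], "support")
})

test_that("simulated histories always satisfy the support constraints", {
  cfg <- synth_config("toy", n_days = 1)
  for (seed in c(1, 7, 23, 99)) {
    ds <- generate_dataset(cfg, seed = seed)
    expect_true(validate_history(ds$events, ds$roster)$ok)
  }
  # conservation: every opened cycle closes exactly once, one win, one loss
  ds <- generate_dataset(cfg, seed = 5)
  n_resp <- sum(ds$events$kind %in% c("response_face_off",
                                      "response_short_fight",
                                      "response_chase"))
  n_dis <- sum(ds$events$kind == "disengage")
  expect_equal(n_resp, n_dis)  # no disturbances in the toy preset
  fs <- ds$model  # final-state check through a replay
  st <- lek_state(ds$roster, day = 1)
  for (i in seq_len(nrow(ds$events)))
    st <- apply_event(st, list(kind = ds$events$kind[i],
                               time = ds$events$time_s[i],
                               day = ds$events$day[i],
                               sender = ds$events$sender[i],
                               receiver = ds$events$receiver[i]),
                      check = FALSE)
  expect_length(st$fights$attacker, 0)
})
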