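test_that("similarity counts intersecting dimensions against the profile", {
  prof <- base_profile(qualities = c("heavy", "tight"), locations = "chest_center",
    radiation = character(0), associated = character(0))
  now <- NOW

  ep <- symptom_episode(qualities = "heavy", locations = "chest_center",
    onset_at = hours_before(now, 1), now = now)
  r <- similarity(ep, prof)
  expect_setequal(r$matched_dimensions, c("quality", "location"))
  expect_true(r$is_similar)

  # all four sets disjoint
  ep2 <- symptom_episode(qualities = "sharp", locations = "back_lower",
    radiation = "neck", associated = "dizzy",
    onset_at = hours_before(now, 1), now = now)
  r2 <- similarity(ep2, prof)
  expect_length(r2$matched_dimensions, 0)
  expect_false(r2$is_similar)

  # identical to profile: all populated dimensions match
  prof_full <- base_profile()
  ep3 <- symptom_episode(
    qualities = prof_full$qualities, locations = prof_full$locations,
    radiation = prof_full$radiation, associated = prof_full$associated,
    onset_at = hours_before(now, 1), now = now
  )
  expect_setequal(similarity(ep3, prof_full)$matched_dimensions,
    c("quality", "location", "radiation", "associated"))
  expect_true(similarity(ep3, prof_full)$is_similar)

  # threshold is configurable
  expect_false(similarity(ep, prof, triage_config(similarity_min_dimensions = 3))$is_similar)
})

test_that("similarity agrees with a set-intersection oracle on random episodes", {
  prof <- base_profile()
  set.seed(401)
  for (i in 1:200) {
    ep <- rand_episode()
    n_match <- sum(
      length(intersect(ep$qualities, prof$qualities)) > 0,
      length(intersect(ep$locations, prof$locations)) > 0,
      length(intersect(ep$radiation, prof$radiation)) > 0,
      length(intersect(ep$associated, prof$associated)) > 0
    )
    r <- similarity(ep, prof)
    expect_identical(length(r$matched_dimensions), as.integer(n_match))
    expect_identical(r$is_similar, n_match >= 2)
  }
})

test_that("high-risk rule: >=3 new typical features or any new associated symptom", {
  now <- NOW
  prof <- base_profile(qualities = "sharp", locations = "chest_center",
    radiation = character(0), associated = character(0))
  ep <- symptom_episode(qualities = c("dull", "heavy", "tight"),
    locations = "back_lower", onset_at = hours_before(now, 1), now = now)
  r <- is_high_risk(ep, prof)
  expect_true(r$is_high_risk)
  expect_setequal(r$new_typical_features, c("dull", "heavy", "tight"))

  ep2 <- symptom_episode(associated = "palpitations",
    onset_at = hours_before(now, 1), now = now)
  r2 <- is_high_risk(ep2, prof)
  expect_true(r2$is_high_risk)
  expect_identical(r2$new_associated, "palpitations")

  # only 2 new typical features, nothing associated: not high risk
  ep3 <- symptom_episode(qualities = c("dull", "heavy"),
    locations = "back_lower", onset_at = hours_before(now, 1), now = now)
  expect_false(is_high_risk(ep3, prof)$is_high_risk)

  # "new" is relative to the profile: features already in the profile don't count
  prof2 <- base_profile(qualities = c("dull", "heavy", "tight"))
  ep4 <- symptom_episode(qualities = c("dull", "heavy", "tight"),
    locations = "back_lower", onset_at = hours_before(now, 1), now = now)
  expect_false(is_high_risk(ep4, prof2)$is_high_risk)
})

test_that("classification follows the red/yellow/green window rules", {
  prof <- base_profile(qualities = c("heavy", "tight"), locations = "chest_center",
    radiation = character(0), associated = character(0))
  now <- NOW
  qualifying_at <- function(h) {
    symptom_episode(qualities = "heavy", locations = "chest_center",
      onset_at = hours_before(now, h), now = now)
  }
  classify1 <- function(ep) {
    classify_heart_check(heart_check("u1", list(ep), asked_at = now), prof, now)
  }

  red <- classify1(qualifying_at(12))
  expect_identical(as.character(red$level), "red")
  expect_identical(red$recommendation, "notify_family_call_911")

  yellow <- classify1(qualifying_at(72))
  expect_identical(as.character(yellow$level), "yellow")
  expect_identical(yellow$recommendation, "primary_care_48h")

  empty <- classify_heart_check(heart_check("u1", list(), asked_at = now), prof, now)
  expect_identical(as.character(empty$level), "green")
  expect_identical(empty$recommendation, "continue_app_access")
  expect_identical(nrow(empty$rationale), 0L)

  # boundaries: red window closed at 24 h, yellow half-open (24, 168]
  expect_identical(as.character(classify1(qualifying_at(24))$level), "red")
  expect_identical(as.character(classify1(qualifying_at(24 + 1e-3))$level), "yellow")
  expect_identical(as.character(classify1(qualifying_at(168))$level), "yellow")
  # qualifying but older than 7 days: outside both categories, stays green
  old <- classify1(qualifying_at(200))
  expect_identical(as.character(old$level), "green")
  expect_identical(old$rationale$window, "expired")

  # non-qualifying recent episode stays green
  neutral <- symptom_episode(qualities = "sharp", locations = "back_lower",
    onset_at = hours_before(now, 2), now = now)
  expect_identical(as.character(classify1(neutral)$level), "green")

  # episode onset after `now` errors
  chk <- heart_check("u1", list(qualifying_at(12)), asked_at = now)
  expect_error(classify_heart_check(chk, prof, hours_before(now, 20)), "after")
})

test_that("adding episodes never lowers the triage level (monotonicity)", {
  prof <- base_profile()
  set.seed(402)
  for (i in 1:50) {
    eps <- lapply(seq_len(sample(1:4, 1)), function(j) rand_episode())
    extra <- rand_episode()
    lvl <- classify_heart_check(heart_check("u", eps, asked_at = NOW), prof, NOW)$level
    lvl2 <- classify_heart_check(heart_check("u", c(eps, list(extra)), asked_at = NOW),
      prof, NOW)$level
    expect_true(lvl2 >= lvl)
  }
})

test_that("unreachable similarity threshold and empty typical set neutralize triage", {
  prof <- base_profile(associated = c("dizzy", "faint"))
  cfg <- triage_config(similarity_min_dimensions = 5, high_risk_typical = character(0))
  set.seed(403)
  for (i in 1:50) {
    ep <- rand_episode()
    # keep the associated arm silent: only symptoms already in the profile
    ep$associated <- intersect(ep$associated, prof$associated)
    chk <- heart_check("u", list(ep), asked_at = NOW)
    expect_identical(
      as.character(classify_heart_check(chk, prof, NOW, cfg)$level),
      "green"
    )
  }
})

test_that("classification matches the independent brute-force oracle", {
  set.seed(404)
  for (i in 1:300) {
    prof <- base_profile(
      qualities = sample(VOCAB$qualities, sample(1:2, 1)),
      locations = sample(VOCAB$regions$code, sample(1:2, 1)),
      radiation = if (runif(1) < 0.5) sample(VOCAB$regions$code, 1) else character(0),
      associated = if (runif(1) < 0.7) sample(VOCAB$associated, 1) else character(0)
    )
    eps <- lapply(seq_len(sample(0:4, 1)), function(j) rand_episode())
    got <- classify_heart_check(heart_check("u", eps, asked_at = NOW), prof, NOW)
    expect_identical(as.character(got$level), oracle_classify(eps, prof, NOW))
  }
})

test_that("triage_config validates its window ordering", {
  expect_error(triage_config(red_window_hours = 200, yellow_window_hours = 168))
  expect_error(triage_config(similarity_min_dimensions = 0))
})
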