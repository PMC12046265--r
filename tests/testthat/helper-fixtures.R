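# Shared fixtures and independent mini-oracles for property tests.

VOCAB <- triage_vocab()
NOW <- "2020-11-30T00:00:00Z"

base_profile <- function(qualities = c("heavy", "tight"),
                         locations = "chest_center",
                         radiation = "jaw_left",
                         associated = "shortness_of_breath") {
  event_profile("u1",
    qualities = qualities, locations = locations,
    radiation = radiation, associated = associated,
    recorded_at = "2020-01-01T00:00:00Z"
  )
}

hours_before <- function(now, h) parse_utc(now) - h * 3600

# Random episode drawn from the full vocabulary; guaranteed non-empty
# (always carries at least one location).
rand_episode <- function(age_hours = stats::runif(1, 0, 400), now = NOW) {
  pick <- function(pool, max_n) {
    n <- sample(0:max_n, 1)
    if (n == 0) character(0) else sample(pool, n)
  }
  symptom_episode(
    qualities = pick(VOCAB$qualities, 3),
    locations = sample(VOCAB$regions$code, sample(1:2, 1)),
    radiation = pick(VOCAB$regions$code, 2),
    associated = pick(VOCAB$associated, 2),
    onset_at = hours_before(now, age_hours),
    now = now
  )
}

# Independent triage oracle: plain set operations per episode, then a
# max-severity reduction. Deliberately written without similarity()/
# is_high_risk()/classify_heart_check().
oracle_classify <- function(episodes, profile, now,
                            min_dims = 2, typical = c("dull", "heavy", "tight"),
                            red_h = 24, yellow_h = 168) {
  sev <- 0 # 0 green, 1 yellow, 2 red
  for (ep in episodes) {
    n_match <- sum(
      length(intersect(ep$qualities, profile$qualities)) > 0,
      length(intersect(ep$locations, profile$locations)) > 0,
      length(intersect(ep$radiation, profile$radiation)) > 0,
      length(intersect(ep$associated, profile$associated)) > 0
    )
    new_typ <- setdiff(intersect(ep$qualities, typical), profile$qualities)
    new_assoc <- setdiff(ep$associated, profile$associated)
    qualifies <- (n_match >= min_dims) ||
      (length(new_typ) >= 3) || (length(new_assoc) >= 1)
    if (!qualifies) next
    age <- as.numeric(difftime(parse_utc(now), ep$onset_at, units = "hours"))
    if (age <= red_h) sev <- max(sev, 2) else if (age <= yellow_h) sev <- max(sev, 1)
  }
  c("green", "yellow", "red")[sev + 1]
}

# Random wellness library over the 7 domains.
rand_library <- function(n_items = 8) {
  doms <- wellness_domains()
  library_index(data.frame(
    item_id = sprintf("it%03d", seq_len(n_items)),
    kind = sample(c("article", "lay_summary", "video", "podcast"), n_items, TRUE),
    domains = I(lapply(seq_len(n_items), function(i) sample(doms, sample(1:3, 1)))),
    title = sprintf("item %d", seq_len(n_items)),
    stringsAsFactors = FALSE
  ))
}

minimal_script <- function() {
  list(
    start = "greet",
    states = list(
      greet = list(prompts = list("hello"), transitions = list(default = "ask")),
      ask = list(
        prompts = list("ready?"),
        input = list(type = "yes_no"),
        transitions = list(yes = "done", no = "done")
      ),
      done = list(prompts = list("bye"), terminal = TRUE)
    )
  )
}

bundled_script_path <- function() {
  system.file("extdata", "scripts", "usability_scenarios.json",
    package = "hearttriage"
  )
}
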