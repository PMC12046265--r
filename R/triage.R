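#' Triage configuration
#'
#' Defaults reproduce the published rules: similarity on >= 2 of the 4
#' comparison dimensions (quality, location, radiation, associated); high-risk
#' typical features are dull/heavy/tight chest pain; red window 24 h; yellow
#' window 7 days (168 h). The similarity threshold is configurable because the
#' published rule names the four dimensions but not a matching cut-off.
#'
#' @param similarity_min_dimensions integer >= 1; number of dimensions that
#'   must intersect for an episode to count as "similar".
#' @param high_risk_typical character vector of quality codes counted as
#'   typical features for the high-risk rule.
#' @param red_window_hours,yellow_window_hours onset-age windows (hours);
#'   red must be strictly inside yellow.
#' @return object of class `triage_config`.
#' @export
triage_config <- function(similarity_min_dimensions = 2L,
                          high_risk_typical = c("dull", "heavy", "tight"),
                          red_window_hours = 24,
                          yellow_window_hours = 168) {
  similarity_min_dimensions <- as.integer(similarity_min_dimensions)
  stopifnot(
    length(similarity_min_dimensions) == 1, similarity_min_dimensions >= 1,
    is.numeric(red_window_hours), is.numeric(yellow_window_hours),
    red_window_hours > 0, red_window_hours < yellow_window_hours
  )
  structure(
    list(
      similarity_min_dimensions = similarity_min_dimensions,
      high_risk_typical = sort(unique(canonicalize_code(high_risk_typical))),
      red_window_hours = red_window_hours,
      yellow_window_hours = yellow_window_hours
    ),
    class = "triage_config"
  )
}

.dimensions <- c("qualities", "locations", "radiation", "associated")
.dimension_labels <- c(
  qualities = "quality", locations = "location",
  radiation = "radiation", associated = "associated"
)

#' Similarity of an episode to the stored Event Profile
#'
#' A dimension matches iff the episode's code set and the profile's code set
#' for that dimension have a non-empty intersection; the episode is similar
#' iff at least `similarity_min_dimensions` dimensions match.
#'
#' @param episode a [symptom_episode()].
#' @param profile an [event_profile()].
#' @param config a [triage_config()].
#' @return list of class `similarity_result` with `matched_dimensions`
#'   (subset of quality/location/radiation/associated) and `is_similar`.
#' @export
similarity <- function(episode, profile, config = triage_config()) {
  stopifnot(
    inherits(episode, "symptom_episode"), inherits(profile, "event_profile"),
    inherits(config, "triage_config")
  )
  matched <- vapply(
    .dimensions,
    function(d) length(intersect(episode[[d]], profile[[d]])) > 0,
    logical(1)
  )
  structure(
    list(
      matched_dimensions = unname(.dimension_labels[.dimensions[matched]]),
      is_similar = sum(matched) >= config$similarity_min_dimensions
    ),
    class = "similarity_result"
  )
}

#' High-risk symptom rule
#'
#' An episode carries high-risk symptoms iff it reports at least 3 *new*
#' typical features (dull, heavy or tight chest pain, by default) or *any* new
#' associated symptom. "New" means present in the episode and absent from the
#' corresponding Event Profile set; the comparison is always against the
#' stored profile, never against earlier Heart Checks.
#'
#' @inheritParams similarity
#' @return list of class `high_risk_result` with `new_typical_features`,
#'   `new_associated`, `is_high_risk`.
#' @export
is_high_risk <- function(episode, profile, config = triage_config()) {
  stopifnot(
    inherits(episode, "symptom_episode"), inherits(profile, "event_profile"),
    inherits(config, "triage_config")
  )
  new_typical <- setdiff(
    intersect(episode$qualities, config$high_risk_typical),
    profile$qualities
  )
  new_assoc <- setdiff(episode$associated, profile$associated)
  structure(
    list(
      new_typical_features = new_typical,
      new_associated = new_assoc,
      is_high_risk = length(new_typical) >= 3 || length(new_assoc) >= 1
    ),
    class = "high_risk_result"
  )
}

# Care recommendation is a pure function of the level.
recommendation_for_level <- function(level) {
  switch(level,
    red = "notify_family_call_911",
    yellow = "primary_care_48h",
    green = "continue_app_access",
    stop("unknown level: ", level, call. = FALSE)
  )
}

#' Classify a Heart Check into a red/yellow/green level of care
#'
#' An episode *qualifies* iff it is similar to the Event Profile or carries
#' high-risk symptoms. The check is **red** if any qualifying episode began
#' within the red window (age <= 24 h), else **yellow** if any qualifying
#' episode began beyond 24 h but within 7 days (24 h < age <= 168 h), else
#' **green** (no similar or high-risk symptoms in window). Multiple episodes
#' reduce by maximum severity -- safety first. Age is measured from episode
#' onset to `now`, the evaluation clock, because the rule concerns when
#' symptoms occurred, not when they were reported.
#'
#' @param check a [heart_check()].
#' @param profile the user's [event_profile()].
#' @param now evaluation clock (ISO-8601 UTC or `POSIXct`); must not precede
#'   any episode onset.
#' @param config a [triage_config()].
#' @return object of class `risk_category`: `level` (ordered factor
#'   green < yellow < red), `rationale` (data.frame of qualifying episodes with
#'   rule codes and windows), `recommendation` (care-action code).
#' @export
#' @examples
#' vocab <- triage_vocab()
#' prof <- event_profile("u1",
#'   qualities = c("heavy", "tight"),
#'   locations = "chest_center", recorded_at = "2020-01-01T00:00:00Z"
#' )
#' ep <- symptom_episode(
#'   qualities = "heavy", locations = "chest_center",
#'   onset_at = "2020-02-01T00:00:00Z"
#' )
#' chk <- heart_check("u1", list(ep), asked_at = "2020-02-01T06:00:00Z")
#' classify_heart_check(chk, prof, now = "2020-02-01T12:00:00Z")
classify_heart_check <- function(check, profile, now,
                                 config = triage_config()) {
  stopifnot(inherits(check, "heart_check"), inherits(profile, "event_profile"))
  now <- parse_utc(now)
  n <- length(check$episodes)
  rationale <- data.frame(
    episode = integer(0), rule = character(0), age_hours = numeric(0),
    window = character(0), stringsAsFactors = FALSE
  )
  level <- "green"
  for (i in seq_len(n)) {
    ep <- check$episodes[[i]]
    age <- episode_age_hours(ep, now) # errors if onset after now
    sim <- similarity(ep, profile, config)
    hr <- is_high_risk(ep, profile, config)
    if (!sim$is_similar && !hr$is_high_risk) next
    window <- if (age <= config$red_window_hours) {
      "red"
    } else if (age <= config$yellow_window_hours) {
      "yellow"
    } else {
      # qualifying but older than the yellow window: outside both category
      # definitions, so it cannot escalate the level (literal reading of the
      # published categories; flagged in the rationale for auditability)
      "expired"
    }
    rules <- c(
      if (sim$is_similar) "similar",
      if (hr$is_high_risk) "high_risk"
    )
    rationale <- rbind(rationale, data.frame(
      episode = i, rule = paste(rules, collapse = "+"),
      age_hours = age, window = window, stringsAsFactors = FALSE
    ))
    if (window == "red") {
      level <- "red"
    } else if (window == "yellow" && level != "red") {
      level <- "yellow"
    }
  }
  structure(
    list(
      level = factor(level, levels = c("green", "yellow", "red"), ordered = TRUE),
      rationale = rationale,
      recommendation = recommendation_for_level(level)
    ),
    class = "risk_category"
  )
}

#' @export
print.risk_category <- function(x, ...) {
  cat("Heart Check triage:", toupper(as.character(x$level)),
    "->", x$recommendation, "\n"
  )
  if (nrow(x$rationale) > 0) {
    cat("Qualifying episodes:\n")
    print(x$rationale, row.names = FALSE)
  } else {
    cat("No similar or high-risk symptoms.\n")
  }
  invisible(x)
}

#' @rdname as.list.event_profile
#' @export
as.list.risk_category <- function(x, ...) {
  list(
    level = as.character(x$level),
    recommendation = x$recommendation,
    rationale = x$rationale
  )
}
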