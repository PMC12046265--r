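#' Event Profile: the stored baseline description of the index cardiac event
#'
#' The Event Profile is captured once (at first sign-in) and records the
#' quality and body-map location of the cardiac pain or associated symptoms of
#' the user's last treated heart event. Every subsequent Heart Check is
#' compared against it. All codes are canonicalized and checked against the
#' closed vocabulary; the profile must describe *something* (at least one
#' location or one associated symptom).
#'
#' @param user_id opaque user identifier (non-empty string).
#' @param qualities,locations,radiation,associated character vectors of codes
#'   (quality, body-region, body-region, associated-symptom respectively).
#' @param recorded_at ISO-8601 UTC timestamp or `POSIXct`.
#' @param vocab a [triage_vocab()].
#' @param now session clock used to reject future-dated records (defaults to
#'   `recorded_at`, i.e. no check, since replay of historical logs is routine).
#' @return object of class `event_profile`.
#' @export
#' @examples
#' event_profile("u1",
#'   qualities = c("heavy", "tight"), locations = "chest_center",
#'   recorded_at = "2020-03-31T10:00:00Z"
#' )
event_profile <- function(user_id, qualities = character(), locations = character(),
                          radiation = character(), associated = character(),
                          recorded_at, vocab = triage_vocab(), now = recorded_at) {
  stopifnot(is.character(user_id), length(user_id) == 1, nzchar(user_id))
  sets <- validate_symptom_sets(qualities, locations, radiation, associated, vocab)
  if (length(sets$locations) == 0 && length(sets$associated) == 0) {
    stop("empty profile: at least one location or associated symptom required",
      call. = FALSE
    )
  }
  recorded_at <- parse_utc(recorded_at)
  if (recorded_at > parse_utc(now)) {
    stop("recorded_at is in the future relative to the session clock", call. = FALSE)
  }
  structure(
    c(list(user_id = user_id), sets, list(recorded_at = recorded_at)),
    class = "event_profile"
  )
}

# Shared canonicalization of the four symptom dimensions.
validate_symptom_sets <- function(qualities, locations, radiation, associated, vocab) {
  stopifnot(inherits(vocab, "triage_vocab"))
  list(
    qualities = check_codes(qualities, vocab$qualities, "quality"),
    locations = check_codes(locations, vocab$regions$code, "body-region"),
    radiation = check_codes(radiation, vocab$regions$code, "body-region"),
    associated = check_codes(associated, vocab$associated, "associated-symptom")
  )
}

#' Validate a raw Event Profile record
#'
#' Accepts a structured record as parsed from a session log (a named list with
#' optional `user_id`, `qualities`, `locations`, `radiation`, `associated`,
#' `recorded_at`) and returns a validated [event_profile()]. Unknown codes and
#' empty profiles are errors naming the offending code.
#'
#' @param raw named list (typically `jsonlite::fromJSON` output).
#' @inheritParams event_profile
#' @return `event_profile`.
#' @export
validate_event_profile <- function(raw, vocab = triage_vocab(), now = NULL) {
  stopifnot(is.list(raw))
  if (is.null(raw$recorded_at)) stop("profile record lacks recorded_at", call. = FALSE)
  event_profile(
    user_id = if (!is.null(raw$user_id)) as.character(raw$user_id) else "anonymous",
    qualities = raw$qualities, locations = raw$locations,
    radiation = raw$radiation, associated = raw$associated,
    recorded_at = raw$recorded_at, vocab = vocab,
    now = if (is.null(now)) raw$recorded_at else now
  )
}

#' Symptom episode: one current pain/discomfort report
#'
#' The unit compared against the Event Profile. At least one of the four
#' symptom dimensions must be non-empty and the onset cannot postdate the
#' evaluation clock.
#'
#' @inheritParams event_profile
#' @param onset_at ISO-8601 UTC onset timestamp.
#' @param now evaluation clock (defaults to `onset_at`).
#' @return object of class `symptom_episode`.
#' @export
symptom_episode <- function(qualities = character(), locations = character(),
                            radiation = character(), associated = character(),
                            onset_at, vocab = triage_vocab(), now = onset_at) {
  sets <- validate_symptom_sets(qualities, locations, radiation, associated, vocab)
  if (all(lengths(sets) == 0)) {
    stop("empty episode: all four symptom sets are empty", call. = FALSE)
  }
  onset_at <- parse_utc(onset_at)
  if (onset_at > parse_utc(now)) {
    stop("episode onset is in the future relative to the evaluation clock",
      call. = FALSE
    )
  }
  structure(c(sets, list(onset_at = onset_at)), class = "symptom_episode")
}

#' Age of an episode in hours
#'
#' `now - onset_at`, exact to the second, expressed in hours. Supports the
#' 24-hour (red) and 7-day (yellow) triage windows.
#'
#' @param episode a [symptom_episode()].
#' @param now evaluation clock.
#' @return nonnegative numeric hours.
#' @export
episode_age_hours <- function(episode, now) {
  stopifnot(inherits(episode, "symptom_episode"))
  age <- hours_between(episode$onset_at, now)
  if (age < 0) stop("episode onset is after `now`", call. = FALSE)
  age
}

#' Heart Check: a batch of episodes reported at one chatbot check-in
#'
#' Episodes are sorted by onset (ascending) on construction; an empty episode
#' list is a valid Heart Check (it classifies green).
#'
#' @param user_id opaque identifier.
#' @param episodes list of [symptom_episode()] (possibly empty).
#' @param asked_at when the chatbot administered the check; must not precede
#'   any episode onset.
#' @return object of class `heart_check`.
#' @export
heart_check <- function(user_id, episodes = list(), asked_at) {
  stopifnot(is.character(user_id), length(user_id) == 1, is.list(episodes))
  ok <- vapply(episodes, inherits, logical(1), what = "symptom_episode")
  if (length(episodes) > 0 && !all(ok)) {
    stop("episodes must all be symptom_episode objects", call. = FALSE)
  }
  asked_at <- parse_utc(asked_at)
  if (length(episodes) > 0) {
    onsets <- do.call(c, lapply(episodes, `[[`, "onset_at"))
    if (any(onsets > asked_at)) {
      stop("asked_at precedes an episode onset", call. = FALSE)
    }
    episodes <- episodes[order(onsets)]
  }
  structure(
    list(user_id = user_id, episodes = episodes, asked_at = asked_at),
    class = "heart_check"
  )
}

# --- serialization -----------------------------------------------------------

#' Serialize validated records to plain lists (JSON-ready)
#'
#' Canonical form: codes sorted, timestamps formatted ISO-8601 UTC. Round-trips
#' through [validate_event_profile()] / the constructors are the identity.
#'
#' @param x validated object.
#' @param ... unused.
#' @return named list of atomic fields.
#' @export
as.list.event_profile <- function(x, ...) {
  list(
    user_id = x$user_id, qualities = x$qualities, locations = x$locations,
    radiation = x$radiation, associated = x$associated,
    recorded_at = format_utc(x$recorded_at)
  )
}

#' @rdname as.list.event_profile
#' @export
as.list.symptom_episode <- function(x, ...) {
  list(
    qualities = x$qualities, locations = x$locations,
    radiation = x$radiation, associated = x$associated,
    onset_at = format_utc(x$onset_at)
  )
}

#' @rdname as.list.event_profile
#' @export
as.list.heart_check <- function(x, ...) {
  list(
    user_id = x$user_id,
    episodes = lapply(x$episodes, as.list),
    asked_at = format_utc(x$asked_at)
  )
}

#' @export
print.event_profile <- function(x, ...) {
  cat("Event Profile for", x$user_id, "recorded", format_utc(x$recorded_at), "\n")
  for (d in c("qualities", "locations", "radiation", "associated")) {
    cat(sprintf("  %-11s %s\n", paste0(d, ":"), paste(x[[d]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.symptom_episode <- function(x, ...) {
  cat("Symptom episode, onset", format_utc(x$onset_at), "\n")
  for (d in c("qualities", "locations", "radiation", "associated")) {
    if (length(x[[d]])) {
      cat(sprintf("  %-11s %s\n", paste0(d, ":"), paste(x[[d]], collapse = ", ")))
    }
  }
  invisible(x)
}
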