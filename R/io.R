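#' Read a user session log
#'
#' A session log is one JSON object per user with keys `event_profile`,
#' `heart_checks` (array of `{user_id, episodes, asked_at}`) and
#' `wellness_checks` (array of `{user_id, scores, asked_at}`). Every record is
#' validated against the closed vocabulary on load.
#'
#' @param path JSON file path.
#' @param vocab a [triage_vocab()].
#' @return list with validated `profile`, `heart_checks`, `wellness_checks`.
#' @export
read_session <- function(path, vocab = triage_vocab()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$event_profile)) stop("session log lacks event_profile", call. = FALSE)
  profile <- validate_event_profile(raw$event_profile, vocab = vocab)
  checks <- lapply(raw$heart_checks, function(hc) {
    episodes <- lapply(hc$episodes, function(ep) {
      symptom_episode(
        qualities = unlist(ep$qualities), locations = unlist(ep$locations),
        radiation = unlist(ep$radiation), associated = unlist(ep$associated),
        onset_at = ep$onset_at, vocab = vocab, now = hc$asked_at
      )
    })
    heart_check(
      user_id = if (!is.null(hc$user_id)) hc$user_id else profile$user_id,
      episodes = episodes, asked_at = hc$asked_at
    )
  })
  wellness <- lapply(raw$wellness_checks, function(wc) {
    wellness_check(
      user_id = if (!is.null(wc$user_id)) wc$user_id else profile$user_id,
      scores = unlist(wc$scores), asked_at = wc$asked_at
    )
  })
  list(profile = profile, heart_checks = checks, wellness_checks = wellness)
}

#' Write a user session log
#'
#' Inverse of [read_session()]: serializes validated records back to the JSON
#' session schema in canonical form (sorted codes, ISO-8601 UTC timestamps),
#' so read -> write -> read is the identity.
#'
#' @param profile an [event_profile()].
#' @param heart_checks list of [heart_check()].
#' @param wellness_checks list of [wellness_check()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_session <- function(profile, heart_checks = list(),
                          wellness_checks = list(), path) {
  obj <- list(
    event_profile = as.list(profile),
    heart_checks = lapply(heart_checks, as.list),
    wellness_checks = lapply(wellness_checks, as.list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One session-log JSON per user (`<user_id>.json`), a SUS response table
#' (`sus.csv`, columns `user`, `q1..q10`, `adjective`, `score`) and a cohort
#' manifest (`manifest.json` with the config and the per-episode ground-truth
#' labels).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  now <- attr(cohort, "now")
  for (user in cohort) {
    hc <- list(user_heart_check(user, now = now))
    write_session(
      user$profile, hc, user$wellness_series,
      path = file.path(dir, paste0(user$profile$user_id, ".json"))
    )
  }
  sus <- do.call(rbind, lapply(cohort, function(u) {
    data.frame(
      user = u$profile$user_id,
      t(stats::setNames(u$sus$items, paste0("q", 1:10))),
      adjective = if (is.null(u$sus$adjective)) NA_integer_ else u$sus$adjective,
      score = sus_score(u$sus)
    )
  }))
  utils::write.csv(sus, file.path(dir, "sus.csv"), row.names = FALSE)
  cfg <- attr(cohort, "config")
  jsonlite::write_json(
    list(
      config = unclass(cfg), now = format_utc(now),
      ground_truth = attr(cohort, "ground_truth")
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
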