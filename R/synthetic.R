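#' Synthetic cohort configuration
#'
#' The generator emulates the kind of cohort the usability study worked with:
#' 10 women with a stored Event Profile, a recurrent stream of symptom
#' episodes, weekly wellness trajectories and one SUS response each. Episode
#' arrivals follow a homogeneous Poisson process; whether an episode resembles
#' the profile or carries high-risk symptoms is injected *by construction*
#' (copying profile dimensions / adding a new associated symptom), so every
#' episode has a ground-truth label and exact triage outcomes are known.
#'
#' @param n_users positive integer (default 10, the usability sample size).
#' @param seed integer master seed; all randomness derives from it.
#' @param episode_rate_per_week expected episodes per user-week (default 1).
#' @param p_similar probability an episode is made similar to the profile by
#'   copying >= 2 of its dimensions (default 0.25).
#' @param p_high_risk probability an episode is given a new associated symptom
#'   (the high-risk rule's second arm; default 0.1). Independent of
#'   `p_similar`; both may apply.
#' @param wellness_drift length-2 numeric `c(mean, sd)` of the per-week score
#'   change (default 0 and 1: stable wellness with week-to-week noise).
#' @param horizon_weeks simulated follow-up length (default 4).
#' @param sus_target_mean,sus_target_sd targets for the cohort's SUS scores
#'   (defaults 81.75 and 10.41, the published pooled summary).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 10, seed = 1, episode_rate_per_week = 1,
                          p_similar = 0.25, p_high_risk = 0.1,
                          wellness_drift = c(mean = 0, sd = 1),
                          horizon_weeks = 4,
                          sus_target_mean = 81.75, sus_target_sd = 10.41) {
  stopifnot(
    n_users >= 1, n_users == as.integer(n_users),
    length(seed) == 1, seed == as.integer(seed),
    episode_rate_per_week >= 0,
    p_similar >= 0, p_similar <= 1, p_high_risk >= 0, p_high_risk <= 1,
    length(wellness_drift) == 2, wellness_drift[2] >= 0,
    horizon_weeks >= 1, horizon_weeks == as.integer(horizon_weeks),
    sus_target_mean >= 0, sus_target_mean <= 100, sus_target_sd >= 0
  )
  structure(
    list(
      n_users = as.integer(n_users), seed = as.integer(seed),
      episode_rate_per_week = episode_rate_per_week,
      p_similar = p_similar, p_high_risk = p_high_risk,
      wellness_drift = stats::setNames(as.numeric(wellness_drift), c("mean", "sd")),
      horizon_weeks = as.integer(horizon_weeks),
      sus_target_mean = sus_target_mean, sus_target_sd = sus_target_sd
    ),
    class = "cohort_config"
  )
}

# Stable per-user substream seed: congruential mix of (seed, index) mod 2^31-1.
# Adding or removing users never perturbs another user's stream.
user_seed <- function(seed, i) {
  ((as.numeric(seed) %% 2147483647) * 131071 + as.numeric(i) * 524287) %% 2147483647
}

# Profile qualities are drawn from the typical descriptors and episode
# "neutral" qualities from the atypical ones, so a non-injected episode can
# never accidentally be similar or high-risk: its quality/location sets are
# disjoint from the profile and it adds no new typical feature or associated
# symptom. That is what makes p_similar = p_high_risk = 0 provably all-green.
.profile_qualities <- c("heavy", "tight", "pressure")
.neutral_qualities <- c("sharp", "burning")
.profile_locations <- c("chest_center", "chest_left", "chest_right")
.neutral_locations <- c("back_lower", "back_mid", "abdomen_upper", "neck")
.profile_radiation <- c("arm_left", "jaw_left", "shoulder_left")

#' Generate a synthetic cohort
#'
#' Deterministic given `config$seed`. Episode onsets are a homogeneous Poisson
#' process at `episode_rate_per_week` over `horizon_weeks`, ending at `now`.
#' Wellness scores follow a bounded integer random walk clipped to \[0, 10\],
#' one check per week. SUS responses come from [generate_sus_responses()] at
#' the configured targets.
#'
#' @param config a [cohort_config()].
#' @param now simulated "present" instant the horizon ends at (fixed default;
#'   the generator never reads the system clock).
#' @param vocab a [triage_vocab()].
#' @return list of class `synthetic_cohort`; each element is a
#'   `synthetic_user` with `$profile`, `$episodes`, `$wellness_series`,
#'   `$sus`. The attribute `"ground_truth"` is a data.frame with one row per
#'   episode (`user`, `episode`, `onset_at`, `age_hours`, `similar`,
#'   `high_risk`).
#' @export
generate_cohort <- function(config = cohort_config(),
                            now = "2020-11-30T00:00:00Z",
                            vocab = triage_vocab()) {
  stopifnot(inherits(config, "cohort_config"))
  now <- parse_utc(now)
  horizon_h <- config$horizon_weeks * 168
  start <- now - horizon_h * 3600
  users <- vector("list", config$n_users)
  truth <- list()

  for (i in seq_len(config$n_users)) {
    set.seed(user_seed(config$seed, i))
    uid <- sprintf("synth%03d", i)

    prof_q <- sample(.profile_qualities, sample(1:2, 1))
    prof_loc <- sample(.profile_locations, sample(1:2, 1))
    prof_rad <- if (stats::runif(1) < 0.5) sample(.profile_radiation, 1) else character(0)
    prof_assoc <- if (stats::runif(1) < 0.5) sample(vocab$associated, 1) else character(0)
    profile <- event_profile(
      user_id = uid, qualities = prof_q, locations = prof_loc,
      radiation = prof_rad, associated = prof_assoc,
      recorded_at = start - 30 * 86400, vocab = vocab, now = now
    )

    n_ep <- stats::rpois(1, config$episode_rate_per_week * config$horizon_weeks)
    onsets <- sort(start + stats::runif(n_ep) * horizon_h * 3600)
    episodes <- vector("list", n_ep)
    for (k in seq_len(n_ep)) {
      sim <- stats::runif(1) < config$p_similar
      hr <- stats::runif(1) < config$p_high_risk
      if (sim) {
        q <- sample(prof_q, max(1, length(prof_q) - 1))
        loc <- prof_loc
      } else {
        q <- sample(.neutral_qualities, 1)
        loc <- sample(setdiff(.neutral_locations, c(prof_loc, prof_rad)), 1)
      }
      assoc <- if (hr) sample(setdiff(vocab$associated, profile$associated), 1) else character(0)
      episodes[[k]] <- symptom_episode(
        qualities = q, locations = loc, radiation = character(0),
        associated = assoc, onset_at = onsets[k], vocab = vocab, now = now
      )
      truth[[length(truth) + 1]] <- data.frame(
        user = uid, episode = k, onset_at = format_utc(onsets[k]),
        age_hours = hours_between(onsets[k], now),
        similar = sim, high_risk = hr, stringsAsFactors = FALSE
      )
    }

    drift <- config$wellness_drift
    doms <- wellness_domains()
    scores <- sample(5:9, length(doms), replace = TRUE)
    wellness <- vector("list", config$horizon_weeks)
    for (w in seq_len(config$horizon_weeks)) {
      scores <- pmin(10, pmax(0, scores + round(stats::rnorm(length(doms), drift["mean"], drift["sd"]))))
      wellness[[w]] <- wellness_check(
        user_id = uid, scores = stats::setNames(scores, doms),
        asked_at = start + w * 168 * 3600
      )
    }

    users[[i]] <- structure(
      list(
        profile = profile, episodes = episodes,
        wellness_series = wellness, sus = NULL
      ),
      class = "synthetic_user"
    )
  }

  sus <- generate_sus_responses(
    n = config$n_users, target_mean = config$sus_target_mean,
    target_sd = config$sus_target_sd,
    seed = user_seed(config$seed, 0)
  )
  for (i in seq_len(config$n_users)) users[[i]]$sus <- sus[[i]]

  truth <- if (length(truth) > 0) {
    do.call(rbind, truth)
  } else {
    data.frame(
      user = character(0), episode = integer(0), onset_at = character(0),
      age_hours = numeric(0), similar = logical(0), high_risk = logical(0)
    )
  }
  structure(users,
    class = "synthetic_cohort",
    ground_truth = truth, config = config, now = now
  )
}

#' Heart Check over a synthetic user's full episode stream
#'
#' Convenience for end-to-end triage tests: wraps all of a user's episodes
#' into a single [heart_check()] asked at the cohort's `now`.
#'
#' @param user a `synthetic_user` element of a [generate_cohort()] result.
#' @param now evaluation clock (defaults to the cohort horizon end used by the
#'   generator).
#' @return a [heart_check()].
#' @export
user_heart_check <- function(user, now = "2020-11-30T00:00:00Z") {
  stopifnot(inherits(user, "synthetic_user"))
  heart_check(user$profile$user_id, user$episodes, asked_at = now)
}

# Snap to the SUS score lattice (multiples of 2.5 in [0, 100]).
snap_sus <- function(x) {
  pmin(100, pmax(0, round(x / 2.5) * 2.5))
}

# Deterministic even distribution of T lattice units over the 10 items:
# slot k gets floor(T/10) (+1 for the first T mod 10 slots); odd items are
# then pts+1, even items 5-pts. sus_score() recovers the score exactly, and
# T = 20 (score 50) yields the all-neutral vector.
response_from_score <- function(score) {
  units <- round(score / 2.5)
  base <- units %/% 10
  rem <- units %% 10
  pts <- rep(base, 10) + c(rep(1, rem), rep(0, 10 - rem))
  items <- integer(10)
  items[seq(1, 9, 2)] <- pts[seq(1, 9, 2)] + 1
  items[seq(2, 10, 2)] <- 5 - pts[seq(2, 10, 2)]
  adjective <- findInterval(score, c(15, 30, 45, 60, 75, 90)) + 1
  sus_response(items, adjective = adjective)
}

#' Generate SUS responses hitting target summary statistics
#'
#' Draws scores from a normal at the targets, snaps them to the 2.5-point SUS
#' lattice, then deterministically repairs first the sample mean (single-
#' element nudges) and then the sample SD (mean-preserving spread or shrink of
#' the extreme pair), before expanding each score into a 10-item response
#' vector whose [sus_score()] equals it exactly. For n >= 10 the scored sample
#' mean and SD land within 2.5 of the targets.
#'
#' @param n number of responses (>= 1).
#' @param target_mean target sample mean in \[0, 100\].
#' @param target_sd target sample SD (>= 0); `sd > 0` with `n = 1` is
#'   infeasible and errors.
#' @param seed integer seed.
#' @return list of [sus_response()].
#' @export
#' @examples
#' r <- generate_sus_responses(10, 81.75, 10.41, seed = 42)
#' mean(vapply(r, sus_score, numeric(1)))
generate_sus_responses <- function(n, target_mean, target_sd, seed) {
  stopifnot(
    n >= 1, n == as.integer(n),
    target_mean >= 0, target_mean <= 100, target_sd >= 0
  )
  if (n == 1 && target_sd > 0) {
    stop("target sd > 0 is infeasible with n = 1", call. = FALSE)
  }
  set.seed(as.integer(seed %% 2147483647))
  scores <- if (target_sd == 0) {
    rep(snap_sus(target_mean), n)
  } else {
    snap_sus(stats::rnorm(n, target_mean, target_sd))
  }

  # mean repair: move one lattice step at a time toward the target sum
  target_units <- round(target_mean * n / 2.5)
  for (iter in seq_len(200)) {
    diff_units <- target_units - round(sum(scores) / 2.5)
    if (diff_units == 0) break
    if (diff_units > 0) {
      idx <- which(scores < 100)
      if (length(idx) == 0) break
      i <- idx[which.min(scores[idx])]
      scores[i] <- scores[i] + 2.5
    } else {
      idx <- which(scores > 0)
      if (length(idx) == 0) break
      i <- idx[which.max(scores[idx])]
      scores[i] <- scores[i] - 2.5
    }
  }

  # sd repair: symmetric moves of the extreme pair keep the mean fixed
  if (n >= 2 && target_sd > 0) {
    for (iter in seq_len(500)) {
      cur <- stats::sd(scores)
      if (abs(cur - target_sd) <= 1.25) break
      i <- which.min(scores)
      j <- which.max(scores)
      if (i == j) break
      if (cur < target_sd) {
        if (scores[i] < 2.5 || scores[j] > 97.5) break
        scores[i] <- scores[i] - 2.5
        scores[j] <- scores[j] + 2.5
      } else {
        if (scores[j] - scores[i] < 5) break
        scores[i] <- scores[i] + 2.5
        scores[j] <- scores[j] - 2.5
      }
    }
  }

  lapply(scores, response_from_score)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  gt <- attr(x, "ground_truth")
  cat(
    "Synthetic cohort:", length(x), "users,", nrow(gt), "episodes",
    sprintf(
      "(%.0f%% similar, %.0f%% high-risk by construction)\n",
      100 * mean(gt$similar), 100 * mean(gt$high_risk)
    )
  )
  invisible(x)
}
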