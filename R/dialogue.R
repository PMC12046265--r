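#' Load and validate a dialogue script
#'
#' Scripts are declarative finite-state machines stored as JSON: a `states`
#' object mapping state ids to `{prompts, input, transitions, terminal}`, a
#' `start` state id, and optional `pacing` overrides. The loader enforces the
#' structural invariants a safe scripted chatbot needs:
#' * `start` exists and every transition target exists (no dangling edges);
#' * every non-terminal state is reachable from `start`;
#' * from every state some input sequence reaches a terminal state (liveness,
#'   checked by reverse graph search), so no conversation can dead-end.
#'
#' Input schemas: `none` (bot continues via the `default` transition),
#' `yes_no`, `choice` (with `options`), `integer` (with `min`/`max`),
#' `free_text`. `yes_no` and `choice` route by the normalized input; `integer`
#' and `free_text` route through `default`.
#'
#' @param script path to a JSON script file, or an equivalent named list.
#' @param start_state optional override of the script's start state.
#' @return object of class `dialogue_script`.
#' @export
load_script <- function(script, start_state = NULL) {
  if (is.character(script) && length(script) == 1) {
    script <- jsonlite::fromJSON(script, simplifyVector = FALSE)
  }
  stopifnot(is.list(script), !is.null(script$states))
  states <- script$states
  ids <- names(states)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("script states must have unique non-empty ids", call. = FALSE)
  }
  start <- if (!is.null(start_state)) start_state else script$start
  if (is.null(start)) stop("script has no start state", call. = FALSE)
  if (!start %in% ids) stop("missing start state: ", start, call. = FALSE)

  terminal <- vapply(states, function(s) isTRUE(s$terminal), logical(1))
  if (!any(terminal)) stop("script has no terminal state", call. = FALSE)

  edges <- lapply(states, function(s) {
    unlist(s$transitions, use.names = FALSE)
  })
  for (id in ids) {
    s <- states[[id]]
    if (terminal[[id]]) {
      if (length(edges[[id]]) > 0) {
        stop("terminal state '", id, "' has transitions", call. = FALSE)
      }
      next
    }
    if (length(edges[[id]]) == 0) {
      stop("non-terminal state '", id, "' has no transitions", call. = FALSE)
    }
    dangling <- setdiff(edges[[id]], ids)
    if (length(dangling) > 0) {
      stop("dangling transition in state '", id, "' to: ",
        paste(dangling, collapse = ", "),
        call. = FALSE
      )
    }
    type <- input_type(s)
    if (!type %in% c("none", "yes_no", "choice", "integer", "free_text")) {
      stop("state '", id, "' has unknown input type '", type, "'", call. = FALSE)
    }
    keys <- names(s$transitions)
    if (type %in% c("none", "integer", "free_text") && !"default" %in% keys) {
      stop("state '", id, "' (", type, " input) needs a 'default' transition",
        call. = FALSE
      )
    }
    if (type == "yes_no" && !all(c("yes", "no") %in% keys)) {
      stop("state '", id, "' (yes_no input) needs 'yes' and 'no' transitions",
        call. = FALSE
      )
    }
    if (type == "choice") {
      opts <- unlist(s$input$options)
      if (length(opts) == 0) stop("state '", id, "' choice input has no options", call. = FALSE)
      if (!all(opts %in% keys)) {
        stop("state '", id, "' lacks transitions for options: ",
          paste(setdiff(opts, keys), collapse = ", "),
          call. = FALSE
        )
      }
    }
  }

  reach <- graph_reachable(ids, edges, from = start)
  unreachable <- setdiff(ids[!terminal], reach)
  if (length(unreachable) > 0) {
    stop("unreachable state(s): ", paste(unreachable, collapse = ", "), call. = FALSE)
  }
  # liveness: reverse-BFS from terminals must cover every reachable state
  redges <- reverse_edges(ids, edges)
  co_reach <- graph_reachable(ids, redges, from = ids[terminal])
  stuck <- setdiff(reach, co_reach)
  if (length(stuck) > 0) {
    stop("no terminal reachable from state(s): ", paste(stuck, collapse = ", "),
      call. = FALSE
    )
  }

  pacing <- dialogue_pacing(
    base_delay_ms = script$pacing$base_delay_ms,
    per_char_delay_ms = script$pacing$per_char_delay_ms
  )
  structure(
    list(
      name = if (!is.null(script$name)) script$name else "script",
      states = states, start = start,
      terminal_states = ids[terminal], pacing = pacing
    ),
    class = "dialogue_script"
  )
}

input_type <- function(state) {
  if (is.null(state$input) || is.null(state$input$type)) "none" else state$input$type
}

graph_reachable <- function(ids, edges, from) {
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  queue <- intersect(from, ids)
  seen[queue] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in unique(edges[[v]])) {
      if (!seen[[w]]) {
        seen[[w]] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  ids[seen]
}

reverse_edges <- function(ids, edges) {
  r <- stats::setNames(vector("list", length(ids)), ids)
  for (v in ids) {
    for (w in unique(edges[[v]])) r[[w]] <- c(r[[w]], v)
  }
  lapply(r, function(x) if (is.null(x)) character(0) else x)
}

#' Message pacing parameters
#'
#' Each bot message carries a delivery delay
#' `base_delay_ms + per_char_delay_ms * nchar(message)` so longer prompts stay
#' on screen longer -- the chat-speed adjustment that usability testing on
#' mobile devices asked for. Delays are transcript metadata; nothing ever
#' sleeps, so replays and tests are instant.
#'
#' @param base_delay_ms,per_char_delay_ms nonnegative milliseconds; defaults
#'   600 and 35 (roughly reading speed for short health prompts).
#' @return list of class `dialogue_pacing`.
#' @export
dialogue_pacing <- function(base_delay_ms = 600, per_char_delay_ms = 35) {
  if (is.null(base_delay_ms)) base_delay_ms <- 600
  if (is.null(per_char_delay_ms)) per_char_delay_ms <- 35
  stopifnot(base_delay_ms >= 0, per_char_delay_ms >= 0)
  structure(
    list(base_delay_ms = base_delay_ms, per_char_delay_ms = per_char_delay_ms),
    class = "dialogue_pacing"
  )
}

message_delay_ms <- function(msg, pacing) {
  pacing$base_delay_ms + pacing$per_char_delay_ms * nchar(msg)
}

new_transcript <- function() {
  data.frame(
    timestamp = as.POSIXct(character(0), tz = "UTC"),
    speaker = character(0), message = character(0), delay_ms = numeric(0),
    stringsAsFactors = FALSE
  )
}

# Emit the prompts of `state_id`, then auto-advance through `none`-input
# states. Returns updated session.
emit_state <- function(script, session, state_id, now) {
  repeat {
    state <- script$states[[state_id]]
    session$current_state <- state_id
    t <- now
    for (msg in unlist(state$prompts)) {
      delay <- message_delay_ms(msg, script$pacing)
      t <- t + delay / 1000
      session$transcript <- rbind(session$transcript, data.frame(
        timestamp = t, speaker = "bot", message = msg, delay_ms = delay,
        stringsAsFactors = FALSE
      ))
    }
    session$clock <- t
    if (isTRUE(state$terminal)) {
      session$pending_activity <- "none"
      session$done <- TRUE
      return(session)
    }
    if (!is.null(state$activity)) session$pending_activity <- state$activity
    if (input_type(state) != "none") {
      return(session)
    }
    state_id <- state$transitions$default
    now <- session$clock
  }
}

#' Start a dialogue session
#'
#' Emits the start state's prompts (auto-advancing through `none`-input
#' states) against an injected simulated clock; no operation in the dialogue
#' engine ever reads the system clock.
#'
#' @param script a [load_script()] result.
#' @param now simulated clock at session start.
#' @return object of class `dialogue_session` with `current_state`,
#'   `transcript` (timestamp/speaker/message/delay_ms), `pending_activity`,
#'   `clock`, `done`.
#' @export
dialogue_session <- function(script, now) {
  stopifnot(inherits(script, "dialogue_script"))
  session <- structure(
    list(
      current_state = script$start, transcript = new_transcript(),
      pending_activity = "none", clock = parse_utc(now), done = FALSE
    ),
    class = "dialogue_session"
  )
  emit_state(script, session, script$start, parse_utc(now))
}

# Normalize + validate user input against a state's schema.
# Returns list(ok, key) where key indexes the transition table.
match_input <- function(state, user_input) {
  type <- input_type(state)
  raw <- trimws(tolower(as.character(user_input)))
  if (type == "yes_no") {
    if (raw %in% c("yes", "y")) return(list(ok = TRUE, key = "yes"))
    if (raw %in% c("no", "n")) return(list(ok = TRUE, key = "no"))
    return(list(ok = FALSE))
  }
  if (type == "choice") {
    opts <- unlist(state$input$options)
    if (raw %in% tolower(opts)) {
      return(list(ok = TRUE, key = opts[match(raw, tolower(opts))]))
    }
    return(list(ok = FALSE))
  }
  if (type == "integer") {
    if (!grepl("^-?\\d+$", raw)) return(list(ok = FALSE))
    v <- as.integer(raw)
    lo <- if (!is.null(state$input$min)) state$input$min else -Inf
    hi <- if (!is.null(state$input$max)) state$input$max else Inf
    if (v < lo || v > hi) return(list(ok = FALSE))
    return(list(ok = TRUE, key = "default"))
  }
  if (type == "free_text") {
    if (!nzchar(raw)) return(list(ok = FALSE))
    return(list(ok = TRUE, key = "default"))
  }
  stop("state does not accept input", call. = FALSE)
}

#' Advance a dialogue session by one user input
#'
#' Deterministic: valid input follows the state's transition rule and emits
#' the next state's prompts (with pacing delays); input failing the schema
#' re-prompts without a state change. Stepping a finished session is an error.
#'
#' @param script a [load_script()] result.
#' @param session a [dialogue_session()].
#' @param user_input a single message (character scalar).
#' @param now simulated clock for this turn; must not run backwards.
#' @return updated `dialogue_session`.
#' @export
step <- function(script, session, user_input, now) {
  stopifnot(
    inherits(script, "dialogue_script"),
    inherits(session, "dialogue_session")
  )
  if (isTRUE(session$done)) {
    stop("cannot step a session in a terminal state", call. = FALSE)
  }
  now <- parse_utc(now)
  if (now < session$clock) now <- session$clock
  state <- script$states[[session$current_state]]
  session$transcript <- rbind(session$transcript, data.frame(
    timestamp = now, speaker = "user", message = as.character(user_input),
    delay_ms = 0, stringsAsFactors = FALSE
  ))
  session$clock <- now
  m <- match_input(state, user_input)
  if (!m$ok) {
    reprompt <- if (!is.null(state$reprompt)) {
      state$reprompt
    } else {
      "Sorry, I didn't catch that."
    }
    t <- now
    for (msg in c(reprompt, unlist(state$prompts))) {
      delay <- message_delay_ms(msg, script$pacing)
      t <- t + delay / 1000
      session$transcript <- rbind(session$transcript, data.frame(
        timestamp = t, speaker = "bot", message = msg, delay_ms = delay,
        stringsAsFactors = FALSE
      ))
    }
    session$clock <- t
    return(session)
  }
  emit_state(script, session, state$transitions[[m$key]], now)
}

#' Replay a full scripted conversation
#'
#' Feeds `inputs` to the session in order against a simulated clock that
#' advances by each message's pacing delay plus a fixed per-turn think time.
#' Identical script + inputs + start time always produce a byte-identical
#' transcript.
#'
#' @param script a [load_script()] result.
#' @param inputs character vector of user messages.
#' @param start_at simulated session start time.
#' @param think_seconds simulated user response latency per turn (default 5).
#' @return the final `dialogue_session` (its `$transcript` is the full log).
#' @export
run_dialogue <- function(script, inputs, start_at = "2020-03-31T10:00:00Z",
                         think_seconds = 5) {
  session <- dialogue_session(script, start_at)
  for (inp in inputs) {
    if (isTRUE(session$done)) break
    session <- step(script, session, inp, session$clock + think_seconds)
  }
  session
}

#' Serialize a transcript as JSON lines
#'
#' One JSON object per line: `timestamp`, `speaker`, `message`, `delay_ms`.
#'
#' @param session a `dialogue_session`.
#' @param path optional file path; if `NULL` the lines are returned.
#' @return character vector of JSON lines, invisibly when written to `path`.
#' @export
transcript_jsonl <- function(session, path = NULL) {
  tr <- session$transcript
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    jsonlite::toJSON(
      list(
        timestamp = format_utc(tr$timestamp[i]), speaker = tr$speaker[i],
        message = tr$message[i], delay_ms = tr$delay_ms[i]
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# --- check-in scheduler ------------------------------------------------------

#' Check-in schedule state
#'
#' Default cadence reproduces the deployed behaviour: a Heart Check every 3
#' days (72 h) and a Wellness Check every 7 days (168 h) at a minimum.
#'
#' @param last_heart_check_at,last_wellness_check_at timestamp of the last
#'   completed check, or `NULL` if never done.
#' @param heart_check_interval_hours,wellness_interval_hours positive hours.
#' @return object of class `schedule_state`.
#' @export
schedule_state <- function(last_heart_check_at = NULL,
                           last_wellness_check_at = NULL,
                           heart_check_interval_hours = 72,
                           wellness_interval_hours = 168) {
  stopifnot(heart_check_interval_hours > 0, wellness_interval_hours > 0)
  structure(
    list(
      last_heart_check_at =
        if (is.null(last_heart_check_at)) NULL else parse_utc(last_heart_check_at),
      last_wellness_check_at =
        if (is.null(last_wellness_check_at)) NULL else parse_utc(last_wellness_check_at),
      heart_check_interval_hours = heart_check_interval_hours,
      wellness_interval_hours = wellness_interval_hours
    ),
    class = "schedule_state"
  )
}

#' Which check-ins are due now?
#'
#' A Heart Check is due iff it has never been done, the interval (72 h by
#' default) has fully elapsed, or the user asks for one on demand -- asking the
#' chatbot always works, at any time. A Wellness Check is due iff never done
#' or its 168 h interval has elapsed. Pure function of its arguments:
#' re-evaluating at the same `now` gives the same answer.
#'
#' @param schedule a [schedule_state()].
#' @param now evaluation clock.
#' @param on_demand `NULL` or `"heart_check"` (user-initiated request).
#' @return character vector, subset of `c("heart_check", "wellness_check")`.
#' @export
next_due <- function(schedule, now, on_demand = NULL) {
  stopifnot(inherits(schedule, "schedule_state"))
  if (!is.null(on_demand) && !identical(on_demand, "heart_check")) {
    stop("on_demand must be NULL or 'heart_check'", call. = FALSE)
  }
  now <- parse_utc(now)
  due <- character(0)
  hc_elapsed <- is.null(schedule$last_heart_check_at) ||
    hours_between(schedule$last_heart_check_at, now) >=
      schedule$heart_check_interval_hours
  if (hc_elapsed || identical(on_demand, "heart_check")) {
    due <- c(due, "heart_check")
  }
  wc_elapsed <- is.null(schedule$last_wellness_check_at) ||
    hours_between(schedule$last_wellness_check_at, now) >=
      schedule$wellness_interval_hours
  if (wc_elapsed) due <- c(due, "wellness_check")
  due
}
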