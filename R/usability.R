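#' System Usability Scale response
#'
#' Ten Likert items, each 1 (strongly disagree) to 5 (strongly agree), plus an
#' optional 7-point adjective anchor (1 = worst imaginable ... 7 = best
#' imaginable) rating overall user-friendliness.
#'
#' @param items integer vector of exactly 10 values in 1-5.
#' @param adjective optional integer in 1-7.
#' @return object of class `sus_response`.
#' @export
sus_response <- function(items, adjective = NULL) {
  items <- as.numeric(items)
  if (length(items) != 10 || any(is.na(items))) {
    stop("a SUS response has exactly 10 items", call. = FALSE)
  }
  if (any(items != as.integer(items)) || any(items < 1) || any(items > 5)) {
    stop("SUS items must be integers in [1, 5]", call. = FALSE)
  }
  if (!is.null(adjective)) {
    if (length(adjective) != 1 || is.na(adjective) ||
      adjective != as.integer(adjective) || adjective < 1 || adjective > 7) {
      stop("adjective anchor must be an integer in [1, 7]", call. = FALSE)
    }
    adjective <- as.integer(adjective)
  }
  structure(
    list(items = as.integer(items), adjective = adjective),
    class = "sus_response"
  )
}

#' Score a SUS response on the 0-100 scale
#'
#' Standard instrument scoring: odd (positively worded) items contribute
#' `item - 1`, even (negatively worded) items contribute `5 - item`; the sum
#' of contributions (0-40) is multiplied by 2.5, so scores live on a lattice
#' of multiples of 2.5 in \[0, 100\].
#'
#' @param response a [sus_response()] or a bare vector of 10 items in 1-5.
#' @return numeric score in \[0, 100\].
#' @export
#' @examples
#' sus_score(rep(3, 10)) # neutral midpoint: 50
sus_score <- function(response) {
  if (!inherits(response, "sus_response")) response <- sus_response(response)
  items <- response$items
  odd <- items[seq(1, 9, by = 2)]
  even <- items[seq(2, 10, by = 2)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

.adjectives <- c(
  "worst imaginable", "awful", "poor", "ok", "good", "excellent",
  "best imaginable"
)

#' Adjective anchor scale: value to label and back
#'
#' A bijection between the numeric anchors 1-7 and the adjective labels
#' "worst imaginable", "awful", "poor", "ok", "good", "excellent",
#' "best imaginable".
#'
#' @param value integer vector in 1-7.
#' @return character labels.
#' @export
adjective_label <- function(value) {
  value <- as.integer(value)
  if (any(is.na(value)) || any(value < 1) || any(value > 7)) {
    stop("adjective value must be in [1, 7]", call. = FALSE)
  }
  .adjectives[value]
}

#' @rdname adjective_label
#' @param label character vector of adjective labels.
#' @export
adjective_value <- function(label) {
  idx <- match(tolower(trimws(label)), .adjectives)
  if (any(is.na(idx))) {
    stop("unknown adjective label: ",
      paste(label[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  idx
}

#' Group summary (mean, SD, n)
#'
#' SDs are sample standard deviations (n - 1 denominator) throughout, the
#' convention that reproduces the published pooled values.
#'
#' @param mean,sd,n group mean, sample SD, group size.
#' @return object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(
    is.numeric(mean), length(mean) == 1,
    is.numeric(sd), length(sd) == 1, sd >= 0,
    length(n) == 1, n == as.integer(n), n >= 1
  )
  structure(list(mean = mean, sd = sd, n = as.integer(n)), class = "group_summary")
}

as_group_summaries <- function(groups) {
  if (inherits(groups, "group_summary")) groups <- list(groups)
  if (is.data.frame(groups)) {
    groups <- lapply(seq_len(nrow(groups)), function(i) {
      group_summary(groups$mean[i], groups$sd[i], groups$n[i])
    })
  }
  lapply(groups, function(g) {
    if (inherits(g, "group_summary")) g else group_summary(g[[1]], g[[2]], g[[3]])
  })
}

#' Pool group summaries into one combined summary
#'
#' Exact pooling from summary statistics only: the combined mean is the
#' n-weighted mean, and the combined sample SD comes from the sum-of-squares
#' decomposition
#' \deqn{SS_{total} = \sum_i (n_i - 1) sd_i^2 + \sum_i n_i (m_i - \bar m)^2,}
#' \deqn{sd = \sqrt{SS_{total} / (\sum_i n_i - 1)}.}
#' This equals the sample SD that would be computed on the concatenated raw
#' samples.
#'
#' @param groups list of [group_summary()] (or `(mean, sd, n)` triples, or a
#'   data.frame with those columns); at least 2 groups, each with n >= 2.
#' @return a [group_summary()] for the pooled sample.
#' @export
#' @examples
#' pool_group_summaries(list(c(81.5, 8.59, 5), c(82.0, 13.04, 5)))
pool_group_summaries <- function(groups) {
  groups <- as_group_summaries(groups)
  if (length(groups) < 2) stop("need at least 2 groups to pool", call. = FALSE)
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  if (any(n < 2)) stop("every group must have n >= 2 to pool SDs", call. = FALSE)
  N <- sum(n)
  mbar <- sum(n * m) / N
  ss_total <- sum((n - 1) * s^2) + sum(n * (m - mbar)^2)
  group_summary(mean = mbar, sd = sqrt(ss_total / (N - 1)), n = N)
}

#' Two-sample pooled-variance t interval for a difference of means
#'
#' Student's (equal-variance) two-sample t from summary statistics:
#' \deqn{s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}, \quad
#'       se = s_p \sqrt{1/n_1 + 1/n_2}, \quad df = n_1 + n_2 - 2,}
#' with CI `diff +/- qt((1+conf)/2, df) * se` for `g1$mean - g2$mean`.
#' Pooled-variance (not Welch) matches the published degrees of freedom
#' (`df = n1 + n2 - 2`).
#'
#' @param g1,g2 [group_summary()] objects (or `(mean, sd, n)` triples).
#' @param confidence confidence level in (0, 1); default 0.95.
#' @return list of class `t_ci`: `t_statistic`, `df`, `ci_low`, `ci_high`,
#'   plus `estimate` (the difference) and `se`.
#' @export
two_sample_t_ci <- function(g1, g2, confidence = 0.95) {
  g <- as_group_summaries(list(g1, g2))
  g1 <- g[[1]]
  g2 <- g[[2]]
  if (g1$n < 2 || g2$n < 2) stop("both groups need n >= 2", call. = FALSE)
  if (!is.numeric(confidence) || length(confidence) != 1 ||
    confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  df <- as.integer(g1$n + g2$n - 2L)
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  se <- sqrt(sp2) * sqrt(1 / g1$n + 1 / g2$n)
  diff <- g1$mean - g2$mean
  tcrit <- stats::qt((1 + confidence) / 2, df)
  structure(
    list(
      t_statistic = if (se == 0) 0 else diff / se, df = df,
      ci_low = diff - tcrit * se, ci_high = diff + tcrit * se,
      estimate = diff, se = se
    ),
    class = "t_ci"
  )
}

#' @export
print.t_ci <- function(x, digits = 2, ...) {
  cat(sprintf(
    "difference %.2f, t(%d) = %.2f, CI [%s, %s]\n",
    x$estimate, x$df, x$t_statistic,
    format(round(x$ci_low, digits)), format(round(x$ci_high, digits))
  ))
  invisible(x)
}

#' Usability error record
#'
#' Think-aloud testing errors in the closed three-type taxonomy: navigation
#' (failure to locate a function or follow the screen flow), presentation
#' (selection errors due to labeling ambiguity), control use (improper entry
#' field errors).
#'
#' @param scenario integer 1-5.
#' @param type one of navigation|presentation|control_use.
#' @param description free text.
#' @param priority one of high|medium|low.
#' @return object of class `usability_error`.
#' @export
usability_error <- function(scenario, type, description = "",
                            priority = c("low", "medium", "high")) {
  stopifnot(scenario %in% 1:5)
  type <- match.arg(type, c("navigation", "presentation", "control_use"))
  priority <- match.arg(priority, c("low", "medium", "high"))
  structure(
    list(
      scenario = as.integer(scenario), type = type,
      description = description, priority = priority
    ),
    class = "usability_error"
  )
}

#' Tally usability errors by scenario, type and priority
#'
#' Exhaustive cross-tabulation over the full factor levels (zero cells kept),
#' so marginals always sum to the log length.
#'
#' @param log list of [usability_error()] records, or a data.frame with
#'   columns `scenario`, `type`, `priority`.
#' @return a 3-way `table` (scenario x type x priority).
#' @export
tally_errors <- function(log) {
  if (is.data.frame(log)) {
    df <- log
  } else {
    stopifnot(is.list(log))
    log <- lapply(log, function(e) {
      if (inherits(e, "usability_error")) e else do.call(usability_error, e)
    })
    df <- data.frame(
      scenario = vapply(log, `[[`, integer(1), "scenario"),
      type = vapply(log, `[[`, character(1), "type"),
      priority = vapply(log, `[[`, character(1), "priority"),
      stringsAsFactors = FALSE
    )
  }
  table(
    scenario = factor(df$scenario, levels = 1:5),
    type = factor(df$type, levels = c("navigation", "presentation", "control_use")),
    priority = factor(df$priority, levels = c("low", "medium", "high"))
  )
}

#' Read SUS responses from CSV
#'
#' One row per participant: columns `q1` ... `q10` (1-5) and an optional
#' `adjective` column (1-7).
#'
#' @param path CSV file path.
#' @return list of [sus_response()].
#' @export
read_sus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qcols <- paste0("q", 1:10)
  if (!all(qcols %in% names(df))) {
    stop("SUS CSV needs columns q1..q10", call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    sus_response(
      items = as.integer(df[i, qcols]),
      adjective = if ("adjective" %in% names(df) && !is.na(df$adjective[i])) {
        df$adjective[i]
      }
    )
  })
}

#' Summarize a set of SUS responses
#'
#' @param responses list of [sus_response()] (or vectors of 10 items).
#' @return a [group_summary()] of the scored responses.
#' @export
summarize_sus <- function(responses) {
  scores <- vapply(responses, sus_score, numeric(1))
  group_summary(mean(scores), stats::sd(scores), length(scores))
}
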