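# brute-force per-item SUS oracle: explicit loop, no vectorized shortcut
sus_oracle <- function(items) {
  total <- 0
  for (k in 1:10) {
    total <- total + if (k %% 2 == 1) items[k] - 1 else 5 - items[k]
  }
  2.5 * total
}

test_that("sus_score matches the instrument formula and its oracle", {
  expect_equal(sus_score(rep(3, 10)), 50)
  best <- ifelse(seq_len(10) %% 2 == 1, 5, 1)
  expect_equal(sus_score(best), 100)
  worst <- ifelse(seq_len(10) %% 2 == 1, 1, 5)
  expect_equal(sus_score(worst), 0)

  set.seed(601)
  for (i in 1:200) {
    items <- sample(1:5, 10, replace = TRUE)
    expect_identical(sus_score(items), sus_oracle(items))
  }

  expect_error(sus_response(c(rep(3, 9), 6)), "\\[1, 5\\]")
  expect_error(sus_response(rep(3, 9)), "10 items")
})

test_that("incrementing an odd item by one raises the score by exactly 2.5", {
  set.seed(602)
  for (i in 1:50) {
    items <- sample(1:4, 10, replace = TRUE) # room to increment
    k <- sample(seq(1, 9, 2), 1)
    bumped <- items
    bumped[k] <- bumped[k] + 1
    expect_equal(sus_score(bumped) - sus_score(items), 2.5)
  }
})

test_that("pooling equals direct statistics on reconstructed raw samples", {
  set.seed(603)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    samples <- lapply(seq_len(k), function(j) {
      n <- sample(3:12, 1)
      x <- rnorm(n)
      m <- runif(1, 20, 90)
      s <- runif(1, 1, 15)
      m + s * (x - mean(x)) / sd(x) # exact mean m, sample SD s
    })
    groups <- lapply(samples, function(x) group_summary(mean(x), sd(x), length(x)))
    pooled <- pool_group_summaries(groups)
    all_x <- unlist(samples)
    expect_equal(pooled$mean, mean(all_x), tolerance = 1e-9)
    expect_equal(pooled$sd, sd(all_x), tolerance = 1e-9)
    expect_identical(pooled$n, length(all_x))
  }
})

test_that("pooling two identical groups preserves the mean and shrinks SD by the df ratio", {
  g <- group_summary(81.5, 8.59, 5)
  pooled <- pool_group_summaries(list(g, g))
  expect_equal(pooled$mean, 81.5)
  # concatenating two samples with sample SD s gives exactly s*sqrt((2n-2)/(2n-1)),
  # approaching s only as n grows; 8.59 is recovered to ~6% at n = 5
  expect_equal(pooled$sd, 8.59 * sqrt(8 / 9), tolerance = 1e-12)
  expect_equal(pooled$sd, 8.59, tolerance = 0.06)
  expect_identical(pooled$n, 10L)
  expect_error(pool_group_summaries(list(g)), "at least 2")
  expect_error(pool_group_summaries(list(g, group_summary(50, 0, 1))), "n >= 2")
})

test_that("two_sample_t_ci is internally consistent", {
  g <- group_summary(70, 10, 8)
  same <- two_sample_t_ci(g, g)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$ci_low, -same$ci_high)

  set.seed(604)
  for (i in 1:30) {
    g1 <- group_summary(runif(1, 40, 90), runif(1, 2, 15), sample(3:12, 1))
    g2 <- group_summary(runif(1, 40, 90), runif(1, 2, 15), sample(3:12, 1))
    ci <- two_sample_t_ci(g1, g2)
    tcrit <- qt(0.975, ci$df)
    expect_identical(ci$ci_low <= 0 && 0 <= ci$ci_high, abs(ci$t_statistic) <= tcrit)
    expect_identical(ci$df, g1$n + g2$n - 2L)
  }
  expect_error(two_sample_t_ci(g, g, confidence = 1.2), "confidence")
})

test_that("the t critical value agrees with a numerically integrated quantile oracle", {
  # independent oracle: invert the integrated t density with uniroot
  t_quantile_oracle <- function(p, df) {
    # symmetry: P(T <= q) = 0.5 + integral of the density over (0, q)
    cdf <- function(q) {
      0.5 + stats::integrate(function(x) stats::dt(x, df), 0, q,
        rel.tol = 1e-10)$value
    }
    stats::uniroot(function(q) cdf(q) - p, c(0, 50), tol = 1e-9)$root
  }
  for (df in c(4, 8, 20)) {
    expect_equal(qt(0.975, df), t_quantile_oracle(0.975, df), tolerance = 1e-6)
  }
  # and therefore the CI endpoints agree with the oracle-built interval
  g1 <- group_summary(81.5, 8.59, 5)
  g2 <- group_summary(82.0, 13.04, 5)
  ci <- two_sample_t_ci(g1, g2)
  tcrit <- t_quantile_oracle(0.975, 8)
  expect_equal(ci$ci_low, ci$estimate - tcrit * ci$se, tolerance = 1e-6)
  expect_equal(ci$ci_high, ci$estimate + tcrit * ci$se, tolerance = 1e-6)
})

test_that("adjective anchors are a bijection between 1-7 and the labels", {
  expect_identical(adjective_label(1), "worst imaginable")
  expect_identical(adjective_label(7), "best imaginable")
  expect_identical(adjective_value(adjective_label(1:7)), 1:7)
  expect_error(adjective_label(0), "\\[1, 7\\]")
  expect_error(adjective_value("meh"), "unknown")
})

test_that("error tallies are exhaustive and conserve totals", {
  empty <- tally_errors(list())
  expect_identical(sum(empty), 0L)
  expect_identical(dim(empty), c(5L, 3L, 3L))

  # the two published high-priority findings were both in scenario 1
  log <- list(
    usability_error(1, "presentation", "low contrast, small font", "high"),
    usability_error(1, "presentation", "chatbot not identified as nonhuman", "high"),
    usability_error(2, "navigation", "heart check button hard to find", "medium"),
    usability_error(3, "control_use", "library content not tailored", "medium")
  )
  tab <- tally_errors(log)
  expect_identical(sum(tab[1, , "high"]), 2L)
  expect_identical(sum(tab), length(log))

  # naive counting oracle on a random log
  set.seed(605)
  df <- data.frame(
    scenario = sample(1:5, 40, TRUE),
    type = sample(c("navigation", "presentation", "control_use"), 40, TRUE),
    priority = sample(c("low", "medium", "high"), 40, TRUE)
  )
  tab2 <- tally_errors(df)
  for (r in seq_len(nrow(df))) {
    key <- df[r, ]
    expect_identical(
      tab2[as.character(key$scenario), key$type, key$priority],
      sum(df$scenario == key$scenario & df$type == key$type &
        df$priority == key$priority)
    )
  }
  expect_identical(sum(tab2), nrow(df))
})

test_that("SUS CSV round-trips through read_sus_csv and summarize_sus", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(606)
  m <- matrix(sample(1:5, 50, TRUE), nrow = 5)
  df <- as.data.frame(m)
  names(df) <- paste0("q", 1:10)
  df$adjective <- sample(1:7, 5, TRUE)
  write.csv(df, tmp, row.names = FALSE)
  responses <- read_sus_csv(tmp)
  expect_length(responses, 5)
  summ <- summarize_sus(responses)
  scores <- apply(m, 1, sus_oracle)
  expect_equal(summ$mean, mean(scores))
  expect_equal(summ$sd, sd(scores))
})
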