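# build trials whose per-participant p_right is exactly n_right / n_trials
p_right_trials <- function(n_right, n_trials = 16) {
  do.call(rbind, lapply(seq_along(n_right), function(p) {
    ch <- rep(c("right", "left"),
              c(n_right[p], n_trials - n_right[p]))
    data.frame(participant_id = p, delta_value = rnorm(n_trials),
               delta_mem = 0, choice = ch, rt_ms = 800)
  }))
}

test_that("side-bias filter excludes extreme responders in one pass", {
  set.seed(1)
  # near-0.5 cohort with one always-right participant
  tr <- p_right_trials(c(8, 8, 7, 9, 8, 16))
  f <- side_bias_filter(tr)
  expect_equal(f$side_bias_excluded, c(rep(FALSE, 5), TRUE))

  # identical participants: SD 0, nobody excluded
  f0 <- side_bias_filter(p_right_trials(rep(8, 5)))
  expect_false(any(f0$side_bias_excluded))
})

test_that("a participant exactly at mean + 2SD is kept (strict inequality)", {
  # engineered binary-exact cohort: p_right = 12/16, 7/16 x4, 8/16
  # mean = 0.5, sample sd = 0.125 exactly, so 0.75 sits exactly at +2SD
  set.seed(2)
  tr <- p_right_trials(c(12, 7, 7, 7, 7, 8))
  f <- side_bias_filter(tr)
  expect_equal(f$p_right[f$participant_id == "1"], 0.75)
  expect_equal(mean(f$p_right), 0.5)
  expect_equal(sd(f$p_right), 0.125)
  expect_false(any(f$side_bias_excluded))
})

test_that("fast-RT filter uses a strict more-than-half rule", {
  mk <- function(p, rts) data.frame(participant_id = p, delta_value = 1,
                                    delta_mem = 0, choice = "right",
                                    rt_ms = rts)
  tr <- rbind(mk(1, rep(200, 10)),          # all fast -> excluded
              mk(2, rep(1000, 10)),         # all slow -> kept
              mk(3, rep(c(200, 1000), 5)))  # exactly half -> kept
  f <- fast_rt_filter(tr)
  expect_equal(f$fast_rt_excluded[order(f$participant_id)],
               c(TRUE, FALSE, FALSE))
})

test_that("value-sanity filter keeps separated value-consistent choosers", {
  set.seed(3)
  mk <- function(p, rule) {
    dv <- rnorm(40)
    data.frame(participant_id = p, delta_value = dv, delta_mem = 0,
               choice = rule(dv), rt_ms = 700)
  }
  tr <- rbind(
    mk(1, function(dv) ifelse(dv > 0, "right", "left")),   # perfect chooser
    mk(2, function(dv) ifelse(dv > 0, "left", "right")),   # anti-value
    mk(3, function(dv) ifelse(runif(40) < plogis(2 * dv), "right", "left")))
  f <- value_sanity_filter(tr)
  f <- f[order(f$participant_id), ]
  expect_false(f$value_sanity_excluded[1])
  expect_true(f$separated[1])
  expect_true(f$value_sanity_excluded[2])
  expect_false(f$value_sanity_excluded[3])
})

test_that("null choosers are excluded at the theoretical 97.5% rate", {
  # slope <= 0 with prob 1/2, plus positive-but-nonsignificant with ~.475
  set.seed(4)
  excl <- vapply(1:1000, function(r) {
    dv <- rnorm(60)
    y <- rbinom(60, 1, 0.5)
    fit <- suppressWarnings(glm(y ~ dv, family = binomial()))
    s <- coef(fit)[2]; p <- summary(fit)$coefficients[2, 4]
    s <= 0 || p >= 0.05
  }, logical(1))
  expect_lt(abs(mean(excl) - 0.975), 0.02)
})

test_that("combined screening report composes the three flags", {
  set.seed(5)
  good <- function(p) {
    dv <- rnorm(40)
    data.frame(participant_id = p, delta_value = dv, delta_mem = 0,
               choice = ifelse(runif(40) < plogis(3 * dv), "right", "left"),
               rt_ms = runif(40, 500, 1500))
  }
  tr <- do.call(rbind, lapply(1:8, good))
  fast <- tr$participant_id == 8
  tr$rt_ms[fast] <- 150                     # participant 8: all fast
  rep <- screen_participants(tr)
  expect_s3_class(rep, "screening_report")
  expect_true(rep$fast_rt_excluded[rep$participant_id == "8"])
  expect_equal(rep$kept, !(rep$side_bias_excluded | rep$fast_rt_excluded |
                             rep$value_sanity_excluded))
  # fast-RT is participant-local: re-running on the kept subset adds no flags
  kept_tr <- tr[tr$participant_id %in% rep$participant_id[rep$kept], ]
  f2 <- fast_rt_filter(kept_tr)
  expect_false(any(f2$fast_rt_excluded))
})
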