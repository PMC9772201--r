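test_that("Laplace log-likelihood agrees with adaptive quadrature", {
  # gold-standard oracle: 15-node adaptive Gauss-Hermite on a toy problem
  set.seed(1)
  d <- data.frame(participant_id = factor(rep(1:5, each = 50)),
                  x = rnorm(250))
  b <- rnorm(5, 0, 0.8)
  d$.y <- rbinom(250, 1, plogis(0.3 + b[as.integer(d$participant_id)] +
                                  0.5 * d$x))
  laplace <- lme4::glmer(.y ~ x + (1 | participant_id), d, binomial,
                         nAGQ = 1)
  agq <- lme4::glmer(.y ~ x + (1 | participant_id), d, binomial, nAGQ = 15)
  expect_lt(abs(as.numeric(logLik(laplace)) - as.numeric(logLik(agq))), 0.5)
})

test_that("mixed logistic recovers a known value effect", {
  set.seed(2)
  n_sub <- 60; n_tr <- 80; beta <- 1.1
  d <- skeleton_trials(n_sub, n_tr, seed = 3)
  slopes <- rnorm(n_sub, beta, 0.4)
  b0 <- rnorm(n_sub, 0, 0.3)
  id <- d$participant_id
  pr <- plogis(b0[id] + slopes[id] * d$delta_value)
  d$choice <- ifelse(runif(nrow(d)) < pr, "right", "left")
  d$rt_ms <- 700
  fit <- fit_mixed_logistic(d, response = "chose_right",
                            fixed = "delta_value")
  co <- fit$coefficients[fit$coefficients$term == "delta_value", ]
  expect_lt(abs(co$estimate - beta), 2 * co$se)
  expect_lt(co$lrt_p, 1e-6)
  expect_equal(co$or, exp(co$estimate))
  # CI on the same per-z-unit odds scale
  expect_lt(co$ci_lo, co$or); expect_gt(co$ci_hi, co$or)
})

test_that("higher-value coding drops ties and matches direct computation", {
  d <- skeleton_trials(3, 30, seed = 4)
  d$delta_value[1:5] <- 0
  d$choice <- "right"; d$rt_ms <- 600
  prepped <- memchoice:::build_response(d, "chose_higher_value")
  expect_equal(nrow(prepped), nrow(d) - 5)
  expect_equal(prepped$.y, as.integer(prepped$delta_value > 0))
})

test_that("precondition failures raise errors", {
  d <- skeleton_trials(1, 60, seed = 5)
  d$choice <- "right"; d$rt_ms <- 700
  expect_error(fit_mixed_logistic(d, response = "chose_right",
                                  fixed = "delta_value"),
               "at least 2 participants")
  d2 <- skeleton_trials(3, 4, seed = 6)
  d2$choice <- "left"; d2$rt_ms <- 700
  expect_error(fit_mixed_logistic(d2, response = "chose_right",
                                  fixed = "delta_value"),
               "at least 20 trials")
  expect_error(model_spec("chose_right", "delta_value",
                          random_slopes = "delta_mem"),
               "matching fixed effect")
})

test_that("log-RT model recovers a known difficulty slope", {
  set.seed(7)
  n_sub <- 40; n_tr <- 90; slope <- -0.04
  d <- skeleton_trials(n_sub, n_tr, seed = 8)
  inter <- rnorm(n_sub, log(0.9), 0.1)
  d$choice <- "right"
  d$rt_ms <- exp(inter[d$participant_id] + slope * d$abs_delta_value +
                   rnorm(nrow(d), 0, 0.3)) * 1000
  fit <- fit_mixed_linear(d, response = "log_rt", fixed = "abs_delta_value")
  co <- fit$coefficients[fit$coefficients$term == "abs_delta_value", ]
  expect_lt(abs(co$estimate - slope), 2 * co$se)
  expect_lt(co$lrt_p, 0.05)
})

test_that("constant RTs are flagged as degenerate", {
  d <- skeleton_trials(4, 30, seed = 9)
  d$choice <- "right"; d$rt_ms <- 800
  expect_error(fit_mixed_linear(d, response = "log_rt",
                                fixed = "abs_delta_value"),
               "degenerate")
})

test_that("binned summaries average within participant first", {
  d <- skeleton_trials(4, 25, seed = 10)
  d$choice <- "right"
  d$rt_ms <- 100 * d$abs_delta_value + 500
  bs <- binned_summary(d, "abs_delta_value", "rt_ms", n_bins = 5)
  expect_equal(nrow(bs), 5)
  expect_true(all(diff(bs$x_mean) > 0))
  expect_true(all(diff(bs$y_mean) > 0))  # y = x means monotone bins

  # 10 trials, 5 bins -> 2 per bin; oracle by direct grouping
  d10 <- data.frame(participant_id = 1, delta_value = 1, delta_mem = 1,
                    choice = "right", rt_ms = 1:10 * 100,
                    x = 1:10)
  b10 <- binned_summary(d10, "x", "rt_ms", n_bins = 5)
  direct <- tapply(d10$rt_ms, rep(1:5, each = 2), mean)
  expect_equal(b10$y_mean, as.vector(direct))
})

test_that("item-level correlations match direct arithmetic", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  got <- item_level_correlations(x, y)
  expect_equal(got$r, cor(x, y))
  expect_equal(got$df, 3)
  # identical vectors
  expect_equal(item_level_correlations(x, x)$r, 1)
  expect_error(item_level_correlations(x, y[1:3]), "length")

  # null distribution of r matches the t reference (KS over replicates)
  set.seed(11)
  ps <- vapply(1:500, function(i) {
    item_level_correlations(rnorm(20), rnorm(20), spearman = FALSE)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("representativeness scores are averaged participant z-scores", {
  r <- data.frame(participant_id = rep(1:3, each = 3),
                  item_id = rep(1:3, 3),
                  rating = c(1, 2, 3, 2, 4, 6, 3, 2, 1))
  rs <- representativeness_scores(r)
  hand <- rowMeans(cbind(scale(c(1, 2, 3)), scale(c(2, 4, 6)),
                         scale(c(3, 2, 1))))
  expect_equal(as.numeric(rs), hand)
  # one participant: the z-scores themselves
  one <- representativeness_scores(r[r$participant_id == 1, ])
  expect_equal(as.numeric(one), as.numeric(scale(c(1, 2, 3))))
})
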