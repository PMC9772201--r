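grid_params <- expand.grid(a = c(1, 2), v = c(-2, 0, 2),
                           z = c(0.3, 0.5, 0.7))

p_upper_by_integration <- function(a, v, z) {
  integrate(function(t) wfpt_density(t, "upper", a, v, z), 0, Inf,
            rel.tol = 1e-9)$value
}

test_that("first-passage densities integrate to one across the grid", {
  for (i in seq_len(nrow(grid_params))) {
    g <- grid_params[i, ]
    up <- p_upper_by_integration(g$a, g$v, g$z)
    lo <- integrate(function(t) wfpt_density(t, "lower", g$a, g$v, g$z),
                    0, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(up + lo - 1), 1e-4)
  }
})

test_that("upper-boundary mass matches the closed-form absorption law", {
  # symmetry case first: no drift, central start
  expect_equal(p_upper_by_integration(2, 0, 0.5), 0.5, tolerance = 1e-6)
  expect_equal(ddm_absorption_prob(2, 0, 0.5), 0.5)
  for (i in seq_len(nrow(grid_params))) {
    g <- grid_params[i, ]
    expect_equal(p_upper_by_integration(g$a, g$v, g$z),
                 ddm_absorption_prob(g$a, g$v, g$z), tolerance = 1e-5)
  }
})

test_that("likelihood is invariant to boundary relabeling", {
  t <- seq(0.25, 2.5, by = 0.25)
  for (i in seq_len(nrow(grid_params))) {
    g <- grid_params[i, ]
    expect_equal(wfpt_density(t, "upper", g$a, g$v, g$z),
                 wfpt_density(t, "lower", g$a, -g$v, 1 - g$z),
                 tolerance = 1e-12)
  }
})

test_that("upper-boundary probability is monotone in drift and start", {
  for (a in c(1, 2)) {
    pv <- ddm_absorption_prob(a, c(-2, -0.5, 0, 0.5, 2), 0.4)
    expect_true(all(diff(pv) > 0))
    pz <- ddm_absorption_prob(a, 0.8, c(0.2, 0.35, 0.5, 0.65, 0.8))
    expect_true(all(diff(pz) > 0))
  }
})

test_that("degenerate inputs follow the conventions", {
  expect_equal(wfpt_density(c(-1, 0), "upper", 1.5, 1, 0.5), c(0, 0))
  expect_equal(wfpt_density(0.2, "upper", 1.5, 1, 0.5, t0 = 0.3), 0)
  expect_error(wfpt_density(1, "upper", 1.5, 1, 1.2), "z_rel")
  expect_error(simulate_ddm(10, a = 0.1, v = 0, z_rel = 0.5, dt = 0.01),
               "dt")
})

test_that("extreme drift or start point give immediate upper hits", {
  s1 <- simulate_ddm(200, a = 1.5, v = 40, z_rel = 0.5, t0 = 0.3, seed = 1)
  expect_true(all(s1$upper))
  expect_lt(max(s1$rt) - 0.3, 0.2)
  s2 <- simulate_ddm(200, a = 1.5, v = 0, z_rel = 0.999, t0 = 0.3, seed = 2)
  expect_gt(mean(s2$upper), 0.98)
})

test_that("simulated first-passage times agree with the density", {
  # KS comparison on a subset of the grid (fully specified distributions)
  for (g in list(list(a = 1.5, v = 1, z = 0.5),
                 list(a = 1, v = -1, z = 0.6),
                 list(a = 2, v = 0.5, z = 0.4))) {
    n <- 4000
    sim <- simulate_ddm(n, a = g$a, v = g$v, z_rel = g$z, t0 = 0, seed = 42)
    p_up <- ddm_absorption_prob(g$a, g$v, g$z)
    expect_lt(abs(mean(sim$upper, na.rm = TRUE) - p_up),
              3.5 * sqrt(p_up * (1 - p_up) / n) + 0.005)
    rt_up <- sim$rt[which(sim$upper)]
    cdf <- Vectorize(function(q) {
      integrate(function(s) wfpt_density(s, "upper", g$a, g$v, g$z), 0, q,
                rel.tol = 1e-7)$value / p_up
    })
    D <- suppressWarnings(ks.test(rt_up, cdf))$statistic
    expect_lt(unname(D), 1.63 / sqrt(length(rt_up)))  # alpha = 0.01
  }
})

test_that("single-participant DDM regression recovers its parameters", {
  truth <- list(a = 1.6, t0 = 0.35, v0 = 0.6, v_val = 1.4, z0 = 0.3)
  set.seed(5)
  n <- 8000
  d <- data.frame(participant_id = 1, delta_value = rnorm(n), delta_mem = 0)
  v <- truth$v0 + truth$v_val * d$delta_value
  sim <- simulate_ddm(n, a = truth$a, v = v, z_rel = plogis(truth$z0),
                      t0 = truth$t0, seed = 6)
  d$choice <- ifelse(is.na(sim$upper), "none",
                     ifelse(sim$upper, "right", "left"))
  d$rt_ms <- sim$rt * 1000
  fit <- fit_ddm_regression(d, v_covariates = "delta_value",
                            min_trials = 100)
  est <- fit$participants
  expect_false(est$flagged)
  expect_lt(abs(est$a - truth$a) / truth$a, 0.05)
  expect_lt(abs(est$t0 - truth$t0) / truth$t0, 0.05)
  expect_lt(abs(est$v0 - truth$v0) / truth$v0, 0.1)
  expect_lt(abs(est$v_delta_value - truth$v_val) / truth$v_val, 0.1)
  expect_lt(abs(est$z0 - truth$z0), 0.1)
})
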