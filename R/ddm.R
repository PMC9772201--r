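#' Wiener first-passage-time density
#'
#' Density of the first-passage time of a drift-diffusion process (unit
#' noise, boundary separation `a`, drift `v`, relative start point `z_rel`,
#' non-decision time `t0`) at the chosen boundary, evaluated with the
#' small-time / large-time series expansions and an automatic switch to
#' whichever needs fewer terms at the requested accuracy. Vectorized over
#' `t`, `v` and `z_rel`. Times at or below `t0` have density 0 by convention.
#'
#' @param t observed times (seconds, including `t0`).
#' @param boundary `"upper"` or `"lower"`.
#' @param a boundary separation (> 0).
#' @param v drift rate (scalar or per-t vector).
#' @param z_rel relative start point in (0, 1) (scalar or per-t vector).
#' @param t0 non-decision time (s).
#' @param err absolute truncation error of the series (default 1e-10).
#' @return numeric vector of densities.
#' @export
#' @examples
#' wfpt_density(0.6, "upper", a = 2, v = 1, z_rel = 0.5)
wfpt_density <- function(t, boundary = c("upper", "lower"), a, v, z_rel,
                         t0 = 0, err = 1e-10) {
  boundary <- match.arg(boundary)
  if (a <= 0) stop_data("a must be > 0")
  n <- max(length(t), length(v), length(z_rel))
  t <- rep_len(t, n); v <- rep_len(v, n); w <- rep_len(z_rel, n)
  if (any(w <= 0 | w >= 1)) stop_data("z_rel must lie strictly in (0, 1)")
  if (boundary == "upper") { v <- -v; w <- 1 - w }

  out <- numeric(n)
  ok <- which(t - t0 > 0)
  if (!length(ok)) return(out)
  td <- t[ok] - t0
  tau <- td / a^2
  f <- wfpt_f_lower(tau, w[ok], err)
  out[ok] <- f * exp(-v[ok] * a * w[ok] - v[ok]^2 * td / 2) / a^2
  out
}

# standardized (a = 1, v = 0) lower-boundary density at normalized time tau
wfpt_f_lower <- function(tau, w, err) {
  # terms needed by each expansion
  ks <- ifelse(2 * sqrt(2 * pi * tau) * err < 1,
               2 + sqrt(-2 * tau * log(2 * sqrt(2 * pi * tau) * err)),
               sqrt(tau) + 1)
  ks <- pmax(ks, sqrt(tau) + 1)
  kl <- ifelse(pi * tau * err < 1,
               sqrt(-2 * log(pi * tau * err) / (pi^2 * tau)),
               1 / (pi * sqrt(tau)))
  kl <- pmax(kl, 1 / (pi * sqrt(tau)))

  f <- numeric(length(tau))
  small <- ks < kl
  if (any(small)) {
    K <- ceiling(max(ks[small]))
    kk <- seq.int(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    ws <- outer(w[small], 2 * kk, `+`)
    f[small] <- rowSums(ws * exp(-ws^2 / (2 * tau[small]))) /
      sqrt(2 * pi * tau[small]^3)
  }
  if (any(!small)) {
    K <- ceiling(max(kl[!small]))
    kk <- seq_len(K)
    f[!small] <- pi * rowSums(
      outer(tau[!small], kk, function(tt, k) k * exp(-k^2 * pi^2 * tt / 2)) *
        outer(w[!small], kk, function(ww, k) sin(k * pi * ww)))
  }
  pmax(f, 0)
}

#' Closed-form boundary absorption probability
#'
#' Probability that a unit-noise diffusion with drift `v` started at
#' `z = z_rel * a` is absorbed at the upper boundary:
#' `(1 - exp(-2 v z)) / (1 - exp(-2 v a))`, with the `v -> 0` limit `z / a`.
#'
#' @inheritParams wfpt_density
#' @return probability of upper-boundary absorption.
#' @export
ddm_absorption_prob <- function(a, v, z_rel) {
  z <- z_rel * a
  ifelse(abs(v) < 1e-9, z / a,
         (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * a)))
}

#' Simulate drift-diffusion trials
#'
#' Euler-Maruyama path simulation of the Wiener process until absorption;
#' `rt = passage time + t0`. Paths still unabsorbed at `max_t` are recorded
#' as no-response (`NA` choice and RT).
#'
#' @param n number of trials.
#' @param a boundary separation.
#' @param v drift (scalar or length-n).
#' @param z_rel relative start point (scalar or length-n).
#' @param t0 non-decision time (s).
#' @param dt Euler step (s, default 1e-4; must be small relative to `a^2`).
#' @param seed integer seed.
#' @param max_t runaway cap on decision time (s, default 10).
#' @return `data.frame` with `upper` (logical, `NA` = no response) and `rt`
#'   (seconds, includes `t0`).
#' @export
#' @examples
#' sim <- simulate_ddm(100, a = 1.5, v = 1, z_rel = 0.5, t0 = 0.3, seed = 1)
#' mean(sim$upper, na.rm = TRUE)
simulate_ddm <- function(n, a, v, z_rel, t0 = 0.3, dt = 1e-4, seed = NULL,
                         max_t = 10) {
  if (dt >= a^2 / 10) stop_data("dt must be small relative to a^2")
  if (!is.null(seed)) set.seed(seed)
  res <- ddm_sim_cpp(as.integer(n), a, as.numeric(v), as.numeric(z_rel),
                     dt, max_t)
  data.frame(upper = res$upper, rt = res$rt + t0)
}

#' Fit per-participant DDM regressions and group-level tests
#'
#' For each participant, maximum-likelihood estimation of a drift-diffusion
#' model in which the drift rate is a linear function of trial covariates
#' (`v = v0 + sum(v_k * x_k)`) and the relative start point is an
#' inverse-logit-linear function (`z_rel = inv_logit(z0 + sum(z_k * x_k))`).
#' The upper boundary codes "chose right"; the likelihood is the Wiener
#' first-passage density at the observed boundary and RT. `t0` is kept below
#' 95% of the participant's minimum RT. Group-level inference is a one-sample
#' t-test of each regression weight across participants; participants whose
#' optimization fails or lands on the parameter-space boundary are flagged
#' and dropped from the group tests.
#'
#' @param trials responded choice-trial table (`rt_ms`, `choice`, covariate
#'   columns).
#' @param v_covariates covariate columns entering the drift regression
#'   (default `c("delta_value", "delta_mem")`; use
#'   `"delta_value:delta_mem"` for the interaction).
#' @param z_covariates covariate columns entering the start-point regression
#'   (default none: a free intercept `z0` only).
#' @param min_trials minimum responded trials per participant (default 80).
#' @param n_starts random restarts per participant (default 3).
#' @return an object of class `ddm_fit`: list with `participants` (per-
#'   participant parameter estimates, log-likelihood, convergence flag) and
#'   `group` (per-weight mean, SE, t, df, p, significant at 95%).
#' @export
fit_ddm_regression <- function(trials,
                               v_covariates = c("delta_value", "delta_mem"),
                               z_covariates = character(0),
                               min_trials = 80L, n_starts = 3L) {
  resp <- responded(trials)
  sp <- split(resp, resp$participant_id)
  rows <- lapply(sp, function(d) {
    if (nrow(d) < min_trials) {
      stop_data("participant ", d$participant_id[1], " has fewer than ",
                min_trials, " responded trials")
    }
    fit_ddm_one(d, v_covariates, z_covariates, n_starts)
  })
  part <- do.call(rbind, rows)
  rownames(part) <- NULL

  weights <- c("a", "t0", "v0", paste0("v_", v_covariates),
               "z0", if (length(z_covariates)) paste0("z_", z_covariates))
  ok <- part[!part$flagged, ]
  group <- do.call(rbind, lapply(setdiff(weights, c("a", "t0")), function(wn) {
    x <- ok[[wn]]
    if (length(x) < 2) {
      # group inference needs at least two participants
      return(data.frame(term = wn, mean = mean(x), se = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_,
                        significant = NA))
    }
    tt <- t.test(x)
    data.frame(term = wn, mean = mean(x), se = sd(x) / sqrt(length(x)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < 0.05)
  }))
  rownames(group) <- NULL
  structure(list(participants = part, group = group,
                 v_covariates = v_covariates, z_covariates = z_covariates),
            class = "ddm_fit")
}

ddm_design_matrix <- function(d, covariates) {
  if (!length(covariates)) return(matrix(0, nrow(d), 0))
  cols <- lapply(covariates, function(cv) {
    if (grepl(":", cv, fixed = TRUE)) {
      parts <- strsplit(cv, ":", fixed = TRUE)[[1]]
      Reduce(`*`, lapply(parts, function(p) d[[p]]))
    } else d[[cv]]
  })
  do.call(cbind, cols)
}

fit_ddm_one <- function(d, v_cov, z_cov, n_starts) {
  rt <- d$rt_ms / 1000
  up <- d$choice == "right"
  Xv <- ddm_design_matrix(d, v_cov)
  Xz <- ddm_design_matrix(d, z_cov)
  t0_max <- 0.95 * min(rt)

  # parameters: log a, logit(t0/t0_max), v0, v weights, z0, z weights
  nll <- function(par) {
    a <- exp(par[1])
    t0 <- t0_max * inv_logit(par[2])
    v <- par[3] + if (ncol(Xv)) drop(Xv %*% par[3 + seq_len(ncol(Xv))]) else 0
    zi <- 3 + ncol(Xv)
    z <- inv_logit(par[zi + 1] +
                     if (ncol(Xz)) drop(Xz %*% par[zi + 1 + seq_len(ncol(Xz))])
                     else 0)
    f_up <- wfpt_density(rt, "upper", a, v, z, t0, err = 1e-8)
    f_lo <- wfpt_density(rt, "lower", a, v, z, t0, err = 1e-8)
    f <- ifelse(up, f_up, f_lo)
    if (any(!is.finite(f)) || any(f <= 0)) return(1e10)
    -sum(log(f))
  }
  npar <- 4 + ncol(Xv) + ncol(Xz)
  acc_dir <- qlogis(clip(mean(up), 0.05, 0.95))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- c(log(1.5), 0, 0.3 * acc_dir, rep(0, ncol(Xv)), 0,
               rep(0, ncol(Xz)))
    if (s > 1) start <- start + rnorm(npar, 0, 0.3)
    opt <- tryCatch(nlminb(start, nll, control = list(iter.max = 500)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective)) {
      best <- opt
    }
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10) {
    est <- rep(NA_real_, npar)
    return(ddm_row(d$participant_id[1], est, v_cov, z_cov, NA_real_, TRUE,
                   t0_max))
  }
  flagged <- best$convergence > 1 || abs(best$par[1]) > 3 ||
    abs(best$par[2]) > 6
  ddm_row(d$participant_id[1], best$par, v_cov, z_cov, -best$objective,
          flagged, t0_max)
}

ddm_row <- function(pid, par, v_cov, z_cov, ll, flagged, t0_max) {
  nv <- length(v_cov); nz <- length(z_cov)
  out <- data.frame(participant_id = pid,
                    a = exp(par[1]),
                    t0 = t0_max * inv_logit(par[2]),
                    v0 = par[3])
  for (i in seq_len(nv)) out[[paste0("v_", v_cov[i])]] <- par[3 + i]
  out$z0 <- par[4 + nv]
  for (i in seq_len(nz)) out[[paste0("z_", z_cov[i])]] <- par[4 + nv + i]
  out$loglik <- ll
  out$flagged <- flagged
  out
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit> %d participants (%d flagged)\n",
              nrow(x$participants), sum(x$participants$flagged)))
  print(x$group, row.names = FALSE)
  invisible(x)
}
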