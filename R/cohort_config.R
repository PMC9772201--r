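#' Configuration for a synthetic behavioral cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: item counts,
#' cohort sizes, the latent memorability/value correlation, recognition-task
#' participant-effect SDs, rating noise, and the choice generator (logistic or
#' drift-diffusion backend). Defaults mirror the study conditions the package
#' emulates: 138 items, 199 recognition participants each seeing 29 targets
#' and 109 fillers, and 44 choice participants rating all items and choosing
#' among 138 bespoke pairs.
#'
#' Latent item memorability (`theta_mem`, a logit-scale hit propensity) and
#' latent population-mean value (`mu_value`, on the 0-10 rating scale) are
#' coupled through a Gaussian copula with target Pearson correlation
#' `mem_value_corr` (default 0.15, the empirical item-level correlation the
#' analyses anticipate).
#'
#' @param n_items number of stimulus items (default 138).
#' @param n_mem_participants recognition-task cohort size (default 199).
#' @param n_choice_participants choice-task cohort size (default 44).
#' @param mem_value_corr target Pearson correlation between latent
#'   memorability and latent value, in \[-1, 1\].
#' @param mem_dist marginal family for `theta_mem`: "normal" or "logistic".
#' @param theta_mean,theta_sd location/scale of the memorability marginal
#'   (logit scale). Defaults give an expected hit rate near 0.62 and, with the
#'   false-alarm defaults, a median corrected recognition near 0.5.
#' @param phi_mean,phi_sd location/scale of the item false-alarm marginal
#'   (logit scale); the default mean -2.2 gives a ~10% false-alarm rate.
#' @param alpha_sd,gamma_sd SDs of the recognition participant effects on the
#'   hit and false-alarm logits.
#' @param rating_noise_sd SD of participant-by-item Gaussian rating noise on
#'   the 0-10 slider scale.
#' @param choice_params a [logistic_choice_params()] or [ddm_params()] object
#'   driving the choice generator.
#' @param modality "image" or "word" (label only; the pipeline is identical).
#' @param seed integer root seed; all stages derive named substreams from it.
#' @return an object of class `cohort_config` (a named list).
#' @seealso [make_item_bank()], [simulate_recognition()], [simulate_ratings()],
#'   [simulate_choices()]
#' @export
#' @examples
#' cfg <- cohort_config(seed = 7)
#' cfg$n_items
cohort_config <- function(n_items = 138,
                          n_mem_participants = 199,
                          n_choice_participants = 44,
                          mem_value_corr = 0.15,
                          mem_dist = c("normal", "logistic"),
                          theta_mean = 0.5, theta_sd = 0.9,
                          phi_mean = -2.2, phi_sd = 0.5,
                          alpha_sd = 0.7, gamma_sd = 0.5,
                          rating_noise_sd = 1.5,
                          choice_params = logistic_choice_params(),
                          modality = c("image", "word"),
                          seed = 1L) {
  mem_dist <- match.arg(mem_dist)
  modality <- match.arg(modality)
  if (!is.numeric(mem_value_corr) || abs(mem_value_corr) > 1) {
    stop("mem_value_corr must lie in [-1, 1]", call. = FALSE)
  }
  counts <- c(n_items = n_items, n_mem_participants = n_mem_participants,
              n_choice_participants = n_choice_participants)
  if (any(counts < 2)) stop("all cohort counts must be >= 2", call. = FALSE)
  if (rating_noise_sd < 0) stop("rating_noise_sd must be >= 0", call. = FALSE)
  structure(list(
    n_items = as.integer(n_items),
    n_mem_participants = as.integer(n_mem_participants),
    n_choice_participants = as.integer(n_choice_participants),
    mem_value_corr = mem_value_corr,
    mem_dist = mem_dist,
    theta_mean = theta_mean, theta_sd = theta_sd,
    phi_mean = phi_mean, phi_sd = phi_sd,
    alpha_sd = alpha_sd, gamma_sd = gamma_sd,
    rating_noise_sd = rating_noise_sd,
    choice_params = choice_params,
    modality = modality,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Logistic choice-generator parameters
#'
#' Generative twin of the fixed effects in the mixed-effects logistic choice
#' models: the probability of choosing the right-hand item is
#' `inv_logit(beta0 + beta_value * dvalue + beta_mem * dmem)` with by-subject
#' Gaussian variation around each coefficient. `beta_mem = 0` reproduces the
#' null world in which memorability plays no causal role in choice.
#' Reaction times are lognormal with a log-mean decreasing in the absolute
#' value difference; draws past the 3 s deadline become no-response trials.
#'
#' @param beta0 side-bias intercept (log-odds of choosing right).
#' @param beta_value coefficient on the signed z-value difference; the default
#'   `log(3.6)` matches an odds ratio of 3.6 per z-unit.
#' @param beta_mem coefficient on the signed z-memorability difference
#'   (default 0: the null world).
#' @param sd_beta0,sd_beta_value,sd_beta_mem by-subject SDs of the three
#'   coefficients.
#' @param rt_meanlog baseline log-mean of RT in seconds.
#' @param rt_value_slope additive change in log-mean RT per unit `|dvalue|`
#'   (negative: easier choices are faster).
#' @param rt_mem_slope additive change in log-mean RT per unit `|dmem|`.
#' @param rt_sdlog lognormal scale of RT.
#' @param sd_rt_intercept by-subject SD of the RT log-mean.
#' @param deadline_s response deadline in seconds; slower draws are recorded
#'   as no-response.
#' @return an object of class `logistic_choice_params`.
#' @export
logistic_choice_params <- function(beta0 = 0,
                                   beta_value = log(3.6),
                                   beta_mem = 0,
                                   sd_beta0 = 0.3,
                                   sd_beta_value = 0.5,
                                   sd_beta_mem = 0,
                                   rt_meanlog = log(0.9),
                                   rt_value_slope = -0.04,
                                   rt_mem_slope = 0,
                                   rt_sdlog = 0.35,
                                   sd_rt_intercept = 0.15,
                                   deadline_s = 3) {
  p <- list(beta0 = beta0, beta_value = beta_value, beta_mem = beta_mem,
            sd_beta0 = sd_beta0, sd_beta_value = sd_beta_value,
            sd_beta_mem = sd_beta_mem,
            rt_meanlog = rt_meanlog, rt_value_slope = rt_value_slope,
            rt_mem_slope = rt_mem_slope, rt_sdlog = rt_sdlog,
            sd_rt_intercept = sd_rt_intercept, deadline_s = deadline_s)
  if (!all(vapply(p, is.finite, logical(1)))) {
    stop("all logistic choice parameters must be finite", call. = FALSE)
  }
  structure(p, class = "logistic_choice_params")
}

#' Drift-diffusion choice-generator parameters
#'
#' Parameters of the Wiener diffusion generator used by the DDM backend of
#' [simulate_choices()]. Noise scale is fixed at 1 (the usual scaling
#' convention); drift on each trial is
#' `v = v0 + v_val * dvalue + v_mem * dmem + v_int * dvalue * dmem` and the
#' relative start point is `inv_logit(z0 + z_val * dvalue + z_mem * dmem +
#' z_int * dvalue * dmem)`, keeping it inside (0, 1). The upper boundary codes
#' "chose right".
#'
#' @param a boundary separation (> 0).
#' @param t0 non-decision time in seconds (>= 0).
#' @param v0,v_val,v_mem,v_int drift-rate regression weights.
#' @param z0,z_val,z_mem,z_int start-point regression weights on the logit
#'   scale (`z0 = 0` is an unbiased start).
#' @param sv_subject by-subject SD of the drift intercept.
#' @param deadline_s response deadline in seconds.
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(a = 1.6, t0 = 0.35,
                       v0 = 0, v_val = 1.2, v_mem = 0, v_int = 0,
                       z0 = 0, z_val = 0, z_mem = 0, z_int = 0,
                       sv_subject = 0.2, deadline_s = 3) {
  if (a <= 0) stop("boundary separation a must be > 0", call. = FALSE)
  if (t0 < 0) stop("non-decision time t0 must be >= 0", call. = FALSE)
  structure(list(a = a, t0 = t0, v0 = v0, v_val = v_val, v_mem = v_mem,
                 v_int = v_int, z0 = z0, z_val = z_val, z_mem = z_mem,
                 z_int = z_int, sv_subject = sv_subject,
                 deadline_s = deadline_s),
            class = "ddm_params")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  items: %d (%s), mem participants: %d, choice participants: %d\n",
              x$n_items, x$modality, x$n_mem_participants,
              x$n_choice_participants))
  cat(sprintf("  mem/value copula r = %.3f, rating noise sd = %.2f, seed = %d\n",
              x$mem_value_corr, x$rating_noise_sd, x$seed))
  cat(sprintf("  choice backend: %s\n", class(x$choice_params)[1]))
  invisible(x)
}
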