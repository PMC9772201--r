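#' Simulate key presses for recognition streams
#'
#' Generates per-trial "repeat" key presses from the latent item bank. On any
#' repeat presentation of item i, participant p presses with probability
#' `inv_logit(alpha_p + theta_mem_i)`; on any first presentation the press is
#' a false alarm with probability `inv_logit(gamma_p + phi_fa_i)`. The
#' participant effects `alpha_p ~ N(0, alpha_sd)` and `gamma_p ~ N(0,
#' gamma_sd)` capture between-observer response-criterion variation.
#'
#' @param bank an [make_item_bank()] item bank.
#' @param streams stacked streams from [build_streams()].
#' @param config a [cohort_config()] (supplies `alpha_sd`, `gamma_sd`, seed).
#' @param alpha,gamma optional fixed participant effects (named by participant
#'   id); drawn from the config SDs when `NULL`.
#' @return the streams `data.frame` with a logical `pressed` column.
#' @export
simulate_recognition <- function(bank, streams, config,
                                 alpha = NULL, gamma = NULL) {
  unknown <- setdiff(unique(streams$item_id), bank$item_id)
  if (length(unknown)) {
    stop_data("stream references unknown item_id(s): ",
              paste(head(unknown, 5), collapse = ", "))
  }
  set.seed(substream_seed(config$seed, "recognition"))
  pids <- unique(streams$participant_id)
  if (is.null(alpha)) alpha <- setNames(rnorm(length(pids), 0, config$alpha_sd),
                                        pids)
  if (is.null(gamma)) gamma <- setNames(rnorm(length(pids), 0, config$gamma_sd),
                                        pids)
  theta <- setNames(bank$theta_mem, bank$item_id)
  phi <- setNames(bank$phi_fa, bank$item_id)

  ii <- as.character(streams$item_id)
  pp <- as.character(streams$participant_id)
  is_repeat <- streams$role %in% c("target_repeat", "filler_repeat")
  eta <- ifelse(is_repeat, alpha[pp] + theta[ii], gamma[pp] + phi[ii])
  streams$pressed <- runif(nrow(streams)) < inv_logit(eta)
  streams
}

#' Simulate the rating phase
#'
#' Each participant rates every item on a continuous 0-10 slider: the latent
#' population mean `mu_value` plus participant-by-item Gaussian noise, clipped
#' to the scale (slider values are retained as continuous, not rounded).
#'
#' @param bank an item bank.
#' @param n_participants number of raters.
#' @param noise_sd Gaussian noise SD on the 0-10 scale (>= 0).
#' @param seed integer seed.
#' @return a long `data.frame` with `participant_id`, `item_id`, `rating`.
#' @export
#' @examples
#' bank <- make_item_bank(cohort_config(n_items = 10, seed = 1))
#' r <- simulate_ratings(bank, n_participants = 3, noise_sd = 1, seed = 2)
#' range(r$rating)
simulate_ratings <- function(bank, n_participants, noise_sd = 1.5, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  n_i <- nrow(bank)
  out <- data.frame(
    participant_id = rep(seq_len(n_participants), each = n_i),
    item_id = rep(bank$item_id, n_participants),
    rating = clip(rep(bank$mu_value, n_participants) +
                    rnorm(n_i * n_participants, 0, noise_sd), 0, 10)
  )
  attr(out, "seed") <- seed
  out
}

#' Simulate choice outcomes and reaction times
#'
#' Generates choices and RTs for assembled choice trials under either backend:
#'
#' * **logistic**: choose-right is Bernoulli with log-odds
#'   `beta0 + beta_value * delta_value + beta_mem * delta_mem` (by-subject
#'   Gaussian coefficient variation), and RT is lognormal with log-mean
#'   decreasing in `|delta_value|`.
#' * **ddm**: a Wiener diffusion first-passage simulation; drift
#'   `v = v0 + v_val * delta_value + v_mem * delta_mem + v_int *
#'   delta_value * delta_mem`, start point through an inverse-logit link, and
#'   the upper boundary coding "chose right".
#'
#' Draws slower than the 3 s deadline are recorded as no-response
#' (`choice = "none"`, missing RT), mirroring the task deadline; downstream
#' analyses drop them.
#'
#' @param trials a trial skeleton from [assemble_choice_trials()] (must carry
#'   `delta_value` and `delta_mem`).
#' @param params a [logistic_choice_params()] or [ddm_params()] object.
#' @param seed integer seed.
#' @return `trials` with `choice` ("left"/"right"/"none") and `rt_ms` filled.
#' @export
simulate_choices <- function(trials, params, seed = 1L) {
  need <- c("participant_id", "delta_value", "delta_mem")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop_data("trials missing covariates: ", paste(missing, collapse = ", "))
  }
  set.seed(seed)
  if (inherits(params, "logistic_choice_params")) {
    simulate_choices_logistic(trials, params)
  } else if (inherits(params, "ddm_params")) {
    simulate_choices_ddm(trials, params)
  } else {
    stop_data("params must be logistic_choice_params or ddm_params")
  }
}

simulate_choices_logistic <- function(trials, p) {
  pids <- unique(trials$participant_id)
  np <- length(pids)
  b0 <- setNames(rnorm(np, p$beta0, p$sd_beta0), pids)
  bv <- setNames(rnorm(np, p$beta_value, p$sd_beta_value), pids)
  bm <- setNames(rnorm(np, p$beta_mem, p$sd_beta_mem), pids)
  ri <- setNames(rnorm(np, 0, p$sd_rt_intercept), pids)
  id <- as.character(trials$participant_id)

  eta <- b0[id] + bv[id] * trials$delta_value + bm[id] * trials$delta_mem
  right <- runif(nrow(trials)) < inv_logit(eta)
  mlog <- p$rt_meanlog + ri[id] +
    p$rt_value_slope * abs(trials$delta_value) +
    p$rt_mem_slope * abs(trials$delta_mem)
  rt <- rlnorm(nrow(trials), mlog, p$rt_sdlog)

  timeout <- rt > p$deadline_s
  trials$choice <- ifelse(timeout, "none", ifelse(right, "right", "left"))
  trials$rt_ms <- ifelse(timeout, NA_real_, rt * 1000)
  trials
}

simulate_choices_ddm <- function(trials, p) {
  pids <- unique(trials$participant_id)
  vsub <- setNames(rnorm(length(pids), 0, p$sv_subject), pids)
  id <- as.character(trials$participant_id)
  inter <- trials$delta_value * trials$delta_mem
  v <- p$v0 + vsub[id] + p$v_val * trials$delta_value +
    p$v_mem * trials$delta_mem + p$v_int * inter
  z <- inv_logit(p$z0 + p$z_val * trials$delta_value +
                   p$z_mem * trials$delta_mem + p$z_int * inter)
  sim <- simulate_ddm(n = nrow(trials), a = p$a, v = v, z_rel = z,
                      t0 = p$t0, seed = sample.int(.Machine$integer.max, 1),
                      max_t = p$deadline_s)
  timeout <- is.na(sim$rt) | sim$rt > p$deadline_s
  trials$choice <- ifelse(timeout, "none",
                          ifelse(sim$upper, "right", "left"))
  trials$rt_ms <- ifelse(timeout, NA_real_, sim$rt * 1000)
  trials
}
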