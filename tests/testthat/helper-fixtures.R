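# shared fixture builders; everything is generated in code at test time

# hand-built item bank with chosen latents (bypasses the copula generator)
manual_bank <- function(theta, phi = rep(-2, length(theta)),
                        mu = rep(5, length(theta))) {
  bank <- data.frame(item_id = seq_along(theta),
                     name = sprintf("item_%03d", seq_along(theta)),
                     modality = "image",
                     theta_mem = theta, phi_fa = phi, mu_value = mu,
                     stringsAsFactors = FALSE)
  class(bank) <- c("item_bank", "data.frame")
  bank
}

# a small feasible stream design for fast cohorts
tiny_streams <- function(item_ids, n_participants, n_targets = 4,
                         n_fillers = 8, min_gap = 5, seed = 1) {
  build_streams(item_ids, n_participants, n_targets = n_targets,
                n_fillers = n_fillers, min_target_gap = min_gap,
                seed = seed)
}

# replicate one stream design across many participant ids (shared design,
# independent responses) -- cheap large-cohort recognition fixtures
replicate_stream <- function(stream, n_participants) {
  out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    s <- stream; s$participant_id <- p; s
  }))
  rownames(out) <- NULL
  out
}

# choice-trial skeleton with iid covariates (no pairing structure)
skeleton_trials <- function(n_participants, n_trials, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    participant_id = rep(seq_len(n_participants), each = n_trials),
    trial = rep(seq_len(n_trials), n_participants),
    delta_value = rnorm(n_participants * n_trials),
    delta_mem = rnorm(n_participants * n_trials))
  d$abs_delta_value <- abs(d$delta_value)
  d$abs_delta_mem <- abs(d$delta_mem)
  d$sum_mem <- rnorm(nrow(d))
  d
}

# deterministic trials with a chosen choice vector and constant RT
with_choices <- function(trials, choice, rt_ms = 800) {
  trials$choice <- choice
  trials$rt_ms <- ifelse(choice == "none", NA_real_, rt_ms)
  trials
}

# a small screened synthetic cohort ready for model fitting
small_cohort_trials <- function(n_participants = 20, n_items = 40,
                                params = logistic_choice_params(),
                                seed = 1) {
  cfg <- cohort_config(n_items = n_items,
                       n_mem_participants = 10,
                       n_choice_participants = n_participants,
                       mem_value_corr = 0, seed = seed)
  bank <- make_item_bank(cfg)
  mem_z <- setNames((bank$theta_mem - mean(bank$theta_mem)) /
                      sd(bank$theta_mem), bank$item_id)
  ratings <- zscore_ratings(simulate_ratings(bank, n_participants, 1.5,
                                             seed = seed + 1))
  ranks <- rank_items(ratings, seed = seed + 2)
  pairs <- build_choice_pairs(ranks)
  trials <- assemble_choice_trials(pairs, ratings, mem_z, seed = seed + 3)
  simulate_choices(trials, params, seed = seed + 4)
}
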