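# hand-built four-participant recognition log used in several tests
hand_log <- function() {
  mk <- function(p, target, filler, hit, fa) {
    data.frame(participant_id = p, trial_index = 0:3,
               item_id = c(target, filler, filler, target),
               role = c("target_first", "filler_first", "filler_repeat",
                        "target_repeat"),
               pressed = c(fa, FALSE, TRUE, hit))
  }
  rbind(mk(1, 1, 3, hit = TRUE,  fa = FALSE),
        mk(2, 1, 3, hit = FALSE, fa = TRUE),
        mk(3, 1, 3, hit = TRUE,  fa = FALSE),
        mk(4, 2, 3, hit = TRUE,  fa = FALSE))
}

test_that("memory exclusions catch non-performers and keep the boundary", {
  st <- tiny_streams(1:20, 1, n_targets = 4, n_fillers = 10, seed = 1)
  always <- st; always$pressed <- TRUE    # zero correct rejections
  never <- st; never$pressed <- FALSE     # zero hits
  ex_a <- exclude_memory_participants(always)
  ex_n <- exclude_memory_participants(never)
  expect_equal(ex_a$excluded, 1)
  expect_equal(ex_n$excluded, 1)

  # boundary: exactly 3 hits and exactly 3 correct rejections -> kept
  boundary <- st
  reps <- which(boundary$role == "target_repeat")
  firsts <- which(boundary$role %in% c("target_first", "filler_first"))
  boundary$pressed <- TRUE
  boundary$pressed[reps[4]] <- FALSE              # 3 of 4 hits
  boundary$pressed[firsts[seq_len(3)]] <- FALSE   # exactly 3 CRs
  ex_b <- exclude_memory_participants(boundary)
  expect_equal(ex_b$summary$n_hits, 3)
  expect_equal(ex_b$summary$n_correct_rejections, 3)
  expect_equal(ex_b$kept, 1)
})

test_that("corrected recognition matches hand arithmetic", {
  tab <- score_memorability(hand_log())
  expect_equal(tab$hit_rate[tab$item_id == 1], 2 / 3)
  expect_equal(tab$fa_rate[tab$item_id == 1], 1 / 3)
  expect_equal(tab$cr[tab$item_id == 1], 1 / 3)
  expect_equal(tab$cr[tab$item_id == 2], 1)
  expect_equal(tab$n_target_participants, c(3L, 1L))
  # identity holds exactly
  expect_equal(tab$cr, tab$hit_rate - tab$fa_rate)
})

test_that("items never assigned as target are flagged, not zeroed", {
  expect_warning(tab <- score_memorability(hand_log(), item_ids = 1:4),
                 "never assigned")
  expect_true(all(is.na(tab$cr[tab$item_id %in% 3:4])))
  expect_identical(attr(tab, "missing_items"), 3:4)
})

test_that("perfect memory gives CR 1; equal propensities give CR 0", {
  bank <- manual_bank(theta = rep(20, 12), phi = rep(-20, 12))
  st <- replicate_stream(tiny_streams(1:12, 1, n_targets = 3, n_fillers = 6,
                                      seed = 4), 30)
  cfg <- cohort_config(n_items = 12, n_mem_participants = 30,
                       n_choice_participants = 5, seed = 2)
  zero <- setNames(rep(0, 30), 1:30)
  resp <- simulate_recognition(bank, st, cfg, alpha = zero, gamma = zero)
  tab <- score_memorability(resp)
  expect_true(all(tab$cr == 1))

  # hit and false-alarm propensities equal -> expected CR 0
  bank0 <- manual_bank(theta = rep(0.3, 12), phi = rep(0.3, 12))
  st0 <- replicate_stream(tiny_streams(1:12, 1, n_targets = 3, n_fillers = 6,
                                       seed = 5), 1500)
  resp0 <- simulate_recognition(bank0, st0, cfg,
                                alpha = setNames(rep(0, 1500), 1:1500),
                                gamma = setNames(rep(0, 1500), 1:1500))
  tab0 <- score_memorability(resp0)
  expect_true(all(abs(tab0$cr) < 0.06))
})

test_that("hit rates converge to the marginalized inverse-logit mean", {
  theta <- c(1.5, 0.5, -0.5)
  bank <- manual_bank(theta = c(theta, rep(0, 9)))
  base <- tiny_streams(1:12, 1, n_targets = 3, n_fillers = 6, seed = 11)
  # force items 1:3 to be the targets by remapping ids
  tmap <- setNames(seq_len(12), c(unique(base$item_id[startsWith(base$role, "target")]),
                                  setdiff(base$item_id, base$item_id[startsWith(base$role, "target")])))
  base$item_id <- unname(tmap[as.character(base$item_id)])
  n <- 4000
  st <- replicate_stream(base, n)
  cfg <- cohort_config(n_items = 12, n_mem_participants = n,
                       n_choice_participants = 5, alpha_sd = 0.7, seed = 9)
  resp <- simulate_recognition(bank, st, cfg)
  tab <- score_memorability(resp)
  # law-of-large-numbers oracle: E[invlogit(alpha + theta)], alpha ~ N(0, .7)
  oracle <- vapply(theta, function(th) {
    integrate(function(a) plogis(a + th) * dnorm(a, 0, 0.7), -6, 6)$value
  }, numeric(1))
  got <- tab$hit_rate[match(1:3, tab$item_id)]
  expect_true(all(abs(got - oracle) < 0.02))
})

test_that("unknown item ids in a stream are a data error", {
  bank <- manual_bank(theta = rep(0, 4))
  st <- data.frame(participant_id = 1, trial_index = 0, item_id = 99,
                   role = "filler_first")
  cfg <- cohort_config(n_items = 4, n_mem_participants = 2,
                       n_choice_participants = 2, seed = 1)
  expect_error(simulate_recognition(bank, st, cfg), "unknown item_id")
})
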