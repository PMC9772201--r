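test_that("default streams satisfy every spacing invariant", {
  s <- build_stream(1:138, seed = 7)
  expect_s3_class(s, "recognition_stream")
  expect_equal(sum(s$role == "target_first"), 29)
  expect_equal(sum(s$role == "target_repeat"), 29)
  expect_equal(length(unique(s$item_id[startsWith(s$role, "filler")])), 109)
  # every target repeat comes more than 60 trials after its first showing
  tg <- s[startsWith(s$role, "target"), ]
  gaps <- tapply(tg$trial_index, tg$item_id, function(x) diff(sort(x)))
  expect_true(all(gaps >= 61))
  expect_silent(validate_stream(s))
})

test_that("minimal feasible design is constructed", {
  s <- build_stream(1:71, n_targets = 1, n_fillers = 70, min_target_gap = 61,
                    seed = 3)
  expect_silent(validate_stream(s, n_targets = 1, n_fillers = 70,
                                min_target_gap = 61))
})

test_that("infeasible constraints raise a construction error", {
  # 2 targets with a gap no stream of this length can hold
  expect_error(
    build_stream(1:10, n_targets = 2, n_fillers = 4, min_target_gap = 50,
                 filler_repeat_fraction = 0, seed = 1, max_retries = 25),
    "attempts")
})

test_that("filler repeat gaps always fall in the allowed window", {
  # exhaustive scan over many seeded streams
  for (seed in 1:150) {
    s <- build_stream(1:30, n_targets = 5, n_fillers = 20, min_target_gap = 8,
                      filler_gap_range = c(1L, 7L), seed = seed)
    fl <- s[startsWith(s$role, "filler"), ]
    rep_items <- fl$item_id[fl$role == "filler_repeat"]
    gaps <- vapply(rep_items, function(id) {
      diff(sort(fl$trial_index[fl$item_id == id]))
    }, numeric(1))
    expect_true(all(gaps >= 1 & gaps <= 7))
  }
})

test_that("validator catches violated invariants", {
  s <- build_stream(1:138, seed = 1)
  broken <- s
  # move a target repeat right after its first showing
  tg <- which(broken$role == "target_repeat")[1]
  first_idx <- broken$trial_index[broken$item_id == broken$item_id[tg] &
                                    broken$role == "target_first"]
  other <- which(broken$trial_index == first_idx + 1)
  tmp <- broken[tg, c("item_id", "role")]
  broken[tg, c("item_id", "role")] <- broken[other, c("item_id", "role")]
  broken[other, c("item_id", "role")] <- tmp
  expect_error(validate_stream(broken), "gap|pair|twice|expected")
})

test_that("target assignment balance has the exact expected mean", {
  st <- tiny_streams(1:20, 25, n_targets = 4, n_fillers = 10, seed = 2)
  counts <- assignment_balance(st, item_ids = 1:20)
  expect_equal(mean(counts), 25 * 4 / 20)

  # one participant: indicator counts summing to n_targets
  one <- tiny_streams(1:20, 1, n_targets = 4, n_fillers = 10, seed = 3)
  c1 <- assignment_balance(one, item_ids = 1:20)
  expect_true(all(c1 %in% 0:1))
  expect_equal(sum(c1), 4)
})

test_that("a balanced rotation design yields equal counts", {
  # constructed oracle: participant p gets targets {p, p+1, p+2} mod 9
  n <- 9
  streams <- do.call(rbind, lapply(seq_len(n), function(p) {
    targets <- ((p - 1) + 0:2) %% n + 1
    data.frame(participant_id = p, trial_index = 0:2,
               item_id = targets, role = "target_first")
  }))
  counts <- assignment_balance(streams, item_ids = 1:n)
  expect_true(all(counts == 3))
})
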