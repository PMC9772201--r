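#' Build one continuous-recognition stream
#'
#' Constructs the ordered presentation design for a single participant of the
#' continuous recognition task: a random subset of items become *targets*,
#' each shown twice with a long separation (more than 60 intervening-trial
#' positions by default), and the remaining *fillers* fill the gaps, a
#' configurable fraction of them repeating once after a short 1-7 trial
#' delay (attention probes). The construction places the target
#' first/repeat positions by rejection sampling under the gap constraint and
#' then schedules filler firsts and short-gap repeats over the free slots,
#' retrying the whole stream up to `max_retries` times.
#'
#' @param item_ids integer vector of available item ids.
#' @param participant_id participant label stored in the output.
#' @param n_targets number of target items (default 29).
#' @param n_fillers number of filler items (default 109).
#' @param min_target_gap minimum allowed `repeat - first` trial-index
#'   difference for targets (default 61, i.e. strictly more than 60 trials).
#' @param filler_gap_range length-2 integer vector of allowed filler repeat
#'   gaps (default `c(1, 7)`).
#' @param filler_repeat_fraction fraction of fillers that repeat (default 0.5).
#' @param seed integer seed.
#' @param max_retries rejection-sampling retry cap (default 1000).
#' @return a `data.frame` of class `recognition_stream` with columns
#'   `participant_id`, `trial_index` (0-based), `item_id`, `role` (one of
#'   `target_first`, `target_repeat`, `filler_first`, `filler_repeat`).
#' @export
#' @examples
#' s <- build_stream(1:138, participant_id = 1, seed = 2)
#' table(s$role)
build_stream <- function(item_ids, participant_id = 1L,
                         n_targets = 29L, n_fillers = 109L,
                         min_target_gap = 61L, filler_gap_range = c(1L, 7L),
                         filler_repeat_fraction = 0.5,
                         seed = 1L, max_retries = 1000L) {
  if (n_targets + n_fillers > length(item_ids)) {
    stop_data("n_targets + n_fillers exceeds the number of items")
  }
  set.seed(seed)
  n_rep <- round(filler_repeat_fraction * n_fillers)
  len <- 2L * n_targets + n_fillers + n_rep
  gmin <- filler_gap_range[1]; gmax <- filler_gap_range[2]

  for (attempt in seq_len(max_retries)) {
    chosen <- sample(item_ids, n_targets + n_fillers)
    targets <- chosen[seq_len(n_targets)]
    fillers <- chosen[-seq_len(n_targets)]

    pos <- sort(sample.int(len, 2L * n_targets))
    first <- pos[seq_len(n_targets)]
    second <- pos[n_targets + seq_len(n_targets)]
    if (any(second - first < min_target_gap)) next

    sched <- schedule_fillers(setdiff(seq_len(len), pos), fillers,
                              n_rep, gmin, gmax)
    if (is.null(sched)) next

    item <- integer(len); role <- character(len)
    perm <- sample.int(n_targets)  # random target-to-slot-pair assignment
    item[first] <- targets[perm];  role[first] <- "target_first"
    item[second] <- targets[perm]; role[second] <- "target_repeat"
    item[sched$slot] <- sched$item
    role[sched$slot] <- sched$role

    out <- data.frame(participant_id = participant_id,
                      trial_index = seq_len(len) - 1L,
                      item_id = item, role = role,
                      stringsAsFactors = FALSE)
    class(out) <- c("recognition_stream", "data.frame")
    validate_stream(out, n_targets = n_targets, n_fillers = n_fillers,
                    min_target_gap = min_target_gap,
                    filler_gap_range = filler_gap_range)
    return(out)
  }
  stop_data("could not construct a valid stream after ", max_retries,
            " attempts; constraints may be unsatisfiable")
}

# Schedule filler firsts and short-gap repeats over the ordered free slots.
# Returns NULL on a dead end (caller retries the whole stream).
schedule_fillers <- function(free, fillers, n_rep, gmin, gmax) {
  n_free <- length(free)
  repeaters <- c(sample(fillers, n_rep), rep(NA_integer_, 0))
  firsts <- sample(fillers)  # presentation order of first showings
  is_rep <- firsts %in% repeaters

  slot <- integer(n_free); item <- integer(n_free); role <- character(n_free)
  open_id <- integer(0); open_t <- integer(0)   # placed repeaters awaiting repeat
  fi <- 1L; k <- 0L

  for (si in seq_len(n_free)) {
    t <- free[si]
    if (length(open_t) && any(open_t + gmax < t)) return(NULL)  # window missed
    nxt <- if (si < n_free) free[si + 1L] else Inf
    eligible <- which(open_t + gmin <= t & open_t + gmax >= t)
    forced <- eligible[open_t[eligible] + gmax < nxt]
    k <- k + 1L; slot[k] <- t

    place_repeat <- function(j) {
      item[k] <<- open_id[j]; role[k] <<- "filler_repeat"
      open_id <<- open_id[-j]; open_t <<- open_t[-j]
    }
    if (length(forced) > 1L) return(NULL)
    if (length(forced) == 1L) {
      place_repeat(forced[1L])
    } else if (length(eligible) && (fi > length(firsts) || runif(1) < 0.6)) {
      place_repeat(sample(eligible, 1L))
    } else if (fi <= length(firsts)) {
      item[k] <- firsts[fi]; role[k] <- "filler_first"
      if (is_rep[fi]) { open_id <- c(open_id, firsts[fi]); open_t <- c(open_t, t) }
      fi <- fi + 1L
    } else {
      return(NULL)  # no firsts left and no eligible repeat
    }
  }
  if (length(open_id) || fi <= length(firsts)) return(NULL)
  list(slot = slot, item = item, role = role)
}

#' Validate a recognition stream
#'
#' Re-verifies every design invariant of a [build_stream()] output: role
#' vocabulary, exact target/filler counts, no item shown more than twice,
#' target first/repeat separation of at least `min_target_gap`, and filler
#' repeat gaps inside `filler_gap_range`.
#'
#' @inheritParams build_stream
#' @param stream a stream `data.frame` (one participant).
#' @return the stream, invisibly; errors with a message naming the violated
#'   invariant.
#' @export
validate_stream <- function(stream, n_targets = 29L, n_fillers = 109L,
                            min_target_gap = 61L,
                            filler_gap_range = c(1L, 7L)) {
  roles <- c("target_first", "target_repeat", "filler_first", "filler_repeat")
  if (!all(stream$role %in% roles)) stop_data("unknown role in stream")
  if (!identical(sort(stream$trial_index),
                 seq_len(nrow(stream)) - 1L)) {
    stop_data("trial_index must be 0..n-1 with no gaps")
  }
  stream <- stream[order(stream$trial_index), ]
  tab <- table(stream$item_id)
  if (any(tab > 2)) stop_data("an item appears more than twice")

  tg <- stream[startsWith(stream$role, "target"), ]
  if (length(unique(tg$item_id)) != n_targets) {
    stop_data("expected ", n_targets, " target items")
  }
  fl <- stream[startsWith(stream$role, "filler"), ]
  if (length(unique(fl$item_id)) != n_fillers) {
    stop_data("expected ", n_fillers, " filler items")
  }
  for (id in unique(tg$item_id)) {
    idx <- tg$trial_index[tg$item_id == id]
    rol <- tg$role[tg$item_id == id]
    if (length(idx) != 2L || !setequal(rol, c("target_first", "target_repeat"))) {
      stop_data("target item ", id, " lacks a first/repeat pair")
    }
    if (diff(sort(idx)) < min_target_gap) {
      stop_data("target item ", id, " repeat gap below ", min_target_gap)
    }
  }
  rep_items <- fl$item_id[fl$role == "filler_repeat"]
  for (id in rep_items) {
    idx <- sort(fl$trial_index[fl$item_id == id])
    if (length(idx) != 2L) stop_data("filler repeat without a first showing")
    g <- diff(idx)
    if (g < filler_gap_range[1] || g > filler_gap_range[2]) {
      stop_data("filler item ", id, " repeat gap ", g, " outside range")
    }
  }
  invisible(stream)
}

#' Build streams for a whole cohort
#'
#' Vectorized wrapper around [build_stream()]: one stream per participant,
#' with per-participant seeds derived from the root seed so any single stream
#' can be regenerated alone.
#'
#' @inheritParams build_stream
#' @param n_participants number of streams.
#' @return a single `data.frame` stacking all streams.
#' @export
build_streams <- function(item_ids, n_participants,
                          n_targets = 29L, n_fillers = 109L,
                          min_target_gap = 61L, filler_gap_range = c(1L, 7L),
                          filler_repeat_fraction = 0.5, seed = 1L) {
  out <- lapply(seq_len(n_participants), function(p) {
    build_stream(item_ids, participant_id = p, n_targets = n_targets,
                 n_fillers = n_fillers, min_target_gap = min_target_gap,
                 filler_gap_range = filler_gap_range,
                 filler_repeat_fraction = filler_repeat_fraction,
                 seed = substream_seed(seed, paste0("stream", p)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-item target-assignment balance
#'
#' Counts, for every item, how many participants had it assigned as a target.
#' With uniformly random assignment the mean count is exactly
#' `n_participants * n_targets / n_items`.
#'
#' @param streams stacked streams from [build_streams()].
#' @param item_ids the full item universe (defaults to the items appearing in
#'   `streams`).
#' @return named integer vector of per-item target counts over `item_ids`.
#' @export
assignment_balance <- function(streams, item_ids = NULL) {
  if (nrow(streams) == 0) stop_data("need at least one stream")
  if (is.null(item_ids)) item_ids <- sort(unique(streams$item_id))
  tf <- streams[streams$role == "target_first", ]
  counts <- table(factor(tf$item_id, levels = item_ids))
  setNames(as.integer(counts), as.character(item_ids))
}
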