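#' Z-score ratings within participant
#'
#' Standardizes each participant's ratings to mean 0, SD 1 (sample SD, n-1
#' denominator). A participant with zero rating variance gets `z_value = 0`
#' and is flagged in the `zero_variance` attribute — a candidate for
#' downstream exclusion rather than a hard error.
#'
#' @param ratings long `data.frame` with `participant_id`, `item_id`,
#'   `rating`.
#' @return the same table with a `z_value` column; flagged participants in
#'   `attr(, "zero_variance")`.
#' @export
#' @examples
#' r <- data.frame(participant_id = 1, item_id = 1:3, rating = c(0, 5, 10))
#' zscore_ratings(r)$z_value
zscore_ratings <- function(ratings) {
  sp <- split(ratings$rating, ratings$participant_id)
  flagged <- character(0)
  z <- lapply(names(sp), function(p) {
    x <- sp[[p]]
    s <- sd(x)
    if (is.na(s) || s == 0) {
      flagged <<- c(flagged, p)
      rep(0, length(x))
    } else (x - mean(x)) / s
  })
  ratings$z_value <- unsplit(setNames(z, names(sp)), ratings$participant_id)
  attr(ratings, "zero_variance") <- flagged
  ratings
}

#' Rank items by subjective value within participant
#'
#' Produces, for each participant, a strict total order of items by rated
#' value (rank 1 = highest value). Ties are broken uniformly at random with a
#' participant-scoped seed, so the same root seed reproduces the same
#' rankings participant by participant.
#'
#' @param ratings table with `z_value` (from [zscore_ratings()]).
#' @param seed integer root seed for tie-breaking.
#' @return `data.frame` with `participant_id`, `item_id`, `rank`.
#' @export
rank_items <- function(ratings, seed = 1L) {
  if (!"z_value" %in% names(ratings)) stop_data("run zscore_ratings() first")
  sp <- split(ratings, ratings$participant_id)
  out <- lapply(names(sp), function(p) {
    d <- sp[[p]]
    set.seed(substream_seed(seed, paste0("rank", p)))
    ord <- order(-d$z_value, runif(nrow(d)))
    data.frame(participant_id = d$participant_id[1],
               item_id = d$item_id[ord], rank = seq_len(nrow(d)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build close and far choice pairs from a ranking
#'
#' Implements the bespoke pair design: items with adjacent ranks (1-2, 3-4,
#' ...) form the *close* pairs, and the rank-k item is paired with the rank
#' `k + far_offset` item (default `n/2`, i.e. 1-70, 2-71, ... for 138 items)
#' to form the *far* pairs. For n items this yields n pairs — n/2 per type —
#' with every item appearing in exactly two pairs, once per type, and all
#' pairs distinct.
#'
#' @param ranking one participant's ranking (`item_id`, `rank`), or a
#'   multi-participant ranking table (pairs are built per participant).
#' @param far_offset rank distance of far pairs; defaults to `n/2`, the only
#'   offset that tiles an even item set into disjoint far pairs.
#' @return `data.frame` with `participant_id` (if present), `item_lo`,
#'   `item_hi` (the lower/higher-rank-number, i.e. higher/lower-valued item),
#'   `rank_lo`, `rank_hi`, `pair_type` ("close"/"far"), `rank_distance`.
#' @export
#' @examples
#' rk <- data.frame(item_id = 101:104, rank = 1:4)
#' build_choice_pairs(rk)
build_choice_pairs <- function(ranking, far_offset = NULL) {
  if ("participant_id" %in% names(ranking) &&
      length(unique(ranking$participant_id)) > 1) {
    return(build_choice_pairs_cohort(ranking, far_offset))
  }
  n <- nrow(ranking)
  if (n %% 2 != 0) stop_data("pair construction needs an even item count")
  if (is.null(far_offset)) far_offset <- n %/% 2
  if (far_offset < 1 || far_offset > n - 1) stop_data("invalid far_offset")
  item_of <- setNames(ranking$item_id, ranking$rank)
  half <- n %/% 2
  close <- data.frame(rank_lo = 2 * seq_len(half) - 1,
                      rank_hi = 2 * seq_len(half),
                      pair_type = "close")
  far <- data.frame(rank_lo = seq_len(n - far_offset),
                    rank_hi = seq_len(n - far_offset) + far_offset,
                    pair_type = "far")
  pairs <- rbind(close, far)
  pairs$item_lo <- unname(item_of[as.character(pairs$rank_lo)])
  pairs$item_hi <- unname(item_of[as.character(pairs$rank_hi)])
  pairs$rank_distance <- pairs$rank_hi - pairs$rank_lo
  if ("participant_id" %in% names(ranking)) {
    pairs <- cbind(participant_id = ranking$participant_id[1], pairs)
  }
  pairs[, intersect(c("participant_id", "item_lo", "item_hi", "rank_lo",
                      "rank_hi", "pair_type", "rank_distance"), names(pairs))]
}

# vectorized multi-participant pair construction: every participant shares
# the same rank pattern, so one template indexes all rankings at once
build_choice_pairs_cohort <- function(ranking, far_offset = NULL) {
  counts <- table(ranking$participant_id)
  n <- unname(counts[1])
  if (any(counts != n)) stop_data("participants differ in item count")
  if (n %% 2 != 0) stop_data("pair construction needs an even item count")
  if (is.null(far_offset)) far_offset <- n %/% 2
  if (far_offset < 1 || far_offset > n - 1) stop_data("invalid far_offset")

  ranking <- ranking[order(ranking$participant_id, ranking$rank), ]
  half <- n %/% 2
  rank_lo <- c(2 * seq_len(half) - 1, seq_len(n - far_offset))
  rank_hi <- c(2 * seq_len(half), seq_len(n - far_offset) + far_offset)
  ptype <- rep(c("close", "far"), c(half, n - far_offset))

  np <- length(counts)
  base <- rep((seq_len(np) - 1) * n, each = length(rank_lo))
  lo_idx <- base + rep(rank_lo, np)
  hi_idx <- base + rep(rank_hi, np)
  data.frame(
    participant_id = ranking$participant_id[lo_idx],
    item_lo = ranking$item_id[lo_idx],
    item_hi = ranking$item_id[hi_idx],
    rank_lo = rep(rank_lo, np),
    rank_hi = rep(rank_hi, np),
    pair_type = rep(ptype, np),
    rank_distance = rep(rank_hi - rank_lo, np),
    stringsAsFactors = FALSE)
}

#' Z-score memorability across items
#'
#' Memorability enters the choice analyses as a single z-scored vector over
#' the item set, computed once and shared by all participants.
#'
#' @param mem_table a [score_memorability()] table (or any table with
#'   `item_id` and `cr`).
#' @return named numeric vector of z-scored memorability by item id.
#' @export
zscore_memorability <- function(mem_table) {
  cr <- mem_table$cr
  if (anyNA(cr)) stop_data("memorability missing for some items")
  setNames((cr - mean(cr)) / sd(cr), mem_table$item_id)
}

#' Assemble choice trials with covariates
#'
#' Turns a participant's pairs into presentation-ready trials: trial order is
#' shuffled, left/right placement is Bernoulli(0.5), and the model covariates
#' are attached — `delta_value` (right minus left within-participant z-value),
#' `delta_mem` (right minus left across-item z-memorability), their absolute
#' versions, and `sum_mem` (the pair's summed z-memorability, side-invariant).
#'
#' @param pairs pair table from [build_choice_pairs()] (any participants).
#' @param ratings z-scored rating table from [zscore_ratings()].
#' @param mem_z named z-scored memorability vector from
#'   [zscore_memorability()].
#' @param seed integer root seed (participant-scoped substreams).
#' @return `data.frame` with one row per trial: `participant_id`, `trial`,
#'   `left_item`, `right_item`, `pair_type`, `delta_value`, `delta_mem`,
#'   `abs_delta_value`, `abs_delta_mem`, `sum_mem`, plus empty `choice`/
#'   `rt_ms` columns ready for [simulate_choices()] or observed data.
#' @export
assemble_choice_trials <- function(pairs, ratings, mem_z, seed = 1L) {
  miss <- setdiff(unique(c(pairs$item_lo, pairs$item_hi)), names(mem_z))
  if (length(miss)) {
    stop_data("memorability missing for item(s): ",
              paste(head(miss, 5), collapse = ", "))
  }
  # per-participant substreams for order and sides; all lookups vectorized
  sp_idx <- split(seq_len(nrow(pairs)), pairs$participant_id)
  new_order <- integer(nrow(pairs))
  lo_left <- logical(nrow(pairs))
  trial <- integer(nrow(pairs))
  pos <- 0L
  for (p in names(sp_idx)) {
    idx <- sp_idx[[p]]
    set.seed(substream_seed(seed, paste0("trials", p)))
    take <- idx[sample.int(length(idx))]
    rows <- pos + seq_along(idx)
    new_order[rows] <- take
    lo_left[rows] <- runif(length(idx)) < 0.5
    trial[rows] <- seq_along(idx)
    pos <- pos + length(idx)
  }
  d <- pairs[new_order, ]
  left <- ifelse(lo_left, d$item_lo, d$item_hi)
  right <- ifelse(lo_left, d$item_hi, d$item_lo)

  key <- paste(ratings$participant_id, ratings$item_id, sep = ":")
  zl <- ratings$z_value[match(paste(d$participant_id, left, sep = ":"), key)]
  zr <- ratings$z_value[match(paste(d$participant_id, right, sep = ":"), key)]
  ml <- unname(mem_z[match(left, names(mem_z))])
  mr <- unname(mem_z[match(right, names(mem_z))])

  res <- data.frame(participant_id = d$participant_id, trial = trial,
                    left_item = left, right_item = right,
                    pair_type = d$pair_type,
                    delta_value = zr - zl, delta_mem = mr - ml,
                    abs_delta_value = abs(zr - zl),
                    abs_delta_mem = abs(mr - ml),
                    sum_mem = mr + ml,
                    choice = NA_character_, rt_ms = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Median split on an absolute covariate difference
#'
#' Restricts trials to the half with the *lower* absolute covariate
#' difference, isolating the other covariate's effect. The median is pooled
#' across all responded trials of the sample (not per participant); trials
#' strictly below the median form the low half, and trials tied at the median
#' are assigned to it in stable trial order until the halves are as equal as
#' possible.
#'
#' @param trials trial table with responses (`choice` of "left"/"right"/
#'   "none"); no-response trials are dropped first.
#' @param variable `"abs_delta_mem"` or `"abs_delta_value"`.
#' @return the low-half subset of the responded trials.
#' @export
median_split <- function(trials,
                         variable = c("abs_delta_mem", "abs_delta_value")) {
  variable <- match.arg(variable)
  resp <- trials[!is.na(trials$choice) & trials$choice != "none", ]
  if (nrow(resp) < 2) stop_data("need at least 2 responded trials")
  x <- resp[[variable]]
  med <- median(x)
  low <- x < med
  target <- nrow(resp) %/% 2
  if (sum(low) < target) {
    ties <- which(x == med)
    take <- head(ties, target - sum(low))
    low[take] <- TRUE
  }
  resp[low, ]
}
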