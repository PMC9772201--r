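#' Apply the memory-task exclusion rule
#'
#' A participant is excluded when they produced fewer than 3 hits (presses on
#' target repeats) or fewer than 3 correct rejections. A correct rejection is
#' a no-press on any first presentation (target or filler), so the rule
#' catches both the never-presser (no hits) and the always-presser (no
#' correct rejections).
#'
#' @param responses streams with a `pressed` column
#'   (from [simulate_recognition()] or loaded logs).
#' @param min_hits,min_cr exclusion thresholds (default 3 each; participants
#'   with counts below the threshold are excluded, at-threshold kept).
#' @return list with `kept` and `excluded` participant-id vectors and a
#'   per-participant `summary` data.frame (hits, correct rejections).
#' @export
exclude_memory_participants <- function(responses, min_hits = 3L,
                                        min_cr = 3L) {
  if (!"pressed" %in% names(responses)) {
    stop_data("responses must carry a 'pressed' column aligned to the stream")
  }
  sp <- split(responses, responses$participant_id)
  summary <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      participant_id = d$participant_id[1],
      n_hits = sum(d$pressed & d$role == "target_repeat"),
      n_correct_rejections = sum(!d$pressed &
                                   d$role %in% c("target_first", "filler_first"))
    )
  }))
  rownames(summary) <- NULL
  summary$excluded <- summary$n_hits < min_hits |
    summary$n_correct_rejections < min_cr
  list(kept = summary$participant_id[!summary$excluded],
       excluded = summary$participant_id[summary$excluded],
       summary = summary)
}

#' Per-participant item memory outcomes
#'
#' Long table of the two scored binary outcomes per (participant, item-as-
#' target) pair: `hit` (pressed at the item's target repeat) and `fa` (pressed
#' at the item's first presentation). This is the resampling unit for
#' [split_half_consistency()] and the input to [score_memorability()].
#'
#' @param responses streams with `pressed`.
#' @param keep optional participant ids to retain (e.g. the kept set from
#'   [exclude_memory_participants()]).
#' @return `data.frame` with `participant_id`, `item_id`, `hit`, `fa`.
#' @export
participant_item_scores <- function(responses, keep = NULL) {
  if (!is.null(keep)) {
    responses <- responses[responses$participant_id %in% keep, ]
  }
  tr <- responses[responses$role == "target_repeat",
                  c("participant_id", "item_id", "pressed")]
  tf <- responses[responses$role == "target_first",
                  c("participant_id", "item_id", "pressed")]
  names(tr)[3] <- "hit"; names(tf)[3] <- "fa"
  m <- merge(tr, tf, by = c("participant_id", "item_id"))
  if (nrow(m) != nrow(tr)) {
    stop_data("misaligned logs: some target repeats lack a first presentation")
  }
  m$hit <- as.numeric(m$hit); m$fa <- as.numeric(m$fa)
  m[order(m$participant_id, m$item_id), ]
}

#' Score per-item memorability (corrected recognition)
#'
#' For each item, over the participants for whom it was a target: hit rate
#' (presses on its repeat), false-alarm rate (presses on its first showing),
#' and corrected recognition `cr = hit_rate - fa_rate`. Items never assigned
#' as a target for any retained participant are flagged as missing, never
#' silently scored zero.
#'
#' @param responses streams with `pressed`, or a table already produced by
#'   [participant_item_scores()].
#' @param keep optional participant ids to retain.
#' @param item_ids full item universe for missing-item reporting (defaults to
#'   items observed as targets).
#' @return a `data.frame` of class `memorability_table` with `item_id`,
#'   `hit_rate`, `fa_rate`, `cr`, `n_target_participants`; unscored items (if
#'   `item_ids` is wider) appear with `NA` scores and are listed in the
#'   `missing_items` attribute.
#' @export
score_memorability <- function(responses, keep = NULL, item_ids = NULL) {
  scores <- if (all(c("hit", "fa") %in% names(responses))) {
    if (!is.null(keep)) responses[responses$participant_id %in% keep, ]
    else responses
  } else {
    participant_item_scores(responses, keep)
  }
  if (nrow(scores) == 0) stop_data("no scored (participant, target) pairs")
  agg <- aggregate(cbind(hit, fa) ~ item_id, data = scores, FUN = mean)
  n <- aggregate(hit ~ item_id, data = scores, FUN = length)
  tab <- data.frame(item_id = agg$item_id,
                    hit_rate = agg$hit, fa_rate = agg$fa,
                    cr = agg$hit - agg$fa,
                    n_target_participants = n$hit)
  missing <- character(0)
  if (!is.null(item_ids)) {
    miss <- setdiff(item_ids, tab$item_id)
    if (length(miss)) {
      tab <- rbind(tab, data.frame(item_id = miss, hit_rate = NA_real_,
                                   fa_rate = NA_real_, cr = NA_real_,
                                   n_target_participants = 0L))
      missing <- miss
      warning(length(miss), " item(s) never assigned as target; flagged NA",
              call. = FALSE)
    }
  }
  tab <- tab[order(tab$item_id), ]
  rownames(tab) <- NULL
  attr(tab, "missing_items") <- missing
  class(tab) <- c("memorability_table", "data.frame")
  tab
}

#' @export
print.memorability_table <- function(x, ...) {
  cat(sprintf("<memorability_table> %d items, median CR = %.2f (range %.2f to %.2f)\n",
              nrow(x), median(x$cr, na.rm = TRUE), min(x$cr, na.rm = TRUE),
              max(x$cr, na.rm = TRUE)))
  NextMethod()
}
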