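#' Split-half consistency of memorability scores
#'
#' Measures whether different observers remember and forget the same items.
#' On each of `n_iter` iterations, participants are split into two random
#' disjoint halves, per-item corrected recognition is computed within each
#' half, and the Spearman rank correlation across items between halves is
#' recorded. The permuted-chance distribution relabels items within each
#' participant (the exchangeable no-item-signal null) and recomputes the
#' *mean* split-half rho with the identical procedure, once per permuted
#' dataset; the permutation p-value uses the add-one estimator
#' `p = (1 + #\{null means >= mean_rho\}) / (n_null + 1)`.
#'
#' Items unscored in one half of an iteration (never a target for that half)
#' are dropped pairwise for that iteration and counted in `n_dropped`.
#'
#' @param scores per-participant item outcomes from
#'   [participant_item_scores()].
#' @param n_iter number of random splits for the observed statistic
#'   (default 1000).
#' @param n_null number of permuted datasets in the chance distribution
#'   (default `n_iter`); each contributes one *mean* split-half rho computed
#'   with the identical procedure, so the null draws are distributed like the
#'   observed statistic under no item signal (a single-shuffle null would be
#'   far more dispersed than a mean over iterations and the p-value would
#'   not be calibrated).
#' @param seed integer seed.
#' @return an object of class `consistency_result`: list with `mean_rho`,
#'   `rhos`, `null_rhos` (one mean per permuted dataset), `p_value`,
#'   `n_iterations`, `n_dropped`.
#' @export
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_items = 30, n_mem_participants = 40, seed = 1)
#' bank <- make_item_bank(cfg)
#' st <- build_streams(bank$item_id, 40, n_targets = 8, n_fillers = 20,
#'                     min_target_gap = 10, seed = 1)
#' resp <- simulate_recognition(bank, st, cfg)
#' sc <- participant_item_scores(resp)
#' split_half_consistency(sc, n_iter = 50, seed = 2)$mean_rho
#' }
split_half_consistency <- function(scores, n_iter = 1000L, n_null = n_iter,
                                   seed = 1L) {
  pids <- unique(scores$participant_id)
  if (length(pids) < 4) stop_data("need at least 4 participants")
  set.seed(seed)
  m <- score_matrices(scores)
  obs <- mean_split_rho(m$H, m$FA, n_iter)
  nulls <- vapply(seq_len(n_null), function(k) {
    p <- permute_items_within(m$H, m$FA)
    mean_split_rho(p$H, p$FA, n_iter)$mean
  }, numeric(1))
  p <- (1 + sum(nulls >= obs$mean)) / (n_null + 1)
  structure(list(mean_rho = obs$mean, rhos = obs$rhos, null_rhos = nulls,
                 p_value = p, n_iterations = n_iter, n_dropped = obs$dropped),
            class = "consistency_result")
}

# participants x items hit/fa matrices; NA where an item was not scored
score_matrices <- function(scores) {
  pids <- unique(scores$participant_id)
  items <- sort(unique(scores$item_id))
  H <- matrix(NA_real_, length(pids), length(items),
              dimnames = list(pids, items))
  FA <- H
  pi <- match(scores$participant_id, pids)
  ii <- match(scores$item_id, items)
  H[cbind(pi, ii)] <- scores$hit
  FA[cbind(pi, ii)] <- scores$fa
  list(H = H, FA = FA)
}

# mean Spearman correlation of per-half item CRs over random disjoint splits;
# all splits are materialized as one indicator matrix so the per-half sums
# are two BLAS multiplies
mean_split_rho <- function(H, FA, n_iter) {
  np <- nrow(H); h1n <- np %/% 2L
  scored <- 1 * !is.na(H)
  D <- ifelse(is.na(H), 0, H - FA)
  S <- matrix(0, n_iter, np)
  for (it in seq_len(n_iter)) S[it, sample.int(np, h1n)] <- 1
  cr1 <- (S %*% D) / (S %*% scored)
  cr2 <- ((1 - S) %*% D) / ((1 - S) %*% scored)
  rhos <- numeric(n_iter); dropped <- 0L
  for (it in seq_len(n_iter)) {
    ok <- is.finite(cr1[it, ]) & is.finite(cr2[it, ])
    dropped <- dropped + sum(!ok)
    rhos[it] <- spearman(cr1[it, ok], cr2[it, ok])
  }
  list(mean = mean(rhos, na.rm = TRUE), rhos = rhos, dropped = dropped)
}

# relabel items within each participant (the exchangeable no-signal null)
permute_items_within <- function(H, FA) {
  for (r in seq_len(nrow(H))) {
    idx <- which(!is.na(H[r, ]))
    if (length(idx) > 1) {
      to <- sample(idx)
      H[r, to] <- H[r, idx]
      FA[r, to] <- FA[r, idx]
    }
  }
  list(H = H, FA = FA)
}

# one random disjoint split -> per-item CR for each half
half_crs <- function(scores, pids) {
  perm <- sample(pids)
  h1 <- perm[seq_len(floor(length(pids) / 2))]
  in1 <- scores$participant_id %in% h1
  cr_by_item <- function(d) {
    agg <- aggregate(cbind(hit, fa) ~ item_id, data = d, FUN = mean)
    setNames(agg$hit - agg$fa, agg$item_id)
  }
  c1 <- cr_by_item(scores[in1, ]); c2 <- cr_by_item(scores[!in1, ])
  items <- union(names(c1), names(c2))
  list(item_id = items, cr1 = c1[items], cr2 = c2[items])
}

spearman <- function(x, y) {
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(rank(x), rank(y))  # average ranks for ties
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf(
    "<consistency_result> mean Spearman rho = %.3f over %d splits, p = %.4g\n",
    x$mean_rho, x$n_iterations, x$p_value))
  if (x$n_dropped > 0) {
    cat(sprintf("  (%d item-iterations dropped pairwise)\n", x$n_dropped))
  }
  invisible(x)
}

#' Ranked consistency curve
#'
#' Plot-ready aggregation of the split-half procedure: on each iteration,
#' items are ranked by the first half's CR; the curve reports, per rank, the
#' mean CR of the first half, the second half, and a label-shuffled null of
#' the second half, averaged over iterations. A rising second-half curve
#' against a flat null visualizes cross-observer consistency.
#'
#' @inheritParams split_half_consistency
#' @return a `data.frame` with `rank`, `group1_mean`, `group2_mean`,
#'   `null_mean`.
#' @export
rank_consistency_curve <- function(scores, n_iter = 1000L, seed = 1L) {
  pids <- unique(scores$participant_id)
  if (length(pids) < 4) stop_data("need at least 4 participants")
  set.seed(seed)
  acc <- NULL; cnt <- NULL
  for (it in seq_len(n_iter)) {
    half <- half_crs(scores, pids)
    ok <- complete.cases(half$cr1, half$cr2)
    c1 <- half$cr1[ok]; c2 <- half$cr2[ok]
    ord <- order(c1)
    m <- cbind(g1 = c1[ord], g2 = c2[ord], null = sample(c2)[ord])
    k <- nrow(m)
    if (is.null(acc) || nrow(acc) < k) {
      pad <- function(a) rbind(a, matrix(0, k - nrow(a %||% m[0, , drop = FALSE]),
                                         3, dimnames = list(NULL, colnames(m))))
      acc <- if (is.null(acc)) matrix(0, k, 3, dimnames = list(NULL, colnames(m))) else pad(acc)
      cnt <- c(cnt, rep(0, k - length(cnt)))
    }
    acc[seq_len(k), ] <- acc[seq_len(k), ] + m
    cnt[seq_len(k)] <- cnt[seq_len(k)] + 1
  }
  data.frame(rank = seq_len(nrow(acc)),
             group1_mean = acc[, "g1"] / cnt,
             group2_mean = acc[, "g2"] / cnt,
             null_mean = acc[, "null"] / cnt)
}
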