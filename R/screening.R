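#' Side-bias exclusion flags
#'
#' A participant is excluded when their probability of choosing the
#' right-hand item lies strictly more than 2 sample SDs (over participants)
#' from the cohort mean. Computed in a single pass on the full cohort; if the
#' cohort SD is zero nobody is excluded. No-response trials are dropped from
#' the denominator.
#'
#' @param trials responded choice-trial table for the full cohort.
#' @return `data.frame` with `participant_id`, `p_right`,
#'   `side_bias_excluded`.
#' @export
side_bias_filter <- function(trials) {
  resp <- responded(trials)
  pids <- unique(resp$participant_id)
  if (length(pids) < 3) stop_data("need at least 3 participants")
  pr <- vapply(split(resp$choice, resp$participant_id),
               function(ch) mean(ch == "right"), numeric(1))
  m <- mean(pr); s <- sd(pr)
  flag <- if (is.na(s) || s == 0) rep(FALSE, length(pr)) else abs(pr - m) > 2 * s
  data.frame(participant_id = names(pr), p_right = unname(pr),
             side_bias_excluded = unname(flag), stringsAsFactors = FALSE)
}

#' Fast-RT exclusion flags
#'
#' A participant is excluded when the proportion of their responded trials
#' with RT below `threshold_ms` strictly exceeds `fraction` ("less than
#' 300 ms in more than half of the trials").
#'
#' @param trials choice-trial table with `rt_ms`.
#' @param threshold_ms fast-trial cutoff (default 300).
#' @param fraction exclusion fraction (default 0.5, strict inequality).
#' @return `data.frame` with `participant_id`, `p_fast`, `fast_rt_excluded`.
#' @export
fast_rt_filter <- function(trials, threshold_ms = 300, fraction = 0.5) {
  resp <- responded(trials)
  pf <- vapply(split(resp$rt_ms, resp$participant_id),
               function(rt) mean(rt < threshold_ms), numeric(1))
  data.frame(participant_id = names(pf), p_fast = unname(pf),
             fast_rt_excluded = unname(pf > fraction),
             stringsAsFactors = FALSE)
}

#' Value-sanity exclusion flags
#'
#' Fits, per participant, a simple logistic regression of choosing the
#' right-hand item on `delta_value` (intercept + slope). A participant is
#' excluded when the slope is non-positive or its Wald p-value is >= `alpha`:
#' such participants' stated values do not track their choices. Perfect
#' separation (a perfectly value-consistent chooser) is detected and resolved
#' by the data direction: a positive-direction separated fit is kept, with
#' the p-value treated as below `alpha`. Non-convergent fits are flagged and
#' treated as excluded.
#'
#' @param trials choice-trial table with `delta_value`.
#' @param alpha significance cutoff for the Wald test (default 0.05).
#' @param min_trials minimum responded trials required per participant
#'   (default 10).
#' @return `data.frame` with `participant_id`, `value_slope`, `value_p`,
#'   `separated`, `value_sanity_excluded`.
#' @export
value_sanity_filter <- function(trials, alpha = 0.05, min_trials = 10L) {
  resp <- responded(trials)
  out <- lapply(split(resp, resp$participant_id), function(d) {
    if (nrow(d) < min_trials) {
      stop_data("participant ", d$participant_id[1], " has fewer than ",
                min_trials, " responded trials")
    }
    y <- as.integer(d$choice == "right")
    fit <- tryCatch(
      suppressWarnings(glm.fit(cbind(1, d$delta_value), y,
                               family = binomial())),
      error = function(e) NULL)
    slope <- if (is.null(fit)) NA_real_ else fit$coefficients[2]
    if (is.null(fit) || is.na(slope)) {
      return(data.frame(participant_id = d$participant_id[1],
                        value_slope = NA_real_, value_p = NA_real_,
                        separated = FALSE, value_sanity_excluded = TRUE))
    }
    # perfect separation: IRLS hits the iteration cap with fitted values at
    # the boundary; glm flags converged = FALSE there too
    sep <- abs(slope) > 12 || max(abs(fit$fitted.values - 0.5)) > 0.4999 ||
      !fit$converged
    if (sep) {
      # direction from the data, p treated as significant
      dir <- sign(cor(d$delta_value, y))
      return(data.frame(participant_id = d$participant_id[1],
                        value_slope = unname(slope), value_p = 0,
                        separated = TRUE,
                        value_sanity_excluded = dir <= 0))
    }
    # Wald z from the unscaled IRLS covariance (binomial dispersion 1)
    p1 <- seq_len(fit$rank)
    se <- sqrt(diag(chol2inv(fit$qr$qr[p1, p1, drop = FALSE])))[2]
    p <- 2 * pnorm(-abs(slope / se))
    data.frame(participant_id = d$participant_id[1],
               value_slope = unname(slope), value_p = unname(p),
               separated = FALSE,
               value_sanity_excluded = slope <= 0 || p >= alpha)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full choice-phase screening report
#'
#' Applies the three exclusion criteria — side bias, fast RT, value sanity —
#' each computed on the full cohort in one pass, and combines them: a
#' participant is kept iff no criterion flags them.
#'
#' @inheritParams value_sanity_filter
#' @param threshold_ms,fraction fast-RT parameters.
#' @return an object of class `screening_report`: a `data.frame` with all
#'   per-criterion columns plus `kept`.
#' @export
#' @examples
#' \donttest{
#' # see vignette for a full worked example
#' }
screen_participants <- function(trials, threshold_ms = 300, fraction = 0.5,
                                alpha = 0.05, min_trials = 10L) {
  sb <- side_bias_filter(trials)
  fr <- fast_rt_filter(trials, threshold_ms, fraction)
  vs <- value_sanity_filter(trials, alpha, min_trials)
  rep <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                list(sb, fr, vs))
  rep$kept <- !(rep$side_bias_excluded | rep$fast_rt_excluded |
                  rep$value_sanity_excluded)
  class(rep) <- c("screening_report", "data.frame")
  rep
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "<screening_report> %d participants: %d side-bias, %d fast-RT, %d value-sanity excluded; %d kept\n",
    nrow(x), sum(x$side_bias_excluded), sum(x$fast_rt_excluded),
    sum(x$value_sanity_excluded), sum(x$kept)))
  invisible(x)
}

responded <- function(trials) {
  if (!"choice" %in% names(trials)) stop_data("trials lack a 'choice' column")
  trials[!is.na(trials$choice) & trials$choice != "none", ]
}
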