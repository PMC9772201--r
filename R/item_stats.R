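#' Item-level correlation report
#'
#' Pearson correlation (with `df = n - 2` and two-sided p) between two
#' aligned per-item vectors — e.g. memorability scores against mean
#' subjective value, representativeness, or external per-item predictions —
#' optionally with the Spearman rank correlation alongside.
#'
#' @param x,y aligned numeric item vectors.
#' @param labels optional length-2 character vector naming the two measures.
#' @param spearman also report the Spearman correlation (default `TRUE`).
#' @return `data.frame` with `measure_x`, `measure_y`, `r`, `df`, `p`, and
#'   optionally `rho`, `rho_p`.
#' @export
#' @examples
#' item_level_correlations(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
item_level_correlations <- function(x, y, labels = c("x", "y"),
                                    spearman = TRUE) {
  if (length(x) != length(y)) stop_data("item vectors differ in length")
  ok <- complete.cases(x, y)
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  out <- data.frame(measure_x = labels[1], measure_y = labels[2],
                    r = unname(ct$estimate), df = unname(ct$parameter),
                    p = ct$p.value)
  if (spearman) {
    st <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    out$rho <- unname(st$estimate)
    out$rho_p <- st$p.value
  }
  out
}

#' Per-item representativeness scores
#'
#' Standardizes each participant's ratings across items (sample SD) and
#' averages the z-scores per item across participants. Constant raters are
#' flagged and contribute zeros, matching [zscore_ratings()].
#'
#' @param ratings long table with `participant_id`, `item_id`, `rating`.
#' @return named numeric vector of per-item mean z-scores; flagged raters in
#'   `attr(, "zero_variance")`.
#' @export
representativeness_scores <- function(ratings) {
  z <- zscore_ratings(ratings)
  agg <- aggregate(z_value ~ item_id, data = z, FUN = mean)
  out <- setNames(agg$z_value, agg$item_id)
  attr(out, "zero_variance") <- attr(z, "zero_variance")
  out
}

#' Binned trial summary for figure tables
#'
#' Bins trials into `n_bins` equal-count bins by the x covariate (pooled
#' quantile ranks), then summarizes y within each bin by averaging within
#' participant first and across participants second; the SEM is across
#' participants. This is the aggregation behind the binned descriptive
#' figures.
#'
#' @param trials responded trial table.
#' @param x,y column names of the binning covariate and the outcome.
#' @param n_bins number of equal-count bins (default 5).
#' @return `data.frame` with `bin`, `x_mean`, `y_mean`, `sem`,
#'   `n_participants`.
#' @export
binned_summary <- function(trials, x, y, n_bins = 5L) {
  d <- responded(trials)
  d <- d[!is.na(d[[y]]), ]
  if (nrow(d) < n_bins) stop_data("fewer trials than bins")
  r <- rank(d[[x]], ties.method = "first")
  d$.bin <- ceiling(r / (nrow(d) / n_bins))
  d$.bin <- pmin(d$.bin, n_bins)
  per_part <- aggregate(d[, c(x, y)],
                        by = list(bin = d$.bin,
                                  participant_id = d$participant_id),
                        FUN = mean)
  out <- do.call(rbind, lapply(split(per_part, per_part$bin), function(b) {
    data.frame(bin = b$bin[1],
               x_mean = mean(b[[x]]),
               y_mean = mean(b[[y]]),
               sem = sd(b[[y]]) / sqrt(nrow(b)),
               n_participants = nrow(b))
  }))
  rownames(out) <- NULL
  out
}
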