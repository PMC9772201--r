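#' Generate a synthetic item bank
#'
#' Draws per-item latent ground truth: a logit-scale hit propensity
#' (`theta_mem`), a logit-scale false-alarm propensity (`phi_fa`) and a
#' population-mean subjective value (`mu_value`, on the 0-10 rating scale).
#' `theta_mem` and `mu_value` are coupled through a Gaussian copula whose
#' parameter is rescaled (by a numerically integrated attenuation factor) so
#' that the *Pearson* correlation of the two marginals matches
#' `config$mem_value_corr` in expectation. The memorability marginal family
#' is configurable ("normal" or "logistic"); `mu_value` has a scaled
#' Beta(2, 2) marginal, a smooth unimodal density supported exactly on the
#' rating scale.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` of class `item_bank` with columns `item_id`, `name`,
#'   `modality`, `theta_mem`, `phi_fa`, `mu_value`.
#' @export
#' @examples
#' bank <- make_item_bank(cohort_config(n_items = 20, seed = 1))
#' head(bank)
make_item_bank <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_items < 4) stop("need at least 4 items", call. = FALSE)
  if (abs(config$mem_value_corr) > 1) {
    stop("mem_value_corr magnitude must not exceed 1", call. = FALSE)
  }
  n <- config$n_items
  set.seed(substream_seed(config$seed, "items"))

  # marginal transforms applied to standard-normal copula coordinates
  g_mem <- switch(config$mem_dist,
    normal   = function(z) config$theta_mean + config$theta_sd * z,
    logistic = function(z) config$theta_mean +
      config$theta_sd * sqrt(3) / pi * qlogis(pnorm(z))
  )
  g_val <- function(z) 10 * qbeta(pnorm(z), 2, 2)

  r <- copula_param(config$mem_value_corr, g_mem, g_val)
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)

  theta <- g_mem(z1)
  mu <- g_val(z2)
  phi <- rnorm(n, config$phi_mean, config$phi_sd)

  bank <- data.frame(
    item_id = seq_len(n),
    name = sprintf("item_%03d", seq_len(n)),
    modality = config$modality,
    theta_mem = theta,
    phi_fa = phi,
    mu_value = mu,
    stringsAsFactors = FALSE
  )
  validate_item_bank(bank)
  attr(bank, "seed") <- config$seed
  attr(bank, "config_hash") <- config_hash(config)
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' Validate an item bank
#'
#' Checks the item-bank invariants: unique item ids, finite latent
#' propensities, and population-mean values inside the 0-10 rating scale.
#'
#' @param bank a data.frame with `item_id`, `theta_mem`, `phi_fa`, `mu_value`.
#' @return the bank, invisibly; errors on violation.
#' @export
validate_item_bank <- function(bank) {
  req <- c("item_id", "theta_mem", "phi_fa", "mu_value")
  missing <- setdiff(req, names(bank))
  if (length(missing)) {
    stop_data("item bank missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(bank$item_id)) stop_data("item_ids must be unique")
  if (!all(is.finite(bank$theta_mem)) || !all(is.finite(bank$phi_fa))) {
    stop_data("latent propensities must be finite")
  }
  if (any(bank$mu_value < 0 | bank$mu_value > 10)) {
    stop_data("mu_value must lie in [0, 10]")
  }
  invisible(bank)
}

# Rescale a Gaussian-copula parameter so the Pearson correlation of the two
# transformed marginals hits the target. For monotone transforms g1, g2 of
# jointly normal (Z1, Z2) with corr r: corr(g1(Z1), g2(Z2)) = r * c1 * c2 /
# (s1 * s2) with ck = E[Z g_k(Z)] (Stein), sk = sd(g_k(Z)); invert for r.
copula_param <- function(target, g1, g2) {
  if (target == 0) return(0)
  m <- function(g) integrate(function(z) g(z) * dnorm(z), -8, 8)$value
  s <- function(g) sqrt(integrate(function(z) g(z)^2 * dnorm(z), -8, 8)$value -
                          m(g)^2)
  cg <- function(g) integrate(function(z) z * g(z) * dnorm(z), -8, 8)$value
  atten <- (cg(g1) / s(g1)) * (cg(g2) / s(g2))
  clip(target / atten, -1, 1)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d %s items\n", nrow(x), x$modality[1]))
  cat(sprintf("  theta_mem: mean %.2f sd %.2f | phi_fa: mean %.2f | mu_value: mean %.2f\n",
              mean(x$theta_mem), sd(x$theta_mem), mean(x$phi_fa),
              mean(x$mu_value)))
  NextMethod()
}
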