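#' Specify a conditional choice/RT model
#'
#' A small declarative description of one analysis model: the response, the
#' fixed effects (matching covariate columns of the trial table, `:` for
#' interactions), the by-subject random slopes (defaults to all fixed
#' effects, alongside a by-subject intercept), and an optional median-split
#' trial filter applied before fitting.
#'
#' @param response one of `"chose_higher_value"`, `"chose_more_memorable"`,
#'   `"chose_right"`, `"log_rt"`.
#' @param fixed character vector of fixed-effect terms, e.g.
#'   `c("abs_delta_value")` or `c("delta_value", "sum_mem",
#'   "delta_value:sum_mem")`.
#' @param random_slopes character vector of by-subject random slopes; must be
#'   a subset of `fixed` (every random slope has a matching fixed effect).
#' @param split_on optional `"abs_delta_mem"` or `"abs_delta_value"`: fit on
#'   the low half of a pooled [median_split()] on this covariate.
#' @param rt_transform for `log_rt`: `"log"` (natural log of RT in seconds,
#'   the default) or `"logit"` (logit of RT scaled by the 3 s deadline).
#' @return an object of class `model_spec`.
#' @export
#' @examples
#' model_spec("chose_more_memorable", "abs_delta_mem",
#'            split_on = "abs_delta_value")
model_spec <- function(response = c("chose_higher_value",
                                    "chose_more_memorable",
                                    "chose_right", "log_rt"),
                       fixed, random_slopes = fixed, split_on = NULL,
                       rt_transform = c("log", "logit")) {
  response <- match.arg(response)
  rt_transform <- match.arg(rt_transform)
  base <- unique(unlist(strsplit(fixed, ":", fixed = TRUE)))
  if (!all(random_slopes %in% fixed)) {
    stop("every random slope needs a matching fixed effect", call. = FALSE)
  }
  if (!is.null(split_on)) {
    split_on <- match.arg(split_on, c("abs_delta_mem", "abs_delta_value"))
  }
  structure(list(response = response, fixed = fixed,
                 random_slopes = random_slopes, base_covariates = base,
                 split_on = split_on, rt_transform = rt_transform),
            class = "model_spec")
}

# build the response vector; tie trials dropped for higher/memorable codings
build_response <- function(trials, response, rt_transform = "log") {
  switch(response,
    chose_right = {
      trials$.y <- as.integer(trials$choice == "right"); trials
    },
    chose_higher_value = {
      trials <- trials[trials$delta_value != 0, ]
      trials$.y <- as.integer((trials$choice == "right") ==
                                (trials$delta_value > 0))
      trials
    },
    chose_more_memorable = {
      trials <- trials[trials$delta_mem != 0, ]
      trials$.y <- as.integer((trials$choice == "right") ==
                                (trials$delta_mem > 0))
      trials
    },
    log_rt = {
      rt_s <- trials$rt_ms / 1000
      trials$.y <- if (rt_transform == "log") log(rt_s)
        else qlogis(clip(rt_s / 3, 1e-6, 1 - 1e-6))
      trials
    })
}

model_formula <- function(fixed, random_slopes) {
  rs <- if (length(random_slopes)) paste(random_slopes, collapse = " + ")
    else "1"
  stats::as.formula(paste0(
    ".y ~ ", paste(fixed, collapse = " + "),
    " + (1 + ", rs, " | participant_id)"))
}

#' Fit a repeated-measures mixed-effects logistic choice model
#'
#' Maximum-likelihood fit (Laplace approximation over the by-subject random
#' effects, unstructured random covariance) of a binary choice response on
#' trial covariates, with by-subject intercepts and random slopes. For each
#' fixed effect the odds ratio `exp(beta)` and its Wald 95% CI are reported,
#' and the p-value comes from a likelihood-ratio test against a refit without
#' that fixed effect (random structure retained). On a convergence failure
#' the model is refit with uncorrelated random effects, then with a random
#' intercept only, and the fallback is flagged in the result.
#'
#' @param trials responded choice trials (apply [median_split()] first for
#'   the conditional models, or pass a `model_spec` with `split_on`).
#' @param spec a [model_spec()] with a binary response; alternatively pass
#'   `response`/`fixed` directly.
#' @param response,fixed,random_slopes shortcut arguments when `spec` is not
#'   given.
#' @param control an optional [lme4::glmerControl()]; the default uses bobyqa.
#' @return an object of class `model_fit`: list with a `coefficients` table
#'   (`term`, `estimate`, `se`, `or`, `ci_lo`, `ci_hi`, `lrt_chisq`,
#'   `lrt_p`), `n_trials`, `n_participants`, `converged`, `fallback`, and the
#'   underlying lme4 `model`.
#' @export
fit_mixed_logistic <- function(trials, spec = NULL, response = NULL,
                               fixed = NULL, random_slopes = NULL,
                               control = NULL) {
  if (is.null(spec)) {
    spec <- model_spec(response, fixed, random_slopes %||% fixed)
  }
  if (spec$response == "log_rt") stop_data("use fit_mixed_linear for log_rt")
  d <- prepare_model_data(trials, spec)
  if (length(unique(d$participant_id)) < 2) {
    stop_data("need at least 2 participants")
  }
  if (nrow(d) < 20) stop_data("need at least 20 trials")
  control <- control %||% lme4::glmerControl(optimizer = "bobyqa")

  fit1 <- fit_glmer_fallback(model_formula(spec$fixed, spec$random_slopes),
                             d, control)
  coefs <- summarize_binomial_fit(fit1, spec, d, control)
  structure(list(coefficients = coefs,
                 n_trials = nrow(d),
                 n_participants = length(unique(d$participant_id)),
                 converged = fit1$converged, fallback = fit1$fallback,
                 spec = spec, family = "binomial", model = fit1$model),
            class = "model_fit")
}

#' Fit a mixed-effects linear model of transformed RT
#'
#' RTs are right-skewed, so the model is linear on log RT (natural log of
#' seconds; a logit-on-scaled-RT variant is available through the spec).
#' Fitting is by maximum likelihood (`REML = FALSE`) so that the per-term
#' likelihood-ratio tests are valid; betas carry Wald 95% CIs.
#'
#' @inheritParams fit_mixed_logistic
#' @return a `model_fit` (with `beta` in place of odds ratios).
#' @export
fit_mixed_linear <- function(trials, spec = NULL, response = "log_rt",
                             fixed = NULL, random_slopes = NULL) {
  if (is.null(spec)) {
    spec <- model_spec(response, fixed, random_slopes %||% fixed)
  }
  d <- prepare_model_data(trials, spec)
  if (length(unique(d$participant_id)) < 2) {
    stop_data("need at least 2 participants")
  }
  if (nrow(d) < 20) stop_data("need at least 20 trials")
  if (sd(d$.y) < 1e-12) stop_data("degenerate response: zero RT variance")

  form <- model_formula(spec$fixed, spec$random_slopes)
  fit <- lme4::lmer(form, data = d, REML = FALSE)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  terms <- setdiff(names(est), "(Intercept)")
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      ci_lo = unname(est - 1.96 * se),
                      ci_hi = unname(est + 1.96 * se),
                      lrt_chisq = NA_real_, lrt_p = NA_real_)
  for (tm in terms) {
    reduced <- setdiff(spec$fixed, tm)
    f0 <- model_formula(if (length(reduced)) reduced else "1",
                        spec$random_slopes)
    fit0 <- lme4::lmer(f0, data = d, REML = FALSE)
    lr <- as.numeric(2 * (logLik(fit) - logLik(fit0)))
    i <- coefs$term == tm
    coefs$lrt_chisq[i] <- lr
    coefs$lrt_p[i] <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  structure(list(coefficients = coefs, n_trials = nrow(d),
                 n_participants = length(unique(d$participant_id)),
                 converged = TRUE, fallback = "none",
                 spec = spec, family = "gaussian", model = fit),
            class = "model_fit")
}

prepare_model_data <- function(trials, spec) {
  d <- responded(trials)
  if (!is.null(spec$split_on)) d <- median_split(d, spec$split_on)
  d <- build_response(d, spec$response, spec$rt_transform)
  d$participant_id <- factor(d$participant_id)
  d
}

fit_glmer_fallback <- function(form, d, control) {
  try_fit <- function(f) {
    w <- character(0)
    m <- withCallingHandlers(
      tryCatch(lme4::glmer(f, data = d, family = binomial(), control = control),
               error = function(e) e),
      warning = function(wc) {
        w <<- c(w, conditionMessage(wc)); invokeRestart("muffleWarning")
      })
    list(model = m, warnings = w)
  }
  bad <- function(r) inherits(r$model, "error") ||
    any(grepl("failed to converge|Model failed", r$warnings))
  r <- try_fit(form)
  fallback <- "none"
  if (bad(r)) {
    fstr <- paste(deparse(form, width.cutoff = 500), collapse = " ")
    r2 <- try_fit(stats::as.formula(gsub(" \\| ", " || ", fstr)))
    if (!bad(r2)) {
      r <- r2; fallback <- "uncorrelated_re"
    } else {
      r3 <- try_fit(stats::as.formula(paste(
        sub("\\+ \\(.*\\)$", "", fstr), "+ (1 | participant_id)")))
      if (!inherits(r3$model, "error")) { r <- r3; fallback <- "intercept_only" }
    }
  }
  if (inherits(r$model, "error")) {
    stop_data("mixed logistic fit failed: ", conditionMessage(r$model))
  }
  list(model = r$model, converged = !bad(r) || fallback != "none",
       fallback = fallback, warnings = r$warnings)
}

summarize_binomial_fit <- function(fit1, spec, d, control) {
  m <- fit1$model
  est <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(vcov(m))))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      or = exp(unname(est)),
                      ci_lo = exp(unname(est - 1.96 * se)),
                      ci_hi = exp(unname(est + 1.96 * se)),
                      lrt_chisq = NA_real_, lrt_p = NA_real_)
  for (tm in setdiff(names(est), "(Intercept)")) {
    reduced <- setdiff(spec$fixed, tm)
    f0 <- model_formula(if (length(reduced)) reduced else "1",
                        spec$random_slopes)
    fit0 <- fit_glmer_fallback(f0, d, control)
    lr <- as.numeric(2 * (logLik(m) - logLik(fit0$model)))
    i <- coefs$term == tm
    coefs$lrt_chisq[i] <- lr
    coefs$lrt_p[i] <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  coefs
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s: %s ~ %s | %d trials, %d participants\n",
              x$family, x$spec$response,
              paste(x$spec$fixed, collapse = " + "),
              x$n_trials, x$n_participants))
  if (x$fallback != "none") cat("  fallback:", x$fallback, "\n")
  co <- x$coefficients
  if (x$family == "binomial") {
    for (i in seq_len(nrow(co))) {
      cat(sprintf("  %-22s OR = %.3f [%.3f, %.3f]%s\n", co$term[i], co$or[i],
                  co$ci_lo[i], co$ci_hi[i],
                  if (!is.na(co$lrt_p[i]))
                    sprintf(", LRT p = %.3g", co$lrt_p[i]) else ""))
    }
  } else {
    for (i in seq_len(nrow(co))) {
      cat(sprintf("  %-22s beta = %.4f [%.4f, %.4f]%s\n", co$term[i],
                  co$estimate[i], co$ci_lo[i], co$ci_hi[i],
                  if (!is.na(co$lrt_p[i]))
                    sprintf(", LRT p = %.3g", co$lrt_p[i]) else ""))
    }
  }
  invisible(x)
}
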