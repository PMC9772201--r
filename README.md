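# memchoice

Does stimulus memorability bias value-based choice? Some images are reliably
remembered and others reliably forgotten across observers — an intrinsic item
property captured by a *memorability score*, here corrected recognition
(CR = hit rate − false-alarm rate) from a continuous recognition task. If
memorable options are retrieved more readily, they might be chosen more often
even when they are not valued more. memchoice is an R package for running
that question end to end: it measures memorability, builds the bespoke choice
design, screens participants, and asks — with frequentist tests, Bayes
factors, power simulations, and a drift-diffusion decomposition — whether the
absolute memorability difference between two options (|Δmem|) predicts choice
once value differences (|Δvalue|) are controlled.

It is written for cognitive and decision scientists who want a tested,
reusable implementation of this analysis chain, either on synthetic cohorts
(everything is simulable under one seed) or on their own trial logs via a
documented CSV interchange schema.

## The models at the core

* **Memorability**: per-item CR over the participants who saw the item as a
  target; cross-observer consistency as the mean split-half Spearman ρ over
  1000 random halves against a label-shuffled permutation null.
* **Choice design**: items ranked by each participant's value ratings;
  close pairs join adjacent ranks, far pairs join rank k with rank k + n/2;
  sides randomized; covariates Δvalue (within-participant z), Δmem
  (across-item z of CR), |Δvalue|, |Δmem|, SumMem.
* **Conditional inference**: mixed-effects logistic models, e.g.
  `chose_more_memorable ~ |Δmem| + (1 + |Δmem| | participant)` on the
  low-|Δvalue| half of trials (pooled median split), Laplace ML fits, odds
  ratios with Wald 95% CIs, likelihood-ratio p-values; linear mixed models
  on log RT; Savage–Dickey BF01 for the point null with prior-width
  sensitivity; full-pipeline simulation-based power; per-participant Wiener
  first-passage (DDM) regressions of drift rate and start point on Δvalue
  and Δmem with group-level tests.
* **Synthetic cohorts**: latent item memorability and value joined by a
  Gaussian copula; recognition presses, 0–10 slider ratings, and choices
  (logistic or DDM backend) generated under named seed substreams.

## Worked example

Simulate the default cohort (138 items; 199 recognition participants with
29 targets and 109 fillers each; 44 choice participants with 138 pairs
each), score memorability, build and run the choice phase, screen, and fit
the two headline models:

```r
library(memchoice)
cfg <- cohort_config(seed = 11)
bank <- make_item_bank(cfg)

streams   <- build_streams(bank$item_id, cfg$n_mem_participants, seed = 5)
responses <- simulate_recognition(bank, streams, cfg)
kept_mem  <- exclude_memory_participants(responses)$kept
scores    <- participant_item_scores(responses, keep = kept_mem)
mem_table <- score_memorability(scores)
split_half_consistency(scores, n_iter = 1000, seed = 2)
#> <consistency_result> mean Spearman rho = 0.669 over 1000 splits, p = 0.000999

ratings <- zscore_ratings(simulate_ratings(bank, cfg$n_choice_participants,
                                           cfg$rating_noise_sd, seed = 9))
pairs   <- build_choice_pairs(rank_items(ratings, seed = 4))
trials  <- assemble_choice_trials(pairs, ratings,
                                  zscore_memorability(mem_table), seed = 6)
trials  <- simulate_choices(trials, logistic_choice_params(), seed = 7)

screening <- screen_participants(trials)
screening
#> <screening_report> 44 participants: 5 side-bias, 0 fast-RT, 0 value-sanity excluded; 39 kept
kept <- trials[trials$participant_id %in%
                 screening$participant_id[screening$kept], ]

fit_mixed_logistic(kept, model_spec("chose_higher_value", "abs_delta_value",
                                    split_on = "abs_delta_mem"))
#> <model_fit> binomial: chose_higher_value ~ abs_delta_value | 2622 trials, 39 participants
#>   (Intercept)            OR = 1.053 [0.937, 1.184]
#>   abs_delta_value        OR = 3.491 [2.935, 4.151], LRT p = 5.18e-18

fit_mixed_logistic(kept, model_spec("chose_more_memorable", "abs_delta_mem",
                                    split_on = "abs_delta_value"))
#> <model_fit> binomial: chose_more_memorable ~ abs_delta_mem | 2677 trials, 39 participants
#>   (Intercept)            OR = 1.019 [0.894, 1.161]
#>   abs_delta_mem          OR = 0.980 [0.894, 1.073], LRT p = 0.657

fit_mixed_linear(kept, model_spec("log_rt", "abs_delta_value",
                                  split_on = "abs_delta_mem"))
#> <model_fit> gaussian: log_rt ~ abs_delta_value | 2688 trials, 39 participants
#>   (Intercept)            beta = -0.0657 [-0.1104, -0.0210]
#>   abs_delta_value        beta = -0.0354 [-0.0515, -0.0192], LRT p = 3.43e-05
```

Reading the output: value differences strongly drive simulated choices
(odds of picking the higher-valued item multiply by ~3.5 per z-unit of
|Δvalue|) and speed them up (log-RT slope ≈ −0.035 per z-unit), while — in
this default null world where the generator gives memorability no causal
role — the |Δmem| odds ratio sits at ~0.98 with a CI straddling 1.
Memorability scores themselves are strongly consistent across random
participant halves (ρ = 0.67 over the whole simulated cohort).

`run_pipeline(pipeline_config(...), out_dir = "...")` orchestrates all of
the above (plus optional Bayes factors, power curves, and the DDM stage)
and writes CSV/JSON outputs with seed and config-hash provenance sidecars;
`inst/cli/memchoice.R` is a thin command-line wrapper around it.

## Package layout

* `R/` — generators (`cohort_config`, `make_item_bank`, `simulate_*`),
  recognition design and scoring (`build_stream`, `score_memorability`,
  `split_half_consistency`), choice design (`build_choice_pairs`,
  `assemble_choice_trials`, `median_split`), screening
  (`screen_participants`), inference (`fit_mixed_logistic`,
  `fit_mixed_linear`, `fit_bayesian_mixed_logistic`, `power_simulation`,
  `binned_summary`), DDM (`wfpt_density`, `simulate_ddm`,
  `fit_ddm_regression`), and orchestration (`run_pipeline`,
  `load_external_trials`).
* `src/` — the Euler–Maruyama path simulator (Rcpp).
* `vignettes/memorability-choice-methods.Rmd` — the models, design
  decisions, numerical choices, and what the synthetic cohorts do and do
  not capture.
* `tests/testthat/` — unit, property, and acceptance suites.
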