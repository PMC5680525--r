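#!/usr/bin/env Rscript
# Stage 4: geographic prevalence from term-query fractions.
#
# Two experiments. (a) On the stage-1 log: per-county fraction of users
# querying each target synonym, stepwise-regressed on the planted county
# prevalence. (b) A dedicated feature-level scenario (100 fine units,
# 13 candidate terms, 3 informative) fit at fine and coarse resolution,
# with the coarse model transferred to fine units — the cross-resolution
# question of whether survey data at one aggregation level can calibrate
# predictions at another.

suppressPackageStartupMessages({
  library(querysignal)
  library(data.table)
})

seed <- 20260917L
if (!file.exists("scratch/sim/query_log.tsv")) {
  stop("missing scratch/sim/query_log.tsv: run analysis/01_simulate.R first")
}

## (a) county-level fractions from the simulated log
log <- read_query_log("scratch/sim/query_log.tsv")
log <- filter_news(log, detect_news_texts(log))
ft <- build_geo_features(log, c("cannabis", "marijuana"), level = "county")
truth <- fread("scratch/sim/truth_users.csv")[, .(n = .N,
  prev = mean(is_exposed)), by = unit]
obs <- truth[, .(unit, observed_prevalence = prev)]
m_log <- fit_stepwise(ft, obs)
message(sprintf("log-based county model: R^2 = %.2f over %d counties (%s)",
                m_log$r_squared, m_log$n_units,
                paste(m_log$selected_terms, collapse = ", ")))
fwrite(merge(apply_model(m_log, ft), obs, by = "unit"),
       "results/04_county_predictions.csv")

## (b) fine/coarse scenario and cross-resolution transfer
sc <- generate_prevalence_scenario(n_units = 100, n_terms = 13,
                                   n_informative = 3, noise_frac = 0.1,
                                   n_coarse = 20, seed = seed)
fine <- fit_stepwise(sc$features, sc$observed)
coarse <- fit_stepwise(sc$coarse_features, sc$coarse_observed)
pred_fine <- apply_model(coarse, sc$features)
transfer <- evaluate_predictions(pred_fine$predicted,
                                 sc$observed$observed_prevalence)
r_truth <- cor(pred_fine$predicted, sc$truth$true_prevalence)

message(sprintf("fine model:   R^2 = %.2f (n=%d), terms: %s",
                fine$r_squared, fine$n_units,
                paste(fine$selected_terms, collapse = ", ")))
message(sprintf("coarse model: R^2 = %.2f (n=%d), terms: %s",
                coarse$r_squared, coarse$n_units,
                paste(coarse$selected_terms, collapse = ", ")))
message(sprintf("coarse model applied to fine units: r = %.2f vs observed, %.2f vs truth",
                transfer$pearson_r, r_truth))

out <- list(
  log_based = list(level = "county", r_squared = m_log$r_squared,
                   n_units = m_log$n_units,
                   selected_terms = m_log$selected_terms,
                   coefficients = as.list(m_log$coefficients),
                   intercept = m_log$intercept),
  fine = list(r_squared = fine$r_squared, n_units = fine$n_units,
              selected_terms = fine$selected_terms,
              informative_terms = sc$informative_terms),
  coarse = list(r_squared = coarse$r_squared, n_units = coarse$n_units,
                selected_terms = coarse$selected_terms),
  transfer = list(pearson_r_vs_observed = transfer$pearson_r,
                  r_squared_vs_observed = transfer$r_squared,
                  pearson_r_vs_truth = r_truth))
jsonlite::write_json(out, "results/04_prevalence.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
fwrite(pred_fine, "results/04_fine_predictions.csv")
message("wrote results/04_prevalence.json and prediction CSVs")
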