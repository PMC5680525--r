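#!/usr/bin/env Rscript
# Stage 5: temporal profiles of symptom queries relative to day 0.
#
# For each planted reaction, computes the lag-aligned share of ADR queries
# matching the concept (exposed users only), smooths it with a 7-day
# centered moving average, marks the 25% highest-activity days, and
# estimates the onset lag. The planted onsets are 0 (anxiety, overdose,
# paranoia), 5 (headache) and 40 days (cough).

suppressPackageStartupMessages({
  library(querysignal)
  library(data.table)
})

if (!file.exists("scratch/sim/day0_map.csv")) {
  stop("missing scratch/sim/day0_map.csv: run analysis/02_measures.R first")
}
log <- read_query_log("scratch/sim/query_log.tsv")
log <- filter_news(log, detect_news_texts(log))
lx <- lexicon(fread("scratch/sim/lexicon.csv"))
map <- fread("scratch/sim/day0_map.csv")
map[, day0 := as.Date(day0)]

planted <- fread("scratch/sim/truth_planted.csv")$concept
true_lags <- c(anxiety = 0, overdose = 0, paranoia = 0, headache = 5,
               cough = 40)

profiles <- list()
onsets <- data.table(adr_concept = planted, true_onset = true_lags[planted],
                     estimated_onset = NA_integer_)
for (cc in planted) {
  prof <- smooth_moving_average(
    temporal_profile(log, lx, map, cc, lag_min = -90, lag_max = 120))
  profiles[[cc]] <- prof
  onsets[adr_concept == cc,
         estimated_onset := estimate_onset(prof)]
}
write_profiles(profiles, "results/05_temporal_profiles.csv")
fwrite(onsets, "results/05_onsets.csv")

message("estimated onset lags (days since first target query):")
message(paste(sprintf("  %-10s true %2d  estimated %s", onsets$adr_concept,
                      onsets$true_onset, onsets$estimated_onset),
              collapse = "\n"))
message("wrote results/05_temporal_profiles.csv, results/05_onsets.csv")
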