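#!/usr/bin/env Rscript
# Stage 1: simulate a six-month query log with planted structure.
#
# Generates the study population: 10,000 users across 20 counties whose
# exposure prevalence spans 0.06-0.20, five planted adverse reactions
# (three immediate, one with 5-day onset, one with 40-day onset), a
# news-driven query spike, and a matching reference report set. The raw log
# is large and ephemeral, so it goes under scratch/; summary tables and the
# ground truth go under results/.

suppressPackageStartupMessages({
  library(querysignal)
  library(data.table)
})

seed <- 20260915L
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(
  seed = seed,
  news_events = list(list(text = "cannabis legalization vote news",
                          total = 12000, spike_days = 3)))
sim <- generate_query_log(cfg)
refset <- generate_reference_reports(cfg)

write_query_log(sim$log, "scratch/sim/query_log.tsv")
fwrite(as.data.table(sim$lexicon), "scratch/sim/lexicon.csv")
fwrite(sim$truth$day0_by_user, "scratch/sim/truth_day0.csv")
fwrite(sim$truth$user_units, "scratch/sim/truth_users.csv")
fwrite(data.table(concept = sim$truth$planted_adrs),
       "scratch/sim/truth_planted.csv")
write_reference_reports(refset, "scratch/sim/reference_reports.csv")

summary_tab <- data.table(
  quantity = c("users", "records", "exposed_users", "adr_concepts",
               "planted_adrs", "news_texts_injected", "seed"),
  value = c(cfg$n_users, nrow(sim$log), length(sim$truth$exposed_users),
            nrow(cfg$adr_specs), length(sim$truth$planted_adrs),
            length(cfg$news_events), seed))
fwrite(summary_tab, "results/01_simulation_summary.csv")

message(sprintf(
  "simulated %d records from %d users (%d exposed, %.1f%%); %d ADR concepts, %d planted",
  nrow(sim$log), cfg$n_users, length(sim$truth$exposed_users),
  100 * length(sim$truth$exposed_users) / cfg$n_users,
  nrow(cfg$adr_specs), length(sim$truth$planted_adrs)))
message("wrote scratch/sim/* and results/01_simulation_summary.csv")
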