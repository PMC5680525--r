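#!/usr/bin/env Rscript
# Stage 2: news filtering, day-0 anchoring, and the four association
# measures. Reads the stage-1 log, removes news-driven texts, anchors every
# user's timeline (pseudo-anchors for non-exposed users), builds the
# per-ADR contingency tables and writes the QR / QLRS / QPRR / PQR scores.

suppressPackageStartupMessages({
  library(querysignal)
  library(data.table)
})

seed <- 20260916L
if (!file.exists("scratch/sim/query_log.tsv")) {
  stop("missing scratch/sim/query_log.tsv: run analysis/01_simulate.R first")
}

log <- read_query_log("scratch/sim/query_log.tsv")
lx <- lexicon(fread("scratch/sim/lexicon.csv"))

news <- detect_news_texts(log)
filtered <- filter_news(log, news)
message(sprintf("news filter: %d text(s), %d of %d records removed",
                length(news), nrow(log) - nrow(filtered), nrow(log)))

map <- build_day0_map(filtered, lx, seed = seed)
write_day0_map(map, "scratch/sim/day0_map.csv")
message(sprintf("cohort: %d users, %d exposed", nrow(map),
                sum(map$is_exposed)))

# sanity: matcher recovers the planted exposure cohort exactly
truth <- fread("scratch/sim/truth_day0.csv")
stopifnot(setequal(map$user_id[map$is_exposed], truth$user_id))

measures <- compute_all_measures(filtered, lx, map)
write_measures(measures, "results/02_measures.csv")

top <- head(measures[order(-qlrs)], 10)
message("top ADR concepts by QLRS:")
message(paste(sprintf("  %-14s qlrs=%8.1f qr=%5.2f", top$adr_concept,
                      top$qlrs, top$qr), collapse = "\n"))
message("wrote scratch/sim/day0_map.csv, results/02_measures.csv")
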