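#!/usr/bin/env Rscript
# Stage 3: validation of the query-log measures against the reference
# report set. Labels likely reactions by top-95% report coverage, computes
# each measure's ROC AUC and Spearman correlation with report counts, and
# repeats the correlation after greedy exclusion of up to five outliers.

suppressPackageStartupMessages({
  library(querysignal)
  library(data.table)
})

if (!file.exists("results/02_measures.csv")) {
  stop("missing results/02_measures.csv: run analysis/02_measures.R first")
}
measures <- fread("results/02_measures.csv")
refset <- read_reference_reports("scratch/sim/reference_reports.csv")

n_eval <- sum(refset$report_count >= 1)
k <- min(5L, n_eval - 3L)
val <- validate_measures(measures, refset, coverage = 0.95, k = k)

message(sprintf("positives (top 95%% of %d reports): %s",
                sum(refset$report_count),
                paste(val$positives, collapse = ", ")))
for (m in names(val$auc_by_measure)) {
  message(sprintf("  %-5s AUC = %.2f  rho = %+.2f", m,
                  val$auc_by_measure[[m]], val$rho_by_measure[[m]]))
}
message(sprintf("qlrs rho after removing %d outliers (%s): %+.2f", k,
                paste(val$outliers, collapse = ", "),
                val$rho_path[length(val$rho_path)]))

planted <- fread("scratch/sim/truth_planted.csv")$concept
auc_truth <- as.numeric(roc_auc(setNames(measures$qlrs,
                                         measures$adr_concept), planted))
message(sprintf("QLRS AUC against the planted ground truth: %.2f", auc_truth))

out <- c(val[c("positives", "auc_by_measure", "rho_by_measure",
               "n_evaluated", "n_undefined_by_measure", "outlier_measure",
               "outliers", "rho_path")],
         list(auc_qlrs_vs_planted_truth = auc_truth))
jsonlite::write_json(out, "results/03_validation.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("wrote results/03_validation.json")
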