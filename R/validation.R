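#' Read an aggregated reference report set
#'
#' CSV with columns `adr_concept,report_count`, one row per concept —
#' spontaneous-report counts pre-aggregated to the lexicon's ADR concepts.
#'
#' @param path CSV path.
#' @return `data.table` with columns `adr_concept`, `report_count`.
#' @export
read_reference_reports <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  if (!all(c("adr_concept", "report_count") %in% names(df))) {
    stopf("reference report file needs columns adr_concept,report_count")
  }
  data.table::as.data.table(df)
}

#' Label likely ADRs from a reference report set
#'
#' Concepts are sorted by report count descending (ties broken
#' lexicographically by concept id) and the minimal prefix whose cumulative
#' report count reaches `coverage` of the total is labelled positive. With
#' heavily skewed spontaneous-report counts this yields a small head set of
#' likely reactions, as intended; all other concepts are treated as
#' negatives.
#'
#' @param refset data.frame with `adr_concept`, `report_count`.
#' @param coverage fraction of total reports the positive set must cover
#'   (default 0.95).
#' @return character vector of positive concept ids.
#' @export
label_positives <- function(refset, coverage = 0.95) {
  rs <- data.table::as.data.table(refset)
  if (!nrow(rs) || sum(rs$report_count) <= 0) {
    stopf("reference report set is empty")
  }
  data.table::setorder(rs, -report_count, adr_concept)
  cum <- cumsum(rs$report_count)
  k <- which(cum >= coverage * sum(rs$report_count))[1]
  rs$adr_concept[seq_len(k)]
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' The AUC equals the probability that a randomly chosen positive concept
#' scores above a randomly chosen negative one, with ties counting one half;
#' computed from midranks. Concepts with undefined (`NA`) scores are excluded
#' and their count is recorded in the `n_excluded` attribute.
#'
#' @param scores named numeric vector, names are concept ids; `NA` allowed.
#' @param labels character vector of positive concept ids.
#' @return AUC in `[0, 1]`, with attributes `n_pos`, `n_neg`, `n_excluded`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.null(names(scores))) stopf("scores must be a named vector")
  keep <- !is.na(scores)
  n_excluded <- sum(!keep)
  s <- scores[keep]
  y <- names(s) %in% labels
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stopf("AUC needs at least one positive and one negative with defined scores")
  }
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(auc, n_pos = n_pos, n_neg = n_neg, n_excluded = n_excluded)
}

#' Spearman correlation between scores and reference report counts
#'
#' Rank correlation (midrank ties) between a measure's scores and the number
#' of reference reports, over concepts with at least `min_count` reports and
#' a defined score. Concepts with undefined scores are excluded, not imputed.
#'
#' @param scores named numeric vector of a measure's scores.
#' @param refset data.frame with `adr_concept`, `report_count`.
#' @param min_count minimum report count for inclusion (default 1).
#' @return Spearman rho, with attribute `n` (concepts used).
#' @export
spearman_vs_reports <- function(scores, refset, min_count = 1) {
  p <- paired_scores(scores, refset, min_count)
  if (nrow(p) < 3) stopf("need at least 3 concepts with defined scores")
  structure(stats::cor(p$score, p$report_count, method = "spearman"), n = nrow(p))
}

paired_scores <- function(scores, refset, min_count) {
  rs <- data.table::as.data.table(refset)[report_count >= min_count]
  s <- scores[!is.na(scores)]
  rs <- rs[rs$adr_concept %in% names(s)]
  rs[, score := as.numeric(s[adr_concept])]
  data.table::setorder(rs, adr_concept)
  rs
}

#' Greedy outlier exclusion for rank correlation
#'
#' Iteratively removes the single concept whose exclusion maximizes the
#' Spearman correlation between scores and reference report counts (ties
#' broken by concept id), `k` times. Typical outliers are reactions with many
#' reference reports but a low query score, or vice versa. Each step is
#' locally optimal; the correlation path is not guaranteed monotone.
#'
#' @inheritParams spearman_vs_reports
#' @param k number of outliers to remove (default 5).
#' @return list with `outliers` (removal order) and `rho_path` (length
#'   `k + 1`: the correlation of the full set followed by the correlation
#'   after each removal).
#' @export
greedy_outlier_removal <- function(scores, refset, k = 5, min_count = 1) {
  p <- paired_scores(scores, refset, min_count)
  if (nrow(p) < k + 3) {
    stopf("need at least k+3 = %d evaluable concepts, have %d", k + 3, nrow(p))
  }
  rho <- function(d) stats::cor(d$score, d$report_count, method = "spearman")
  outliers <- character(0)
  rho_path <- rho(p)
  for (step in seq_len(k)) {
    cand <- p$adr_concept
    rhos <- vapply(cand, function(cc) rho(p[p$adr_concept != cc, ]), numeric(1))
    best <- cand[order(-rhos, cand)][1] # ties by concept id
    outliers <- c(outliers, best)
    p <- p[p$adr_concept != best, ]
    rho_path <- c(rho_path, rho(p))
  }
  list(outliers = outliers, rho_path = rho_path)
}

#' Validate all measures against a reference report set
#'
#' Convenience wrapper: labels positives by top-coverage, then computes each
#' measure's AUC and Spearman correlation, plus the correlation after greedy
#' outlier exclusion for one chosen measure.
#'
#' @param measures output of [compute_all_measures()].
#' @param refset data.frame with `adr_concept`, `report_count`.
#' @param coverage passed to [label_positives()].
#' @param min_count passed to [spearman_vs_reports()].
#' @param k outliers to remove for `outlier_measure`.
#' @param outlier_measure measure name for the outlier analysis
#'   (default `"qlrs"`).
#' @return list with `positives`, `auc_by_measure`, `rho_by_measure`,
#'   `n_evaluated`, `n_undefined_by_measure`, `outliers`, `rho_path`.
#' @export
validate_measures <- function(measures, refset, coverage = 0.95, min_count = 1,
                              k = 5, outlier_measure = "qlrs") {
  ms <- data.table::as.data.table(measures)
  measure_names <- c("qr", "qlrs", "qprr", "pqr")
  positives <- label_positives(refset, coverage)
  svec <- function(m) stats::setNames(ms[[m]], ms$adr_concept)
  auc <- vapply(measure_names, function(m) as.numeric(roc_auc(svec(m), positives)),
                numeric(1))
  rho <- vapply(measure_names,
                function(m) as.numeric(spearman_vs_reports(svec(m), refset, min_count)),
                numeric(1))
  undef <- vapply(measure_names, function(m) sum(is.na(ms[[m]])), integer(1))
  out <- greedy_outlier_removal(svec(outlier_measure), refset, k, min_count)
  list(positives = positives,
       auc_by_measure = auc,
       rho_by_measure = rho,
       n_evaluated = nrow(ms),
       n_undefined_by_measure = undef,
       outlier_measure = outlier_measure,
       outliers = out$outliers,
       rho_path = out$rho_path)
}
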