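# Per-user matched summary used by both tables: one row per user with
# exposure status and, per ADR concept, whether the user ever queried it and
# whether they did so before / on-or-after their (pseudo-)day 0.
# Counts are of people, not queries.
match_adr_users <- function(log, lexicon, day0map) {
  dt <- data.table::as.data.table(log)
  la <- lexicon[lexicon$kind == "adr", ]
  m <- match_texts(dt$text, la)
  if (!nrow(m)) {
    return(data.table::data.table(user_id = character(), concept_id = character(),
                                  ever = logical(), after = logical(),
                                  before = logical()))
  }
  hits <- data.table::data.table(user_id = dt$user_id[m$idx],
                                 date = dt$date[m$idx],
                                 concept_id = m$concept_id)
  hits <- merge(hits, data.table::as.data.table(day0map)[, .(user_id, day0)],
                by = "user_id")
  hits[, .(
    ever = TRUE,
    after = any(date >= day0),  # day 0 itself counts as post-exposure
    before = any(date < day0)
  ), by = .(user_id, concept_id)]
}

user_exposure <- function(log, day0map) {
  users <- unique(data.table::as.data.table(log)$user_id)
  map <- data.table::as.data.table(day0map)
  miss <- setdiff(users, map$user_id)
  if (length(miss)) {
    stopf("day0 map does not cover %d user(s), e.g. %s", length(miss), miss[1])
  }
  map[map$user_id %in% users, .(user_id, day0, is_exposed)]
}

#' Ever-queried 2x2 table for one ADR concept
#'
#' Classifies every user in the log by (ever queried the target substance) x
#' (ever queried the ADR concept). Cells: `a` neither, `b` target only,
#' `c` ADR only, `d` both. Counts are of people.
#'
#' @param log a (news-filtered) query log.
#' @param lexicon a [lexicon].
#' @param day0map a `day0_map` covering all users in the log (exposure status
#'   is taken from it, so target matching happens once, not per table).
#' @param adr an ADR concept id.
#' @return a `table1_counts` list with elements `a`, `b`, `c`, `d`.
#' @export
build_table1 <- function(log, lexicon, day0map, adr) {
  build_all_tables(log, lexicon, day0map, adrs = adr)$table1[[adr]]
}

#' Before/after-day-0 2x2 table for one ADR concept
#'
#' Rows condition on when ADR queries occur relative to the user's
#' (pseudo-)day 0: a user enters the "after" row if they have at least one
#' ADR query dated on or after day 0, and the "before" row if at least one is
#' dated strictly before. A user with ADR queries on both sides contributes
#' to both rows: the rows are separate conditions on the same population,
#' not a partition. Cells: `e` after/no-target, `f` after/target,
#' `g` before/no-target, `h` before/target.
#'
#' @inheritParams build_table1
#' @return a `table2_counts` list with elements `e`, `f`, `g`, `h`.
#' @export
build_table2 <- function(log, lexicon, day0map, adr) {
  build_all_tables(log, lexicon, day0map, adrs = adr)$table2[[adr]]
}

build_all_tables <- function(log, lexicon, day0map, adrs = NULL) {
  adrs <- adrs %||% adr_concepts(lexicon)
  bad <- setdiff(adrs, adr_concepts(lexicon))
  if (length(bad)) stopf("not adr concepts: %s", paste(bad, collapse = ", "))
  exp <- user_exposure(log, day0map)
  n_exposed <- sum(exp$is_exposed)
  n_total <- nrow(exp)
  au <- match_adr_users(log, lexicon, day0map)
  au <- merge(au, exp[, .(user_id, is_exposed)], by = "user_id")
  t1 <- vector("list", length(adrs))
  t2 <- vector("list", length(adrs))
  names(t1) <- names(t2) <- adrs
  for (cc in adrs) {
    sub <- au[au$concept_id == cc, ]
    d <- sum(sub$is_exposed & sub$ever)
    c_ <- sum(!sub$is_exposed & sub$ever)
    f <- sum(sub$is_exposed & sub$after)
    e <- sum(!sub$is_exposed & sub$after)
    h <- sum(sub$is_exposed & sub$before)
    g <- sum(!sub$is_exposed & sub$before)
    t1[[cc]] <- structure(list(a = (n_total - n_exposed) - c_,
                               b = n_exposed - d, c = c_, d = d),
                          class = "table1_counts")
    t2[[cc]] <- structure(list(e = e, f = f, g = g, h = h),
                          class = "table2_counts")
  }
  list(table1 = t1, table2 = t2)
}

undefined_score <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' Query ratio (QR)
#'
#' `(f + h) / (e + g)`: the number of target-substance users who queried the
#' ADR (either side of day 0) relative to the number of non-target users who
#' did. Undefined when `e + g == 0`; undefined scores are returned as `NA`
#' with a `reason` attribute, never silently as 0, so downstream ranking can
#' distinguish "no signal" from "no data".
#'
#' @param t2 a `table2_counts`.
#' @return numeric score, or `NA` with attribute `reason`.
#' @export
query_ratio <- function(t2) {
  if (t2$e + t2$g == 0) return(undefined_score("e+g == 0"))
  (t2$f + t2$h) / (t2$e + t2$g)
}

#' Query log reaction score (QLRS)
#'
#' The Pearson chi-squared statistic of the before/after table, measuring the
#' change in ADR querying after first substance queries:
#' `N (e h - f g)^2 / ((e+f)(g+h)(e+g)(f+h))` with `N = e+f+g+h`.
#' No continuity correction is applied. By convention the score is 0 when any
#' margin is 0 (a degenerate table carries no association evidence).
#'
#' @param t2 a `table2_counts`.
#' @return non-negative numeric score.
#' @export
qlrs <- function(t2) {
  e <- t2$e; f <- t2$f; g <- t2$g; h <- t2$h
  margins <- c(e + f, g + h, e + g, f + h)
  if (any(margins == 0)) return(0)
  n <- e + f + g + h
  n * (e * h - f * g)^2 / prod(margins)
}

#' Query proportional rate ratio (QPRR)
#'
#' `(d/(d+b)) / (c/(a+c))`: the rate of ever querying the ADR among
#' target-substance users relative to the rest of the population — a relative
#' risk on the ever-queried table. Undefined when `d+b == 0`, `a+c == 0`, or
#' `c == 0` (an infinite signal is reported as undefined, not clamped).
#'
#' @param t1 a `table1_counts`.
#' @return numeric score, or `NA` with attribute `reason`.
#' @export
qprr <- function(t1) {
  if (t1$d + t1$b == 0) return(undefined_score("d+b == 0"))
  if (t1$a + t1$c == 0) return(undefined_score("a+c == 0"))
  if (t1$c == 0) return(undefined_score("c == 0"))
  (t1$d / (t1$d + t1$b)) / (t1$c / (t1$a + t1$c))
}

#' Proportionality query ratio (PQR)
#'
#' `(h/(f+h)) / (g/(e+g))`: the before-day-0 share of ADR queriers among
#' target users relative to the same share among non-target users. Undefined
#' when `f+h == 0`, `e+g == 0`, or `g == 0`.
#'
#' @param t2 a `table2_counts`.
#' @return numeric score, or `NA` with attribute `reason`.
#' @export
pqr <- function(t2) {
  if (t2$f + t2$h == 0) return(undefined_score("f+h == 0"))
  if (t2$e + t2$g == 0) return(undefined_score("e+g == 0"))
  if (t2$g == 0) return(undefined_score("g == 0"))
  (t2$h / (t2$f + t2$h)) / (t2$g / (t2$e + t2$g))
}

#' Compute all four association measures for every ADR concept
#'
#' Builds the ever-queried and before/after tables for each ADR concept in
#' the lexicon and evaluates QR, QLRS, QPRR and PQR. Deterministic given its
#' inputs.
#'
#' @inheritParams build_table1
#' @return `data.table` with one row per ADR concept: `adr_concept`, the
#'   eight cell counts `a`..`h`, the four scores (NA where undefined), and
#'   `undefined_reasons` (semicolon-joined, empty when all defined).
#' @export
compute_all_measures <- function(log, lexicon, day0map) {
  adrs <- adr_concepts(lexicon)
  if (!length(adrs)) stopf("lexicon has no adr concepts")
  if (!length(target_concepts(lexicon))) stopf("lexicon has no target concepts")
  tabs <- build_all_tables(log, lexicon, day0map, adrs)
  rows <- lapply(adrs, function(cc) {
    t1 <- tabs$table1[[cc]]
    t2 <- tabs$table2[[cc]]
    scores <- list(qr = query_ratio(t2), qlrs = qlrs(t2),
                   qprr = qprr(t1), pqr = pqr(t2))
    reasons <- unlist(lapply(names(scores), function(m) {
      r <- attr(scores[[m]], "reason")
      if (is.null(r)) NULL else paste0(m, ": ", r)
    }))
    data.table::data.table(
      adr_concept = cc,
      a = t1$a, b = t1$b, c = t1$c, d = t1$d,
      e = t2$e, f = t2$f, g = t2$g, h = t2$h,
      qr = as.numeric(scores$qr), qlrs = as.numeric(scores$qlrs),
      qprr = as.numeric(scores$qprr), pqr = as.numeric(scores$pqr),
      undefined_reasons = paste(reasons, collapse = "; "))
  })
  out <- data.table::rbindlist(rows)
  data.table::setkey(out, adr_concept)
  out[]
}

#' Write a measures table as CSV
#'
#' Columns `adr_concept,a,b,c,d,e,f,g,h,qr,qlrs,qprr,pqr`; undefined scores
#' are written as empty fields.
#'
#' @param scores output of [compute_all_measures()].
#' @param path output path.
#' @export
write_measures <- function(scores, path) {
  cols <- c("adr_concept", letters[1:8], "qr", "qlrs", "qprr", "pqr")
  data.table::fwrite(data.table::as.data.table(scores)[, ..cols], path, na = "")
  invisible(path)
}
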