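#' Date of first target-concept query per user
#'
#' For each user with at least one query matching any of the given target
#' concepts, returns the calendar date of the earliest such query ("day 0",
#' the exposure anchor). Users without a target query are absent from the
#' result. The result is a pure function of the record set, invariant to
#' record order.
#'
#' @param log a query log.
#' @param lexicon a [lexicon].
#' @param target_concepts concept ids of kind `"target"` to anchor on;
#'   defaults to all target concepts in the lexicon.
#' @return `data.table` with columns `user_id`, `day0` (`Date`).
#' @export
find_day0 <- function(log, lexicon, target_concepts = NULL) {
  dt <- data.table::as.data.table(log)
  tc <- target_concepts %||% target_concepts(lexicon)
  if (!length(tc)) stopf("no target concepts given")
  bad <- setdiff(tc, target_concepts(lexicon))
  if (length(bad)) {
    stopf("not target concepts in this lexicon: %s", paste(bad, collapse = ", "))
  }
  lt <- lexicon[lexicon$kind == "target" & lexicon$concept_id %in% tc, ]
  m <- match_texts(dt$text, lt)
  if (!nrow(m)) {
    return(data.table::data.table(user_id = character(), day0 = as.Date(character())))
  }
  hits <- dt[m$idx, .(user_id, date)]
  out <- hits[, .(day0 = min(date)), by = user_id]
  data.table::setkey(out, user_id)
  out[]
}

#' Assign calendar-matched pseudo-day-0 dates to non-exposed users
#'
#' Users who never query the target substance still need a timeline anchor so
#' that their symptom queries can be split into before/after columns of the
#' exposure table. Each non-exposed user receives a pseudo-day-0 sampled with
#' replacement from the empirical distribution of the exposed users' day-0
#' dates; calendar matching controls for secular and seasonal query trends.
#'
#' @param non_exposed_users character vector of user ids.
#' @param exposed_day0_dates `Date` vector (with multiplicity) of exposed
#'   users' day-0 dates.
#' @param seed integer; the assignment is deterministic given the seed.
#' @return `data.table` with columns `user_id`, `day0`.
#' @export
assign_reference_day0 <- function(non_exposed_users, exposed_day0_dates, seed) {
  if (!length(exposed_day0_dates)) {
    stopf("cannot anchor the comparison population: no exposed day-0 dates")
  }
  users <- sort(unique(as.character(non_exposed_users)))
  day0 <- with_seed(seed, sample(exposed_day0_dates, length(users), replace = TRUE))
  data.table::data.table(user_id = users, day0 = as.Date(day0, origin = "1970-01-01"))
}

#' Build the full day-0 map for a filtered log
#'
#' Combines [find_day0()] for exposed users with [assign_reference_day0()]
#' for everyone else, so the map covers every user in the log exactly once.
#'
#' @inheritParams find_day0
#' @param seed integer seed for the pseudo-day-0 assignment.
#' @return A `day0_map`: `data.table` with columns `user_id`, `day0`,
#'   `is_exposed`, with attributes `log_start` and `log_end`.
#' @export
build_day0_map <- function(log, lexicon, seed, target_concepts = NULL) {
  dt <- data.table::as.data.table(log)
  exposed <- find_day0(dt, lexicon, target_concepts)
  all_users <- unique(dt$user_id)
  non_exposed <- setdiff(all_users, exposed$user_id)
  parts <- list(
    if (nrow(exposed)) exposed[, .(user_id, day0, is_exposed = TRUE)],
    if (length(non_exposed)) {
      assign_reference_day0(non_exposed, exposed$day0, seed)[,
        .(user_id, day0, is_exposed = FALSE)]
    }
  )
  map <- data.table::rbindlist(Filter(Negate(is.null), parts))
  if (!nrow(map)) {
    map <- data.table::data.table(user_id = character(),
                                  day0 = as.Date(character()),
                                  is_exposed = logical())
  }
  data.table::setkey(map, user_id)
  data.table::setattr(map, "log_start", if (nrow(dt)) min(dt$date) else as.Date(NA))
  data.table::setattr(map, "log_end", if (nrow(dt)) max(dt$date) else as.Date(NA))
  data.table::setattr(map, "class", c("day0_map", class(map)))
  map
}

#' Export a day-0 map as CSV
#'
#' Columns `user_id,day0,is_exposed`.
#'
#' @param map a `day0_map`.
#' @param path output path.
#' @export
write_day0_map <- function(map, path) {
  data.table::fwrite(data.table::as.data.table(map), path)
  invisible(path)
}
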