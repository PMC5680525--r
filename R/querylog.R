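#' Read a query log from a TSV file
#'
#' The log format is tab-separated with a header and columns
#' `user_id`, `timestamp` (ISO 8601, `YYYY-MM-DDThh:mm:ss`), `state`,
#' `region`, `county`, `text`. Geographic columns may be empty for analyses
#' that do not use them. Rows with an empty `user_id` or `text`, or an
#' unparseable timestamp, are rejected and counted, not fatal.
#'
#' @param path path to the TSV file.
#' @param chunk_size rows per chunk when `callback` is given; bounds memory
#'   for logs far larger than RAM.
#' @param callback optional `function(chunk)` invoked once per validated
#'   chunk (a `data.table`). When supplied, chunks are not accumulated and
#'   the function returns only the row accounting.
#' @return When `callback` is `NULL`, a `query_log`: a `data.table` with the
#'   six input columns plus `date` (the calendar `Date` of the timestamp),
#'   carrying attribute `n_rejected`. Otherwise an invisible list
#'   `(n_read, n_rejected)`.
#' @seealso [write_query_log()], [generate_query_log()]
#' @export
read_query_log <- function(path, chunk_size = 100000L, callback = NULL) {
  if (!file.exists(path)) stopf("query log not found: %s", path)
  cols <- c("user_id", "timestamp", "state", "region", "county", "text")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, cols)) {
    stopf("query log %s must have header: %s", path, paste(cols, collapse = "\t"))
  }
  n_read <- 0L
  n_rejected <- 0L
  parts <- list()
  skip <- 1L
  repeat {
    chunk <- tryCatch(
      data.table::fread(
        path, sep = "\t", header = FALSE, col.names = cols,
        colClasses = list(character = 1:6), skip = skip, nrows = chunk_size,
        quote = "", showProgress = FALSE),
      error = function(e) NULL) # skip beyond end of file
    if (is.null(chunk) || !nrow(chunk)) break
    n_read <- n_read + nrow(chunk)
    skip <- skip + nrow(chunk)
    chunk <- validate_records(chunk)
    n_rejected <- n_rejected + attr(chunk, "n_rejected")
    if (is.null(callback)) parts[[length(parts) + 1L]] <- chunk else callback(chunk)
  }
  if (!is.null(callback)) {
    return(invisible(list(n_read = n_read, n_rejected = n_rejected)))
  }
  log <- data.table::rbindlist(parts)
  if (!nrow(log)) {
    log <- data.table::data.table(
      user_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      state = character(), region = character(), county = character(),
      text = character(), date = as.Date(character()))
  }
  as_query_log(log, n_rejected = n_rejected)
}

validate_records <- function(chunk) {
  ts <- as.POSIXct(chunk$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ok <- !is.na(ts) & nzchar(chunk$user_id) & nzchar(chunk$text)
  n_rejected <- sum(!ok)
  if (n_rejected) {
    message(sprintf("read_query_log: rejected %d malformed row(s)", n_rejected))
  }
  out <- chunk[ok]
  out[, timestamp := ts[ok]]
  out[, date := as.Date(timestamp)]
  attr(out, "n_rejected") <- n_rejected
  out
}

as_query_log <- function(dt, n_rejected = 0L) {
  dt <- data.table::as.data.table(dt)
  if (!"date" %in% names(dt)) dt[, date := as.Date(timestamp)]
  data.table::setattr(dt, "n_rejected", n_rejected)
  if (!inherits(dt, "query_log")) {
    data.table::setattr(dt, "class", c("query_log", class(dt)))
  }
  dt
}

#' Write a query log to TSV
#'
#' Inverse of [read_query_log()]; timestamps are written as ISO 8601.
#'
#' @param log a query log `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_query_log <- function(log, path) {
  out <- data.table::as.data.table(log)[, .(
    user_id,
    timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    state, region, county, text)]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' News-event filter configuration
#'
#' Query texts driven by news coverage show a characteristic volume pattern:
#' a large total count concentrated in a few high-volume days. A text is
#' flagged when (i) its total occurrence count over the log period is at
#' least `total_threshold` and (ii) the number of days on which its daily
#' count exceeds `spike_threshold` lies between `min_spike_days` and
#' `max_spike_days` inclusive.
#'
#' @param total_threshold minimum total occurrences (default 10000).
#' @param spike_threshold daily count a spike day must exceed (default 1000).
#' @param min_spike_days,max_spike_days inclusive bounds on the number of
#'   spike days (defaults 1 and 10).
#' @return a `news_filter_config` list.
#' @export
news_filter_config <- function(total_threshold = 10000L, spike_threshold = 1000L,
                               min_spike_days = 1L, max_spike_days = 10L) {
  cfg <- list(total_threshold = as.numeric(total_threshold),
              spike_threshold = as.numeric(spike_threshold),
              min_spike_days = as.integer(min_spike_days),
              max_spike_days = as.integer(max_spike_days))
  if (any(unlist(cfg) <= 0)) stopf("news filter thresholds must be positive")
  if (cfg$min_spike_days > cfg$max_spike_days) {
    stopf("min_spike_days must not exceed max_spike_days")
  }
  structure(cfg, class = "news_filter_config")
}

#' Detect news-driven query texts
#'
#' Identifies texts whose volume pattern indicates media-driven rather than
#' personal-interest querying; see [news_filter_config()] for the rule.
#' "Same text" means equality after [normalize_text()], the same
#' normalization used for concept matching, so a text filtered here can never
#' be matched downstream in a different form. The result depends only on the
#' per-text daily counts, not on record order.
#'
#' @param log a query log.
#' @param cfg a [news_filter_config()].
#' @return character vector of normalized texts to exclude.
#' @export
detect_news_texts <- function(log, cfg = news_filter_config()) {
  dt <- data.table::as.data.table(log)
  if (!nrow(dt)) return(character())
  norm <- NULL
  daily <- dt[, .(norm = normalize_text(text), date)][, .N, by = .(norm, date)]
  stats <- daily[, .(
    total = sum(N),
    spike_days = sum(N > cfg$spike_threshold)
  ), by = norm]
  flagged <- stats[total >= cfg$total_threshold &
                     spike_days >= cfg$min_spike_days &
                     spike_days <= cfg$max_spike_days]
  sort(flagged$norm)
}

#' Remove records whose text is news-flagged
#'
#' @param log a query log.
#' @param news_texts character vector of normalized texts, typically from
#'   [detect_news_texts()].
#' @return the log restricted to records whose normalized text is not in
#'   `news_texts`; record order is preserved.
#' @export
filter_news <- function(log, news_texts) {
  dt <- data.table::as.data.table(log)
  if (!length(news_texts) || !nrow(dt)) return(as_query_log(dt))
  keep <- !(normalize_text(dt$text) %in% news_texts)
  as_query_log(dt[keep])
}
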