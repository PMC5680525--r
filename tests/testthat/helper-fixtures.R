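# Shared fixtures: small lexicons and hand-built logs. Logs are plain
# data.tables with the query_log columns; package functions accept them.

tiny_lexicon <- function() {
  lexicon(data.frame(
    concept_id = c("cannabis", "cannabis", "cough", "cough", "headache",
                   "nausea"),
    kind = c("target", "target", "adr", "adr", "adr", "adr"),
    synonym = c("cannabis", "marijuana", "cough", "coughing", "headache",
                "nausea")))
}

# Build a log from parallel vectors; dates as "YYYY-MM-DD" strings.
make_log <- function(user, date, text, state = "", region = "", county = "") {
  n <- length(text)
  data.table::data.table(
    user_id = rep_len(user, n),
    timestamp = as.POSIXct(paste0(rep_len(date, n), "T12:00:00"),
                           format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    state = rep_len(state, n), region = rep_len(region, n),
    county = rep_len(county, n),
    text = text,
    date = as.Date(rep_len(date, n)))
}

# A day0 map built by hand (bypasses build_day0_map for table unit tests).
make_day0_map <- function(user_id, day0, is_exposed) {
  m <- data.table::data.table(user_id = user_id, day0 = as.Date(day0),
                              is_exposed = is_exposed)
  data.table::setkey(m, user_id)
  m
}

# Random small log over a fixed vocabulary for oracle-equivalence tests:
# n_users users, up to max_adr ADR concepts, random mix of target / ADR /
# noise queries on random dates.
random_small_log <- function(n_users = 20, n_adr = 3, n_queries = 120,
                             start = as.Date("2017-01-01"), n_days = 40) {
  adrs <- paste0("sym", seq_len(n_adr))
  lx <- lexicon(data.frame(
    concept_id = c("cannabis", adrs),
    kind = c("target", rep("adr", n_adr)),
    synonym = c("cannabis", adrs)))
  vocab <- c("cannabis", adrs, "noisea", "noiseb")
  users <- paste0("u", sample.int(n_users, n_queries, replace = TRUE))
  dates <- start + sample.int(n_days, n_queries, replace = TRUE) - 1L
  texts <- sample(vocab, n_queries, replace = TRUE)
  texts[1] <- "cannabis"  # at least one exposed user to anchor day 0
  list(log = make_log(users, as.character(dates), texts), lexicon = lx,
       adrs = adrs)
}
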