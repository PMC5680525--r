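#' Default geographic units for simulation
#'
#' Twenty county-level units nested two-per-region in ten regions, which nest
#' two-per-state in five states. True exposure prevalence spans 0.06-0.20
#' across counties (the range of annual use prevalence across US states),
#' and users are spread evenly.
#'
#' @return data.frame with columns `county`, `region`, `state`,
#'   `true_prevalence`, `share`.
#' @export
default_units <- function() {
  n <- 20L
  data.frame(
    county = sprintf("c%02d", 1:n),
    region = sprintf("r%02d", rep(1:(n / 2), each = 2)),
    state = sprintf("s%02d", rep(1:(n / 4), each = 4)),
    true_prevalence = seq(0.06, 0.20, length.out = n),
    share = rep(1 / n, n))
}

#' Default ADR concept specifications for simulation
#'
#' Twenty symptom concepts at a baseline query rate of 0.001 per user-day.
#' Five are planted as true reactions at a rate multiplier of 5 during a
#' post-exposure window: three with immediate onset (day 0), one with onset
#' 5 days after first exposure, and one with late onset at 40 days —
#' mirroring the qualitative temporal patterns this kind of analysis aims to
#' recover (most reactions immediate, headache-like delayed by a few days,
#' cough-like appearing after weeks).
#'
#' @return data.frame with columns `concept`, `baseline_daily_rate`,
#'   `multiplier`, `onset_lag`, `duration`.
#' @export
default_adr_specs <- function() {
  concepts <- c("anxiety", "overdose", "paranoia", "headache", "cough",
                "pain", "depression", "withdrawal", "seizure", "hallucination",
                "nausea", "vomiting", "fatigue", "insomnia", "dizziness",
                "sweating", "agitation", "drowsiness", "appetite", "syncope")
  spec <- data.frame(concept = concepts,
                     baseline_daily_rate = 0.001,
                     multiplier = 1,
                     onset_lag = 0L,
                     duration = 30L)
  planted <- c(anxiety = 0L, overdose = 0L, paranoia = 0L,
               headache = 5L, cough = 40L)
  idx <- match(names(planted), spec$concept)
  spec$multiplier[idx] <- 5
  spec$onset_lag[idx] <- unname(planted)
  spec
}

#' Simulation configuration
#'
#' Defines the statistical structure of a generated query log: a population
#' of users assigned to geographic units, a subset exposed to the target
#' substance (with probability equal to their unit's true prevalence) who
#' issue a target-term query at a uniformly random day 0, elevated ADR query
#' rates after exposure, background noise vocabulary, and optional
#' news-driven query spikes. The defaults emulate a six-month national log
#' at a scale where per-symptom association signals are recoverable.
#'
#' @param n_users number of users (default 10000).
#' @param start,end inclusive log date range (defaults 2016-11-01 to
#'   2017-04-30, a six-month window).
#' @param units data.frame as [default_units()].
#' @param target_synonyms synonyms of the single target concept
#'   (default `c("cannabis", "marijuana")`).
#' @param background_vocab_size number of background noise terms, disjoint
#'   from all lexicon synonyms by construction (default 500).
#' @param queries_per_user_day Poisson rate of background queries per
#'   user-day (default 0.05; the generator emulates only the health-relevant
#'   slice of a query stream, not total search volume).
#' @param target_query_prob probability an exposed user issues a further
#'   target query on each day after day 0 (default 0.02).
#' @param adr_specs data.frame as [default_adr_specs()].
#' @param news_events list of `list(text=, total=, spike_days=,
#'   spike_height=)` news-driven texts to inject (default none).
#' @param template_prob probability a query is wrapped in a longer phrase
#'   template rather than issued as the bare term (default 0.3).
#' @param ref_report_floor baseline mean reference-report count per concept
#'   (default 0.5).
#' @param ref_report_scale factor converting excess query rate
#'   `(multiplier - 1) * baseline_daily_rate` into mean report counts
#'   (default 12500, putting planted concepts near 50 mean reports).
#' @param ref_report_dispersion negative-binomial overdispersion; the NB size
#'   parameter is `1 / dispersion` (default 0.5).
#' @param seed integer master seed; every generated artifact is
#'   deterministic given it.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_users = 10000L,
                              start = "2016-11-01", end = "2017-04-30",
                              units = default_units(),
                              target_synonyms = c("cannabis", "marijuana"),
                              background_vocab_size = 500L,
                              queries_per_user_day = 0.05,
                              target_query_prob = 0.02,
                              adr_specs = default_adr_specs(),
                              news_events = list(),
                              template_prob = 0.3,
                              ref_report_floor = 0.5,
                              ref_report_scale = 12500,
                              ref_report_dispersion = 0.5,
                              seed = 1L) {
  cfg <- list(n_users = as.integer(n_users), start = as.Date(start),
              end = as.Date(end), units = units,
              target_synonyms = target_synonyms,
              background_vocab_size = as.integer(background_vocab_size),
              queries_per_user_day = queries_per_user_day,
              target_query_prob = target_query_prob,
              adr_specs = adr_specs, news_events = news_events,
              template_prob = template_prob,
              ref_report_floor = ref_report_floor,
              ref_report_scale = ref_report_scale,
              ref_report_dispersion = ref_report_dispersion,
              seed = as.integer(seed))
  if (cfg$n_users <= 0) stopf("invalid config field n_users: must be positive")
  if (is.na(cfg$start) || is.na(cfg$end) || cfg$end < cfg$start) {
    stopf("invalid config fields start/end: need a non-empty date range")
  }
  need_u <- c("county", "region", "state", "true_prevalence", "share")
  if (!all(need_u %in% names(cfg$units))) {
    stopf("invalid config field units: needs columns %s",
          paste(need_u, collapse = ", "))
  }
  if (any(cfg$units$true_prevalence < 0 | cfg$units$true_prevalence > 1)) {
    stopf("invalid config field units$true_prevalence: must lie in [0, 1]")
  }
  need_a <- c("concept", "baseline_daily_rate", "multiplier", "onset_lag",
              "duration")
  if (!all(need_a %in% names(cfg$adr_specs))) {
    stopf("invalid config field adr_specs: needs columns %s",
          paste(need_a, collapse = ", "))
  }
  if (any(cfg$adr_specs$baseline_daily_rate < 0)) {
    stopf("invalid config field adr_specs$baseline_daily_rate: must be >= 0")
  }
  if (any(cfg$adr_specs$multiplier < 1)) {
    stopf("invalid config field adr_specs$multiplier: must be >= 1")
  }
  if (cfg$queries_per_user_day < 0) {
    stopf("invalid config field queries_per_user_day: must be >= 0")
  }
  if (cfg$template_prob < 0 || cfg$template_prob > 1) {
    stopf("invalid config field template_prob: must lie in [0, 1]")
  }
  for (ev in cfg$news_events) {
    if (is.null(ev$text) || is.null(ev$total) || is.null(ev$spike_days)) {
      stopf("invalid config field news_events: each needs text, total, spike_days")
    }
  }
  structure(cfg, class = "simulation_config")
}

#' Lexicon matching a simulation configuration
#'
#' One target concept (`"cannabis"`) with the configured synonyms, and one
#' ADR concept per `adr_specs` row whose synonym is the concept name.
#'
#' @param config a [simulation_config()].
#' @return a [lexicon].
#' @export
simulated_lexicon <- function(config) {
  lexicon(rbind(
    data.frame(concept_id = "cannabis", kind = "target",
               synonym = config$target_synonyms),
    data.frame(concept_id = config$adr_specs$concept, kind = "adr",
               synonym = config$adr_specs$concept)))
}

query_templates <- c("%s", "about %s", "%s help", "why %s", "%s forum")

#' Generate a synthetic query log with planted ground truth
#'
#' Users are assigned to counties by share; each user is exposed with
#' probability equal to their county's true prevalence. Every exposed user
#' issues one target-term query at a uniformly random day 0 (guaranteeing
#' exact exposure-set recovery by the matcher) plus further target queries
#' with `target_query_prob` per post-day-0 day. Every user emits background
#' queries as a Poisson process over a vocabulary disjoint from all lexicon
#' synonyms, and per-concept ADR queries at `baseline_daily_rate`, elevated
#' to `baseline * multiplier` for exposed users during
#' `[day0 + onset_lag, day0 + onset_lag + duration - 1]`. Configured news
#' events inject their spike pattern from randomly chosen users. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `log` (a query log `data.table`), `truth` (list:
#'   `user_units` covering every simulated user — users with no queries are
#'   absent from the log but present here —, `exposed_users`,
#'   `day0_by_user`, `planted_adrs`, `unit_prevalence`), and `lexicon`
#'   (the matching [lexicon]).
#' @export
generate_query_log <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_query_log_impl(config))
}

generate_query_log_impl <- function(cfg) {
  n_days <- as.integer(cfg$end - cfg$start) + 1L
  n <- cfg$n_users
  users <- sprintf("u%06d", seq_len(n))
  ui <- sample.int(nrow(cfg$units), n, replace = TRUE, prob = cfg$units$share)
  prev <- cfg$units$true_prevalence[ui]
  exposed <- stats::rbinom(n, 1L, prev) == 1L
  day0 <- rep(NA_integer_, n)
  day0[exposed] <- sample.int(n_days, sum(exposed), replace = TRUE) - 1L

  parts <- list()
  emit <- function(uidx, day, text) {
    if (!length(uidx)) return(invisible(NULL))
    parts[[length(parts) + 1L]] <<- data.table::data.table(
      uidx = uidx, day = as.integer(day), text = text)
  }

  # target queries: the anchoring day-0 query plus repeat queries
  eidx <- which(exposed)
  emit(eidx, day0[eidx],
       sample(cfg$target_synonyms, length(eidx), replace = TRUE))
  n_active <- n_days - 1L - day0[eidx]
  k <- stats::rbinom(length(eidx), pmax(0L, n_active), cfg$target_query_prob)
  rep_u <- rep(eidx, k)
  if (length(rep_u)) {
    offs <- floor(stats::runif(length(rep_u)) * rep(n_active, k)) + 1L
    emit(rep_u, day0[rep_u] + offs,
         sample(cfg$target_synonyms, length(rep_u), replace = TRUE))
  }

  # background noise vocabulary, disjoint from lexicon synonyms by prefix
  if (cfg$background_vocab_size > 0 && cfg$queries_per_user_day > 0) {
    vocab <- sprintf("bgword%04d", seq_len(cfg$background_vocab_size))
    nb <- stats::rpois(n, cfg$queries_per_user_day * n_days)
    rep_u <- rep(seq_len(n), nb)
    emit(rep_u, sample.int(n_days, length(rep_u), replace = TRUE) - 1L,
         sample(vocab, length(rep_u), replace = TRUE))
  }

  # ADR queries: baseline for everyone, excess for exposed in the window
  for (i in seq_len(nrow(cfg$adr_specs))) {
    sp <- cfg$adr_specs[i, ]
    if (sp$baseline_daily_rate > 0) {
      nbase <- stats::rpois(n, sp$baseline_daily_rate * n_days)
      rep_u <- rep(seq_len(n), nbase)
      emit(rep_u, sample.int(n_days, length(rep_u), replace = TRUE) - 1L,
           rep(sp$concept, length(rep_u)))
    }
    if (sp$multiplier > 1 && sp$baseline_daily_rate > 0 && length(eidx)) {
      w0 <- day0[eidx] + sp$onset_lag
      w1 <- pmin(w0 + sp$duration - 1L, n_days - 1L)
      len <- pmax(0L, w1 - w0 + 1L)
      nex <- stats::rpois(length(eidx),
                          sp$baseline_daily_rate * (sp$multiplier - 1) * len)
      rep_u <- rep(eidx, nex)
      if (length(rep_u)) {
        offs <- floor(stats::runif(length(rep_u)) * rep(len, nex))
        emit(rep_u, rep(w0, nex) + offs, rep(sp$concept, length(rep_u)))
      }
    }
  }

  log <- data.table::rbindlist(parts)
  if (!nrow(log)) {
    log <- data.table::data.table(uidx = integer(), day = integer(),
                                  text = character())
  }
  # phrase templates (bare term or a longer wrapping phrase)
  if (nrow(log) && cfg$template_prob > 0) {
    ti <- sample.int(length(query_templates), nrow(log), replace = TRUE,
                     prob = c(1 - cfg$template_prob,
                              rep(cfg$template_prob / (length(query_templates) - 1),
                                  length(query_templates) - 1)))
    log[, text := sprintf(query_templates[ti], text)]
  }

  # news events keep their exact text so daily counts accumulate per text
  for (ev in cfg$news_events) {
    height <- ev$spike_height %||% 1500L
    sdays <- sample.int(n_days, ev$spike_days) - 1L
    n_spike <- ev$spike_days * height
    rest <- max(0L, as.integer(ev$total) - n_spike)
    day <- c(rep(sdays, each = height),
             if (rest > 0) sample(setdiff(seq_len(n_days) - 1L, sdays), rest,
                                  replace = TRUE))
    nev <- length(day)
    news <- data.table::data.table(uidx = sample.int(n, nev, replace = TRUE),
                                   day = as.integer(day), text = ev$text)
    log <- data.table::rbindlist(list(log, news))
  }

  secs <- floor(stats::runif(nrow(log)) * 86400)
  log[, `:=`(
    user_id = users[uidx],
    timestamp = as.POSIXct(cfg$start, tz = "UTC") + day * 86400 + secs,
    state = cfg$units$state[ui[uidx]],
    region = cfg$units$region[ui[uidx]],
    county = cfg$units$county[ui[uidx]]
  )]
  log[, date := as.Date(timestamp)]
  log <- log[, .(user_id, timestamp, state, region, county, text, date)]
  data.table::setorder(log, timestamp, user_id, text)

  truth <- list(
    user_units = data.table::data.table(user_id = users,
                                        unit = cfg$units$county[ui],
                                        is_exposed = exposed),
    exposed_users = users[eidx],
    day0_by_user = data.table::data.table(
      user_id = users[eidx], day0 = cfg$start + day0[eidx])[order(user_id)],
    planted_adrs = cfg$adr_specs$concept[cfg$adr_specs$multiplier > 1],
    unit_prevalence = data.table::data.table(
      unit = cfg$units$county, true_prevalence = cfg$units$true_prevalence))
  list(log = as_query_log(log), truth = truth,
       lexicon = simulated_lexicon(cfg))
}

#' Generate a reference report set matching a simulation
#'
#' Per-concept spontaneous-report counts drawn from a negative binomial with
#' mean `floor + scale * (multiplier - 1) * baseline_daily_rate`, so planted
#' reactions dominate the counts. Spontaneous-report counts are
#' overdispersed in practice, hence negative binomial rather than Poisson.
#' Deterministic given `config$seed` (a substream independent of the log's).
#'
#' @param config a [simulation_config()].
#' @param ground_truth the `truth` element from [generate_query_log()]
#'   (accepted for interface symmetry; counts depend only on the config).
#' @return `data.table` with columns `adr_concept`, `report_count`.
#' @export
generate_reference_reports <- function(config, ground_truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  sp <- config$adr_specs
  mu <- config$ref_report_floor +
    config$ref_report_scale * (sp$multiplier - 1) * sp$baseline_daily_rate
  counts <- with_seed(config$seed + 104729L, {
    ifelse(mu > 0,
           stats::rnbinom(nrow(sp), mu = mu,
                          size = 1 / config$ref_report_dispersion),
           0L)
  })
  out <- data.table::data.table(adr_concept = sp$concept,
                                report_count = as.numeric(counts))
  data.table::setorder(out, adr_concept)
  out[]
}

#' Generate a geographic prevalence scenario
#'
#' Builds a per-unit feature table directly (term-user fractions drawn
#' uniformly), with true prevalence an exact linear function of
#' `n_informative` of the terms plus Gaussian observation noise whose
#' standard deviation is `noise_frac` of the noiseless signal range. Fine
#' units are grouped consecutively into coarse aggregates for
#' cross-resolution experiments.
#'
#' @param n_units number of fine units (default 100).
#' @param n_terms number of candidate terms (default 13).
#' @param n_informative number of terms with nonzero true coefficients
#'   (default 3).
#' @param noise_frac observation noise sd as a fraction of signal range
#'   (default 0.1; 0 gives a noise-free scenario).
#' @param n_coarse number of coarse aggregates (default 20).
#' @param seed integer seed.
#' @return list with `features` (a `geo_feature_table`), `observed`
#'   (`unit`, `observed_prevalence`), `truth` (`unit`, `true_prevalence`),
#'   `informative_terms`, `true_coefficients` (named, signed), `intercept`,
#'   `mapping` (`unit`, `coarse_unit`), `coarse_features`, `coarse_observed`.
#' @export
generate_prevalence_scenario <- function(n_units = 100L, n_terms = 13L,
                                         n_informative = 3L, noise_frac = 0.1,
                                         n_coarse = 20L, seed = 1L) {
  stopifnot(n_informative <= n_terms, n_coarse <= n_units)
  with_seed(seed, {
    terms <- sprintf("term%02d", seq_len(n_terms))
    units <- sprintf("u%03d", seq_len(n_units))
    x <- matrix(stats::runif(n_units * n_terms, 0, 0.2), n_units, n_terms,
                dimnames = list(NULL, terms))
    informative <- sort(sample(terms, n_informative))
    beta <- stats::setNames(
      sample(c(-1, 1), n_informative, replace = TRUE) *
        stats::runif(n_informative, 0.5, 1.5),
      informative)
    intercept <- 0.10
    signal <- intercept + as.vector(x[, informative, drop = FALSE] %*% beta)
    noise_sd <- noise_frac * (max(signal) - min(signal))
    observed <- signal + stats::rnorm(n_units, 0, noise_sd)
    ft <- data.table::data.table(unit = units, level = "fine",
                                 n_users = sample(500:1500, n_units,
                                                  replace = TRUE))
    for (tn in terms) ft[, (tn) := x[, tn]]
    data.table::setattr(ft, "terms", terms)
    data.table::setattr(ft, "class", c("geo_feature_table", class(ft)))
    mapping <- data.table::data.table(
      unit = units,
      coarse_unit = sprintf("g%02d", rep(seq_len(n_coarse),
                                         length.out = n_units)))
    coarse <- aggregate_features(ft, mapping, level = "coarse")
    w <- ft$n_users
    cobs <- data.table::data.table(unit = mapping$coarse_unit,
                                   w = w, v = observed)[
      , .(observed_prevalence = sum(w * v) / sum(w)), by = unit]
    data.table::setorder(cobs, unit)
    list(features = ft,
         observed = data.table::data.table(unit = units,
                                           observed_prevalence = observed),
         truth = data.table::data.table(unit = units,
                                        true_prevalence = signal),
         informative_terms = informative,
         true_coefficients = beta,
         intercept = intercept,
         mapping = mapping,
         coarse_features = coarse,
         coarse_observed = cobs)
  })
}

#' Write a reference report set as CSV
#'
#' @param refset `data.table` with `adr_concept`, `report_count`.
#' @param path output path.
#' @export
write_reference_reports <- function(refset, path) {
  data.table::fwrite(data.table::as.data.table(refset), path)
  invisible(path)
}
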