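#' Lag-aligned temporal profile of one ADR concept
#'
#' For each lag `t` (days since the user's day 0, negative = before), over
#' exposed users only, computes the fraction of ADR queries at that lag that
#' match the given concept: `raw[t] = (# queries matching adr at lag t) /
#' (# queries matching any ADR concept at lag t)`. Queries, not users, are
#' the counting unit here. Lags where no ADR query occurs have an undefined
#' (`NA`) fraction. Profiles are invariant to record order.
#'
#' @param log a (news-filtered) query log.
#' @param lexicon a [lexicon].
#' @param day0map a `day0_map`.
#' @param adr the ADR concept to profile.
#' @param lag_min,lag_max inclusive lag range in days (defaults -60, 120).
#' @param exposed_only normalize by ADR queries from exposed users only
#'   (default `TRUE`, consistent with the lag alignment existing only for
#'   exposed users); set `FALSE` to include pseudo-anchored users.
#' @return A `temporal_profile`: `data.table` with columns `adr_concept`,
#'   `lag`, `n_adr`, `n_all`, `raw`, and `smoothed` (`NA` until
#'   [smooth_moving_average()] is applied).
#' @export
temporal_profile <- function(log, lexicon, day0map, adr,
                             lag_min = -60L, lag_max = 120L,
                             exposed_only = TRUE) {
  if (!adr %in% adr_concepts(lexicon)) stopf("'%s' is not an adr concept", adr)
  dt <- data.table::as.data.table(log)
  map <- data.table::as.data.table(day0map)
  if (exposed_only) map <- map[map$is_exposed == TRUE, ]
  if (!nrow(map)) stopf("no exposed users in day0 map")
  la <- lexicon[lexicon$kind == "adr", ]
  m <- match_texts(dt$text, la)
  lags <- seq.int(lag_min, lag_max)
  out <- data.table::data.table(adr_concept = adr, lag = lags,
                                n_adr = 0L, n_all = 0L)
  if (nrow(m)) {
    hits <- data.table::data.table(user_id = dt$user_id[m$idx],
                                   date = dt$date[m$idx],
                                   concept_id = m$concept_id)
    hits <- merge(hits, map[, .(user_id, day0)], by = "user_id")
    hits[, lag := as.integer(date - day0)]
    hits <- hits[lag >= lag_min & lag <= lag_max]
    all_cnt <- hits[, .N, by = lag]
    adr_cnt <- hits[concept_id == adr, .N, by = lag]
    out[match(all_cnt$lag, lags), n_all := all_cnt$N]
    out[match(adr_cnt$lag, lags), n_adr := adr_cnt$N]
  }
  out[, raw := ifelse(n_all > 0, n_adr / n_all, NA_real_)]
  out[, smoothed := NA_real_]
  data.table::setattr(out, "class", c("temporal_profile", class(out)))
  out
}

#' Smooth a temporal profile with a centered moving average
#'
#' Centered moving average of the raw per-lag fractions. At the series edges
#' the window is truncated to the available lags; undefined (`NA`) raw values
#' are excluded from both the numerator and the divisor, so a window
#' containing some undefined lags averages over the defined ones. A constant
#' series is unchanged.
#'
#' @param profile a `temporal_profile`.
#' @param window odd positive window width in days (default 7).
#' @return the profile with the `smoothed` column filled.
#' @export
smooth_moving_average <- function(profile, window = 7L) {
  window <- as.integer(window)
  if (window <= 0L || window %% 2L == 0L) stopf("window must be odd and positive")
  half <- window %/% 2L
  x <- profile$raw
  n <- length(x)
  sm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (length(w)) sm[i] <- mean(w)
  }
  out <- data.table::copy(profile)
  out[, smoothed := sm]
  out
}

#' Select the highest-activity lags
#'
#' Returns the lags whose smoothed fraction is at least the `m`-th largest
#' defined value, where `m = ceiling(quantile * n_defined)`; ties at the
#' threshold are included (so the result can exceed `m` lags, and a constant
#' series returns every defined lag).
#'
#' @param profile a smoothed `temporal_profile`.
#' @param quantile fraction of highest-activity days to keep (default 0.25).
#' @return integer vector of lags.
#' @export
top_activity_days <- function(profile, quantile = 0.25) {
  sm <- profile$smoothed
  def <- which(!is.na(sm))
  if (!length(def)) stopf("no defined smoothed values; run smooth_moving_average")
  m <- max(1L, as.integer(ceiling(quantile * length(def))))
  thr <- sort(sm[def], decreasing = TRUE)[m]
  profile$lag[def][sm[def] >= thr]
}

#' Estimate the onset lag of an elevated symptom profile
#'
#' Estimates when a symptom's query share rises above its pre-exposure
#' baseline. Because the number of ADR queries per lag varies strongly with
#' lag (few users contribute observations at extreme lags), a fixed threshold
#' on the smoothed fraction would be mis-calibrated; instead the detector
#' works on the windowed counts underlying the smoothed profile. The baseline
#' share `p0` is the pooled proportion `sum(n_adr) / sum(n_all)` over lags
#' `<= baseline_max_lag` (the default -4 keeps the centered 7-day window at
#' those lags free of post-exposure days even for an onset at day 0). For
#' each later lag, the concept's query count summed over the centered window
#' is compared with a binomial null `Bin(window total, p0)`; the onset
#' estimate is the first lag opening `min_run` consecutive windows whose
#' upper binomial tail probability falls below `alpha`.
#'
#' Because the baseline counts are themselves a sample, each window is
#' compared with the pooled baseline by a one-sided Fisher exact test rather
#' than a plain binomial tail. Detection marks the first lag opening
#' `min_run` consecutive windows with tail probability below `alpha`; the
#' centered window makes that lag a slightly late, diluted estimate of the
#' true onset, so the estimate then backtracks along the leading edge to the
#' first contiguous earlier lag whose raw share still exceeds
#' `backtrack_ratio` times the baseline share.
#'
#' @param profile a `temporal_profile` (the raw per-lag counts are used; the
#'   smoothed column need not be filled).
#' @param baseline_max_lag last lag of the baseline window (default -4).
#' @param window centered window width in days, matching the smoothing window
#'   (default 7, must be odd).
#' @param alpha per-window Fisher tail probability for detection
#'   (default 1e-4).
#' @param min_run consecutive detecting windows required (default 2),
#'   suppressing single-window noise excursions.
#' @param backtrack_ratio multiple of the baseline share the raw series must
#'   exceed for the leading-edge backtrack (default 2).
#' @return integer onset lag, or `NA` if no sustained exceedance is found.
#' @export
estimate_onset <- function(profile, baseline_max_lag = -4L, window = 7L,
                           alpha = 1e-4, min_run = 2L, backtrack_ratio = 2) {
  window <- as.integer(window)
  if (window <= 0L || window %% 2L == 0L) stopf("window must be odd and positive")
  half <- window %/% 2L
  lag <- profile$lag
  n_adr <- profile$n_adr
  n_all <- profile$n_all
  base <- lag <= baseline_max_lag
  if (sum(n_all[base] > 0) < 3) stopf("need at least 3 informative baseline lags")
  a0 <- sum(n_adr[base])
  n0 <- sum(n_all[base])
  p0 <- a0 / n0
  # one-sided hypergeometric tail: window counts enriched over baseline
  tail_p <- function(a, n) {
    if (n == 0) return(1)
    stats::phyper(a - 1L, a + a0, (n - a) + (n0 - a0), n, lower.tail = FALSE)
  }
  cand <- which(lag > baseline_max_lag)
  run <- 0L
  detect_i <- NA_integer_
  for (i in cand) {
    w <- max(1L, i - half):min(length(lag), i + half)
    a <- sum(n_adr[w])
    n <- sum(n_all[w])
    if (n > 0 && tail_p(a, n) < alpha) {
      run <- run + 1L
      if (run >= min_run) {
        detect_i <- i - min_run + 1L
        break
      }
    } else if (n > 0) {
      run <- 0L
    } # windows without observations neither extend nor break a run
  }
  if (is.na(detect_i)) return(NA_integer_)
  # leading-edge backtrack, at most half a window
  t <- detect_i
  while (t > 1L && detect_i - t < half) {
    prev <- profile$raw[t - 1L]
    if (is.na(prev) || prev <= backtrack_ratio * p0) break
    t <- t - 1L
  }
  lag[t]
}

#' Write temporal profiles as CSV
#'
#' Columns `adr_concept,lag,raw,smoothed,is_top_day`.
#'
#' @param profiles one `temporal_profile` or a list of them.
#' @param path output path.
#' @param quantile passed to [top_activity_days()].
#' @export
write_profiles <- function(profiles, path, quantile = 0.25) {
  if (inherits(profiles, "temporal_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    top <- top_activity_days(p, quantile)
    data.table::as.data.table(p)[, .(adr_concept, lag, raw, smoothed,
                                     is_top_day = lag %in% top)]
  })
  data.table::fwrite(data.table::rbindlist(rows), path, na = "")
  invisible(path)
}
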