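temporal_fixture <- function() {
  lx <- tiny_lexicon()
  log <- make_log(
    c("u1", "u1", "u1", "u1", "u2", "u2", "u3"),
    c("2017-01-10", "2017-01-08", "2017-01-10", "2017-01-15",
      "2017-01-12", "2017-01-13", "2017-01-20"),
    c("cannabis", "cough", "headache", "coughing",
      "marijuana", "cough", "noise"))
  map <- build_day0_map(log, lx, seed = 1)
  list(lx = lx, log = log, map = map)
}

test_that("raw profile is the per-lag share of the concept's ADR queries", {
  fx <- temporal_fixture()
  p <- temporal_profile(fx$log, fx$lx, fx$map, "cough", lag_min = -5,
                        lag_max = 6)
  # u1 day0 Jan 10: cough at -2, headache at 0, coughing at +5
  # u2 day0 Jan 12: cough at +1
  expect_equal(p$raw[p$lag == -2], 1)
  expect_equal(p$raw[p$lag == 0], 0)   # headache query only
  expect_equal(p$raw[p$lag == 1], 1)
  expect_equal(p$raw[p$lag == 5], 1)
  expect_true(is.na(p$raw[p$lag == 3]))  # no ADR query at that lag
  # shares across concepts sum to one at every defined lag
  ph <- temporal_profile(fx$log, fx$lx, fx$map, "headache", -5, 6)
  pn <- temporal_profile(fx$log, fx$lx, fx$map, "nausea", -5, 6)
  tot <- p$raw + ph$raw + pn$raw
  expect_equal(tot[!is.na(tot)], rep(1, sum(!is.na(tot))))
  # invariant to record order
  perm <- fx$log[sample.int(nrow(fx$log)), ]
  expect_equal(as.data.frame(temporal_profile(perm, fx$lx, fx$map, "cough",
                                              -5, 6)),
               as.data.frame(p))
  # degenerate denominators: a never-queried concept is 0 where defined
  expect_true(all(pn$raw[!is.na(pn$raw)] == 0))
})

test_that("moving average is centered, truncated at edges, NA-aware", {
  base <- data.table::data.table(adr_concept = "x", lag = -10:10,
                                 n_adr = 0L, n_all = 1L, raw = 0.3,
                                 smoothed = NA_real_)
  cls <- c("temporal_profile", class(data.table::data.table()))
  data.table::setattr(base, "class", cls)
  sm <- smooth_moving_average(base, 7)
  expect_equal(sm$smoothed, rep(0.3, 21))  # constant series unchanged

  imp <- data.table::copy(base)
  imp[, raw := as.numeric(lag == 0)]
  smi <- smooth_moving_average(imp, 7)
  expect_equal(smi$smoothed[abs(smi$lag) <= 3], rep(1 / 7, 7))
  expect_equal(smi$smoothed[smi$lag == 5], 0)
  # edge truncation: first lag averages over the 4 available values
  expect_equal(smi$smoothed[1], 0)
  edge <- data.table::copy(base)
  edge[, raw := seq_len(21)]
  expect_equal(smooth_moving_average(edge, 7)$smoothed[1], mean(1:4))

  set.seed(9)
  for (i in 1:10) {
    rnd <- data.table::copy(base)
    vals <- runif(21)
    vals[sample.int(21, 4)] <- NA
    rnd[, raw := vals]
    expect_equal(smooth_moving_average(rnd, 7)$smoothed,
                 oracle_moving_average(vals, 7))
  }
  expect_error(smooth_moving_average(base, 4), "odd")
})

test_that("top-activity days are the upper quantile with ties included", {
  prof <- data.table::data.table(adr_concept = "x", lag = 1:100,
                                 n_adr = 0L, n_all = 1L, raw = 0,
                                 smoothed = as.numeric(100:1))
  expect_setequal(top_activity_days(prof, 0.25), 1:25)
  prof2 <- data.table::copy(prof)
  prof2[, smoothed := 1]
  expect_setequal(top_activity_days(prof2, 0.25), 1:100)  # all tied
  set.seed(4)
  for (i in 1:10) {
    prof3 <- data.table::copy(prof)
    vals <- sample(1:20, 100, replace = TRUE) + 0
    vals[sample.int(100, 10)] <- NA
    prof3[, smoothed := vals]
    got <- top_activity_days(prof3, 0.25)
    m <- ceiling(0.25 * sum(!is.na(vals)))
    want <- which(!is.na(vals) &
                    vapply(vals, function(v)
                      !is.na(v) && sum(vals > v, na.rm = TRUE) < m, logical(1)))
    expect_setequal(got, want)
  }
})

test_that("planted onset lags are recovered from the profile counts", {
  concepts <- c("anxiety", "headache", "cough")
  spec <- default_adr_specs()
  hits <- setNames(numeric(3), concepts)
  for (seed in 1:3) {
    cfg <- simulation_config(n_users = 10000, seed = 400 + seed)
    sim <- generate_query_log(cfg)
    map <- build_day0_map(sim$log, sim$lexicon, seed = 500 + seed)
    for (concept in concepts) {
      true_lag <- spec$onset_lag[spec$concept == concept]
      prof <- smooth_moving_average(
        temporal_profile(sim$log, sim$lexicon, map, concept, -90, 120))
      est <- estimate_onset(prof)
      if (!is.na(est) && abs(est - true_lag) <= 2) {
        hits[concept] <- hits[concept] + 1
      }
      if (seed == 1) {
        # top-activity days concentrate inside the elevated window
        top <- top_activity_days(prof, 0.25)
        dur <- spec$duration[spec$concept == concept]
        inside <- seq(true_lag, true_lag + dur - 1)
        outside <- setdiff(prof$lag, seq(true_lag - 3, true_lag + dur + 3))
        expect_gt(mean(inside %in% top), 0.7)
        expect_gt(mean(inside %in% top), 2 * mean(outside %in% top))
      }
    }
    if (seed == 1) {
      # a non-planted concept shows no sustained exceedance
      flat <- temporal_profile(sim$log, sim$lexicon, map, "syncope", -90, 120)
      expect_true(is.na(estimate_onset(flat)))
    }
  }
  # onset recovery within +/-2 days in at least 2 of 3 seeds per concept
  expect_true(all(hits >= 2))
})
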