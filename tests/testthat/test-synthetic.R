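test_that("generation is deterministic given the seed, to the byte", {
  cfg <- simulation_config(n_users = 200, seed = 5,
                           news_events = list(list(text = "big news story",
                                                   total = 300,
                                                   spike_days = 2,
                                                   spike_height = 120)))
  tdir <- withr::local_tempdir()
  p1 <- file.path(tdir, "a.tsv")
  p2 <- file.path(tdir, "b.tsv")
  write_query_log(generate_query_log(cfg)$log, p1)
  write_query_log(generate_query_log(cfg)$log, p2)
  expect_identical(readLines(p1), readLines(p2))
  other <- generate_query_log(simulation_config(n_users = 200, seed = 6))
  expect_false(identical(readLines(p1), write_query_log(other$log, p2) |>
                           readLines()))
  # generating does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_query_log(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero prevalence yields no exposed users and no target queries", {
  units <- default_units()
  units$true_prevalence <- 0
  cfg <- simulation_config(n_users = 300, units = units, seed = 3)
  sim <- generate_query_log(cfg)
  expect_length(sim$truth$exposed_users, 0)
  expect_length(match_texts <- find_day0(sim$log, sim$lexicon)$user_id, 0)
})

test_that("invalid configuration fields are named in errors", {
  expect_error(simulation_config(n_users = 0), "n_users")
  expect_error(simulation_config(start = "2017-05-01", end = "2017-01-01"),
               "start/end")
  u <- default_units(); u$true_prevalence[1] <- 1.5
  expect_error(simulation_config(units = u), "true_prevalence")
  a <- default_adr_specs(); a$multiplier[1] <- 0.5
  expect_error(simulation_config(adr_specs = a), "multiplier")
  expect_error(simulation_config(news_events = list(list(text = "x"))),
               "news_events")
  expect_error(simulation_config(template_prob = 2), "template_prob")
})

test_that("null configuration leaves exposed and non-exposed rates equal", {
  specs <- default_adr_specs()
  specs$multiplier <- 1
  cfg <- simulation_config(n_users = 8000, adr_specs = specs,
                           queries_per_user_day = 0, seed = 12)
  sim <- generate_query_log(cfg)
  lab <- data.table::data.table(user_id = unique(sim$log$user_id))
  lab[, exposed := user_id %in% sim$truth$exposed_users]
  adr_rows <- sim$log[normalize_text(sim$log$text) %in%
                        paste(c("", "about ", "why "), "anxiety", sep = "") |
                        grepl("anxiety", sim$log$text), ]
  cnt <- adr_rows[, .N, by = user_id]
  lab <- merge(lab, cnt, by = "user_id", all.x = TRUE)
  lab[is.na(N), N := 0]
  # two-sample comparison of per-user ADR query counts
  p <- wilcox.test(N ~ exposed, data = lab, exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("exposed shares per unit track the configured prevalence", {
  cfg <- simulation_config(n_users = 20000, seed = 9,
                           queries_per_user_day = 0,
                           adr_specs = default_adr_specs()[1:2, ])
  sim <- generate_query_log(cfg)
  # measured over all simulated users: users without queries are absent
  # from the log, which would bias a log-presence denominator
  byu <- sim$truth$user_units[, .(frac = mean(is_exposed), n = .N), by = unit]
  byu <- merge(byu, sim$truth$unit_prevalence, by = "unit")
  se <- sqrt(byu$true_prevalence * (1 - byu$true_prevalence) / byu$n)
  expect_true(all(abs(byu$frac - byu$true_prevalence) < 4 * se + 1e-9))
})

test_that("news spike patterns satisfy the filter's two clauses", {
  cfg <- simulation_config(
    n_users = 500, seed = 33,
    news_events = list(list(text = "huge celebrity scandal", total = 12000,
                            spike_days = 3, spike_height = 1500)))
  sim <- generate_query_log(cfg)
  flagged <- detect_news_texts(sim$log)
  expect_equal(flagged, "huge celebrity scandal")
  kept <- filter_news(sim$log, flagged)
  expect_false(any(normalize_text(kept$text) == "huge celebrity scandal"))
  # filtering removes no planted exposure signal
  d0 <- find_day0(kept, sim$lexicon)
  expect_setequal(d0$user_id, sim$truth$exposed_users)
})

test_that("reference reports let planted reactions dominate the counts", {
  specs <- default_adr_specs()
  specs$multiplier <- 1
  specs$multiplier[specs$concept == "nausea"] <- 10
  wins <- 0
  for (seed in 1:100) {
    cfg <- simulation_config(n_users = 10, adr_specs = specs, seed = seed,
                             ref_report_dispersion = 0.1)
    rs <- generate_reference_reports(cfg)
    top <- rs$adr_concept[which.max(rs$report_count)]
    if (top == "nausea") wins <- wins + 1
  }
  expect_gte(wins, 95)
  # zero floor and multiplier 1 give zero counts
  specs$multiplier <- 1
  cfg0 <- simulation_config(n_users = 10, adr_specs = specs,
                            ref_report_floor = 0, seed = 2)
  expect_true(all(generate_reference_reports(cfg0)$report_count == 0))
  # all-equal multipliers: no concept is positionally favoured
  means <- rowMeans(sapply(1:200, function(s) {
    generate_reference_reports(simulation_config(
      n_users = 10, adr_specs = specs, seed = s))$report_count
  }))
  expect_lt(max(means) - min(means), 1.0)  # floor mean is 0.5 per concept
})
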