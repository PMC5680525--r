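test_that("geo features are distinct-user fractions per unit", {
  lx <- tiny_lexicon()
  # unit A: 10 users, 2 of whom query cannabis (one of them twice)
  users_a <- paste0("a", 1:10)
  log <- data.table::rbindlist(list(
    make_log(users_a, "2017-01-05", rep("noise", 10), state = "A"),
    make_log(c("a1", "a1", "a2"), "2017-01-06",
             c("cannabis", "cannabis laws", "marijuana"), state = "A"),
    make_log("b1", "2017-01-05", "cough", state = "B")))
  ft <- build_geo_features(log, lx, level = "state")
  expect_s3_class(ft, "geo_feature_table")
  expect_equal(ft$n_users, c(10, 1))
  expect_equal(ft$cannabis, c(0.2, 0))      # duplicate queries count once
  expect_equal(ft$cough, c(0, 1))
  expect_equal(ft$nausea, c(0, 0))          # term queried by nobody
  # invariant to record order
  perm <- log[sample.int(nrow(log)), ]
  expect_equal(as.data.frame(build_geo_features(perm, lx, level = "state")),
               as.data.frame(ft))
  # plain term vectors work like single-term concepts
  ft2 <- build_geo_features(log, c("cannabis", "cough"), level = "state")
  expect_equal(ft2$cannabis, c(0.1, 0))     # term, not concept: no synonyms
  # empty geographic fields are dropped with a warning
  log$state[1] <- ""
  expect_warning(build_geo_features(log, lx, level = "state"), "empty")
})

test_that("stepwise selection recovers exact and noisy linear structure", {
  sc <- generate_prevalence_scenario(n_units = 60, n_terms = 8,
                                     n_informative = 1, noise_frac = 0,
                                     seed = 11)
  m <- fit_stepwise(sc$features, sc$observed)
  expect_equal(m$selected_terms, sc$informative_terms)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_equal(m$coefficients[[sc$informative_terms]],
               sc$true_coefficients[[sc$informative_terms]], tolerance = 1e-6)
  expect_equal(m$intercept, sc$intercept, tolerance = 1e-6)

  sc3 <- generate_prevalence_scenario(n_units = 100, n_terms = 13,
                                      n_informative = 3, noise_frac = 0.1,
                                      seed = 12)
  m3 <- fit_stepwise(sc3$features, sc3$observed)
  expect_true(all(sc3$informative_terms %in% m3$selected_terms))
  expect_equal(sign(m3$coefficients[sc3$informative_terms]),
               sign(sc3$true_coefficients), ignore_attr = TRUE)
  # deterministic: repeated fits identical
  expect_identical(m3, fit_stepwise(sc3$features, sc3$observed))
})

test_that("constant features are dropped and degenerate input errors", {
  sc <- generate_prevalence_scenario(n_units = 40, n_terms = 4, seed = 3)
  sc$features[, term01 := 0.5]
  attr_terms <- attr(sc$features, "terms")
  expect_warning(m <- fit_stepwise(sc$features, sc$observed), "constant")
  expect_false("term01" %in% m$selected_terms)
  expect_error(fit_stepwise(sc$features, sc$observed[1:10, ]), "missing")
})

test_that("model application reproduces fitted values and flags gaps", {
  sc <- generate_prevalence_scenario(n_units = 50, n_terms = 6,
                                     n_informative = 2, noise_frac = 0.05,
                                     seed = 21)
  m <- fit_stepwise(sc$features, sc$observed)
  pred <- apply_model(m, sc$features)
  ev <- evaluate_predictions(pred$predicted, sc$observed$observed_prevalence)
  expect_equal(ev$r_squared, m$r_squared, tolerance = 1e-9)
  expect_true(all(pred$predicted_clipped >= 0 & pred$predicted_clipped <= 1))
  # intercept-only model predicts a constant
  m0 <- m
  m0$selected_terms <- character(0)
  m0$coefficients <- numeric(0)
  expect_equal(unique(apply_model(m0, sc$features)$predicted), m0$intercept)
  # missing selected term is a named error
  ftbad <- data.table::copy(sc$features)
  ftbad[, (m$selected_terms[1]) := NULL]
  expect_error(apply_model(m, ftbad), m$selected_terms[1], fixed = TRUE)
})

test_that("prediction evaluation separates correlation from calibration", {
  obs <- c(0.1, 0.2, 0.3, 0.4)
  ev <- evaluate_predictions(obs, obs)
  expect_equal(ev$r_squared, 1)
  expect_equal(ev$pearson_r, 1)
  off <- evaluate_predictions(obs + 0.1, obs)
  expect_equal(off$pearson_r, 1)
  expect_lt(off$r_squared, 1)
  set.seed(17)
  for (i in 1:10) {
    p <- runif(8); o <- runif(8)
    ev2 <- evaluate_predictions(p, o)
    expect_equal(ev2$pearson_r, cor(p, o))
    expect_equal(ev2$r_squared, 1 - sum((o - p)^2) / sum((o - mean(o))^2))
  }
  expect_error(evaluate_predictions(1:4 / 4, rep(0.5, 4)), "constant")
})

test_that("aggregation pools users and weights fractions accordingly", {
  sc <- generate_prevalence_scenario(n_units = 10, n_terms = 2,
                                     n_informative = 1, n_coarse = 2,
                                     seed = 5)
  co <- aggregate_features(sc$features, sc$mapping, level = "coarse")
  expect_equal(sum(co$n_users), sum(sc$features$n_users))
  grp <- sc$mapping$coarse_unit[1]
  fine <- sc$features[sc$mapping$coarse_unit == grp, ]
  expect_equal(co$term01[co$unit == grp],
               sum(fine$term01 * fine$n_users) / sum(fine$n_users))
})

test_that("planted per-unit target fractions track true prevalence", {
  cfg <- simulation_config(n_users = 4000, seed = 19,
                           queries_per_user_day = 0.01,
                           adr_specs = default_adr_specs()[1:3, ])
  sim <- generate_query_log(cfg)
  ft <- build_geo_features(sim$log, sim$lexicon, level = "county")
  tp <- merge(ft, sim$truth$unit_prevalence, by.x = "unit", by.y = "unit")
  # exposed users always query the target at day 0, so the fraction
  # estimates prevalence within binomial error
  se <- sqrt(tp$true_prevalence * (1 - tp$true_prevalence) / tp$n_users)
  expect_true(all(abs(tp$cannabis - tp$true_prevalence) < 3.5 * se + 1e-9))
  expect_gt(cor(tp$cannabis, tp$true_prevalence), 0.8)
})
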