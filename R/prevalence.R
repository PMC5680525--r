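#' Per-unit term-user fractions
#'
#' For each geographic unit at the requested level and each term, computes
#' the number of distinct users in the unit with at least one query matching
#' the term, divided by the number of distinct users in the unit. Counting is
#' user-level, so duplicate queries by one user do not change a fraction, and
#' the result is invariant to record order. Records with an empty geographic
#' field are dropped with a warning.
#'
#' @param log a query log.
#' @param terms either a character vector of terms (each term is its own
#'   feature, matched as a whole-token phrase) or a [lexicon] (one feature
#'   per concept).
#' @param level one of `"state"`, `"region"`, `"county"`.
#' @return A `geo_feature_table`: `data.table` with columns `unit`, `level`,
#'   `n_users`, then one column per term with the user fraction in `[0, 1]`.
#'   Attribute `terms` holds the feature column names.
#' @export
build_geo_features <- function(log, terms, level = c("state", "region", "county")) {
  level <- match.arg(level)
  dt <- data.table::as.data.table(log)
  if (!level %in% names(dt)) stopf("log has no '%s' column", level)
  dt <- dt[, .(user_id, unit = get(level), text)]
  n_empty <- sum(!nzchar(dt$unit) | is.na(dt$unit))
  if (n_empty) {
    warnf("dropping %d record(s) with empty '%s' field", n_empty, level)
    dt <- dt[nzchar(unit) & !is.na(unit)]
  }
  if (!nrow(dt)) stopf("no records with a '%s' value", level)
  if (inherits(terms, "lexicon")) {
    lx <- terms
    term_names <- unique(lx$concept_id)
  } else {
    term_names <- sort(unique(as.character(terms)))
    lx <- lexicon(data.frame(concept_id = term_names, kind = "target",
                             synonym = term_names))
  }
  users <- unique(dt[, .(user_id, unit)])
  # a user querying from several units counts in each unit they appear in
  base <- users[, .(n_users = .N), by = unit]
  m <- match_texts(dt$text, lx)
  out <- data.table::data.table(unit = base$unit, level = level,
                                n_users = base$n_users)
  for (tn in term_names) out[, (tn) := 0]
  if (nrow(m)) {
    hits <- unique(data.table::data.table(user_id = dt$user_id[m$idx],
                                          unit = dt$unit[m$idx],
                                          term = m$concept_id))
    frac <- hits[, .(n_term = .N), by = .(unit, term)]
    for (tn in term_names) {
      ft <- frac[frac$term == tn, ]
      idx <- match(ft$unit, out$unit)
      out[idx, (tn) := ft$n_term / out$n_users[idx]]
    }
  }
  data.table::setorder(out, unit)
  data.table::setattr(out, "terms", term_names)
  data.table::setattr(out, "class", c("geo_feature_table", class(out)))
  out
}

#' Aggregate a feature table to a coarser level
#'
#' Combines fine units into coarse units by user-weighted averaging of the
#' term fractions (equivalent to recomputing the fractions over the pooled
#' users when users belong to a single fine unit).
#'
#' @param features a `geo_feature_table`.
#' @param mapping data.frame with columns `unit` (fine) and `coarse_unit`.
#' @param level label for the aggregated level (default `"aggregate"`).
#' @return a `geo_feature_table` at the coarse level.
#' @export
aggregate_features <- function(features, mapping, level = "aggregate") {
  terms <- attr(features, "terms")
  lvl <- level
  ft <- merge(data.table::as.data.table(features),
              data.table::as.data.table(mapping), by = "unit")
  if (nrow(ft) < nrow(features)) {
    warnf("%d unit(s) missing from mapping were dropped",
          nrow(features) - nrow(ft))
  }
  out <- ft[, c(list(level = lvl, n_users = sum(n_users)),
                lapply(.SD, function(v) sum(v * n_users) / sum(n_users))),
            by = .(unit = coarse_unit), .SDcols = terms]
  data.table::setorder(out, unit)
  data.table::setattr(out, "terms", terms)
  data.table::setattr(out, "class", c("geo_feature_table", class(out)))
  out
}

#' Stepwise linear model of prevalence on term fractions
#'
#' Forward-backward stepwise ordinary least squares: at each step the
#' excluded term with the smallest partial-F p-value is added if below
#' `p_enter`, then any included term whose p-value exceeds `p_remove` is
#' removed (worst first). Ties are broken by term name, so selection is
#' deterministic given the data. Terminates when no change occurs (or a
#' previously visited model recurs). Constant features are dropped up front
#' with a warning.
#'
#' @param features a `geo_feature_table`.
#' @param observed observed prevalence per unit: data.frame with columns
#'   `unit`, `observed_prevalence` covering every unit in `features`.
#' @param p_enter partial-F p-value to enter (default 0.05).
#' @param p_remove p-value above which an included term is removed
#'   (default 0.10).
#' @return A `prevalence_model`: list with `selected_terms` (in selection
#'   order), `coefficients` (named, excluding intercept), `intercept`,
#'   `r_squared`, `n_units`, `fit_level`, `p_enter`, `p_remove`.
#' @export
fit_stepwise <- function(features, observed, p_enter = 0.05, p_remove = 0.10) {
  terms <- attr(features, "terms")
  ft <- data.table::as.data.table(features)
  obs <- data.table::as.data.table(observed)
  if (!all(c("unit", "observed_prevalence") %in% names(obs))) {
    stopf("observed needs columns unit, observed_prevalence")
  }
  d <- merge(ft, obs[, .(unit, observed_prevalence)], by = "unit")
  if (nrow(d) < nrow(ft)) {
    stopf("observed prevalence missing for %d unit(s)", nrow(ft) - nrow(d))
  }
  if (anyNA(d$observed_prevalence)) stopf("observed prevalence contains NA")
  const <- terms[vapply(terms, function(tn) stats::var(d[[tn]]) == 0, logical(1))]
  if (length(const)) {
    warnf("dropping constant feature(s): %s", paste(const, collapse = ", "))
    terms <- setdiff(terms, const)
  }
  if (nrow(d) <= length(terms)) {
    stopf("need more units (%d) than candidate terms (%d)", nrow(d), length(terms))
  }
  # syntactic column names for the formula interface; map back at the end
  safe <- paste0("x", seq_along(terms))
  names(safe) <- terms
  df <- data.frame(.y = d$observed_prevalence)
  for (tn in terms) df[[safe[tn]]] <- d[[tn]]

  # add1/drop1 warn on exact fits ("essentially perfect fit"); a noise-free
  # linear response is a legitimate input here, so muffle just that warning
  quiet_exact <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  selected <- character(0) # original term names, in selection order
  fit <- stats::lm(.y ~ 1, data = df)
  refit <- function(sel) {
    rhs <- if (length(sel)) paste(safe[sel], collapse = " + ") else "1"
    stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  }
  seen <- character(0)
  repeat {
    changed <- FALSE
    # on a numerically exact fit the residual is machine noise and partial-F
    # p-values are meaningless; selection stops
    ss_tot <- sum((df$.y - mean(df$.y))^2)
    exact <- sum(stats::residuals(fit)^2) <= 1e-12 * ss_tot
    excl <- if (exact) character(0) else setdiff(terms, selected)
    if (length(excl)) {
      scope <- stats::as.formula(paste("~ . +", paste(safe[excl], collapse = " + ")))
      a <- quiet_exact(stats::add1(fit, scope = scope, test = "F"))
      p <- a[["Pr(>F)"]]
      names(p) <- rownames(a)
      p <- p[safe[excl]]
      cand <- excl[order(p, excl)] # tie-break by term name
      if (length(cand) && is.finite(p[safe[cand[1]]]) &&
          p[safe[cand[1]]] < p_enter) {
        selected <- c(selected, cand[1])
        fit <- refit(selected)
        changed <- TRUE
      }
    }
    if (length(selected) > 1) {
      dr <- quiet_exact(stats::drop1(fit, test = "F"))
      p <- dr[["Pr(>F)"]]
      names(p) <- rownames(dr)
      p <- p[safe[selected]]
      worst <- selected[order(-p, selected)][1]
      if (is.finite(p[safe[worst]]) && p[safe[worst]] > p_remove) {
        selected <- setdiff(selected, worst)
        fit <- refit(selected)
        changed <- TRUE
      }
    }
    key <- paste(sort(selected), collapse = "|")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }
  coefs <- stats::coef(fit)
  beta <- stats::setNames(as.numeric(coefs[safe[selected]]), selected)
  structure(list(
    selected_terms = selected,
    coefficients = beta,
    intercept = as.numeric(coefs[["(Intercept)"]]),
    r_squared = quiet_exact(summary(fit)$r.squared),
    n_units = nrow(df),
    fit_level = if (nrow(d)) d$level[1] else NA_character_,
    p_enter = p_enter, p_remove = p_remove
  ), class = "prevalence_model")
}

#' @export
print.prevalence_model <- function(x, ...) {
  cat(sprintf("<prevalence_model> level=%s, n=%d, R^2=%.3f\n  terms: %s\n",
              x$fit_level, x$n_units, x$r_squared,
              if (length(x$selected_terms))
                paste(sprintf("%s (%+.3g)", x$selected_terms, x$coefficients),
                      collapse = ", ")
              else "(intercept only)"))
  invisible(x)
}

#' Apply a prevalence model to a feature table
#'
#' Linear prediction `intercept + sum(coefficient * fraction)`. The feature
#' table may be at a different aggregation level than the fitting data
#' (cross-resolution transfer); it must contain every selected term.
#' Predictions can fall outside `[0, 1]` and are reported both raw and
#' clipped.
#'
#' @param model a `prevalence_model`.
#' @param features a `geo_feature_table`.
#' @return `data.table` with columns `unit`, `predicted`, `predicted_clipped`.
#' @export
apply_model <- function(model, features) {
  miss <- setdiff(model$selected_terms, names(features))
  if (length(miss)) {
    stopf("feature table lacks selected term(s): %s", paste(miss, collapse = ", "))
  }
  ft <- data.table::as.data.table(features)
  pred <- rep(model$intercept, nrow(ft))
  for (tn in model$selected_terms) {
    pred <- pred + model$coefficients[[tn]] * ft[[tn]]
  }
  data.table::data.table(unit = ft$unit, predicted = pred,
                         predicted_clipped = pmin(1, pmax(0, pred)))
}

#' Evaluate predictions against observations
#'
#' Pearson correlation and coefficient of determination
#' `1 - SS_res / SS_tot`. The two differ under miscalibration: a constant
#' offset leaves `r = 1` but lowers `R^2`.
#'
#' @param predicted,observed numeric vectors of equal length (>= 3).
#' @return list with `r_squared` and `pearson_r`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  if (length(observed) < 3) stopf("need at least 3 paired units")
  if (stats::var(observed) == 0) stopf("observed vector is constant")
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       pearson_r = stats::cor(predicted, observed))
}
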