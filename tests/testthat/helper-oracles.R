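# Independent brute-force oracles. These re-derive every quantity with
# explicit loops and direct formulas, sharing no code path with the package
# implementations they check.

# Token-level matcher: does `phrase` occur as a contiguous token run in text?
oracle_match_concepts <- function(text, lx) {
  toks <- strsplit(tolower(gsub("[^a-z0-9]+", " ", tolower(text))), " +")[[1]]
  toks <- toks[nzchar(toks)]
  hit <- character(0)
  for (i in seq_len(nrow(lx))) {
    ptoks <- strsplit(lx$synonym[i], " ", fixed = TRUE)[[1]]
    k <- length(ptoks)
    if (k == 0 || k > length(toks)) next
    for (s in seq_len(length(toks) - k + 1)) {
      if (all(toks[s:(s + k - 1)] == ptoks)) {
        hit <- c(hit, lx$concept_id[i])
        break
      }
    }
  }
  unique(hit)
}

# Per-user enumeration of both contingency tables for one ADR concept,
# classifying users by the day0 map's exposure flag and anchor date.
oracle_tables <- function(log, lx, day0map, adr) {
  log <- as.data.frame(log)
  map <- as.data.frame(day0map)
  a <- b <- c_ <- d <- e <- f <- g <- h <- 0L
  for (u in unique(log$user_id)) {
    rows <- log[log$user_id == u, ]
    mrow <- map[map$user_id == u, ]
    stopifnot(nrow(mrow) == 1)
    exposed <- mrow$is_exposed
    day0 <- mrow$day0
    ever <- FALSE; after <- FALSE; before <- FALSE
    for (j in seq_len(nrow(rows))) {
      concepts <- oracle_match_concepts(rows$text[j], lx)
      if (adr %in% concepts) {
        ever <- TRUE
        if (rows$date[j] >= day0) after <- TRUE else before <- TRUE
      }
    }
    if (exposed) {
      if (ever) d <- d + 1L else b <- b + 1L
      if (after) f <- f + 1L
      if (before) h <- h + 1L
    } else {
      if (ever) c_ <- c_ + 1L else a <- a + 1L
      if (after) e <- e + 1L
      if (before) g <- g + 1L
    }
  }
  list(t1 = list(a = a, b = b, c = c_, d = d),
       t2 = list(e = e, f = f, g = g, h = h))
}

# Direct formula evaluation (NA for undefined, no reason attributes).
oracle_measures <- function(t1, t2) {
  e <- t2$e; f <- t2$f; g <- t2$g; h <- t2$h
  qr <- if (e + g == 0) NA_real_ else (f + h) / (e + g)
  n <- e + f + g + h
  den <- (e + f) * (g + h) * (e + g) * (f + h)
  ql <- if (den == 0) 0 else n * (e * h - f * g)^2 / den
  qp <- if (t1$d + t1$b == 0 || t1$a + t1$c == 0 || t1$c == 0) NA_real_
        else (t1$d / (t1$d + t1$b)) / (t1$c / (t1$a + t1$c))
  pq <- if (f + h == 0 || e + g == 0 || g == 0) NA_real_
        else (h / (f + h)) / (g / (e + g))
  list(qr = qr, qlrs = ql, qprr = qp, pqr = pq)
}

# AUC as the fraction of (positive, negative) pairs correctly ordered,
# ties counting one half.
oracle_auc <- function(scores, labels) {
  s <- scores[!is.na(scores)]
  pos <- s[names(s) %in% labels]
  neg <- s[!names(s) %in% labels]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
    }
  }
  tot / (length(pos) * length(neg))
}

# Midrank Spearman via Pearson on explicit ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Exhaustive greedy outlier search: at each of k steps try every single
# removal and keep the one maximizing Spearman rho (ties by concept id).
oracle_greedy <- function(scores, counts, k) {
  ids <- names(scores)
  removed <- character(0)
  path <- oracle_spearman(scores, counts)
  for (step in seq_len(k)) {
    keep <- setdiff(ids, removed)
    best_id <- NA_character_
    best_rho <- -Inf
    for (cc in sort(keep)) {
      rest <- setdiff(keep, cc)
      r <- oracle_spearman(scores[rest], counts[rest])
      if (r > best_rho + 1e-15) {
        best_rho <- r
        best_id <- cc
      }
    }
    removed <- c(removed, best_id)
    path <- c(path, best_rho)
  }
  list(outliers = removed, rho_path = path)
}

# Brute-force truncated-window moving average with NA exclusion.
oracle_moving_average <- function(x, window) {
  half <- window %/% 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (length(w) > 0) out[i] <- sum(w) / length(w)
  }
  out
}
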