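# Independent oracles and hand-built fixtures. Everything here is written
# brute-force (explicit loops, sorted arrays, direct formula evaluation) so
# it shares no code path with the package implementation it checks.

# Build a survey_design directly from an event table, bypassing the
# generator, for tests that need full control over events.
make_design <- function(events) {
  n <- nrow(events)
  events$event_id <- events$event_id %||% sprintf("e%05d", seq_len(n))
  events$unit_16km <- events$unit_16km %||% rep("P001", n)
  events$subregion <- events$subregion %||% rep("MF", n)
  events$effort_units <- events$effort_units %||% rep("m2", n)
  events$year <- events$year %||% rep(2020, n)
  units <- unique(events[, c("unit_1km", "unit_16km", "subregion")])
  rownames(units) <- NULL
  structure(list(events = events, units = units, methods = survey_methods()),
            class = "survey_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear-interpolation quantile on a sorted array (type-7 definition),
# written from the definition.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# 41-node adaptive Gauss-Hermite evaluation of the marginal log-likelihood
# of an intercept-only NB model with offset(log(effort)) and one random
# intercept per unit, at fixed parameters.
gh_loglik_nb <- function(dat, beta0, k, sd_unit, nodes = 41) {
  gh <- pracma::gaussHermite(nodes)
  ll <- 0
  for (u in unique(dat$unit_1km)) {
    d <- dat[dat$unit_1km == u, ]
    f <- function(bv) vapply(bv, function(b1) {
      sum(dnbinom(d$count, size = k,
                  mu = exp(beta0 + b1 + log(d$effort)), log = TRUE)) +
        dnorm(b1, 0, sd_unit, log = TRUE)
    }, numeric(1))
    bhat <- optimize(function(b1) -f(b1), c(-8, 8))$minimum
    h <- -((f(bhat + 1e-4) - 2 * f(bhat) + f(bhat - 1e-4)) / 1e-8)
    s <- 1 / sqrt(h)
    vals <- f(bhat + sqrt(2) * s * gh$x)
    m <- max(vals)
    ll <- ll + log(sum(gh$w * exp(vals + gh$x^2 - m))) + m + log(sqrt(2) * s)
  }
  ll
}

# Spreadsheet-style oracle for the index pipeline: expected abundance per
# effort, min-max rescaling, group indices, evenness and overall index,
# computed cell by cell with explicit loops.
index_oracle <- function(lambda_tbl, weights, groups) {
  units <- sort(unique(lambda_tbl$unit_1km))
  taxa <- unique(lambda_tbl$taxon)
  methods <- unique(lambda_tbl$method)

  mu <- array(NA_real_, dim = c(length(taxa), length(methods), length(units)),
              dimnames = list(taxa, methods, units))
  for (t in taxa) for (i in methods) for (u in units) {
    rows <- lambda_tbl$taxon == t & lambda_tbl$method == i & lambda_tbl$unit_1km == u
    if (any(rows)) {
      mu[t, i, u] <- sum(lambda_tbl$lambda[rows]) / sum(lambda_tbl$effort[rows])
    }
  }
  mup <- mu
  for (t in taxa) for (i in methods) {
    v <- mu[t, i, ]
    if (all(is.na(v))) next
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    mup[t, i, ] <- if (hi - lo == 0) ifelse(is.na(v), NA, 0) else (v - lo) / (hi - lo)
  }
  B <- matrix(NA_real_, length(units), length(unique(groups)),
              dimnames = list(units, unique(groups)))
  for (g in unique(groups)) {
    gtaxa <- taxa[groups[match(taxa, names(groups))] == g]
    for (u in units) {
      valid_methods <- character()
      for (i in methods) {
        if (any(!is.na(mup[gtaxa, i, u]))) valid_methods <- c(valid_methods, i)
      }
      if (!length(valid_methods)) next
      acc <- 0
      for (t in gtaxa) {
        s <- 0
        for (i in valid_methods) if (!is.na(mup[t, i, u])) s <- s + mup[t, i, u]
        acc <- acc + s / length(valid_methods) * weights$W[weights$taxon == t]
      }
      B[u, g] <- acc
    }
  }
  H <- Bo <- rep(NA_real_, length(units)); names(H) <- names(Bo) <- units
  for (u in units) {
    bg <- B[u, ]
    if (any(is.na(bg))) next
    tot <- sum(bg)
    if (tot == 0) { H[u] <- 0; Bo[u] <- 0; next }
    p <- bg / tot
    h <- 0
    for (pp in p) if (pp > 0) h <- h - pp * log(pp)
    H[u] <- h / log(length(bg))
    Bo[u] <- H[u] * tot
  }
  list(mu = mu, mu_prime = mup, B = B, H = H, B_o = Bo)
}

# Sort-and-slice decile oracle: average ordinal ranks for ties, then
# ceil(10 r / N).
decile_oracle <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (1 + ties) / 2
  }
  as.integer(ceiling(10 * r / n))
}
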