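test_that("effort standardization and min-max rescaling follow the formulas", {
  lam <- data.frame(taxon = "t1", method = "dive",
                    unit_1km = c("u1", "u1", "u2"),
                    effort = c(100, 100, 50), lambda = c(2, 4, 1))
  mu <- mu_per_effort(lam)
  expect_equal(mu$mu[mu$unit_1km == "u1"], 0.03)   # (2+4)/(100+100)
  expect_equal(mu$mu[mu$unit_1km == "u2"], 0.02)   # single event: lambda/E

  m <- data.frame(taxon = "t1", method = "dive", unit_1km = c("a", "b", "c"),
                  mu = c(0.01, 0.03, 0.05))
  expect_equal(minmax_rescale(m)$mu_prime, c(0, 0.5, 1))
  const <- data.frame(taxon = "t1", method = "dive", unit_1km = c("a", "b"),
                      mu = c(0.2, 0.2))
  expect_equal(minmax_rescale(const)$mu_prime, c(0, 0))
})

test_that("group index combines methods and weights as specified", {
  w1 <- data.frame(taxon = "t1", W = 1)
  one <- data.frame(taxon = "t1", method = "dive", unit_1km = "u1",
                    mu = 1, mu_prime = 1)
  expect_equal(group_index(one, w1)$B, 1)
  zero <- transform(one, mu_prime = 0)
  expect_equal(group_index(zero, w1)$B, 0)

  # 2 taxa x 2 methods hand example
  tbl <- expand.grid(taxon = c("t1", "t2"), method = c("dive", "video_mid"),
                     unit_1km = c("u1", "u2"), stringsAsFactors = FALSE)
  tbl$mu_prime <- c(1, 0.5, 0.2, 0.8, 0, 0.25, 0.6, 0.4)
  w <- data.frame(taxon = c("t1", "t2"), W = c(1, 0.5))
  B <- group_index(tbl, w)
  # unit u1: t1 (1 + 0.2)/2 * 1 + t2 (0.5 + 0.8)/2 * 0.5
  expect_equal(B$B[B$unit_1km == "u1"], (1 + 0.2) / 2 * 1 + (0.5 + 0.8) / 2 * 0.5)
  expect_equal(B$B[B$unit_1km == "u2"], (0 + 0.6) / 2 * 1 + (0.25 + 0.4) / 2 * 0.5)
  expect_error(group_index(tbl, data.frame(taxon = "t1", W = 1)), "missing weight")
})

test_that("the overall index is evenness times total abundance", {
  B <- data.frame(unit_1km = c("u1", "u2", "u3"),
                  B_SEB = c(1, 5, 2), B_Cor = c(1, 0, 1), B_Sp = c(1, 0, 1))
  ov <- overall_index(B)
  expect_equal(ov$H[1], 1)
  expect_equal(ov$B_o[1], 3)
  expect_equal(ov$H[2], 0)        # single-group dominance
  expect_equal(ov$B_o[2], 0)
  expect_equal(ov$H[3], 0.946, tolerance = 5e-4)
  expect_equal(ov$B_o[3], 3.786, tolerance = 5e-4)
  # all-zero unit: no abundance, no hotspot signal
  z <- overall_index(data.frame(unit_1km = "u", B_SEB = 0, B_Cor = 0, B_Sp = 0))
  expect_equal(z$B_o, 0)
  # units missing a group survey are excluded
  miss <- overall_index(data.frame(unit_1km = c("u1", "u2"),
                                   B_SEB = c(1, NA), B_Cor = c(1, 1),
                                   B_Sp = c(1, 1)))
  expect_equal(miss$unit_1km, "u1")
})

test_that("decile ranks slice ordinal ranks into ten bins with shared ties", {
  set.seed(77)
  x10 <- sample(stats::runif(10))
  expect_setequal(decile_ranks(x10), 1:10)
  expect_equal(decile_ranks(x10)[which.max(x10)], 10L)

  x20 <- stats::runif(20)
  expect_equal(as.integer(table(decile_ranks(x20))), rep(2L, 10))

  # heavy zero mass: zeros share the low ranks, positives take the top
  x <- c(rep(0, 14), stats::runif(6) + 0.5)
  rk <- decile_ranks(x)
  expect_equal(rk, decile_oracle(x))
  expect_true(all(rk[x == 0] == rk[1]))
  expect_true(all(rk[x > 0] > rk[1]))
  # weak monotonicity
  o <- order(x)
  expect_true(all(diff(rk[o]) >= 0))
})

test_that("hotspot classification uses rank 9 generally but 10 for corals", {
  expect_true(classify_hotspots(9L, "sebastidae"))
  expect_true(classify_hotspots(10L, "sponge"))
  expect_false(classify_hotspots(9L, "coral"))
  expect_true(classify_hotspots(10L, "coral"))
  expect_false(classify_hotspots(1L, "overall"))
})

test_that("16-km aggregation averages the best child with the rest", {
  expect_equal(aggregate_16km(c(0.9, 0.1, 0.2), rep("P1", 3))$value,
               (0.9 + 0.15) / 2)
  expect_equal(aggregate_16km(0.4, "P1")$value, 0.4)

  set.seed(303)
  vals <- stats::runif(40)
  parent <- sample(sprintf("P%d", 1:10), 40, replace = TRUE)
  agg <- aggregate_16km(vals, parent)
  for (p in unique(parent)) {
    v <- vals[parent == p]
    oracle <- if (length(v) == 1) v else {
      vmax <- max(v)
      rest <- v[-which.max(v)]
      (vmax + sum(rest) / length(rest)) / 2
    }
    expect_equal(agg$value[agg$unit_16km == p], oracle, tolerance = 1e-12)
    # aggregation bound
    expect_gte(agg$value[agg$unit_16km == p], min(v))
    expect_lte(agg$value[agg$unit_16km == p], max(v))
  }
})

test_that("index invariants hold under randomized inputs", {
  set.seed(404)
  for (rep in 1:10) {
    n_u <- 25
    units <- sprintf("u%02d", 1:n_u)
    tbl <- expand.grid(taxon = c("t1", "t2", "t3"),
                       method = c("dive", "video_mid"),
                       unit_1km = units, stringsAsFactors = FALSE)
    tbl$mu <- stats::rexp(nrow(tbl))
    tbl <- minmax_rescale(tbl)
    w <- data.frame(taxon = c("t1", "t2", "t3"), W = stats::runif(3, 0.2, 1))
    B <- group_index(tbl, w)
    expect_true(all(B$B >= 0 & B$B <= sum(w$W) + 1e-12))

    # permuting unit order changes no rank
    rk <- decile_ranks(B$B)
    perm <- sample(n_u)
    expect_equal(decile_ranks(B$B[perm]), rk[perm])

    # raising one mu_prime weakly raises that unit's B and its rank
    i <- sample(nrow(tbl), 1)
    tbl2 <- tbl
    tbl2$mu_prime[i] <- min(1, tbl2$mu_prime[i] + 0.5)
    B2 <- group_index(tbl2, w)
    u <- tbl$unit_1km[i]
    expect_gte(B2$B[B2$unit_1km == u], B$B[B$unit_1km == u])
    expect_gte(decile_ranks(B2$B)[B2$unit_1km == u], rk[B$unit_1km == u])

    # evenness stays in [0, 1]
    Bw <- data.frame(unit_1km = units,
                     B_SEB = stats::rexp(n_u), B_Cor = stats::rexp(n_u),
                     B_Sp = stats::rexp(n_u))
    ov <- overall_index(Bw)
    expect_true(all(ov$H >= 0 & ov$H <= 1 + 1e-12))
    expect_true(all(ov$B_o <= Bw$B_SEB + Bw$B_Cor + Bw$B_Sp + 1e-12))
  }
})
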