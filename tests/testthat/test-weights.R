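seb_traits <- function(r, depletion = NA, TL = NA, ED = NA) {
  n <- length(r)
  data.frame(taxon = sprintf("s%02d", seq_len(n)), group = "sebastidae",
             r = r, depletion = rep_len(depletion, n), TL = rep_len(TL, n),
             ED = rep_len(ED, n), h = NA_real_, planktivore = FALSE,
             stringsAsFactors = FALSE)
}

test_that("component scores follow the ratio and min-max normalizations", {
  tr <- seb_traits(r = c(0.05, 0.10, 0.20), depletion = 0.5, TL = 3.5, ED = 10)
  sc <- score_components(tr)
  expect_equal(sc$Score1, c(4, 2, 1))

  tr2 <- seb_traits(r = c(0.05, 0.2), depletion = c(0.8, 0.2),
                    TL = c(3.0, 4.2), ED = c(5, 20))
  sc2 <- score_components(tr2)
  expect_equal(sc2$Score1[1], 4)           # species attaining max(1/r)
  expect_equal(sc2$Score3[1], 0)           # species at min(TL)
  expect_equal(sc2$Score3[2], 2)
  expect_equal(sc2$Score4[2], 2)
  expect_equal(sc2$Score2, c(4 * 0.2 / 0.8, 4))

  expect_warning(score_components(seb_traits(r = c(0.1, 0.2), depletion = c(1.3, 0.5),
                                             TL = 3, ED = 1)),
                 "clamped")
  expect_error(score_components(seb_traits(r = c(NA, NA), TL = 3)), "missing")
})

test_that("species weights renormalize over available components", {
  # all-maximal species: W = (4+4+2+2)/12 = 1
  tr <- seb_traits(r = c(0.05, 0.1), depletion = c(0, 0.5),
                   TL = c(4.5, 3.0), ED = c(30, 10))
  W <- weight_sebastidae(score_components(tr))
  expect_equal(W$W[1], 1)

  # ED and depletion missing; Score1 = 4 and Score3 = 2 give W = 6/6 = 1
  tr2 <- seb_traits(r = c(0.05, 0.1), TL = c(4.5, 3.0))
  W2 <- weight_sebastidae(score_components(tr2))
  expect_equal(W2$W[1], 1)
  expect_equal(W2$W[2], (2 + 0) / 6)

  # 4-species table against independent spreadsheet-style arithmetic
  tr3 <- seb_traits(r = c(0.05, 0.1, 0.2, 0.4),
                    depletion = c(0.2, 0.5, NA, 0.8),
                    TL = c(3.0, 3.5, 4.2, 2.9),
                    ED = c(10, 40, NA, 5))
  W3 <- weight_sebastidae(score_components(tr3))
  inv_r <- 1 / tr3$r
  s1 <- 4 * inv_r / 20
  s2 <- 4 * (1 - tr3$depletion) / 0.8
  s3 <- 2 * (tr3$TL - 2.9) / (4.2 - 2.9)
  s4 <- 2 * tr3$ED / 40
  oracle <- c((s1[1] + s2[1] + s3[1] + s4[1]) / 12,
              (s1[2] + s2[2] + s3[2] + s4[2]) / 12,
              (s1[3] + s3[3]) / 6,
              (s1[4] + s2[4] + s3[4] + s4[4]) / 12)
  expect_equal(W3$W, oracle, tolerance = 1e-12)

  sc_none <- score_components(seb_traits(r = c(0.1, 0.2)))
  sc_none[1, c("Score1")] <- NA  # species with nothing computable
  expect_error(weight_sebastidae(sc_none), "no computable")
})

test_that("coral weights are height ratios and sponge weight is unity", {
  corals <- data.frame(taxon = c("c1", "c2", "c3"), group = "coral",
                       h = c(10, 20, 40))
  expect_equal(weight_coral(corals)$W, c(0.25, 0.5, 1))
  one <- data.frame(taxon = "c1", group = "coral", h = 33)
  expect_equal(weight_coral(one)$W, 1)
  expect_error(weight_coral(data.frame(taxon = "c1", group = "coral", h = -2)),
               "h must be")

  ws <- weight_sponge()
  expect_equal(ws$W, 1)
  expect_equal(nrow(ws), 1)          # one pooled taxon
  expect_identical(weight_sponge(), weight_sponge())
})

test_that("weights are bounded, scale-invariant and extremum-stable", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    tr <- seb_traits(r = stats::runif(n, 0.02, 0.5),
                     depletion = stats::runif(n),
                     TL = stats::runif(n, 2.5, 4.8),
                     ED = stats::rexp(n, 1 / 15))
    tr$ED[stats::runif(n) < 0.2] <- NA
    W <- weight_sebastidae(score_components(tr))
    expect_true(all(W$W > 0 & W$W <= 1))
    expect_true(any(abs(W$Score1 - 4) < 1e-12))

    # positive rescaling of r and ED leaves ratio scores unchanged;
    # affine TL shifts leave the min-max score unchanged
    tr_sc <- tr
    tr_sc$r <- tr$r * 3.7
    tr_sc$ED <- tr$ED * 0.21
    tr_sc$TL <- tr$TL + 1.3
    W_sc <- weight_sebastidae(score_components(tr_sc))
    expect_equal(W_sc$Score1, W$Score1, tolerance = 1e-12)
    expect_equal(W_sc$Score3, W$Score3, tolerance = 1e-12)
    expect_equal(W_sc$Score4, W$Score4, tolerance = 1e-12)

    # dropping a species that holds no extremum leaves the others unchanged
    interior <- which(!(tr$r %in% range(tr$r)) &
                        !(tr$TL %in% range(tr$TL)) &
                        !(tr$depletion %in% range(tr$depletion)) &
                        !is.na(tr$ED) & tr$ED != max(tr$ED, na.rm = TRUE))
    if (length(interior)) {
      i <- interior[1]
      W_drop <- weight_sebastidae(score_components(tr[-i, ]))
      expect_equal(W_drop$W, W$W[-i], tolerance = 1e-12)
    }
    # dropping the max-1/r holder changes the Score1 of the rest
    i_max <- which.min(tr$r)
    if (n > 2 && length(unique(tr$r)) == n) {
      W_drop2 <- weight_sebastidae(score_components(tr[-i_max, ]))
      expect_false(isTRUE(all.equal(W_drop2$Score1, W$Score1[-i_max])))
    }

    corals <- data.frame(taxon = sprintf("c%d", 1:4), group = "coral",
                         h = stats::runif(4, 1, 100))
    expect_true(all(weight_coral(corals)$W > 0))
    expect_equal(max(weight_coral(corals)$W), 1)
  }
})

test_that("taxon_weights covers all groups in one table", {
  tr <- rbind(seb_traits(r = c(0.05, 0.1), depletion = 0.4, TL = c(3, 4), ED = 8),
              data.frame(taxon = "c1", group = "coral", r = NA, depletion = NA,
                         TL = NA, ED = NA, h = 25, planktivore = NA),
              data.frame(taxon = "sp_pooled", group = "sponge", r = NA,
                         depletion = NA, TL = NA, ED = NA, h = NA, planktivore = NA))
  W <- taxon_weights(tr)
  expect_setequal(W$taxon, c("s01", "s02", "c1", "sp_pooled"))
  expect_equal(W$W[W$taxon == "c1"], 1)        # single coral is the maximum
  expect_equal(W$W[W$taxon == "sp_pooled"], 1)
  expect_true(all(W$W > 0 & W$W <= 1))
})
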