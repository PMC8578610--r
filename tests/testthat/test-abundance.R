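sim_nb_data <- function(n_u = 30, n_e = 20, beta0 = -4, beta_d = 0.004,
                        sd_u = 0.3, k = 1.5, zi = 0, seed = 1) {
  set.seed(seed)
  dat <- data.frame(unit_1km = rep(sprintf("u%02d", seq_len(n_u)), each = n_e),
                    effort = stats::runif(n_u * n_e, 75, 130),
                    depth_m = stats::runif(n_u * n_e, 10, 300),
                    method = "video_mid", taxon = "t1")
  b <- stats::rnorm(n_u, 0, sd_u)
  eta <- beta0 + beta_d * dat$depth_m + rep(b, each = n_e) + log(dat$effort)
  y <- stats::rnbinom(nrow(dat), size = k, mu = exp(eta))
  if (zi > 0) y[stats::runif(nrow(dat)) < zi] <- 0L
  dat$count <- y
  dat
}

test_that("model specs are validated", {
  expect_error(abundance_model_spec("nbinom", "depth2"), "quadratic")
  expect_error(abundance_model_spec("nbinom", "salinity"), "unknown covariate")
  s <- abundance_model_spec("beta", c("depth"))
  expect_false(s$offset)                      # cover is already standardized
  expect_true(abundance_model_spec("nbinom")$offset)
})

test_that("NB mixed fit recovers parameters and honors the offset contract", {
  dat <- sim_nb_data(seed = 11)
  fit <- fit_abundance(abundance_model_spec("nbinom", "depth"), dat)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["(Intercept)"]] - (-4)), 3 * fit$se[["(Intercept)"]])
  expect_lt(abs(fit$beta[["depth_m"]] - 0.004), 3 * fit$se[["depth_m"]])
  expect_equal(fit$AIC, 2 * fit$npar - 2 * fit$logLik)

  # lambda equals the closed-form linear predictor with conditional modes
  lam <- predict_lambda(fit, dat)
  eta_hand <- fit$beta[["(Intercept)"]] + fit$beta[["depth_m"]] * dat$depth_m +
    fit$b_u[dat$unit_1km] + log(dat$effort)
  expect_equal(lam$lambda, unname(exp(eta_hand)), tolerance = 1e-8)
  expect_true(all(lam$lambda >= 0))

  # doubling effort doubles the expected count
  dat2 <- dat
  dat2$effort <- dat$effort * 2
  lam2 <- predict_lambda(fit, dat2)
  expect_equal(lam2$lambda, 2 * lam$lambda, tolerance = 1e-10)
})

test_that("zero-inflated predictions scale lambda by 1 - pi", {
  dat <- sim_nb_data(zi = 0.3, seed = 12)
  fit <- fit_abundance(abundance_model_spec("nbinom", "depth", zi = TRUE), dat)
  expect_true(fit$converged)
  expect_gt(fit$zi_prob, 0.15)
  lam <- predict_lambda(fit, dat)
  mu_cond <- stats::predict(fit$tmb, newdata = dat, type = "conditional",
                            allow.new.levels = TRUE)
  expect_equal(lam$lambda, as.numeric((1 - fit$zi_prob) * mu_cond),
               tolerance = 1e-8)
})

test_that("the NB fit approaches a Poisson fixed-effects fit as k grows", {
  set.seed(13)
  n <- 800
  dat <- data.frame(unit_1km = rep(sprintf("u%02d", 1:20), each = n / 20),
                    effort = 100, depth_m = stats::runif(n, 10, 200),
                    method = "video_mid", taxon = "t1")
  dat$count <- stats::rpois(n, exp(-3.5 + 0.003 * dat$depth_m + log(dat$effort)))
  fit <- fit_abundance(abundance_model_spec("nbinom", "depth"), dat,
                       start = list(theta = log(1e-3), betad = log(1e6)),
                       map = list(theta = factor(NA), betad = factor(NA)))
  glm_fit <- stats::glm(count ~ depth_m + offset(log(effort)), data = dat,
                        family = stats::poisson())
  expect_equal(unname(fit$beta), unname(stats::coef(glm_fit)), tolerance = 1e-3)
})

test_that("AIC selection prefers the generating structure", {
  dat <- sim_nb_data(beta_d = 0.008, seed = 14)
  cands <- list(abundance_model_spec("nbinom"),
                abundance_model_spec("nbinom", "depth"))
  best <- select_abundance_model(cands, dat)
  expect_true("depth_m" %in% names(best$beta))
  tab <- attr(best, "aic_table")
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$AIC) >= 0))

  # single candidate comes back as-is
  solo <- select_abundance_model(cands[2], dat)
  expect_equal(solo$beta, best$beta)

  # AIC is invariant to response row order
  perm <- sample(nrow(dat))
  best_perm <- select_abundance_model(cands, dat[perm, ])
  expect_equal(best_perm$AIC, best$AIC, tolerance = 1e-6)

  # every candidate failing is an error, not a silent fit
  bad <- list(abundance_model_spec("nbinom", c("taxon", "depth")))
  expect_error(select_abundance_model(bad, dat), "single taxon|no candidate")
})

test_that("predicted zero fraction tracks the observed one for a matched model", {
  dat <- sim_nb_data(n_u = 50, n_e = 100, seed = 15)   # n = 5000
  fit <- fit_abundance(abundance_model_spec("nbinom", "depth"), dat)
  zc <- zero_check(fit)
  expect_lt(abs(zc$difference), 0.02)
  expect_equal(zc$predicted - zc$observed, zc$difference)

  # a Poisson-like fit (dispersion pinned huge) underpredicts zeroes on
  # overdispersed data; the matched NB fit does better
  dat_od <- sim_nb_data(n_u = 40, n_e = 50, k = 0.4, seed = 16)
  fit_nb <- fit_abundance(abundance_model_spec("nbinom", "depth"), dat_od)
  fit_pois <- fit_abundance(abundance_model_spec("nbinom", "depth"), dat_od,
                            start = list(betad = log(1e6)),
                            map = list(betad = factor(NA)))
  expect_gt(abs(zero_check(fit_pois)$difference),
            abs(zero_check(fit_nb)$difference))
})

test_that("Laplace marginal log-likelihood matches 41-node quadrature", {
  skip_if_not_installed("pracma")
  set.seed(17)
  # high-information tiny instances: the Laplace approximation should agree
  # with adaptive Gauss-Hermite integration of the same likelihood
  for (s in c(1, 2, 3)) {
    set.seed(s)
    dat <- data.frame(unit_1km = "u1", effort = 100, method = "dive",
                      depth_m = 20, taxon = "t1",
                      count = stats::rnbinom(5, size = 50, mu = 500))
    fit <- fit_abundance(abundance_model_spec("nbinom"), dat,
                         start = list(theta = log(0.05)),
                         map = list(theta = factor(NA)))
    oracle <- gh_loglik_nb(dat, fit$beta[["(Intercept)"]], fit$dispersion, 0.05)
    expect_lt(abs(fit$logLik - oracle), 1e-4)
  }
})

test_that("beta cover fits run on compressed category midpoints", {
  set.seed(18)
  n <- 600
  dat <- data.frame(unit_1km = rep(sprintf("u%02d", 1:20), each = n / 20),
                    effort = 120, depth_m = stats::runif(n, 10, 150),
                    method = rep(c("dive", "video_mid"), n / 2), taxon = "sp")
  p <- stats::plogis(-1 + 0.01 * dat$depth_m)
  dat$cover_category <- cover_category(stats::rbeta(n, p * 30, (1 - p) * 30))
  dat$count <- NA_integer_
  fit <- fit_abundance(abundance_model_spec("beta", c("depth")), dat)
  expect_true(fit$converged)
  expect_gt(fit$beta[["depth_m"]], 0)
  lam <- predict_lambda(fit, dat)
  expect_true(all(lam$lambda > 0 & lam$lambda < 1))
})
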