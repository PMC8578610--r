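#' Logistic model of hotspot occurrence on depth and subregion
#'
#' Fits a multiple logistic regression of the per-unit hotspot flag on the
#' maximum depth sampled in the unit (raw linear and quadratic terms, so the
#' coefficients are interpretable per metre and per metre-squared and the
#' vertex depth can be read off them) and the oceanographic subregion, with
#' Mainland Fjords (MF) as the reference level. Subregions in which no
#' hotspot was recorded are excluded from the fit, as their contrast is not
#' estimable without separation. Complete separation in the remaining data
#' is detected and handled by refitting with Firth's penalized likelihood,
#' flagged on the returned object.
#'
#' @param records Data frame: one row per 1-km^2 unit with columns
#'   \code{hotspot} (logical/0-1), \code{max_depth_m} (> 0) and
#'   \code{subregion}.
#' @param reference Reference subregion level (default \code{"MF"}).
#' @param quadratic Include the quadratic depth term (default TRUE).
#' @return An object of class \code{"occurrence_fit"} with coefficients,
#'   standard errors, vcov, AIC, the observed depth range, the excluded
#'   subregions, and a separation flag.
#' @export
fit_occurrence <- function(records, reference = "MF", quadratic = TRUE) {
  stop_if_missing_cols(records, c("hotspot", "max_depth_m", "subregion"),
                       "occurrence records")
  dat <- as.data.frame(records)
  dat$hotspot <- as.integer(dat$hotspot)
  if (any(dat$max_depth_m <= 0)) stop("max_depth_m must be > 0")
  if (all(dat$hotspot == 0)) stop("no hotspots in the data; nothing to model")

  hs_by_sub <- tapply(dat$hotspot, dat$subregion, sum)
  excluded <- names(hs_by_sub)[hs_by_sub == 0]
  dat <- dat[!dat$subregion %in% excluded, , drop = FALSE]
  levs <- unique(as.character(dat$subregion))
  if (!reference %in% levs) reference <- levs[1]
  dat$subregion <- factor(dat$subregion, levels = c(reference, setdiff(levs, reference)))

  form <- if (quadratic) {
    hotspot ~ max_depth_m + I(max_depth_m^2) + subregion
  } else {
    hotspot ~ max_depth_m + subregion
  }
  if (length(levs) < 2) form <- stats::update(form, . ~ . - subregion)

  warn <- character()
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  separated <- any(grepl("fitted probabilities numerically 0 or 1", warn)) ||
    any(abs(stats::coef(fit)) > 15)

  if (separated) {
    pen <- firth_logistic(stats::model.matrix(fit), dat$hotspot)
    beta <- pen$beta
    V <- pen$vcov
    aic <- NA_real_
  } else {
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    aic <- stats::AIC(fit)
  }

  structure(list(
    coefficients = beta,
    se = sqrt(diag(V)),
    vcov = V,
    AIC = aic,
    separation = separated,
    excluded_subregions = excluded,
    reference = reference,
    quadratic = quadratic,
    depth_range = range(dat$max_depth_m),
    formula = form,
    n = nrow(dat),
    glm = if (separated) NULL else fit
  ), class = "occurrence_fit")
}

# Firth-penalized logistic regression: maximizes logL + 0.5 log det(X'WX),
# removing the first-order bias and keeping estimates finite under
# separation.
firth_logistic <- function(X, y, max_iter = 200, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XtWX <- crossprod(X * w, X)
    XtWXinv <- solve(XtWX)
    # hat diagonal of the weighted design
    h <- rowSums((X %*% XtWXinv) * X) * w
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(XtWXinv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  V <- solve(crossprod(X * w, X))
  dimnames(V) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(beta, colnames(X)), vcov = V)
}

#' @export
print.occurrence_fit <- function(x, ...) {
  cat("Hotspot occurrence logistic model\n")
  cat(sprintf("  n = %d units; reference subregion: %s\n", x$n, x$reference))
  if (length(x$excluded_subregions)) {
    cat("  excluded (no hotspots):", paste(x$excluded_subregions, collapse = ", "), "\n")
  }
  if (x$separation) cat("  ** separation detected; Firth-penalized fit **\n")
  print(round(cbind(Estimate = x$coefficients, SE = x$se), 6))
  if (!is.na(x$AIC)) cat(sprintf("  AIC %.2f\n", x$AIC))
  pk <- peak_depth(x)
  if (!is.na(pk)) cat(sprintf("  peak occurrence depth: %.0f m\n", pk))
  invisible(x)
}

#' @export
coef.occurrence_fit <- function(object, ...) object$coefficients

#' @export
summary.occurrence_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  out <- list(coefficients = cbind(Estimate = object$coefficients, SE = object$se,
                                   z = z, p = 2 * stats::pnorm(-abs(z))),
              AIC = object$AIC, n = object$n,
              excluded_subregions = object$excluded_subregions,
              separation = object$separation)
  class(out) <- "summary.occurrence_fit"
  out
}

#' @export
print.summary.occurrence_fit <- function(x, ...) {
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Odds ratio for a fitted contrast
#'
#' exp(direction * beta) for the named coefficient. The direction argument
#' makes the comparison explicit: +1 gives the odds of the named level
#' relative to the reference, -1 the reference relative to the level.
#'
#' @param fit An \code{occurrence_fit}, or a named coefficient vector.
#' @param contrast Coefficient name (e.g. \code{"subregionEQCS"}).
#' @param direction +1 or -1.
#' @return The odds ratio.
#' @export
odds_ratio <- function(fit, contrast, direction = 1) {
  stopifnot(direction %in% c(-1, 1))
  beta <- if (inherits(fit, "occurrence_fit")) fit$coefficients else fit
  if (!contrast %in% names(beta)) stop("unknown contrast: ", contrast)
  unname(exp(direction * beta[contrast]))
}

#' Depth at which the fitted occurrence probability peaks
#'
#' The vertex of the quadratic depth polynomial, -b1 / (2 * b2), defined
#' when the quadratic coefficient is negative. When the fit carries an
#' observed depth range the vertex is reported only if it falls inside that
#' range (an exterior vertex is extrapolation, not a peak).
#'
#' @param fit An \code{occurrence_fit}, or a numeric vector
#'   c(linear, quadratic) of depth coefficients.
#' @param within_range Restrict to the observed depth range when available.
#' @return Peak depth in metres, or NA when there is no interior maximum.
#' @export
peak_depth <- function(fit, within_range = TRUE) {
  if (inherits(fit, "occurrence_fit")) {
    if (!fit$quadratic) return(NA_real_)
    b1 <- fit$coefficients[["max_depth_m"]]
    b2 <- fit$coefficients[["I(max_depth_m^2)"]]
    rng <- fit$depth_range
  } else {
    stopifnot(is.numeric(fit), length(fit) == 2)
    b1 <- fit[[1]]
    b2 <- fit[[2]]
    rng <- NULL
  }
  if (is.na(b2) || b2 >= 0) return(NA_real_)
  vertex <- -b1 / (2 * b2)
  if (within_range && !is.null(rng) && (vertex < rng[1] || vertex > rng[2])) {
    return(NA_real_)
  }
  vertex
}

#' Predicted probability of hotspot occurrence
#'
#' Inverse-logit of the fitted linear predictor at the requested depths and
#' subregion, with an optional Wald confidence interval computed on the
#' logit scale.
#'
#' @param fit An \code{occurrence_fit}.
#' @param depth Depths (m).
#' @param subregion Single subregion label (default: the reference level).
#' @param ci Include a 95 percent Wald interval?
#' @return Data frame: subregion, depth, p (and lo, hi with \code{ci}).
#' @export
predict_probability <- function(fit, depth, subregion = NULL, ci = TRUE) {
  stopifnot(inherits(fit, "occurrence_fit"))
  beta <- fit$coefficients
  X <- cbind(1, depth)
  cn <- c("(Intercept)", "max_depth_m")
  if (fit$quadratic) {
    X <- cbind(X, depth^2)
    cn <- c(cn, "I(max_depth_m^2)")
  }
  sub_cols <- grep("^subregion", names(beta), value = TRUE)
  for (sc in sub_cols) {
    on <- !is.null(subregion) && identical(paste0("subregion", subregion), sc)
    X <- cbind(X, as.numeric(on))
    cn <- c(cn, sc)
  }
  colnames(X) <- cn
  X <- X[, names(beta), drop = FALSE]
  eta <- drop(X %*% beta)
  out <- data.frame(subregion = subregion %||% fit$reference, depth = depth,
                    p = stats::plogis(eta), stringsAsFactors = FALSE)
  if (ci) {
    se <- sqrt(rowSums((X %*% fit$vcov) * X))
    out$lo <- stats::plogis(eta - 1.96 * se)
    out$hi <- stats::plogis(eta + 1.96 * se)
  }
  out
}

#' Published logistic-regression coefficients for hotspot occurrence
#'
#' The per-group logistic coefficients (linear and quadratic depth terms and
#' subregion contrasts, with standard errors) reported by the coastwide
#' field study this package's methodology reimplements, shipped as a
#' plain-text table. Useful as worked-example inputs for
#' \code{\link{peak_depth}} and \code{\link{odds_ratio}}.
#'
#' @return Data frame: response, predictor, estimate, se.
#' @export
published_occurrence_coefficients <- function() {
  path <- system.file("extdata", "published_occurrence_coefficients.csv",
                      package = "reefhotspots", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
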