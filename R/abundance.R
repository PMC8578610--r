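#' Specify a candidate abundance GLMM
#'
#' Describes one candidate generalized linear mixed model for survey
#' abundance: a zero-inflated negative binomial for counts (log link) or a
#' beta model for percent cover (logit link), with a planning-unit random
#' intercept, optional covariates, and — for count families — a log-effort
#' offset so the linear predictor models expected count per unit effort.
#'
#' @param family \code{"nbinom"} for counts or \code{"beta"} for cover.
#' @param covariates Subset of \code{c("method", "depth", "depth2", "taxon")};
#'   the intercept is always present and \code{"depth2"} requires
#'   \code{"depth"}.
#' @param zi Logical: include a constant zero-inflation term?
#' @param dispersion One-sided formula for the NB dispersion model
#'   (default \code{~1}).
#' @param offset Logical: include \code{offset(log(effort))}. Defaults to
#'   TRUE for counts and FALSE for cover (cover is already area-standardized).
#' @param unit Name of the random-intercept grouping column.
#' @return An object of class \code{"abundance_spec"}.
#' @export
abundance_model_spec <- function(family = c("nbinom", "beta"),
                                 covariates = character(),
                                 zi = FALSE,
                                 dispersion = ~1,
                                 offset = NULL,
                                 unit = "unit_1km") {
  family <- match.arg(family)
  allowed <- c("method", "depth", "depth2", "taxon")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  if ("depth2" %in% covariates && !"depth" %in% covariates) {
    stop("a quadratic depth term requires the linear depth term")
  }
  if (is.null(offset)) offset <- family == "nbinom"
  structure(list(family = family, covariates = covariates, zi = isTRUE(zi),
                 dispersion = dispersion, offset = isTRUE(offset), unit = unit),
            class = "abundance_spec")
}

#' @export
print.abundance_spec <- function(x, ...) {
  cat(sprintf("abundance model spec: %s, ~ %s, zi = %s, offset = %s\n",
              x$family, spec_rhs(x), x$zi, x$offset))
  invisible(x)
}

spec_rhs <- function(spec) {
  terms <- c("1",
             if ("taxon" %in% spec$covariates) "taxon",
             if ("method" %in% spec$covariates) "method",
             if ("depth" %in% spec$covariates) "depth_m",
             if ("depth2" %in% spec$covariates) "I(depth_m^2)",
             sprintf("(1 | %s)", spec$unit),
             if (spec$offset) "offset(log(effort))")
  paste(terms, collapse = " + ")
}

spec_formula <- function(spec, response) {
  stats::as.formula(paste(response, "~", spec_rhs(spec)), env = globalenv())
}

# Map cover categories to interval midpoints, then compress into the open
# unit interval (y*(n-1)+0.5)/n so the beta likelihood is defined at the
# boundary categories.
cover_to_proportion <- function(category, n) {
  mid <- c(0, 0.125, 0.375, 0.625, 0.875)[category + 1L]
  (mid * (n - 1) + 0.5) / n
}

#' Fit an abundance GLMM
#'
#' Maximizes the marginal likelihood of the specified model with the
#' planning-unit random intercept integrated out by the Laplace
#' approximation (via \pkg{glmmTMB}, the estimation engine used throughout).
#' Counts use a negative binomial with log link (variance =
#' mean + mean^2/k); cover categories are mapped to interval midpoints,
#' compressed into (0, 1), and fitted with a beta likelihood on the logit
#' scale. Zero inflation, when requested, is a constant logit-scale mixture
#' term. Non-convergence sets a flag rather than raising; a singular fit
#' (random-intercept SD collapsing to 0) is reported the same way.
#'
#' @param spec An \code{\link{abundance_model_spec}}.
#' @param obs Observation table, already passed through
#'   \code{\link{filter_observations}}; needs at least 2 planning units (or a
#'   fixed random-intercept SD via \code{start}/\code{map}).
#' @param start,map Optional \pkg{glmmTMB} start values and parameter maps,
#'   e.g. to hold the random-intercept SD (\code{theta}) or the dispersion
#'   (\code{betad}) fixed for diagnostic fits.
#' @return An object of class \code{"abundance_fit"}.
#' @export
fit_abundance <- function(spec, obs, start = NULL, map = NULL) {
  stopifnot(inherits(spec, "abundance_spec"))
  dat <- as.data.frame(obs)
  if (length(unique(dat[[spec$unit]])) < 2 && !"theta" %in% names(map)) {
    stop("need at least 2 planning units to estimate a random intercept")
  }
  if (spec$family == "nbinom") {
    dat <- dat[!is.na(dat$count), , drop = FALSE]
    dat$.y <- dat$count
    fam <- glmmTMB::nbinom2(link = "log")
  } else {
    dat <- dat[!is.na(dat$cover_category), , drop = FALSE]
    dat$.y <- cover_to_proportion(dat$cover_category, nrow(dat))
    fam <- glmmTMB::beta_family(link = "logit")
  }
  if ("taxon" %in% spec$covariates && length(unique(dat$taxon)) < 2) {
    stop("taxon covariate requested but a single taxon present")
  }
  form <- spec_formula(spec, ".y")
  zif <- if (spec$zi) ~1 else ~0

  warn <- character()
  fit <- withCallingHandlers(
    tryCatch(
      glmmTMB::glmmTMB(form, data = dat, family = fam, ziformula = zif,
                       dispformula = spec$dispersion,
                       start = start %||% list(), map = map %||% list()),
      error = function(e) e
    ),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(fit, "error")) {
    return(structure(list(spec = spec, converged = FALSE,
                          error = conditionMessage(fit)),
                     class = "abundance_fit"))
  }

  converged <- isTRUE(fit$fit$convergence == 0) &&
    !isTRUE(fit$sdr$pdHess == FALSE)
  ss <- suppressWarnings(summary(fit)$coefficients$cond)
  vc <- glmmTMB::VarCorr(fit)$cond
  sd_unit <- if (length(vc)) sqrt(unname(vc[[1]][1, 1])) else NA_real_
  re <- glmmTMB::ranef(fit)$cond
  b_u <- if (length(re)) stats::setNames(re[[1]][, 1], rownames(re[[1]])) else numeric()
  ll <- as.numeric(stats::logLik(fit))
  npar <- attr(stats::logLik(fit), "df")

  structure(list(
    spec = spec,
    beta = stats::setNames(ss[, "Estimate"], rownames(ss)),
    se = stats::setNames(ss[, "Std. Error"], rownames(ss)),
    dispersion = if (spec$family == "nbinom") glmmTMB::sigma(fit) else glmmTMB::sigma(fit),
    zi_prob = if (spec$zi) stats::plogis(glmmTMB::fixef(fit)$zi[[1]]) else 0,
    sd_unit = sd_unit,
    b_u = b_u,
    logLik = ll,
    npar = npar,
    AIC = 2 * npar - 2 * ll,
    converged = converged,
    singular = isTRUE(!is.na(sd_unit) && sd_unit < 1e-4),
    warnings = warn,
    tmb = fit,
    data = dat
  ), class = "abundance_fit")
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf("Abundance GLMM (%s)\n", x$spec$family))
  if (!isTRUE(x$converged)) cat("  ** did not converge **\n")
  if (!is.null(x$error)) {
    cat("  error:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf("  logLik %.3f, AIC %.2f, %d parameters\n", x$logLik, x$AIC, x$npar))
  cat(sprintf("  random-intercept SD (%s): %.4f%s\n", x$spec$unit, x$sd_unit,
              if (isTRUE(x$singular)) "  [singular]" else ""))
  if (x$spec$zi) cat(sprintf("  zero-inflation probability: %.4f\n", x$zi_prob))
  cat(sprintf("  dispersion: %.4f\n", x$dispersion))
  print(round(cbind(Estimate = x$beta, SE = x$se), 4))
  invisible(x)
}

#' @export
coef.abundance_fit <- function(object, ...) object$beta

#' @export
logLik.abundance_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, class = "logLik")
}

#' @export
summary.abundance_fit <- function(object, ...) {
  out <- list(spec = object$spec,
              coefficients = cbind(Estimate = object$beta, SE = object$se,
                                   z = object$beta / object$se),
              sd_unit = object$sd_unit, dispersion = object$dispersion,
              zi_prob = object$zi_prob, AIC = object$AIC,
              converged = object$converged)
  class(out) <- "summary.abundance_fit"
  out
}

#' @export
print.summary.abundance_fit <- function(x, ...) {
  cat(sprintf("Abundance GLMM (%s), AIC %.2f, converged: %s\n",
              x$spec$family, x$AIC, x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Select the best abundance model by AIC
#'
#' Fits every candidate specification and returns the converged fit with the
#' lowest AIC. The full AIC table (including non-converged candidates) is
#' attached as the \code{"aic_table"} attribute.
#'
#' @param specs List of \code{\link{abundance_model_spec}} objects.
#' @param obs Filtered observation table.
#' @return The winning \code{abundance_fit}.
#' @export
select_abundance_model <- function(specs, obs) {
  if (inherits(specs, "abundance_spec")) specs <- list(specs)
  fits <- lapply(specs, fit_abundance, obs = obs)
  tab <- data.frame(
    candidate = vapply(specs, function(s)
      paste0(s$family, ": ", paste(c("1", s$covariates), collapse = "+"),
             if (s$zi) " +zi" else ""), character(1)),
    AIC = vapply(fits, function(f) f$AIC %||% NA_real_, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    stringsAsFactors = FALSE
  )
  ok <- which(tab$converged & !is.na(tab$AIC))
  if (!length(ok)) stop("no candidate abundance model converged")
  best <- fits[[ok[which.min(tab$AIC[ok])]]]
  attr(best, "aic_table") <- tab[order(tab$AIC), ]
  best
}

#' Default candidate model set
#'
#' The nested covariate sets considered for each taxonomic group — intercept
#' only, + survey method, + linear depth, + quadratic depth, and (for
#' multi-taxon groups) + taxon — each with and without a constant
#' zero-inflation term.
#'
#' @param family Response family.
#' @param multi_taxon Include candidates with a taxon covariate?
#' @return List of \code{abundance_spec} objects.
#' @export
default_candidate_specs <- function(family = "nbinom", multi_taxon = FALSE) {
  covsets <- list(character(), "method", c("method", "depth"),
                  c("method", "depth", "depth2"))
  if (multi_taxon) {
    covsets <- c(covsets, lapply(covsets, function(cv) c("taxon", cv)))
  }
  out <- list()
  for (cv in covsets) {
    for (zi in c(FALSE, TRUE)) {
      out[[length(out) + 1L]] <- abundance_model_spec(family, cv, zi = zi)
    }
  }
  out
}

#' Predict expected abundance per sampling event
#'
#' Returns lambda, the model's expected count (or expected cover) at each
#' event given its covariates and effort: the conditional mean using the
#' unit's conditional-mode random intercept, multiplied by one minus the
#' zero-inflation probability.
#'
#' @param fit An \code{abundance_fit}.
#' @param events Data frame of events (with \code{taxon} when the model has a
#'   taxon covariate). Defaults to the fitting data.
#' @return Data frame: the identifying columns plus \code{lambda}.
#' @export
predict_lambda <- function(fit, events = NULL) {
  stopifnot(inherits(fit, "abundance_fit"))
  if (is.null(fit$tmb)) stop("model did not fit; no predictions available")
  nd <- if (is.null(events)) fit$data else as.data.frame(events)
  lam <- stats::predict(fit$tmb, newdata = nd, type = "response",
                        allow.new.levels = TRUE)
  keep <- intersect(c("event_id", "unit_1km", "unit_16km", "subregion",
                      "method", "depth_m", "effort", "taxon"), names(nd))
  out <- data.frame(nd[, keep, drop = FALSE], lambda = as.numeric(lam))
  rownames(out) <- NULL
  out
}

#' Compare predicted and observed zero fractions
#'
#' Sums each event's model probability of a zero count (zero-inflation mass
#' plus the negative binomial mass at zero) and reports the difference from
#' the observed zero fraction — the same posterior check the abundance models
#' are screened with.
#'
#' @param fit A converged negative binomial \code{abundance_fit}.
#' @param obs Observation table the model was fitted to (defaults to the
#'   model frame).
#' @return List: \code{predicted}, \code{observed}, \code{difference}.
#' @export
zero_check <- function(fit, obs = NULL) {
  stopifnot(inherits(fit, "abundance_fit"))
  if (fit$spec$family != "nbinom") stop("zero check applies to count models")
  dat <- if (is.null(obs)) fit$data else as.data.frame(obs)
  y <- if (".y" %in% names(dat)) dat$.y else dat$count
  mu <- stats::predict(fit$tmb, newdata = dat, type = "conditional",
                       allow.new.levels = TRUE)
  pz <- if (fit$spec$zi) {
    stats::predict(fit$tmb, newdata = dat, type = "zprob",
                   allow.new.levels = TRUE)
  } else 0
  k <- fit$dispersion
  p0 <- pz + (1 - pz) * stats::dnbinom(0, size = k, mu = mu)
  list(predicted = mean(p0), observed = mean(y == 0),
       difference = mean(p0) - mean(y == 0))
}
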