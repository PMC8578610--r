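#' Survey method catalogue
#'
#' The four fishery-independent survey methods emulated by the synthetic-data
#' generator: shallow diver transects, mid-depth video transects, deep video
#' transects, and hook-and-line sessions. Visual methods measure effort as
#' area surveyed (m^2); hook-and-line as session duration (minutes, sessions
#' of 15 or 30).
#'
#' @return A data frame with one row per method: \code{method}, \code{type}
#'   (\code{"visual"} or \code{"hookline"}), operating depth limits
#'   \code{depth_min}/\code{depth_max} (m), and \code{effort_units}.
#' @export
survey_methods <- function() {
  data.frame(
    method       = c("dive", "video_mid", "video_deep", "hookline"),
    type         = c("visual", "visual", "visual", "hookline"),
    depth_min    = c(5, 15, 100, 15),
    depth_max    = c(35, 200, 500, 205),
    effort_units = c("m2", "m2", "m2", "min"),
    stringsAsFactors = FALSE
  )
}

#' Generative ("true") parameters for the synthetic survey simulator
#'
#' Bundles the per-taxon and shared parameters that drive
#' \code{\link{simulate_counts}} and \code{\link{simulate_cover}}: log-scale
#' intercepts (expected count per unit effort), linear and quadratic depth
#' coefficients (per m, per m^2), per-method multiplicative bias and subregion
#' effects (log scale), the planning-unit random-intercept SD, negative
#' binomial dispersion \code{k} (variance = mean + mean^2/k), a
#' zero-inflation probability, and the beta precision for percent cover.
#'
#' @param taxa Data frame with columns \code{taxon}, \code{group} (one of
#'   \code{"sebastidae"}, \code{"coral"}, \code{"sponge"}), \code{intercept},
#'   \code{depth1}, \code{depth2}.
#' @param method_bias Named numeric, log-scale bias per method; missing
#'   methods default to 0.
#' @param subregion_effect Named numeric, log-scale effect per subregion;
#'   missing subregions default to 0.
#' @param sd_unit Planning-unit random-intercept SD (log scale), >= 0.
#' @param k Negative binomial dispersion, > 0.
#' @param zi Zero-inflation probability in [0, 1).
#' @param phi Beta precision for cover, > 0.
#' @param cover_intercept,cover_depth1,cover_depth2 Logit-scale mean model for
#'   the latent sponge-cover proportion.
#' @param zi_cover Excess-zero probability for cover in [0, 1).
#' @return An object of class \code{"true_parameters"}.
#' @export
true_parameters <- function(taxa, method_bias = numeric(), subregion_effect = numeric(),
                            sd_unit = 0.3, k = 1, zi = 0, phi = 20,
                            cover_intercept = -1, cover_depth1 = 0, cover_depth2 = 0,
                            zi_cover = 0) {
  stop_if_missing_cols(taxa, c("taxon", "group", "intercept", "depth1", "depth2"),
                       "taxa truth table")
  if (!all(taxa$group %in% c("sebastidae", "coral", "sponge"))) {
    stop("taxon group must be one of 'sebastidae', 'coral', 'sponge'")
  }
  if (k <= 0) stop("NB dispersion k must be > 0")
  if (zi < 0 || zi >= 1) stop("zero-inflation probability must be in [0, 1)")
  if (zi_cover < 0 || zi_cover >= 1) stop("zero-inflation probability must be in [0, 1)")
  if (sd_unit < 0) stop("random-intercept SD must be >= 0")
  if (phi <= 0) stop("beta precision phi must be > 0")
  structure(
    list(taxa = taxa, method_bias = method_bias, subregion_effect = subregion_effect,
         sd_unit = sd_unit, k = k, zi = zi, phi = phi,
         cover_intercept = cover_intercept, cover_depth1 = cover_depth1,
         cover_depth2 = cover_depth2, zi_cover = zi_cover),
    class = "true_parameters"
  )
}

#' Generate a seeded multi-method survey design on a planning-unit grid
#'
#' Builds a nested grid of 1-km^2 planning units within 16-km^2 parents,
#' assigns each parent to an oceanographic subregion, and attaches sampling
#' events (dive transects, video bins, hook-and-line sessions) with depths
#' drawn from the subregion's depth profile intersected with each method's
#' operating range, and effort drawn per method.
#'
#' The default per-unit sample-count distribution, 1 + NegBin(mu = 3.2,
#' size = 1.2), is right-skewed with median 3 and quartiles 2 and 6,
#' emulating the sampling intensity of the field program the simulator mimics.
#'
#' @param n_units_1km Number of 1-km^2 planning units (>= 1).
#' @param units_per_16km Children per 16-km^2 parent unit (default 4).
#' @param subregion_depth_profiles Named list of c(min, max) sampled-depth
#'   spans (m) per subregion. Defaults span shallow banks (ABU), mid-depth
#'   shelf (EQCS), and deep fjords (MF, exceeding 200 m).
#' @param methods Character vector of methods from \code{\link{survey_methods}}.
#' @param events_per_unit List with \code{mu} and \code{size} for the shifted
#'   negative binomial per-unit event count.
#' @param year Survey year stamped on events.
#' @param seed Integer seed; identical inputs and seed give identical designs.
#' @return An object of class \code{"survey_design"}: list with \code{events}
#'   (one row per sampling event), \code{units} (grid table) and
#'   \code{methods}.
#' @export
generate_design <- function(n_units_1km,
                            units_per_16km = 4,
                            subregion_depth_profiles = list(
                              ABU = c(5, 80), EQCS = c(10, 130), MF = c(10, 450)),
                            methods = c("dive", "video_mid", "video_deep", "hookline"),
                            events_per_unit = list(mu = 3.2, size = 1.2),
                            year = 2020,
                            seed = 1) {
  if (n_units_1km < 1) stop("n_units_1km must be >= 1")
  if (units_per_16km < 1) stop("units_per_16km must be >= 1")
  cat_methods <- survey_methods()
  unknown <- setdiff(methods, cat_methods$method)
  if (length(unknown)) {
    stop("unknown method name(s): ", paste(unknown, collapse = ", "))
  }
  meths <- cat_methods[cat_methods$method %in% methods, , drop = FALSE]
  subregions <- names(subregion_depth_profiles)
  if (is.null(subregions) || !length(subregions)) {
    stop("subregion_depth_profiles must be a named list")
  }

  with_seed(seed, {
    unit_1km  <- sprintf("u%04d", seq_len(n_units_1km))
    unit_16km <- sprintf("P%03d", ceiling(seq_len(n_units_1km) / units_per_16km))
    # parents cycle across subregions so each parent lies in one subregion
    parent_ids <- unique(unit_16km)
    parent_sub <- rep_len(subregions, length(parent_ids))
    names(parent_sub) <- parent_ids
    units <- data.frame(unit_1km = unit_1km, unit_16km = unit_16km,
                        subregion = unname(parent_sub[unit_16km]),
                        stringsAsFactors = FALSE)

    n_events <- 1L + stats::rnbinom(n_units_1km,
                                    size = events_per_unit$size,
                                    mu = events_per_unit$mu)
    rows <- vector("list", n_units_1km)
    eid <- 0L
    for (j in seq_len(n_units_1km)) {
      prof <- subregion_depth_profiles[[units$subregion[j]]]
      # methods whose operating range intersects the subregion depth span
      ok <- meths$depth_min <= prof[2] & meths$depth_max >= prof[1]
      feas <- meths[ok, , drop = FALSE]
      if (!nrow(feas)) next
      m_idx <- sample.int(nrow(feas), n_events[j], replace = TRUE)
      lo <- pmax(feas$depth_min[m_idx], prof[1])
      hi <- pmin(feas$depth_max[m_idx], prof[2])
      depth <- stats::runif(n_events[j], lo, hi)
      effort <- vapply(m_idx, function(i) {
        switch(feas$method[i],
               dive       = 120,
               video_mid  = stats::runif(1, 75, 130),
               video_deep = stats::runif(1, 75, 130),
               hookline   = sample(c(15, 30), 1))
      }, numeric(1))
      rows[[j]] <- data.frame(
        event_id  = sprintf("e%06d", eid + seq_len(n_events[j])),
        unit_1km  = units$unit_1km[j],
        unit_16km = units$unit_16km[j],
        subregion = units$subregion[j],
        method    = feas$method[m_idx],
        depth_m   = depth,
        effort    = effort,
        effort_units = feas$effort_units[m_idx],
        year      = year,
        stringsAsFactors = FALSE
      )
      eid <- eid + n_events[j]
    }
    events <- do.call(rbind, rows)
    rownames(events) <- NULL
    structure(list(events = events, units = units, methods = meths),
              class = "survey_design")
  })
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Synthetic survey design\n")
  cat(sprintf("  %d events in %d 1-km^2 units (%d 16-km^2 parents)\n",
              nrow(x$events), nrow(x$units), length(unique(x$units$unit_16km))))
  cat("  methods:", paste(x$methods$method, collapse = ", "), "\n")
  cat("  subregions:", paste(unique(x$units$subregion), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate zero-inflated negative binomial counts on a survey design
#'
#' Draws counts for each (taxon, event) pair from the generative model the
#' abundance stage assumes: log mean = taxon intercept + depth and depth^2
#' effects + method bias + subregion effect + planning-unit random intercept +
#' log(effort); the count is 0 with the zero-inflation probability and
#' otherwise negative binomial with dispersion \code{k}. Unit random
#' intercepts are drawn once per (taxonomic group, unit) and shared across
#' that group's taxa.
#'
#' @param design A \code{survey_design}.
#' @param truth A \code{\link{true_parameters}} object.
#' @param taxa Character vector of taxa to simulate (default: all count taxa
#'   in \code{truth}). Each must have a truth entry.
#' @param seed Integer seed.
#' @return Observation data frame: the event columns plus \code{taxon},
#'   \code{group}, \code{count}, \code{cover_category} (NA for counts).
#' @export
simulate_counts <- function(design, truth, taxa = NULL, seed = 1) {
  stopifnot(inherits(design, "survey_design"), inherits(truth, "true_parameters"))
  tt <- truth$taxa
  if (is.null(taxa)) taxa <- tt$taxon
  miss <- setdiff(taxa, tt$taxon)
  if (length(miss)) stop("missing truth entry for taxa: ", paste(miss, collapse = ", "))
  tt <- tt[match(taxa, tt$taxon), , drop = FALSE]
  ev <- design$events

  with_seed(seed, {
    groups <- unique(tt$group)
    units <- design$units$unit_1km
    # one random intercept per (group, unit)
    b <- matrix(stats::rnorm(length(groups) * length(units), 0, truth$sd_unit),
                nrow = length(groups), dimnames = list(groups, units))
    out <- vector("list", nrow(tt))
    for (s in seq_len(nrow(tt))) {
      mb <- truth$method_bias[ev$method]
      mb[is.na(mb)] <- 0
      sr <- truth$subregion_effect[ev$subregion]
      sr[is.na(sr)] <- 0
      eta <- tt$intercept[s] + tt$depth1[s] * ev$depth_m +
        tt$depth2[s] * ev$depth_m^2 + mb + sr +
        b[tt$group[s], ev$unit_1km] + log(ev$effort)
      mu <- exp(eta)
      y <- stats::rnbinom(nrow(ev), size = truth$k, mu = mu)
      if (truth$zi > 0) {
        y[stats::runif(nrow(ev)) < truth$zi] <- 0L
      }
      out[[s]] <- data.frame(ev, taxon = tt$taxon[s], group = tt$group[s],
                             count = y, cover_category = NA_integer_,
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Convert a latent cover proportion to the field category scale
#'
#' Percent cover of large-bodied sponges is recorded in five categories:
#' 0 = 0\%, 1 = 1–25\%, 2 = 26–50\%, 3 = 51–75\%, 4 = 76–100\%. The
#' continuous partition is half-open: category 1 is (0, 0.25], category 2 is
#' (0.25, 0.50], and so on; exactly 0 maps to category 0.
#'
#' @param p Proportions in [0, 1].
#' @return Integer categories in 0..4.
#' @export
cover_category <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("cover proportion must be in [0, 1]")
  ifelse(p == 0, 0L, pmin(as.integer(ceiling(p * 4)), 4L))
}

#' Simulate categorical percent-cover observations
#'
#' For dive and mid-depth video events only (the methods that record sponge
#' cover as categories), draws a latent proportion from a beta distribution
#' whose logit-scale mean follows the cover model in \code{truth}, optionally
#' inflates category 0 with an excess-zero mass, and bins the proportion with
#' \code{\link{cover_category}}.
#'
#' @inheritParams simulate_counts
#' @param taxon Label for the pooled cover taxon.
#' @return Observation data frame with \code{cover_category} filled and
#'   \code{count} NA.
#' @export
simulate_cover <- function(design, truth, taxon = "large_sponges", seed = 1) {
  stopifnot(inherits(design, "survey_design"), inherits(truth, "true_parameters"))
  if (truth$phi <= 0) stop("beta precision phi must be > 0")
  ev <- design$events[design$events$method %in% c("dive", "video_mid"), , drop = FALSE]
  with_seed(seed, {
    sr <- truth$subregion_effect[ev$subregion]
    sr[is.na(sr)] <- 0
    p_mean <- stats::plogis(truth$cover_intercept + truth$cover_depth1 * ev$depth_m +
                              truth$cover_depth2 * ev$depth_m^2 + sr)
    y <- stats::rbeta(nrow(ev), p_mean * truth$phi, (1 - p_mean) * truth$phi)
    if (truth$zi_cover > 0) {
      y[stats::runif(nrow(ev)) < truth$zi_cover] <- 0
    }
    res <- data.frame(ev, taxon = taxon, group = "sponge",
                      count = NA_integer_, cover_category = cover_category(y),
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
}

#' Generate a synthetic trait table
#'
#' Draws the conservation-prioritization proxies used by the weighting stage:
#' intrinsic population growth rate r (per year), depletion ratio B_y/B_0,
#' trophic level, evolutionary distinctiveness, planktivore status for
#' Sebastidae, and mean colony height (cm) for corals. A requested fraction
#' of the evolutionary-distinctiveness and depletion entries is set missing,
#' mirroring the incomplete stock assessments and phylogenies real trait
#' tables suffer from.
#'
#' @param taxa Data frame with columns \code{taxon} and \code{group}.
#' @param missingness Named list of missingness rates in [0, 1] for
#'   \code{ED} and \code{depletion}.
#' @param seed Integer seed.
#' @return Trait data frame: taxon, group, r, depletion, TL, ED, h,
#'   planktivore.
#' @export
generate_traits <- function(taxa, missingness = list(ED = 0.2, depletion = 0.2),
                            seed = 1) {
  stop_if_missing_cols(taxa, c("taxon", "group"), "taxa table")
  rates <- unlist(missingness)
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]")
  n <- nrow(taxa)
  with_seed(seed, {
    seb <- taxa$group == "sebastidae"
    cor <- taxa$group == "coral"
    tr <- data.frame(
      taxon = taxa$taxon, group = taxa$group,
      r = NA_real_, depletion = NA_real_, TL = NA_real_, ED = NA_real_,
      h = NA_real_, planktivore = NA,
      stringsAsFactors = FALSE
    )
    tr$r[seb] <- exp(stats::rnorm(sum(seb), log(0.08), 0.5))
    tr$depletion[seb] <- stats::runif(sum(seb), 0.1, 0.9)
    tr$TL[seb] <- stats::runif(sum(seb), 2.8, 4.5)
    tr$ED[seb] <- stats::rexp(sum(seb), 1 / 20)
    tr$planktivore[seb] <- stats::runif(sum(seb)) < 0.3
    tr$h[cor] <- stats::runif(sum(cor), 5, 80)
    ed_rate <- missingness$ED %||% 0
    dep_rate <- missingness$depletion %||% 0
    tr$ED[seb][stats::runif(sum(seb)) < ed_rate] <- NA_real_
    tr$depletion[seb][stats::runif(sum(seb)) < dep_rate] <- NA_real_
    tr
  })
}
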