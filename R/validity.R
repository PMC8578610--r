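#' Depth profile sampled by each survey method
#'
#' The 10th and 90th percentiles of the depths of all events carried out with
#' each method, pooled across planning units. These percentiles define the
#' span a method samples reliably and drive the validity rule for undetected
#' Sebastidae.
#'
#' @param design A \code{survey_design}, or a data frame of events with
#'   \code{method} and \code{depth_m} columns.
#' @return Data frame: method, p10, p90, n_events.
#' @export
method_profiles <- function(design) {
  ev <- if (inherits(design, "survey_design")) design$events else design
  stop_if_missing_cols(ev, c("method", "depth_m"), "event table")
  if (!nrow(ev)) stop("no events to profile")
  sp <- split(ev$depth_m, ev$method)
  out <- data.frame(
    method = names(sp),
    p10 = vapply(sp, function(d) unname(stats::quantile(d, 0.10)), numeric(1)),
    p90 = vapply(sp, function(d) unname(stats::quantile(d, 0.90)), numeric(1)),
    n_events = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Vectorized core of the validity decision; all arguments same length.
valid_sample <- function(group, planktivore, range_min, range_max,
                         method_type, p10, p90, event_depth, detected,
                         rule = c("containment", "overlap")) {
  rule <- match.arg(rule)
  n <- length(group)
  out <- logical(n)

  # A detection proves the method can sample the taxon there.
  out[detected] <- TRUE
  und <- !detected

  # Hook-and-line cannot systematically sample sessile benthos or
  # planktivores: undetected zeroes there are structural, never valid.
  hook_bad <- und & method_type == "hookline" &
    (group %in% c("coral", "sponge") | (group == "sebastidae" & planktivore %in% TRUE))
  out[hook_bad] <- FALSE

  rest <- und & !hook_bad
  if (any(rest & (is.na(range_min) | is.na(range_max)))) {
    stop("missing expected depth range for an undetected taxon")
  }
  seb <- rest & group == "sebastidae"
  if (rule == "containment") {
    out[seb] <- p10[seb] <= range_min[seb] & p90[seb] >= range_max[seb]
  } else {
    out[seb] <- p10[seb] <= range_max[seb] & p90[seb] >= range_min[seb]
  }
  ben <- rest & group %in% c("coral", "sponge")
  out[ben] <- event_depth[ben] >= range_min[ben]
  out
}

#' Is a (taxon, method, event) combination a valid sample?
#'
#' Encodes the depth and gear selectivity rules that separate biologically
#' meaningful zeroes from unjustified ones before model fitting:
#' \itemize{
#'   \item a detection is always valid, whatever the gear;
#'   \item hook-and-line is never valid for undetected corals, sponges, or
#'     planktivorous Sebastidae;
#'   \item an undetected Sebastidae zero is valid only if the method's
#'     sampled 10th–90th depth percentile span encompasses the species'
#'     expected depth range (or merely overlaps it, with
#'     \code{rule = "overlap"});
#'   \item an undetected coral or sponge zero is valid only if the event is
#'     at or below the taxon's minimum expected depth.
#' }
#'
#' @param group Taxonomic group: "sebastidae", "coral" or "sponge".
#' @param range Numeric c(min, max): expected depth range of the taxon (m).
#' @param profile Numeric c(p10, p90): the method's sampled depth percentiles.
#' @param method_type "visual" or "hookline".
#' @param event_depth Depth of the sampling event (m).
#' @param detected Was the taxon detected at the event?
#' @param planktivore Is the taxon a planktivorous Sebastidae?
#' @param rule Containment (default) or overlap reading of "encompassed".
#' @return Logical.
#' @export
is_valid <- function(group, range, profile, method_type, event_depth,
                     detected, planktivore = FALSE,
                     rule = c("containment", "overlap")) {
  valid_sample(group, planktivore, range[1], range[2], method_type,
               profile[1], profile[2], event_depth, detected,
               match.arg(rule))
}

#' Filter an observation table by the selectivity rules
#'
#' Applies \code{\link{is_valid}} row by row: detections are always kept,
#' undetected rows are dropped when the method could not have sampled the
#' taxon at that depth. The per-taxon-by-method removal counts are attached
#' as the \code{"filter_report"} attribute. The operation is idempotent.
#'
#' @param obs Observation table (see \code{\link{simulate_counts}}).
#' @param traits Trait table carrying \code{planktivore} for Sebastidae.
#' @param depth_ranges Data frame: taxon, min_depth_m, max_depth_m.
#' @param design A \code{survey_design} (used for the method depth profiles
#'   and gear types); profiles are computed from all its events.
#' @param rule Containment (default) or overlap.
#' @return The filtered observation table, with attribute
#'   \code{"filter_report"}.
#' @export
filter_observations <- function(obs, traits, depth_ranges, design,
                                rule = c("containment", "overlap")) {
  rule <- match.arg(rule)
  if (!nrow(obs)) {
    attr(obs, "filter_report") <- data.frame(taxon = character(),
                                             method = character(),
                                             removed = integer())
    return(obs)
  }
  stop_if_missing_cols(obs, c("taxon", "group", "method", "depth_m"), "observations")
  stop_if_missing_cols(depth_ranges, c("taxon", "min_depth_m", "max_depth_m"),
                       "depth range table")
  prof <- method_profiles(design)
  meths <- if (inherits(design, "survey_design")) design$methods else survey_methods()

  i_rng <- match(obs$taxon, depth_ranges$taxon)
  i_pr <- match(obs$method, prof$method)
  i_mt <- match(obs$method, meths$method)
  if (anyNA(i_pr) || anyNA(i_mt)) stop("observation method absent from design")
  plank <- rep(FALSE, nrow(obs))
  if (!is.null(traits) && "planktivore" %in% names(traits)) {
    pl <- traits$planktivore[match(obs$taxon, traits$taxon)]
    plank <- !is.na(pl) & pl
  }
  detected <- (!is.na(obs$count) & obs$count > 0) |
    (!is.na(obs$cover_category) & obs$cover_category > 0)

  keep <- valid_sample(obs$group, plank,
                       depth_ranges$min_depth_m[i_rng],
                       depth_ranges$max_depth_m[i_rng],
                       meths$type[i_mt], prof$p10[i_pr], prof$p90[i_pr],
                       obs$depth_m, detected, rule)
  removed <- obs[!keep, c("taxon", "method")]
  if (nrow(removed)) {
    report <- as.data.frame(table(taxon = removed$taxon, method = removed$method),
                            stringsAsFactors = FALSE)
    names(report)[3] <- "removed"
    report <- report[report$removed > 0, , drop = FALSE]
    rownames(report) <- NULL
  } else {
    report <- data.frame(taxon = character(), method = character(),
                         removed = integer())
  }
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}
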