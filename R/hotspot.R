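#' Effort-standardized abundance per planning unit
#'
#' For each (taxon, method, planning unit), divides the summed expected
#' abundances over the unit's events by the summed effort: the
#' model-standardized count (or cover) per unit of effort. Combinations with
#' no events are simply absent from the result.
#'
#' @param lambda_tbl Output of \code{\link{predict_lambda}}: one row per
#'   (taxon, event), with \code{unit_1km}, \code{method}, \code{effort},
#'   \code{lambda}.
#' @param group Optional group label to attach.
#' @return Data frame: taxon, method, unit_1km, mu, n_events, effort.
#' @export
mu_per_effort <- function(lambda_tbl, group = NULL) {
  stop_if_missing_cols(lambda_tbl, c("taxon", "method", "unit_1km", "effort", "lambda"),
                       "lambda table")
  key <- interaction(lambda_tbl$taxon, lambda_tbl$method, lambda_tbl$unit_1km,
                     drop = TRUE, sep = "\r")
  agg <- function(v, f) vapply(split(v, key), f, numeric(1))
  sums_l <- agg(lambda_tbl$lambda, sum)
  sums_e <- agg(lambda_tbl$effort, sum)
  parts <- do.call(rbind, strsplit(names(sums_l), "\r", fixed = TRUE))
  out <- data.frame(taxon = parts[, 1], method = parts[, 2], unit_1km = parts[, 3],
                    mu = unname(sums_l / sums_e),
                    n_events = unname(agg(lambda_tbl$lambda, length)),
                    effort = unname(sums_e),
                    stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- group
  out <- out[order(out$taxon, out$method, out$unit_1km), ]
  rownames(out) <- NULL
  out
}

#' Min-max rescale standardized abundance across planning units
#'
#' Within each (taxon, method), subtracts the minimum across units and
#' divides by the range, putting every method on a common [0, 1] scale so
#' methods with different fields of view or catchability become comparable.
#' A zero range (all units equal) carries no spatial signal and maps to 0
#' everywhere.
#'
#' @param mu_tbl Output of \code{\link{mu_per_effort}}.
#' @return The same table with a \code{mu_prime} column.
#' @export
minmax_rescale <- function(mu_tbl) {
  stop_if_missing_cols(mu_tbl, c("taxon", "method", "mu"), "mu table")
  key <- interaction(mu_tbl$taxon, mu_tbl$method, drop = TRUE)
  mu_tbl$mu_prime <- stats::ave(mu_tbl$mu, key, FUN = function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  })
  mu_tbl
}

#' Per-group hotspot index
#'
#' For taxonomic group g and planning unit u,
#' B_[g,u] = sum over taxa of ( sum over valid methods of mu' / n_methods ) * W_t,
#' where n_methods counts the methods with a rescaled abundance for that
#' group in that unit. Units never validly sampled for the group are absent
#' from its index.
#'
#' @param mu_tbl Rescaled table from \code{\link{minmax_rescale}}, restricted
#'   to (or carrying a \code{group} column identifying) one taxonomic group.
#' @param weights Data frame with \code{taxon} and \code{W}.
#' @param group Group label to select when \code{mu_tbl} covers several.
#' @return Data frame: unit_1km, B, n_methods.
#' @export
group_index <- function(mu_tbl, weights, group = NULL) {
  stop_if_missing_cols(mu_tbl, c("taxon", "method", "unit_1km", "mu_prime"), "mu table")
  if (!is.null(group) && "group" %in% names(mu_tbl)) {
    mu_tbl <- mu_tbl[mu_tbl$group == group, , drop = FALSE]
  }
  if (!nrow(mu_tbl)) return(data.frame(unit_1km = character(), B = numeric(),
                                       n_methods = integer()))
  W <- weights$W[match(mu_tbl$taxon, weights$taxon)]
  if (anyNA(W)) {
    stop("missing weight for taxa: ",
         paste(unique(mu_tbl$taxon[is.na(W)]), collapse = ", "))
  }
  units <- unique(mu_tbl$unit_1km)
  out <- data.frame(unit_1km = units, B = NA_real_, n_methods = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(units)) {
    rows <- mu_tbl$unit_1km == units[i]
    n_m <- length(unique(mu_tbl$method[rows]))
    per_taxon <- tapply((mu_tbl$mu_prime * W)[rows], mu_tbl$taxon[rows], sum)
    out$B[i] <- sum(per_taxon) / n_m
    out$n_methods[i] <- n_m
  }
  out[order(out$unit_1km), ]
}

#' Evenness-weighted overall hotspot index
#'
#' For planning units surveyed for all three taxonomic groups, computes
#' Shannon's evenness H of the group proportions p_g = B_g / sum(B_g)
#' (natural log, normalized by ln of the number of groups, with 0 ln 0 = 0)
#' and the overall index B_o = H * sum(B_g). A unit with all-zero group
#' indices, or dominated by a single group, gets B_o = 0.
#'
#' @param B_wide Data frame with \code{unit_1km} and one column of group
#'   index values per taxonomic group (e.g. \code{B_SEB}, \code{B_Cor},
#'   \code{B_Sp}). Rows with any missing group value are dropped.
#' @return Data frame: unit_1km, H, B_o.
#' @export
overall_index <- function(B_wide) {
  stop_if_missing_cols(B_wide, "unit_1km", "group index table")
  bcols <- setdiff(names(B_wide), "unit_1km")
  if (length(bcols) < 2) stop("need at least two group index columns")
  Bm <- as.matrix(B_wide[, bcols])
  keep <- stats::complete.cases(Bm)
  Bm <- Bm[keep, , drop = FALSE]
  if (any(Bm < 0)) stop("group index values must be >= 0")
  tot <- rowSums(Bm)
  G <- ncol(Bm)
  H <- numeric(nrow(Bm))
  pos <- tot > 0
  if (any(pos)) {
    p <- Bm[pos, , drop = FALSE] / tot[pos]
    plogp <- ifelse(p > 0, p * log(p), 0)
    H[pos] <- -rowSums(plogp) / log(G)
  }
  data.frame(unit_1km = B_wide$unit_1km[keep], H = H, B_o = H * tot,
             stringsAsFactors = FALSE)
}

#' Decile ranks of an index across planning units
#'
#' Values are normalized as a proportion of their maximum and converted to
#' decile ranks 1..10: ordinal ranks (ties averaged) are sliced into ten
#' equal-count bins, so a larger value never gets a smaller rank and tied
#' values share a rank.
#'
#' @param x Numeric index values (one per unit).
#' @return Integer ranks in 1..10.
#' @export
decile_ranks <- function(x) {
  if (!length(x)) return(integer())
  if (anyNA(x)) stop("index values must not be missing")
  v <- if (max(x) > 0) x / max(x) else x
  r <- rank(v, ties.method = "average")
  as.integer(ceiling(10 * r / length(r)))
}

#' Flag hotspot planning units from decile ranks
#'
#' Sebastidae, large-bodied sponges and the overall index treat decile ranks
#' 9 and 10 as hotspots; structural corals, whose index is near zero outside
#' the very best units, use rank 10 only.
#'
#' @param ranks Integer decile ranks.
#' @param group Taxonomic group ("sebastidae", "coral", "sponge", "overall").
#' @param thresholds Named list of minimum hotspot ranks; \code{default}
#'   covers groups not named.
#' @return Logical flags.
#' @export
classify_hotspots <- function(ranks, group = "overall",
                              thresholds = list(coral = 10, default = 9)) {
  thr <- thresholds[[group]] %||% thresholds$default
  ranks >= thr
}

#' Aggregate 1-km^2 index values to 16-km^2 parents
#'
#' Each parent takes the average of its best child and the mean of the
#' remaining children, balancing parents with one exceptional unit against
#' parents that are good throughout. A single-child parent keeps its child's
#' value.
#'
#' @param values Index values of 1-km^2 units.
#' @param parent Parent (16-km^2) unit id per value.
#' @return Data frame: unit_16km, value.
#' @export
aggregate_16km <- function(values, parent) {
  stopifnot(length(values) == length(parent))
  agg <- vapply(split(values, parent), function(v) {
    if (length(v) == 1L) return(v)
    (max(v) + mean(v[-which.max(v)])) / 2
  }, numeric(1))
  data.frame(unit_16km = names(agg), value = unname(agg),
             stringsAsFactors = FALSE)
}

#' Assemble the per-unit hotspot table
#'
#' Joins the per-group indices, computes the overall index for units
#' surveyed for all groups, and attaches decile ranks and hotspot flags per
#' index.
#'
#' @param B_list Named list of per-group index tables from
#'   \code{\link{group_index}}; names are used as column suffixes and for the
#'   coral threshold rule (a name containing "cor" is treated as coral).
#' @param thresholds Passed to \code{\link{classify_hotspots}}.
#' @return Data frame with one row per unit: B, rank and hotspot columns per
#'   group, plus H, B_o, rank_overall, hotspot_overall where defined.
#' @export
hotspot_table <- function(B_list, thresholds = list(coral = 10, default = 9)) {
  stopifnot(is.list(B_list), !is.null(names(B_list)))
  units <- sort(unique(unlist(lapply(B_list, `[[`, "unit_1km"))))
  out <- data.frame(unit_1km = units, stringsAsFactors = FALSE)
  for (nm in names(B_list)) {
    out[[paste0("B_", nm)]] <- B_list[[nm]]$B[match(units, B_list[[nm]]$unit_1km)]
  }
  for (nm in names(B_list)) {
    b <- out[[paste0("B_", nm)]]
    ok <- !is.na(b)
    rk <- rep(NA_integer_, length(b))
    rk[ok] <- decile_ranks(b[ok])
    grp <- if (grepl("cor", nm, ignore.case = TRUE)) "coral" else nm
    out[[paste0("rank_", nm)]] <- rk
    out[[paste0("hotspot_", nm)]] <- ifelse(is.na(rk), NA,
                                            classify_hotspots(rk, grp, thresholds))
  }
  ov <- overall_index(out[, c("unit_1km", paste0("B_", names(B_list)))])
  out$H <- ov$H[match(units, ov$unit_1km)]
  out$B_o <- ov$B_o[match(units, ov$unit_1km)]
  ok <- !is.na(out$B_o)
  rk <- rep(NA_integer_, nrow(out))
  rk[ok] <- decile_ranks(out$B_o[ok])
  out$rank_overall <- rk
  out$hotspot_overall <- ifelse(is.na(rk), NA,
                                classify_hotspots(rk, "overall", thresholds))
  out
}
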