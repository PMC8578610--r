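#' Component conservation scores for Sebastidae
#'
#' Computes the four prioritization components for rockfishes and
#' thornyheads from their trait proxies:
#' \itemize{
#'   \item Score1 (fishery vulnerability) = x1 * (1/r) / max(1/r)
#'   \item Score2 (depletion level)       = x2 * (1 - B_y/B_0) / max(1 - B_y/B_0)
#'   \item Score3 (ecological role)       = x3 * (TL - min TL) / (max TL - min TL)
#'   \item Score4 (evolutionary distinctiveness) = x4 * ED / max(ED)
#' }
#' with default maxima x = (4, 4, 2, 2), so vulnerability and depletion can
#' contribute twice as much as trophic role and distinctiveness. Extrema are
#' taken over the species with the proxy present; a missing proxy leaves that
#' species' score missing. Depletion ratios above 1 (stocks above unfished
#' biomass) are clamped to 1 with a warning so Score2 stays non-negative.
#'
#' @param traits Trait data frame (see \code{\link{generate_traits}});
#'   only rows with \code{group == "sebastidae"} are used.
#' @param x Numeric length 4: the maximum attainable value of each score.
#' @return Data frame: taxon, Score1..Score4 (NA where not computable).
#' @export
score_components <- function(traits, x = c(4, 4, 2, 2)) {
  stop_if_missing_cols(traits, c("taxon", "group"), "trait table")
  stopifnot(length(x) == 4, all(x >= 0))
  tr <- traits[traits$group == "sebastidae", , drop = FALSE]
  if (!nrow(tr)) stop("no Sebastidae rows in trait table")
  if (all(is.na(tr$r))) stop("growth rate r missing for every species")
  if (any(!is.na(tr$r) & tr$r <= 0)) stop("growth rate r must be > 0")

  dep <- tr$depletion
  if (any(!is.na(dep) & dep > 1)) {
    warning("depletion ratio B_y/B_0 > 1 clamped to 1")
    dep <- pmin(dep, 1)
  }
  if (any(!is.na(dep) & dep < 0)) stop("depletion ratio must be >= 0")

  score_ratio <- function(v, xi) {
    if (all(is.na(v))) return(rep(NA_real_, length(v)))
    xi * v / max(v, na.rm = TRUE)
  }
  s1 <- score_ratio(1 / tr$r, x[1])
  s2 <- score_ratio(1 - dep, x[2])
  s4 <- score_ratio(tr$ED, x[4])
  # min-max for trophic level; degenerate (zero-range or all-missing) column
  # carries no information and is dropped
  s3 <- rep(NA_real_, nrow(tr))
  if (!all(is.na(tr$TL))) {
    rng <- range(tr$TL, na.rm = TRUE)
    if (diff(rng) > 0) {
      s3 <- x[3] * (tr$TL - rng[1]) / diff(rng)
    } else {
      message("trophic level has zero range; Score3 dropped for all species")
    }
  }
  for (nm in c("depletion", "TL", "ED")) {
    if (all(is.na(tr[[nm]]))) {
      message("proxy '", nm, "' missing for all species; its score is dropped")
    }
  }
  out <- data.frame(taxon = tr$taxon, Score1 = s1, Score2 = s2, Score3 = s3,
                    Score4 = s4, stringsAsFactors = FALSE)
  attr(out, "x") <- x
  out
}

#' Overall conservation weight for Sebastidae species
#'
#' W_t = sum of the computable component scores divided by the sum of their
#' maxima, where a component whose proxy is missing contributes neither to
#' the numerator nor the denominator. W_t therefore stays in (0, 1] and is
#' comparable across species with different data coverage.
#'
#' @param scores Output of \code{\link{score_components}}.
#' @param x Score maxima; defaults to those used to build \code{scores}.
#' @return Data frame: taxon, Score1..Score4, W.
#' @export
weight_sebastidae <- function(scores, x = attr(scores, "x") %||% c(4, 4, 2, 2)) {
  sc <- as.matrix(scores[, c("Score1", "Score2", "Score3", "Score4")])
  none <- rowSums(!is.na(sc)) == 0
  if (any(none)) {
    stop("no computable score component for species: ",
         paste(scores$taxon[none], collapse = ", "))
  }
  denom <- (!is.na(sc)) %*% x
  W <- rowSums(sc, na.rm = TRUE) / as.vector(denom)
  data.frame(scores, W = W, stringsAsFactors = FALSE)
}

#' Conservation weight for structural corals
#'
#' Coral taxa are weighted by mean colony height, W_t = h / max(h): taller
#' colonies supply more biogenic habitat and are more vulnerable to
#' bottom-contact gear.
#'
#' @param traits Trait data frame; only rows with \code{group == "coral"} used.
#' @return Data frame: taxon, W.
#' @export
weight_coral <- function(traits) {
  tr <- traits[traits$group == "coral", , drop = FALSE]
  if (!nrow(tr)) stop("no coral rows in trait table")
  if (any(is.na(tr$h)) || any(tr$h <= 0)) {
    stop("mean colony height h must be present and > 0 for all corals")
  }
  data.frame(taxon = tr$taxon, W = tr$h / max(tr$h), stringsAsFactors = FALSE)
}

#' Conservation weight for the pooled large-bodied sponge group
#'
#' Large-bodied sponges are treated as one functional group with no
#' between-species differentiation, so W_t = 1 for the pooled taxon.
#'
#' @param taxon Label of the pooled sponge taxon.
#' @return Data frame: taxon, W = 1.
#' @export
weight_sponge <- function(taxon = "large_sponges") {
  data.frame(taxon = taxon, W = 1, stringsAsFactors = FALSE)
}

#' Conservation weights for all taxa
#'
#' Dispatches on taxonomic group: Sebastidae get the four-component score,
#' corals the height ratio, sponges weight 1.
#'
#' @param traits Trait data frame covering all analyzed taxa.
#' @param x Score maxima for the Sebastidae components.
#' @param sponge_taxon Label(s) of pooled sponge taxa present in
#'   \code{traits}; used only if the table has sponge rows.
#' @return Data frame: taxon, group, W (and Score1..4 for Sebastidae rows,
#'   NA elsewhere).
#' @export
taxon_weights <- function(traits, x = c(4, 4, 2, 2), sponge_taxon = NULL) {
  pieces <- list()
  if (any(traits$group == "sebastidae")) {
    ws <- weight_sebastidae(score_components(traits, x), x)
    pieces$seb <- data.frame(taxon = ws$taxon, group = "sebastidae",
                             ws[, c("Score1", "Score2", "Score3", "Score4")],
                             W = ws$W, stringsAsFactors = FALSE)
  }
  if (any(traits$group == "coral")) {
    wc <- weight_coral(traits)
    pieces$cor <- data.frame(taxon = wc$taxon, group = "coral",
                             Score1 = NA_real_, Score2 = NA_real_,
                             Score3 = NA_real_, Score4 = NA_real_,
                             W = wc$W, stringsAsFactors = FALSE)
  }
  sponges <- unique(c(traits$taxon[traits$group == "sponge"], sponge_taxon))
  if (length(sponges)) {
    pieces$sp <- data.frame(taxon = sponges, group = "sponge",
                            Score1 = NA_real_, Score2 = NA_real_,
                            Score3 = NA_real_, Score4 = NA_real_,
                            W = 1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
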