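#' Default synthetic study scenario
#'
#' The reference conditions under which the pipeline is exercised end to
#' end: a three-subregion grid sampled by all four methods, six Sebastidae
#' species (one planktivore), three structural coral taxa, and one pooled
#' large-bodied sponge group. Depth preferences are unimodal on the log
#' scale, with optima spanning shallow (40 m) to deep (250 m) taxa; counts
#' are overdispersed (k = 1.2), moderately zero-inflated (0.1), and share a
#' planning-unit random intercept (SD 0.4) within each taxonomic group. Each
#' taxon's expected depth range is the span where its depth response is
#' within a factor of ~e^2 of its peak, which is what a field guide's
#' "expected depth range" conveys.
#'
#' @param n_units_1km Number of 1-km^2 units (default 120, i.e. 30 parents
#'   across 3 subregions).
#' @param seed Integer seed for the design and observations.
#' @return List: \code{design}, \code{truth}, \code{taxa}, \code{traits},
#'   \code{depth_ranges}, \code{obs} (counts and cover rows combined).
#' @export
default_scenario <- function(n_units_1km = 120, seed = 1) {
  opt <- c(40, 60, 100, 150, 200, 250)   # Sebastidae depth optima (m)
  opt_cor <- c(60, 150, 250)
  curv <- 8e-5                            # shared quadratic curvature per m^2
  taxa <- data.frame(
    taxon = c(sprintf("seb_%02d", 1:6), sprintf("coral_%02d", 1:3)),
    group = c(rep("sebastidae", 6), rep("coral", 3)),
    stringsAsFactors = FALSE
  )
  all_opt <- c(opt, opt_cor)
  truth_taxa <- data.frame(
    taxa,
    # intercept chosen so the peak log-density per unit effort is ~ -4
    # (sebastidae) / -5.5 (corals, rarer)
    intercept = c(rep(-4, 6), rep(-5.5, 3)) - curv * all_opt^2,
    depth1 = 2 * curv * all_opt,
    depth2 = -curv,
    stringsAsFactors = FALSE
  )
  truth <- true_parameters(
    truth_taxa,
    method_bias = c(dive = 0, video_mid = -0.3, video_deep = -0.3, hookline = -2.5),
    subregion_effect = c(ABU = 0, EQCS = 0.3, MF = 0.5),
    sd_unit = 0.4, k = 1.2, zi = 0.1, phi = 8,
    cover_intercept = -3.5, cover_depth1 = 0.025, cover_depth2 = -6e-5,
    zi_cover = 0.3
  )
  # expected depth range: where the quadratic response is within 2 log units
  # of its optimum, truncated below at 5 m
  half <- sqrt(2 / curv)
  depth_ranges <- data.frame(
    taxon = c(taxa$taxon, "large_sponges"),
    min_depth_m = pmax(c(all_opt - half, 30), 5),
    max_depth_m = c(all_opt + half, 400),
    stringsAsFactors = FALSE
  )
  design <- generate_design(n_units_1km, seed = seed)
  traits <- generate_traits(taxa, seed = seed + 1)
  traits <- rbind(traits, data.frame(taxon = "large_sponges", group = "sponge",
                                     r = NA, depletion = NA, TL = NA, ED = NA,
                                     h = NA, planktivore = NA))
  counts <- simulate_counts(design, truth, seed = seed + 2)
  # sponge counts on deep video only; cover categories on dive/mid video
  sponge_truth <- true_parameters(
    data.frame(taxon = "large_sponges", group = "sponge",
               intercept = -6 - 6e-5 * 180^2, depth1 = 2 * 6e-5 * 180,
               depth2 = -6e-5, stringsAsFactors = FALSE),
    method_bias = truth$method_bias, subregion_effect = truth$subregion_effect,
    sd_unit = 0.4, k = 1.2, zi = 0.1
  )
  sponge_counts <- simulate_counts(design, sponge_truth, seed = seed + 3)
  sponge_counts <- sponge_counts[sponge_counts$method == "video_deep", , drop = FALSE]
  cover <- simulate_cover(design, truth, seed = seed + 4)
  obs <- rbind(counts, sponge_counts, cover)
  rownames(obs) <- NULL
  list(design = design, truth = truth, sponge_truth = sponge_truth,
       taxa = taxa, traits = traits, depth_ranges = depth_ranges, obs = obs)
}
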