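#' Read a pipeline configuration file
#'
#' The pipeline is driven by a single YAML file. Recognized fields (all
#' optional, with defaults): \code{seed}, \code{n_units_1km},
#' \code{validity_rule} ("containment" or "overlap"), \code{candidates}
#' ("reduced" or "full"), \code{hotspot_thresholds} (named list),
#' \code{outdir}, and an \code{inputs} block of CSV paths (observations,
#' traits, depth_ranges, grid) for running on existing files instead of the
#' synthetic scenario.
#'
#' @param path Path to a YAML file.
#' @return A named list with class \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, n_units_1km = 120L, validity_rule = "containment",
                   candidates = "reduced", outdir = NULL, inputs = NULL,
                   hotspot_thresholds = list(coral = 10, default = 9))
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("config 'seed' must be an integer")
  }
  if (!cfg$validity_rule %in% c("containment", "overlap")) {
    stop("config 'validity_rule' must be 'containment' or 'overlap'")
  }
  if (!is.null(cfg$inputs)) {
    missing_files <- unlist(cfg$inputs)[!file.exists(unlist(cfg$inputs))]
    if (length(missing_files)) {
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Simulate a synthetic survey data set to disk
#'
#' Runs the synthetic scenario for the configured seed and grid size and
#' writes \code{observations.csv}, \code{traits.csv},
#' \code{depth_ranges.csv}, \code{grid.csv} and a \code{truth.json} sidecar
#' holding the generating parameters. Files are stamped with the
#' configuration hash; rerunning with the same configuration reproduces them
#' byte for byte.
#'
#' @param config A \code{pipeline_config} (or list with the same fields).
#' @param outdir Output directory (created if needed); defaults to the
#'   config's \code{outdir}.
#' @return Invisibly, the named vector of file paths.
#' @export
run_simulation <- function(config, outdir = config$outdir) {
  if (is.null(outdir)) stop("no output directory configured")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hash <- config_hash(config[c("seed", "n_units_1km")])
  sc <- default_scenario(n_units_1km = config$n_units_1km %||% 120,
                         seed = config$seed %||% 1)
  obs_cols <- c("event_id", "unit_1km", "unit_16km", "subregion", "method",
                "depth_m", "effort", "effort_units", "year", "taxon", "group",
                "count", "cover_category")
  paths <- c(observations = file.path(outdir, "observations.csv"),
             traits = file.path(outdir, "traits.csv"),
             depth_ranges = file.path(outdir, "depth_ranges.csv"),
             grid = file.path(outdir, "grid.csv"),
             truth = file.path(outdir, "truth.json"))
  write_stamped_csv(sc$obs[, obs_cols], paths["observations"], hash)
  write_stamped_csv(sc$traits, paths["traits"], hash)
  write_stamped_csv(sc$depth_ranges, paths["depth_ranges"], hash)
  write_stamped_csv(sc$design$units, paths["grid"], hash)
  truth_out <- list(config_hash = hash,
                    taxa = sc$truth$taxa,
                    method_bias = as.list(sc$truth$method_bias),
                    subregion_effect = as.list(sc$truth$subregion_effect),
                    sd_unit = sc$truth$sd_unit, k = sc$truth$k, zi = sc$truth$zi,
                    phi = sc$truth$phi, zi_cover = sc$truth$zi_cover,
                    sponge = sc$sponge_truth$taxa)
  jsonlite::write_json(truth_out, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# Candidate specs conditioned on the data at hand: covariates with a single
# observed level are dropped (their contrasts are inestimable), and the
# nested set always contains a simple fallback so sparse groups can converge.
reduced_candidates <- function(dat, family = "nbinom") {
  base <- character()
  if (length(unique(dat$taxon)) > 1) base <- c(base, "taxon")
  if (length(unique(dat$method)) > 1) base <- c(base, "method")
  covsets <- list(base, c(base, "depth"), c(base, "depth", "depth2"))
  out <- list()
  for (cv in covsets) for (zi in c(FALSE, TRUE)) {
    out[[length(out) + 1L]] <- abundance_model_spec(family, cv, zi = zi)
  }
  out
}

#' Run the hotspot delineation pipeline
#'
#' Executes the full analysis on an observation table: conservation weights,
#' validity filtering, AIC-selected abundance GLMMs per taxonomic group
#' (negative binomial for counts; beta for sponge cover categories),
#' standardized abundance per unit of effort, min-max rescaling, per-group
#' and overall hotspot indices with decile ranks and hotspot flags at both
#' the 1-km^2 and 16-km^2 scales, and logistic occurrence models against
#' quadratic depth and subregion.
#'
#' @param obs Observation table (counts and/or cover rows).
#' @param traits Trait table for all analyzed taxa.
#' @param depth_ranges Expected depth range table.
#' @param design The \code{survey_design} the observations came from.
#' @param candidates \code{"reduced"} (depth models with and without the
#'   quadratic term and zero inflation) or \code{"full"}
#'   (\code{\link{default_candidate_specs}}).
#' @param validity_rule Passed to \code{\link{filter_observations}}.
#' @param hotspot_thresholds Passed to \code{\link{classify_hotspots}}.
#' @param outdir Optional directory: writes the output CSVs and a JSON run
#'   manifest.
#' @param config Optional configuration list recorded in the manifest hash.
#' @return List with elements \code{weights}, \code{filter_report},
#'   \code{fits}, \code{aic_tables}, \code{lambda}, \code{mu},
#'   \code{hotspots_1km}, \code{hotspots_16km}, \code{occurrence},
#'   \code{occurrence_summary}, \code{manifest}.
#' @export
run_hotspot_pipeline <- function(obs, traits, depth_ranges, design,
                                 candidates = "reduced",
                                 validity_rule = "containment",
                                 hotspot_thresholds = list(coral = 10, default = 9),
                                 outdir = NULL, config = NULL) {
  weights <- taxon_weights(traits)

  filtered <- filter_observations(obs, traits, depth_ranges, design,
                                  rule = validity_rule)
  freport <- attr(filtered, "filter_report")

  cand <- function(dat, family = "nbinom") {
    if (identical(candidates, "full")) {
      default_candidate_specs(family, multi_taxon = length(unique(dat$taxon)) > 1)
    } else {
      reduced_candidates(dat, family)
    }
  }

  fits <- list()
  lam <- list()
  for (grp in c("sebastidae", "coral")) {
    sub <- filtered[filtered$group == grp & !is.na(filtered$count), , drop = FALSE]
    if (!nrow(sub)) next
    fits[[grp]] <- select_abundance_model(cand(sub), sub)
    lam[[grp]] <- cbind(predict_lambda(fits[[grp]], sub), group = grp)
  }
  sp_counts <- filtered[filtered$group == "sponge" & !is.na(filtered$count), , drop = FALSE]
  if (nrow(sp_counts)) {
    fits$sponge_counts <- select_abundance_model(cand(sp_counts), sp_counts)
    lam$sponge_counts <- cbind(predict_lambda(fits$sponge_counts, sp_counts),
                               group = "sponge")
  }
  sp_cover <- filtered[filtered$group == "sponge" & !is.na(filtered$cover_category), , drop = FALSE]
  if (nrow(sp_cover)) {
    cover_specs <- Filter(function(s) !s$zi, cand(sp_cover, "beta"))
    fits$sponge_cover <- select_abundance_model(cover_specs, sp_cover)
    lam$sponge_cover <- cbind(predict_lambda(fits$sponge_cover, sp_cover),
                              group = "sponge")
  }
  lambda <- do.call(rbind, lam)
  rownames(lambda) <- NULL

  mu <- minmax_rescale(mu_per_effort(lambda))
  mu$group <- weights$group[match(mu$taxon, weights$taxon)]
  B_list <- list()
  for (grp in intersect(c("sebastidae", "coral", "sponge"), unique(mu$group))) {
    nm <- c(sebastidae = "SEB", coral = "Cor", sponge = "Sp")[[grp]]
    B_list[[nm]] <- group_index(mu, weights, group = grp)
  }
  hot1 <- hotspot_table(B_list, thresholds = hotspot_thresholds)

  # 16-km^2 scale: aggregate each index, re-rank, re-flag
  parent <- design$units$unit_16km[match(hot1$unit_1km, design$units$unit_1km)]
  hot16 <- NULL
  for (col in c(paste0("B_", names(B_list)), "B_o")) {
    ok <- !is.na(hot1[[col]])
    agg <- aggregate_16km(hot1[[col]][ok], parent[ok])
    names(agg)[2] <- col
    hot16 <- if (is.null(hot16)) agg else merge(hot16, agg, all = TRUE)
  }
  for (col in c(paste0("B_", names(B_list)), "B_o")) {
    ok <- !is.na(hot16[[col]])
    rk <- rep(NA_integer_, nrow(hot16))
    rk[ok] <- decile_ranks(hot16[[col]][ok])
    suffix <- if (col == "B_o") "overall" else sub("^B_", "", col)
    grp <- switch(suffix, Cor = "coral", overall = "overall",
                  SEB = "sebastidae", "sponge")
    hot16[[paste0("rank_", suffix)]] <- rk
    hot16[[paste0("hotspot_", suffix)]] <-
      ifelse(is.na(rk), NA, classify_hotspots(rk, grp, hotspot_thresholds))
  }

  # occurrence models: per-unit max sampled depth + subregion
  ev <- design$events
  max_depth <- tapply(ev$depth_m, ev$unit_1km, max)
  occ <- list()
  occ_rows <- list()
  flag_cols <- c(sebastidae = "hotspot_SEB", coral = "hotspot_Cor",
                 sponge = "hotspot_Sp", overall = "hotspot_overall")
  for (grp in names(flag_cols)) {
    fc <- flag_cols[[grp]]
    if (!fc %in% names(hot1)) next
    ok <- !is.na(hot1[[fc]])
    rec <- data.frame(
      unit_1km = hot1$unit_1km[ok],
      hotspot = hot1[[fc]][ok],
      max_depth_m = as.numeric(max_depth[hot1$unit_1km[ok]]),
      subregion = design$units$subregion[match(hot1$unit_1km[ok],
                                               design$units$unit_1km)],
      stringsAsFactors = FALSE)
    fit <- tryCatch(fit_occurrence(rec), error = function(e) e)
    if (inherits(fit, "error")) next
    occ[[grp]] <- fit
    occ_rows[[grp]] <- data.frame(
      response = grp,
      predictor = names(fit$coefficients),
      estimate = unname(fit$coefficients),
      se = unname(fit$se),
      peak_depth_m = peak_depth(fit),
      stringsAsFactors = FALSE)
  }
  occ_summary <- do.call(rbind, occ_rows)
  rownames(occ_summary) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefhotspots")),
    r_version = R.version.string,
    config_hash = config_hash(config %||% list(candidates = candidates,
                                               validity_rule = validity_rule,
                                               hotspot_thresholds = hotspot_thresholds)),
    n_obs_in = nrow(obs), n_obs_filtered = nrow(filtered),
    n_units_1km = nrow(hot1), n_units_16km = nrow(hot16),
    aic_tables = lapply(fits, function(f) attr(f, "aic_table")),
    filter_rows_removed = sum(freport$removed %||% 0)
  )

  res <- list(weights = weights, filter_report = freport, fits = fits,
              lambda = lambda, mu = mu, hotspots_1km = hot1,
              hotspots_16km = hot16, occurrence = occ,
              occurrence_summary = occ_summary, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hash <- res$manifest$config_hash
  write_stamped_csv(res$weights, file.path(outdir, "weights.csv"), hash)
  write_stamped_csv(res$filter_report, file.path(outdir, "filter_report.csv"), hash)
  write_stamped_csv(res$lambda, file.path(outdir, "lambda.csv"), hash)
  write_stamped_csv(res$mu, file.path(outdir, "mu.csv"), hash)
  write_stamped_csv(res$hotspots_1km, file.path(outdir, "hotspots_1km.csv"), hash)
  write_stamped_csv(res$hotspots_16km, file.path(outdir, "hotspots_16km.csv"), hash)
  if (!is.null(res$occurrence_summary)) {
    write_stamped_csv(res$occurrence_summary,
                      file.path(outdir, "occurrence_summary.csv"), hash)
  }
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Run the pipeline from a configuration file or object
#'
#' Reads the configured inputs (or simulates the synthetic scenario when no
#' input files are configured) and runs
#' \code{\link{run_hotspot_pipeline}}, writing outputs to the configured
#' directory.
#'
#' @param config Path to a YAML config, or a \code{pipeline_config}.
#' @return The pipeline result list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(config$inputs)) {
    obs <- read_stamped_csv(config$inputs$observations)
    traits <- read_stamped_csv(config$inputs$traits)
    depth_ranges <- read_stamped_csv(config$inputs$depth_ranges)
    grid <- read_stamped_csv(config$inputs$grid)
    design <- structure(list(
      events = unique(obs[, c("event_id", "unit_1km", "unit_16km", "subregion",
                              "method", "depth_m", "effort", "effort_units",
                              "year")]),
      units = grid,
      methods = survey_methods()
    ), class = "survey_design")
  } else {
    sc <- default_scenario(n_units_1km = config$n_units_1km %||% 120,
                           seed = config$seed %||% 1)
    obs <- sc$obs
    traits <- sc$traits
    depth_ranges <- sc$depth_ranges
    design <- sc$design
  }
  invisible(run_hotspot_pipeline(
    obs, traits, depth_ranges, design,
    candidates = config$candidates %||% "reduced",
    validity_rule = config$validity_rule %||% "containment",
    hotspot_thresholds = config$hotspot_thresholds %||% list(coral = 10, default = 9),
    outdir = config$outdir, config = unclass(config)))
}

#' Summarize a pipeline run
#'
#' Hotspot counts per taxonomic group and spatial scale, plus the
#' occurrence-model coefficient table, from an in-memory result or a results
#' directory written by \code{\link{run_hotspot_pipeline}}.
#'
#' @param x A pipeline result list, or a directory path.
#' @return List with \code{hotspot_counts} (data frame: group, scale, n_units,
#'   n_hotspots) and \code{occurrence} (coefficient table).
#' @export
pipeline_report <- function(x) {
  if (is.character(x)) {
    if (!dir.exists(x)) stop("results directory not found: ", x)
    h1 <- file.path(x, "hotspots_1km.csv")
    if (!file.exists(h1)) stop("no pipeline outputs in ", x)
    x <- list(hotspots_1km = read_stamped_csv(h1),
              hotspots_16km = read_stamped_csv(file.path(x, "hotspots_16km.csv")),
              occurrence_summary =
                if (file.exists(file.path(x, "occurrence_summary.csv"))) {
                  read_stamped_csv(file.path(x, "occurrence_summary.csv"))
                })
  }
  count_flags <- function(df, scale) {
    cols <- grep("^hotspot_", names(df), value = TRUE)
    data.frame(group = sub("^hotspot_", "", cols), scale = scale,
               n_units = vapply(cols, function(cl) sum(!is.na(df[[cl]])), integer(1)),
               n_hotspots = vapply(cols, function(cl) sum(df[[cl]], na.rm = TRUE),
                                   integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  counts <- rbind(count_flags(x$hotspots_1km, "1km"),
                  count_flags(x$hotspots_16km, "16km"))
  list(hotspot_counts = counts, occurrence = x$occurrence_summary)
}
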