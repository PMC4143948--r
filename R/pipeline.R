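#' Pipeline run configuration
#'
#' Resolved configuration for an end-to-end synthetic run. Defaults are the
#' standard analysis constants: 10 nm rendering, mask blur 1 px, mask
#' thresholds 0.15 (CAZ) and 0.08 (precision spots), minimum CAZ area 300 px,
#' photon cutoff 1,000, clustering at eps 20 nm / k 16, unit rule 4 clusters
#' in 200 nm, background QC at 2.3 spots per um^2. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the default keys.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_units = 6L,
    primary_dilution = 5e-4,
    cy5_fraction = 1,
    secondary_sat_d0 = 0.225,
    locs_per_cluster = NULL,
    unclustered_mode = "molecule",
    bin_size = 10,
    blur_sigma = 1,
    threshold = 0.15,
    precision_threshold = 0.08,
    min_area_px = 300,
    photon_cutoff = 1000,
    eps = 20, k = 16, unit_radius = 200, unit_min_clusters = 4,
    qc_max_spot_density = 2.3,
    background_density = 78,
    localization_sigma = 7.16,
    titration_dilutions = c(1, 1/2, 1/10, 1/100, 1/1000, 1e-4, 1e-5),
    titration_n_caz = 200,
    molecules_per_caz = 137.5,
    input = NULL,
    stp_model = 0L)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

write_config_dcf <- function(config, path) {
  flat <- lapply(unclass(config), function(v)
    if (is.null(v)) "NULL" else paste(format(v, digits = 12), collapse = " "))
  write.dcf(as.data.frame(flat, check.names = FALSE), path)
  invisible(path)
}

#' Run the synthetic analysis pipeline
#'
#' Executes simulate -> render -> photon filter -> segment -> QC -> cluster
#' -> quantify on synthetic data (or on a localization file given as
#' `input`), writing per-stage CSV tables, a summary table (AZ count, area,
#' localizations, molecules) and the resolved configuration next to the
#' outputs. All randomness flows from `config$seed`.
#'
#' @param config a [run_config()] (or a list of overrides).
#' @param out_dir output directory (created if missing); `NULL` suppresses
#'   all file output.
#' @return invisibly, a list with the per-stage results and the summary data
#'   frame.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  set.seed(config$seed)
  labeling <- labeling_model(secondary_sat_d0 = config$secondary_sat_d0)
  acquisition <- acquisition_model(
    localization_sigma = config$localization_sigma,
    background_density = config$background_density)

  ## stage: simulate (or load)
  truth <- NULL
  if (!is.null(config$input)) {
    table <- stage("load", {
      if (!file.exists(config$input))
        stop("input file not found: ", config$input)
      read_localizations(config$input)
    })
  } else {
    sim <- stage("simulate", {
      tp <- caz_truth_priors(unclustered_mode = config$unclustered_mode,
                             locs_per_cluster = config$locs_per_cluster)
      generate_caz_field(config$n_units, truth = tp, labeling = labeling,
                         acquisition = acquisition,
                         primary_dilution = config$primary_dilution,
                         cy5_fraction = config$cy5_fraction)
    })
    table <- sim$table
    truth <- sim$truth
  }

  ## stage: photon filter + render
  table <- stage("filter", filter_photons(table, config$photon_cutoff))
  image <- stage("render", render(table, config$bin_size))

  ## stage: segment + QC
  regions <- stage("segment",
                   segment_caz(image, table, config$blur_sigma,
                               config$threshold, config$min_area_px))
  bg <- stage("background", background_density(table, regions))
  qc_pass <- qc_background(bg$spot_density, config$qc_max_spot_density)

  ## stage: cluster
  params <- cluster_params(eps = config$eps, k = config$k,
                           unit_radius = config$unit_radius,
                           unit_min_clusters = config$unit_min_clusters)
  clustering <- stage("cluster",
                      cluster_localizations(table, params, regions))
  summ <- cluster_summary(clustering)

  ## stage: quantify (published calibration constants)
  cal <- brp_calibration()
  cf <- conversion_factor(cal)
  region_df <- do.call(rbind, lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    mol <- molecules(r$localization_count, cf)
    data.frame(region = i, area_um2 = r$area_um2,
               localizations = r$localization_count,
               molecules = mol$rounded,
               centroid_x = r$centroid_nm["x"], centroid_y = r$centroid_nm["y"])
  }))
  if (is.null(region_df))
    region_df <- data.frame(region = integer(), area_um2 = numeric(),
                            localizations = integer(), molecules = numeric(),
                            centroid_x = numeric(), centroid_y = numeric())
  summary_df <- data.frame(
    az_count = length(regions),
    mean_area_um2 = if (length(regions)) mean(region_df$area_um2) else NA,
    mean_localizations = if (length(regions))
      mean(region_df$localizations) else NA,
    mean_molecules = if (length(regions)) mean(region_df$molecules) else NA,
    background_per_um2 = bg$loc_density,
    spot_density_per_um2 = bg$spot_density,
    qc_pass = qc_pass,
    n_clusters = nrow(summ$per_cluster),
    n_caz_units = length(clustering$units),
    seed = config$seed)

  if (!is.null(out_dir)) {
    utils::write.csv(region_df, file.path(out_dir, "regions.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$per_cluster, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$per_unit, file.path(out_dir, "units.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    write_config_dcf(config, file.path(out_dir, "config.dcf"))
    if (!qc_pass)
      writeLines(sprintf(
        "EXCLUDED: background spot density %.2f per um^2 exceeds %.2f",
        bg$spot_density, config$qc_max_spot_density),
        file.path(out_dir, "qc_excluded.txt"))
  }
  invisible(list(table = table, truth = truth, image = image,
                 regions = regions, background = bg, qc_pass = qc_pass,
                 clustering = clustering, cluster_summary = summ,
                 regions_table = region_df, summary = summary_df,
                 config = config))
}
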