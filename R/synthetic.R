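#' Antibody labeling model
#'
#' The statistical model linking molecules to localizations. A molecule is
#' recognized by a primary antibody with an occupancy that saturates with the
#' primary concentration (one-site binding, Hill coefficient 1, half-
#' saturation `primary_d0` on the concentration-fraction scale where 1 is the
#' undiluted stock). Each bound primary carries one or two secondary
#' fragments (mean `secondaries_mean`); each secondary carries the imaged
#' fluorophore with a probability set by the Cy5 mixing fraction, attenuated
#' in the crowded CAZ environment by a saturable factor d/(d + d0) when
#' `secondary_sat_d0` is set. A detected fluorophore yields at least one
#' localization; the count is drawn from `locs_family` with mean
#' `locs_mean` (the geometric default is overdispersed, reflecting
#' photoswitching kinetics).
#'
#' Defaults reproduce the published calibration statistics: 1.59 secondaries
#' per primary, 16.1 localizations per secondary, primary half-saturation
#' 9.07e-4 (so occupancy is 0.355 at the 1/2,000 working dilution) and CAZ
#' secondary saturation 0.225.
#'
#' @param primary_d0 half-saturation of primary occupancy (fraction scale).
#' @param secondaries_mean mean secondaries per bound primary, in \[1, 2\]
#'   (drawn as 1 + Bernoulli(mean - 1)).
#' @param locs_mean mean localizations per detected fluorophore.
#' @param locs_family "geometric" (1 + geometric, overdispersed), "poisson"
#'   (1 + Poisson) or "fixed".
#' @param secondary_sat_d0 half-saturation of secondary decoration in the CAZ
#'   (NULL disables the attenuation; isolated antibodies are always fully
#'   decorated).
#' @param fluorophore_fraction Cy5 mixing fraction of the secondary pool.
#' @param linkage_sigma isotropic displacement (s.d., nm) of each secondary
#'   fluorophore from its epitope, reflecting the ~13 nm primary +
#'   F(ab')2 complex (default 6.5).
#' @export
labeling_model <- function(primary_d0 = 9.07e-4, secondaries_mean = 1.59,
                           locs_mean = 16.1,
                           locs_family = c("geometric", "poisson", "fixed"),
                           secondary_sat_d0 = NULL,
                           fluorophore_fraction = 1,
                           linkage_sigma = 6.5) {
  locs_family <- match.arg(locs_family)
  stopifnot(primary_d0 > 0, secondaries_mean >= 1, secondaries_mean <= 2,
            locs_mean >= 1, fluorophore_fraction >= 0,
            fluorophore_fraction <= 1, linkage_sigma >= 0)
  structure(list(primary_d0 = primary_d0,
                 secondaries_mean = secondaries_mean,
                 locs_mean = locs_mean, locs_family = locs_family,
                 secondary_sat_d0 = secondary_sat_d0,
                 fluorophore_fraction = fluorophore_fraction,
                 linkage_sigma = linkage_sigma),
            class = "labeling_model")
}

#' Primary-antibody occupancy at a given dilution
#' @param labeling a [labeling_model()].
#' @param dilution primary concentration fraction in (0, 1].
#' @return occupancy probability.
#' @export
primary_occupancy <- function(labeling, dilution) {
  dilution / (dilution + labeling$primary_d0)
}

# probability that a bound secondary is a detected Cy5 fluorophore at Cy5
# mixing fraction d (in the CAZ: saturable attenuation; isolated: linear)
active_prob <- function(labeling, d, in_caz = TRUE) {
  if (d <= 0) return(0)
  if (in_caz && !is.null(labeling$secondary_sat_d0))
    d / (d + labeling$secondary_sat_d0)
  else d
}

draw_secondaries <- function(labeling, n) {
  1L + stats::rbinom(n, 1L, labeling$secondaries_mean - 1)
}

draw_locs <- function(labeling, n) {
  switch(labeling$locs_family,
         geometric = 1L + stats::rgeom(n, 1 / labeling$locs_mean),
         poisson = 1L + stats::rpois(n, labeling$locs_mean - 1),
         fixed = rep(as.integer(round(labeling$locs_mean)), n))
}

#' Acquisition model
#'
#' Imaging-level parameters of the simulated localization experiment.
#'
#' @param localization_sigma isotropic localization precision (s.d., nm);
#'   default 7.16.
#' @param background_density unspecific localizations per square micrometre;
#'   default 78.
#' @param field_size `c(width, height)` in nm; `NULL` lets generators size
#'   the field from their content.
#' @param n_frames number of camera frames; default 15000.
#' @param photon_meanlog,photon_sdlog lognormal photon-count parameters
#'   (nuisance columns; defaults clear the standard 1000-photon filter).
#' @export
acquisition_model <- function(localization_sigma = 7.16,
                              background_density = 78,
                              field_size = NULL, n_frames = 15000,
                              photon_meanlog = log(2500),
                              photon_sdlog = 0.35) {
  stopifnot(localization_sigma >= 0, background_density >= 0)
  structure(list(localization_sigma = localization_sigma,
                 background_density = background_density,
                 field_size = field_size, n_frames = n_frames,
                 photon_meanlog = photon_meanlog,
                 photon_sdlog = photon_sdlog),
            class = "acquisition_model")
}

#' Ground-truth priors for CAZ-unit geometry
#'
#' A CAZ-unit is built from a Poisson number of elliptical multiprotein
#' clusters (mean `mean_clusters`) whose centres are dart-thrown inside a
#' disc of radius `placement_radius` with a hard-core minimum separation,
#' plus unclustered molecules at the configured fraction of total content.
#' The planted ellipse radii describe the epitope spread of one CAZ filament
#' (about a 10 nm structure); fitted cluster ellipses come out larger because
#' the enclosing ellipse also absorbs localization noise.
#'
#' @param mean_clusters mean clusters per unit (default 14.5).
#' @param molecules_per_cluster_mean mean molecules per cluster (default 7;
#'   drawn as 1 + Poisson(mean - 1)).
#' @param unclustered_fraction fraction of unit content not in clusters
#'   (default 0.26).
#' @param unclustered_mode "molecule": unclustered molecules placed uniformly
#'   in the unit disc and put through the labeling model (spiky, the default);
#'   "localizations": the unclustered fraction is added as spatially uniform
#'   localizations (diffuse).
#' @param locs_per_cluster when set, clusters are planted directly at the
#'   localization level with Poisson(`locs_per_cluster`) localizations each,
#'   bypassing the labeling chain (the configuration used for clustering-
#'   algorithm recovery studies, where the per-cluster localization count is
#'   the controlled quantity).
#' @param cluster_long,cluster_short planted ellipse radii, nm.
#' @param cluster_min_sep hard-core separation of cluster centres, nm
#'   (default 40; clustering-recovery studies use 60 so every planted
#'   cluster is a resolvable entity).
#' @param placement_radius disc radius for cluster centres, nm (must stay
#'   within 200 nm of the unit centre).
#' @param unclustered_radius disc radius for unclustered content, nm
#'   (default 130, keeping default units contiguous under the standard
#'   segmentation thresholds).
#' @param unit_radius nominal unit radius (200 nm, the grouping rule scale).
#' @export
caz_truth_priors <- function(mean_clusters = 14.5,
                             molecules_per_cluster_mean = 7,
                             unclustered_fraction = 0.26,
                             unclustered_mode = c("molecule", "localizations"),
                             locs_per_cluster = NULL,
                             cluster_long = 10, cluster_short = 5,
                             cluster_min_sep = 40, placement_radius = 100,
                             unclustered_radius = 130, unit_radius = 200) {
  unclustered_mode <- match.arg(unclustered_mode)
  stopifnot(mean_clusters > 0, molecules_per_cluster_mean >= 1,
            unclustered_fraction >= 0, unclustered_fraction < 1,
            placement_radius + cluster_long <= unit_radius)
  structure(list(mean_clusters = mean_clusters,
                 molecules_per_cluster_mean = molecules_per_cluster_mean,
                 unclustered_fraction = unclustered_fraction,
                 unclustered_mode = unclustered_mode,
                 locs_per_cluster = locs_per_cluster,
                 cluster_long = cluster_long, cluster_short = cluster_short,
                 cluster_min_sep = cluster_min_sep,
                 placement_radius = placement_radius,
                 unclustered_radius = unclustered_radius,
                 unit_radius = unit_radius),
            class = "caz_truth_priors")
}

# dart-throwing with hard core; relaxes the separation if placement stalls
place_hardcore <- function(n, radius, min_sep, max_tries = 4000) {
  pts <- matrix(NA_real_, n, 2)
  sep2 <- min_sep^2
  i <- 1L; tries <- 0L
  while (i <= n) {
    r <- radius * sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
    p <- c(r * cos(a), r * sin(a))
    ok <- i == 1L ||
      all((pts[seq_len(i - 1L), 1] - p[1])^2 +
            (pts[seq_len(i - 1L), 2] - p[2])^2 >= sep2)
    if (ok) { pts[i, ] <- p; i <- i + 1L; tries <- 0L }
    else {
      tries <- tries + 1L
      if (tries > max_tries) { sep2 <- sep2 * 0.9; tries <- 0L }
    }
  }
  pts
}

runif_disc <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n)); a <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a))
}

runif_ellipse <- function(n, long, short, orientation) {
  r <- sqrt(stats::runif(n)); a <- stats::runif(n, 0, 2 * pi)
  x <- long * r * cos(a); y <- short * r * sin(a)
  co <- cos(orientation); si <- sin(orientation)
  cbind(co * x - si * y, si * x + co * y)
}

# labeling chain for a set of molecule positions -> fluorophore positions and
# localization counts
label_molecules <- function(pos, labeling, occupancy, p_active) {
  n <- nrow(pos)
  if (n == 0 || occupancy <= 0 || p_active <= 0)
    return(list(fluor_pos = matrix(numeric(0), 0, 2), locs = integer(0),
                labelled = logical(n)))
  lab <- stats::runif(n) < occupancy
  idx <- which(lab)
  fp <- list(); lc <- list()
  if (length(idx)) {
    nsec <- draw_secondaries(labeling, length(idx))
    ls <- labeling$linkage_sigma
    for (j in seq_along(idx)) {
      act <- stats::rbinom(1L, nsec[j], p_active)
      if (act > 0) {
        fp[[length(fp) + 1L]] <-
          matrix(rep(pos[idx[j], ], act), ncol = 2, byrow = TRUE) +
          matrix(stats::rnorm(2L * act, 0, ls), ncol = 2)
        lc[[length(lc) + 1L]] <- draw_locs(labeling, act)
      }
    }
  }
  list(fluor_pos = if (length(fp)) do.call(rbind, fp) else
         matrix(numeric(0), 0, 2),
       locs = if (length(lc)) unlist(lc) else integer(0),
       labelled = lab)
}

# expand fluorophores into localizations with Gaussian noise, burst frames
# and lognormal photon counts
emit_localizations <- function(fluor_pos, locs, acquisition) {
  total <- sum(locs)
  if (total == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      frame = integer(0), photons = numeric(0)))
  cx <- rep(fluor_pos[, 1], locs)
  cy <- rep(fluor_pos[, 2], locs)
  s <- acquisition$localization_sigma
  starts <- sample.int(acquisition$n_frames, length(locs), replace = TRUE)
  frames <- (rep(starts, locs) + sequence(locs) - 1L - 1L) %%
    acquisition$n_frames + 1L
  data.frame(x = cx + stats::rnorm(total, 0, s),
             y = cy + stats::rnorm(total, 0, s),
             frame = frames,
             photons = stats::rlnorm(total, acquisition$photon_meanlog,
                                     acquisition$photon_sdlog))
}

#' Generate a localization field of CAZ-units with ground truth
#'
#' Units are placed on a grid with at least `unit_spacing` nm between unit
#' centres. Each planted molecule goes through the labeling model; each
#' detected fluorophore emits a drawn number of localizations displaced by
#' isotropic Gaussian noise of the localization precision; uniform background
#' localizations are added at the configured density.
#'
#' @param n_units number of CAZ-units (>= 0).
#' @param truth a [caz_truth_priors()].
#' @param labeling a [labeling_model()].
#' @param acquisition an [acquisition_model()].
#' @param primary_dilution primary concentration fraction; `NULL` means
#'   saturating occupancy 1.
#' @param cy5_fraction Cy5 mixing fraction of the secondary pool (default 1).
#' @param unit_spacing minimum distance between unit centres, nm (default 1500).
#' @param seed optional RNG seed.
#' @return list with `table` (a [loc_table()]) and `truth` (list of
#'   `caz_ground_truth` records: unit centre, cluster centres and ellipses,
#'   molecules per cluster, unclustered positions, molecule and localization
#'   totals).
#' @export
generate_caz_field <- function(n_units, truth = caz_truth_priors(),
                               labeling = labeling_model(),
                               acquisition = acquisition_model(),
                               primary_dilution = NULL, cy5_fraction = 1,
                               unit_spacing = 1500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_units >= 0)
  occ <- if (is.null(primary_dilution)) 1 else
    primary_occupancy(labeling, primary_dilution)
  p_act <- active_prob(labeling, cy5_fraction, in_caz = TRUE) *
    labeling$fluorophore_fraction
  margin <- truth$unit_radius + 100
  ncol_grid <- max(1L, ceiling(sqrt(max(n_units, 1L))))
  nrow_grid <- max(1L, ceiling(max(n_units, 1L) / ncol_grid))
  fw <- ncol_grid * unit_spacing + 2 * margin
  fh <- nrow_grid * unit_spacing + 2 * margin
  if (!is.null(acquisition$field_size)) {
    fs <- acquisition$field_size
    if (n_units > 0 && (fs[1] < fw - unit_spacing / 2 ||
                        fs[2] < fh - unit_spacing / 2))
      stop("placement error: field too small for the requested units")
    fw <- fs[1]; fh <- fs[2]
  }
  rows <- list(); gts <- list()
  for (u in seq_len(n_units)) {
    gi <- (u - 1L) %% ncol_grid
    gj <- (u - 1L) %/% ncol_grid
    centre <- c(margin + (gi + 0.5) * unit_spacing,
                margin + (gj + 0.5) * unit_spacing)
    nc <- max(1L, stats::rpois(1, truth$mean_clusters))
    ccent <- place_hardcore(nc, truth$placement_radius, truth$cluster_min_sep)
    ccent <- sweep(ccent, 2, centre, "+")
    ell <- cbind(long = pmax(2, stats::rnorm(nc, truth$cluster_long,
                                             truth$cluster_long * 0.1)),
                 short = pmax(1, stats::rnorm(nc, truth$cluster_short,
                                              truth$cluster_short * 0.1)),
                 orientation = stats::runif(nc, 0, pi))
    nmol <- 1L + stats::rpois(nc, truth$molecules_per_cluster_mean - 1)
    f <- truth$unclustered_fraction
    unc_pos <- matrix(numeric(0), 0, 2)
    unit_rows <- list()
    if (is.null(truth$locs_per_cluster)) {
      mol_pos <- do.call(rbind, lapply(seq_len(nc), function(i) {
        sweep(runif_ellipse(nmol[i], ell[i, 1], ell[i, 2], ell[i, 3]),
              2, ccent[i, ], "+")
      }))
      lm_cl <- label_molecules(mol_pos, labeling, occ, p_act)
      unit_rows$cl <- emit_localizations(lm_cl$fluor_pos, lm_cl$locs,
                                         acquisition)
    } else {
      nloc <- stats::rpois(nc, truth$locs_per_cluster)
      pos <- do.call(rbind, lapply(seq_len(nc), function(i) {
        sweep(runif_ellipse(nloc[i], ell[i, 1], ell[i, 2], ell[i, 3]),
              2, ccent[i, ], "+")
      }))
      unit_rows$cl <- emit_localizations(pos, rep(1L, sum(nloc)), acquisition)
      nmol <- nloc
    }
    if (f > 0) {
      if (truth$unclustered_mode == "molecule") {
        n_unc <- stats::rpois(1, sum(nmol) * f / (1 - f))
        unc_pos <- sweep(runif_disc(n_unc, truth$unclustered_radius), 2, centre, "+")
        lm_unc <- label_molecules(unc_pos, labeling, occ, p_act)
        unit_rows$unc <- emit_localizations(lm_unc$fluor_pos, lm_unc$locs,
                                            acquisition)
      } else {
        n_unc_locs <- stats::rpois(1, nrow(unit_rows$cl) * f / (1 - f))
        pos <- sweep(runif_disc(n_unc_locs, truth$unclustered_radius), 2, centre, "+")
        unit_rows$unc <- emit_localizations(
          pos, rep(1L, n_unc_locs), acquisition)
      }
    }
    df <- do.call(rbind, unit_rows)
    rows[[u]] <- df
    gts[[u]] <- structure(
      list(unit_centre = centre, cluster_centres = ccent,
           cluster_ellipses = ell, molecules_per_cluster = nmol,
           unclustered_molecule_positions = unc_pos,
           molecule_total = sum(nmol) + nrow(unc_pos),
           n_localizations = nrow(df),
           unclustered_mode = truth$unclustered_mode),
      class = "caz_ground_truth")
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), frame = integer(0),
               photons = numeric(0))
  area_um2 <- fw * fh / 1e6
  nbg <- stats::rpois(1, acquisition$background_density * area_um2)
  if (nbg > 0) {
    bg <- data.frame(x = stats::runif(nbg, 0, fw),
                     y = stats::runif(nbg, 0, fh),
                     frame = sample.int(acquisition$n_frames, nbg,
                                        replace = TRUE),
                     photons = stats::rlnorm(nbg, acquisition$photon_meanlog,
                                             acquisition$photon_sdlog))
    df <- rbind(df, bg)
  }
  df <- df[df$x >= 0 & df$y >= 0 & df$x <= fw & df$y <= fh, , drop = FALSE]
  tab <- loc_table(df$x, df$y, df$frame, df$photons, field = c(fw, fh))
  list(table = tab, truth = gts)
}

#' Generate antibody titration series with ground truth
#'
#' Count-level simulation of the two calibration experiments. Per-CAZ
#' localization counts at each dilution are drawn as Poisson about the
#' logistic titration mean (one-site saturation, Hill coefficient 1), the
#' same distributional model the downstream Poisson histogram fit assumes.
#' In secondary mode the Cy5 secondary pool is diluted at fixed experimental
#' primary occupancy; in primary mode the primary is diluted at a fixed Cy5
#' mixing fraction.
#'
#' @param dilutions concentration fractions in (0, 1].
#' @param mode "secondary" or "primary".
#' @param labeling a [labeling_model()].
#' @param n_caz CAZs measured per dilution.
#' @param molecules_per_caz mean molecules per CAZ-unit (default 137.5).
#' @param primary_dilution_exp experimental primary concentration fraction
#'   used in secondary mode (default 5e-4, i.e. 1/2,000).
#' @param cy5_fraction_primary Cy5 mixing fraction used in primary mode
#'   (default 0.01).
#' @param seed optional RNG seed.
#' @return list with `series` (a `titration_series`: mode plus a list of
#'   per-dilution count vectors) and `truth` (planted logistic parameters
#'   `L1`, `L2`, `d0`).
#' @export
generate_titration_series <- function(dilutions,
                                      mode = c("secondary", "primary"),
                                      labeling = labeling_model(
                                        secondary_sat_d0 = 0.225),
                                      n_caz = 200,
                                      molecules_per_caz = 137.5,
                                      primary_dilution_exp = 5e-4,
                                      cy5_fraction_primary = 0.01,
                                      seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (length(dilutions) == 0) stop("empty dilution list")
  stopifnot(all(dilutions > 0), all(dilutions <= 1), n_caz >= 1)
  ff <- labeling$fluorophore_fraction
  L2_sec <- labeling$locs_mean
  if (mode == "secondary") {
    occ <- primary_occupancy(labeling, primary_dilution_exp)
    Lsat <- molecules_per_caz * occ * labeling$secondaries_mean *
      labeling$locs_mean * ff
    d0 <- if (is.null(labeling$secondary_sat_d0)) NA_real_ else
      labeling$secondary_sat_d0
    mean_fun <- function(d) {
      if (ff == 0) return(0)
      g <- if (is.na(d0)) d else d / (d + d0)
      L2_sec + (Lsat - L2_sec) * g
    }
    planted <- list(L1 = Lsat, L2 = L2_sec, d0 = if (is.na(d0)) 0 else d0)
  } else {
    p_act <- active_prob(labeling, cy5_fraction_primary, in_caz = TRUE)
    L_ab <- labeling$secondaries_mean * p_act * labeling$locs_mean * ff
    Lsat <- molecules_per_caz * labeling$secondaries_mean * p_act *
      labeling$locs_mean * ff
    mean_fun <- function(d) {
      if (ff == 0) return(0)
      g <- primary_occupancy(labeling, d)
      L_ab + (Lsat - L_ab) * g
    }
    planted <- list(L1 = Lsat, L2 = L_ab, d0 = labeling$primary_d0)
  }
  counts <- lapply(dilutions, function(d) {
    m <- mean_fun(d)
    if (m <= 0) rep(0L, n_caz) else stats::rpois(n_caz, m)
  })
  series <- titration_series(dilutions, counts, mode)
  list(series = series, truth = planted)
}

#' Generate isolated, unspecifically bound antibodies
#'
#' `n` well-separated antibody positions on a jittered grid; each contributes
#' a drawn number of localizations displaced by the localization precision.
#' Used for precision-estimator studies and for calibrating localizations per
#' isolated primary antibody.
#'
#' @param n number of antibodies (>= 1).
#' @param acquisition an [acquisition_model()] (its background is not used).
#' @param locs_per_antibody either a function `n -> counts`, a single number
#'   (fixed count), or `NULL` for the full compound secondary model of
#'   `labeling` (fully decorated isolated antibodies).
#' @param labeling a [labeling_model()] backing the `NULL` default.
#' @param spacing grid spacing in nm (default 300).
#' @param seed optional RNG seed.
#' @return list with `table` (a [loc_table()]), `groups` (integer antibody
#'   label per localization) and `truth` (positions and per-antibody counts).
#' @export
generate_isolated_antibodies <- function(n, acquisition = acquisition_model(),
                                         locs_per_antibody = NULL,
                                         labeling = labeling_model(),
                                         spacing = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  counts <- if (is.null(locs_per_antibody)) {
    nsec <- draw_secondaries(labeling, n)
    vapply(nsec, function(k) sum(draw_locs(labeling, k)), numeric(1))
  } else if (is.function(locs_per_antibody)) {
    locs_per_antibody(n)
  } else {
    rep(as.integer(round(locs_per_antibody)), n)
  }
  counts <- as.integer(counts)
  ncol_grid <- ceiling(sqrt(n))
  margin <- spacing / 2
  gi <- (seq_len(n) - 1L) %% ncol_grid
  gj <- (seq_len(n) - 1L) %/% ncol_grid
  pos <- cbind(margin + (gi + 0.5) * spacing +
                 stats::runif(n, -spacing / 8, spacing / 8),
               margin + (gj + 0.5) * spacing +
                 stats::runif(n, -spacing / 8, spacing / 8))
  fw <- ncol_grid * spacing + 2 * margin
  fh <- (ceiling(n / ncol_grid)) * spacing + 2 * margin
  df <- emit_localizations(pos, counts, acquisition)
  keep <- df$x >= 0 & df$y >= 0 & df$x <= fw & df$y <= fh
  groups <- rep(seq_len(n), counts)[keep]
  df <- df[keep, , drop = FALSE]
  tab <- loc_table(df$x, df$y, df$frame, df$photons, field = c(fw, fh))
  list(table = tab, groups = groups,
       truth = list(positions = pos, counts = counts))
}

#' Generate noisy evoked-current trains from a vesicle-pool model
#'
#' Forward-simulates the deterministic short-term-plasticity model for the
#' given protocol and applies multiplicative Gaussian amplitude noise per
#' sweep.
#'
#' @param params an [stp_params1()] or [stp_params2()].
#' @param protocol a [stimulus_protocol()].
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_sweeps number of sweeps (0 gives an empty list).
#' @param seed optional RNG seed.
#' @return list of `epsc_train` objects.
#' @export
generate_stp_dataset <- function(params, protocol = stimulus_protocol(),
                                 noise_cv = 0, n_sweeps = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise_cv >= 0, n_sweeps >= 0)
  base <- simulate_stp(params, protocol)
  lapply(seq_len(n_sweeps), function(i) {
    tr <- base
    if (noise_cv > 0)
      tr$amplitude <- tr$amplitude *
        (1 + stats::rnorm(nrow(tr), 0, noise_cv))
    tr
  })
}
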