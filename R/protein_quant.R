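#' Titration series
#'
#' Per-CAZ localization counts measured at a set of antibody dilutions.
#' Dilutions are concentration fractions in (0, 1] (1 = undiluted working
#' concentration); the titration response rises with the fraction.
#'
#' @param dilutions concentration fractions.
#' @param counts list of per-CAZ localization count vectors, one per
#'   dilution (at least 4 counts each).
#' @param mode "secondary" (fluorophore-labelled secondary diluted at fixed
#'   primary) or "primary" (primary diluted at fixed secondary).
#' @export
titration_series <- function(dilutions, counts,
                             mode = c("secondary", "primary")) {
  mode <- match.arg(mode)
  if (length(dilutions) == 0) stop("empty dilution list")
  stopifnot(length(dilutions) == length(counts),
            all(dilutions > 0), all(dilutions <= 1))
  if (any(vapply(counts, length, integer(1)) < 4))
    stop("need at least 4 per-CAZ counts per dilution point")
  if (any(unlist(counts) < 0)) stop("negative localization counts")
  structure(list(dilutions = as.numeric(dilutions), counts = counts,
                 mode = mode),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series (%s mode), %d dilution points\n",
              x$mode, length(x$dilutions)))
  for (i in seq_along(x$dilutions)) {
    pm <- poisson_mean(x$counts[[i]])
    cat(sprintf("  d = %-10.3g n = %-4d mean = %.1f +/- %.1f\n",
                x$dilutions[i], length(x$counts[[i]]), pm$mean, pm$sem))
  }
  invisible(x)
}

#' Poisson mean of per-CAZ localization counts
#'
#' The maximum-likelihood Poisson rate (identical to the arithmetic mean)
#' with its standard error sqrt(mean / n). A least-squares fit of the Poisson
#' probability function to the count histogram is available as a cross-check
#' via `method = "histogram"`.
#'
#' @param counts nonnegative per-CAZ localization totals (>= 4).
#' @param method "mle" (default) or "histogram".
#' @return list with `mean`, `sem`, `n`.
#' @export
poisson_mean <- function(counts, method = c("mle", "histogram")) {
  method <- match.arg(method)
  if (length(counts) == 0) stop("empty count list")
  if (length(counts) < 4) stop("need at least 4 counts")
  if (any(counts < 0)) stop("negative counts")
  n <- length(counts)
  if (method == "mle") {
    m <- mean(counts)
  } else {
    # least squares of binned histogram proportions against the Poisson
    # bin probabilities (binning keeps the objective well conditioned for
    # large rates, where individual count probabilities are all tiny)
    w <- max(1L, ceiling((max(counts) + 1) / 20))
    edges <- seq(-0.5, max(counts) + w + 0.5, by = w)
    h <- graphics::hist(counts, breaks = edges, plot = FALSE)
    obs <- h$counts / n
    lo <- edges[-length(edges)]
    hi <- edges[-1]
    f <- function(lam) sum((obs - (stats::ppois(hi, lam) -
                                     stats::ppois(lo, lam)))^2)
    # coarse grid then local refinement: the objective plateaus once the
    # model mass leaves the histogram support, which strands a plain
    # golden-section search
    grid <- seq(max(mean(counts) / 3, 1e-6), mean(counts) * 3,
                length.out = 61)
    g0 <- grid[which.min(vapply(grid, f, numeric(1)))]
    step <- grid[2] - grid[1]
    m <- stats::optimize(f, c(g0 - step, g0 + step))$minimum
  }
  list(mean = m, sem = sqrt(m / n), n = n)
}

#' Fit the logistic titration function
#'
#' Per-dilution Poisson means are fitted with the one-site logistic
#' L(d) = L2 + (L1 - L2) * (1 + d0/d)^-1 (Hill coefficient fixed to 1),
#' where d is the concentration fraction: L1 is the saturated localization
#' count and L2 the count contributed by a single labelled antibody, the
#' asymptote at high dilution. Points are weighted by their inverse squared
#' standard errors.
#'
#' @param series a [titration_series()].
#' @param weighted inverse-variance weights (default) or unweighted.
#' @return a `titration_fit` with `L1`, `L2`, `d0` (each value + sem), the
#'   fitted object, and a `flag` ("ok", "flat" when the response is not
#'   identifiable).
#' @export
fit_titration <- function(series, weighted = TRUE) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$dilutions) < 4)
    stop("need at least 4 dilution points")
  pm <- lapply(series$counts, poisson_mean)
  m <- vapply(pm, `[[`, numeric(1), "mean")
  sems <- vapply(pm, `[[`, numeric(1), "sem")
  d <- series$dilutions
  if (max(m) < 1e-9 || max(m) / max(min(m), 1e-9) < 1.2) {
    est <- c(L1 = mean(m), L2 = mean(m), d0 = NA_real_)
    return(structure(list(coefficients = est,
                          sem = c(L1 = NA, L2 = NA, d0 = NA),
                          flag = "flat", means = m, dilutions = d),
                     class = "titration_fit"))
  }
  w <- if (weighted) 1 / pmax(sems, 1e-6)^2 else rep(1, length(m))
  dat <- data.frame(d = d, m = m)
  fit <- minpack.lm::nlsLM(
    m ~ L2 + (L1 - L2) / (1 + d0 / d), data = dat, weights = w,
    start = list(L1 = max(m), L2 = max(min(m), 1e-3), d0 = 0.1),
    lower = c(0, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(coefficients = cf, sem = se, fit = fit, flag = "ok",
                 means = m, sems = sems, dilutions = d, mode = series$mode),
            class = "titration_fit")
}

#' @export
coef.titration_fit <- function(object, ...) object$coefficients

#' @export
print.titration_fit <- function(x, ...) {
  cf <- x$coefficients
  if (x$flag == "flat") {
    cat(sprintf("Titration fit: FLAT response (L1 = L2 = %.2f, d0 unidentifiable)\n",
                cf["L1"]))
  } else {
    cat(sprintf("Titration fit: L1 = %.1f +/- %.1f, L2 = %.2f +/- %.2f, d0 = %.3g\n",
                cf["L1"], x$sem["L1"], cf["L2"], x$sem["L2"], cf["d0"]))
  }
  invisible(x)
}

#' @export
predict.titration_fit <- function(object, dilutions = object$dilutions, ...) {
  cf <- object$coefficients
  if (object$flag == "flat") return(rep(cf["L1"], length(dilutions)))
  unname(cf["L2"] + (cf["L1"] - cf["L2"]) / (1 + cf["d0"] / dilutions))
}

#' Secondary antibodies per primary antibody
#'
#' Ratio of the localizations measured for an isolated primary antibody
#' (with its full complement of secondaries) to the localizations of a
#' single secondary.
#'
#' @param L_E localizations per isolated primary antibody.
#' @param L2 localizations per single secondary antibody.
#' @export
secondaries_per_primary <- function(L_E, L2) {
  if (L_E <= 0 || L2 <= 0) stop("inputs must be positive")
  L_E / L2
}

#' Calibration constants from the antibody titrations
#'
#' The seven localization statistics that calibrate the molecule conversion:
#' mean localizations per CAZ-unit, the secondary-titration asymptotes
#' (single secondary `L2_cy5` and saturated `L1_cy5`), the measured count at
#' 100% Cy5, the localizations per isolated primary `L_E_nc82`, and the
#' primary-titration asymptote `L1_nc82` with the measured count at the
#' experimental 1/2,000 primary dilution.
#'
#' @param loc_caz_unit,L2_cy5,L1_cy5,L_caz_cy5,L_E_nc82,L1_nc82,L_caz_nc82
#'   localization values (all > 0).
#' @param sem named numeric vector of standard errors for any of the seven
#'   values (missing entries default to 0).
#' @export
calibration_constants <- function(loc_caz_unit, L2_cy5, L1_cy5, L_caz_cy5,
                                  L_E_nc82, L1_nc82, L_caz_nc82,
                                  sem = NULL) {
  v <- c(loc_caz_unit = as.numeric(loc_caz_unit)[1],
         L2_cy5 = as.numeric(L2_cy5)[1], L1_cy5 = as.numeric(L1_cy5)[1],
         L_caz_cy5 = as.numeric(L_caz_cy5)[1],
         L_E_nc82 = as.numeric(L_E_nc82)[1],
         L1_nc82 = as.numeric(L1_nc82)[1],
         L_caz_nc82 = as.numeric(L_caz_nc82)[1])
  if (any(v <= 0)) stop("all calibration constants must be positive")
  if (L1_cy5 < L2_cy5) stop("L1_cy5 must be >= L2_cy5")
  s <- stats::setNames(rep(0, 7), names(v))
  if (!is.null(sem)) s[names(sem)] <- sem
  structure(list(values = v, sem = s), class = "calibration_constants")
}

#' Published calibration statistics
#'
#' The seven localization values (with standard errors) measured for the
#' wild-type Drosophila NMJ Brp calibration: localizations per CAZ-unit
#' 1,020.5; single Cy5 secondary 16.1; Cy5 titration asymptote 1,212.2;
#' count at 100% Cy5 992.5; isolated primary 25.6; primary-titration
#' asymptote 198.9; count at the experimental 1/2,000 primary dilution 70.7.
#'
#' @return a [calibration_constants()] object.
#' @export
brp_calibration <- function() {
  calibration_constants(
    loc_caz_unit = 1020.5, L2_cy5 = 16.1, L1_cy5 = 1212.2,
    L_caz_cy5 = 992.5, L_E_nc82 = 25.6, L1_nc82 = 198.9, L_caz_nc82 = 70.7,
    sem = c(loc_caz_unit = 42.7, L2_cy5 = 1.0, L1_cy5 = 117.4,
            L_caz_cy5 = 100.9, L_E_nc82 = 1.4, L1_nc82 = 6.4,
            L_caz_nc82 = 7.6))
}

#' Molecules-per-localization conversion factor
#'
#' The calibration product
#' C = (1 / L_E) * (L1_nc82 / L_caz_nc82) * (L1_cy5 / L_caz_cy5):
#' the reciprocal localizations per primary antibody, corrected for
#' incomplete primary-epitope saturation at the working dilution and for
#' incomplete secondary decoration in the CAZ at 100% Cy5. In the
#' uncancelled form the single-secondary count L2(Cy5) appears once in the
#' numerator and once in the denominator (L_E = L2 * secondaries-per-
#' primary); its relative error therefore enters the first-order quadrature
#' propagation twice, as two independent factors.
#'
#' @param constants a [calibration_constants()].
#' @return a `conversion_factor`: `value` (molecules per localization) and
#'   `sem`.
#' @export
conversion_factor <- function(constants) {
  stopifnot(inherits(constants, "calibration_constants"))
  v <- constants$values
  C <- (1 / v["L_E_nc82"]) * (v["L1_nc82"] / v["L_caz_nc82"]) *
    (v["L1_cy5"] / v["L_caz_cy5"])
  rel <- constants$sem / v
  rel2 <- rel[c("L_E_nc82", "L1_nc82", "L_caz_nc82", "L1_cy5",
                "L_caz_cy5")]^2
  sem <- unname(C) * sqrt(sum(rel2) + 2 * rel["L2_cy5"]^2)
  structure(list(value = unname(C), sem = unname(sem)),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("Conversion factor: %.3f +/- %.3f molecules per localization\n",
              x$value, x$sem))
  invisible(x)
}

#' Convert localization counts to molecule estimates
#'
#' @param localizations localization count (>= 0), optionally with a
#'   standard error in `loc_sem`.
#' @param factor a `conversion_factor` (or plain number).
#' @param loc_sem standard error of the localization count (default 0).
#' @return list with `estimate`, `sem` (relative errors of count and factor
#'   combined in quadrature) and `rounded` (nearest integer, the reported
#'   molecule number).
#' @export
molecules <- function(localizations, factor, loc_sem = 0) {
  stopifnot(localizations >= 0)
  fv <- if (inherits(factor, "conversion_factor")) factor$value else factor
  fs <- if (inherits(factor, "conversion_factor")) factor$sem else 0
  est <- localizations * fv
  rel <- 0
  if (est > 0)
    rel <- sqrt((loc_sem / localizations)^2 + (fs / fv)^2)
  list(estimate = est, sem = est * rel, rounded = round(est))
}
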