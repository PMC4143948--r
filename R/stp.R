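#' Parameters of the one-pool vesicle model (model 1)
#'
#' Mean-field model of a readily releasable vesicle pool (capacity `N`)
#' refilled from a finite supply pool (capacity `N0`). The refill flux is
#' `k_plus1 * (n0/N0) * (N - n1)` (free-release-site limited and scaled by
#' supply occupancy) with back-transfer `k_minus1 * n1`; the supply pool
#' exchanges with an external reservoir at `k_plus0` / `k_minus0`. Release
#' probability is derived from the single free parameter `alpha` as
#' `p = 1 - exp(-alpha)` and facilitated by a residual-calcium variable (see
#' [facilitated_pvr()]). With `k_plus0 = k_minus0 = 0` the system is closed:
#' pool contents plus cumulative release are conserved.
#'
#' The constrained (non-free) parameters are required configuration inputs;
#' the defaults are documented placeholders on the scale of reported
#' neuromuscular-junction estimates, not measured values.
#'
#' @param alpha release-probability parameter (> 0).
#' @param N readily releasable pool capacity (vesicles).
#' @param N0 supply pool capacity.
#' @param k_plus1,k_minus1 RRP refill / unbinding rates (1/s).
#' @param k_plus0,k_minus0 supply refill / loss rates (1/s).
#' @param gamma calcium dependence of facilitation (1/um, default 0.4).
#' @param gamma_length length scale converting `gamma` to a dimensionless
#'   facilitation gain (um, default 1: gain = gamma * gamma_length).
#' @param tau_f facilitation decay time constant (s, default 0.1).
#' @param quantal_size current per vesicle (normalized default 1).
#' @export
stp_params1 <- function(alpha = 0.6, N = 500, N0 = 3000,
                        k_plus1 = 10, k_minus1 = 1,
                        k_plus0 = 0.05, k_minus0 = 0,
                        gamma = 0.4, gamma_length = 1, tau_f = 0.1,
                        quantal_size = 1) {
  stopifnot(alpha > 0, N >= 0, N0 >= 0, k_plus1 >= 0, k_minus1 >= 0,
            k_plus0 >= 0, k_minus0 >= 0, gamma >= 0, tau_f > 0,
            quantal_size > 0)
  p <- 1 - exp(-alpha)
  stopifnot(p >= 0, p <= 1)
  structure(list(alpha = alpha, N = N, N0 = N0, k_plus1 = k_plus1,
                 k_minus1 = k_minus1, k_plus0 = k_plus0,
                 k_minus0 = k_minus0, gamma = gamma,
                 gamma_length = gamma_length, tau_f = tau_f,
                 quantal_size = quantal_size, model = 1L),
            class = c("stp_params1", "stp_params"))
}

#' Parameters of the two-pool heterogeneous-release model (model 2)
#'
#' As model 1, plus a small pool `N2` of release-ready vesicles with high
#' release probability `p_vr2`, refilled at rate `k2` from the larger pool
#' `N1` (low probability `p_vr1`), which in turn is refilled from the supply
#' pool. When `p_vr1` is `NULL` it is derived from `alpha` as
#' `1 - exp(-alpha)`; model semantics require `p_vr2 >= p_vr1`.
#'
#' @inheritParams stp_params1
#' @param N1 large low-probability pool capacity.
#' @param N2 small high-probability pool capacity.
#' @param p_vr1 base release probability of `N1` (`NULL`: from `alpha`).
#' @param p_vr2 base release probability of `N2`.
#' @param k2 refill rate of `N2` from `N1` (1/s).
#' @export
stp_params2 <- function(alpha = 0.3, N1 = 500, N2 = 80, N0 = 3000,
                        p_vr1 = NULL, p_vr2 = 0.8, k2 = 15,
                        k_plus1 = 10, k_minus1 = 1,
                        k_plus0 = 0.05, k_minus0 = 0,
                        gamma = 0.4, gamma_length = 1, tau_f = 0.1,
                        quantal_size = 1) {
  p1 <- if (is.null(p_vr1)) 1 - exp(-alpha) else p_vr1
  stopifnot(alpha > 0, N1 >= 0, N2 >= 0, N0 >= 0, k2 >= 0,
            p_vr2 >= 0, p_vr2 <= 1, p1 >= 0, p1 <= 1,
            k_plus1 >= 0, k_minus1 >= 0, k_plus0 >= 0, k_minus0 >= 0,
            gamma >= 0, tau_f > 0, quantal_size > 0)
  if (p_vr2 < p1)
    stop("model 2 semantics: p_vr2 (small pool) must be >= p_vr1")
  structure(list(alpha = alpha, N1 = N1, N2 = N2, N0 = N0,
                 p_vr1 = p_vr1, p_vr2 = p_vr2, k2 = k2,
                 k_plus1 = k_plus1, k_minus1 = k_minus1,
                 k_plus0 = k_plus0, k_minus0 = k_minus0,
                 gamma = gamma, gamma_length = gamma_length, tau_f = tau_f,
                 quantal_size = quantal_size, model = 2L),
            class = c("stp_params2", "stp_params"))
}

#' Stimulation protocol
#'
#' @param n_pulses pulses in the high-frequency train (default 100).
#' @param frequency train frequency in Hz (default 60).
#' @param recovery_intervals_ms intervals after the train at which recovery
#'   is probed (ms).
#' @param paired_pulse_intervals_ms paired-pulse inter-stimulus intervals
#'   (ms).
#' @export
stimulus_protocol <- function(n_pulses = 100, frequency = 60,
                              recovery_intervals_ms = c(
                                25, 50, 100, 200, 500, 1000, 2000, 5000,
                                10000, 20000, 50000, 100000),
                              paired_pulse_intervals_ms = c(
                                10, 30, 100, 300, 1000)) {
  stopifnot(n_pulses >= 1, frequency > 0,
            all(diff(recovery_intervals_ms) > 0),
            all(recovery_intervals_ms > 0))
  structure(list(n_pulses = n_pulses, frequency = frequency,
                 recovery_intervals_ms = recovery_intervals_ms,
                 paired_pulse_intervals_ms = paired_pulse_intervals_ms),
            class = "stimulus_protocol")
}

#' Facilitated release probability
#'
#' Residual-facilitation model: every preceding stimulus deposits one unit
#' of facilitation that decays exponentially with `tau_f`; the release
#' probability at time t is
#' `clamp(p_base * (1 + gamma_eff * F(t)), 0, 1)` with
#' `p_base = 1 - exp(-alpha)` and the dimensionless gain
#' `gamma_eff = gamma * gamma_length`. `gamma = 0` gives a constant
#' probability. The mapping from the calcium-scale facilitation parameter to
#' the gain is isolated here so an alternative biophysical form can be
#' swapped in.
#'
#' @param alpha release-probability parameter.
#' @param gamma facilitation parameter (1/um).
#' @param stimulus_times times of preceding stimuli (s).
#' @param t evaluation time (s).
#' @param tau_f facilitation decay constant (s).
#' @param gamma_length gain length scale (um).
#' @return release probability in \[0, 1\].
#' @export
facilitated_pvr <- function(alpha, gamma, stimulus_times, t, tau_f = 0.1,
                            gamma_length = 1) {
  stopifnot(alpha > 0, gamma >= 0)
  p_base <- 1 - exp(-alpha)
  prev <- stimulus_times[stimulus_times < t]
  f <- sum(exp(-(t - prev) / tau_f))
  min(1, max(0, p_base * (1 + gamma * gamma_length * f)))
}

# one exponential-Euler macro step of length dt for model 1/2 state
# state: list(n1, n0[, n2]); params p; returns updated state
step_pools <- function(state, p, dt) {
  if (dt <= 0) return(state)
  two <- p$model == 2L
  Ncap <- if (two) p$N1 else p$N
  # substep scale: external exchange and supply drain are the slow modes
  slow <- p$k_plus0 + p$k_minus0 +
    (if (p$N0 > 0) p$k_plus1 * Ncap / p$N0 else 0) +
    (if (two && p$N1 > 0) p$k2 * p$N2 / p$N1 else 0)
  nsub <- max(1L, min(200L, ceiling(dt * slow / 0.2)))
  h <- dt / nsub
  n1 <- state$n1; n0 <- state$n0; n2 <- if (two) state$n2 else 0
  for (s in seq_len(nsub)) {
    u0 <- if (p$N0 > 0) n0 / p$N0 else 1
    # tentative n2 update (uses start-of-substep n1)
    dn2 <- 0
    if (two && p$N2 > 0) {
      u1 <- if (p$N1 > 0) n1 / p$N1 else 0
      b2 <- p$k2 * u1
      dn2 <- if (b2 > 0) (p$N2 - n2) * (1 - exp(-b2 * h)) else 0
    }
    # tentative n1 update: linear ODE with frozen u0 and frozen n2-drain
    drain2 <- if (two && p$N1 > 0) p$k2 * max(p$N2 - n2, 0) / p$N1 else 0
    a <- p$k_plus1 * u0 * Ncap
    b <- p$k_plus1 * u0 + p$k_minus1 + drain2
    dn1 <- if (b > 0) (a / b - n1) * (1 - exp(-b * h)) else a * h
    # a frozen-occupancy substep may ask for more vesicles than the supply
    # holds; net uptake is capped at the available supply (refill stalls as
    # the supply empties)
    uptake <- dn1 + dn2
    if (uptake > n0 && uptake > 0) {
      scale <- n0 / uptake
      dn1 <- dn1 * scale
      dn2 <- dn2 * scale
    }
    n1 <- n1 + dn1
    n2 <- n2 + dn2
    # supply: conservation-consistent transfer, then external exchange
    n0 <- n0 - (dn1 + dn2)
    e <- p$k_plus0 + p$k_minus0
    if (e > 0) {
      c0 <- p$k_plus0 * p$N0
      n0 <- c0 / e + (n0 - c0 / e) * exp(-e * h)
    }
    if (n1 < -1e-9 || n0 < -1e-9 || n2 < -1e-9)
      stop("integration failure: negative pool occupancy")
    n1 <- max(n1, 0); n0 <- max(n0, 0); if (two) n2 <- max(n2, 0)
  }
  out <- list(n1 = n1, n0 = n0)
  if (two) out$n2 <- n2
  out
}

# deterministic mean-field simulation shared by both models
simulate_stp_engine <- function(p, protocol, reset_facilitation = TRUE) {
  two <- p$model == 2L
  p1b <- if (two && !is.null(p$p_vr1)) p$p_vr1 else 1 - exp(-p$alpha)
  p2b <- if (two) p$p_vr2 else NA_real_
  if (two && p2b < p1b)
    stop("model 2 semantics: p_vr2 must be >= p_vr1")
  gain <- p$gamma * p$gamma_length
  dt_train <- 1 / protocol$frequency
  n_p <- protocol$n_pulses
  state <- list(n1 = if (two) p$N1 else p$N, n0 = p$N0)
  if (two) state$n2 <- p$N2
  times <- (seq_len(n_p) - 1L) * dt_train
  amps <- numeric(n_p)
  fac <- 0 # residual facilitation just before the current pulse
  for (i in seq_len(n_p)) {
    p1 <- min(1, max(0, p1b * (1 + gain * fac)))
    rel <- p1 * state$n1
    amp <- rel
    state$n1 <- state$n1 - rel
    if (two) {
      p2 <- min(1, max(0, p2b * (1 + gain * fac)))
      rel2 <- p2 * state$n2
      amp <- amp + rel2
      state$n2 <- state$n2 - rel2
    }
    amps[i] <- p$quantal_size * amp
    if (i < n_p) {
      state <- step_pools(state, p, dt_train)
      fac <- (fac + 1) * exp(-dt_train / p$tau_f)
    }
  }
  # recovery: independent single-pulse probes of the post-train state
  rec_s <- protocol$recovery_intervals_ms / 1000
  rec_amp <- numeric(length(rec_s))
  st <- state
  fac_end <- fac + 1 # facilitation immediately after the last train pulse
  t_prev <- 0
  for (j in seq_along(rec_s)) {
    st <- step_pools(st, p, rec_s[j] - t_prev)
    t_prev <- rec_s[j]
    fprobe <- if (reset_facilitation) 0 else
      fac_end * exp(-rec_s[j] / p$tau_f)
    p1 <- min(1, max(0, p1b * (1 + gain * fprobe)))
    a <- p1 * st$n1
    if (two) {
      p2 <- min(1, max(0, p2b * (1 + gain * fprobe)))
      a <- a + p2 * st$n2
    }
    rec_amp[j] <- p$quantal_size * a
  }
  df <- data.frame(
    time = c(times, times[n_p] + rec_s),
    amplitude = c(amps, rec_amp),
    phase = c(rep("train", n_p), rep("recovery", length(rec_s))))
  structure(df, class = c("epsc_train", "data.frame"),
            params = p, protocol = protocol)
}

#' Simulate an evoked-current train with recovery (model 1)
#'
#' Deterministic mean-field simulation: at each pulse the released fraction
#' of the pool sets the amplitude (quantal size x vesicles released);
#' between pulses the pools relax by the two-compartment refill kinetics.
#' Recovery amplitudes are independent single-pulse probes of the post-train
#' state at the protocol's intervals; by default the probe release
#' probability has facilitation reset to baseline while pool occupancies
#' carry over.
#'
#' @param params an [stp_params1()].
#' @param protocol a [stimulus_protocol()].
#' @param reset_facilitation reset facilitation for recovery probes?
#' @return an `epsc_train` data frame: `time` (s), `amplitude`, `phase`.
#' @export
simulate_model1 <- function(params, protocol = stimulus_protocol(),
                            reset_facilitation = TRUE) {
  stopifnot(inherits(params, "stp_params1"))
  simulate_stp_engine(params, protocol, reset_facilitation)
}

#' Simulate an evoked-current train with recovery (model 2)
#' @param params an [stp_params2()].
#' @inheritParams simulate_model1
#' @export
simulate_model2 <- function(params, protocol = stimulus_protocol(),
                            reset_facilitation = TRUE) {
  stopifnot(inherits(params, "stp_params2"))
  simulate_stp_engine(params, protocol, reset_facilitation)
}

#' Simulate either model
#' @param params an [stp_params1()] or [stp_params2()].
#' @inheritParams simulate_model1
#' @export
simulate_stp <- function(params, protocol = stimulus_protocol(),
                         reset_facilitation = TRUE) {
  simulate_stp_engine(params, protocol, reset_facilitation)
}

#' @export
print.epsc_train <- function(x, ...) {
  tr <- x$amplitude[x$phase == "train"]
  cat(sprintf(
    "EPSC train: %d pulses (first %.3g, steady-state %.3g), %d recovery probes\n",
    length(tr), tr[1], mean(utils::tail(tr, 10)),
    sum(x$phase == "recovery")))
  invisible(x)
}

#' @export
plot.epsc_train <- function(x, ...) {
  graphics::plot(x$time, x$amplitude, type = "b", pch = 16, cex = 0.5,
                 log = "x", xlab = "time (s)", ylab = "amplitude", ...)
  invisible(x)
}

#' Fit the three free model parameters to train + recovery data
#'
#' Least squares over the concatenated train and recovery amplitudes with
#' free parameters alpha, the releasable pool capacity (N for model 1, N1
#' for model 2) and the refill rate k_plus1; all other parameters are fixed
#' at their configured values. Optimization is Nelder-Mead on log-scale
#' parameters with a polishing restart; uncertainties come from the
#' finite-difference Hessian of the residual sum of squares.
#'
#' @param data an `epsc_train`, or a list of sweeps (amplitudes averaged
#'   pointwise before fitting).
#' @param model 1 or 2.
#' @param fixed an [stp_params1()] / [stp_params2()] providing the fixed
#'   parameters (and fallback starting values).
#' @param start optional named starting values for `alpha`, `N`/`N1`,
#'   `k_plus1`.
#' @param protocol the protocol the data were recorded with (defaults to the
#'   protocol attribute of `data`).
#' @param reltol Nelder-Mead relative tolerance (default 1e-14; loosen for
#'   noisy data where the optimum is shallow).
#' @param restarts polishing restarts from the previous optimum (default 1).
#' @return an `stp_fit`: `coefficients`, `se`, `sse`, `convergence`,
#'   fitted params object, and the data used.
#' @export
fit_train <- function(data, model = 1, fixed = NULL, start = NULL,
                      protocol = NULL, reltol = 1e-14, restarts = 1) {
  if (is.list(data) && !is.data.frame(data)) {
    amp <- rowMeans(vapply(data, function(d) d$amplitude,
                           numeric(nrow(data[[1]]))))
    tmpl <- data[[1]]
    tmpl$amplitude <- amp
    data <- tmpl
  }
  if (is.null(protocol)) protocol <- attr(data, "protocol")
  if (is.null(protocol)) stop("no protocol available for the fit")
  if (is.null(fixed))
    fixed <- if (model == 1) stp_params1() else stp_params2()
  pool_name <- if (model == 1) "N" else "N1"
  obs <- data$amplitude
  make_params <- function(th) {
    p <- fixed
    p$alpha <- th[1]
    p[[pool_name]] <- th[2]
    p$k_plus1 <- th[3]
    p
  }
  objective <- function(lth) {
    th <- exp(lth)
    sim <- tryCatch(simulate_stp_engine(make_params(th), protocol),
                    error = function(e) NULL)
    if (is.null(sim)) return(1e12)
    sum((obs - sim$amplitude)^2)
  }
  th0 <- c(alpha = fixed$alpha, pool = fixed[[pool_name]],
           k_plus1 = max(fixed$k_plus1, 1e-3))
  if (!is.null(start)) {
    nm <- c("alpha", pool_name, "k_plus1")
    for (i in seq_along(nm)) if (nm[i] %in% names(start))
      th0[i] <- start[[nm[i]]]
  }
  opt <- stats::optim(log(th0), objective, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = reltol))
  for (r in seq_len(restarts))
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = reltol))
  th <- exp(opt$par)
  names(th) <- c("alpha", pool_name, "k_plus1")
  # finite-difference Hessian of SSE in log space -> delta-method s.e.
  n <- length(obs)
  sse <- opt$value
  g <- length(th)
  H <- matrix(0, g, g)
  eps <- 1e-4
  f0 <- opt$value
  for (i in seq_len(g)) for (j in i:g) {
    ei <- ej <- rep(0, g); ei[i] <- eps; ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (objective(opt$par + ei + ej) - objective(opt$par + ei) -
         objective(opt$par + ej) + f0) / eps^2
  }
  se <- rep(NA_real_, g)
  cov <- tryCatch({
    s2 <- sse / max(n - g, 1)
    V <- 2 * s2 * solve(H)
    dg <- diag(V)
    ok <- is.finite(dg) & dg >= 0
    se[ok] <- sqrt(dg[ok]) * th[ok] # log-scale delta method
    se
  }, error = function(e) se)
  structure(list(coefficients = th, se = cov, sse = sse,
                 convergence = opt$convergence, params = make_params(th),
                 model = model, data = data, protocol = protocol),
            class = "stp_fit")
}

#' @export
coef.stp_fit <- function(object, ...) object$coefficients

#' @export
print.stp_fit <- function(x, ...) {
  cat(sprintf("STP model %d fit (SSE %.4g%s)\n", x$model, x$sse,
              if (x$convergence != 0) ", NOT CONVERGED" else ""))
  cf <- x$coefficients
  for (i in seq_along(cf))
    cat(sprintf("  %-8s %.4g +/- %.3g\n", names(cf)[i], cf[i], x$se[i]))
  invisible(x)
}

#' @export
predict.stp_fit <- function(object, protocol = object$protocol, ...) {
  simulate_stp_engine(object$params, protocol)
}

#' @export
residuals.stp_fit <- function(object, ...) {
  object$data$amplitude - predict(object)$amplitude
}

#' @export
plot.stp_fit <- function(x, ...) {
  graphics::plot(x$data$time, x$data$amplitude, pch = 16, cex = 0.5,
                 log = "x", xlab = "time (s)", ylab = "amplitude", ...)
  sim <- predict(x)
  graphics::lines(sim$time, sim$amplitude, col = "red3")
  invisible(x)
}

#' Synthesize a continuous two-pulse current trace
#'
#' Difference-of-exponentials kernel (peak normalized to 1) placed at each
#' stimulus time and scaled by the given amplitudes; used to exercise the
#' paired-pulse measurement rule on overlapping responses.
#'
#' @param stim_times stimulus times (s).
#' @param amplitudes response amplitudes.
#' @param tau_rise,tau_decay kernel time constants (s).
#' @param dt sample interval (s).
#' @param duration trace length (s).
#' @return an `epsc_trace`: data frame with `t` and `y`.
#' @export
epsc_trace <- function(stim_times, amplitudes, tau_rise = 0.001,
                       tau_decay = 0.008, dt = 1e-4,
                       duration = max(stim_times) + 10 * tau_decay) {
  t <- seq(0, duration, by = dt)
  y <- numeric(length(t))
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  for (i in seq_along(stim_times)) {
    u <- t - stim_times[i]
    k <- ifelse(u >= 0, (exp(-u / tau_decay) - exp(-u / tau_rise)) / peak, 0)
    y <- y + amplitudes[i] * k
  }
  structure(data.frame(t = t, y = y), class = c("epsc_trace", "data.frame"),
            stim_times = stim_times)
}

#' Paired-pulse ratio with tail extrapolation
#'
#' The first amplitude is its peak over baseline; the second amplitude is
#' measured from its peak down to the mono-exponential extrapolation of the
#' first response's decaying tail (fitted between the first peak and the
#' second stimulus), which corrects for the overlap at short intervals.
#'
#' @param trace an [epsc_trace()] (or data frame with `t`, `y`).
#' @param stim_times the two stimulus times (s); defaults to the trace
#'   attribute.
#' @return list with `ratio`, `A1`, `A2`.
#' @export
measure_paired_pulse <- function(trace, stim_times = attr(trace,
                                                          "stim_times")) {
  if (is.null(stim_times) || length(stim_times) < 2)
    stop("two stimulus times required")
  t <- trace$t; y <- trace$y
  t1 <- stim_times[1]; t2 <- stim_times[2]
  w1 <- which(t >= t1 & t < t2)
  if (!length(w1)) stop("no identifiable first response")
  i1 <- w1[which.max(y[w1])]
  A1 <- y[i1]
  if (A1 <= 0) stop("no identifiable peaks")
  # mono-exponential fit to the decaying tail of response 1, skipping the
  # rise-contaminated region just after the peak
  tail_idx <- which(t > t[i1] & t < t2 & y > 0.02 * A1)
  tail_idx <- tail_idx[y[tail_idx] < 0.75 * A1]
  w2 <- which(t >= t2 & t <= t2 + (t2 - t1) + 0.05)
  i2 <- w2[which.max(y[w2])]
  if (length(tail_idx) >= 5) {
    fit <- stats::lm(log(y[tail_idx]) ~ t[tail_idx])
    base2 <- exp(unname(stats::coef(fit)[1] + stats::coef(fit)[2] * t[i2]))
  } else {
    base2 <- 0 # responses do not overlap measurably
  }
  A2 <- y[i2] - base2
  list(ratio = A2 / A1, A1 = A1, A2 = unname(A2))
}

#' Release sites per active zone
#'
#' The model prediction of the releasable pool (average of the two models'
#' `N`) divided by the number of active zones on the recorded muscle (taken
#' as `muscle6_fraction` of the AZ count of the whole NMJ).
#'
#' @param N_model1,N_model2 fitted pool capacities.
#' @param az_count_nmj Brp-positive AZ count of the NMJ.
#' @param muscle6_fraction fraction of AZs on the recorded muscle
#'   (default 0.5).
#' @export
vesicles_per_az <- function(N_model1, N_model2, az_count_nmj,
                            muscle6_fraction = 0.5) {
  if (az_count_nmj <= 0) stop("AZ count must be positive")
  mean(c(N_model1, N_model2)) / (az_count_nmj * muscle6_fraction)
}
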