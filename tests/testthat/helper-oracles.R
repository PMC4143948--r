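# Independent oracles used across the suite. These deliberately use naive
# O(n^2) / recursive / stochastic formulations so they share no code path
# with the implementations they check.

# brute-force pairwise density
brute_density <- function(xy, eps, count_self = FALSE) {
  n <- nrow(xy)
  out <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    out[i] <- sum(d2 <= eps^2) - (!count_self)
  }
  out
}

# recursive reference implementation of the density-gradient expansion
brute_expand <- function(xy, dens, centres, eps, k) {
  n <- nrow(xy)
  assignment <- integer(n)
  nb <- function(i) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    setdiff(which(d2 <= eps^2), i)
  }
  for (ci in order(-dens[centres], centres)) {
    c0 <- centres[ci]
    if (assignment[c0] != 0L) next
    assignment[c0] <- ci
    grow <- function(i) {
      for (j in nb(i)) {
        if (assignment[j] != 0L || dens[j] >= dens[i]) next
        assignment[j] <<- ci
        if (dens[j] > k) grow(j)
      }
    }
    # process in decreasing discoverer-density order: recursion from the
    # centre visits highest-density frontier first when neighbours sorted
    grow(c0)
  }
  assignment
}

# per-vesicle stochastic simulator for model 1 (large supply regime)
stochastic_model1 <- function(params, n_pulses, dt, n_trials = 10000) {
  p_rel <- 1 - exp(-params$alpha)
  N <- params$N
  q_ref <- 1 - exp(-params$k_plus1 * dt) # supply occupancy ~ 1
  occ <- matrix(TRUE, n_trials, N)
  amps <- numeric(n_pulses)
  for (i in seq_len(n_pulses)) {
    rel <- occ & matrix(stats::runif(n_trials * N) < p_rel, n_trials, N)
    amps[i] <- mean(rowSums(rel)) * params$quantal_size
    occ <- occ & !rel
    refill <- matrix(stats::runif(n_trials * N) < q_ref, n_trials, N)
    occ <- occ | (!occ & refill)
  }
  amps
}

# analytic application of the paired-pulse measurement rule to a known
# superposition of difference-of-exponential responses
analytic_paired_pulse <- function(A1, A2, t1, t2, tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  kern <- function(u) ifelse(u >= 0,
                             (exp(-u / tau_decay) - exp(-u / tau_rise)) / peak,
                             0)
  f <- function(t) A1 * kern(t - t1) + A2 * kern(t - t2)
  g1 <- stats::optimize(f, c(t1, t2), maximum = TRUE)
  g2 <- stats::optimize(f, c(t2, t2 + (t2 - t1) + 5 * tau_decay),
                        maximum = TRUE)
  meas2 <- g2$objective - A1 * kern(g2$maximum - t1)
  meas2 / g1$objective
}

expt_labeling <- function() labeling_model(secondary_sat_d0 = 0.225)

# study conditions for the clustering-recovery experiments: localization-
# level planting with resolvable clusters
recovery_priors <- function(locs_per_cluster = 52)
  caz_truth_priors(unclustered_mode = "localizations",
                   locs_per_cluster = locs_per_cluster,
                   cluster_min_sep = 60, placement_radius = 150,
                   unclustered_radius = 200)
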