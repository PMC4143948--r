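test_that("facilitation obeys its closed form and limits", {
  # gamma = 0: constant baseline probability
  p0 <- vapply(c(0.001, 0.05, 1), function(t)
    facilitated_pvr(0.6, 0, c(0), t), numeric(1))
  expect_true(all(p0 == 1 - exp(-0.6)))
  # one preceding pulse decays back to baseline
  expect_equal(facilitated_pvr(0.6, 0.4, 0, 1e4),
               1 - exp(-0.6), tolerance = 1e-12)
  # two pulses 16.7 ms apart: F = exp(-16.7/tau) exactly
  tau <- 0.1
  expected <- min(1, (1 - exp(-0.6)) * (1 + 0.4 * exp(-0.0167 / tau)))
  expect_equal(facilitated_pvr(0.6, 0.4, 0, 0.0167, tau_f = tau), expected)
  expect_gt(facilitated_pvr(0.6, 0.4, 0, 0.0167), 1 - exp(-0.6))
})

test_that("simulation limits: instant refill and pure depletion", {
  inst <- stp_params1(alpha = 0.6, N = 500, N0 = 1e8, k_plus1 = 1e6,
                      k_minus1 = 0, k_plus0 = 0, k_minus0 = 0, gamma = 0)
  tr <- simulate_model1(inst)
  a <- tr$amplitude[tr$phase == "train"]
  expect_equal(a, rep(500 * (1 - exp(-0.6)), 100), tolerance = 1e-5)
  dep <- stp_params1(alpha = 50, N = 500, k_plus1 = 0, k_minus1 = 0,
                     k_plus0 = 0, k_minus0 = 0, gamma = 0)
  trd <- simulate_model1(dep)
  ad <- trd$amplitude[trd$phase == "train"]
  expect_equal(ad[1], 500, tolerance = 1e-8)
  expect_lt(max(ad[-1]), 1e-6)
})

test_that("steady-state train amplitude matches the analytic balance", {
  # gamma = 0, large supply: release at steady state equals refill between
  # pulses: p*n1 = (N - n1)(1 - exp(-k dt)) with n1 the pre-pulse occupancy
  p <- stp_params1(alpha = 0.3, N = 400, N0 = 1e8, k_plus1 = 6,
                   k_minus1 = 0, k_plus0 = 0, k_minus0 = 0, gamma = 0)
  tr <- simulate_model1(p)
  a <- tr$amplitude[tr$phase == "train"]
  ss <- mean(a[91:100])
  pv <- 1 - exp(-0.3)
  dt <- 1 / 60
  q <- 1 - exp(-6 * dt)
  # fixed point: n_pre = (1-pv) n_pre + (N - (1-pv) n_pre) q
  n_pre <- 400 * q / (1 - (1 - pv) * (1 - q))
  expect_equal(ss, pv * n_pre, tolerance = 1e-3)
})

test_that("pool stepping agrees with a stiff ODE solver", {
  skip_if_not_installed("deSolve")
  p <- stp_params1(gamma = 0)
  rhs <- function(t, s, q) {
    u0 <- s[2] / q$N0
    J <- q$k_plus1 * u0 * (q$N - s[1]) - q$k_minus1 * s[1]
    list(c(J, -J + q$k_plus0 * (q$N0 - s[2]) - q$k_minus0 * s[2]))
  }
  st <- c(300, 2000)
  for (dt in c(1 / 60, 0.5, 5, 60)) {
    mine <- cazquant:::step_pools(list(n1 = st[1], n0 = st[2]), p, dt)
    ode <- deSolve::lsoda(st, c(0, dt), rhs, p,
                          rtol = 1e-10, atol = 1e-10)[2, 2:3]
    expect_lt(max(abs(c(mine$n1, mine$n0) - ode) / ode), 2e-3)
  }
})

test_that("closed systems conserve vesicles and occupancies stay in range", {
  set.seed(61)
  for (rep in 1:6) {
    p <- stp_params1(alpha = runif(1, 0.2, 1.5), N = sample(100:800, 1),
                     N0 = sample(1000:5000, 1), k_plus1 = runif(1, 1, 40),
                     k_minus1 = runif(1, 0, 3), k_plus0 = 0, k_minus0 = 0,
                     gamma = runif(1, 0, 0.6))
    proto <- stimulus_protocol(n_pulses = 30)
    tr <- simulate_model1(p, proto)
    released <- sum(tr$amplitude[tr$phase == "train"]) / p$quantal_size
    # reconstruct final pool contents by replaying the engine state
    st <- list(n1 = p$N, n0 = p$N0)
    fac <- 0
    for (i in 1:30) {
      pv <- min(1, (1 - exp(-p$alpha)) * (1 + p$gamma * fac))
      st$n1 <- st$n1 - pv * st$n1
      if (i < 30) {
        st <- cazquant:::step_pools(st, p, 1 / 60)
        fac <- (fac + 1) * exp(-(1 / 60) / p$tau_f)
      }
    }
    expect_equal(st$n1 + st$n0 + released, p$N + p$N0, tolerance = 1e-6)
    expect_true(all(tr$amplitude >= 0))
    expect_true(st$n1 <= p$N + 1e-9 && st$n0 <= p$N0 + 1e-9)
  }
})

test_that("recovery amplitudes are non-decreasing without facilitation", {
  p <- stp_params1(gamma = 0)
  tr <- simulate_model1(p)
  rec <- tr$amplitude[tr$phase == "recovery"]
  expect_true(all(diff(rec) >= -1e-9))
  p2 <- stp_params2(gamma = 0)
  tr2 <- simulate_model2(p2)
  rec2 <- tr2$amplitude[tr2$phase == "recovery"]
  expect_true(all(diff(rec2) >= -1e-9))
})

test_that("mean-field model 1 matches the per-vesicle stochastic oracle", {
  set.seed(62)
  p <- stp_params1(alpha = 0.5, N = 300, N0 = 1e9, k_plus1 = 8,
                   k_minus1 = 0, k_plus0 = 0, k_minus0 = 0, gamma = 0)
  proto <- stimulus_protocol(n_pulses = 10, recovery_intervals_ms = c(25))
  det <- simulate_model1(p, proto)
  det_a <- det$amplitude[det$phase == "train"]
  sto <- stochastic_model1(p, n_pulses = 10, dt = 1 / 60, n_trials = 10000)
  expect_true(all(abs(det_a - sto) / sto < 0.02))
})

test_that("noiseless self-fit recovers the generating parameters exactly", {
  truth <- stp_params1(alpha = 0.8, N = 420, k_plus1 = 14)
  dat <- simulate_model1(truth)
  fit <- fit_train(dat, model = 1, fixed = stp_params1())
  expect_lt(max(abs(coef(fit) - c(0.8, 420, 14)) / c(0.8, 420, 14)), 1e-4)
  expect_equal(fit$convergence, 0)
  expect_lt(fit$sse, 1e-10)
})

test_that("three parameters are recovered from noisy sweeps within 15%", {
  truth <- stp_params1(alpha = 0.8, N = 420, k_plus1 = 14)
  errs <- vapply(1:12, function(s) {
    sw <- generate_stp_dataset(truth, noise_cv = 0.1, n_sweeps = 10,
                               seed = 600 + s)
    fit <- fit_train(sw, model = 1, fixed = stp_params1(), reltol = 1e-10,
                     restarts = 0)
    max(abs(coef(fit) - c(0.8, 420, 14)) / c(0.8, 420, 14))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
})

test_that("model 2 data are fitted better by model 2 than by model 1", {
  d2 <- simulate_model2(stp_params2())
  f1 <- fit_train(d2, model = 1, fixed = stp_params1(), reltol = 1e-10,
                  restarts = 0)
  f2 <- fit_train(d2, model = 2, fixed = stp_params2(), reltol = 1e-10,
                  restarts = 0)
  expect_lt(f2$sse, f1$sse)
})

test_that("paired-pulse measurement matches the analytic superposition rule", {
  # non-overlapping responses: plain amplitude ratios
  tr <- epsc_trace(c(0.02, 0.4), c(1, 1))
  expect_equal(measure_paired_pulse(tr)$ratio, 1, tolerance = 1e-3)
  tr2 <- epsc_trace(c(0.02, 0.4), c(1, 0.5))
  expect_equal(measure_paired_pulse(tr2)$ratio, 0.5, tolerance = 1e-3)
  # overlapping at 10 and 30 ms: compare with the analytic application of
  # the same peak-minus-extrapolated-tail rule
  for (iv in c(0.01, 0.03)) for (a2 in c(0.4, 0.8)) {
    tr3 <- epsc_trace(c(0.02, 0.02 + iv), c(1, a2))
    got <- measure_paired_pulse(tr3)$ratio
    want <- analytic_paired_pulse(1, a2, 0.02, 0.02 + iv, 0.001, 0.008)
    expect_lt(abs(got - want) / want, 0.02)
  }
  flat <- structure(data.frame(t = seq(0, 1, 1e-3), y = 0),
                    stim_times = c(0.1, 0.2))
  expect_error(measure_paired_pulse(flat), "peak")
})

test_that("release sites per AZ is the two-model average per muscle-6 AZ", {
  expect_equal(vesicles_per_az(600, 600, 480), 2.5)
  expect_equal(vesicles_per_az(0, 0, 480), 0)
  expect_error(vesicles_per_az(600, 600, 0), "positive")
  # round trip: planted per-AZ pool of 3 on 236 AZs -> N = 354
  truth <- stp_params1(alpha = 0.8, N = 3 * 236 * 0.5, k_plus1 = 14)
  dat <- simulate_model1(truth)
  fit <- fit_train(dat, model = 1, fixed = stp_params1(), reltol = 1e-10,
                   restarts = 0)
  expect_equal(vesicles_per_az(coef(fit)[["N"]], coef(fit)[["N"]], 236),
               3, tolerance = 0.01)
})

test_that("invalid model-2 probability ordering is rejected", {
  expect_error(stp_params2(p_vr1 = 0.9, p_vr2 = 0.5), "p_vr2")
})
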