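test_that("empty tables segment to no regions", {
  tab <- loc_table(numeric(0), numeric(0), field = c(2000, 2000))
  img <- render(tab, 10)
  regs <- segment_caz(img, tab)
  expect_length(regs, 0L)
})

test_that("a planted unit segments as one region with consistent counts", {
  g <- generate_caz_field(1, labeling = expt_labeling(),
                          primary_dilution = 5e-4, seed = 33)
  img <- render(g$table, 10)
  regs <- segment_caz(img, g$table)
  expect_length(regs, 1L)
  r <- regs[[1]]
  # the region count equals the localizations whose pixel lies in the
  # footprint (ground-truth bookkeeping, checked independently)
  lab <- attr(regs, "label_matrix")
  px <- floor(g$table$x / 10) + 1L
  py <- floor(g$table$y / 10) + 1L
  inside <- lab[cbind(py, px)] == 1L
  expect_equal(r$localization_count, sum(inside))
  expect_equal(r$area_um2, length(r$pixels) * 100 / 1e6)
  # and captures the bulk of the planted unit content
  expect_gt(r$localization_count, 0.75 * g$truth[[1]]$n_localizations)
})

test_that("two well-separated units give two independent regions", {
  g <- generate_caz_field(2, labeling = expt_labeling(),
                          primary_dilution = 5e-4, unit_spacing = 2000,
                          seed = 34)
  img <- render(g$table, 10)
  regs <- segment_caz(img, g$table)
  expect_length(regs, 2L)
  counts <- sort(vapply(regs, function(r) r$localization_count, numeric(1)))
  planted <- sort(vapply(g$truth, function(t) t$n_localizations, numeric(1)))
  expect_true(all(counts > 0.7 * planted))
})

test_that("region counts and background partition the table", {
  g <- generate_caz_field(3, labeling = expt_labeling(),
                          primary_dilution = 5e-4, seed = 35)
  img <- render(g$table, 10)
  regs <- segment_caz(img, g$table)
  bg <- background_density(g$table, regs)
  expect_equal(sum(vapply(regs, function(r) r$localization_count,
                          numeric(1))) + bg$n_outside,
               nrow(g$table))
})

test_that("uniform background density is estimated without bias", {
  set.seed(36)
  area <- 16 # 4 x 4 um
  n <- rpois(1, 78 * area)
  tab <- loc_table(runif(n, 0, 4000), runif(n, 0, 4000),
                   field = c(4000, 4000))
  img <- render(tab, 10)
  regs <- segment_caz(img, tab)
  bg <- background_density(tab, regs)
  expect_lt(abs(bg$loc_density - 78), 3 * sqrt(78 / area))
  empty <- loc_table(numeric(0), numeric(0), field = c(4000, 4000))
  bg0 <- background_density(empty, segment_caz(render(empty, 10), empty))
  expect_equal(bg0$loc_density, 0)
})

test_that("background QC applies the 2.3 spots per um^2 exclusion rule", {
  expect_false(qc_background(2.4))
  expect_true(qc_background(2.2))
  expect_true(qc_background(2.3)) # excluded only when strictly above
})

test_that("raising the mask threshold never increases total region area", {
  g <- generate_caz_field(2, labeling = expt_labeling(),
                          primary_dilution = 5e-4, seed = 37)
  img <- render(g$table, 10)
  areas <- vapply(c(0.1, 0.15, 0.25, 0.4), function(th) {
    regs <- segment_caz(img, g$table, threshold = th, min_area_px = 1)
    sum(vapply(regs, function(r) r$area_um2, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-12))
})

test_that("precision spot selection applies size and ellipticity gates", {
  g <- generate_isolated_antibodies(
    60, acquisition_model(localization_sigma = 7, background_density = 0),
    locs_per_antibody = function(n) 12 + stats::rpois(n, 3), seed = 38)
  img <- render(g$table, 10)
  sel <- select_precision_spots(img, g$table)
  expect_gt(length(sel), 0)
  # every selected group sits inside one antibody's localization set
  for (s in sel) expect_equal(length(unique(g$groups[s])), 1L)
  # an elongated double antibody 40 nm apart fails the ellipticity gate
  set.seed(39)
  double <- loc_table(
    c(rnorm(60, 480, 7), rnorm(60, 520, 7)),
    c(rnorm(60, 500, 7), rnorm(60, 500, 7)), field = c(1000, 1000))
  sel2 <- select_precision_spots(render(double, 10), double)
  expect_length(sel2, 0L)
  # an area just above the upper gate is rejected: dense wide blob
  set.seed(40)
  big <- loc_table(runif(600, 400, 620), runif(600, 400, 620),
                   field = c(1000, 1000))
  imgb <- render(big, 10)
  comp <- select_precision_spots(imgb, big, size_range = c(16, 100))
  expect_length(comp, 0L)
})

test_that("histogram precision estimator is unbiased within 5% across sigma", {
  for (s in c(3, 7.16, 15)) {
    est <- vapply(1:4, function(seed) {
      g <- generate_isolated_antibodies(
        800, acquisition_model(localization_sigma = s,
                               background_density = 0),
        locs_per_antibody = function(n) 12 + stats::rpois(n, 3),
        seed = seed)
      img <- render(g$table, 10)
      e <- estimate_precision(select_precision_spots(img, g$table), g$table)
      expect_true(e$sigma_x <= e$sigma & e$sigma <= e$sigma_y ||
                    e$sigma_y <= e$sigma & e$sigma <= e$sigma_x)
      e$sigma
    }, numeric(1))
    expect_lt(abs(mean(est) - s) / s, 0.05)
  }
  expect_error(estimate_precision(list(1:3), min_groups = 10), "at least")
})

test_that("NeNA recovers sigma and flags tables without repeats", {
  g <- generate_isolated_antibodies(
    800, acquisition_model(localization_sigma = 7, background_density = 0),
    locs_per_antibody = function(n) 12 + stats::rpois(n, 3), seed = 43)
  ne <- estimate_precision_nena(g$table)
  expect_equal(ne$flag, "ok")
  expect_lt(abs(ne$sigma - 7), 1)
  # cross-method consistency on the same data
  img <- render(g$table, 10)
  hist_est <- estimate_precision(select_precision_spots(img, g$table),
                                 g$table)
  expect_lt(abs(ne$sigma - hist_est$sigma) / hist_est$sigma, 0.15)
  # spatially random table: no frame-adjacent short-range correlation,
  # reported as an error or a flagged/NA estimate
  set.seed(44)
  rnd <- loc_table(runif(3000, 0, 20000), runif(3000, 0, 20000),
                   frame = sample(1500, 3000, replace = TRUE),
                   field = c(20000, 20000))
  out <- tryCatch(estimate_precision_nena(rnd), error = function(e) e)
  expect_true(inherits(out, "error") || is.na(out$sigma) ||
                out$flag != "ok")
  noframe <- loc_table(1:5, 1:5)
  expect_error(estimate_precision_nena(noframe), "frame")
})

test_that("spot counting finds separated maxima and merges shallow ones", {
  m <- matrix(0, 120, 120)
  for (i in 0:4) for (j in 0:4) {
    cx <- 12 + 24 * i; cy <- 12 + 24 * j
    for (a in -5:5) for (b in -5:5)
      m[cy + a, cx + b] <- m[cy + a, cx + b] +
        100 * exp(-(a^2 + b^2) / (2 * 2^2))
  }
  expect_equal(count_spots(m, blur_sigma = 0.9, threshold = 5,
                           prominence = 10), 25L)
  expect_equal(count_spots(matrix(0, 50, 50), threshold = 5,
                           prominence = 10), 0L)
  # two spots closer than the blur merge into one counted maximum
  m2 <- matrix(0, 60, 60)
  for (a in -6:6) for (b in -6:6) {
    m2[30 + a, 28 + b] <- m2[30 + a, 28 + b] + 100 * exp(-(a^2 + b^2) / 8)
    m2[30 + a, 31 + b] <- m2[30 + a, 31 + b] + 90 * exp(-(a^2 + b^2) / 8)
  }
  expect_equal(count_spots(m2, blur_sigma = 2, threshold = 5,
                           prominence = 30), 1L)
})
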