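# Helper: minimal synthetic spectrum built from explicit Lorentzian lines.
lorentz_spectrum <- function(lines, noise_sigma = 0.5, seed = 1,
                             n_points = 2^15, lo = -1, hi = 11,
                             linewidth_hz = 0.9, field = 600.13) {
  ppm <- seq(hi, lo, length.out = n_points)
  hw <- linewidth_hz / field / 2
  y <- numeric(n_points)
  for (ln in lines) {
    y <- y + ln$h * hw^2 / ((ppm - ln$d)^2 + hw^2)
  }
  set.seed(seed)
  y <- y + rnorm(n_points, 0, noise_sigma)
  shiftnav:::new_spectrum(ppm, y, list(
    n_points = n_points, field_mhz = field, linewidth_hz = linewidth_hz,
    spectral_width_hz = (hi - lo) * field, noise_sigma = noise_sigma))
}

test_that("peak picking finds isolated and resolved lines, not noise", {
  sp <- lorentz_spectrum(list(list(d = 3.0, h = 500),
                              list(d = 3.005, h = 400)))
  # noise-only window: empty
  expect_equal(nrow(pick_peaks(sp, c(5, 6))), 0)
  # two singlets > 3 linewidths apart: two peaks at the right places
  pk <- pick_peaks(sp, c(2.9, 3.1), snr_threshold = 20)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$position[1] - 3.0), 2e-4)
  expect_lt(abs(pk$position[2] - 3.005), 2e-4)
  expect_lt(abs(pk$width_hz[1] - 0.9), 0.3)
  # window validation
  expect_error(pick_peaks(sp, c(10, 12)), "outside spectrum")
})

test_that("peak detection is invariant to uniform intensity rescaling", {
  sp <- lorentz_spectrum(list(list(d = 3.0, h = 500)))
  sp10 <- sp; sp10$intensity <- sp$intensity * 10
  expect_equal(pick_peaks(sp, c(2.9, 3.1))$position,
               pick_peaks(sp10, c(2.9, 3.1))$position)
})

test_that("citrate finder applies J and intensity-ratio criteria", {
  j_ppm <- 15.9 / 600.13
  mk <- function(centers, heights, js = rep(15.9, length(centers))) {
    lines <- list()
    for (i in seq_along(centers)) {
      o <- js[i] / 600.13 / 2
      lines <- c(lines, list(list(d = centers[i] - o, h = heights[i]),
                             list(d = centers[i] + o, h = heights[i] * 0.9)))
    }
    lines
  }
  sp <- lorentz_spectrum(mk(c(2.545, 2.655), c(800, 820)), seed = 2)
  pk <- pick_peaks(sp, c(2.47, 2.73))
  cit <- find_citrate(pk, list(c(2.49, 2.60), c(2.61, 2.71)))
  expect_equal(cit, c(2.545, 2.655), tolerance = 1e-3)

  # only singlets: no pair satisfies the J criterion
  sp_s <- lorentz_spectrum(list(list(d = 2.53, h = 700),
                                list(d = 2.65, h = 650)), seed = 3)
  expect_error(
    find_citrate(pick_peaks(sp_s, c(2.47, 2.73)),
                 list(c(2.49, 2.60), c(2.61, 2.71))),
    "citrate navigators not found")

  # decoy doublet with J off by 5 Hz loses to the true pair
  sp_d <- lorentz_spectrum(
    mk(c(2.545, 2.555, 2.655), c(800, 900, 820), js = c(15.9, 20.9, 15.9)),
    seed = 4)
  cit2 <- find_citrate(pick_peaks(sp_d, c(2.47, 2.73)),
                       list(c(2.49, 2.60), c(2.61, 2.71)))
  expect_equal(cit2[1], 2.545, tolerance = 1e-3)
})

test_that("creatinine finder uses the 3:2 ratio and dominance", {
  p1 <- data.frame(position = c(3.02, 3.05), height = c(3000, 90),
                   width_hz = 0.9)
  p2 <- data.frame(position = 4.06, height = 2000, width_hz = 0.9)
  expect_equal(find_creatinine(p1, p2), c(3.02, 4.06))

  # empty second window
  expect_error(find_creatinine(p1, p2[0, ]), "creatinine navigators")

  # a 10x-height decoy fails the ratio test
  decoy <- data.frame(position = 3.03, height = 20000, width_hz = 0.9)
  expect_equal(find_creatinine(rbind(decoy, p1), p2), c(3.02, 4.06))

  # no consistent pair at all
  expect_error(find_creatinine(decoy, p2), "creatinine navigators")
})

test_that("glycine is located through the auxiliary model", {
  bundle <- fx_bundle_small()
  ts <- fx_train_small()
  nav_ids <- unname(bundle$navigator_ids)
  # in-sample: prediction error within a few CV RMSE for most samples
  SH <- as.matrix(ts$shifts[, nav_ids])
  pred <- vapply(seq_len(25), function(k) {
    predict_glycine_shift(bundle$glycine_model, SH[k, 1:2], SH[k, 3:4])
  }, numeric(1))
  err <- abs(pred - SH[1:25, 5])
  expect_lt(stats::median(err), bundle$glycine_model$fit_stats$rmse_cv * 2)

  # empty glycine window aborts with the manual-entry instruction
  panel <- fx_panel()
  row <- fx_holdout()$concentrations[3, ]
  row$glycine <- 0
  sp <- render_spectrum(panel, fx_responses(), row, seed = 17)
  expect_error(find_navigators(sp, panel, bundle), "manual")
})

test_that("automatic navigator assignment matches ground truth", {
  bundle <- fx_bundle_small()
  panel <- fx_panel(); resp <- fx_responses()
  hold <- fx_holdout()
  truth <- fx_truth_shifts(hold)
  nav_ids <- unname(bundle$navigator_ids)
  lw <- default_linewidth_ppm
  for (k in 1:6) {
    sp <- render_spectrum(panel, resp, hold$concentrations[k, ],
                          seed = 300 + k)
    ns <- find_navigators(sp, panel, bundle)
    expect_equal(ns$provenance, "auto")
    got <- c(ns$citrate_dd1, ns$citrate_dd2, ns$creatinine_s1,
             ns$creatinine_s2, ns$glycine_s)
    expect_true(all(abs(got - truth[k, nav_ids]) < 0.5 * lw),
                label = sprintf("sample %d navigators within half linewidth",
                                k))
  }
})

test_that("manual navigator entry validates against the panel windows", {
  bundle <- fx_bundle_small()
  sp <- fx_spectrum()
  vals <- c(2.55, 2.66, 3.04, 4.06, 3.56)
  ns <- find_navigators(sp, fx_panel(), bundle, mode = "manual",
                        manual_values = vals)
  expect_equal(ns$provenance, "manual")
  expect_equal(ns$citrate_dd1, 2.55)
  expect_error(
    find_navigators(sp, fx_panel(), bundle, mode = "manual",
                    manual_values = c(2.55, 2.66, 3.04, 4.06, 3.80)),
    "outside window")
  expect_error(
    find_navigators(sp, fx_panel(), bundle, mode = "manual",
                    manual_values = c(2.55, 2.66)),
    "5 values")
})

test_that("a spectrum without citrate stops the analysis", {
  panel <- fx_panel()
  row <- fx_holdout()$concentrations[4, ]
  row$citrate <- 0
  sp <- render_spectrum(panel, fx_responses(), row, seed = 23)
  err <- tryCatch(find_navigators(sp, panel, fx_bundle_small()),
                  error = function(e) conditionMessage(e))
  expect_match(err, "citrate")
  expect_match(err, "cannot proceed")
  expect_match(err, "manual")
})

test_that("navigators are recovered on a batch of seeded spectra", {
  # sustained zero-misassignment check on 200 rendered spectra
  panel <- fx_panel(); resp <- fx_responses()
  bundle <- fx_bundle_small()
  hold <- build_test_set(panel, resp, 200, seed = 20200)
  truth <- fx_truth_shifts(hold)
  nav_ids <- unname(bundle$navigator_ids)
  lw <- default_linewidth_ppm
  worst <- 0
  for (k in seq_len(200)) {
    sp <- render_spectrum(panel, resp, hold$concentrations[k, ],
                          seed = 40000 + k)
    ns <- find_navigators(sp, panel, bundle)
    got <- c(ns$citrate_dd1, ns$citrate_dd2, ns$creatinine_s1,
             ns$creatinine_s2, ns$glycine_s)
    worst <- max(worst, max(abs(got - truth[k, nav_ids])))
  }
  expect_lt(worst, 0.5 * lw)
})
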