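test_that("concentration sampling respects ranges, schemes and seeds", {
  panel <- fx_panel()
  comp <- panel$components

  # degenerate case: n = 0 keeps the full column set
  m0 <- sample_concentrations(panel, 0, seed = 1)
  expect_equal(nrow(m0), 0)
  expect_equal(names(m0), c("sample_id", comp$name, "pH", "T"))

  for (scheme in c("latin_hypercube", "uniform_random", "dilution_lhs")) {
    m <- sample_concentrations(panel, 60, scheme = scheme, seed = 3)
    for (j in seq_len(nrow(comp))) {
      v <- m[[comp$name[j]]]
      expect_true(all(v >= comp$conc_min[j] & v <= comp$conc_max[j]),
                  label = paste(scheme, comp$name[j], "in range"))
    }
    expect_true(all(m$pH >= 6.4 & m$pH <= 7.6))
    expect_true(all(m$T >= 300 & m$T <= 302.7))
    m2 <- sample_concentrations(panel, 60, scheme = scheme, seed = 3)
    expect_identical(m, m2)
  }
  expect_error(sample_concentrations(panel, -1), "n must be")
})

test_that("Latin hypercube stratification is exact: one sample per bin", {
  panel <- fx_panel()
  m <- sample_concentrations(panel, 100, scheme = "latin_hypercube",
                             seed = 11)
  for (nm in c(panel$components$name, "pH")) {
    lo <- if (nm == "pH") 6.4 else
      panel$components$conc_min[panel$components$name == nm]
    hi <- if (nm == "pH") 7.6 else
      panel$components$conc_max[panel$components$name == nm]
    bins <- findInterval((m[[nm]] - lo) / (hi - lo),
                         seq(0, 1, by = 0.01), rightmost.closed = TRUE)
    expect_equal(sort(unique(bins)), 1:100,
                 label = paste("decile occupancy of", nm))
  }
})

test_that("LHS marginals are uniform (Kolmogorov-Smirnov, alpha = 0.01)", {
  panel <- fx_panel()
  m <- sample_concentrations(panel, 150, scheme = "latin_hypercube",
                             seed = 21)
  for (nm in c(panel$components$name[c(1, 5, 9)], "pH")) {
    lo <- if (nm == "pH") 6.4 else
      panel$components$conc_min[panel$components$name == nm]
    hi <- if (nm == "pH") 7.6 else
      panel$components$conc_max[panel$components$name == nm]
    p <- suppressWarnings(
      stats::ks.test((m[[nm]] - lo) / (hi - lo), "punif")$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("dilution scheme couples solutes through a shared factor", {
  m <- sample_concentrations(fx_panel(), 200, scheme = "dilution_lhs",
                             seed = 5)
  r <- cor(log(m$creatinine), log(m[["Na+"]]))
  expect_gt(r, 0.7)
  # pH stays independent of the dilution factor
  expect_lt(abs(cor(log(m$creatinine), m$pH)), 0.2)
})

test_that("true_shift evaluates the fast-exchange response model", {
  r <- list(spin_system_id = "x", delta_free = 3.5,
            modulators = list(list(component = "A", amplitude = 0.01,
                                   half_saturation = 1000)),
            ph_term = list(delta_acid_shift = 0.05, pKa_eff = 6.5),
            temp_coeff = 1e-3)

  # all terms vanish: C = 0, pH >> pKa, T = 300
  expect_equal(true_shift(r, c(A = 0, pH = 20, T = 300)), 3.5,
               tolerance = 1e-12)
  # saturation limit: C -> infinity adds the full amplitude
  expect_equal(true_shift(r, c(A = 1e12, pH = 20, T = 300)), 3.51,
               tolerance = 1e-9)
  # half-saturation: C = K adds a/2
  expect_equal(true_shift(r, c(A = 1000, pH = 20, T = 300)), 3.505,
               tolerance = 1e-9)
  # acid limit adds delta_acid; temperature term is linear
  expect_equal(true_shift(r, c(A = 0, pH = -10, T = 300)), 3.55,
               tolerance = 1e-9)
  expect_equal(true_shift(r, c(A = 0, pH = 20, T = 302.7)), 3.5027,
               tolerance = 1e-12)

  expect_error(true_shift(r, c(pH = 7, T = 300)), "missing modulator.*A")
  expect_warning(true_shift(r, c(A = 0, pH = 20, T = 300),
                            window = c(3.6, 3.7)), "outside window")
})

test_that("responses are monotone in each modulator concentration", {
  resp <- fx_responses()
  panel <- fx_panel()
  base <- sample_concentrations(panel, 1, seed = 9)
  for (id in names(resp)[c(1, 3, 6, 10)]) {
    r <- resp[[id]]
    for (m in r$modulators) {
      cmax <- panel$components$conc_max[panel$components$name == m$component]
      grid <- seq(0, cmax, length.out = 9)
      vals <- vapply(grid, function(cc) {
        row <- base; row[[m$component]] <- cc
        true_shift(r, row[-1])
      }, numeric(1))
      d <- diff(vals)
      expect_true(all(d >= 0) || all(d <= 0),
                  label = paste(id, "monotone in", m$component))
      expect_equal(unique(sign(d[abs(d) > 0])), sign(m$amplitude),
                   label = paste(id, "direction matches amplitude sign"))
    }
  }
})

test_that("training sets honour the two-temperature design", {
  panel <- fx_panel(); resp <- fx_responses()
  ts <- build_training_set(panel, resp, 100, frac_second_temp = 0.2,
                           seed = 31)
  expect_equal(nrow(ts$concentrations), 120)
  expect_equal(sum(ts$concentrations$T == 302.7), 20)
  dup <- grepl("_T2$", ts$concentrations$sample_id)
  expect_equal(sum(dup), 20)
  base_ids <- sub("_T2$", "", ts$concentrations$sample_id[dup])
  for (nm in c("creatinine", "Na+")) {
    expect_equal(
      ts$concentrations[[nm]][dup],
      ts$concentrations[[nm]][match(base_ids, ts$concentrations$sample_id)])
  }
  # default mirrors the 726/3775 re-acquisition ratio
  expect_equal(eval(formals(build_training_set)$frac_second_temp),
               726 / 3775)
  expect_error(build_training_set(panel, resp, 10, shift_noise_sigma = -1),
               "sigma")
  # determinism
  ts2 <- build_training_set(panel, resp, 100, frac_second_temp = 0.2,
                            seed = 31)
  expect_identical(ts, ts2)
})

test_that("zero-noise shift matrices equal the exact response surface", {
  panel <- fx_panel(); resp <- fx_responses()
  ts <- build_training_set(panel, resp, 25, shift_noise_sigma = 0, seed = 8)
  truth <- shiftnav:::true_shift_matrix(resp, ts$concentrations)
  for (id in names(resp)) {
    ok <- !is.na(ts$shifts[[id]])
    expect_equal(ts$shifts[[id]][ok], truth[ok, id], tolerance = 1e-12)
  }
  # every recorded shift lies inside its spin system's window
  ss <- panel$spin_systems
  for (i in seq_len(nrow(ss))) {
    v <- ts$shifts[[ss$id[i]]]
    expect_true(all(v[!is.na(v)] >= ss$window_lo[i] &
                      v[!is.na(v)] <= ss$window_hi[i]),
                label = paste("window containment of", ss$id[i]))
  }
})

test_that("passive metabolites are absent in part of the samples", {
  ts <- build_training_set(fx_panel(), fx_responses(), 200, seed = 13)
  frac <- mean(ts$concentrations$creatine > 0)
  expect_gt(frac, 0.5); expect_lt(frac, 0.9)
  expect_identical(is.na(ts$shifts$crt_h2), ts$concentrations$creatine == 0)
})

test_that("rendered spectra follow the acquisition defaults", {
  sp <- fx_spectrum()
  expect_equal(length(sp$ppm), 65536L)
  expect_equal(sp$meta$spectral_width_hz, 12019)
  expect_equal(sp$meta$field_mhz, 600.13)
  expect_true(all(diff(sp$ppm) < 0))          # descending ppm axis
  # TSP reference maximum within +-0.001 ppm of 0
  near0 <- abs(sp$ppm) < 0.05
  expect_lt(abs(sp$ppm[near0][which.max(sp$intensity[near0])]), 0.001)
})

test_that("an empty mixture renders noise plus TSP only", {
  panel <- fx_panel()
  row <- sample_concentrations(panel, 1, seed = 2)
  row[, panel$components$name] <- 0
  sp <- render_spectrum(panel, fx_responses(), row, seed = 5)
  off <- abs(sp$ppm) > 0.5
  expect_lte(max(sp$intensity[off]), 5.5 * sp$meta$noise_sigma)
})

test_that("noise-free peak apexes match true shifts within 1/4 grid step", {
  panel <- fx_panel(); resp <- fx_responses()
  row <- fx_holdout()$concentrations[2, ]
  acq <- acq_params(noise_sigma = 0)
  sp <- render_spectrum(panel, resp, row, acq = acq, seed = 1)
  step <- abs(sp$ppm[1] - sp$ppm[2])
  ss <- panel$spin_systems
  for (id in c("tmao_h1", "gly_h2", "cre_h3", "for_h1")) {
    i <- match(id, ss$id)
    truth <- true_shift(resp[[id]], row[-1])
    pk <- pick_peaks(sp, c(ss$window_lo[i], ss$window_hi[i]),
                     snr_threshold = 0.001)
    expect_gt(nrow(pk), 0)
    expect_lt(min(abs(pk$position - truth)), step / 4)
  }
})

test_that("peak integrals are linear in concentration", {
  panel <- fx_panel(); resp <- fx_responses()
  row <- sample_concentrations(panel, 1, seed = 4)
  row2 <- row; row2$TMAO <- 2 * row$TMAO
  acq <- acq_params(noise_sigma = 0)
  sp1 <- render_spectrum(panel, resp, row, acq = acq)
  sp2 <- render_spectrum(panel, resp, row2, acq = acq)
  sel <- sp1$ppm > 3.22 & sp1$ppm < 3.32
  a1 <- sum(sp1$intensity[sel]); a2 <- sum(sp2$intensity[sel])
  expect_equal(a2 / a1, 2, tolerance = 0.01)
})

test_that("render_spectrum validates its inputs", {
  row <- sample_concentrations(fx_panel(), 1, seed = 2)
  expect_error(
    render_spectrum(fx_panel(), fx_responses(), row[, 1:4]),
    "lacks component|missing modulator")
  resp_missing <- fx_responses()[-1]
  class(resp_missing) <- "shift_responses"
  expect_error(render_spectrum(fx_panel(), resp_missing, row),
               "no response for spin system")
})

test_that("response sets are reproducible and persistent", {
  r1 <- shift_responses(fx_panel())
  r2 <- shift_responses(fx_panel())
  expect_identical(unclass(r1)[], unclass(r2)[])
  f <- tempfile(fileext = ".json")
  write_responses(r1, f)
  r3 <- read_responses(f)
  conc <- sample_concentrations(fx_panel(), 3, seed = 77)
  expect_identical(shiftnav:::true_shift_matrix(r1, conc),
                   shiftnav:::true_shift_matrix(r3, conc))
})
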