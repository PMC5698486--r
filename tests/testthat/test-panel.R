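test_that("the built-in demo panel satisfies the study conditions", {
  panel <- fx_panel()
  expect_s3_class(panel, "nmr_panel")
  expect_equal(panel$ph_range, c(6.4, 7.6))
  expect_setequal(panel$temp_levels_K, c(300.0, 302.7))
  expect_gte(nrow(panel$components), 12)
  expect_gte(sum(panel$components$role == "inorganic_ion"), 5)
  expect_true(all(c("citrate", "creatinine", "glycine", "histidine",
                    "TMAO") %in% panel$components$name))
  expect_true(all(c("Na+", "Cl-", "Ca2+", "Mg2+", "K+") %in%
                    panel$components$name))
  expect_equal(sum(panel$spin_systems$is_navigator), 5L)
  nav <- panel$spin_systems[panel$spin_systems$is_navigator, ]
  expect_equal(sum(nav$multiplicity == "dd"), 2L)
  expect_equal(sum(nav$multiplicity == "s"), 3L)
})

test_that("panel config round-trips field-for-field", {
  f <- tempfile(fileext = ".json")
  write_panel(fx_panel(), f)
  p2 <- load_panel(f)
  f2 <- tempfile(fileext = ".json")
  write_panel(p2, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_equal(p2$components, fx_panel()$components)
  expect_equal(p2$spin_systems, fx_panel()$spin_systems)
  expect_equal(p2$ph_range, fx_panel()$ph_range)
})

test_that("the shipped demo panel file equals the built-in panel", {
  f <- system.file("extdata", "demo_panel.json", package = "shiftnav")
  expect_true(nzchar(f))
  p <- load_panel(f)
  expect_equal(p$components, fx_panel()$components)
  expect_equal(p$spin_systems, fx_panel()$spin_systems)
})

test_that("TMAO singlet at 3.27 ppm is inside its search window", {
  ss <- fx_panel()$spin_systems
  tmao <- ss[ss$metabolite == "TMAO", ]
  expect_equal(tmao$delta_free, 3.27)
  expect_true(tmao$window_lo < 3.27 && 3.27 < tmao$window_hi)
})

test_that("panel validation rejects broken configurations", {
  p <- fx_panel()

  # omit glycine: navigator roster incomplete
  p1 <- p
  keep <- p1$components$name != "glycine"
  p1$components <- p1$components[keep, ]
  p1$spin_systems <- p1$spin_systems[p1$spin_systems$metabolite != "glycine", ]
  expect_error(validate_panel(p1), "navigator")

  # reference shift outside window
  p2 <- p
  p2$spin_systems$delta_free[1] <- p2$spin_systems$window_hi[1] + 1
  expect_error(validate_panel(p2), "delta_free outside window")

  # inverted concentration range, naming the component
  p3 <- p
  p3$components$conc_min[3] <- p3$components$conc_max[3] + 1
  expect_error(validate_panel(p3), p3$components$name[3], fixed = TRUE)

  # ion carrying a spin system
  p4 <- p
  i <- which(p4$components$role == "inorganic_ion")[1]
  p4$components$spin_systems[[i]] <- p4$spin_systems$id[1]
  expect_error(validate_panel(p4), "referenced by more than one|ion")

  # pH range outside the allowed band
  p5 <- p
  p5$ph_range <- c(4, 9)
  expect_error(validate_panel(p5), "ph_range")
})

test_that("load_panel reports missing files and schema violations", {
  expect_error(load_panel(tempfile()), "not found")
  f <- tempfile(fileext = ".json")
  writeLines('{"components": []}', f)
  expect_error(load_panel(f), "missing top-level field")
})
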