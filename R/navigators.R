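#' Peak picking in a spectral window
#'
#' Local maxima above `snr_threshold` times a robust noise estimate (median
#' absolute deviation of a signal-free region), with the apex refined by a
#' three-point parabola and the full width at half maximum measured by
#' linear interpolation of the half-height crossings.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param window `[ppm_lo, ppm_hi]` scan region (must lie inside the
#'   spectrum).
#' @param snr_threshold Minimum apex height in noise-sigma units.
#' @param noise_region Signal-free region used for the noise estimate.
#' @return Data frame with columns `position` (ppm), `height`, `width_hz`,
#'   sorted by ppm.
#' @export
pick_peaks <- function(spectrum, window, snr_threshold = 5,
                       noise_region = c(9.5, 10)) {
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  if (window[1] >= window[2]) stop("pick_peaks: window must be [lo, hi]")
  if (window[1] < min(ppm) || window[2] > max(ppm)) {
    stop("pick_peaks: window outside spectrum range")
  }
  nz <- y[ppm >= noise_region[1] & ppm <= noise_region[2]]
  sigma <- if (length(nz) > 10) stats::mad(nz) else stats::mad(y)
  if (sigma <= 0) sigma <- 1e-12

  idx <- which(ppm >= window[1] & ppm <= window[2])
  idx <- idx[idx > 1 & idx < length(ppm)]
  thr <- snr_threshold * sigma
  # apex must dominate a neighbourhood of about one linewidth, which
  # suppresses noise ripples riding on the tails of strong lines
  hz_per_pt <- abs(ppm[2] - ppm[1]) * (spectrum$meta$field_mhz %||% 600.13)
  k <- max(2L, as.integer(round((spectrum$meta$linewidth_hz %||% 1) /
                                  hz_per_pt)))
  out <- list()
  for (i in idx) {
    if (y[i] > thr && y[i] > y[i - 1] && y[i] >= y[i + 1] &&
        y[i] >= max(y[max(1, i - k):min(length(y), i + k)])) {
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      off <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
      off <- max(min(off, 0.5), -0.5)
      step <- ppm[i + 1] - ppm[i]              # negative (descending axis)
      pos <- ppm[i] + off * step
      height <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * off
      out[[length(out) + 1L]] <- c(pos, height, peak_fwhm_hz(spectrum, i))
    }
  }
  if (length(out) == 0) {
    return(data.frame(position = numeric(0), height = numeric(0),
                      width_hz = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("position", "height", "width_hz")
  df[order(df$position), , drop = FALSE]
}

# FWHM of the peak whose apex index is i, by half-height crossings.
peak_fwhm_hz <- function(spectrum, i) {
  ppm <- spectrum$ppm; y <- spectrum$intensity
  half <- y[i] / 2
  l <- i
  while (l > 1 && y[l - 1] > half && y[l - 1] < y[l]) l <- l - 1
  r <- i
  while (r < length(y) && y[r + 1] > half && y[r + 1] < y[r]) r <- r + 1
  interp <- function(a, b) {
    if (y[a] == y[b]) return(ppm[a])
    ppm[a] + (half - y[a]) * (ppm[b] - ppm[a]) / (y[b] - y[a])
  }
  lo <- if (l > 1) interp(l, l - 1) else ppm[l]
  hi <- if (r < length(y)) interp(r, r + 1) else ppm[r]
  abs(lo - hi) * spectrum$meta$field_mhz
}

#' Locate the two citrate doublet-of-doublets navigators
#'
#' Scans the picked peaks for two-line multiplets whose internal splitting
#' matches the expected J coupling within `j_tol_hz` and whose line
#' intensity ratio falls inside `ratio_range`; one multiplet centre must
#' fall in each of the two citrate windows. Among several candidates per
#' window, the pair whose splitting is closest to the expected J wins.
#'
#' @param peaks Peak table from the citrate scan region (see
#'   [pick_peaks()]).
#' @param windows List of two `[lo, hi]` windows (low-field and high-field
#'   citrate dd centre windows).
#' @param j_hz_expected Expected splitting in Hz.
#' @param j_tol_hz Tolerance on the splitting.
#' @param ratio_range Acceptable low/high line intensity ratio interval.
#' @param field_mhz Spectrometer frequency used to convert ppm to Hz.
#' @return Numeric vector of the two multiplet centres (ppm, ascending).
#' @export
find_citrate <- function(peaks, windows, j_hz_expected = 15.9,
                         j_tol_hz = 1.5, ratio_range = c(0.6, 1.4),
                         field_mhz = 600.13) {
  if (nrow(peaks) < 4) stop("citrate navigators not found (too few peaks)")
  cand <- list()
  for (i in seq_len(nrow(peaks) - 1)) {
    for (j in (i + 1):nrow(peaks)) {
      split_hz <- (peaks$position[j] - peaks$position[i]) * field_mhz
      if (abs(split_hz - j_hz_expected) > j_tol_hz) next
      ratio <- peaks$height[i] / peaks$height[j]
      if (ratio < ratio_range[1] || ratio > ratio_range[2]) next
      cand[[length(cand) + 1L]] <- c(
        center = mean(peaks$position[c(i, j)]),
        dev = abs(split_hz - j_hz_expected), i = i, j = j)
    }
  }
  if (length(cand) == 0) stop("citrate navigators not found")
  cand <- as.data.frame(do.call(rbind, cand))
  cand$hmin <- pmin(peaks$height[cand$i], peaks$height[cand$j])
  centers <- rep(NA_real_, 2)
  used <- integer(0)
  for (w in 1:2) {
    in_w <- cand[cand$center >= windows[[w]][1] &
                 cand$center <= windows[[w]][2] &
                 !(cand$i %in% used) & !(cand$j %in% used), , drop = FALSE]
    if (nrow(in_w) == 0) stop("citrate navigators not found")
    # discard implausibly weak pairs (noise ripples can match J by chance;
    # the citrate lines dominate their window), then take the pair whose
    # splitting is closest to the expected J
    in_w <- in_w[in_w$hmin >= 0.2 * max(in_w$hmin), , drop = FALSE]
    best <- in_w[which.min(in_w$dev), ]
    centers[w] <- best$center
    used <- c(used, best$i, best$j)
  }
  sort(centers)
}

#' Locate the two creatinine singlet navigators
#'
#' Selects the singlet pair (one peak per creatinine window) whose height
#' ratio matches the 3:2 proton-count expectation within a relative
#' tolerance; among ratio-consistent pairs the tallest pair wins (the
#' creatinine singlets dominate their windows).
#'
#' @param peaks_window1 Peak table of the 3-proton (methyl) window.
#' @param peaks_window2 Peak table of the 2-proton (methylene) window.
#' @param ratio_expected Expected height ratio window1/window2.
#' @param ratio_tol Relative tolerance on the ratio.
#' @return Numeric vector `(ppm_window1, ppm_window2)`.
#' @export
find_creatinine <- function(peaks_window1, peaks_window2,
                            ratio_expected = 1.5, ratio_tol = 0.35) {
  if (nrow(peaks_window1) == 0 || nrow(peaks_window2) == 0) {
    stop("creatinine navigators not found (empty window)")
  }
  best <- NULL
  for (i in seq_len(nrow(peaks_window1))) {
    for (j in seq_len(nrow(peaks_window2))) {
      r <- peaks_window1$height[i] / peaks_window2$height[j]
      dev <- abs(r / ratio_expected - 1)
      if (dev > ratio_tol) next
      h <- peaks_window1$height[i] + peaks_window2$height[j]
      # among ratio-consistent pairs take the dominant (tallest) one:
      # the creatinine singlets are by far the strongest lines in their
      # windows, while noise or overlap artifacts are weak
      if (is.null(best) || h > best$h) {
        best <- list(h = h, p1 = peaks_window1$position[i],
                     p2 = peaks_window2$position[j])
      }
    }
  }
  if (is.null(best)) stop("creatinine navigators not found")
  c(best$p1, best$p2)
}

#' Predict the glycine navigator shift from the other four navigators
#'
#' The glycine singlet carries no J-coupling or intensity-ratio constraint,
#' so its position is predicted by an auxiliary model trained on the
#' citrate and creatinine navigator shifts; the picked peak nearest this
#' prediction (within a tolerance) is taken downstream.
#'
#' @param glycine_model The auxiliary `mars_model` of a trained bundle.
#' @param citrate Numeric vector of the two citrate dd centres (ppm).
#' @param creatinine Numeric vector of the two creatinine singlets (ppm).
#' @return Predicted glycine shift in ppm.
#' @export
predict_glycine_shift <- function(glycine_model, citrate, creatinine) {
  x <- matrix(c(citrate, creatinine), nrow = 1)
  colnames(x) <- glycine_model$predictor_names
  predict(glycine_model, x)
}

#' Detect or validate the five navigator signals in a spectrum
#'
#' In automatic mode the citrate, creatinine and glycine finders are
#' composed; in manual mode user-supplied positions are validated against
#' the panel windows. If any navigator cannot be assigned the analysis
#' cannot proceed and the error instructs manual entry.
#'
#' @param spectrum A TSP-referenced `nmr_spectrum`.
#' @param panel A validated `nmr_panel`.
#' @param bundle A trained [train_bundle()] object (provides the glycine
#'   auxiliary model and detection defaults).
#' @param mode `"auto"` or `"manual"`.
#' @param manual_values Numeric vector of 5 ppm values (citrate dd low/high
#'   field, creatinine s low/high field, glycine s) for manual mode.
#' @param snr_threshold Peak detection threshold in noise-sigma units.
#' @return A list of class `navigator_set` with elements `citrate_dd1`,
#'   `citrate_dd2`, `creatinine_s1`, `creatinine_s2`, `glycine_s` (all
#'   ppm, fixed low-field-first ordering as listed) and `provenance`.
#' @export
find_navigators <- function(spectrum, panel, bundle,
                            mode = c("auto", "manual"),
                            manual_values = NULL, snr_threshold = 5) {
  mode <- match.arg(mode)
  ss <- panel$spin_systems
  nav <- ss[ss$is_navigator, , drop = FALSE]
  nav <- nav[order(nav$delta_free), ]
  cit <- nav[nav$multiplicity == "dd", , drop = FALSE]
  cre <- nav[nav$multiplicity == "s" &
               tolower(nav$metabolite) == "creatinine", , drop = FALSE]
  gly <- nav[tolower(nav$metabolite) == "glycine", , drop = FALSE]
  win <- function(row) c(row$window_lo, row$window_hi)

  if (mode == "manual") {
    if (length(manual_values) != 5) {
      stop("find_navigators: manual mode needs 5 values ",
           "(citrate dd1, dd2, creatinine s1, s2, glycine s)")
    }
    wins <- list(win(cit[1, ]), win(cit[2, ]), win(cre[1, ]), win(cre[2, ]),
                 win(gly[1, ]))
    for (k in 1:5) {
      if (manual_values[k] < wins[[k]][1] || manual_values[k] > wins[[k]][2]) {
        stop(sprintf(
          "find_navigators: manual value %.4f ppm outside window [%g, %g]",
          manual_values[k], wins[[k]][1], wins[[k]][2]))
      }
    }
    return(structure(list(citrate_dd1 = manual_values[1],
                          citrate_dd2 = manual_values[2],
                          creatinine_s1 = manual_values[3],
                          creatinine_s2 = manual_values[4],
                          glycine_s = manual_values[5],
                          provenance = "manual"), class = "navigator_set"))
  }

  fail <- function(what, e) {
    stop(what, " (", conditionMessage(e), "); the analysis cannot proceed - ",
         "re-run with mode = \"manual\" and manual_values = c(citrate_dd1, ",
         "citrate_dd2, creatinine_s1, creatinine_s2, glycine_s)",
         call. = FALSE)
  }
  field <- spectrum$meta$field_mhz
  lw_ppm <- (spectrum$meta$linewidth_hz %||% 1) / field
  j_exp <- cit$j_hz[[1]][1]
  pad <- j_exp / (2 * field) + 2 * lw_ppm
  scan <- c(min(cit$window_lo) - pad, max(cit$window_hi) + pad)

  cit_pos <- tryCatch({
    pk <- pick_peaks(spectrum, scan, snr_threshold)
    find_citrate(pk, list(win(cit[1, ]), win(cit[2, ])),
                 j_hz_expected = j_exp, field_mhz = field)
  }, error = function(e) fail("citrate navigator detection failed", e))

  cre_pos <- tryCatch({
    p1 <- pick_peaks(spectrum, win(cre[1, ]), snr_threshold)
    p2 <- pick_peaks(spectrum, win(cre[2, ]), snr_threshold)
    find_creatinine(p1, p2,
                    ratio_expected = cre$n_protons[1] / cre$n_protons[2])
  }, error = function(e) fail("creatinine navigator detection failed", e))

  gly_pos <- tryCatch({
    pk <- pick_peaks(spectrum, win(gly[1, ]), snr_threshold)
    if (nrow(pk) == 0) stop("no peaks in glycine window")
    pred <- predict_glycine_shift(bundle$glycine_model, cit_pos, cre_pos)
    tol <- max(3 * bundle$glycine_model$fit_stats$rmse_cv, 0.002)
    d <- abs(pk$position - pred)
    if (min(d) > tol) {
      stop(sprintf("glycine navigator not found within %.4f ppm of %.4f",
                   tol, pred))
    }
    pk$position[which.min(d)]
  }, error = function(e) fail("glycine navigator detection failed", e))

  structure(list(citrate_dd1 = cit_pos[1], citrate_dd2 = cit_pos[2],
                 creatinine_s1 = cre_pos[1], creatinine_s2 = cre_pos[2],
                 glycine_s = gly_pos, provenance = "auto"),
            class = "navigator_set")
}

#' @export
print.navigator_set <- function(x, ...) {
  cat(sprintf(paste0("Navigator signals (%s): citrate dd %.4f / %.4f, ",
                     "creatinine s %.4f / %.4f, glycine s %.4f ppm\n"),
              x$provenance, x$citrate_dd1, x$citrate_dd2,
              x$creatinine_s1, x$creatinine_s2, x$glycine_s))
  invisible(x)
}
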