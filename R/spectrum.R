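#' Acquisition parameters for the spectrum simulator
#'
#' Defaults follow standard urine 1H NMR practice on a 600 MHz instrument:
#' 65,536 data points over a 12,019 Hz spectral width, 600.13 MHz proton
#' frequency, an effective Lorentzian linewidth of 0.9 Hz (the 0.3 Hz
#' exponential line broadening applied during processing is folded into
#' this effective width rather than simulated as apodization), and a TSP
#' reference singlet at 0 ppm.
#'
#' Intensity units: one unit of peak height corresponds to a 1 uM x 1
#' proton line at the default linewidth, so a line's height is
#' `concentration * n_protons * line_fraction * (0.9 / linewidth_hz)` and
#' integrals scale linearly with concentration at fixed linewidth. The
#' default noise standard deviation of 5 units puts the detection limit
#' (SNR 3) near 15 uM-protons, a realistic urine figure.
#'
#' @param n_points Number of points of the digitised spectrum.
#' @param spectral_width_hz Spectral width in Hz.
#' @param field_mhz Proton Larmor frequency in MHz.
#' @param center_ppm Centre of the spectral window in ppm.
#' @param linewidth_hz Effective full width at half maximum of every line.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param roof_ratio Intensity ratio (weaker/stronger line) of the two-line
#'   doublet-of-doublets rendering, emulating the roof effect of the
#'   strongly coupled citrate AB system.
#' @param tsp_height Peak height of the TSP reference singlet.
#' @return A list of class `acq_params`.
#' @export
acq_params <- function(n_points = 65536L, spectral_width_hz = 12019,
                       field_mhz = 600.13, center_ppm = 4.7,
                       linewidth_hz = 0.9, noise_sigma = 5,
                       roof_ratio = 0.85, tsp_height = 5e4) {
  stopifnot(n_points > 16, spectral_width_hz > 0, field_mhz > 0,
            linewidth_hz > 0, noise_sigma >= 0,
            roof_ratio > 0, roof_ratio <= 1)
  structure(list(n_points = as.integer(n_points),
                 spectral_width_hz = spectral_width_hz,
                 field_mhz = field_mhz, center_ppm = center_ppm,
                 linewidth_hz = linewidth_hz, noise_sigma = noise_sigma,
                 roof_ratio = roof_ratio, tsp_height = tsp_height),
            class = "acq_params")
}

new_spectrum <- function(ppm, intensity, meta) {
  stopifnot(length(ppm) == length(intensity))
  structure(list(ppm = ppm, intensity = intensity, meta = meta),
            class = "nmr_spectrum")
}

# Multiplet line positions (ppm offsets from the centre) and area fractions.
# dd systems are rendered as two lines split by J, with the roof-effect
# ratio favouring the line nearer the coupling partner.
multiplet_lines <- function(mult, j_hz, field_mhz, roof_ratio = 1,
                            partner_side = 0) {
  if (mult == "s" || mult == "m" || length(j_hz) == 0) {
    return(list(offset = 0, frac = 1))
  }
  j_ppm <- j_hz[1] / field_mhz
  if (mult == "d") {
    list(offset = c(-j_ppm / 2, j_ppm / 2), frac = c(0.5, 0.5))
  } else if (mult == "dd") {
    w <- c(1, 1)
    if (partner_side > 0) w <- c(roof_ratio, 1)       # partner upfield->no;
    if (partner_side < 0) w <- c(1, roof_ratio)       # stronger inner line
    list(offset = c(-j_ppm / 2, j_ppm / 2), frac = w / sum(w))
  } else if (mult == "t") {
    list(offset = c(-j_ppm, 0, j_ppm), frac = c(0.25, 0.5, 0.25))
  } else {
    list(offset = 0, frac = 1)
  }
}

# Add one Lorentzian line to `intensity` in place (evaluated on a +-1.5 ppm
# neighbourhood; the omitted tail is < 1e-6 of the peak height).
add_lorentzian <- function(ppm, intensity, delta, height, width_ppm) {
  lo <- findInterval(-(delta + 1.5), -ppm) + 1L  # ppm is descending
  hi <- findInterval(-(delta - 1.5), -ppm)
  lo <- max(lo, 1L); hi <- min(hi, length(ppm))
  if (lo > hi) return(intensity)
  idx <- lo:hi
  hw <- width_ppm / 2
  intensity[idx] <- intensity[idx] +
    height * hw^2 / ((ppm[idx] - delta)^2 + hw^2)
  intensity
}

#' Render a 1D spectrum of one mixture
#'
#' Sums Lorentzian multiplets: every spin system of the panel is centred at
#' its ground-truth shift for the given concentration row, split according
#' to its multiplicity and coupling constants, with total area proportional
#' to concentration x number of protons. A TSP reference singlet is placed
#' at exactly 0 ppm and Gaussian noise is added.
#'
#' @param panel A validated `nmr_panel`.
#' @param responses A [shift_responses()] object.
#' @param concentration_row One row of a concentration matrix (data frame
#'   or named vector with all component columns, `pH`, `T`).
#' @param acq An [acq_params()] list.
#' @param seed Integer seed for the noise draw.
#' @return An `nmr_spectrum`: descending `ppm` axis, `intensity`, and
#'   acquisition metadata.
#' @export
render_spectrum <- function(panel, responses, concentration_row,
                            acq = acq_params(), seed = 1L) {
  if (is.data.frame(concentration_row)) {
    concentration_row <- as.list(concentration_row[1, , drop = FALSE])
  } else {
    concentration_row <- as.list(concentration_row)
  }
  conc <- lapply(concentration_row[setdiff(names(concentration_row),
                                           "sample_id")], as.numeric)
  ss <- panel$spin_systems
  missing_ss <- setdiff(ss$id, names(responses))
  if (length(missing_ss) > 0) {
    stop("render_spectrum: no response for spin system(s): ",
         paste(missing_ss, collapse = ", "))
  }
  sw_ppm <- acq$spectral_width_hz / acq$field_mhz
  ppm <- seq(acq$center_ppm + sw_ppm / 2, acq$center_ppm - sw_ppm / 2,
             length.out = acq$n_points)
  width_ppm <- acq$linewidth_hz / acq$field_mhz
  height_scale <- 0.9 / acq$linewidth_hz
  intensity <- numeric(acq$n_points)

  for (i in seq_len(nrow(ss))) {
    met <- ss$metabolite[i]
    if (is.null(conc[[met]])) {
      stop("render_spectrum: concentration row lacks component '", met,
           "' for spin system ", ss$id[i])
    }
    ci <- as.numeric(conc[[met]])
    if (ci <= 0) next
    delta <- true_shift(responses[[ss$id[i]]], conc,
                        window = c(ss$window_lo[i], ss$window_hi[i]))
    partner_side <- 0
    if (ss$multiplicity[i] == "dd") {
      sib <- which(ss$metabolite == met & ss$multiplicity == "dd" &
                     ss$id != ss$id[i])
      if (length(sib) == 1) {
        partner_side <- sign(ss$delta_free[sib] - ss$delta_free[i])
      }
    }
    ml <- multiplet_lines(ss$multiplicity[i], ss$j_hz[[i]], acq$field_mhz,
                          acq$roof_ratio, partner_side)
    for (k in seq_along(ml$offset)) {
      h <- ci * ss$n_protons[i] * ml$frac[k] * height_scale
      intensity <- add_lorentzian(ppm, intensity, delta + ml$offset[k], h,
                                  width_ppm)
    }
  }
  intensity <- add_lorentzian(ppm, intensity, 0, acq$tsp_height, width_ppm)
  if (acq$noise_sigma > 0) {
    intensity <- intensity + local_seed(seed,
      stats::rnorm(acq$n_points, 0, acq$noise_sigma))
  }
  tK <- if (!is.null(conc$T)) as.numeric(conc$T) else NA_real_
  new_spectrum(ppm, intensity, list(
    n_points = acq$n_points, spectral_width_hz = acq$spectral_width_hz,
    field_mhz = acq$field_mhz, temperature_K = tK,
    linewidth_hz = acq$linewidth_hz, noise_sigma = acq$noise_sigma,
    seed = seed))
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("1D NMR spectrum: %d points, %.1f to %.1f ppm, %.2f MHz\n",
              length(x$ppm), max(x$ppm), min(x$ppm),
              x$meta$field_mhz %||% NA))
  invisible(x)
}
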