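#' Sample a concentration matrix for a panel
#'
#' Draws `n` mixtures with every component inside its panel range, pH inside
#' the buffered pH range and temperature inside the panel's temperature
#' limits. Three schemes are available:
#'
#' * `"latin_hypercube"`: each column independently stratified into `n`
#'   equal-probability bins with exactly one sample per bin.
#' * `"uniform_random"`: independent uniform draws.
#' * `"dilution_lhs"` (the training default of [build_training_set()]): a
#'   Latin-hypercube draw in an underlying space consisting of one shared
#'   log-scale urinary dilution factor plus one residual factor per solute;
#'   `log c_j = log c_min,j + log(c_max,j / c_min,j) * (w * u_D + (1 - w) *
#'   u_j)` with dilution weight `w = dilution_weight`. This emulates the
#'   dominant hydration-status variation of real urine (osmolality spans
#'   more than an order of magnitude between dilute and concentrated
#'   samples), under which all solute concentrations rise and fall
#'   together; pH and T remain independent.
#'
#' @param panel A validated `nmr_panel`.
#' @param n Number of samples (>= 0).
#' @param scheme Sampling scheme (see above).
#' @param seed Integer seed; identical inputs give identical matrices.
#' @param dilution_weight Share `w` of the log-concentration excursion
#'   carried by the shared dilution factor under `"dilution_lhs"`.
#' @return A data frame with columns `sample_id`, one column per component
#'   (uM), `pH` and `T` (K).
#' @export
sample_concentrations <- function(panel, n,
                                  scheme = c("latin_hypercube",
                                             "uniform_random",
                                             "dilution_lhs"),
                                  seed = 1L, dilution_weight = 0.85) {
  scheme <- match.arg(scheme)
  validate_panel(panel)
  if (n < 0) stop("sample_concentrations: n must be >= 0")
  comp <- panel$components
  p <- nrow(comp)
  if (p == 0) stop("sample_concentrations: empty panel")
  cols <- c(comp$name, "pH", "T")
  t_lim <- range(panel$temp_levels_K)

  if (n == 0) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), length(cols))),
      c("sample_id", cols)), check.names = FALSE)
    return(out)
  }

  U <- local_seed(seed, switch(scheme,
    latin_hypercube = lhs::randomLHS(n, p + 2L),
    uniform_random = matrix(stats::runif(n * (p + 2L)), n, p + 2L),
    dilution_lhs = lhs::randomLHS(n, p + 3L)))

  if (scheme == "dilution_lhs") {
    w <- dilution_weight
    u_d <- U[, 1]
    vals <- vapply(seq_len(p), function(j) {
      u <- w * u_d + (1 - w) * U[, j + 1L]
      comp$conc_min[j] * (comp$conc_max[j] / comp$conc_min[j])^u
    }, numeric(n))
    ph <- panel$ph_range[1] + diff(panel$ph_range) * U[, p + 2L]
    tt <- t_lim[1] + diff(t_lim) * U[, p + 3L]
  } else {
    vals <- vapply(seq_len(p), function(j) {
      comp$conc_min[j] + (comp$conc_max[j] - comp$conc_min[j]) * U[, j]
    }, numeric(n))
    ph <- panel$ph_range[1] + diff(panel$ph_range) * U[, p + 1L]
    tt <- t_lim[1] + diff(t_lim) * U[, p + 2L]
  }
  vals <- matrix(vals, nrow = n)
  out <- data.frame(sample_id = sprintf("S%d-%05d", as.integer(seed),
                                        seq_len(n)),
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1] <- comp$name
  out$pH <- ph
  out$T <- tt
  out
}

#' Build a synthetic training set (concentration matrix + shift matrix)
#'
#' Samples `n_samples` mixtures at the first temperature level, duplicates a
#' random subset of `ceiling(frac_second_temp * n_samples)` rows at the
#' second temperature level (same concentrations, recomputed shifts) —
#' mirroring a design in which a minority of mixtures is re-acquired warm —
#' adds Gaussian shift-measurement noise, and blanks passive metabolites in
#' a random subset of samples (their concentration is set to 0 and their
#' shift entry to `NA`).
#'
#' @param panel A validated `nmr_panel`.
#' @param responses A [shift_responses()] object for the panel.
#' @param n_samples Number of base mixtures.
#' @param frac_second_temp Fraction of mixtures re-measured at the second
#'   temperature level (default mirrors 726/3775).
#' @param shift_noise_sigma Gaussian standard deviation of the shift
#'   measurement noise, ppm (default 5e-5: shifts recorded to the 5th
#'   decimal of ppm).
#' @param seed Integer seed.
#' @param scheme Concentration sampling scheme (see
#'   [sample_concentrations()]).
#' @param passive_presence Probability that a passive metabolite is present
#'   in a given sample.
#' @return A list of class `urine_training_set` with elements
#'   `concentrations` (data frame) and `shifts` (data frame, `sample_id` +
#'   one ppm column per spin system; `NA` where a passive metabolite is
#'   absent).
#' @export
build_training_set <- function(panel, responses, n_samples,
                               frac_second_temp = 726 / 3775,
                               shift_noise_sigma = 5e-5,
                               seed = 1L,
                               scheme = "dilution_lhs",
                               passive_presence = 0.7) {
  if (frac_second_temp < 0 || frac_second_temp > 1) {
    stop("build_training_set: frac_second_temp must be in [0, 1]")
  }
  if (shift_noise_sigma < 0) {
    stop("build_training_set: shift_noise_sigma must be >= 0")
  }
  conc <- sample_concentrations(panel, n_samples, scheme = scheme,
                                seed = seed)
  conc$T <- panel$temp_levels_K[1]
  conc <- mask_passives(conc, panel, passive_presence, seed = seed + 1L)

  n2 <- ceiling(frac_second_temp * n_samples)
  if (n2 > 0 && length(panel$temp_levels_K) > 1) {
    idx <- local_seed(seed + 2L, sample(n_samples, n2))
    dup <- conc[idx, , drop = FALSE]
    dup$T <- panel$temp_levels_K[2]
    dup$sample_id <- paste0(dup$sample_id, "_T2")
    conc <- rbind(conc, dup)
  }
  shifts <- shift_matrix_from_conc(panel, responses, conc,
                                   shift_noise_sigma, seed + 3L)
  structure(list(concentrations = conc, shifts = shifts,
                 meta = list(n_samples = n_samples,
                             frac_second_temp = frac_second_temp,
                             shift_noise_sigma = shift_noise_sigma,
                             seed = seed, scheme = scheme)),
            class = "urine_training_set")
}

#' Build a synthetic hold-out set with continuously random temperature
#'
#' Like [build_training_set()] but every mixture gets a temperature drawn
#' uniformly between the panel's temperature limits (the regime of an
#' independent test acquisition), and no second-temperature duplication.
#'
#' @inheritParams build_training_set
#' @param n Number of hold-out mixtures.
#' @return A list of class `urine_training_set`.
#' @export
build_test_set <- function(panel, responses, n, shift_noise_sigma = 5e-5,
                           seed = 2L, scheme = "dilution_lhs",
                           passive_presence = 0.7) {
  conc <- sample_concentrations(panel, n, scheme = scheme, seed = seed)
  conc <- mask_passives(conc, panel, passive_presence, seed = seed + 1L)
  shifts <- shift_matrix_from_conc(panel, responses, conc,
                                   shift_noise_sigma, seed + 3L)
  structure(list(concentrations = conc, shifts = shifts,
                 meta = list(n_samples = n,
                             shift_noise_sigma = shift_noise_sigma,
                             seed = seed, scheme = scheme)),
            class = "urine_training_set")
}

# Zero out passive metabolites in a random subset of rows.
mask_passives <- function(conc, panel, passive_presence, seed) {
  pas <- panel$components$name[panel$components$role == "passive_metabolite"]
  if (length(pas) == 0 || nrow(conc) == 0) return(conc)
  local_seed(seed, {
    for (nm in pas) {
      absent <- stats::runif(nrow(conc)) > passive_presence
      conc[[nm]][absent] <- 0
    }
  })
  conc
}

# Ground-truth shift matrix + measurement noise; NA for absent passives.
shift_matrix_from_conc <- function(panel, responses, conc,
                                   shift_noise_sigma, seed) {
  truth <- true_shift_matrix(responses, conc)
  if (shift_noise_sigma > 0 && nrow(truth) > 0) {
    truth <- truth + local_seed(seed,
      matrix(stats::rnorm(length(truth), 0, shift_noise_sigma),
             nrow(truth), ncol(truth)))
  }
  ss <- panel$spin_systems
  for (i in seq_len(nrow(ss))) {
    met <- ss$metabolite[i]
    if (!is.null(conc[[met]])) {
      truth[conc[[met]] <= 0, ss$id[i]] <- NA_real_
    }
  }
  data.frame(sample_id = conc$sample_id, truth, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' @export
print.urine_training_set <- function(x, ...) {
  cat("Synthetic urine set:", nrow(x$concentrations), "rows x",
      ncol(x$concentrations) - 1L, "columns;",
      ncol(x$shifts) - 1L, "spin-system shifts\n")
  invisible(x)
}
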