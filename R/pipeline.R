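#' Train the full and reduced model banks of the shift/concentration predictor
#'
#' Four MARS model banks are fitted from a training concentration matrix and
#' the matching shift matrix:
#'
#' * full shift models — one per spin system, predictors = the shifts of the
#'   other active-metabolite signals (the internal relationships within the
#'   shift matrix);
#' * reduced shift models — one per non-navigator spin system, predictors =
#'   the five navigator shifts;
#' * full concentration models — one per modelled component plus pH and T,
#'   predictors = all active-signal shifts (the inverse, concentration-from-
#'   shift relationship);
#' * reduced concentration models — same responses, predictors = the five
#'   navigator shifts;
#'
#' plus the auxiliary glycine model (glycine navigator shift from the four
#' citrate/creatinine navigator shifts). Every model is cross-validated and
#' its uncertainty is stored as rRMSE x response range (i.e. the CV RMSE in
#' response units).
#'
#' @param conc_matrix Concentration data frame (`sample_id`, components,
#'   `pH`, `T`), e.g. from [build_training_set()].
#' @param shift_matrix Shift data frame (`sample_id`, spin-system columns).
#' @param panel The `nmr_panel` the matrices refer to.
#' @param mars_config A [mars_control()]; the default (additive
#'   piecewise-linear basis, up to 21 terms) matches the near-additive
#'   structure of the signal-to-signal relations.
#' @param seed Integer seed (cross-validation fold assignment).
#' @param k_folds Cross-validation folds per model.
#' @param navigator_error Uncertainty (ppm) attached to directly observed
#'   navigator shifts.
#' @param extrapolation_factor Uncertainty inflation applied when navigator
#'   inputs fall outside the training hull.
#' @return A list of class `predictor_bundle`.
#' @export
train_bundle <- function(conc_matrix, shift_matrix, panel,
                         mars_config = mars_control(),
                         seed = 1L, k_folds = 10L,
                         navigator_error = 5e-5,
                         extrapolation_factor = 2) {
  validate_panel(panel)
  if (!identical(conc_matrix$sample_id, shift_matrix$sample_id)) {
    stop("train_bundle: concentration and shift matrices must share ",
         "sample ids (same order)")
  }
  n <- nrow(conc_matrix)
  need <- 10L * mars_config$max_terms
  if (n < need) {
    stop("train_bundle: insufficient samples: have ", n, ", need >= ", need,
         " (10 x max_terms)")
  }
  ss <- panel$spin_systems
  active <- active_signal_ids(panel)
  nav <- navigator_map(panel)
  nav_ids <- unname(nav)
  comps <- modelled_component_names(panel)
  targets <- c(comps, "pH", "T")
  SH <- as.matrix(shift_matrix[, ss$id, drop = FALSE])
  CM <- as.matrix(conc_matrix[, targets, drop = FALSE])

  midx <- 0L
  fit1 <- function(Xcols, y, name) {
    midx <<- midx + 1L
    ok <- stats::complete.cases(SH[, Xcols, drop = FALSE]) & !is.na(y)
    fit_mars_cv(SH[ok, Xcols, drop = FALSE], y[ok], mars_config,
                k_folds = k_folds, seed = seed + midx,
                response_name = name)
  }

  full_shift <- lapply(ss$id, function(id) {
    fit1(setdiff(active, id), SH[, id], id)
  })
  names(full_shift) <- ss$id
  reduced_shift <- lapply(setdiff(ss$id, nav_ids), function(id) {
    fit1(nav_ids, SH[, id], id)
  })
  names(reduced_shift) <- setdiff(ss$id, nav_ids)
  full_conc <- lapply(targets, function(tg) fit1(active, CM[, tg], tg))
  names(full_conc) <- targets
  reduced_conc <- lapply(targets, function(tg) fit1(nav_ids, CM[, tg], tg))
  names(reduced_conc) <- targets
  glycine_model <- fit1(setdiff(nav_ids, nav[["glycine_s"]]),
                        SH[, nav[["glycine_s"]]], "glycine_navigator")

  err_of <- function(m) max(m$fit_stats$rmse_cv, 1e-9)
  bundle <- structure(list(
    panel = panel,
    navigator_ids = nav,
    active_ids = active,
    full_shift_models = full_shift,
    reduced_shift_models = reduced_shift,
    full_conc_models = full_conc,
    reduced_conc_models = reduced_conc,
    glycine_model = glycine_model,
    shift_err_full = vapply(full_shift, err_of, numeric(1)),
    shift_err_reduced = c(
      vapply(reduced_shift, err_of, numeric(1)),
      stats::setNames(rep(navigator_error, length(nav_ids)), nav_ids)),
    conc_err_full = vapply(full_conc, err_of, numeric(1)),
    conc_err_reduced = vapply(reduced_conc, err_of, numeric(1)),
    navigator_error = navigator_error,
    extrapolation_factor = extrapolation_factor,
    provenance = list(n = n, seed = seed, k_folds = k_folds,
                      mars_config = unclass(mars_config),
                      sample_ids = conc_matrix$sample_id,
                      config_hash = config_hash(list(unclass(mars_config),
                                                     seed, k_folds, n)))),
    class = "predictor_bundle")
  bundle
}

# Canonical navigator role -> spin system id map (low-field first).
navigator_map <- function(panel) {
  ss <- panel$spin_systems
  nav <- ss[ss$is_navigator, , drop = FALSE]
  cit <- nav$id[nav$multiplicity == "dd"][order(
    nav$delta_free[nav$multiplicity == "dd"])]
  cre_rows <- nav$multiplicity == "s" & tolower(nav$metabolite) == "creatinine"
  cre <- nav$id[cre_rows][order(nav$delta_free[cre_rows])]
  gly <- nav$id[tolower(nav$metabolite) == "glycine"]
  c(citrate_dd1 = cit[1], citrate_dd2 = cit[2],
    creatinine_s1 = cre[1], creatinine_s2 = cre[2], glycine_s = gly[1])
}

nav_matrix <- function(bundle, navigators) {
  x <- vapply(names(bundle$navigator_ids), function(role)
    as.numeric(navigators[[role]]), numeric(1))
  m <- matrix(x, nrow = 1)
  colnames(m) <- unname(bundle$navigator_ids)
  m
}

# Vectorised reduced-route estimates for an n x 5 matrix of navigator
# shifts (columns named by navigator spin-system ids).
reduced_estimates <- function(bundle, NAVX) {
  ss_ids <- bundle$panel$spin_systems$id
  nav_ids <- unname(bundle$navigator_ids)
  n <- nrow(NAVX)
  # extrapolation flag against the training hull of the reduced models
  hull <- bundle$reduced_conc_models[[1]]$x_range
  extra <- rep(FALSE, n)
  for (j in seq_along(nav_ids)) {
    extra <- extra | NAVX[, nav_ids[j]] < hull[1, j] |
      NAVX[, nav_ids[j]] > hull[2, j]
  }
  if (any(extra)) {
    warning("reduced route: navigator shifts outside the training hull for ",
            sum(extra), " sample(s); uncertainty inflated")
  }
  est <- vapply(bundle$reduced_conc_models, function(m) predict(m, NAVX),
                numeric(n))
  est <- matrix(est, nrow = n,
                dimnames = list(NULL, names(bundle$reduced_conc_models)))
  clipped <- est < 0
  conc_cols <- setdiff(colnames(est), c("pH", "T"))
  est[, conc_cols][est[, conc_cols] < 0] <- 0

  delta <- matrix(NA_real_, n, length(ss_ids),
                  dimnames = list(NULL, ss_ids))
  delta[, nav_ids] <- NAVX[, nav_ids]
  for (id in names(bundle$reduced_shift_models)) {
    delta[, id] <- predict(bundle$reduced_shift_models[[id]], NAVX)
  }
  err <- bundle$shift_err_reduced[ss_ids]
  list(estimates = est, delta = delta, err = err,
       conc_err = bundle$conc_err_reduced, extrapolated = extra,
       clipped = clipped)
}

full_estimates <- function(bundle, DELTA) {
  ss_ids <- bundle$panel$spin_systems$id
  n <- nrow(DELTA)
  X <- DELTA[, bundle$active_ids, drop = FALSE]
  delta_full <- matrix(NA_real_, n, length(ss_ids),
                       dimnames = list(NULL, ss_ids))
  for (id in ss_ids) {
    delta_full[, id] <- predict(bundle$full_shift_models[[id]], X)
  }
  est <- vapply(bundle$full_conc_models, function(m) predict(m, X),
                numeric(n))
  est <- matrix(est, nrow = n,
                dimnames = list(NULL, names(bundle$full_conc_models)))
  conc_cols <- setdiff(colnames(est), c("pH", "T"))
  est[, conc_cols][est[, conc_cols] < 0] <- 0
  list(delta = delta_full, err = bundle$shift_err_full[ss_ids],
       estimates = est, conc_err = bundle$conc_err_full)
}

#' Reduced-route prediction from the five navigator shifts
#'
#' Evaluates the reduced concentration/pH/T models and the reduced shift
#' models on the five navigator shifts; the navigator signals' own shifts
#' pass through as observed. Navigator values outside the training hull
#' trigger an extrapolation warning and inflate the reported uncertainties.
#'
#' @param bundle A trained `predictor_bundle`.
#' @param navigators A `navigator_set` from [find_navigators()].
#' @return List with `concentrations` (named vector), `pH`, `T`, `delta`
#'   (named shift vector, all spin systems), `err` (per-signal
#'   uncertainty), `conc_uncertainty`, `extrapolated` and `clipped`.
#' @export
route_reduced <- function(bundle, navigators) {
  NAVX <- nav_matrix(bundle, navigators)
  re <- reduced_estimates(bundle, NAVX)
  infl <- if (re$extrapolated[1]) bundle$extrapolation_factor else 1
  est <- re$estimates[1, ]
  comps <- setdiff(names(est), c("pH", "T"))
  list(concentrations = est[comps],
       pH = unname(est["pH"]), T = unname(est["T"]),
       delta = re$delta[1, ], err = re$err * infl,
       conc_uncertainty = re$conc_err * infl,
       extrapolated = re$extrapolated[1],
       clipped = re$clipped[1, ])
}

#' Full-route prediction from the reduced-route shift vector
#'
#' Evaluates the full shift models (each signal predicted from the other
#' active signals) and the full concentration models on the shift vector
#' produced by the reduced route, yielding the second, independent
#' prediction per signal.
#'
#' @param bundle A trained `predictor_bundle`.
#' @param delta_reduced Named shift vector from [route_reduced()].
#' @param concentrations_reduced Optional reduced-route concentration
#'   vector (carried through for reporting).
#' @return List with `delta` (named vector), `err`, `concentrations`,
#'   `pH`, `T`, `conc_uncertainty`.
#' @export
route_full <- function(bundle, delta_reduced, concentrations_reduced = NULL) {
  if (is.null(delta_reduced) || anyNA(delta_reduced[bundle$active_ids])) {
    stop("route_full: reduced-route shift vector is missing or incomplete")
  }
  DELTA <- matrix(delta_reduced, nrow = 1,
                  dimnames = list(NULL, names(delta_reduced)))
  fe <- full_estimates(bundle, DELTA)
  est <- fe$estimates[1, ]
  comps <- setdiff(names(est), c("pH", "T"))
  list(delta = fe$delta[1, ], err = fe$err,
       concentrations = est[comps],
       pH = unname(est["pH"]), T = unname(est["T"]),
       conc_uncertainty = fe$conc_err)
}

#' Combine the reduced- and full-route shift predictions
#'
#' When the two predictions agree within their combined uncertainty
#' (`|delta_reduced - delta_full| <= err_reduced + err_full`, i.e. the two
#' uncertainty intervals overlap), the result is their weighted average
#' with weights inversely proportional to each route's uncertainty;
#' otherwise the reduced-route value is taken (it has the lower average
#' rRMSE on training data).
#'
#' @param delta_reduced,delta_full Numeric vectors of the two route
#'   predictions (ppm).
#' @param err_reduced,err_full Positive uncertainty vectors (ppm).
#' @return List with `delta_best` and `route_used` (per-element
#'   `"weighted_average"` or `"reduced_fallback"`).
#' @export
combine_predictions <- function(delta_reduced, err_reduced,
                                delta_full, err_full) {
  if (any(err_reduced <= 0) || any(err_full <= 0)) {
    stop("combine_predictions: uncertainties must be > 0")
  }
  overlap <- abs(delta_reduced - delta_full) <= (err_reduced + err_full)
  wavg <- (delta_reduced / err_reduced + delta_full / err_full) /
    (1 / err_reduced + 1 / err_full)
  delta_best <- ifelse(overlap, wavg, delta_reduced)
  route <- ifelse(overlap, "weighted_average", "reduced_fallback")
  names(delta_best) <- names(delta_reduced)
  list(delta_best = delta_best, route_used = route)
}

#' Run the full prediction pipeline on one spectrum
#'
#' Navigator detection, reduced route, full route, per-signal combination,
#' and report assembly: predicted shift (with multiplicity and route), the
#' concentration/pH/T estimates (reduced bank by default) with
#' uncertainties and optional clinical-range flags.
#'
#' @param spectrum A TSP-referenced `nmr_spectrum`.
#' @param bundle A trained `predictor_bundle`.
#' @param mode Navigator identification mode, `"auto"` or `"manual"`.
#' @param manual_values Manual navigator positions (see
#'   [find_navigators()]).
#' @param conc_bank Which concentration bank to report: `"reduced"`
#'   (default, lowest rRMSE) or `"full"`.
#' @param clinical_ranges Optional data frame (`component`, `lo`, `hi`) for
#'   range flagging of the reported concentrations.
#' @return A list of class `prediction_report` with elements `signals`
#'   (data frame), `components` (data frame), `pH`, `T`, `navigators`,
#'   `provenance`.
#' @export
run_pipeline <- function(spectrum, bundle, mode = c("auto", "manual"),
                         manual_values = NULL,
                         conc_bank = c("reduced", "full"),
                         clinical_ranges = NULL) {
  mode <- match.arg(mode)
  conc_bank <- match.arg(conc_bank)
  navs <- find_navigators(spectrum, bundle$panel, bundle, mode = mode,
                          manual_values = manual_values)
  rr <- route_reduced(bundle, navs)
  rf <- route_full(bundle, rr$delta, rr$concentrations)
  cmb <- combine_predictions(rr$delta, rr$err, rf$delta, rf$err)

  ss <- bundle$panel$spin_systems
  signals <- data.frame(
    spin_system_id = ss$id,
    metabolite = ss$metabolite,
    multiplicity = ss$multiplicity,
    delta_reduced = rr$delta[ss$id],
    delta_full = rf$delta[ss$id],
    delta_best = cmb$delta_best[ss$id],
    error_reduced = rr$err[ss$id],
    error_full = rf$err[ss$id],
    route_used = cmb$route_used,
    row.names = NULL, stringsAsFactors = FALSE)

  src <- if (conc_bank == "reduced") rr else rf
  comp_names <- names(src$concentrations)
  flags <- rep("", length(comp_names))
  if (!is.null(clinical_ranges)) {
    m <- match(comp_names, clinical_ranges$component)
    flags <- ifelse(is.na(m), "",
      ifelse(src$concentrations < clinical_ranges$lo[m], "low",
      ifelse(src$concentrations > clinical_ranges$hi[m], "high", "normal")))
    flags[is.na(flags)] <- ""
  }
  clip <- if (conc_bank == "reduced") {
    rr$clipped[comp_names]
  } else rep(FALSE, length(comp_names))
  components <- data.frame(
    component = comp_names,
    concentration = unname(src$concentrations),
    uncertainty = unname(src$conc_uncertainty[comp_names]),
    clipped = unname(clip),
    flag = flags,
    row.names = NULL, stringsAsFactors = FALSE)

  report <- structure(list(signals = signals, components = components,
                           pH = src$pH, T = src$T,
                           navigators = navs,
                           provenance = list(
                             conc_bank = conc_bank,
                             extrapolated = rr$extrapolated,
                             bundle_hash = bundle$provenance$config_hash)),
                      class = "prediction_report")
  attr(report, "panel") <- bundle$panel
  report
}

#' Evaluate a trained predictor on held-out data
#'
#' Runs the two-route prediction for every hold-out sample — either from a
#' hold-out shift matrix (navigator columns act as the observed navigator
#' shifts) or from rendered spectra via the full pipeline — and reports
#' per-signal Pearson R (x100), RMSE, maximum absolute error and the
#' fraction of predictions within 1.5 linewidths, plus per-component
#' concentration recovery.
#'
#' @param bundle A trained `predictor_bundle`.
#' @param test_conc Hold-out concentration data frame.
#' @param test_shifts Hold-out shift data frame (matrix mode), or `NULL`.
#' @param spectra List of `nmr_spectrum` objects (spectrum mode), or
#'   `NULL`; `test_shifts` then provides the reference shifts.
#' @param linewidth_ppm Linewidth used for the within-linewidths fraction.
#' @param n_linewidths Accuracy band in linewidths (default 1.5).
#' @return List of class `predictor_evaluation` with data frames `signals`
#'   and `components` and a `summary` list.
#' @export
evaluate_predictor <- function(bundle, test_conc, test_shifts = NULL,
                               spectra = NULL,
                               linewidth_ppm = 0.9 / 600.13,
                               n_linewidths = 1.5) {
  if (any(test_conc$sample_id %in% bundle$provenance$sample_ids)) {
    stop("evaluate_predictor: test sample ids overlap the training set")
  }
  ss_ids <- bundle$panel$spin_systems$id
  ref <- as.matrix(test_shifts[, ss_ids, drop = FALSE])
  n <- nrow(test_conc)

  if (is.null(spectra)) {
    nav_ids <- unname(bundle$navigator_ids)
    NAVX <- as.matrix(test_shifts[, nav_ids, drop = FALSE])
    re <- reduced_estimates(bundle, NAVX)
    fe <- full_estimates(bundle, re$delta)
    pred <- matrix(NA_real_, n, length(ss_ids),
                   dimnames = list(NULL, ss_ids))
    for (id in ss_ids) {
      cmb <- combine_predictions(re$delta[, id], re$err[[id]],
                                 fe$delta[, id], fe$err[[id]])
      pred[, id] <- cmb$delta_best
    }
    est <- re$estimates
  } else {
    if (length(spectra) != n) {
      stop("evaluate_predictor: need one spectrum per test sample")
    }
    reports <- lapply(spectra, run_pipeline, bundle = bundle)
    pred <- t(vapply(reports, function(r) {
      stats::setNames(r$signals$delta_best, r$signals$spin_system_id)[ss_ids]
    }, numeric(length(ss_ids))))
    est <- t(vapply(reports, function(r) {
      c(stats::setNames(r$components$concentration, r$components$component),
        pH = r$pH, T = r$T)
    }, numeric(nrow(reports[[1]]$components) + 2L)))
  }

  signals <- do.call(rbind, lapply(ss_ids, function(id) {
    ok <- !is.na(ref[, id]) & !is.na(pred[, id])
    e <- pred[ok, id] - ref[ok, id]
    data.frame(
      spin_system_id = id,
      n = sum(ok),
      r_x100 = if (sum(ok) > 2 && stats::sd(ref[ok, id]) > 0)
        100 * stats::cor(pred[ok, id], ref[ok, id]) else NA_real_,
      rmse = sqrt(mean(e^2)),
      max_abs_err = max(abs(e)),
      max_err_linewidths = max(abs(e)) / linewidth_ppm,
      frac_within = mean(abs(e) <= n_linewidths * linewidth_ppm),
      stringsAsFactors = FALSE)
  }))

  targets <- intersect(colnames(est),
                       c(modelled_component_names(bundle$panel), "pH", "T"))
  components <- do.call(rbind, lapply(targets, function(tg) {
    truth <- test_conc[[tg]]
    e <- est[, tg] - truth
    data.frame(
      component = tg,
      r_x100 = if (stats::sd(truth) > 0)
        100 * stats::cor(est[, tg], truth) else NA_real_,
      r2 = if (stats::sd(truth) > 0)
        1 - sum(e^2) / sum((truth - mean(truth))^2) else NA_real_,
      rmse = sqrt(mean(e^2)),
      stringsAsFactors = FALSE)
  }))

  structure(list(
    signals = signals, components = components,
    summary = list(
      min_signal_r_x100 = min(signals$r_x100, na.rm = TRUE),
      max_err_linewidths = max(signals$max_err_linewidths),
      min_component_r2 = min(components$r2, na.rm = TRUE),
      frac_within = mean(signals$frac_within))),
    class = "predictor_evaluation")
}

#' @export
print.predictor_bundle <- function(x, ...) {
  cat("Predictor bundle:", length(x$full_shift_models), "spin systems,",
      length(x$full_conc_models), "concentration/pH/T targets\n")
  cat(sprintf("  trained on n = %d (seed %d, %s basis, max %d terms)\n",
              x$provenance$n, x$provenance$seed,
              x$provenance$mars_config$order,
              x$provenance$mars_config$max_terms))
  invisible(x)
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Prediction report\n")
  cat(sprintf("  navigators (%s): %.4f %.4f %.4f %.4f %.4f ppm\n",
              x$navigators$provenance, x$navigators$citrate_dd1,
              x$navigators$citrate_dd2, x$navigators$creatinine_s1,
              x$navigators$creatinine_s2, x$navigators$glycine_s))
  cat(sprintf("  pH %.3f, T %.2f K, %d signals, %d components (%s bank)\n",
              x$pH, x$T, nrow(x$signals), nrow(x$components),
              x$provenance$conc_bank))
  invisible(x)
}

#' @export
print.predictor_evaluation <- function(x, ...) {
  cat("Hold-out evaluation\n")
  cat(sprintf("  min signal R x100: %.2f; max |err|: %.3f linewidths\n",
              x$summary$min_signal_r_x100, x$summary$max_err_linewidths))
  cat(sprintf("  min component R2: %.3f\n", x$summary$min_component_r2))
  invisible(x)
}
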