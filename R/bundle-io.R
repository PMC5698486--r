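# Versioned structured-text (JSON) serialization for models, response sets
# and predictor bundles. Numbers are written at full precision
# (jsonlite digits = I(17)), so serialization round-trips exactly.

MODEL_FORMAT_VERSION <- "1.0"
BUNDLE_FORMAT_VERSION <- "1.0"

mars_model_to_list <- function(model) {
  list(
    format = "shiftnav-mars-model", version = MODEL_FORMAT_VERSION,
    response_name = model$response_name,
    predictor_names = as.list(model$predictor_names),
    intercept = model$intercept,
    M = model$M,
    terms = lapply(model$terms, function(tr) list(
      coefficient = tr$coefficient,
      factors = lapply(tr$factors, function(f) list(
        var = f$var, knot = f$knot, dir = f$dir, order = f$order,
        t_lo = f$t_lo, t_hi = f$t_hi)))),
    x_range = lapply(seq_len(ncol(model$x_range)),
                     function(j) model$x_range[, j]),
    y_range = model$y_range,
    n = model$n,
    control = unclass(model$control),
    fit_stats = model$fit_stats)
}

mars_model_from_list <- function(obj) {
  if (!identical(obj$format, "shiftnav-mars-model")) {
    stop("read_mars_model: not a shiftnav MARS model file")
  }
  pnames <- unlist(obj$predictor_names)
  xr <- do.call(cbind, lapply(obj$x_range, as.numeric))
  colnames(xr) <- pnames
  ctl <- obj$control
  ctl$max_terms <- as.integer(ctl$max_terms)
  ctl$degree <- as.integer(ctl$degree)
  structure(list(
    intercept = as.numeric(obj$intercept),
    terms = lapply(obj$terms, function(tr) list(
      coefficient = as.numeric(tr$coefficient),
      factors = lapply(tr$factors, function(f) list(
        var = as.integer(f$var), knot = as.numeric(f$knot),
        dir = as.integer(f$dir), order = f$order,
        t_lo = as.numeric(f$t_lo %||% NA), t_hi = as.numeric(f$t_hi %||% NA))))),
    M = as.integer(obj$M),
    predictor_names = pnames,
    response_name = obj$response_name,
    x_range = xr,
    y_range = as.numeric(obj$y_range),
    n = as.integer(obj$n),
    control = structure(ctl, class = "mars_control"),
    fit_stats = lapply(obj$fit_stats, as.numeric)),
    class = "mars_model")
}

#' Serialize / restore a MARS model
#'
#' Human-readable, versioned JSON; round-trips exactly (full numeric
#' precision).
#'
#' @param model A `mars_model`.
#' @param path File path.
#' @return `path` invisibly / the restored `mars_model`.
#' @export
write_mars_model <- function(model, path) {
  writeLines(jsonlite::toJSON(mars_model_to_list(model), auto_unbox = TRUE,
                              digits = I(17), pretty = TRUE, na = "null"), path)
  invisible(path)
}

#' @rdname write_mars_model
#' @export
read_mars_model <- function(path) {
  mars_model_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' Serialize / restore a shift response set
#'
#' @param responses A [shift_responses()] object.
#' @param path File path.
#' @return `path` invisibly / the restored `shift_responses`.
#' @export
write_responses <- function(responses, path) {
  obj <- list(format = "shiftnav-responses", version = "1.0",
              seed = attr(responses, "seed"),
              panel_hash = attr(responses, "panel_hash"),
              responses = unclass(responses))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "shiftnav-responses")) {
    stop("read_responses: not a shiftnav response file")
  }
  resp <- lapply(obj$responses, function(r) {
    r$delta_free <- as.numeric(r$delta_free)
    r$temp_coeff <- as.numeric(r$temp_coeff)
    r$ph_term <- lapply(r$ph_term, as.numeric)
    r$modulators <- lapply(r$modulators, function(m) list(
      component = m$component, amplitude = as.numeric(m$amplitude),
      half_saturation = as.numeric(m$half_saturation)))
    r
  })
  structure(resp, class = "shift_responses", seed = obj$seed,
            panel_hash = obj$panel_hash)
}

panel_to_list <- function(panel) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_panel(panel, f)
  jsonlite::fromJSON(f, simplifyDataFrame = FALSE)
}

panel_from_list <- function(obj) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), f)
  load_panel(f)
}

#' Serialize / restore a trained predictor bundle
#'
#' The bundle file embeds the panel, all four model banks, the glycine
#' auxiliary model, the per-model uncertainties and the training
#' provenance (n, seed, configuration hash). Identical retraining produces
#' a byte-identical file.
#'
#' @param bundle A `predictor_bundle`.
#' @param path File path.
#' @return `path` invisibly / the restored `predictor_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  obj <- list(
    format = "shiftnav-bundle", version = BUNDLE_FORMAT_VERSION,
    panel = panel_to_list(bundle$panel),
    navigator_ids = as.list(bundle$navigator_ids),
    active_ids = as.list(bundle$active_ids),
    full_shift_models = lapply(bundle$full_shift_models, mars_model_to_list),
    reduced_shift_models = lapply(bundle$reduced_shift_models,
                                  mars_model_to_list),
    full_conc_models = lapply(bundle$full_conc_models, mars_model_to_list),
    reduced_conc_models = lapply(bundle$reduced_conc_models,
                                 mars_model_to_list),
    glycine_model = mars_model_to_list(bundle$glycine_model),
    navigator_error = bundle$navigator_error,
    extrapolation_factor = bundle$extrapolation_factor,
    provenance = bundle$provenance)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "shiftnav-bundle")) {
    stop("read_bundle: not a shiftnav bundle file")
  }
  panel <- panel_from_list(obj$panel)
  bundle <- structure(list(
    panel = panel,
    navigator_ids = unlist(obj$navigator_ids),
    active_ids = unlist(obj$active_ids),
    full_shift_models = lapply(obj$full_shift_models, mars_model_from_list),
    reduced_shift_models = lapply(obj$reduced_shift_models,
                                  mars_model_from_list),
    full_conc_models = lapply(obj$full_conc_models, mars_model_from_list),
    reduced_conc_models = lapply(obj$reduced_conc_models,
                                 mars_model_from_list),
    glycine_model = mars_model_from_list(obj$glycine_model),
    navigator_error = as.numeric(obj$navigator_error),
    extrapolation_factor = as.numeric(obj$extrapolation_factor),
    provenance = obj$provenance), class = "predictor_bundle")
  err_of <- function(m) max(m$fit_stats$rmse_cv, 1e-9)
  bundle$shift_err_full <- vapply(bundle$full_shift_models, err_of, numeric(1))
  bundle$shift_err_reduced <- c(
    vapply(bundle$reduced_shift_models, err_of, numeric(1)),
    stats::setNames(rep(bundle$navigator_error,
                        length(bundle$navigator_ids)),
                    unname(bundle$navigator_ids)))
  bundle$conc_err_full <- vapply(bundle$full_conc_models, err_of, numeric(1))
  bundle$conc_err_reduced <- vapply(bundle$reduced_conc_models, err_of,
                                    numeric(1))
  bundle$provenance$sample_ids <- unlist(bundle$provenance$sample_ids)
  bundle
}
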