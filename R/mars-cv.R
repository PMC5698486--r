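#' k-fold cross-validation of a MARS configuration
#'
#' Fits the model on each training fold and pools the out-of-fold
#' predictions. `r2_cv = 1 - SS_res / SS_tot` over the pooled predictions,
#' `rmse` is in response units, and `rrmse = rmse / range(y)`.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @param control A [mars_control()] list.
#' @param k_folds Number of folds (>= 2); `n >= 2 * k_folds` required.
#' @param seed Integer seed controlling the fold assignment.
#' @return List with `r2_cv`, `rmse`, `rrmse` and the pooled out-of-fold
#'   prediction vector `oof`.
#' @export
cross_validate <- function(X, y, control = mars_control(), k_folds = 10L,
                           seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (k_folds < 2) stop("cross_validate: k_folds must be >= 2")
  if (n < 2 * k_folds) stop("cross_validate: need n >= 2 * k_folds")
  folds <- local_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  oof <- rep(NA_real_, n)
  for (k in seq_len(k_folds)) {
    test <- folds == k
    ytr <- y[!test]
    if (stats::var(ytr) == 0) {
      warning("cross_validate: fold ", k, " has constant response; skipped")
      next
    }
    fit <- fit_mars(X[!test, , drop = FALSE], ytr, control)
    oof[test] <- predict(fit, X[test, , drop = FALSE])
  }
  ok <- !is.na(oof)
  ss_res <- sum((y[ok] - oof[ok])^2)
  ss_tot <- sum((y[ok] - mean(y[ok]))^2)
  rmse <- sqrt(mean((y[ok] - oof[ok])^2))
  yr <- diff(range(y))
  list(r2_cv = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       rmse = rmse,
       rrmse = if (yr > 0) rmse / yr else NA_real_,
       oof = oof)
}

# Fit + cross-validate and store the CV statistics inside the model.
fit_mars_cv <- function(X, y, control = mars_control(), k_folds = 10L,
                        seed = 1L, response_name = "y") {
  model <- fit_mars(X, y, control, response_name = response_name)
  cv <- cross_validate(X, y, control, k_folds = k_folds, seed = seed)
  model$fit_stats$r2_cv <- cv$r2_cv
  model$fit_stats$rmse_cv <- cv$rmse
  model$fit_stats$rrmse_cv <- cv$rrmse
  model
}

#' ANOVA decomposition of predictor importance
#'
#' For each predictor, all basis functions involving it are removed, the
#' remaining coefficients are refitted, and the importance is the resulting
#' increase in GCV, rescaled so that the largest importance is 100. Unused
#' predictors have importance 0.
#'
#' @param model A `mars_model`.
#' @param X,y The training data.
#' @return A data frame with columns `predictor_name`, `importance`
#'   (0-100) and `n_terms_involving`.
#' @export
anova_decompose <- function(model, X, y) {
  X <- as.matrix(X)
  if (!is.null(colnames(X))) X <- X[, model$predictor_names, drop = FALSE]
  y <- as.numeric(y)
  p <- length(model$predictor_names)
  out <- data.frame(predictor_name = model$predictor_names,
                    importance = 0, n_terms_involving = 0L,
                    stringsAsFactors = FALSE)
  if (model$M == 0) return(out)

  factors <- c(list(list()), lapply(model$terms, `[[`, "factors"))
  B <- mars_basis_matrix(factors, X)
  n <- nrow(B)
  vars_per_term <- lapply(factors, function(fl) {
    unique(vapply(fl, `[[`, integer(1), "var"))
  })
  refit_gcv <- function(cols, M) {
    cf <- qr.coef(qr(B[, cols, drop = FALSE]), y)
    cf[is.na(cf)] <- 0
    rss <- sum((y - B[, cols, drop = FALSE] %*% cf)^2)
    gcv_from_rss(rss, n, M, model$control$penalty)
  }
  gcv_full <- refit_gcv(seq_along(factors), model$M)
  raw <- numeric(p)
  for (v in seq_len(p)) {
    involved <- vapply(vars_per_term, function(vs) v %in% vs, logical(1))
    out$n_terms_involving[v] <- sum(involved)
    if (!any(involved)) next
    keep <- which(!involved)
    raw[v] <- max(refit_gcv(keep, length(keep) - 1L) - gcv_full, 0)
  }
  if (max(raw) > 0) out$importance <- 100 * raw / max(raw)
  out
}

#' Choose between linear and cubic basis order by cross-validated RMSE
#'
#' @inheritParams cross_validate
#' @return The winning [mars_control()] (lowest CV RMSE).
#' @export
select_spline_order <- function(X, y, control = mars_control(),
                                k_folds = 10L, seed = 1L) {
  ctl_lin <- control; ctl_lin$order <- "linear"
  ctl_cub <- control; ctl_cub$order <- "cubic"
  rmse_lin <- cross_validate(X, y, ctl_lin, k_folds, seed)$rmse
  rmse_cub <- cross_validate(X, y, ctl_cub, k_folds, seed)$rmse
  if (rmse_cub < rmse_lin) ctl_cub else ctl_lin
}
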