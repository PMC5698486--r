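#' Control parameters for MARS fitting
#'
#' @param max_terms Maximum number of basis functions (including the
#'   intercept) retained by the forward pass. The backward pass can only
#'   shrink the model.
#' @param degree Maximum interaction degree, i.e. number of hinge factors
#'   multiplied together in one basis function. The default is 1 (additive
#'   model), which matches the additive fast-exchange physics the package's
#'   simulator produces; set 2 or more for interaction models.
#' @param penalty GCV cost per knot, the `d` in
#'   `enp = M + 1 + penalty * M / 2`. Conventional default 3.
#' @param thresh Forward-pass stopping threshold: stop when the best
#'   candidate pair reduces the residual sum of squares by less than
#'   `thresh * SST`.
#' @param max_knots Cap on candidate knots per predictor, or `"auto"`
#'   (all distinct values when `n <= 64`, otherwise 15). Candidate knots are
#'   the observed predictor values thinned to at most `max_knots` by a
#'   minimum-span rule (evenly spaced order statistics).
#' @param order `"linear"` for piecewise-linear hinges, `"cubic"` for the
#'   fit-then-smooth truncated-cubic reparameterisation of the pruned
#'   linear model.
#' @param ridge Relative ridge applied to the Gram matrix diagonal in
#'   every least-squares solve (`diag <- diag * (1 + ridge)`). Stabilises the
#'   coefficients when predictors are strongly collinear (e.g. shift
#'   matrices whose columns share common drivers), at a bias that is
#'   negligible for well-conditioned fits. Off by default: the end-span
#'   rule already prevents the unstable boundary hinges, and in shift-scale
#'   regressions even a tiny relative shrinkage biases the large natural
#'   coefficients measurably.
#' @param endspan Number of observations that must lie strictly outside
#'   the outermost candidate knots of every predictor (`"auto"`:
#'   `max(7, ceiling(log2(n)))`). Knots too close to the data boundary sit
#'   on a handful of observations and produce enormous, unstable hinge
#'   coefficients; the span rule excludes them.
#' @param ortho_tol Minimum fraction of a candidate basis column's squared
#'   norm that must lie outside the span of the current basis. Candidates
#'   below the threshold are almost copies of existing columns (their
#'   orthogonal remainder is measurement noise) and produce wildly
#'   unstable coefficients if admitted; they are dropped.
#' @param prune Run the GCV backward (pruning) pass. Disable to inspect the
#'   raw forward-pass model.
#' @return A list of class `mars_control`.
#' @export
mars_control <- function(max_terms = 21L, degree = 1L, penalty = 3,
                         thresh = 1e-7, max_knots = "auto",
                         order = c("linear", "cubic"), ridge = 0,
                         endspan = "auto", ortho_tol = 0, prune = TRUE) {
  order <- match.arg(order)
  stopifnot(max_terms >= 1, degree >= 1, penalty >= 0, thresh >= 0,
            ridge >= 0, ortho_tol >= 0)
  structure(list(max_terms = as.integer(max_terms),
                 degree = as.integer(degree),
                 penalty = penalty, thresh = thresh,
                 max_knots = max_knots, order = order, ridge = ridge,
                 endspan = endspan, ortho_tol = ortho_tol,
                 prune = isTRUE(prune)),
            class = "mars_control")
}

# Ridge-stabilised least squares on a basis matrix: coefficients and the
# true (unpenalised) residual sum of squares of those coefficients.
ridge_ls <- function(B, y, ridge) {
  G <- crossprod(B)
  g <- drop(crossprod(B, y))
  Gr <- G
  if (ridge > 0) diag(Gr) <- diag(Gr) * (1 + ridge)
  cf <- solve_psd(Gr, g)
  rss <- max(sum(y^2) - 2 * sum(g * cf) + drop(crossprod(cf, G %*% cf)), 0)
  list(coef = cf, rss = rss)
}

# Candidate knots for one predictor: sorted distinct values minus the global
# maximum (whose ascending hinge would be identically zero), restricted by
# the end-span rule (at least `endspan` observations strictly on each side
# of any knot, so no hinge rests on a handful of boundary points), then
# thinned to at most max_knots evenly spaced order statistics, which also
# enforces a minimum span between consecutive knots.
mars_knots <- function(x, max_knots, endspan = "auto") {
  n <- length(x)
  if (identical(endspan, "auto")) {
    endspan <- max(7L, as.integer(ceiling(log2(n))))
  }
  u <- sort(unique(x))
  u <- u[-length(u)]
  if (endspan > 0 && length(u) > 1) {
    n_above <- vapply(u, function(t) sum(x > t), numeric(1))
    n_below <- vapply(u, function(t) sum(x < t), numeric(1))
    keep <- n_above >= endspan & n_below >= endspan
    if (any(keep)) u <- u[keep]
    else u <- u[which.min(abs(u - stats::median(x)))]
  }
  if (length(u) == 0) return(numeric(0))
  if (identical(max_knots, "auto")) {
    max_knots <- if (n <= 64) Inf else 15L
  }
  if (is.finite(max_knots) && length(u) > max_knots) {
    idx <- unique(round(seq(1, length(u), length.out = max_knots)))
    u <- u[idx]
  }
  u
}

# Expand the parent-pointer representation returned by the C++ forward pass
# into one factor list per basis column (column 1 is the intercept).
mars_expand_factors <- function(fw) {
  ncols <- length(fw$parent)
  lapply(seq_len(ncols), function(q) {
    facs <- list()
    while (q > 1) {
      facs[[length(facs) + 1L]] <-
        list(var = fw$var[q] + 1L, knot = fw$knot[q], dir = fw$dir[q],
             order = "linear", t_lo = NA_real_, t_hi = NA_real_)
      q <- fw$parent[q] + 1L
    }
    rev(facs)
  })
}

# Evaluate one basis factor at x (a numeric vector of its variable).
eval_factor <- function(fac, x) {
  if (identical(fac$order, "cubic")) {
    eval_cubic_hinge(x, fac$knot, fac$t_lo, fac$t_hi, fac$dir)
  } else if (fac$dir > 0) {
    pmax(x - fac$knot, 0)
  } else {
    pmax(fac$knot - x, 0)
  }
}

# Truncated cubic spline replacement of a hinge (value- and slope-continuous
# at the side knots t_lo < t < t_hi), mirrored for descending hinges.
eval_cubic_hinge <- function(x, t, t_lo, t_hi, dir) {
  if (dir < 0) return(eval_cubic_hinge(-x, -t, -t_hi, -t_lo, 1L))
  out <- numeric(length(x))
  hi <- x >= t_hi
  mid <- x > t_lo & x < t_hi
  out[hi] <- x[hi] - t
  if (any(mid)) {
    d <- t_hi - t_lo
    pp <- (2 * t_hi + t_lo - 3 * t) / d^2
    rr <- (2 * t - t_hi - t_lo) / d^3
    z <- x[mid] - t_lo
    out[mid] <- pp * z^2 + rr * z^3
  }
  out
}

mars_basis_matrix <- function(factors, X) {
  n <- nrow(X)
  B <- matrix(1, n, length(factors))
  for (j in seq_along(factors)) {
    for (fac in factors[[j]]) {
      B[, j] <- B[, j] * eval_factor(fac, X[, fac$var])
    }
  }
  B
}

# GCV backward pass: iteratively delete the term whose removal increases the
# RSS least, keep the best subset of every size, return the subset with the
# smallest GCV. Works entirely on the Gram matrix of the forward basis.
mars_backward <- function(B, y, penalty, ridge = 0) {
  n <- nrow(B)
  G <- crossprod(B)
  g <- crossprod(B, y)[, 1]
  yy <- sum(y^2)
  rss_of <- function(idx) {
    Gs <- G[idx, idx, drop = FALSE]
    Gr <- Gs
    if (ridge > 0) diag(Gr) <- diag(Gr) * (1 + ridge)
    cf <- solve_psd(Gr, g[idx])
    max(yy - 2 * sum(g[idx] * cf) + drop(crossprod(cf, Gs %*% cf)), 0)
  }
  current <- seq_len(ncol(B))
  best_by_size <- list(list(idx = current, rss = rss_of(current)))
  while (length(current) > 1) {
    cand_rss <- vapply(current[-1], function(drop_j) {
      rss_of(setdiff(current, drop_j))
    }, numeric(1))
    j <- current[-1][which.min(cand_rss)]
    current <- setdiff(current, j)
    best_by_size[[length(best_by_size) + 1L]] <-
      list(idx = current, rss = min(cand_rss))
  }
  gcvs <- vapply(best_by_size, function(s) {
    gcv_from_rss(s$rss, n, length(s$idx) - 1L, penalty)
  }, numeric(1))
  best_by_size[[which.min(gcvs)]]$idx
}

gcv_from_rss <- function(rss, n, M, penalty) {
  enp <- M + 1 + penalty * M / 2
  if (enp >= n) return(Inf)
  (rss / n) / (1 - enp / n)^2
}

#' Fit a multivariate adaptive regression splines model
#'
#' Greedy forward selection of reflected hinge pairs (knots at observed
#' predictor values) followed by a GCV backward pruning pass. With
#' `control$order = "cubic"` the pruned piecewise-linear model is
#' reparameterised with truncated cubic basis functions (side knots midway
#' between adjacent knots of the same variable) and the coefficients are
#' refitted, giving a continuously differentiable surface.
#'
#' @param X Numeric matrix or data frame of predictors (no missing values).
#' @param y Numeric response vector.
#' @param control A [mars_control()] list.
#' @param response_name Label stored in the model (used by reports).
#' @return An object of class `mars_model` with elements `intercept`,
#'   `terms` (each a list of `coefficient` and `factors`), `M`,
#'   `predictor_names`, `response_name` and `fit_stats`.
#' @export
fit_mars <- function(X, y, control = mars_control(), response_name = "y") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("fit_mars: missing values in X or y")
  n <- nrow(X)
  if (n != length(y)) stop("fit_mars: nrow(X) != length(y)")
  if (n <= control$max_terms) {
    stop("fit_mars: need more samples (n = ", n,
         ") than max_terms (", control$max_terms, ")")
  }
  pnames <- colnames(X)
  if (is.null(pnames)) pnames <- paste0("x", seq_len(ncol(X)))

  knots <- lapply(seq_len(ncol(X)), function(v) {
    mars_knots(X[, v], control$max_knots, control$endspan %||% "auto")
  })
  fw <- mars_forward_cpp(X, y, knots, control$max_terms, control$degree,
                         control$thresh, control$ridge,
                         control$ortho_tol %||% 1e-3)
  factors <- mars_expand_factors(fw)
  B <- fw$B

  keep <- if (control$prune) mars_backward(B, y, control$penalty,
                                           control$ridge)
          else seq_along(factors)
  keep <- sort(keep)
  factors <- factors[keep]
  B <- B[, keep, drop = FALSE]

  if (control$order == "cubic") {
    factors <- cubify_factors(factors, X)
    B <- mars_basis_matrix(factors, X)
  }

  ls <- ridge_ls(B, y, control$ridge)
  cf <- ls$coef
  fitted <- drop(B %*% cf)
  rss <- sum((y - fitted)^2)
  M <- length(factors) - 1L
  sst <- sum((y - mean(y))^2)

  model <- structure(list(
    intercept = cf[1],
    terms = if (M > 0) lapply(seq_len(M) + 1L, function(j) {
      list(coefficient = cf[j], factors = factors[[j]])
    }) else list(),
    M = M,
    predictor_names = pnames,
    response_name = response_name,
    x_range = apply(X, 2, range),
    y_range = range(y),
    n = n,
    control = control,
    fit_stats = list(
      rss = rss,
      gcv = gcv_from_rss(rss, n, M, control$penalty),
      r2_train = if (sst > 0) 1 - rss / sst else 1,
      rmse = sqrt(rss / n),
      rrmse = if (diff(range(y)) > 0) sqrt(rss / n) / diff(range(y)) else 0,
      r2_cv = NA_real_, rmse_cv = NA_real_, rrmse_cv = NA_real_),
    fitted = fitted), class = "mars_model")
  model
}

# Replace every linear hinge with its truncated-cubic version; side knots of
# each knot are midway to the adjacent knots used by the model on the same
# variable (data range limits at the ends).
cubify_factors <- function(factors, X) {
  used <- list()
  for (fl in factors) for (fac in fl) {
    v <- as.character(fac$var)
    used[[v]] <- sort(unique(c(used[[v]], fac$knot)))
  }
  lapply(factors, function(fl) {
    lapply(fl, function(fac) {
      v <- fac$var
      ks <- used[[as.character(v)]]
      lo <- min(X[, v]); hi <- max(X[, v])
      i <- match(fac$knot, ks)
      t_lo <- if (i == 1) (lo + fac$knot) / 2 else (ks[i - 1] + fac$knot) / 2
      t_hi <- if (i == length(ks)) (hi + fac$knot) / 2
              else (ks[i + 1] + fac$knot) / 2
      if (t_lo >= fac$knot || t_hi <= fac$knot) {
        fac  # degenerate spacing: keep the linear hinge
      } else {
        fac$order <- "cubic"; fac$t_lo <- t_lo; fac$t_hi <- t_hi
        fac
      }
    })
  })
}

#' Predict from a MARS model
#'
#' Exact evaluation of `c0 + sum_m c_m B_m(x)`.
#'
#' @param object A `mars_model`.
#' @param newdata Matrix or data frame containing (at least) the model's
#'   predictor columns, matched by name when names are present.
#' @param ... Unused.
#' @export
predict.mars_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (!is.null(colnames(X))) {
    missing <- setdiff(object$predictor_names, colnames(X))
    if (length(missing) > 0) {
      stop("predict.mars_model: missing predictor columns: ",
           paste(missing, collapse = ", "))
    }
    X <- X[, object$predictor_names, drop = FALSE]
  } else if (ncol(X) != length(object$predictor_names)) {
    stop("predict.mars_model: newdata has ", ncol(X), " columns; model needs ",
         length(object$predictor_names))
  }
  out <- rep(unname(object$intercept), nrow(X))
  for (term in object$terms) {
    b <- rep(1, nrow(X))
    for (fac in term$factors) b <- b * eval_factor(fac, X[, fac$var])
    out <- out + term$coefficient * b
  }
  unname(out)
}

#' Generalized cross-validation score of a fitted model
#'
#' `GCV = (RSS/n) / (1 - enp/n)^2` with effective number of parameters
#' `enp = M + 1 + penalty * M / 2`.
#'
#' @param model A `mars_model`.
#' @param X,y Data on which to evaluate the residual sum of squares (the
#'   same `n` as used at fit time).
#' @param penalty GCV penalty per knot (default 3).
#' @return The GCV value; `+Inf` (with a warning) when `enp >= n`.
#' @export
gcv_score <- function(model, X, y, penalty = 3) {
  rss <- sum((y - predict(model, X))^2)
  out <- gcv_from_rss(rss, length(y), model$M, penalty)
  if (!is.finite(out)) {
    warning("gcv_score: effective number of parameters >= n; returning Inf")
  }
  out
}

#' @export
print.mars_model <- function(x, ...) {
  cat("MARS model: ", x$response_name, " ~ ",
      paste(x$predictor_names, collapse = " + "), "\n", sep = "")
  cat(sprintf("  terms: %d (+ intercept), order: %s\n", x$M, x$control$order))
  cat(sprintf("  RSS %.6g  GCV %.6g  R2(train) %.5f\n",
              x$fit_stats$rss, x$fit_stats$gcv, x$fit_stats$r2_train))
  if (!is.na(x$fit_stats$r2_cv)) {
    cat(sprintf("  R2(cv) %.5f  RMSE(cv) %.6g  rRMSE(cv) %.5f\n",
                x$fit_stats$r2_cv, x$fit_stats$rmse_cv, x$fit_stats$rrmse_cv))
  }
  invisible(x)
}

#' Human-readable basis function expressions of a MARS model
#'
#' @param model A `mars_model`.
#' @return Character vector, one entry per term (intercept first).
#' @export
mars_term_labels <- function(model) {
  fmt_fac <- function(fac) {
    v <- model$predictor_names[fac$var]
    h <- if (fac$dir > 0) sprintf("h(%s - %.6g)", v, fac$knot)
         else sprintf("h(%.6g - %s)", fac$knot, v)
    if (identical(fac$order, "cubic")) sub("^h", "C", h) else h
  }
  c(sprintf("%.8g", model$intercept),
    vapply(model$terms, function(tr) {
      paste0(sprintf("%.8g * ", tr$coefficient),
             paste(vapply(tr$factors, fmt_fac, character(1)), collapse = " * "))
    }, character(1)))
}
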