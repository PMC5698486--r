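# Shared fixtures, built lazily and memoized for the whole test run.

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (!exists(key, envir = .fx_cache)) {
    assign(key, builder(), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

fx_panel <- function() fx_memo("panel", default_panel)

fx_responses <- function() {
  fx_memo("responses", function() shift_responses(fx_panel()))
}

# A modest training set + bundle for unit-level pipeline tests.
fx_train_small <- function() {
  fx_memo("train_small", function() {
    build_training_set(fx_panel(), fx_responses(), 300, seed = 42)
  })
}

fx_bundle_small <- function() {
  fx_memo("bundle_small", function() {
    ts <- fx_train_small()
    train_bundle(ts$concentrations, ts$shifts, fx_panel(), seed = 7)
  })
}

fx_holdout <- function() {
  fx_memo("holdout", function() {
    build_test_set(fx_panel(), fx_responses(), 30, seed = 4242)
  })
}

# One rendered hold-out spectrum (first hold-out mixture).
fx_spectrum <- function() {
  fx_memo("spectrum", function() {
    render_spectrum(fx_panel(), fx_responses(),
                    fx_holdout()$concentrations[1, ], seed = 99)
  })
}

# Ground-truth shifts with absent passive metabolites masked NA.
fx_truth_shifts <- function(tset) {
  truth <- shiftnav:::true_shift_matrix(fx_responses(), tset$concentrations)
  mask <- is.na(as.matrix(tset$shifts[, colnames(truth)]))
  truth[mask] <- NA
  truth
}

default_linewidth_ppm <- 0.9 / 600.13

# Exhaustive single-step MARS oracle: best least-squares fit of
# intercept + reflected hinge pair over every candidate knot of a single
# predictor. Independent of the package's forward-pass implementation.
oracle_hinge_pair_rss <- function(x, y) {
  knots <- sort(unique(x))
  knots <- knots[-length(knots)]
  best <- sum((y - mean(y))^2)
  for (t in knots) {
    h1 <- pmax(x - t, 0)
    h2 <- pmax(t - x, 0)
    fit <- stats::lm.fit(cbind(1, h1, h2), y)
    rss <- sum(fit$residuals^2)
    if (rss < best) best <- rss
  }
  best
}
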