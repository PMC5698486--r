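test_that("constant response yields an intercept-only model", {
  x <- matrix(runif(40), ncol = 1)
  m <- fit_mars(x, rep(3.14, 40), mars_control(max_terms = 10))
  expect_equal(m$M, 0L)
  expect_equal(m$intercept, 3.14)
  expect_equal(predict(m, matrix(0.5)), 3.14)
})

test_that("a single hinge with noiseless data is recovered", {
  set.seed(1)
  x <- matrix(sort(runif(200)), ncol = 1)
  y <- 2 * pmax(x[, 1] - 0.3, 0) + 1
  m <- fit_mars(x, y, mars_control(max_terms = 4, max_knots = 1e9))
  knots <- unlist(lapply(m$terms, function(tr) tr$factors[[1]]$knot))
  grid_step <- max(diff(sort(unique(x[, 1]))))
  expect_lt(min(abs(knots - 0.3)), grid_step + 1e-12)
  best <- m$terms[[which.min(abs(knots - 0.3))]]
  expect_lt(abs(best$coefficient - 2) / 2, 0.01)
  expect_lt(m$fit_stats$rss, 1e-6)
})

test_that("forward pass matches the exhaustive knot-enumeration oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(c(30, 50), 1)
    x <- matrix(runif(n), ncol = 1)
    y <- sin(3 * x[, 1]) + 0.2 * rnorm(n)
    m <- fit_mars(x, y, mars_control(max_terms = 3, max_knots = 1e9,
                                     endspan = 0, prune = FALSE,
                                     thresh = 0))
    expect_equal(m$fit_stats$rss, oracle_hinge_pair_rss(x[, 1], y),
                 tolerance = 1e-10)
  }
})

test_that("hand-built model evaluates Eq.-style basis expansion exactly", {
  m <- structure(list(
    intercept = 1,
    terms = list(list(coefficient = 2, factors = list(
      list(var = 1L, knot = 0.5, dir = 1L, order = "linear",
           t_lo = NA, t_hi = NA)))),
    M = 1L, predictor_names = "x", response_name = "y",
    control = mars_control()), class = "mars_model")
  expect_equal(predict(m, matrix(0.75, dimnames = list(NULL, "x"))), 1.5)
  expect_equal(predict(m, matrix(0.25, dimnames = list(NULL, "x"))), 1.0)
})

test_that("prediction at training points reproduces fitted values", {
  set.seed(2)
  X <- matrix(runif(120), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + pmax(X[, 2] - 0.4, 0) + rnorm(60, 0, 0.05)
  m <- fit_mars(X, y, mars_control(max_terms = 11))
  expect_equal(predict(m, X), m$fitted, tolerance = 1e-12)
  sst <- sum((y - mean(y))^2)
  expect_equal(m$fit_stats$r2_train, 1 - m$fit_stats$rss / sst,
               tolerance = 1e-12)
})

test_that("predict errors on missing columns", {
  X <- matrix(runif(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_mars(X, X[, 1] + X[, 2], mars_control(max_terms = 5))
  bad <- matrix(runif(10), ncol = 1, dimnames = list(NULL, "a"))
  expect_error(predict(m, bad), "missing predictor columns.*b")
})

test_that("GCV follows the effective-parameter formula", {
  x <- matrix(1:4, ncol = 1)
  y <- c(0, 1, 0, 1)
  m <- fit_mars(x, y, mars_control(max_terms = 1))
  expect_equal(m$M, 0L)
  # RSS = 1, enp = 1: (1/4) / (1 - 1/4)^2 = 4/9
  expect_equal(gcv_score(m, x, y, penalty = 3), 4 / 9, tolerance = 1e-12)

  # perfect fit: GCV 0 (no end-span restriction at n = 4)
  y2 <- 2 * x[, 1]
  m2 <- fit_mars(x, y2, mars_control(max_terms = 3, endspan = 0))
  expect_lt(gcv_score(m2, x, y2), 1e-20)

  # a zero-coefficient extra term strictly increases GCV (same RSS)
  m3 <- m
  m3$terms <- list(list(coefficient = 0, factors = list(
    list(var = 1L, knot = 2, dir = 1L, order = "linear",
         t_lo = NA, t_hi = NA))))
  m3$M <- 1L
  expect_gt(gcv_score(m3, x, y, penalty = 3), gcv_score(m, x, y, penalty = 3))

  # enp >= n: +Inf with a warning
  m4 <- m3
  m4$M <- 10L
  expect_warning(g <- gcv_score(m4, x, y), "Inf")
  expect_identical(g, Inf)
})

test_that("backward pass never increases GCV relative to the forward model", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(runif(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- pmax(X[, 1] - 0.5, 0) + rnorm(100, 0, 0.1)
    ctl <- mars_control(max_terms = 15)
    ctl_fw <- ctl; ctl_fw$prune <- FALSE
    m_fw <- fit_mars(X, y, ctl_fw)
    m_bw <- fit_mars(X, y, ctl)
    expect_lte(m_bw$fit_stats$gcv, m_fw$fit_stats$gcv + 1e-12)
  }
})

test_that("fits are affine-equivariant in the response scale", {
  set.seed(3)
  X <- matrix(runif(80), ncol = 1, dimnames = list(NULL, "x"))
  y <- pmax(X[, 1] - 0.35, 0) - 0.5 * pmax(0.6 - X[, 1], 0)
  a <- 3.7; b <- -1.2
  ctl <- mars_control(max_terms = 7, max_knots = 1e9)
  m1 <- fit_mars(X, y, ctl)
  m2 <- fit_mars(X, a * y + b, ctl)
  Xn <- matrix(seq(0.05, 0.95, length.out = 21),
               dimnames = list(NULL, "x"))
  expect_equal(predict(m2, Xn), a * predict(m1, Xn) + b, tolerance = 1e-8)
})

test_that("cubic reparameterisation stays close to the linear fit and is smooth", {
  set.seed(4)
  X <- matrix(runif(300), ncol = 1, dimnames = list(NULL, "x"))
  y <- sin(2.5 * X[, 1])
  lin <- fit_mars(X, y, mars_control(max_terms = 11, order = "linear"))
  cub <- fit_mars(X, y, mars_control(max_terms = 11, order = "cubic"))
  expect_gt(cub$fit_stats$r2_train, 0.999)
  # numerical first derivative of the cubic fit is continuous (no jumps of
  # the size the linear fit has at its knots)
  g <- seq(0.02, 0.98, by = 1e-3)
  for (m in list(cub)) {
    p <- predict(m, matrix(g, dimnames = list(NULL, "x")))
    d2 <- diff(diff(p))
    expect_lt(max(abs(d2)), 1e-4)  # bounded curvature per step
  }
})

test_that("cross-validation separates signal from noise", {
  set.seed(5)
  X <- matrix(runif(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y_true <- 1 + 2 * pmax(X[, 1] - 0.3, 0) - pmax(0.6 - X[, 2], 0)
  cv_sig <- cross_validate(X, y_true, mars_control(max_terms = 9),
                           k_folds = 10, seed = 1)
  expect_gt(cv_sig$r2_cv, 0.999)
  expect_lt(cv_sig$rmse, 0.01 * diff(range(y_true)))

  y_noise <- rnorm(200)
  cv_n <- cross_validate(X, y_noise, mars_control(max_terms = 9),
                         k_folds = 10, seed = 1)
  expect_lte(cv_n$r2_cv, 0.1)

  expect_error(cross_validate(X, y_true, k_folds = 1), "k_folds")
})

test_that("cross-validation is reproducible given the seed", {
  set.seed(6)
  X <- matrix(runif(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(100, 0, 0.1)
  cv1 <- cross_validate(X, y, mars_control(max_terms = 7), 5, seed = 33)
  cv2 <- cross_validate(X, y, mars_control(max_terms = 7), 5, seed = 33)
  expect_identical(cv1, cv2)
})

test_that("ANOVA decomposition ranks predictors by their contribution", {
  set.seed(7)
  X <- matrix(runif(600), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 * pmax(X[, 1] - 0.4, 0) + 0.01 * X[, 2]
  m <- fit_mars(X, y, mars_control(max_terms = 11))
  imp <- anova_decompose(m, X, y)
  expect_equal(imp$importance[imp$predictor_name == "a"], 100)
  expect_lt(imp$importance[imp$predictor_name == "b"], 10)
  expect_lt(imp$importance[imp$predictor_name == "c"], 1)

  # a predictor with no terms has importance exactly 0
  m_hand <- structure(list(
    intercept = 0,
    terms = list(list(coefficient = 3, factors = list(
      list(var = 1L, knot = 0.4, dir = 1L, order = "linear",
           t_lo = NA, t_hi = NA)))),
    M = 1L, predictor_names = c("a", "b", "c"), response_name = "y",
    control = mars_control()), class = "mars_model")
  imp_h <- anova_decompose(m_hand, X, y)
  expect_equal(imp_h$importance[imp_h$predictor_name == "a"], 100)
  expect_equal(imp_h$importance[imp_h$predictor_name %in% c("b", "c")],
               c(0, 0))
  expect_equal(imp_h$n_terms_involving[imp_h$predictor_name == "c"], 0L)

  # single-predictor model: that predictor 100, the rest 0
  m1 <- fit_mars(X[, 1, drop = FALSE], y, mars_control(max_terms = 11))
  imp1 <- anova_decompose(m1, X[, 1, drop = FALSE], y)
  expect_equal(imp1$importance, 100)

  # intercept-only model: all zeros
  m0 <- fit_mars(X, rep(1, 200), mars_control(max_terms = 5))
  expect_true(all(anova_decompose(m0, X, rep(1, 200))$importance == 0))
})

test_that("model serialization round-trips exactly", {
  set.seed(8)
  X <- matrix(runif(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- pmax(X[, 1] - 0.5, 0) + 0.3 * X[, 2] + rnorm(100, 0, 0.02)
  m <- fit_mars(X, y, mars_control(max_terms = 9, order = "cubic"))
  f <- tempfile(fileext = ".json")
  write_mars_model(m, f)
  m2 <- read_mars_model(f)
  Xn <- matrix(runif(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(predict(m2, Xn), predict(m, Xn))
  expect_identical(m2$fit_stats$rss, m$fit_stats$rss)
  expect_identical(m2$M, m$M)
})
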