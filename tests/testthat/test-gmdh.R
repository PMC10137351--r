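test_that("quadratic neuron fits recover known coefficient patterns", {
  set.seed(101)
  d <- random_design(12L)
  # constant target
  n1 <- fit_neuron(d$xi[1:10], d$xj[1:10], rep(5, 10))
  expect_equal(unname(n1$coefficients), c(5, 0, 0, 0, 0, 0), tolerance = 1e-9)
  # pure interaction term
  n2 <- fit_neuron(d$xi, d$xj, d$xi * d$xj)
  expect_equal(unname(n2$coefficients), c(0, 0, 0, 0, 0, 1), tolerance = 1e-9)
  # mixed polynomial, cross-checked against the normal-equations oracle
  set.seed(202)
  xi <- runif(20); xj <- runif(20)
  y <- 1 + 2 * xi + 3 * xj + 0.5 * xi^2
  n3 <- fit_neuron(xi, xj, y)
  expect_equal(unname(n3$coefficients), c(1, 2, 3, 0.5, 0, 0), tolerance = 1e-8)
  expect_equal(unname(n3$coefficients), oracle_quad_fit(xi, xj, y),
               tolerance = 1e-8)
})

test_that("neuron fits match the normal-equations oracle on random designs", {
  set.seed(303)
  for (rep in 1:20) {
    d <- random_design(25L)
    y <- rnorm(25)
    fit <- fit_neuron(d$xi, d$xj, y)
    expect_equal(unname(fit$coefficients), oracle_quad_fit(d$xi, d$xj, y),
                 tolerance = 1e-8)
  }
})

test_that("neuron fits are locally optimal in the sum of squared residuals", {
  set.seed(404)
  d <- random_design(40L)
  y <- rnorm(40)
  fit <- fit_neuron(d$xi, d$xj, y)
  ssr <- function(cf) {
    sum((y - drop(cbind(1, d$xi, d$xj, d$xi^2, d$xj^2, d$xi * d$xj) %*% cf))^2)
  }
  base <- ssr(fit$coefficients)
  for (k in 1:6) for (delta in c(-1e-3, 1e-3)) {
    cf <- fit$coefficients
    cf[k] <- cf[k] + delta
    expect_gte(ssr(cf), base)
  }
})

test_that("rank-deficient designs return the deterministic minimum-norm fit", {
  xi <- rep(0.5, 10)                     # constant feature
  xj <- seq(0.1, 1, length.out = 10)
  y <- 2 + xj
  fit1 <- fit_neuron(xi, xj, y)
  fit2 <- fit_neuron(xi, xj, y)
  expect_identical(fit1$coefficients, fit2$coefficients)
  pred <- neuron_predict(fit1, xi, xj)
  expect_equal(pred, y, tolerance = 1e-9)
})

test_that("neuron fit input contracts are enforced", {
  expect_error(fit_neuron(1:5, 1:5, 1:5), "underdetermined neuron fit")
  expect_error(fit_neuron(c(1:9, NA), 1:10, 1:10), "non-finite")
  expect_error(fit_neuron(1:10, 1:9, 1:10), "same length")
})

test_that("neuron evaluation follows the quadratic form", {
  n <- list(coefficients = c(1, 0, 0, 0, 0, 0))
  expect_equal(neuron_predict(n, runif(5), runif(5)), rep(1, 5))
  n2 <- list(coefficients = c(0, 1, 1, 0, 0, 0))
  expect_equal(neuron_predict(n2, 0.2, 0.3), 0.5)
  n3 <- list(coefficients = c(1, 2, 3, 0.5, 0, 0))
  expect_equal(neuron_predict(n3, 1, 1), 6.5)
  expect_error(neuron_predict(n3, 1:3, 1:2), "lengths differ")
})

test_that("build_layer evaluates every pair and selects by the external criterion", {
  set.seed(505)
  n <- 80L
  feats <- matrix(runif(n * 4), n, 4)
  # target generated exactly by a quadratic of features 1 and 2
  y <- 0.3 + feats[, 1] - 2 * feats[, 2] + feats[, 1] * feats[, 2]
  fit_idx <- 1:56; sel_idx <- 57:80
  layer <- build_layer(feats, y, fit_idx, sel_idx, width_k = 6L)
  expect_length(layer$neurons, 6L)   # C(4,2) candidates, all kept
  best <- layer$neurons[[1L]]
  expect_identical(c(best$input_i, best$input_j), c(1L, 2L))
  expect_lt(best$criterion_score, 1e-9)
  # independent oracle: exhaustively score all pairs with the normal equations
  oracle_scores <- apply(utils::combn(4, 2), 2, function(p) {
    cf <- oracle_quad_fit(feats[fit_idx, p[1]], feats[fit_idx, p[2]], y[fit_idx])
    pr <- drop(cbind(1, feats[sel_idx, p[1]], feats[sel_idx, p[2]],
                     feats[sel_idx, p[1]]^2, feats[sel_idx, p[2]]^2,
                     feats[sel_idx, p[1]] * feats[sel_idx, p[2]]) %*% cf)
    sqrt(mean((y[sel_idx] - pr)^2))
  })
  got <- vapply(layer$neurons, `[[`, numeric(1), "criterion_score")
  expect_equal(got, sort(oracle_scores), tolerance = 1e-8)
  # survivors sorted ascending by score
  expect_true(!is.unsorted(got))
})

test_that("layer pruning keeps the requested width and rejects bad subsets", {
  set.seed(506)
  feats <- matrix(runif(200), 50, 4)
  y <- rnorm(50)
  layer <- build_layer(feats, y, 1:35, 36:50, width_k = 4L)
  expect_length(layer$neurons, 4L)
  expect_error(build_layer(feats[, 1, drop = FALSE], y, 1:35, 36:50, 2L),
               "cannot pair features")
  expect_error(build_layer(feats, y, 1:35, 30:50, 2L), "disjoint")
  expect_error(build_layer(feats, y, integer(0), 36:50, 2L), "non-empty")
})

test_that("a single-neuron target is recovered exactly by the network", {
  set.seed(607)
  n <- 120L
  X <- cbind(phi = runif(n), theta = runif(n), r = runif(n), v = runif(n))
  y <- 0.2 + 1.5 * X[, 1] - 0.7 * X[, 3] +
    0.4 * X[, 1]^2 - 0.1 * X[, 3]^2 + 0.9 * X[, 1] * X[, 3]
  model <- fit_gmdh(X, y, seed = 5)
  expect_length(model$layers, 1L)     # growth stops at numerical zero
  pred <- predict(model, X)
  expect_lt(sqrt(mean((y - pred)^2)), 1e-8)
})

test_that("network fitting is bit-deterministic given the seed", {
  set.seed(708)
  n <- 90L
  X <- matrix(runif(n * 4), n, 4)
  y <- X[, 1]^2 + X[, 2] * X[, 4] + 0.05 * sin(10 * X[, 3])
  m1 <- fit_gmdh(X, y, gmdh_control(width_k = 3L, max_layers = 3L), seed = 42)
  m2 <- fit_gmdh(X, y, gmdh_control(width_k = 3L, max_layers = 3L), seed = 42)
  expect_identical(lapply(m1$layers, function(l) lapply(l$neurons, `[[`, "coefficients")),
                   lapply(m2$layers, function(l) lapply(l$neurons, `[[`, "coefficients")))
  expect_identical(predict(m1, X), predict(m2, X))
})

test_that("retained layers improve the selection criterion monotonically", {
  set.seed(809)
  n <- 200L
  X <- matrix(runif(n * 4), n, 4)
  y <- exp(X[, 1]) * (1 + X[, 2]) + X[, 3]^3
  for (ctrl in list(gmdh_control(width_k = 4L, max_layers = 6L),
                    gmdh_control(max_layers = 25L, growth = "cascade"))) {
    model <- fit_gmdh(X, y, ctrl, seed = 7)
    best <- vapply(model$layers,
                   function(l) l$neurons[[1L]]$criterion_score, numeric(1))
    expect_true(all(diff(best) < 0))
  }
})

test_that("prediction validates inputs and warns on extrapolation", {
  set.seed(910)
  X <- matrix(runif(240), 60, 4)
  y <- X[, 1] + X[, 2]
  model <- fit_gmdh(X, y, seed = 1)
  expect_error(predict(model, X[, 1:3]), "expected 4 input columns")
  expect_warning(predict(model, matrix(2, 1, 4)), "outside the training range")
  expect_silent(p <- predict(model, X))
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(runif(240), 60, 4)
  expect_error(fit_gmdh(X[, 1:3], rnorm(60)), "at least 4 input columns")
  expect_error(fit_gmdh(X, rep(1, 60)), "degenerate target")
  expect_error(fit_gmdh(X[1:20, ], rnorm(20)), "at least 50 rows")
})

test_that("log target transform reproduces a multiplicative field", {
  set.seed(117)
  n <- 150L
  X <- cbind(runif(n, 0, 20), runif(n, 0, 360), runif(n, 250, 1250),
             runif(n, 40, 140))
  y <- 2e-6 * exp(-0.1 * X[, 1]) * (250 / X[, 3])^2
  ctrl <- gmdh_control(max_layers = 40L, growth = "cascade",
                       target_transform = "log")
  model <- fit_gmdh(X, y, ctrl, seed = 3)
  pred <- predict(model, X)
  expect_true(all(pred > 0))
  expect_lt(median(abs(pred - y) / y), 0.02)
  expect_error(fit_gmdh(X, y - 1, ctrl, seed = 3), "positive")
})

test_that("model JSON round trip is bit-faithful and predicts identically", {
  set.seed(121)
  X <- matrix(runif(320), 80, 4)
  y <- X[, 1] * X[, 2] + 0.3 * X[, 4]^2
  for (ctrl in list(gmdh_control(width_k = 3L, max_layers = 2L),
                    gmdh_control(max_layers = 10L, growth = "cascade",
                                 target_transform = "log"))) {
    yy <- if (ctrl$target_transform == "log") y + 1 else y
    model <- fit_gmdh(X, yy, ctrl, seed = 9)
    path <- tempfile(fileext = ".json")
    write_gmdh_model(model, path)
    back <- read_gmdh_model(path)
    expect_identical(
      lapply(model$layers, function(l) lapply(l$neurons, `[[`, "coefficients")),
      lapply(back$layers, function(l) lapply(l$neurons, `[[`, "coefficients")))
    expect_identical(predict(model, X), predict(back, X))
    unlink(path)
  }
})
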