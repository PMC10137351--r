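# Group Method of Data Handling (GMDH) polynomial network.
#
# The network grows layers of quadratic two-input units
#   Z = c1 + c2*xi + c3*xj + c4*xi^2 + c5*xj^2 + c6*xi*xj,
# each fit by least squares on a "fit" subset of the training rows and ranked
# by its RMSE on a disjoint "select" subset (the external regularity
# criterion). The best units survive; their outputs become the candidate
# inputs of the next layer. Stacking quadratic units realizes high-order
# Kolmogorov-Gabor polynomials of the raw inputs.

#' Training settings for the GMDH network
#'
#' @param width_k neurons retained per layer (layer width). Default 4.
#' @param max_layers maximum number of layers grown. Default 2. Growth also
#'   stops earlier when a new layer fails to improve the best selection-subset
#'   RMSE of the previous layer.
#' @param inner_split fraction of the training rows used to fit neuron
#'   coefficients; the remainder forms the selection subset that scores them.
#'   Default 0.7.
#' @param min_rows minimum number of training rows accepted. Default 50.
#' @param growth layer-growth scheme. `"compose"` (default, the classical
#'   multilayer scheme): each layer pairs the previous layer's surviving
#'   neuron outputs and the best final-layer neuron is the network output.
#'   `"cascade"`: each layer holds the single external-criterion-winning
#'   neuron fit to the current residual over a pool of the raw inputs and
#'   recent layer outputs; the network output is the accumulated sum. The
#'   cascade converges far deeper on smooth multiplicative fields (see the
#'   package vignette) at the cost of a non-classical topology.
#' @param target_transform `"none"` (default) fits the kerma values as-is;
#'   `"log"` fits log-kerma (requires strictly positive targets), which turns
#'   the field's multiplicative structure additive and makes least squares
#'   minimize relative rather than absolute error.
#' @param pool_cap in cascade growth, the maximum number of candidate
#'   features retained (raw inputs plus the most recent layer outputs).
#' @return a list of class `gmdh_control`.
#' @export
gmdh_control <- function(width_k = 4L, max_layers = 2L,
                         inner_split = 0.7, min_rows = 50L,
                         growth = c("compose", "cascade"),
                         target_transform = c("none", "log"),
                         pool_cap = 24L) {
  growth <- match.arg(growth)
  target_transform <- match.arg(target_transform)
  if (width_k < 1L) abort("width_k must be at least 1")
  if (max_layers < 1L) abort("max_layers must be at least 1")
  if (inner_split <= 0 || inner_split >= 1)
    abort("inner_split must lie strictly between 0 and 1")
  if (pool_cap < 6L) abort("pool_cap must be at least 6")
  structure(list(width_k = as.integer(width_k),
                 max_layers = as.integer(max_layers),
                 inner_split = inner_split,
                 min_rows = as.integer(min_rows),
                 growth = growth,
                 target_transform = target_transform,
                 pool_cap = as.integer(pool_cap)),
            class = "gmdh_control")
}

# Minimum-norm least squares via SVD; singular values below tol * max(d)
# are treated as zero so rank-deficient designs (e.g. a constant feature)
# yield a deterministic solution.
lsq_min_norm <- function(A, y, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) return(rep(0, ncol(A)))
  drop(sv$v[, keep, drop = FALSE] %*%
         (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
}

quad_design <- function(x_i, x_j) {
  cbind(1, x_i, x_j, x_i^2, x_j^2, x_i * x_j, deparse.level = 0)
}

#' Fit one quadratic GMDH neuron by least squares
#'
#' Finds the six coefficients of
#' Z = c1 + c2*xi + c3*xj + c4*xi^2 + c5*xj^2 + c6*xi*xj minimizing the sum
#' of squared residuals against `y`. Rank-deficient designs return the
#' minimum-norm solution.
#'
#' @param x_i,x_j numeric vectors, the two input features.
#' @param y numeric vector, the target.
#' @param input_i,input_j optional indices recording which features feed the
#'   neuron (stored on the returned object).
#' @return an object of class `gmdh_neuron` with fields `input_i`, `input_j`,
#'   `coefficients` (length 6, named c1..c6) and `criterion_score`
#'   (NA until the neuron is scored by [build_layer()]).
#' @examples
#' set.seed(1)
#' xi <- runif(20); xj <- runif(20)
#' n <- fit_neuron(xi, xj, 1 + 2 * xi + 3 * xj + 0.5 * xi^2)
#' round(n$coefficients, 6)
#' @export
fit_neuron <- function(x_i, x_j, y, input_i = 1L, input_j = 2L) {
  if (length(x_i) != length(x_j) || length(x_i) != length(y))
    abort("x_i, x_j and y must have the same length")
  if (length(y) < 6L) abort("underdetermined neuron fit: need at least 6 samples")
  if (!all(is.finite(x_i), is.finite(x_j), is.finite(y)))
    abort("non-finite values in neuron fit inputs")
  cf <- lsq_min_norm(quad_design(x_i, x_j), y)
  names(cf) <- paste0("c", 1:6)
  structure(list(input_i = as.integer(input_i), input_j = as.integer(input_j),
                 coefficients = cf, criterion_score = NA_real_),
            class = "gmdh_neuron")
}

#' Evaluate a quadratic neuron
#'
#' @param neuron a `gmdh_neuron` (or any list with a 6-vector `coefficients`).
#' @param x_i,x_j numeric vectors of equal length.
#' @return numeric vector of neuron outputs.
#' @export
neuron_predict <- function(neuron, x_i, x_j) {
  if (length(x_i) != length(x_j)) abort("x_i and x_j lengths differ")
  cf <- neuron$coefficients
  stopifnot(length(cf) == 6L)
  drop(quad_design(x_i, x_j) %*% cf)
}

#' Build one GMDH layer by exhaustive pairing and external-criterion selection
#'
#' Fits one candidate neuron per unordered pair of feature columns on the fit
#' subset, scores each by RMSE on the disjoint selection subset, discards the
#' "dead" neurons and keeps the `width_k` best, sorted by ascending score
#' (ties broken by input indices).
#'
#' @param features numeric matrix, N rows x m >= 2 feature columns.
#' @param y numeric target vector of length N.
#' @param fit_idx,select_idx disjoint, non-empty row index vectors.
#' @param width_k number of surviving neurons.
#' @return an object of class `gmdh_layer` holding the surviving neurons.
#' @export
build_layer <- function(features, y, fit_idx, select_idx, width_k) {
  features <- as.matrix(features)
  m <- ncol(features)
  if (m < 2L) abort("cannot pair features: need at least 2 columns")
  if (width_k < 1L) abort("width_k must be at least 1")
  if (length(fit_idx) == 0L || length(select_idx) == 0L)
    abort("fit and select subsets must both be non-empty")
  if (length(intersect(fit_idx, select_idx)) > 0L)
    abort("fit and select subsets must be disjoint")

  pairs <- utils::combn(m, 2L)
  cands <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    nrn <- fit_neuron(features[fit_idx, i], features[fit_idx, j], y[fit_idx],
                      input_i = i, input_j = j)
    pred <- neuron_predict(nrn, features[select_idx, i], features[select_idx, j])
    nrn$criterion_score <- sqrt(mean((y[select_idx] - pred)^2))
    cands[[p]] <- nrn
  }
  score <- vapply(cands, `[[`, numeric(1), "criterion_score")
  ii <- vapply(cands, `[[`, integer(1), "input_i")
  jj <- vapply(cands, `[[`, integer(1), "input_j")
  keep <- order(score, ii, jj)[seq_len(min(width_k, length(cands)))]
  structure(list(neurons = cands[keep]), class = "gmdh_layer")
}

layer_outputs <- function(layer, features) {
  out <- vapply(layer$neurons, function(n) {
    neuron_predict(n, features[, n$input_i], features[, n$input_j])
  }, numeric(nrow(features)))
  matrix(out, nrow = nrow(features))
}

#' Fit a GMDH polynomial network
#'
#' Normalizes inputs and output to [0, 1], splits the rows into fit and
#' selection subsets with a seeded shuffle, then grows layers: each layer
#' pairs the previous layer's surviving neuron outputs (the raw inputs feed
#' only the first layer), keeps the `width_k` units with the lowest
#' selection-subset RMSE, and growth stops when a new layer fails to improve
#' on the previous layer's best score or `max_layers` is reached. The best
#' unit of the final layer is the network output; predictions are returned in
#' original (denormalized) units.
#'
#' @param X numeric matrix with at least 4 columns — canonically tangent
#'   angle phi (deg), polar angle theta (deg), distance r (mm) and tube
#'   voltage V (kV).
#' @param y numeric target vector (air kerma, original units).
#' @param control a [gmdh_control()] list.
#' @param seed integer seed driving the internal fit/select split.
#' @return an object of class `gmdh_model`.
#' @seealso [predict.gmdh_model()], [write_gmdh_model()]
#' @export
fit_gmdh <- function(X, y, control = gmdh_control(), seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 4L)
    abort("need at least 4 input columns (phi, theta, r, V)")
  n <- nrow(X)
  if (length(y) != n) abort("X and y row counts differ")
  if (n < control$min_rows)
    abort(sprintf("need at least %d rows, got %d", control$min_rows, n))
  if (max(y) == min(y)) abort("degenerate target: y is constant")
  yt <- if (control$target_transform == "log") {
    if (any(y <= 0)) abort("log target transform requires positive values")
    log(y)
  } else y

  norm <- fit_normalization(cbind(X, .y = yt))
  m <- ncol(X)
  Z <- normalize_columns(norm, cbind(X, yt))
  Xn <- Z[, seq_len(m), drop = FALSE]
  yn <- Z[, m + 1L]

  split_seed <- derive_seed(seed, "inner-split")
  perm <- with_local_seed(split_seed, sample.int(n))
  n_fit <- max(1L, min(n - 1L, floor(control$inner_split * n)))
  fit_idx <- perm[seq_len(n_fit)]
  select_idx <- perm[(n_fit + 1L):n]

  layers <- list()
  best_prev <- Inf
  if (control$growth == "compose") {
    feats <- Xn
    for (depth in seq_len(control$max_layers)) {
      layer <- build_layer(feats, yn, fit_idx, select_idx, control$width_k)
      best <- layer$neurons[[1L]]$criterion_score
      if (best >= best_prev) break # no improvement: discard layer, stop
      layers[[depth]] <- layer
      best_prev <- best
      if (best <= 1e-12) break     # selection RMSE at numerical zero
      feats <- layer_outputs(layer, feats)
      if (ncol(feats) < 2L) break  # a single survivor cannot be paired further
    }
  } else {
    # cascade: each layer's winner is fit to the residual of the accumulated
    # model, so its criterion score IS the model's selection RMSE after the
    # layer; the candidate pool holds the raw inputs plus recent outputs.
    pool <- Xn
    resid <- yn
    for (depth in seq_len(control$max_layers)) {
      layer <- build_layer(pool, resid, fit_idx, select_idx, 1L)
      best <- layer$neurons[[1L]]$criterion_score
      if (best >= best_prev) break
      layers[[depth]] <- layer
      best_prev <- best
      out <- layer_outputs(layer, pool)[, 1L]
      resid <- resid - out
      pool <- cap_pool(cbind(pool, out), m, control$pool_cap)
      if (best <= 1e-12) break
    }
  }
  if (length(layers) == 0L)
    abort("no layer improved the selection criterion; cannot build model")

  structure(
    list(layers = layers, normalization = norm,
         n_raw_inputs = m, output_neuron = 1L,
         growth = control$growth,
         target_transform = control$target_transform,
         pool_cap = control$pool_cap,
         control = control, seed = as.integer(seed)),
    class = "gmdh_model"
  )
}

# keep the m raw-input columns and the most recent outputs, at most cap total
cap_pool <- function(pool, m, cap) {
  if (ncol(pool) <= cap) return(pool)
  keep_out <- (ncol(pool) - (cap - m - 1L)):ncol(pool)
  pool[, c(seq_len(m), keep_out), drop = FALSE]
}

#' Predict air kerma with a fitted GMDH network
#'
#' Deterministic: inputs are normalized with the parameters stored in the
#' model, propagated through the layers, and the output unit's value is
#' mapped back to original units. Inputs outside the training range are
#' extrapolated (polynomials evaluate everywhere) with a warning.
#'
#' @param object a `gmdh_model`.
#' @param newdata numeric matrix or data frame with `n_raw_inputs` columns.
#' @param ... unused.
#' @return numeric vector of predictions in original units.
#' @export
predict.gmdh_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_raw_inputs)
    abort(sprintf("expected %d input columns, got %d",
                  object$n_raw_inputs, ncol(X)))
  norm <- object$normalization
  m <- object$n_raw_inputs
  lo <- norm$min[seq_len(m)]; hi <- norm$max[seq_len(m)]
  outside <- any(sweep(X, 2L, lo, `<`)) || any(sweep(X, 2L, hi, `>`))
  if (outside)
    warning("inputs outside the training range: polynomial extrapolation",
            call. = FALSE)
  feats <- normalize_columns(norm, cbind(X, 0))[, seq_len(m), drop = FALSE]
  if ((object$growth %||% "compose") == "compose") {
    for (layer in object$layers) feats <- layer_outputs(layer, feats)
    yn <- feats[, object$output_neuron]
  } else {
    pool <- feats
    yn <- numeric(nrow(X))
    for (layer in object$layers) {
      out <- layer_outputs(layer, pool)[, 1L]
      yn <- yn + out
      pool <- cap_pool(cbind(pool, out), m, object$pool_cap)
    }
  }
  ycol <- m + 1L
  yt <- if (norm$constant[ycol]) rep(norm$min[ycol], nrow(X))
        else yn * (norm$max[ycol] - norm$min[ycol]) + norm$min[ycol]
  if ((object$target_transform %||% "none") == "log") exp(yt) else yt
}

#' @export
print.gmdh_model <- function(x, ...) {
  widths <- vapply(x$layers, function(l) length(l$neurons), integer(1))
  arch <- if ((x$growth %||% "compose") == "cascade")
    sprintf("residual cascade of %d neurons", length(x$layers))
  else
    sprintf("%d layer(s), width %s", length(x$layers),
            paste(widths, collapse = "/"))
  cat(sprintf("GMDH polynomial network: %d raw inputs, %s%s\n",
              x$n_raw_inputs, arch,
              if ((x$target_transform %||% "none") == "log")
                ", log target" else ""))
  cat(sprintf("  final selection-subset RMSE (normalized units): %.3e\n",
              x$layers[[length(x$layers)]]$neurons[[x$output_neuron]]$criterion_score))
  invisible(x)
}
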