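# Error criteria and the train/evaluate experiment harness.

#' Mean relative error, in percent
#'
#' 100/N * sum(|expected - predicted| / denominator). The default denominator
#' is the predicted value; `denominator = "expected"` gives the conventional
#' variant.
#'
#' @param expected,predicted numeric vectors of equal length.
#' @param denominator `"predicted"` (default) or `"expected"`.
#' @return MRE in percent (scale-invariant).
#' @export
mre_percent <- function(expected, predicted,
                        denominator = c("predicted", "expected")) {
  denominator <- match.arg(denominator)
  if (length(expected) != length(predicted))
    abort("expected and predicted lengths differ")
  if (length(expected) < 1L) abort("need at least one pair")
  den <- if (denominator == "predicted") predicted else expected
  if (any(den == 0)) abort("division by zero in relative error")
  100 * mean(abs(expected - predicted) / den)
}

#' Root mean square error
#'
#' @param expected,predicted numeric vectors of equal length.
#' @return sqrt(mean((expected - predicted)^2)), in the data's units.
#' @export
rmse <- function(expected, predicted) {
  if (length(expected) != length(predicted))
    abort("expected and predicted lengths differ")
  if (length(expected) < 1L) abort("need at least one pair")
  sqrt(mean((expected - predicted)^2))
}

eval_report <- function(expected, predicted, subset_label, split_seed,
                        denominator = "predicted") {
  structure(
    list(n_samples = length(expected),
         mre_percent = mre_percent(expected, predicted,
                                   denominator = denominator),
         rmse = rmse(expected, predicted),
         split_seed = as.integer(split_seed),
         subset_label = subset_label),
    class = "kerma_eval_report"
  )
}

#' @export
print.kerma_eval_report <- function(x, ...) {
  cat(sprintf("%s subset: n = %d, MRE = %.4f%%, RMSE = %.4e\n",
              x$subset_label, x$n_samples, x$mre_percent, x$rmse))
  invisible(x)
}

#' Train a GMDH network on a kerma dataset and evaluate it
#'
#' Shuffles the dataset with a seeded permutation, trains on the first
#' floor(split_fraction * N) rows and evaluates on both subsets in original
#' units. On the default 8250-row grid the 0.7 split gives exactly 5775
#' training and 2475 test rows.
#'
#' @param dataset data frame with columns `phi_deg`, `theta_deg`, `r_mm`,
#'   `v_kv`, `kerma` (as written by [generate_dataset()]).
#' @param control a [gmdh_control()].
#' @param split_fraction training fraction, strictly between 0 and 1.
#'   Default 0.7.
#' @param seed master integer seed (drives the outer split and the network's
#'   internal fit/select split through independent derived streams).
#' @param denominator relative-error denominator, see [mre_percent()].
#' @return a list of class `gmdh_experiment` with elements `model`,
#'   `train` and `test` (evaluation reports), and `split` (row indices).
#' @export
run_experiment <- function(dataset, control = gmdh_control(),
                           split_fraction = 0.7, seed = 1L,
                           denominator = "predicted") {
  req <- c("phi_deg", "theta_deg", "r_mm", "v_kv", "kerma")
  miss <- setdiff(req, names(dataset))
  if (length(miss) > 0L)
    abort(sprintf("dataset is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  n <- nrow(dataset)
  if (n < 50L) abort("dataset must hold at least 50 rows")
  if (split_fraction <= 0 || split_fraction >= 1)
    abort("split_fraction must lie strictly between 0 and 1")

  perm <- with_local_seed(derive_seed(seed, "outer-split"), sample.int(n))
  n_train <- floor(split_fraction * n)
  train_idx <- perm[seq_len(n_train)]
  test_idx <- perm[(n_train + 1L):n]

  Xcols <- c("phi_deg", "theta_deg", "r_mm", "v_kv")
  X <- as.matrix(dataset[Xcols])
  y <- dataset$kerma
  model <- fit_gmdh(X[train_idx, , drop = FALSE], y[train_idx],
                    control = control, seed = derive_seed(seed, "gmdh-fit"))

  pred_train <- predict(model, X[train_idx, , drop = FALSE])
  pred_test <- predict(model, X[test_idx, , drop = FALSE])
  structure(
    list(model = model,
         train = eval_report(y[train_idx], pred_train, "train", seed,
                             denominator),
         test = eval_report(y[test_idx], pred_test, "test", seed,
                            denominator),
         split = list(train = train_idx, test = test_idx),
         seed = as.integer(seed)),
    class = "gmdh_experiment"
  )
}

#' @export
print.gmdh_experiment <- function(x, ...) {
  cat("GMDH air-kerma experiment (seed", x$seed, ")\n")
  print(x$model)
  print(x$train)
  print(x$test)
  invisible(x)
}
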