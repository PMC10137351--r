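# Min-max normalization of model inputs and output. The network is fit in
# normalized [0, 1] coordinates and predictions are mapped back to original
# units, so all error reports are in the units of the data.

#' Fit per-column min-max normalization
#'
#' Computes, per column, the minimum and maximum over the supplied samples.
#' Normalization maps each column's observed range onto [0, 1]. Columns whose
#' range is degenerate (max == min) are flagged constant and normalize to 0.
#'
#' @param x numeric matrix or data frame (rows = samples, columns = variables).
#' @return an object of class `kerma_normalization` with fields `min`, `max`,
#'   `constant` (logical per column) and `columns` (names).
#' @examples
#' np <- fit_normalization(cbind(a = c(250, 500, 750, 1000, 1250)))
#' normalize_columns(np, cbind(a = 750))  # 0.5
#' @export
fit_normalization <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) abort("empty dataset")
  if (nrow(x) < 2L) abort("need at least 2 samples to fit normalization")
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("non-finite value at row %d, column %s",
                  bad[1L, 1L], colnames(x)[bad[1L, 2L]] %||% bad[1L, 2L]))
  }
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  structure(
    list(min = mins, max = maxs, constant = maxs == mins,
         columns = colnames(x)),
    class = "kerma_normalization"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply min-max normalization
#'
#' @param params a `kerma_normalization` object.
#' @param x matrix with the same columns the parameters were fit on.
#' @return matrix of the same shape, each column mapped by
#'   (v - min) / (max - min); constant columns map to 0.
#' @export
normalize_columns <- function(params, x) {
  x <- as.matrix(x)
  stopifnot(inherits(params, "kerma_normalization"),
            ncol(x) == length(params$min))
  out <- x
  for (j in seq_len(ncol(x))) {
    if (params$constant[j]) {
      out[, j] <- 0
    } else {
      out[, j] <- (x[, j] - params$min[j]) / (params$max[j] - params$min[j])
    }
  }
  out
}

#' Invert min-max normalization
#'
#' @inheritParams normalize_columns
#' @return matrix in original units; constant columns are restored to their
#'   single observed value.
#' @export
denormalize_columns <- function(params, x) {
  x <- as.matrix(x)
  stopifnot(inherits(params, "kerma_normalization"),
            ncol(x) == length(params$min))
  out <- x
  for (j in seq_len(ncol(x))) {
    if (params$constant[j]) {
      out[, j] <- params$min[j]
    } else {
      out[, j] <- x[, j] * (params$max[j] - params$min[j]) + params$min[j]
    }
  }
  out
}
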