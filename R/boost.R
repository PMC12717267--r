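#' Fit gradient-boosted classification trees
#'
#' Compact in-package gradient boosting for binary outcomes with the usual
#' second-order regularized split gain and shrinkage. Supports the standard
#' knobs: learning rate `eta`, `max_depth`, `min_child_weight` (minimum
#' hessian per child), row `subsample`, per-tree column subsampling
#' `colsample_bytree`, and L2/L1/complexity penalties `lambda`, `alpha`,
#' `gamma`. Subsampling uses R's RNG, so fits are reproducible under
#' `set.seed()`.
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 outcome vector.
#' @param nrounds Number of boosting rounds.
#' @param eta,max_depth,min_child_weight,subsample,colsample_bytree,lambda,alpha,gamma
#'   Boosting hyperparameters.
#' @return A `gbt` model object.
#' @export
fit_gbt <- function(x, y, nrounds = 150, eta = 0.3, max_depth = 5,
                    min_child_weight = 2, subsample = 0.7,
                    colsample_bytree = 0.4, lambda = 1.5, alpha = 1e-5,
                    gamma = 0.3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  base <- min(max(mean(y), 1e-6), 1 - 1e-6)
  fit <- gbt_fit_cpp(x, y, as.integer(nrounds), eta, as.integer(max_depth),
                     min_child_weight, subsample, colsample_bytree, lambda,
                     alpha, gamma, base)
  structure(
    list(trees = fit$trees, base_margin = fit$base_margin,
         feature_names = colnames(x),
         params = list(nrounds = nrounds, eta = eta, max_depth = max_depth,
                       min_child_weight = min_child_weight,
                       subsample = subsample,
                       colsample_bytree = colsample_bytree, lambda = lambda,
                       alpha = alpha, gamma = gamma)),
    class = "gbt"
  )
}

#' @param object A `gbt` model.
#' @param newdata Feature matrix with the training columns.
#' @param type `"response"` (probabilities) or `"margin"`.
#' @param ... Unused.
#' @rdname fit_gbt
#' @export
predict.gbt <- function(object, newdata, type = c("response", "margin"),
                        ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (!all(object$feature_names %in% colnames(x))) {
      stop("missing feature columns: ",
           paste(setdiff(object$feature_names, colnames(x)), collapse = ", "))
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  storage.mode(x) <- "double"
  margin <- gbt_predict_cpp(list(trees = object$trees,
                                 base_margin = object$base_margin), x)
  if (type == "margin") margin else 1 / (1 + exp(-margin))
}

#' @export
print.gbt <- function(x, ...) {
  cat(sprintf(
    "gbt: %d trees, depth <= %d, eta = %.2f\n",
    length(x$trees), x$params$max_depth, x$params$eta
  ))
  invisible(x)
}
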