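#' Regression error metrics for IE% predictions
#'
#' Computes the four metrics used to judge inhibition-efficiency models:
#' \itemize{
#' \item MAPE \eqn{= (1/n) \sum |(y_i - \hat y_i)/y_i| \times 100} (percent);
#'   requires all \eqn{y_i \neq 0};
#' \item MSE \eqn{= (1/n) \sum (y_i - \hat y_i)^2} (percent squared);
#' \item RMSE \eqn{= \sqrt{MSE}} (percent);
#' \item SD: the n-1 sample standard deviation of the residuals
#'   \eqn{\hat y_i - y_i} about their mean (percent). This is the only
#'   reading of the residual-spread statistic consistent with SD < RMSE in
#'   published (SD, RMSE) pairs for this class of model.
#' }
#'
#' @param y observed values (length >= 2).
#' @param yhat predicted values, same length.
#' @return A list of class `qsar_metrics` with elements `mape`, `sd`, `mse`,
#'   `rmse`. When some `y` is zero, `mape` is `NA` with a warning; the other
#'   metrics are still returned.
#' @examples
#' compute_metrics(c(100, 50), c(90, 55))  # MAPE 10, MSE 62.5
#' @export
compute_metrics <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat), length(y) == length(yhat),
            length(y) >= 2L, all(is.finite(y)), all(is.finite(yhat)))
  res <- yhat - y
  mse <- mean(res^2)
  mape <- if (any(y == 0)) {
    warning("MAPE undefined: some observed values are zero", call. = FALSE)
    NA_real_
  } else mean(abs(res / y)) * 100
  structure(list(mape = mape, sd = stats::sd(res), mse = mse,
                 rmse = sqrt(mse)),
            class = "qsar_metrics")
}

#' @export
print.qsar_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("MAPE = %s%%  SD = %s  MSE = %s  RMSE = %s\n",
              signif(x$mape, digits), signif(x$sd, digits),
              signif(x$mse, digits), signif(x$rmse, digits)))
  invisible(x)
}

#' Fivefold cross-validation with MSE-based model promotion
#'
#' Shuffles the records under a fixed seed, splits them into five near-equal
#' folds, and for each fold fits a FROLS model on the remaining four and
#' scores mean squared error on the held-out fold. The model from the fold
#' with the lowest validation MSE is promoted for downstream prediction.
#'
#' @param records compound table with `ie_obs` and the columns needed for
#'   `labels` (see [build_design_matrix()]).
#' @param seed integer seed controlling the fold assignment (the caller's
#'   random state is untouched).
#' @param rho,max_terms,min_gain passed to [frols_select()].
#' @param labels dictionary labels to offer the selector.
#' @param metal,omega_mode passed to [build_design_matrix()].
#' @param k number of folds (default 5).
#' @return Object of class `qsar_cv`: list with `fold_models` (list of
#'   `frols_model`), `fold_mse` (numeric k), `best_index`
#'   (argmin of `fold_mse`), `folds` (validation-fold id per record), `seed`.
#' @export
fivefold_cv <- function(records, seed, rho = 0.005, max_terms = NULL,
                        min_gain = 1e-6,
                        labels = names(descriptor_labels()),
                        metal = metal_reference(),
                        omega_mode = c("table_compatible", "standard"),
                        k = 5L) {
  omega_mode <- match.arg(omega_mode)
  stopifnot(is.data.frame(records), k >= 2L)
  n <- nrow(records)
  if (n < 2L * k)
    stopf("fivefold CV needs at least %d records with observed IE%%, got %d",
          2L * k, n, class = "corrqsar_insufficient_records")
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  fold_models <- vector("list", k)
  fold_mse <- numeric(k)
  for (f in seq_len(k)) {
    tr <- build_design_matrix(records[folds != f, , drop = FALSE], labels,
                              metal, omega_mode)
    va <- build_design_matrix(records[folds == f, , drop = FALSE], labels,
                              metal, omega_mode)
    m <- frols_select(tr, rho = rho, max_terms = max_terms,
                      min_gain = min_gain)
    fold_models[[f]] <- m
    fold_mse[f] <- mean((va$y - predict(m, va))^2)
  }
  structure(list(fold_models = fold_models, fold_mse = fold_mse,
                 best_index = which.min(fold_mse), folds = folds,
                 seed = as.integer(seed)),
            class = "qsar_cv")
}

#' @export
print.qsar_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d); validation MSE per fold:\n",
              length(x$fold_mse), x$seed))
  print(signif(x$fold_mse, 4))
  cat(sprintf("promoted model: fold %d (MSE = %.4g), terms: %s\n",
              x$best_index, x$fold_mse[x$best_index],
              paste(x$fold_models[[x$best_index]]$labels, collapse = ", ")))
  invisible(x)
}

#' The frozen published five-term IE% predictor
#'
#' The reference linear model relating inhibition efficiency to five
#' descriptors, with frozen coefficients (IE% per descriptor unit):
#' \deqn{\hat y = 812.1748\,x_7 + 33.1669\,x_{10} + 823.4630\,x_8 +
#'       6579.0080\,x_9 + 0.5287\,x_2}
#' where x2 = pKa, x7 = E_HOMO (eV), x8 = E_LUMO (eV), x9 = electrophilicity
#' (eV, table-compatible convention), x10 = Delta N.
#'
#' @return Named numeric vector of the five coefficients, in selection order
#'   (x7, x10, x8, x9, x2).
#' @examples
#' published_model()
#' @export
published_model <- function() {
  c(x7 = 812.1748, x10 = 33.1669, x8 = 823.4630, x9 = 6579.0080, x2 = 0.5287)
}

#' Predict IE% with the frozen published model
#'
#' Evaluates the [published_model()] dot product on descriptor values. The
#' `x9` electrophilicity must follow the table-compatible convention
#' (\eqn{\omega = \chi/4}, see [electrophilicity()]) for fidelity with the
#' model's training convention. Predictions are unclipped.
#'
#' @param descriptors a data.frame (or named list/vector for a single
#'   compound) providing `x2`, `x7`, `x8`, `x9`, `x10` — either by those
#'   labels or by descriptor column names (`pka`, `e_homo`, `e_lumo`,
#'   `omega`, `delta_n`).
#' @return Numeric vector of predicted IE%.
#' @examples
#' predict_published(c(x2 = 1, x7 = 0, x8 = 0, x9 = 0, x10 = 0))  # 0.5287
#' @export
predict_published <- function(descriptors) {
  if (!is.data.frame(descriptors)) descriptors <- as.data.frame(as.list(descriptors))
  map <- descriptor_labels()
  coefs <- published_model()
  vals <- matrix(NA_real_, nrow(descriptors), length(coefs),
                 dimnames = list(NULL, names(coefs)))
  for (lab in names(coefs)) {
    col <- if (lab %in% names(descriptors)) lab else map[[lab]]
    if (!col %in% names(descriptors))
      stopf("missing descriptor for term %s (column %s)", lab, map[[lab]],
            class = "corrqsar_unknown_label")
    vals[, lab] <- descriptors[[col]]
  }
  if (any(!is.finite(vals)))
    stopf("non-finite descriptor value for term(s): %s",
          paste(names(coefs)[apply(!is.finite(vals), 2, any)], collapse = ", "),
          class = "corrqsar_invalid_table")
  drop(vals %*% coefs)
}

#' Screen predicted efficiencies into application categories
#'
#' Partitions predictions into the screening bands used to shortlist
#' candidate inhibitors: `unrealistic` (> 100%, excluded as physically
#' impossible), `high` (>= 95%, the regime of industrial interest once model
#' error is allowed for), `moderate` (the intermediate band, by default
#' 84.92–95%), and `low`.
#'
#' @param predictions data.frame with columns `name` and `ie` (predicted
#'   IE%), or a numeric vector of predictions (names optional).
#' @param high lower bound of the high-efficiency band (default 95).
#' @param moderate lower bound of the moderate band (default 84.92).
#' @param unrealistic exclusion threshold (default 100; strictly above is
#'   excluded).
#' @return The input as a data.frame with a `category` factor column
#'   (levels `unrealistic`, `high`, `moderate`, `low`).
#' @examples
#' screen_predictions(data.frame(name = c("a", "b"), ie = c(106.31, 98.71)))
#' @export
screen_predictions <- function(predictions, high = 95, moderate = 84.92,
                               unrealistic = 100) {
  if (!is.data.frame(predictions)) {
    predictions <- data.frame(
      name = if (is.null(names(predictions))) seq_along(predictions)
             else names(predictions),
      ie = as.numeric(predictions))
  }
  stopifnot(all(c("name", "ie") %in% names(predictions)),
            moderate < high, high <= unrealistic)
  ie <- predictions$ie
  cat_ <- ifelse(ie > unrealistic, "unrealistic",
                 ifelse(ie >= high, "high",
                        ifelse(ie >= moderate, "moderate", "low")))
  predictions$category <- factor(cat_, levels = c("unrealistic", "high",
                                                  "moderate", "low"))
  predictions
}
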