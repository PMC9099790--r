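#' Error reduction ratio of a candidate term
#'
#' The fraction of the response's (uncentered) energy explained by a single
#' regressor: \eqn{ERR = (y^T p)^2 / [(p^T p)(y^T y)]}, the squared cosine
#' between `y` and `p`. Lies in \[0, 1\]; 1 means `p` spans `y` exactly, 0
#' means orthogonality.
#'
#' @param y response vector (nonzero norm).
#' @param p candidate regressor (nonzero norm, same length).
#' @return ERR fraction in \[0, 1\].
#' @examples
#' err_ratio(c(1, 2), c(1, 0))  # 0.2
#' @export
err_ratio <- function(y, p) {
  stopifnot(is.numeric(y), is.numeric(p), length(y) == length(p))
  yty <- sum(y^2); ptp <- sum(p^2)
  if (yty == 0 || ptp == 0)
    stopf("err_ratio undefined for zero-norm input",
          class = "corrqsar_division_by_zero")
  sum(y * p)^2 / (ptp * yty)
}

#' Least-squares weights for selected terms
#'
#' Solves \eqn{\min_\beta ||y - Z\beta||^2} by QR factorization. The selected
#' model is linear in its parameters, so once the term set is fixed the
#' weights are the ordinary least-squares solution; the residual is
#' orthogonal to every selected column.
#'
#' @param Z N x k matrix of the selected (original, non-orthogonalized)
#'   columns.
#' @param y length-N response.
#' @param tol relative rank tolerance for the QR decomposition.
#' @return Numeric weight vector beta of length k.
#' @examples
#' estimate_weights(cbind(1, 0:2), c(1, 2, 3))  # (1, 1)
#' @export
estimate_weights <- function(Z, y, tol = 1e-10) {
  Z <- as.matrix(Z)
  stopifnot(is.numeric(y), nrow(Z) == length(y))
  qz <- qr(Z, tol = tol)
  if (qz$rank < ncol(Z)) {
    bad <- sort(qz$pivot[seq(qz$rank + 1L, ncol(Z))])
    stopf("rank-deficient term matrix; offending column(s): %s",
          paste(bad, collapse = ", "), class = "corrqsar_rank_deficient")
  }
  beta <- qr.coef(qz, y)
  as.numeric(beta)[order(qz$pivot)][seq_len(ncol(Z))]
}

#' Forward regression orthogonal least squares (FROLS) term selection
#'
#' Greedy identification of a sparse linear model from a candidate
#' dictionary. The first term is the raw candidate with the highest error
#' reduction ratio ([err_ratio()]). From the second step onward every
#' remaining candidate is orthogonalized (classical Gram-Schmidt with one
#' reorthogonalization pass) against the orthogonal basis of the already
#' selected terms before its ERR is evaluated, so each new term is scored
#' only on information not yet captured. Selection stops when the
#' error-to-signal ratio \eqn{ESR = 1 - \sum ERR} drops to `rho` or below,
#' when no remaining candidate would reduce ESR by more than `min_gain`,
#' when `max_terms` terms are selected, or when the dictionary is exhausted;
#' the rule that fired is recorded. Final weights are re-estimated on the
#' original (non-orthogonal) selected columns via [estimate_weights()].
#'
#' Ties on ERR are broken by the lowest column index, so selection is
#' deterministic. A candidate whose orthogonalized squared norm falls below
#' `collinear_tol` times its original squared norm is numerically inside the
#' selected span and is dropped with a diagnostic.
#'
#' @param design a [build_design_matrix()] result, or any list with elements
#'   `X` (N x M matrix), `y` (length N) and optionally `labels`.
#' @param rho error-to-signal stopping threshold in \[0, 1); the reference
#'   configuration uses 0.005.
#' @param max_terms maximum number of terms to select (default: all M).
#' @param min_gain minimum ESR reduction a candidate must offer for selection
#'   to continue; set 0 to disable and select down to `rho`/`max_terms`.
#' @param collinear_tol relative squared-norm threshold below which an
#'   orthogonalized candidate is considered collinear with the selected set.
#' @return An object of class `frols_model`: list with `terms` (selected
#'   column indices, in selection order), `labels` (their names), `weights`,
#'   `err_per_term`, `serr`, `esr`, `rho`, `min_gain`, `stop_rule`
#'   (one of `"esr"`, `"min_gain"`, `"max_terms"`, `"exhausted"`),
#'   `dictionary_labels`, `n_obs`, `skipped` (collinear candidates).
#' @examples
#' set.seed(1)
#' X <- matrix(runif(40 * 6), 40)
#' y <- 3 * X[, 2] + 0.5 * X[, 5]
#' frols_select(list(X = X, y = y), rho = 0.005)
#' @export
frols_select <- function(design, rho = 0.005, max_terms = NULL,
                         min_gain = 1e-6, collinear_tol = 1e-12) {
  X <- as.matrix(design$X); y <- as.numeric(design$y)
  labels <- design$labels %||% colnames(X) %||% paste0("x", seq_len(ncol(X)))
  M <- ncol(X); n <- nrow(X)
  if (M < 1L || n < 1L)
    stopf("empty candidate dictionary", class = "corrqsar_empty_dictionary")
  stopifnot(length(y) == n, rho >= 0, rho < 1, min_gain >= 0)
  if (is.null(max_terms)) max_terms <- M
  stopifnot(max_terms >= 1L, max_terms <= M)
  yty <- sum(y^2)
  if (yty == 0)
    stopf("response has zero norm", class = "corrqsar_division_by_zero")
  norms0 <- colSums(X^2)

  Q <- matrix(0, n, 0)        # orthogonal basis, selection order
  remaining <- seq_len(M)
  selected <- integer(); errs <- numeric(); skipped <- integer()
  serr <- 0; stop_rule <- "exhausted"

  gs <- function(v) {
    # classical Gram-Schmidt against Q, one reorthogonalization pass
    for (pass in 1:2) {
      if (ncol(Q)) {
        coefs <- drop(crossprod(Q, v)) / colSums(Q^2)
        v <- v - Q %*% coefs
      }
    }
    as.numeric(v)
  }

  while (length(remaining)) {
    W <- vapply(remaining, function(j) gs(X[, j]), numeric(n))
    W <- matrix(W, nrow = n)
    wnorm <- colSums(W^2)
    drop <- wnorm < collinear_tol * norms0[remaining]
    if (any(drop)) {
      skipped <- c(skipped, remaining[drop])
      warning(sprintf("candidate(s) %s collinear with selected set; skipped",
                      paste(labels[remaining[drop]], collapse = ", ")),
              call. = FALSE)
      W <- W[, !drop, drop = FALSE]
      remaining <- remaining[!drop]
      wnorm <- wnorm[!drop]
      if (!length(remaining)) { stop_rule <- "exhausted"; break }
    }
    err <- drop(crossprod(y, W))^2 / (wnorm * yty)
    best <- which.max(err)               # which.max: first (lowest index) wins ties
    if (err[best] < min_gain && min_gain > 0) { stop_rule <- "min_gain"; break }
    selected <- c(selected, remaining[best])
    errs <- c(errs, err[best])
    serr <- serr + err[best]
    Q <- cbind(Q, W[, best])
    remaining <- remaining[-best]
    if (1 - serr <= rho) { stop_rule <- "esr"; break }
    if (length(selected) >= max_terms) { stop_rule <- "max_terms"; break }
  }
  if (!length(selected))
    stopf("no term passed the selection thresholds (min_gain = %g)", min_gain,
          class = "corrqsar_no_selection")

  beta <- estimate_weights(X[, selected, drop = FALSE], y)
  structure(list(terms = selected, labels = labels[selected], weights = beta,
                 err_per_term = errs, serr = serr, esr = 1 - serr,
                 rho = rho, min_gain = min_gain, stop_rule = stop_rule,
                 dictionary_labels = labels, n_obs = n, skipped = skipped),
            class = "frols_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.frols_model <- function(x, digits = 4, ...) {
  cat(sprintf("FROLS model: %d term(s) from %d candidates (n = %d)\n",
              length(x$terms), length(x$dictionary_labels), x$n_obs))
  tab <- data.frame(term = x$labels,
                    weight = signif(x$weights, digits),
                    ERR_pct = signif(100 * x$err_per_term, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("SERR = %.4f%%, ESR = %.3g (rho = %g, stopped by: %s)\n",
              100 * x$serr, x$esr, x$rho, x$stop_rule))
  invisible(x)
}

#' @export
coef.frols_model <- function(object, ...) {
  stats::setNames(object$weights, object$labels)
}

#' Predict inhibition efficiency from a selected model
#'
#' Linear predictor \eqn{\hat y = \sum_j \beta_j x_j} over the model's
#' selected terms. There is no intercept and predictions are not clipped:
#' values outside \[0, 100\] are returned as-is and flagged by
#' [screen_predictions()] downstream.
#'
#' @param object a `frols_model`.
#' @param newdata a [build_design_matrix()] result, matrix, or data.frame
#'   containing the model's term columns (by label).
#' @param ... unused.
#' @return Numeric vector of predicted IE%.
#' @export
predict.frols_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "qsar_design")) newdata$X else as.matrix(newdata)
  miss <- setdiff(object$labels, colnames(X))
  if (length(miss))
    stopf("newdata lacks model term(s): %s", paste(miss, collapse = ", "),
          class = "corrqsar_unknown_label")
  drop(X[, object$labels, drop = FALSE] %*% object$weights)
}

#' Serialize / restore a selected model as JSON
#'
#' Weights are written at full precision and round-trip bit-exactly.
#'
#' @param model a `frols_model`.
#' @param path file path for the JSON document.
#' @return `write_frols()` returns `path` invisibly; `read_frols()` returns
#'   the restored `frols_model`.
#' @export
write_frols <- function(model, path) {
  stopifnot(inherits(model, "frols_model"))
  doc <- list(labels = model$dictionary_labels, terms = model$terms,
              term_labels = model$labels, weights = model$weights,
              weights_hex = sprintf("%a", model$weights),
              err_per_term = model$err_per_term, serr = model$serr,
              esr = model$esr, rho = model$rho, min_gain = model$min_gain,
              stop_rule = model$stop_rule, n_obs = model$n_obs,
              provenance = list(package = "corrqsar",
                                version = as.character(utils::packageVersion("corrqsar"))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frols
#' @export
read_frols <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  # hex floats restore the weights bit-exactly; plain numbers are fallback
  w <- if (!is.null(doc$weights_hex)) as.numeric(doc$weights_hex)
       else as.numeric(doc$weights)
  structure(list(terms = as.integer(doc$terms), labels = doc$term_labels,
                 weights = w,
                 err_per_term = as.numeric(doc$err_per_term),
                 serr = doc$serr, esr = doc$esr, rho = doc$rho,
                 min_gain = doc$min_gain, stop_rule = doc$stop_rule,
                 dictionary_labels = doc$labels, n_obs = doc$n_obs,
                 skipped = integer()),
            class = "frols_model")
}
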