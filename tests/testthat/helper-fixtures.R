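# Shared builders for synthetic linear systems and small oracles.

# Gaussian dictionary with a known sparse generating model.
make_linear_system <- function(n = 40, m = 10, support = c(2, 5),
                               weights = c(3, 0.5), noise_sd = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  colnames(X) <- paste0("x", seq_len(m))
  y <- drop(X[, support, drop = FALSE] %*% weights)
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  list(X = X, y = y, support = support, weights = weights)
}

# Exhaustive best-k-subset least squares: minimal RSS over all k-subsets.
# Independent oracle for the greedy selector (combn + qr solve, no reuse of
# the package's selection path).
best_subset <- function(X, y, k) {
  subsets <- utils::combn(ncol(X), k, simplify = FALSE)
  rss <- vapply(subsets, function(s) {
    fit <- lm.fit(X[, s, drop = FALSE], y)
    sum(fit$residuals^2)
  }, numeric(1))
  list(subset = subsets[[which.min(rss)]], rss = min(rss))
}

# The ten-row bundled reference descriptor table.
reference_drugs <- function() {
  read_compounds(corrqsar_example("high_efficiency_drugs.csv"))
}
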