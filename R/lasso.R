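# Minimal lasso solver used inside the random-lasso ensemble.
#
# Objective (glmnet's parameterization, unstandardized predictors, with
# intercept):  (1/2n) * sum_i (y_i - b0 - x_i'b)^2 + lambda * sum_j |b_j|.
# Solved by coordinate descent on the Gram matrix after centering
# (compiled; see src/lasso.cpp), which is far cheaper than a general solver
# for the ~1e5 tiny fits the ensemble needs. Correctness is checked against
# glmnet in the test suite.

#' Lasso fit at a fixed penalty
#'
#' Solves `(1/2n)||y - b0 - Xb||^2 + lambda ||b||_1` exactly (coordinate
#' descent to tolerance), with an unpenalized intercept and no internal
#' standardization of `X`.
#'
#' @param X Predictor matrix (no missing values).
#' @param y Response vector.
#' @param lambda Nonnegative penalty.
#' @return List with `beta` (length `ncol(X)`), `intercept`, and `lambda`.
#' @export
lasso_fit <- function(X, y, lambda) {
  stopifnot(nrow(X) == length(y), lambda >= 0)
  fit <- lasso_fixed_cpp(X, y, lambda, 1e-10, 2000L)
  list(beta = drop(fit$beta), intercept = fit$intercept, lambda = fit$lambda)
}

# internal: lasso along a geometric path with warm starts; penalty selected
# by the extended BIC (n log(RSS/n) + df (log n + 2 gamma log p)); ties
# resolve to the larger penalty.
lasso_bic <- function(X, y, n_lambda = 25L, lambda_min_ratio = 0.01,
                      gamma = 0.5) {
  fit <- lasso_bic_cpp(X, y, as.integer(n_lambda), lambda_min_ratio, gamma,
                       1e-7, 1000L)
  list(beta = drop(fit$beta), intercept = fit$intercept, lambda = fit$lambda)
}
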