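#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)` — the elementary update of coordinate
#' descent for the L1 penalty.
#'
#' @param z Numeric vector.
#' @param gamma Non-negative threshold.
#' @return Numeric vector of the same length.
#' @examples
#' soft_threshold(3, 1)     # 2
#' soft_threshold(-0.5, 1)  # 0
#' @export
soft_threshold <- function(z, gamma) {
  stopifnot(gamma >= 0)
  sign(z) * pmax(abs(z) - gamma, 0)
}

# Centre (and optionally scale) predictors and centre the response.
# Scaling uses the population standard deviation (denominator n); constant
# columns are left as zero columns so their coefficients stay pinned at 0.
prep_xy <- function(X, y, standardize) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm, "-")
  xs <- rep(1, ncol(X))
  norms <- sqrt(colSums(Xc^2) / n)
  constant <- norms == 0
  if (standardize) {
    xs <- ifelse(constant, 1, norms)
    Xc <- sweep(Xc, 2L, xs, "/")
  }
  ym <- mean(y)
  list(X = Xc, y = y - ym, xm = xm, xs = xs, ym = ym, constant = constant)
}

# The penalty is P(beta) = sum_j (1/2)|beta_j|, so a user-facing lambda maps
# onto the standard L1 objective with lambda_eff = lambda / 2.
lambda_effective <- function(lambda) lambda / 2

#' Log-spaced penalty path
#'
#' Computes `lambda_max`, the smallest penalty at which every coefficient is
#' exactly zero (`2 * max_j |x_j'(y - mean(y))| / n`, on the internally
#' standardized scale when `standardize = TRUE`; the factor 2 reflects the
#' half-weighted L1 penalty), and returns `n_lambda` values log-spaced down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param X Predictor matrix (genes x miRNAs).
#' @param y Response vector.
#' @param n_lambda Path length (>= 2), default 100.
#' @param lambda_min_ratio Ratio of smallest to largest value, default 1e-3.
#' @param standardize Match the standardization used by the fit.
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(X, y, n_lambda = 100L, lambda_min_ratio = 1e-3,
                        standardize = TRUE) {
  stopifnot(n_lambda >= 2L, lambda_min_ratio > 0, lambda_min_ratio < 1)
  pr <- prep_xy(X, y, standardize)
  lmax <- 2 * .cd_colmax_dot(pr$X, pr$y)
  if (lmax == 0)
    stop("lambda_max is undefined: the response is constant (or no predictor varies)")
  path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  path[1L] <- lmax                       # exact null-solution boundary
  path[n_lambda] <- lmax * lambda_min_ratio
  path
}

#' Fit the Lasso over a penalty path by cyclic coordinate descent
#'
#' Minimizes `1/(2n) ||y - b0 - X beta||^2 + (lambda/2) ||beta||_1` for each
#' penalty in `lambda`, warm-starting along the (decreasing) path. The factor
#' 1/2 on the penalty mirrors the model's half-weighted L1 term; reported
#' `lambda` values are on that scale throughout. The intercept is unpenalized
#' and recovered from the column means; with `standardize = TRUE` columns are
#' scaled internally and coefficients returned on the original scale.
#'
#' @param X Predictor matrix (rows = genes, columns = miRNAs).
#' @param y Response vector in the same row order.
#' @param lambda Non-negative penalty values, ideally decreasing.
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   sweep (internal scale). Default 1e-8.
#' @param max_iter Maximum sweeps per penalty value. Default 1e5.
#' @param standardize Centre/scale predictors internally. Default `TRUE`.
#' @return A list with `lambda`, `beta` (p x length(lambda), original scale),
#'   `intercept`, `niter`, `kkt` (worst Karush-Kuhn-Tucker violation, internal
#'   scale, in units of the effective penalty).
#' @export
fit_lasso_path <- function(X, y, lambda, tol = 1e-8, max_iter = 100000L,
                           standardize = TRUE) {
  X <- as.matrix(X)
  pr <- prep_xy(X, y, standardize)
  if (any(pr$constant))
    warning("constant predictor column(s) pinned to zero: ",
            paste(colnames(X)[pr$constant], collapse = ", "))
  res <- .cd_lasso_path(pr$X, pr$y, lambda_effective(lambda),
                        tol, as.integer(max_iter),
                        numeric(ncol(X)))
  if (!res$converged)
    stop("coordinate descent did not converge within ", max_iter,
         " sweeps (worst KKT violation ", format(max(res$kkt)), ")")
  beta <- res$beta / pr$xs
  dimnames(beta) <- list(colnames(X), NULL)
  intercept <- pr$ym - as.numeric(crossprod(beta, pr$xm))
  list(lambda = lambda, beta = beta, intercept = intercept,
       niter = res$niter, kkt = res$kkt)
}

#' Fit the Lasso at a single penalty value
#'
#' @inheritParams fit_lasso_path
#' @param lambda A single non-negative penalty.
#' @return A list with `intercept`, `beta` (named, original scale), `lambda`,
#'   `niter`, `kkt`.
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-8, max_iter = 100000L,
                      standardize = TRUE) {
  stopifnot(length(lambda) == 1L, lambda >= 0)
  fit <- fit_lasso_path(X, y, lambda, tol = tol, max_iter = max_iter,
                        standardize = standardize)
  list(intercept = fit$intercept[1L],
       beta = stats::setNames(fit$beta[, 1L], colnames(as.matrix(X))),
       lambda = lambda, niter = fit$niter[1L], kkt = fit$kkt[1L])
}

#' k-fold cross-validation of the penalty path
#'
#' Rows (genes) are shuffled with the given seed and cut into `n_folds`
#' contiguous blocks. For each penalty, the mean held-out squared error across
#' folds is recorded; the selected penalty minimizes that curve, with ties
#' resolved toward the largest penalty (sparser model).
#'
#' @inheritParams fit_lasso_path
#' @param lambda Decreasing penalty path (e.g. from [lambda_path()]).
#' @param n_folds Number of folds (>= 2), default 10.
#' @param seed Integer seed for the fold shuffle.
#' @return A list with `lambda`, `cv_mse` (mean curve), `cv_mse_folds`
#'   (n_folds x n_lambda matrix), `fold_id` (per row), `lambda_selected`,
#'   `index_selected`.
#' @export
cross_validate <- function(X, y, lambda, n_folds = 10L, seed = 17L,
                           tol = 1e-8, max_iter = 100000L,
                           standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n_folds >= 2L, n >= n_folds)
  perm <- with_seed(seed, sample.int(n))
  bounds <- round(seq(0, n, length.out = n_folds + 1))
  fold_id <- integer(n)
  for (f in seq_len(n_folds))
    fold_id[perm[(bounds[f] + 1):bounds[f + 1]]] <- f
  fold_mse <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    test <- fold_id == f
    fit <- fit_lasso_path(X[!test, , drop = FALSE], y[!test], lambda,
                          tol = tol, max_iter = max_iter,
                          standardize = standardize)
    pred <- sweep(X[test, , drop = FALSE] %*% fit$beta, 2L,
                  fit$intercept, "+")
    fold_mse[f, ] <- colMeans((y[test] - pred)^2)
  }
  cvm <- colMeans(fold_mse)
  idx <- which.min(cvm)   # path is decreasing: first minimum = largest lambda
  list(lambda = lambda, cv_mse = cvm, cv_mse_folds = fold_mse,
       fold_id = fold_id, lambda_selected = lambda[idx],
       index_selected = idx)
}
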