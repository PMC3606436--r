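#' Fit the disease-miRNA Lasso model for one disease
#'
#' Takes one disease's gene-signature column as response and the NetmiR
#' influence matrix as predictors, computes the penalty path, selects the
#' penalty by k-fold cross-validation (minimum mean squared error, ties to
#' the sparser model) and returns the fit at the selected penalty.
#'
#' @param netmir A [build_netmir()] result (predictors).
#' @param disease_matrix A [build_disease_matrix()] result (responses).
#' @param disease Disease (column) identifier to fit.
#' @param control A [mirlasso_control()] list.
#' @return An object of class `"mirlasso_fit"` with components `disease`,
#'   `mirna_ids`, `beta`, `intercept`, `lambda_selected`, `lambda_path`,
#'   `cv_mse`, `cv_mse_folds`, `beta_path`, `intercept_path`, `fitted`, `y`,
#'   `seed`, `control`.
#' @seealso [mirlasso()] for all diseases at once, [extract_associations()].
#' @export
fit_disease <- function(netmir, disease_matrix, disease,
                        control = mirlasso_control()) {
  both <- intersect_universe(netmir, disease_matrix)
  X <- both$netmir$values
  dm <- both$disease_matrix$values
  disease <- normalize_id(disease)
  if (!disease %in% colnames(dm))
    stop("disease '", disease, "' not in the disease matrix")
  y <- dm[, disease]
  if (stats::var(y) == 0)
    stop("disease '", disease, "' has a zero-variance signature column")
  path <- lambda_path(X, y, n_lambda = control$n_lambda,
                      lambda_min_ratio = control$lambda_min_ratio,
                      standardize = control$standardize)
  cv <- cross_validate(X, y, path, n_folds = control$n_folds,
                       seed = control$seed, tol = control$tol,
                       max_iter = control$max_iter,
                       standardize = control$standardize)
  full <- fit_lasso_path(X, y, path, tol = control$tol,
                         max_iter = control$max_iter,
                         standardize = control$standardize)
  i <- cv$index_selected
  beta <- stats::setNames(full$beta[, i], colnames(X))
  fitted <- as.numeric(X %*% beta + full$intercept[i])
  structure(list(
    disease = disease, mirna_ids = colnames(X),
    beta = beta, intercept = full$intercept[i],
    lambda_selected = cv$lambda_selected, lambda_path = path,
    cv_mse = cv$cv_mse, cv_mse_folds = cv$cv_mse_folds,
    beta_path = full$beta, intercept_path = full$intercept,
    fitted = fitted, y = y, seed = control$seed, control = control,
    call = match.call()
  ), class = "mirlasso_fit")
}

#' Fit the disease-miRNA Lasso model for every disease
#'
#' The main fitting entry point: intersects the gene universes of the
#' predictor (NetmiR) and response (disease signature) matrices and runs
#' [fit_disease()] for each requested disease.
#'
#' @inheritParams fit_disease
#' @param diseases Diseases to fit (default: every column of
#'   `disease_matrix`).
#' @return An object of class `"mirlasso"`: list with `fits` (named list of
#'   `mirlasso_fit`), `gene_ids`, `mirna_ids`, `control`.
#' @examples
#' sim <- simulate_study(synth_config(n_genes = 120, n_mirnas = 8,
#'                                    n_diseases = 2, targets_per_mirna = 12,
#'                                    seed = 1))
#' ctrl <- mirlasso_control(n_lambda = 30, n_folds = 5)
#' dm <- build_disease_matrix(
#'   lapply(names(sim$truth$true_signatures), function(d)
#'     gene_signature(d, up = sim$truth$true_signatures[[d]], source = "text")),
#'   gene_universe = rownames(sim$netmir$values))
#' fit <- mirlasso(sim$netmir, dm, control = ctrl)
#' coef(fit)[1:3, ]
#' @export
mirlasso <- function(netmir, disease_matrix, diseases = NULL,
                     control = mirlasso_control()) {
  if (is.null(diseases)) diseases <- colnames(disease_matrix$values)
  fits <- lapply(diseases, function(d)
    fit_disease(netmir, disease_matrix, d, control = control))
  names(fits) <- normalize_id(diseases)
  structure(list(fits = fits,
                 gene_ids = names(fits[[1L]]$y),
                 mirna_ids = fits[[1L]]$mirna_ids,
                 control = control, call = match.call()),
            class = "mirlasso")
}

#' @export
print.mirlasso_fit <- function(x, ...) {
  cat(sprintf("Disease-miRNA Lasso fit: %s\n", x$disease))
  cat(sprintf("  %d miRNAs, %d genes; lambda = %.4g (CV over %d values)\n",
              length(x$beta), length(x$y), x$lambda_selected,
              length(x$lambda_path)))
  cat(sprintf("  nonzero coefficients: %d (%d positive); min CV MSE = %.4g\n",
              sum(x$beta != 0), sum(x$beta > 0), min(x$cv_mse)))
  invisible(x)
}

#' @export
coef.mirlasso_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
predict.mirlasso_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- if (inherits(newdata, "netmir_matrix")) newdata$values else as.matrix(newdata)
  X <- X[, object$mirna_ids, drop = FALSE]
  as.numeric(X %*% object$beta + object$intercept)
}

#' @export
residuals.mirlasso_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.mirlasso_fit <- function(x, ...) {
  graphics::plot(log(x$lambda_path), x$cv_mse, type = "b", pch = 20,
                 xlab = expression(log(lambda)),
                 ylab = "cross-validated MSE",
                 main = paste("Penalty selection:", x$disease), ...)
  graphics::abline(v = log(x$lambda_selected), lty = 2)
  invisible(x)
}

#' @export
summary.mirlasso_fit <- function(object, ...) {
  nz <- object$beta[object$beta != 0]
  structure(list(disease = object$disease,
                 lambda = object$lambda_selected,
                 cv_mse_min = min(object$cv_mse),
                 coefficients = sort(nz, decreasing = TRUE)),
            class = "summary.mirlasso_fit")
}

#' @export
print.summary.mirlasso_fit <- function(x, ...) {
  cat(sprintf("Disease: %s  (lambda = %.4g, CV MSE = %.4g)\n",
              x$disease, x$lambda, x$cv_mse_min))
  if (length(x$coefficients)) {
    cat("Nonzero miRNA coefficients:\n")
    print(round(x$coefficients, 5))
  } else cat("No nonzero miRNA coefficients.\n")
  invisible(x)
}

#' @export
print.mirlasso <- function(x, ...) {
  cat(sprintf("Disease-miRNA Lasso model: %d diseases x %d miRNAs\n",
              length(x$fits), length(x$mirna_ids)))
  for (f in x$fits)
    cat(sprintf("  %-14s nonzero = %3d  lambda = %.4g\n",
                f$disease, sum(f$beta != 0), f$lambda_selected))
  invisible(x)
}

#' @export
coef.mirlasso <- function(object, ...) {
  sapply(object$fits, `[[`, "beta")
}

#' @export
summary.mirlasso <- function(object, ...) {
  df <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(disease = f$disease, n_nonzero = sum(f$beta != 0),
               n_positive = sum(f$beta > 0),
               lambda = f$lambda_selected, cv_mse = min(f$cv_mse))))
  rownames(df) <- NULL
  df
}

#' Extract the scored disease-miRNA association network
#'
#' Positive coefficients become association edges (negative coefficients have
#' no biological reading under the membership-encoded response and are dropped
#' by default).
#'
#' @param fits A `"mirlasso"` object, a single `"mirlasso_fit"`, or a list of
#'   fits.
#' @param keep_sign `"positive"` (default) keeps only positive coefficients;
#'   `"both"` keeps any nonzero coefficient.
#' @return A data frame of class `"association_network"` with columns
#'   `disease`, `mirna`, `score`.
#' @export
extract_associations <- function(fits, keep_sign = c("positive", "both")) {
  keep_sign <- match.arg(keep_sign)
  if (inherits(fits, "mirlasso")) fits <- fits$fits
  if (inherits(fits, "mirlasso_fit")) fits <- list(fits)
  stopifnot(length(fits) > 0)
  rows <- lapply(fits, function(f) {
    keep <- if (keep_sign == "positive") f$beta > 0 else f$beta != 0
    data.frame(disease = rep(f$disease, sum(keep)),
               mirna = names(f$beta)[keep],
               score = unname(f$beta[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("association_network", "data.frame")
  out
}
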