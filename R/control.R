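#' Control parameters for the disease-miRNA association pipeline
#'
#' Collects every tunable parameter of the modelling pipeline in one validated
#' list, in the spirit of [glm.control()].
#'
#' @param k_up,k_down Number of top up- / down-regulated genes retained in an
#'   expression-derived disease signature (defaults 100 + 100, i.e. a top-200
#'   signature).
#' @param min_relevance Text-mining relevance score that a gene must *exceed*
#'   (strict) to enter a text signature. Default 0.
#' @param min_citations Minimum citation count (inclusive) for a text-signature
#'   gene. Default 11, i.e. strictly more than ten citations.
#' @param min_neighbors Minimum number of directly targeted PPI neighbours for
#'   a gene to count as an indirect miRNA target. Default 5.
#' @param indirect_mode `"per_mirna"` (default): a gene is an indirect target of
#'   miRNA j when at least `min_neighbors` of its PPI neighbours are direct
#'   targets of j and the gene itself is not. `"any_mirna"`: additionally the
#'   gene must not be a direct target of *any* miRNA (literal reading of the
#'   untargeted-protein rule).
#' @param n_folds Cross-validation folds for penalty selection. Default 10.
#' @param n_lambda Length of the log-spaced penalty path. Default 100.
#' @param lambda_min_ratio Smallest path value as a fraction of `lambda_max`.
#'   Default 1e-3.
#' @param seed Integer seed driving the cross-validation fold shuffle.
#' @param keep_sign `"positive"` (default): only positive coefficients become
#'   association edges; `"both"`: any nonzero coefficient.
#' @param signed Encode disease signatures as signed (-1/0/+1) rather than
#'   binary membership (0/1). Default `FALSE`.
#' @param standardize Centre and scale predictor columns internally before the
#'   coordinate descent (coefficients are reported on the original scale).
#'   Default `TRUE`.
#' @param tol Convergence tolerance on the maximum coefficient change per
#'   coordinate-descent sweep. Default 1e-8.
#' @param max_iter Maximum number of coordinate-descent sweeps. Default 1e5.
#'
#' @return A named list of class `"mirlasso_control"`.
#' @examples
#' ctrl <- mirlasso_control(n_folds = 5)
#' ctrl$n_folds
#' @export
mirlasso_control <- function(k_up = 100L, k_down = 100L,
                             min_relevance = 0, min_citations = 11L,
                             min_neighbors = 5L,
                             indirect_mode = c("per_mirna", "any_mirna"),
                             n_folds = 10L, n_lambda = 100L,
                             lambda_min_ratio = 1e-3, seed = 17L,
                             keep_sign = c("positive", "both"),
                             signed = FALSE, standardize = TRUE,
                             tol = 1e-8, max_iter = 100000L) {
  keep_sign <- match.arg(keep_sign)
  indirect_mode <- match.arg(indirect_mode)
  ctrl <- list(
    k_up = as.integer(k_up), k_down = as.integer(k_down),
    min_relevance = as.numeric(min_relevance),
    min_citations = as.integer(min_citations),
    min_neighbors = as.integer(min_neighbors),
    indirect_mode = indirect_mode,
    n_folds = as.integer(n_folds), n_lambda = as.integer(n_lambda),
    lambda_min_ratio = as.numeric(lambda_min_ratio),
    seed = as.integer(seed), keep_sign = keep_sign,
    signed = isTRUE(signed), standardize = isTRUE(standardize),
    tol = as.numeric(tol), max_iter = as.integer(max_iter)
  )
  counts <- c("k_up", "k_down", "min_citations", "min_neighbors",
              "n_folds", "n_lambda", "max_iter")
  for (nm in counts) {
    if (is.na(ctrl[[nm]]) || ctrl[[nm]] < 0L)
      stop(sprintf("'%s' must be a non-negative integer", nm))
  }
  if (ctrl$min_neighbors < 1L) stop("'min_neighbors' must be >= 1")
  if (ctrl$n_folds < 2L) stop("'n_folds' must be >= 2")
  if (ctrl$n_lambda < 2L) stop("'n_lambda' must be >= 2")
  if (!(ctrl$lambda_min_ratio > 0 && ctrl$lambda_min_ratio < 1))
    stop("'lambda_min_ratio' must lie in (0, 1)")
  if (ctrl$min_relevance < 0) stop("'min_relevance' must be >= 0")
  if (ctrl$tol <= 0) stop("'tol' must be > 0")
  class(ctrl) <- "mirlasso_control"
  ctrl
}
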