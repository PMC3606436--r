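enrichment_table <- function(gene_list, mirna_targets, universe) {
  universe <- unique(normalize_id(universe))
  if (!length(universe)) stop("'universe' must be non-empty")
  gene_list <- intersect(unique(normalize_id(gene_list)), universe)
  mirna_targets <- intersect(unique(normalize_id(mirna_targets)), universe)
  a <- length(intersect(gene_list, mirna_targets))
  b <- length(gene_list) - a
  c_ <- length(mirna_targets) - a
  d <- length(universe) - a - b - c_
  list(a = a, b = b, c = c_, d = d,
       list_size = length(gene_list), target_size = length(mirna_targets),
       universe_size = length(universe))
}

#' Fisher exact enrichment of a miRNA's targets in a gene list
#'
#' Two-sided Fisher exact test on the 2x2 table (in-list & target, in-list
#' only, target only, neither). The odds ratio is the sample `ad/bc`
#' (`Inf` when `bc = 0`, `NaN` for the doubly degenerate 0/0 case).
#'
#' @param gene_list Character vector of genes (the query list).
#' @param mirna_targets Character vector of the miRNA's influenced genes.
#' @param universe Character vector of background genes; list and targets are
#'   intersected with it.
#' @param alternative Passed to [stats::fisher.test()]; default
#'   `"two.sided"`.
#' @return A one-row data frame: `overlap`, `list_size`, `target_size`,
#'   `universe_size`, `p_value`, `odds_ratio`.
#' @export
fisher_enrichment <- function(gene_list, mirna_targets, universe,
                              alternative = "two.sided") {
  tb <- enrichment_table(gene_list, mirna_targets, universe)
  m <- matrix(c(tb$a, tb$b, tb$c, tb$d), 2L, byrow = TRUE)
  p <- stats::fisher.test(m, alternative = alternative)$p.value
  or <- if (tb$b * tb$c == 0) {
    if (tb$a * tb$d == 0) NaN else Inf
  } else tb$a * tb$d / (tb$b * tb$c)
  data.frame(overlap = tb$a, list_size = tb$list_size,
             target_size = tb$target_size, universe_size = tb$universe_size,
             p_value = min(p, 1), odds_ratio = or)
}

#' Hypergeometric (over-representation) enrichment
#'
#' One-sided upper-tail probability `P(overlap >= observed)` under the
#' hypergeometric distribution with the same margins as
#' [fisher_enrichment()].
#'
#' @inheritParams fisher_enrichment
#' @return A one-row data frame with the same columns as
#'   [fisher_enrichment()].
#' @export
hypergeometric_enrichment <- function(gene_list, mirna_targets, universe) {
  tb <- enrichment_table(gene_list, mirna_targets, universe)
  p <- stats::phyper(tb$a - 1, tb$target_size,
                     tb$universe_size - tb$target_size,
                     tb$list_size, lower.tail = FALSE)
  or <- if (tb$b * tb$c == 0) {
    if (tb$a * tb$d == 0) NaN else Inf
  } else tb$a * tb$d / (tb$b * tb$c)
  data.frame(overlap = tb$a, list_size = tb$list_size,
             target_size = tb$target_size, universe_size = tb$universe_size,
             p_value = p, odds_ratio = or)
}

#' Rank miRNAs enriched in a gene list
#'
#' Gene-list entry point: the list is encoded as a binary response over the
#' NetmiR gene universe and either regressed on the influence matrix (Lasso
#' coefficients as enrichment scores) or scored per miRNA with an enrichment
#' test.
#'
#' @param gene_list Character vector of query genes.
#' @param netmir A [build_netmir()] result.
#' @param method `"lasso"` (default), `"fisher"` or `"hypergeometric"`.
#' @param control A [mirlasso_control()] (used by the Lasso route).
#' @return A data frame ranked best-first: columns `mirna` and `score`
#'   (coefficient) for the Lasso route, or the enrichment columns plus
#'   `mirna`, ordered by p-value, for the test routes.
#' @export
enrich_mirnas <- function(gene_list, netmir,
                          method = c("lasso", "fisher", "hypergeometric"),
                          control = mirlasso_control()) {
  method <- match.arg(method)
  universe <- rownames(netmir$values)
  gene_list <- intersect(unique(normalize_id(gene_list)), universe)
  if (!length(gene_list)) stop("no query genes in the NetmiR universe")
  if (method == "lasso") {
    y <- as.numeric(universe %in% gene_list)
    X <- netmir$values
    path <- lambda_path(X, y, n_lambda = control$n_lambda,
                        lambda_min_ratio = control$lambda_min_ratio,
                        standardize = control$standardize)
    cv <- cross_validate(X, y, path, n_folds = control$n_folds,
                         seed = control$seed, tol = control$tol,
                         max_iter = control$max_iter,
                         standardize = control$standardize)
    fit <- fit_lasso(X, y, cv$lambda_selected, tol = control$tol,
                     max_iter = control$max_iter,
                     standardize = control$standardize)
    out <- data.frame(mirna = names(fit$beta), score = unname(fit$beta),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$score, out$mirna), ]
  } else {
    test <- if (method == "fisher") fisher_enrichment else hypergeometric_enrichment
    rows <- lapply(colnames(netmir$values), function(m) {
      targets <- universe[netmir$values[, m] != 0]
      cbind(mirna = m, test(gene_list, targets, universe))
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p_value, -out$overlap, out$mirna), ]
  }
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC for a score/label set
#'
#' The AUC is the Mann-Whitney rank statistic with midrank tie correction
#' (the probability that a random positive outranks a random negative, ties
#' counting one half); the curve is a threshold sweep with tied scores
#' collapsed into single steps, so its trapezoidal area equals the rank AUC.
#'
#' @param scores Numeric scores (higher = more confident positive).
#' @param labels Logical or 0/1 vector of the same length.
#' @return An object of class `"roc_result"`: list with `auc`, `points`
#'   (data frame `fpr`, `tpr`, from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L) stop("no positive labels")
  if (n_neg == 0L) stop("no negative labels")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)   # end of each tie group
  tpr <- c(0, cumsum(l)[last] / n_pos)
  fpr <- c(0, cumsum(!l)[last] / n_neg)
  structure(list(auc = auc,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluate predicted associations against a gold standard by ROC
#'
#' Labels are gold-standard membership over the full disease x miRNA grid:
#' every non-gold pair is a negative, and pairs absent from the predictions
#' are scored 0 (the Lasso zeroes non-associations by construction).
#'
#' @param pred An [extract_associations()] data frame (columns `disease`,
#'   `mirna`, `score`).
#' @param gold Directed [edge_list()] of gold-standard disease -> miRNA
#'   edges, or a two-column data frame.
#' @param mirnas Character vector: the miRNA universe defining the grid.
#' @param diseases Diseases to evaluate (default: all diseases in `pred` or
#'   `gold`).
#' @param per_disease Report one ROC per disease (default) in addition to the
#'   pooled ROC over the whole grid.
#' @return A list with `per_disease` (named list of [roc_curve()] results;
#'   diseases without gold positives are skipped with a warning), `pooled`
#'   (single `roc_result`), and `auc` (named vector of per-disease AUCs).
#' @export
roc_auc <- function(pred, gold, mirnas, diseases = NULL, per_disease = TRUE) {
  gold_df <- as.data.frame(gold)[, 1:2]
  names(gold_df) <- c("disease", "mirna")
  gold_df$disease <- normalize_id(gold_df$disease)
  gold_df$mirna <- normalize_id(gold_df$mirna)
  mirnas <- unique(normalize_id(mirnas))
  if (is.null(diseases))
    diseases <- sort(unique(c(pred$disease, gold_df$disease)))
  diseases <- normalize_id(diseases)
  score_grid <- matrix(0, length(diseases), length(mirnas),
                       dimnames = list(diseases, mirnas))
  keep <- pred$disease %in% diseases & pred$mirna %in% mirnas
  if (any(keep))
    score_grid[cbind(match(pred$disease[keep], diseases),
                     match(pred$mirna[keep], mirnas))] <- pred$score[keep]
  label_grid <- matrix(FALSE, length(diseases), length(mirnas),
                       dimnames = list(diseases, mirnas))
  gk <- gold_df$disease %in% diseases & gold_df$mirna %in% mirnas
  label_grid[cbind(match(gold_df$disease[gk], diseases),
                   match(gold_df$mirna[gk], mirnas))] <- TRUE
  if (!any(label_grid)) stop("no gold-standard positives on the grid")
  per <- list()
  if (per_disease) {
    for (d in diseases) {
      if (!any(label_grid[d, ])) {
        warning("disease '", d, "' has no gold positives; skipped")
        next
      }
      if (all(label_grid[d, ])) {
        warning("disease '", d, "' has no negatives; skipped")
        next
      }
      per[[d]] <- roc_curve(score_grid[d, ], label_grid[d, ])
    }
  }
  pooled <- roc_curve(as.numeric(score_grid), as.logical(label_grid))
  list(per_disease = per, pooled = pooled,
       auc = vapply(per, `[[`, 0, "auc"))
}
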