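#' SAM-style moderated d-statistic for two-group differential expression
#'
#' For each gene, `d = (mean(case) - mean(control)) / (s + s0)`, where `s` is
#' the pooled standard error of the mean difference,
#' `s = sqrt((1/n1 + 1/n2) * (SS_control + SS_case) / (n1 + n2 - 2))`,
#' and `s0` is a fudge factor stabilising genes with tiny variance. With
#' `s0 = "auto"` the median of `s` over genes is used.
#'
#' @param expr An [expression_matrix()] with both groups of size >= 2.
#' @param s0 Non-negative fudge factor, or `"auto"` (default).
#' @return A data frame of class `"dstat_result"` with columns `gene` and `d`,
#'   plus attribute `s0`.
#' @examples
#' m <- matrix(c(1, 1, 3, 3), nrow = 1, dimnames = list("G1", paste0("s", 1:4)))
#' e <- expression_matrix(m, c("control", "control", "case", "case"))
#' d_statistic(e, s0 = 1)
#' @export
d_statistic <- function(expr, s0 = "auto") {
  stopifnot(inherits(expr, "expression_matrix"))
  g <- expr$groups
  n1 <- sum(g == "control"); n2 <- sum(g == "case")
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 samples")
  x1 <- expr$values[, g == "control", drop = FALSE]
  x2 <- expr$values[, g == "case", drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  if (identical(s0, "auto")) s0 <- stats::median(s)
  s0 <- as.numeric(s0)
  if (s0 < 0) stop("'s0' must be >= 0")
  if (s0 == 0 && any(s == 0))
    stop("gene(s) with zero variance in both groups; use s0 > 0")
  d <- (m2 - m1) / (s + s0)
  if (!all(is.finite(d))) stop("non-finite d-statistic produced")
  structure(data.frame(gene = rownames(expr$values), d = d,
                       row.names = NULL, stringsAsFactors = FALSE),
            s0 = s0, class = c("dstat_result", "data.frame"))
}

#' Top-k up/down expression signature from a d-statistic
#'
#' `up` holds the `k_up` genes with the largest d among genes with d > 0;
#' `down` the `k_down` genes with the smallest d among genes with d < 0. Ties
#' break by |d| descending then gene id ascending. When fewer genes qualify,
#' all are taken.
#'
#' @param dstat A result of [d_statistic()].
#' @param disease Disease identifier to stamp on the signature.
#' @param k_up,k_down Signature sizes (defaults 100, 100).
#' @return A [gene_signature()] with `source = "expression"`.
#' @export
expression_signature <- function(dstat, disease, k_up = 100L, k_down = 100L) {
  stopifnot(k_up >= 0L, k_down >= 0L)
  pick <- function(idx, decreasing, k) {
    if (!length(idx) || k == 0L) return(character())
    d <- dstat$d[idx]; gene <- dstat$gene[idx]
    ord <- order(if (decreasing) -d else d, -abs(d), gene)
    gene[ord][seq_len(min(k, length(idx)))]
  }
  up <- pick(which(dstat$d > 0), TRUE, k_up)
  down <- pick(which(dstat$d < 0), FALSE, k_down)
  gene_signature(disease, up = up, down = down, source = "expression")
}

#' Text-mining disease signature by relevance and citation filter
#'
#' Keeps genes whose relevance score strictly exceeds `min_relevance` and
#' whose citation count is at least `min_citations` (the default 11 encodes
#' "strictly more than ten citations"). Text mining carries no direction, so
#' all genes land in the `up` slot.
#'
#' @param table A relevance table ([read_relevance_table()] layout).
#' @param disease Disease identifier to extract.
#' @param min_relevance,min_citations Filter thresholds (defaults 0 and 11).
#' @return A [gene_signature()] with `source = "text"`; empty with a warning
#'   when the disease is absent from the table.
#' @export
text_signature <- function(table, disease, min_relevance = 0,
                           min_citations = 11L) {
  stopifnot(min_relevance >= 0, min_citations >= 0)
  disease <- normalize_id(disease)
  rows <- table[normalize_id(table$disease) == disease, , drop = FALSE]
  if (!nrow(rows)) {
    warning("disease '", disease, "' absent from relevance table")
    return(gene_signature(disease, source = "text"))
  }
  keep <- rows$relevance > min_relevance & rows$citations >= min_citations
  gene_signature(disease, up = rows$gene[keep], source = "text")
}

#' Merge an expression signature with a text signature
#'
#' Membership is the union of all genes. Direction is kept from the
#' expression signature where available; text-only genes are recorded as
#' direction-unknown in the `up` slot (membership encoding).
#'
#' @param expr_sig,text_sig [gene_signature()] objects for the same disease.
#' @return A merged [gene_signature()] (`source = "merged"`).
#' @export
merge_signatures <- function(expr_sig, text_sig) {
  stopifnot(inherits(expr_sig, "gene_signature"),
            inherits(text_sig, "gene_signature"))
  if (expr_sig$disease != text_sig$disease)
    stop("disease mismatch: '", expr_sig$disease, "' vs '", text_sig$disease, "'")
  extra <- setdiff(c(text_sig$up, text_sig$down),
                   c(expr_sig$up, expr_sig$down))
  gene_signature(expr_sig$disease,
                 up = c(expr_sig$up, extra), down = expr_sig$down,
                 source = "merged")
}

#' All genes in a signature
#' @param sig A [gene_signature()].
#' @return Character vector of member genes.
#' @export
signature_genes <- function(sig) sort(unique(c(sig$up, sig$down)))

#' Build the disease signature (response) matrix
#'
#' Rows are the supplied gene universe, columns one disease each. Under the
#' default membership encoding an entry is 1 iff the gene belongs to that
#' disease's signature; the signed encoding uses +1 for up, -1 for down
#' (text-only genes count as +1).
#'
#' @param signatures A list of [gene_signature()] objects (one per disease).
#' @param gene_universe Non-empty character vector of gene ids defining the
#'   row space.
#' @param encoding `"membership"` (default) or `"signed"`.
#' @return An object of class `"disease_matrix"`: list with `values`
#'   (genes x diseases matrix) and `encoding`.
#' @export
build_disease_matrix <- function(signatures, gene_universe,
                                 encoding = c("membership", "signed")) {
  encoding <- match.arg(encoding)
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  gene_universe <- unique(normalize_id(gene_universe))
  if (!length(gene_universe)) stop("'gene_universe' must be non-empty")
  diseases <- vapply(signatures, `[[`, "", "disease")
  if (anyDuplicated(diseases)) stop("duplicate disease ids in signatures")
  vals <- matrix(0, nrow = length(gene_universe), ncol = length(diseases),
                 dimnames = list(gene_universe, diseases))
  for (i in seq_along(signatures)) {
    sig <- signatures[[i]]
    up <- intersect(sig$up, gene_universe)
    down <- intersect(sig$down, gene_universe)
    if (!length(up) && !length(down))
      warning("disease '", sig$disease,
              "' has an empty signature after restriction to the universe")
    vals[up, i] <- 1
    vals[down, i] <- if (encoding == "signed") -1 else 1
  }
  structure(list(values = vals, encoding = encoding),
            class = "disease_matrix")
}

#' @export
print.disease_matrix <- function(x, ...) {
  cat(sprintf("Disease signature matrix (%s): %d genes x %d diseases\n",
              x$encoding, nrow(x$values), ncol(x$values)))
  invisible(x)
}
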