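#' Indirect miRNA targets via one-step PPI propagation
#'
#' A gene that is not itself a direct target becomes an *indirect* target of a
#' miRNA when at least `min_neighbors` of its PPI neighbours are direct
#' targets. Under the default per-miRNA rule both conditions refer to the
#' focal miRNA j; under `mode = "any_mirna"` the gene must additionally be
#' untargeted by every miRNA (the literal untargeted-protein reading), while
#' the neighbour count still refers to j so that the result remains a
#' per-miRNA profile.
#'
#' @param ppi Undirected [edge_list()] of protein-protein interactions.
#' @param direct Directed [edge_list()] of miRNA -> gene target edges.
#' @param min_neighbors Minimum number of directly targeted neighbours
#'   (default 5).
#' @param mode `"per_mirna"` (default) or `"any_mirna"`.
#' @return A data frame with columns `gene`, `mirna`, one row per indirect
#'   (gene, miRNA) pair.
#' @export
indirect_targets <- function(ppi, direct, min_neighbors = 5L,
                             mode = c("per_mirna", "any_mirna")) {
  mode <- match.arg(mode)
  stopifnot(min_neighbors >= 1L)
  if (isTRUE(attr(ppi, "directed"))) stop("'ppi' must be undirected")
  if (!isTRUE(attr(direct, "directed"))) stop("'direct' must be directed")
  empty <- data.frame(gene = character(), mirna = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(ppi) || !nrow(direct)) return(empty)
  # adjacency as a named list of neighbour vectors
  adj <- split(c(ppi$to, ppi$from), c(ppi$from, ppi$to))
  targets_by_mirna <- split(direct$to, direct$from)
  any_target <- unique(direct$to)
  out_gene <- character(); out_mirna <- character()
  for (mir in names(targets_by_mirna)) {
    tj <- unique(targets_by_mirna[[mir]])
    # count, for every gene, how many of its neighbours are direct targets of mir
    nb <- unlist(adj[intersect(tj, names(adj))], use.names = FALSE)
    if (!length(nb)) next
    counts <- table(nb)
    cand <- names(counts)[counts >= min_neighbors]
    cand <- setdiff(cand, tj)
    if (mode == "any_mirna") cand <- setdiff(cand, any_target)
    if (length(cand)) {
      out_gene <- c(out_gene, sort(cand))
      out_mirna <- c(out_mirna, rep(mir, length(cand)))
    }
  }
  data.frame(gene = out_gene, mirna = out_mirna, stringsAsFactors = FALSE)
}

#' Build the miRNA influence (NetmiR) matrix
#'
#' Binary genes x miRNAs matrix marking each gene directly or indirectly
#' influenced by each miRNA, with per-entry provenance. Direct and indirect
#' sets cannot overlap by construction (asserted).
#'
#' @param direct Directed [edge_list()] of miRNA -> gene edges.
#' @param indirect Data frame with columns `gene`, `mirna` (output of
#'   [indirect_targets()]); may be empty.
#' @param gene_universe,mirna_universe Non-empty identifier vectors defining
#'   the matrix dimensions; entries outside the universes are dropped.
#' @return An object of class `"netmir_matrix"`: list with `values` (binary
#'   matrix) and `provenance` (character matrix, `""`/`"direct"`/`"indirect"`).
#' @export
build_netmir <- function(direct, indirect = NULL, gene_universe = NULL,
                         mirna_universe = NULL) {
  if (is.null(indirect))
    indirect <- data.frame(gene = character(), mirna = character())
  if (is.null(gene_universe))
    gene_universe <- sort(unique(c(direct$to, indirect$gene)))
  if (is.null(mirna_universe))
    mirna_universe <- sort(unique(c(direct$from, indirect$mirna)))
  gene_universe <- unique(normalize_id(gene_universe))
  mirna_universe <- unique(normalize_id(mirna_universe))
  if (!length(gene_universe) || !length(mirna_universe))
    stop("gene and miRNA universes must be non-empty")
  vals <- matrix(0, length(gene_universe), length(mirna_universe),
                 dimnames = list(gene_universe, mirna_universe))
  prov <- matrix("", length(gene_universe), length(mirna_universe),
                 dimnames = list(gene_universe, mirna_universe))
  di <- direct[direct$to %in% gene_universe &
                 direct$from %in% mirna_universe, , drop = FALSE]
  if (nrow(di)) {
    idx <- cbind(match(di$to, gene_universe), match(di$from, mirna_universe))
    vals[idx] <- 1
    prov[idx] <- "direct"
  }
  ind <- indirect[normalize_id(indirect$gene) %in% gene_universe &
                    normalize_id(indirect$mirna) %in% mirna_universe, ,
                  drop = FALSE]
  if (nrow(ind)) {
    idx <- cbind(match(normalize_id(ind$gene), gene_universe),
                 match(normalize_id(ind$mirna), mirna_universe))
    overlap <- prov[idx] == "direct"
    stopifnot(!any(overlap))   # cannot happen: indirect excludes direct targets
    vals[idx] <- 1
    prov[idx] <- "indirect"
  }
  zero <- colSums(vals) == 0
  if (any(zero))
    warning("miRNA(s) with zero targets in universe kept as zero columns: ",
            paste(mirna_universe[zero], collapse = ", "))
  structure(list(values = vals, provenance = prov), class = "netmir_matrix")
}

#' @export
print.netmir_matrix <- function(x, ...) {
  cat(sprintf(
    "NetmiR influence matrix: %d genes x %d miRNAs (%d direct, %d indirect entries)\n",
    nrow(x$values), ncol(x$values),
    sum(x$provenance == "direct"), sum(x$provenance == "indirect")))
  invisible(x)
}

#' Restrict predictor and response matrices to their common gene universe
#'
#' @param netmir A [build_netmir()] result.
#' @param disease_matrix A [build_disease_matrix()] result.
#' @return A list with both objects restricted to the shared genes, identical
#'   row order (sorted). Errors when the intersection is empty.
#' @export
intersect_universe <- function(netmir, disease_matrix) {
  common <- sort(intersect(rownames(netmir$values),
                           rownames(disease_matrix$values)))
  if (!length(common)) stop("gene universes are disjoint")
  netmir$values <- netmir$values[common, , drop = FALSE]
  netmir$provenance <- netmir$provenance[common, , drop = FALSE]
  disease_matrix$values <- disease_matrix$values[common, , drop = FALSE]
  list(netmir = netmir, disease_matrix = disease_matrix)
}

#' Write / read a NetmiR matrix as a three-column TSV (gene, miRNA, provenance)
#' @param netmir A `netmir_matrix`.
#' @param path File path.
#' @export
write_netmir <- function(netmir, path) {
  nz <- which(netmir$values != 0, arr.ind = TRUE)
  df <- data.frame(gene = rownames(netmir$values)[nz[, 1]],
                   mirna = colnames(netmir$values)[nz[, 2]],
                   provenance = netmir$provenance[nz])
  df <- df[order(df$gene, df$mirna), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_netmir
#' @export
read_netmir <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene", "mirna", "provenance"))
  direct <- tab[tab$provenance == "direct", , drop = FALSE]
  indirect <- tab[tab$provenance == "indirect", c("gene", "mirna"), drop = FALSE]
  build_netmir(edge_list(direct$mirna, direct$gene, directed = TRUE),
               indirect,
               gene_universe = sort(unique(tab$gene)),
               mirna_universe = sort(unique(tab$mirna)))
}
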