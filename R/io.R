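#' Normalize gene / miRNA identifiers
#'
#' Identifiers are compared at the symbol level: surrounding whitespace is
#' stripped and letters are uppercased. No alias resolution is attempted.
#' The operation is idempotent.
#'
#' @param x Character vector of identifiers.
#' @return Normalized character vector.
#' @examples
#' normalize_id(c(" tp53", "miR-21 "))
#' @export
normalize_id <- function(x) toupper(trimws(as.character(x)))

#' Construct an expression matrix with two-group labels
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param groups Character/factor of per-sample labels, values in
#'   `c("control", "case")`.
#' @param validate_groups Require both groups non-empty (needed for
#'   differential analysis). Default `TRUE`.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values` and `groups`.
#' @export
expression_matrix <- function(values, groups, validate_groups = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("'values' must have gene ids as rownames")
  rownames(values) <- normalize_id(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("length of 'groups' must equal the number of samples")
  bad <- setdiff(unique(groups), c("control", "case"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  groups <- factor(groups, levels = c("control", "case"))
  if (validate_groups && (sum(groups == "control") == 0L ||
                          sum(groups == "case") == 0L))
    stop("both 'control' and 'case' groups must be non-empty")
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "case")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix with group labels from TSV
#'
#' The expression file is tab-separated with the gene identifier in the first
#' column and a header row of sample identifiers. Labels come either from a
#' separate headerless two-column TSV (sample id, label) or as a character
#' vector aligned with the sample columns. Gene symbols are normalized
#' ([normalize_id()]); duplicated genes keep the first occurrence with a
#' warning.
#'
#' @param path Path to the expression TSV.
#' @param labels Path to a two-column sample/label TSV, or a character vector
#'   of labels (one per sample, values `"control"`/`"case"`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, labels) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file needs a header and >=1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- trimws(header[-1L])
  width <- length(header)
  widths <- lengths(fields)
  bad <- which(widths != width)
  if (length(bad))
    stop(sprintf("malformed row width at line %d: expected %d fields, found %d",
                 bad[1L], width, widths[bad[1L]]))
  genes <- normalize_id(vapply(fields[-1L], `[[`, "", 1L))
  vals <- t(vapply(fields[-1L],
                   function(f) as.numeric(f[-1L]),
                   numeric(length(samples))))
  if (length(samples) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("duplicated gene row(s) dropped (first occurrence kept): ",
            paste(dup, collapse = ", "))
    vals <- vals[!duplicated(genes), , drop = FALSE]
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    lab <- utils::read.delim(labels, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("sample", "label"))
    idx <- match(samples, trimws(lab$sample))
    if (anyNA(idx))
      stop("label file is missing sample(s): ",
           paste(samples[is.na(idx)], collapse = ", "))
    labels <- trimws(lab$label[idx])
  }
  expression_matrix(vals, labels)
}

#' Construct a canonical edge list
#'
#' Undirected edges are stored canonically (lexicographically ordered pair),
#' self-loops are dropped with a warning in undirected mode, and duplicates are
#' removed. Identifiers are normalized.
#'
#' @param from,to Character vectors of endpoint identifiers.
#' @param directed Logical flag.
#' @return A data frame of class `"edge_list"` with columns `from`, `to` and
#'   attribute `directed`.
#' @export
edge_list <- function(from = character(), to = character(), directed = FALSE) {
  from <- normalize_id(from)
  to <- normalize_id(to)
  if (length(from) != length(to)) stop("'from' and 'to' lengths differ")
  if (!directed) {
    loops <- from == to
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped from undirected edge list")
      from <- from[!loops]; to <- to[!loops]
    }
    a <- pmin(from, to); b <- pmax(from, to)
    from <- a; to <- b
  }
  keep <- !duplicated(paste(from, to, sep = "\r"))
  el <- data.frame(from = from[keep], to = to[keep],
                   stringsAsFactors = FALSE)
  rownames(el) <- NULL
  structure(el, directed = isTRUE(directed), class = c("edge_list", "data.frame"))
}

#' Read a two-column edge list from TSV
#'
#' @param path Path to a headerless two-column TSV (`--header`-style files can
#'   set `header = TRUE`).
#' @param directed Logical; undirected lists are canonicalized.
#' @param header Skip a header line. Default `FALSE`.
#' @return An [edge_list()]. An empty file yields an empty edge list.
#' @export
read_edge_list <- function(path, directed = FALSE, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines)) lines <- lines[-1L]
  if (!length(lines)) return(edge_list(directed = directed))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop(sprintf("malformed edge row at line %d: expected 2 fields",
                 bad[1L] + as.integer(header)))
  edge_list(vapply(fields, `[[`, "", 1L),
            vapply(fields, `[[`, "", 2L), directed = directed)
}

#' Write an edge list as two-column TSV
#' @param el An [edge_list()].
#' @param path Output path.
#' @export
write_edge_list <- function(el, path) {
  utils::write.table(as.data.frame(el)[, c("from", "to")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a text-mining gene-disease relevance table
#'
#' Four-column TSV: disease, gene, relevance score (>= 0), citation count
#' (integer >= 0). A header row is auto-detected when the numeric columns fail
#' to parse on line 1.
#'
#' @param path Path to the TSV.
#' @return A data frame with columns `disease`, `gene`, `relevance`,
#'   `citations`.
#' @export
read_relevance_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("relevance table needs 4 columns")
  tab <- tab[, 1:4]
  names(tab) <- c("disease", "gene", "relevance", "citations")
  if (is.character(tab$relevance) && is.na(suppressWarnings(as.numeric(tab$relevance[1L]))))
    tab <- tab[-1L, , drop = FALSE]          # header row
  tab$disease <- normalize_id(tab$disease)
  tab$gene <- normalize_id(tab$gene)
  tab$relevance <- as.numeric(tab$relevance)
  tab$citations <- as.integer(tab$citations)
  if (any(tab$relevance < 0, na.rm = TRUE)) stop("negative relevance score")
  if (any(tab$citations < 0, na.rm = TRUE)) stop("negative citation count")
  rownames(tab) <- NULL
  tab
}

#' Construct a disease gene signature
#'
#' @param disease Disease identifier.
#' @param up,down Character vectors of gene symbols (normalized on entry).
#'   Text-derived signatures carry no direction: all genes sit in `up`.
#' @param source One of `"expression"`, `"text"`, `"merged"`.
#' @return An object of class `"gene_signature"`.
#' @export
gene_signature <- function(disease, up = character(), down = character(),
                           source = c("expression", "text", "merged")) {
  source <- match.arg(source)
  up <- sort(unique(normalize_id(up)))
  down <- sort(unique(normalize_id(down)))
  up <- up[nzchar(up)]; down <- down[nzchar(down)]
  if (length(intersect(up, down)))
    stop("genes in both up and down sets: ",
         paste(intersect(up, down), collapse = ", "))
  if (source == "text" && length(down))
    stop("text signatures carry no direction; all genes must be 'up'")
  structure(list(disease = normalize_id(disease), up = up, down = down,
                 source = source),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature '%s' (%s): %d up, %d down\n",
              x$disease, x$source, length(x$up), length(x$down)))
  invisible(x)
}

#' Write / read gene signatures in GMT format
#'
#' One tab-separated line per gene set: set name, description (the signature
#' source), then gene ids. Set names follow `<disease>__up`, `<disease>__down`
#' (omitted when empty) and `<disease>__text`. `read_signatures_gmt()` is the
#' exact inverse on valid data.
#'
#' @param signatures A list of [gene_signature()] objects.
#' @param path Output (input) path.
#' @return `write_signatures_gmt()` returns `path` invisibly;
#'   `read_signatures_gmt()` returns a named list of signatures.
#' @export
write_signatures_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- character()
  seen <- character()
  for (sig in signatures) {
    nm <- if (sig$source == "text") paste0(sig$disease, "__text")
          else paste0(sig$disease, "__up")
    if (nm %in% seen) stop("duplicate set name: ", nm)
    seen <- c(seen, nm)
    lines <- c(lines, paste(c(nm, sig$source, sig$up), collapse = "\t"))
    if (sig$source != "text" && length(sig$down)) {
      nm2 <- paste0(sig$disease, "__down")
      if (nm2 %in% seen) stop("duplicate set name: ", nm2)
      seen <- c(seen, nm2)
      lines <- c(lines, paste(c(nm2, sig$source, sig$down), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_signatures_gmt
#' @export
read_signatures_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate set name: ", nms[duplicated(nms)][1L])
  if (!all(grepl("__(up|down|text)$", nms)))
    stop("GMT set names must end in __up, __down or __text")
  disease <- sub("__(up|down|text)$", "", nms)
  kind <- sub("^.*__", "", nms)
  src <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", "")
  genes <- lapply(fields, function(f) if (length(f) > 2L) f[-(1:2)] else character())
  out <- list()
  for (d in unique(disease)) {
    i <- which(disease == d)
    k <- kind[i]
    if ("text" %in% k) {
      if (length(i) > 1L) stop("disease '", d, "' mixes text and directional sets")
      out[[d]] <- gene_signature(d, up = genes[[i]], source = "text")
    } else {
      up <- if ("up" %in% k) genes[[i[k == "up"]]] else character()
      down <- if ("down" %in% k) genes[[i[k == "down"]]] else character()
      source <- src[i[1L]]
      if (!source %in% c("expression", "merged")) source <- "merged"
      out[[d]] <- gene_signature(d, up = up, down = down, source = source)
    }
  }
  out
}
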