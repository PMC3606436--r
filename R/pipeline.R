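#' Build merged disease signatures from expression and text inputs
#'
#' For each disease with an expression matrix: SAM-style d-statistic, top-k
#' up/down expression signature, text signature filtered on relevance and
#' citations, and the union merge of the two.
#'
#' @param expr Named list of [expression_matrix()] objects (names = disease
#'   ids). A disease may map to a list of matrices (one per experiment);
#'   per-experiment signatures are unioned.
#' @param text Optional relevance table ([read_relevance_table()] layout);
#'   `NULL` skips the text route.
#' @param control A [mirlasso_control()].
#' @return Named list of merged [gene_signature()] objects.
#' @export
build_signatures <- function(expr, text = NULL,
                             control = mirlasso_control()) {
  sigs <- list()
  for (d in names(expr)) {
    mats <- expr[[d]]
    if (inherits(mats, "expression_matrix")) mats <- list(mats)
    esig <- NULL
    for (em in mats) {
      one <- expression_signature(d_statistic(em, s0 = "auto"), d,
                                  k_up = control$k_up, k_down = control$k_down)
      esig <- if (is.null(esig)) one else
        gene_signature(d, up = union(esig$up, setdiff(one$up, esig$down)),
                       down = union(esig$down, setdiff(one$down, esig$up)),
                       source = "expression")
    }
    if (!is.null(text)) {
      tsig <- text_signature(text, d,
                             min_relevance = control$min_relevance,
                             min_citations = control$min_citations)
      sigs[[normalize_id(d)]] <- merge_signatures(esig, tsig)
    } else {
      sigs[[normalize_id(d)]] <- esig
    }
  }
  sigs
}

#' Run the full disease-miRNA association pipeline
#'
#' The four-stage flow: (1) merged disease signatures from expression + text;
#' (2) NetmiR influence matrix from direct targets plus (optionally)
#' PPI-propagated indirect targets; (3) per-disease Lasso fits with
#' cross-validated penalty selection; (4) positive-coefficient association
#' network, evaluated by per-disease ROC against a gold standard when one is
#' supplied.
#'
#' @inheritParams build_signatures
#' @param direct Directed miRNA -> gene [edge_list()].
#' @param ppi Undirected PPI [edge_list()] (`NULL` disables the indirect
#'   step).
#' @param gold Optional directed disease -> miRNA gold-standard
#'   [edge_list()].
#' @param use_indirect Include PPI-propagated indirect targets (default
#'   `TRUE`; ignored with a warning when `ppi` is `NULL`).
#' @param control A [mirlasso_control()].
#' @return A list with `signatures`, `netmir`, `disease_matrix`, `model`
#'   (a [mirlasso()] object), `associations` and, when `gold` is given,
#'   `roc` (see [roc_auc()]).
#' @export
run_pipeline <- function(expr, text, direct, ppi = NULL, gold = NULL,
                         use_indirect = TRUE,
                         control = mirlasso_control()) {
  if (use_indirect && is.null(ppi)) {
    warning("no PPI network supplied; indirect-target step skipped")
    use_indirect <- FALSE
  }
  sigs <- build_signatures(expr, text, control)
  ind <- if (use_indirect)
    indirect_targets(ppi, direct, min_neighbors = control$min_neighbors,
                     mode = control$indirect_mode)
  else NULL
  netmir <- suppressWarnings(build_netmir(
    direct, ind,
    gene_universe = sort(unique(c(direct$to, ind$gene))),
    mirna_universe = sort(unique(direct$from))))
  dmat <- suppressWarnings(build_disease_matrix(
    sigs, gene_universe = rownames(netmir$values),
    encoding = if (control$signed) "signed" else "membership"))
  model <- mirlasso(netmir, dmat, control = control)
  assoc <- extract_associations(model, keep_sign = control$keep_sign)
  out <- list(signatures = sigs, netmir = netmir, disease_matrix = dmat,
              model = model, associations = assoc)
  if (!is.null(gold))
    out$roc <- suppressWarnings(
      roc_auc(assoc, gold, mirnas = colnames(netmir$values),
              diseases = names(sigs)))
  out
}

#' Run the pipeline end to end and write every artifact to a directory
#'
#' File-level entry point mirroring the staged flow: inputs are either
#' simulated ([simulate_study()]) or read from the supplied paths, all
#' intermediate artifacts are written in the package's documented formats,
#' and a JSON manifest records the configuration, seed and input/output
#' digests.
#'
#' @param outdir Output directory.
#' @param simulate Generate inputs with [simulate_study()] (default `TRUE`).
#' @param synth A [synth_config()] used when simulating (its `seed` is the
#'   run seed).
#' @param paths When `simulate = FALSE`, a named list of input paths:
#'   `expr` (named character vector of expression TSVs, names = diseases),
#'   `labels` (parallel label TSVs), `text`, `direct`, `ppi` (optional),
#'   `gold` (optional).
#' @param use_indirect Include the indirect-target step (default `TRUE`).
#' @param control A [mirlasso_control()].
#' @return Invisibly, the [run_pipeline()] result; side effect: files
#'   `signatures.gmt`, `netmir.tsv`, `associations.tsv`, `roc_report.tsv`
#'   (when a gold standard exists) and `manifest.json` under `outdir`.
#' @export
run_all <- function(outdir, simulate = TRUE, synth = synth_config(),
                    paths = NULL, use_indirect = TRUE,
                    control = mirlasso_control()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  input_paths <- character()
  if (simulate) {
    sim <- simulate_study(synth, min_neighbors = control$min_neighbors)
    input_paths <- write_simulation(sim, file.path(outdir, "inputs"))
    expr <- sim$expr; text <- sim$text
    direct <- sim$direct; ppi <- sim$ppi; gold <- sim$gold
  } else {
    if (is.null(paths)) stop("either simulate or supply 'paths'")
    expr <- lapply(seq_along(paths$expr), function(i)
      read_expression(paths$expr[[i]], paths$labels[[i]]))
    names(expr) <- names(paths$expr)
    text <- if (!is.null(paths$text)) read_relevance_table(paths$text)
    direct <- read_edge_list(paths$direct, directed = TRUE)
    ppi <- if (!is.null(paths$ppi)) read_edge_list(paths$ppi, directed = FALSE)
    gold <- if (!is.null(paths$gold)) read_edge_list(paths$gold, directed = TRUE)
    input_paths <- unlist(paths)
  }
  res <- run_pipeline(expr, text, direct, ppi = ppi, gold = gold,
                      use_indirect = use_indirect, control = control)
  out_paths <- c(signatures = file.path(outdir, "signatures.gmt"),
                 netmir = file.path(outdir, "netmir.tsv"),
                 associations = file.path(outdir, "associations.tsv"))
  write_signatures_gmt(res$signatures, out_paths[["signatures"]])
  write_netmir(res$netmir, out_paths[["netmir"]])
  utils::write.table(res$associations, out_paths[["associations"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$roc)) {
    rp <- file.path(outdir, "roc_report.tsv")
    rep_df <- data.frame(disease = names(res$roc$auc),
                         auc = unname(res$roc$auc))
    rep_df <- rbind(rep_df,
                    data.frame(disease = "_pooled_",
                               auc = res$roc$pooled$auc))
    utils::write.table(rep_df, rp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out_paths[["roc_report"]] <- rp
  }
  manifest <- list(
    tool = "mirlassonet",
    version = as.character(utils::packageVersion("mirlassonet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (simulate) synth$seed else control$seed,
    control = unclass(control),
    synth = if (simulate) unclass(synth) else NULL,
    inputs = as.list(tools::md5sum(unname(input_paths))),
    outputs = as.list(tools::md5sum(unname(out_paths))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
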