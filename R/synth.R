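#' Configuration of the synthetic benchmark generator
#'
#' Defines the study conditions emulated by [simulate_study()]: coupled PPI,
#' direct-target, expression, text-mining and gold-standard inputs with a
#' planted disease -> miRNA ground truth.
#'
#' @param n_genes Number of genes (default 600).
#' @param n_mirnas Number of miRNAs (default 50).
#' @param n_diseases Number of diseases (default 8).
#' @param targets_per_mirna Direct targets drawn per miRNA, without
#'   replacement (default 30).
#' @param ppi_mean_degree Expected mean degree of the Erdős–Rényi PPI graph
#'   (default 6); `ppi_model = "ba"` gives a Barabási–Albert-style
#'   preferential-attachment graph instead (hubs interact with the
#'   five-neighbour indirect rule).
#' @param planted_mirnas_per_disease Causal miRNAs planted per disease
#'   (default 3).
#' @param signature_noise_frac Fraction of signature genes replaced by random
#'   off-signature genes (default 0.2).
#' @param signature_dropout_frac Fraction of planted-target genes omitted from
#'   the signature (default 0.3).
#' @param effect_size Mean case-group shift on signature genes, in units of
#'   the within-group SD (default 2.0); the shift sign is random per gene and
#'   fixed per disease.
#' @param n_samples_per_group Samples per group in each expression matrix
#'   (default 10).
#' @param seed Master RNG seed; one seed fixes every generated artifact.
#' @param ppi_model `"er"` (default) or `"ba"`.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 600L, n_mirnas = 50L, n_diseases = 8L,
                         targets_per_mirna = 30L, ppi_mean_degree = 6,
                         planted_mirnas_per_disease = 3L,
                         signature_noise_frac = 0.2,
                         signature_dropout_frac = 0.3,
                         effect_size = 2.0, n_samples_per_group = 10L,
                         seed = 17L, ppi_model = c("er", "ba")) {
  ppi_model <- match.arg(ppi_model)
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              n_diseases = as.integer(n_diseases),
              targets_per_mirna = as.integer(targets_per_mirna),
              ppi_mean_degree = as.numeric(ppi_mean_degree),
              planted_mirnas_per_disease = as.integer(planted_mirnas_per_disease),
              signature_noise_frac = as.numeric(signature_noise_frac),
              signature_dropout_frac = as.numeric(signature_dropout_frac),
              effect_size = as.numeric(effect_size),
              n_samples_per_group = as.integer(n_samples_per_group),
              seed = as.integer(seed), ppi_model = ppi_model)
  for (nm in c("n_genes", "n_mirnas", "n_diseases", "targets_per_mirna",
               "planted_mirnas_per_disease", "n_samples_per_group"))
    if (cfg[[nm]] < 1L) stop("'", nm, "' must be a positive integer")
  for (nm in c("signature_noise_frac", "signature_dropout_frac"))
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1)
      stop("'", nm, "' must lie in [0, 1)")
  if (cfg$ppi_mean_degree < 0) stop("'ppi_mean_degree' must be >= 0")
  if (cfg$planted_mirnas_per_disease > cfg$n_mirnas)
    stop("'planted_mirnas_per_disease' cannot exceed 'n_mirnas'")
  if (cfg$targets_per_mirna > cfg$n_genes)
    stop("'targets_per_mirna' cannot exceed 'n_genes'")
  class(cfg) <- "synth_config"
  cfg
}

synth_gene_ids <- function(n) sprintf("G%04d", seq_len(n))
synth_mirna_ids <- function(n) sprintf("MIR-%03d", seq_len(n))
synth_disease_ids <- function(n) sprintf("DISEASE%02d", seq_len(n))

#' Generate the synthetic PPI and direct-target networks
#'
#' The PPI graph is Erdős–Rényi with edge probability
#' `ppi_mean_degree / (n_genes - 1)` (or a preferential-attachment graph with
#' the same mean degree under `ppi_model = "ba"`); each miRNA receives
#' `targets_per_mirna` direct target genes drawn uniformly without
#' replacement. All draws come from the seeded RNG, so the same configuration
#' reproduces identical edge sets.
#'
#' @param config A [synth_config()].
#' @return A list with `ppi` (undirected [edge_list()]) and `direct`
#'   (directed miRNA -> gene [edge_list()]).
#' @export
generate_networks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    genes <- synth_gene_ids(config$n_genes)
    mirnas <- synth_mirna_ids(config$n_mirnas)
    n <- config$n_genes
    if (config$ppi_model == "er") {
      p <- if (n > 1) min(1, config$ppi_mean_degree / (n - 1)) else 0
      first <- rep.int(seq_len(n - 1), rev(seq_len(n - 1)))
      second <- first + sequence(rev(seq_len(n - 1)))
      keep <- stats::runif(length(first)) < p
      ppi <- edge_list(genes[first[keep]], genes[second[keep]],
                       directed = FALSE)
    } else {
      # preferential attachment: m edges per arriving node
      m <- max(1L, round(config$ppi_mean_degree / 2))
      from <- integer(); to <- integer()
      deg <- rep(0L, n)
      for (v in 2:n) {
        k <- min(m, v - 1L)
        w <- deg[seq_len(v - 1L)] + 1
        nb <- sample.int(v - 1L, k, prob = w)
        from <- c(from, rep.int(v, k)); to <- c(to, nb)
        deg[v] <- deg[v] + k; deg[nb] <- deg[nb] + 1L
      }
      ppi <- edge_list(genes[from], genes[to], directed = FALSE)
    }
    direct <- edge_list(
      rep(mirnas, each = config$targets_per_mirna),
      unlist(lapply(mirnas, function(m)
        sample(genes, config$targets_per_mirna))),
      directed = TRUE)
    list(ppi = ppi, direct = direct)
  })
}

#' Generate per-disease expression, text-mining and gold-standard data
#'
#' For each disease a set of planted miRNAs is drawn; the disease signature is
#' the union of their direct and indirect target genes, thinned by
#' `signature_dropout_frac` and with `signature_noise_frac` of the remaining
#' genes replaced by random off-signature genes. Expression: controls are
#' standard normal; cases are shifted by `±effect_size` on signature genes
#' (sign fixed per gene within a disease). The text table contains half of the
#' signature genes (relevance ~ U(0.1, 1), citations ~ 11 + Poisson(20)) plus
#' decoy records that fail the relevance/citation filter. The gold standard
#' holds exactly the planted (disease, miRNA) pairs.
#'
#' @param config A [synth_config()].
#' @param networks Output of [generate_networks()].
#' @param min_neighbors Indirect-target threshold used when planting
#'   signatures (default 5, matching the analysis default).
#' @return A list with `expr` (named list of [expression_matrix()], one per
#'   disease), `text` (relevance data frame), `gold` (directed
#'   disease -> miRNA [edge_list()]) and `truth` (list with `planted` and
#'   `true_signatures`).
#' @export
generate_disease_data <- function(config, networks, min_neighbors = 5L) {
  stopifnot(inherits(config, "synth_config"))
  genes <- synth_gene_ids(config$n_genes)
  mirnas <- synth_mirna_ids(config$n_mirnas)
  diseases <- synth_disease_ids(config$n_diseases)
  indirect <- indirect_targets(networks$ppi, networks$direct,
                               min_neighbors = min_neighbors)
  influence <- split(networks$direct$to, networks$direct$from)
  if (nrow(indirect)) {
    ind_split <- split(indirect$gene, indirect$mirna)
    for (m in names(ind_split))
      influence[[m]] <- union(influence[[m]], ind_split[[m]])
  }
  with_seed(config$seed + 1L, {
    planted <- list(); signatures <- list()
    expr <- list(); text_rows <- list()
    gold_from <- character(); gold_to <- character()
    n_samp <- config$n_samples_per_group
    samples <- sprintf("S%02d", seq_len(2L * n_samp))
    groups <- rep(c("control", "case"), each = n_samp)
    for (d in diseases) {
      pm <- sample(mirnas, config$planted_mirnas_per_disease)
      base <- sort(unique(unlist(influence[pm], use.names = FALSE)))
      sig <- character()
      for (attempt in seq_len(10L)) {
        keep <- base
        n_drop <- round(config$signature_dropout_frac * length(base))
        if (n_drop > 0) keep <- setdiff(keep, sample(base, n_drop))
        n_noise <- round(config$signature_noise_frac * length(keep))
        if (n_noise > 0 && length(keep)) {
          out <- sample(keep, n_noise)
          pool <- setdiff(genes, keep)
          keep <- c(setdiff(keep, out), sample(pool, min(n_noise, length(pool))))
        }
        if (length(keep)) { sig <- sort(keep); break }
        warning("disease '", d, "': empty signature after thinning; resampling")
      }
      if (!length(sig))
        stop("disease '", d, "': signature empty after 10 thinning attempts")
      planted[[d]] <- sort(pm)
      signatures[[d]] <- sig
      vals <- matrix(stats::rnorm(config$n_genes * 2L * n_samp),
                     nrow = config$n_genes,
                     dimnames = list(genes, samples))
      shift_sign <- sample(c(-1, 1), length(sig), replace = TRUE)
      vals[sig, groups == "case"] <- vals[sig, groups == "case"] +
        shift_sign * config$effect_size
      expr[[d]] <- expression_matrix(vals, groups)
      tg <- sample(sig, ceiling(length(sig) / 2))
      n_decoy <- max(2L, length(tg))
      dec_genes <- sample(genes, n_decoy, replace = TRUE)
      half <- seq_len(floor(n_decoy / 2))
      dec_rel <- stats::runif(n_decoy, 0.1, 1)
      dec_cit <- 11L + stats::rpois(n_decoy, 20)
      dec_rel[half] <- 0                                  # fail relevance > 0
      dec_cit[-half] <- sample(0:10, n_decoy - length(half), replace = TRUE)
      text_rows[[d]] <- data.frame(
        disease = d,
        gene = c(tg, dec_genes),
        relevance = c(stats::runif(length(tg), 0.1, 1), dec_rel),
        citations = c(11L + stats::rpois(length(tg), 20), dec_cit),
        stringsAsFactors = FALSE)
      gold_from <- c(gold_from, rep(d, length(pm)))
      gold_to <- c(gold_to, sort(pm))
    }
    list(expr = expr,
         text = do.call(rbind, c(text_rows, make.row.names = FALSE)),
         gold = edge_list(gold_from, gold_to, directed = TRUE),
         truth = list(planted = planted, true_signatures = signatures))
  })
}

#' Generate a complete coupled synthetic study
#'
#' Convenience wrapper running [generate_networks()] and
#' [generate_disease_data()] and additionally assembling the NetmiR influence
#' matrix from the generated networks.
#'
#' @inheritParams generate_disease_data
#' @return A list with `config`, `ppi`, `direct`, `netmir`, `expr`, `text`,
#'   `gold`, `truth`.
#' @export
simulate_study <- function(config = synth_config(), min_neighbors = 5L) {
  nets <- generate_networks(config)
  dat <- generate_disease_data(config, nets, min_neighbors = min_neighbors)
  ind <- indirect_targets(nets$ppi, nets$direct, min_neighbors = min_neighbors)
  netmir <- suppressWarnings(build_netmir(
    nets$direct, ind,
    gene_universe = sort(unique(c(nets$direct$to, ind$gene))),
    mirna_universe = synth_mirna_ids(config$n_mirnas)))
  c(list(config = config, ppi = nets$ppi, direct = nets$direct,
         netmir = netmir), dat)
}

#' Write a simulated study to disk in the package's input formats
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             direct = file.path(dir, "targets.tsv"),
             text = file.path(dir, "text.tsv"),
             gold = file.path(dir, "gold.tsv"))
  write_edge_list(sim$ppi, paths[["ppi"]])
  write_edge_list(sim$direct, paths[["direct"]])
  utils::write.table(sim$text, paths[["text"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_edge_list(sim$gold, paths[["gold"]])
  for (d in names(sim$expr)) {
    ep <- file.path(dir, paste0("expression_", d, ".tsv"))
    lp <- file.path(dir, paste0("labels_", d, ".tsv"))
    em <- sim$expr[[d]]
    tab <- data.frame(gene = rownames(em$values), em$values,
                      check.names = FALSE)
    utils::write.table(tab, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = colnames(em$values), label = as.character(em$groups)),
      lp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths[[paste0("expression_", d)]] <- ep
    paths[[paste0("labels_", d)]] <- lp
  }
  invisible(paths)
}
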