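# Independent oracles used across the suite. Deliberately naive: explicit
# loops and closed forms, no shared code with the implementation.

# Brute-force indirect-target rule: double loop over genes x miRNAs counting
# directly-targeted PPI neighbours.
bf_indirect <- function(ppi, direct, k, mode = "per_mirna") {
  genes <- sort(unique(c(ppi$from, ppi$to, direct$to)))
  mirnas <- sort(unique(direct$from))
  rows <- list()
  for (m in mirnas) {
    tj <- unique(direct$to[direct$from == m])
    for (g in genes) {
      if (g %in% tj) next
      if (mode == "any_mirna" && g %in% direct$to) next
      nb <- unique(c(ppi$to[ppi$from == g], ppi$from[ppi$to == g]))
      if (length(intersect(nb, tj)) >= k)
        rows[[length(rows) + 1L]] <- data.frame(gene = g, mirna = m)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), mirna = character()))
  out <- do.call(rbind, rows)
  out[order(out$mirna, out$gene), , drop = FALSE]
}

# Exhaustive hypergeometric enumeration over all tables with fixed margins.
# Returns the full support and pmf (from choose(), not phyper/dhyper).
enum_tables <- function(list_size, target_size, universe_size) {
  ks <- max(0L, list_size + target_size - universe_size):min(list_size, target_size)
  pmf <- choose(target_size, ks) *
    choose(universe_size - target_size, list_size - ks) /
    choose(universe_size, list_size)
  list(k = ks, pmf = pmf)
}

enum_hyper_p <- function(a, list_size, target_size, universe_size) {
  tb <- enum_tables(list_size, target_size, universe_size)
  sum(tb$pmf[tb$k >= a])
}

# Two-sided exact conditional p: sum of tables no more probable than the
# observed one (with the conventional 1 + 1e-7 relative guard against
# floating-point ties).
enum_fisher_p <- function(a, list_size, target_size, universe_size) {
  tb <- enum_tables(list_size, target_size, universe_size)
  obs <- tb$pmf[tb$k == a]
  min(1, sum(tb$pmf[tb$pmf <= obs * (1 + 1e-7)]))
}

# AUC by exhaustive pair counting: (concordant + ties/2) / (n_pos * n_neg).
pc_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  diff <- outer(pos, neg, "-")
  (sum(diff > 0) + 0.5 * sum(diff == 0)) / (length(pos) * length(neg))
}

trapezoid_area <- function(points) {
  x <- points$fpr; y <- points$tpr
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Lasso objective on the original (uncentred) scale with the half-weighted
# penalty: 1/(2n) ||y - b0 - X beta||^2 + (lambda/2) ||beta||_1.
lasso_objective <- function(X, y, intercept, beta, lambda) {
  r <- y - intercept - as.numeric(X %*% beta)
  sum(r^2) / (2 * length(y)) + (lambda / 2) * sum(abs(beta))
}

# Small deterministic random regression instance.
random_instance <- function(n, p, seed, noise = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("M", seq_len(p))))
  beta <- rnorm(p) * rbinom(p, 1, 0.5)
  y <- as.numeric(X %*% beta) + noise * rnorm(n)
  list(X = X, y = y, beta = beta)
}

# Random PPI + direct-target instance on `n` genes for the indirect rule.
random_network <- function(n, n_mirnas, seed, p_edge = 0.06, p_target = 0.15) {
  set.seed(seed)
  genes <- sprintf("N%03d", seq_len(n))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  ppi <- edge_list(pairs[keep, 1], pairs[keep, 2], directed = FALSE)
  mirnas <- sprintf("MIR-%02d", seq_len(n_mirnas))
  from <- character(); to <- character()
  for (m in mirnas) {
    tg <- genes[runif(n) < p_target]
    from <- c(from, rep(m, length(tg))); to <- c(to, tg)
  }
  list(ppi = ppi, direct = edge_list(from, to, directed = TRUE))
}
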