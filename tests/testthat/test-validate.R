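make_sets <- function(a, list_size, target_size, universe_size) {
  universe <- sprintf("U%03d", seq_len(universe_size))
  targets <- universe[seq_len(target_size)]
  gl <- c(targets[seq_len(a)],
          setdiff(universe, targets)[seq_len(list_size - a)])
  list(gl = gl, targets = targets, universe = universe)
}

test_that("Fisher p-values match hypergeometric enumeration", {
  # the fully separated 5/0/0/5 table plus a sweep of margins
  s <- make_sets(5, 5, 5, 10)
  f <- fisher_enrichment(s$gl, s$targets, s$universe)
  expect_equal(f$p_value, enum_fisher_p(5, 5, 5, 10), tolerance = 1e-12)
  expect_equal(f$overlap, 5)
  expect_true(is.infinite(f$odds_ratio))
  for (us in c(6, 14, 22, 30)) {
    for (ts in unique(c(1, us %/% 3, us %/% 2))) {
      for (ls in unique(c(1, us %/% 4, us %/% 2, us))) {
        for (a in max(0, ls + ts - us):min(ls, ts)) {
          s <- make_sets(a, ls, ts, us)
          got <- fisher_enrichment(s$gl, s$targets, s$universe)$p_value
          expect_equal(got, enum_fisher_p(a, ls, ts, us), tolerance = 1e-10,
                       label = sprintf("fisher a=%d ls=%d ts=%d us=%d",
                                       a, ls, ts, us))
        }
      }
    }
  }
})

test_that("degenerate Fisher margins give p = 1", {
  universe <- sprintf("U%02d", 1:8)
  # gene list == universe: only one table possible
  f <- fisher_enrichment(universe, universe[1:3], universe)
  expect_equal(f$overlap, 3)
  expect_equal(f$p_value, 1)
  # empty gene list
  f2 <- fisher_enrichment(character(), universe[1:3], universe)
  expect_equal(f2$overlap, 0)
  expect_equal(f2$p_value, 1)
  expect_error(fisher_enrichment("A", "A", character()), "non-empty")
})

test_that("hypergeometric tail matches enumeration", {
  # zero overlap: tail from zero is the whole distribution
  s <- make_sets(0, 4, 3, 12)
  expect_equal(hypergeometric_enrichment(s$gl, s$targets, s$universe)$p_value, 1)
  # maximal overlap: single-term tail
  s <- make_sets(3, 3, 3, 9)
  h <- hypergeometric_enrichment(s$gl, s$targets, s$universe)
  expect_equal(h$p_value, enum_hyper_p(3, 3, 3, 9), tolerance = 1e-12)
  expect_equal(h$p_value, 1 / choose(9, 3), tolerance = 1e-12)
  for (us in c(7, 15, 23, 30)) {
    for (ts in unique(c(2, us %/% 3))) {
      for (ls in unique(c(2, us %/% 2))) {
        for (a in max(0, ls + ts - us):min(ls, ts)) {
          s <- make_sets(a, ls, ts, us)
          got <- hypergeometric_enrichment(s$gl, s$targets, s$universe)$p_value
          expect_equal(got, enum_hyper_p(a, ls, ts, us), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("for over-represented overlaps the hypergeometric p never exceeds the two-sided Fisher p", {
  # beyond the distribution mode the upper tail is a subset of the tables the
  # two-sided test sums, so the one-sided p is bounded by the two-sided p;
  # below the mode the inequality genuinely reverses, so only the
  # over-representation regime (the one enrichment analysis uses) is asserted
  set.seed(77)
  for (rep in 1:100) {
    us <- sample(4:30, 1)
    ts <- sample(1:us, 1)
    ls <- sample(1:us, 1)
    mode_k <- floor((ls + 1) * (ts + 1) / (us + 2))
    lo <- max(max(0, ls + ts - us), min(mode_k, min(ls, ts)))
    cand <- seq.int(lo, min(ls, ts))
    a <- cand[sample.int(length(cand), 1)]
    s <- make_sets(a, ls, ts, us)
    ph <- hypergeometric_enrichment(s$gl, s$targets, s$universe)$p_value
    pf <- fisher_enrichment(s$gl, s$targets, s$universe)$p_value
    expect_lte(ph, pf + 1e-12)
  }
})

test_that("perfect and anti-perfect separation give AUC 1 and 0", {
  scores <- c(5, 4, 3, 2, 1)
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_curve(scores, labels)$auc, 1)
  expect_equal(roc_curve(-scores, labels)$auc, 0)
  expect_error(roc_curve(scores, rep(TRUE, 5)), "negative")
  expect_error(roc_curve(scores, rep(FALSE, 5)), "positive")
})

test_that("rank AUC equals exhaustive pair counting under ties", {
  # the 6-pair tied example, checked by hand-enumerable pair counting
  scores <- c(0.9, 0.5, 0.5, 0.5, 0.1, 0.1)
  labels <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  r <- roc_curve(scores, labels)
  expect_equal(r$auc, pc_auc(scores, labels), tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, pc_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("threshold-sweep curve area equals the rank AUC", {
  set.seed(19)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    scores <- round(rnorm(n), sample(0:2, 1))
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    r <- roc_curve(scores, labels)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(trapezoid_area(r$points), r$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  scores <- rnorm(30)
  labels <- runif(30) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  base <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(exp(scores), labels)$auc, base)
  expect_equal(roc_curve(2 * scores + 7, labels)$auc, base)
  expect_equal(roc_curve(atan(scores), labels)$auc, base)
})

test_that("rank AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (rep in 1:10) {
    scores <- c(rnorm(20), rnorm(15, 1))
    labels <- rep(c(FALSE, TRUE), c(20, 15))
    ours <- roc_curve(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("grid evaluation imputes zero for unpredicted pairs", {
  pred <- data.frame(disease = "D1", mirna = "M1", score = 0.5)
  gold <- edge_list(c("D1", "D1"), c("M1", "M2"), directed = TRUE)
  res <- roc_auc(pred, gold, mirnas = c("M1", "M2", "M3", "M4"))
  # positives: M1 (0.5), M2 (0); negatives: M3, M4 (0 each)
  expect_equal(res$per_disease$D1$n_pos, 2L)
  expect_equal(res$per_disease$D1$n_neg, 2L)
  expect_equal(res$per_disease$D1$auc, pc_auc(c(0.5, 0, 0, 0),
                                              c(TRUE, TRUE, FALSE, FALSE)))
  # a disease without gold positives is skipped with a warning
  pred2 <- rbind(pred, data.frame(disease = "D2", mirna = "M3", score = 1))
  expect_warning(res2 <- roc_auc(pred2, gold, mirnas = paste0("M", 1:4)),
                 "no gold positives")
  expect_named(res2$per_disease, "D1")
})

test_that("gene-list enrichment ranks the generating miRNA first", {
  net <- random_network(60, 5, seed = 51, p_target = 0.25)
  nm <- suppressWarnings(build_netmir(net$direct, NULL,
                                      sort(unique(net$direct$to)),
                                      sort(unique(net$direct$from))))
  m <- colnames(nm$values)[2]
  gl <- rownames(nm$values)[nm$values[, m] == 1]
  for (method in c("lasso", "fisher", "hypergeometric")) {
    out <- suppressWarnings(
      enrich_mirnas(gl, nm, method = method,
                    control = mirlasso_control(n_lambda = 40, n_folds = 5)))
    expect_equal(out$mirna[1], m)
  }
  expect_error(enrich_mirnas("NOT-A-GENE", nm), "no query genes")
})
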