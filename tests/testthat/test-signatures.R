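make_expr <- function(values, n_control, n_case) {
  m <- as.matrix(values)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  expression_matrix(m, rep(c("control", "case"), c(n_control, n_case)))
}

test_that("d-statistic matches the pooled-standard-error formula by hand", {
  # one gene, control = (1, 1), case = (3, 3), s0 = 1:
  # pooled SE s = sqrt((1/2 + 1/2) * (0 + 0) / 2) = 0, d = (3 - 1)/(0 + 1) = 2
  em <- make_expr(matrix(c(1, 1, 3, 3), nrow = 1), 2, 2)
  res <- d_statistic(em, s0 = 1)
  expect_equal(res$d, 2)
  # non-degenerate hand case: control = (1, 2), case = (4, 6), s0 = 0.5
  # m1 = 1.5, m2 = 5, SS1 = 0.5, SS2 = 2, s = sqrt(1 * 2.5 / 2) = sqrt(1.25)
  em2 <- make_expr(matrix(c(1, 2, 4, 6), nrow = 1), 2, 2)
  res2 <- d_statistic(em2, s0 = 0.5)
  expect_equal(res2$d, 3.5 / (sqrt(1.25) + 0.5))
})

test_that("d-statistic is exactly antisymmetric under label swap", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rnorm(30 * 9), 30)
    em <- make_expr(m, 4, 5)
    em_swap <- expression_matrix(
      em$values, rev(rep(c("control", "case"), c(5, 4))))
    d1 <- d_statistic(em, s0 = 0.1)$d
    d2 <- d_statistic(em_swap, s0 = 0.1)$d
    expect_identical(d1, -d2)
  }
})

test_that("zero numerator gives d = 0; zero variance needs s0 > 0", {
  em <- make_expr(matrix(c(2, 4, 4, 2), nrow = 1), 2, 2)
  expect_equal(d_statistic(em, s0 = 1)$d, 0)
  flat <- make_expr(matrix(5, 1, 4), 2, 2)
  expect_error(d_statistic(flat, s0 = 0), "s0 > 0")
  expect_error(d_statistic(make_expr(matrix(1:4, 1), 1, 3), s0 = 1), ">= 2")
})

test_that("expression signature takes top-k by direction with stated ties", {
  ds <- structure(data.frame(gene = c("B", "A", "C"), d = c(2, 2, -1)),
                  class = c("dstat_result", "data.frame"))
  sig <- expression_signature(ds, "D", k_up = 1, k_down = 5)
  expect_equal(sig$up, "A")           # tie broken lexicographically
  expect_equal(sig$down, "C")         # fewer qualifying than k: all taken
  allneg <- structure(data.frame(gene = c("A", "B"), d = c(-1, -2)),
                      class = c("dstat_result", "data.frame"))
  expect_equal(expression_signature(allneg, "D", 100, 1)$up, character())
})

test_that("signature sizes never exceed k_up/k_down", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:80, 1)
    ds <- structure(
      data.frame(gene = sprintf("G%03d", 1:n),
                 d = round(rnorm(n), 1)),   # rounded to force ties
      class = c("dstat_result", "data.frame"))
    k_up <- sample(0:20, 1); k_down <- sample(0:20, 1)
    sig <- expression_signature(ds, "D", k_up, k_down)
    expect_lte(length(sig$up), k_up)
    expect_lte(length(sig$down), k_down)
    expect_true(all(ds$d[match(sig$up, ds$gene)] > 0))
    expect_true(all(ds$d[match(sig$down, ds$gene)] < 0))
  }
})

test_that("text signature applies strict relevance and citation filters", {
  tab <- data.frame(disease = "D",
                    gene = c("G1", "G2", "G3"),
                    relevance = c(0.5, 0.0, 0.9),
                    citations = c(12L, 50L, 10L))
  sig <- text_signature(tab, "D")
  expect_equal(sig$up, "G1")        # G2: relevance must exceed 0; G3: <11 cites
  expect_equal(sig$source, "text")
  expect_warning(empty <- text_signature(tab, "ABSENT"), "absent")
  expect_equal(length(empty$up), 0L)
})

test_that("raising either text threshold never adds genes", {
  set.seed(11)
  tab <- data.frame(disease = "D",
                    gene = sprintf("G%03d", 1:60),
                    relevance = round(runif(60, 0, 1), 2),
                    citations = sample(0:40, 60, replace = TRUE))
  prev <- NULL
  for (mr in c(0, 0.2, 0.5)) for (mc in c(0, 11, 25)) {
    cur <- text_signature(tab, "D", min_relevance = mr, min_citations = mc)$up
    base <- text_signature(tab, "D", min_relevance = 0, min_citations = 0)$up
    expect_true(all(cur %in% base))
    looser <- text_signature(tab, "D", min_relevance = 0, min_citations = mc)$up
    expect_true(all(cur %in% looser))
  }
})

test_that("merge keeps expression direction and unions text membership", {
  e <- gene_signature("D", up = "A", down = "B", source = "expression")
  t <- gene_signature("D", up = c("A", "C"), source = "text")
  m <- merge_signatures(e, t)
  expect_setequal(signature_genes(m), c("A", "B", "C"))
  expect_true("C" %in% m$up)                 # text-only: direction unknown -> up
  expect_equal(m$down, "B")
  expect_equal(m$source, "merged")
  # expression "down" wins over text membership
  t2 <- gene_signature("D", up = "B", source = "text")
  expect_equal(merge_signatures(e, t2)$down, "B")
  # empty text signature: merged membership equals expression membership
  m2 <- merge_signatures(e, gene_signature("D", source = "text"))
  expect_setequal(signature_genes(m2), signature_genes(e))
  expect_error(merge_signatures(e, gene_signature("E", source = "text")),
               "mismatch")
})

test_that("disease matrix encodes membership with correct column sums", {
  sigs <- list(gene_signature("D1", up = c("A", "B"), source = "merged"),
               gene_signature("D2", up = "C", source = "merged"))
  dm <- build_disease_matrix(sigs, c("A", "B", "C"))
  expect_equal(dim(dm$values), c(3L, 2L))
  expect_equal(unname(colSums(dm$values)), c(2, 1))
  signed <- build_disease_matrix(
    list(gene_signature("D1", up = "A", down = "B", source = "expression")),
    c("A", "B", "C"), encoding = "signed")
  expect_equal(unname(signed$values[, 1]), c(1, -1, 0))
  expect_warning(
    z <- build_disease_matrix(
      list(gene_signature("D1", up = "Z", source = "merged")), c("A", "B")),
    "empty signature")
  expect_equal(sum(z$values), 0)
})

test_that("column sums equal restricted signature sizes on random cases", {
  set.seed(5)
  universe <- sprintf("G%03d", 1:40)
  for (rep in 1:10) {
    sigs <- lapply(1:4, function(i)
      gene_signature(paste0("D", i),
                     up = sample(sprintf("G%03d", 1:60), sample(0:25, 1)),
                     source = "merged"))
    dm <- suppressWarnings(build_disease_matrix(sigs, universe))
    expected <- vapply(sigs, function(s)
      length(intersect(signature_genes(s), universe)), 0)
    expect_equal(unname(colSums(dm$values)), expected)
  }
})
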