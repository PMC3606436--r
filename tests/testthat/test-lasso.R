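test_that("soft threshold matches its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  z <- c(-2.5, -1e-9, 0, 0.3, 7)
  expect_equal(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(z, 0.4), sign(z) * pmax(abs(z) - 0.4, 0))
})

test_that("orthonormal design recovers soft-thresholded OLS coefficients", {
  # columns centred with x_j'x_j / n = 1 and orthogonal
  X <- cbind(M1 = c(1, 1, -1, -1), M2 = c(1, -1, 1, -1))
  y <- c(0.3, 1.2, -0.5, 2.0)
  ols <- as.numeric(crossprod(X, y - mean(y))) / nrow(X)
  for (lam in c(0, 0.2, 0.8, 1.6, 4)) {
    fit <- fit_lasso(X, y, lam, standardize = FALSE, tol = 1e-12)
    expect_equal(unname(fit$beta), soft_threshold(ols, lam / 2),
                 tolerance = 1e-8)
    expect_equal(fit$intercept, mean(y) - sum(fit$beta * colMeans(X)))
  }
})

test_that("solution matches glmnet's objective on random instances", {
  skip_if_not_installed("glmnet")
  for (seed in 1:10) {
    inst <- random_instance(50, 10, seed)
    lam_max <- lambda_path(inst$X, inst$y, n_lambda = 2,
                           standardize = FALSE)[1]
    lam <- lam_max * 0.3
    ours <- fit_lasso(inst$X, inst$y, lam, standardize = FALSE, tol = 1e-11)
    g <- glmnet::glmnet(inst$X, inst$y, lambda = c(lam, lam / 2) / 2,
                        standardize = FALSE, thresh = 1e-14)
    gb <- as.numeric(g$beta[, 1]); g0 <- g$a0[1]
    f_ours <- lasso_objective(inst$X, inst$y, ours$intercept, ours$beta, lam)
    f_ref <- lasso_objective(inst$X, inst$y, g0, gb, lam)
    expect_lte(f_ours - f_ref, 1e-6)
    expect_equal(unname(ours$beta), gb, tolerance = 1e-4)
  }
})

test_that("KKT conditions hold at every returned solution", {
  for (seed in 1:10) {
    inst <- random_instance(40, 8, seed)
    path <- lambda_path(inst$X, inst$y, n_lambda = 20)
    fit <- fit_lasso_path(inst$X, inst$y, path, tol = 1e-9)
    expect_true(all(fit$kkt <= 10 * 1e-9))
  }
})

test_that("any penalty at or above lambda_max yields an exactly zero fit", {
  for (seed in 1:100) {
    inst <- random_instance(sample(10:40, 1), sample(2:8, 1), seed + 500)
    std <- sample(c(TRUE, FALSE), 1)
    lmax <- lambda_path(inst$X, inst$y, n_lambda = 2, standardize = std)[1]
    for (lam in c(lmax, lmax * 1.5)) {
      fit <- fit_lasso(inst$X, inst$y, lam, standardize = std)
      expect_identical(unname(fit$beta), rep(0, ncol(inst$X)))
    }
  }
})

test_that("penalty path is strictly decreasing with the requested length", {
  inst <- random_instance(30, 5, 1)
  path <- lambda_path(inst$X, inst$y, n_lambda = 100, lambda_min_ratio = 1e-3)
  expect_length(path, 100L)
  expect_true(all(diff(path) < 0))
  expect_equal(path[100] / path[1], 1e-3)
  fit1 <- fit_lasso(inst$X, inst$y, path[1])
  expect_true(all(fit1$beta == 0))
  expect_error(lambda_path(inst$X, rep(2, 30)), "constant")
})

test_that("support grows from the null end to the dense end of the path", {
  for (seed in 1:5) {
    inst <- random_instance(60, 10, seed + 40)
    path <- lambda_path(inst$X, inst$y, n_lambda = 30)
    fit <- fit_lasso_path(inst$X, inst$y, path)
    nz <- colSums(fit$beta != 0)
    expect_equal(nz[1], 0)
    expect_lte(nz[1], nz[30])
  }
})

test_that("constant predictor columns are pinned to zero with a warning", {
  inst <- random_instance(30, 4, 2)
  X <- cbind(inst$X, ZERO = 0)
  expect_warning(fit <- fit_lasso(X, inst$y, 0.1), "pinned to zero")
  expect_equal(unname(fit$beta["ZERO"]), 0)
})

test_that("per-disease fits are deterministic and find planted columns", {
  net <- random_network(60, 5, seed = 21, p_target = 0.3)
  genes <- sort(unique(net$direct$to))
  nm <- suppressWarnings(build_netmir(net$direct, NULL, genes,
                                      sort(unique(net$direct$from))))
  # response = one miRNA's target column
  target_col <- colnames(nm$values)[1]
  dm <- build_disease_matrix(
    list(gene_signature("D1", up = rownames(nm$values)[nm$values[, 1] == 1],
                        source = "merged")),
    genes)
  ctrl <- mirlasso_control(n_lambda = 40, n_folds = 5)
  fit1 <- suppressWarnings(fit_disease(nm, dm, "D1", ctrl))
  fit2 <- suppressWarnings(fit_disease(nm, dm, "D1", ctrl))
  expect_identical(fit1$beta, fit2$beta)
  expect_identical(fit1$cv_mse, fit2$cv_mse)
  expect_equal(names(which.max(fit1$beta)), target_col)
  expect_gt(max(fit1$beta), 0)
  # zero-variance response names the disease
  dm0 <- build_disease_matrix(
    list(gene_signature("EMPTYD", up = genes, source = "merged")), genes)
  expect_error(fit_disease(nm, dm0, "EMPTYD", ctrl), "EMPTYD")
})

test_that("planted miRNAs outrank background ones across simulations", {
  wins <- 0L
  for (seed in 1:20) {
    sim <- simulate_study(synth_config(seed = seed))
    d <- names(sim$truth$planted)[1]
    dm <- build_disease_matrix(
      list(gene_signature(d, up = sim$truth$true_signatures[[d]],
                          source = "merged")),
      rownames(sim$netmir$values))
    fit <- suppressWarnings(fit_disease(sim$netmir, dm, d,
                                        mirlasso_control(n_lambda = 50)))
    r <- rank(fit$beta)
    planted <- names(fit$beta) %in% sim$truth$planted[[d]]
    if (mean(r[planted]) > mean(r[!planted])) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("positive-only extraction drops negatives unless asked", {
  fit <- structure(list(disease = "D1",
                        beta = c(A = 0.3, B = 0, C = -0.2)),
                   class = "mirlasso_fit")
  pos <- extract_associations(fit)
  expect_equal(nrow(pos), 1L)
  expect_equal(pos$score, 0.3)
  both <- extract_associations(fit, keep_sign = "both")
  expect_equal(nrow(both), 2L)
  none <- extract_associations(
    structure(list(disease = "D", beta = c(A = 0, B = 0)),
              class = "mirlasso_fit"))
  expect_equal(nrow(none), 0L)
})
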