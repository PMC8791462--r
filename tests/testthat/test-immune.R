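test_that("CYT score is the geometric mean of the two effector genes", {
  expr <- rbind(GZMB = c(4, 0, 3), PRF1 = c(9, 5, 3))
  colnames(expr) <- paste0("s", 1:3)
  expect_equal(unname(cyt_score(expr)), c(6, 0, 3))
  expr2 <- rbind(GZMA = c(1, 4), PRF1 = c(1, 1))
  expect_equal(unname(cyt_score(expr2, genes = c("GZMA", "PRF1"))), c(1, 2))
  expect_error(cyt_score(expr2), "GZMB")
})

test_that("ssGSEA ranks enriched sets above depleted ones", {
  set.seed(21)
  expr <- setNames(sort(rnorm(50, 5), decreasing = TRUE), paste0("g", 1:50))
  top <- names(expr)[1:10]
  bottom <- names(expr)[41:50]
  expect_gt(ssgsea_score(expr, top), ssgsea_score(expr, bottom))
  expect_equal(ssgsea_score(expr, names(expr)), 0)
  expect_error(ssgsea_score(expr, c("absent1", "absent2")), "intersect")
})

test_that("ssGSEA matches an independent running-sum implementation", {
  set.seed(22)
  for (rep in 1:5) {
    expr <- setNames(rnorm(80, 4, 2), paste0("g", 1:80))
    gs <- sample(names(expr), 10)
    expect_equal(ssgsea_score(expr, gs, weight_exponent = 0.25),
                 oracle_ssgsea(expr, gs, 0.25))
  }
})

test_that("lasso solutions obey the soft-threshold closed form", {
  set.seed(31)
  n <- 60
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # 1/n variance of 1
  y <- x  # inner product x'y/n = 1
  for (lam in c(0.05, 0.3, 0.7, 0.99)) {
    fit <- lasso_fit(matrix(x, ncol = 1, dimnames = list(NULL, "h1")),
                     y, lambda = lam)
    expect_equal(fit$coefficient, 1 - lam, tolerance = 1e-6)
  }
  fit0 <- lasso_fit(matrix(x, ncol = 1, dimnames = list(NULL, "h1")),
                    y, lambda = 1.2)
  expect_equal(fit0$coefficient, 0)
  expect_false(fit0$selected)
})

test_that("unpenalized lasso equals OLS and lambda_max kills every predictor", {
  set.seed(32)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("h", 1:4)))
  y <- drop(X %*% c(1, -0.5, 0.25, 0)) + rnorm(n, 0, 0.3)
  fit <- lasso_fit(X, y, lambda = 0)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(fit$coefficient, unname(ols), tolerance = 1e-6)
  lam_max <- max(abs(crossprod(scale(X, scale = FALSE), y - mean(y)))) / n
  fit_max <- lasso_fit(X, y, lambda = lam_max * 1.001)
  expect_equal(fit_max$coefficient, rep(0, 4))
})

test_that("the number of selected predictors is nonincreasing in lambda", {
  set.seed(33)
  X <- matrix(rnorm(100 * 20), 100, 20)
  y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(100)
  path <- glmnet::glmnet(X, y, standardize = FALSE)
  nsel <- colSums(as.matrix(path$beta) != 0)   # path is decreasing in lambda
  expect_true(all(diff(rev(nsel)) <= 0))
})

test_that("the poisson family accepts continuous nonnegative scores", {
  set.seed(34)
  X <- matrix(rnorm(120 * 5), 120, 5, dimnames = list(NULL, paste0("h", 1:5)))
  y <- exp(0.5 * X[, 1] + rnorm(120, 0, 0.2))  # continuous, nonnegative
  fit <- lasso_fit(X, y, family = "poisson", seed = 2)
  expect_true(fit$selected[1])
  expect_error(lasso_fit(X, -y, family = "poisson"), "nonnegative")
  expect_error(lasso_fit(X, rep(1, 120)), "constant")
})

test_that("cross-validated selection recovers planted predictors", {
  set.seed(35)
  recalls <- sapply(1:3, function(s) {
    set.seed(s)
    n <- 100
    p <- 100
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("h", 1:p)))
    signal <- rowMeans(X[, 1:5])
    y <- signal + rnorm(n, 0, 0.5 * sd(signal))
    fit <- lasso_fit(X, y, seed = s)
    sel <- fit$herv_id[fit$selected]
    c(recall = mean(paste0("h", 1:5) %in% sel),
      false = mean(setdiff(fit$herv_id, paste0("h", 1:5)) %in% sel))
  })
  expect_gte(mean(recalls["recall", ]), 0.8)
  expect_lte(mean(recalls["false", ]), 0.15)
})

test_that("T/NK overexpression flags use an inclusive boundary", {
  lcpm <- rbind(flat = rep(5, 10),
                t_up = c(rep(7, 3), rep(5, 7)),
                boundary = c(rep(6, 3), rep(5, 7)))
  cls <- c(rep("sorted_T", 3), rep("sorted_NK", 3), rep("sorted_other", 4))
  flags <- pbmc_overexpression(lcpm, cls)
  expect_false(flags[["flat"]])
  expect_true(flags[["t_up"]])     # 4-fold (2 log2 units) above the rest
  expect_true(flags[["boundary"]]) # exactly at log2(2): inclusive
  expect_error(pbmc_overexpression(lcpm, rep("sorted_T", 10)), "sorted_NK")
})

test_that("cyt annotation implements A and B and not C", {
  assoc <- data.frame(
    herv_id = c("a", "a", "b", "c", "d"),
    selected = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    kind = c("phenotype", "function", "phenotype", "phenotype", "function"),
    stringsAsFactors = FALSE)
  cflags <- c(a = TRUE, b = FALSE, c = FALSE, d = FALSE)
  ann <- annotate_cyt(c("a", "b", "c", "d"), assoc, cflags)
  got <- setNames(ann$cyt, ann$herv_id)
  expect_false(got[["a"]])  # A, B but C -> rejected
  expect_false(got[["b"]])  # phenotype only
  expect_false(got[["c"]])  # phenotype only
  expect_false(got[["d"]])  # function only
  assoc2 <- rbind(assoc, data.frame(herv_id = "b", selected = TRUE,
                                    kind = "function"))
  ann2 <- annotate_cyt(c("a", "b", "c", "d"), assoc2, cflags)
  expect_true(ann2$cyt[ann2$herv_id == "b"])
  # invariant to row order of the association table
  ann3 <- annotate_cyt(c("d", "c", "b", "a"),
                       assoc2[sample(nrow(assoc2)), ], cflags)
  expect_equal(ann3, ann2)
})
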