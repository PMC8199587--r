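test_that("PCA retention rule, orthonormality and reconstruction bound hold", {
  set.seed(51)
  rank1 <- outer(rnorm(10), rnorm(6))
  p1 <- fit_pca(rank1)
  expect_equal(p1$retained_m, 1)

  X <- matrix(rnorm(50 * 156), 50)
  p <- fit_pca(X)
  B <- p$basis
  expect_lt(max(abs(crossprod(B) - diag(ncol(B)))), 1e-10)
  Xc <- sweep(X, 2, p$center)
  resid <- Xc - Xc %*% B %*% t(B)
  expect_lte(sum(resid^2), (1 - 0.999) * sum(Xc^2) + 1e-8)

  expect_error(fit_pca(matrix(1, 5, 3)), "variance")
})

test_that("canonical axis equals the generalized-eigenproblem Fisher direction", {
  set.seed(52)
  n <- 40
  X <- rbind(
    cbind(rnorm(n, 0, 1), rnorm(n, 0, 3)) %*% matrix(c(1, .4, .2, 1), 2),
    cbind(rnorm(n, 3, 1), rnorm(n, 1, 3)) %*% matrix(c(1, .4, .2, 1), 2))
  lab <- rep(c("early", "metastatic"), each = n)
  ca <- fit_ca(X, lab)

  # independent oracle: leading eigenvector of solve(W) %*% B
  mu1 <- colMeans(X[lab == "metastatic", ]); mu0 <- colMeans(X[lab == "early", ])
  mu <- colMeans(X)
  W <- crossprod(sweep(X[lab == "metastatic", ], 2, mu1)) +
       crossprod(sweep(X[lab == "early", ], 2, mu0))
  B <- n * tcrossprod(mu1 - mu) + n * tcrossprod(mu0 - mu)
  ev <- eigen(solve(W) %*% B)
  oracle <- Re(ev$vectors[, 1])
  cosang <- abs(sum(ca$axis * oracle)) /
    sqrt(sum(ca$axis^2) * sum(oracle^2))
  expect_gt(cosang, 1 - 1e-8)

  # separability: all metastatic training scores above all early ones
  set.seed(53)
  far <- rbind(matrix(rnorm(20 * 3), 20), matrix(rnorm(20 * 3, 15), 20))
  lab2 <- rep(c("early", "metastatic"), each = 20)
  ca2 <- fit_ca(far, lab2)
  s <- far %*% ca2$axis
  expect_gt(min(s[lab2 == "metastatic"]), max(s[lab2 == "early"]))
  expect_gt(ca2$class_means["metastatic"], ca2$class_means["early"])

  expect_error(fit_ca(X, rep("early", 2 * n)), "2 classes")
})

test_that("kNN matches a brute-force sorted-distance oracle and breaks ties by index", {
  set.seed(54)
  tr <- runif(20, -2, 2)
  lab <- sample(c("early", "metastatic"), 20, replace = TRUE)
  q <- runif(15, -2, 2)
  got <- knn_predict(tr, lab, q, k = 9)
  oracle <- vapply(q, function(p) {
    nb <- order(abs(tr - p), seq_along(tr))[1:9]
    names(sort(table(lab[nb]), decreasing = TRUE))[1]
  }, "")
  expect_equal(unname(got), oracle)

  expect_equal(unname(knn_predict(tr, lab, tr[7], k = 1)), lab[7])
  expect_equal(unname(knn_predict(tr, rep("early", 20), 0.3, k = 9)), "early")
  # equidistant neighbours: lower training index wins at k = 1
  expect_equal(unname(knn_predict(c(1, 3), c("metastatic", "early"), 2, k = 1)),
               "metastatic")
  expect_error(knn_predict(tr, lab, q, k = 21), "exceeds")
})

test_that("LOOCV reaches perfect accuracy in the separable limit and has no leakage", {
  b <- separable_binned()
  lab <- separable_labels()
  cv <- loocv_evaluate(b, lab)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)
  expect_equal(sum(cv$confusion), 40)

  # leakage: mutating the held-out row must leave that fold's model unchanged
  folds <- nmrfp:::loocv_folds(b, 0.999, TRUE)
  b2 <- b
  b2[7, -1] <- as.list(as.numeric(b2[7, -1]) * 3 + 5)
  folds2 <- nmrfp:::loocv_folds(b2, 0.999, TRUE)
  expect_equal(folds2[[7]]$train_scores, folds[[7]]$train_scores)
})

test_that("metrics satisfy the accuracy identity with metastatic as positive class", {
  set.seed(55)
  b <- separable_binned(gap = 1.2)
  lab <- separable_labels()
  cv <- loocv_evaluate(b, lab)
  n_met <- sum(lab == "metastatic"); n_early <- sum(lab == "early")
  expect_equal(cv$accuracy * 40,
               cv$sensitivity * n_met + cv$specificity * n_early)
  g <- glance(cv)
  expect_equal(g$accuracy, cv$accuracy)
  expect_equal(nrow(tidy(cv)), 40)
})

test_that("projection applies the stored chain and handles edge cases", {
  b <- separable_binned(gap = 2)
  lab <- separable_labels()
  model <- fit_fingerprint(b, lab)
  resub <- project_fingerprint(model, b)
  cv <- loocv_evaluate(b, lab)
  expect_gte(mean(resub$predicted == lab), cv$accuracy - 0.02)

  empty <- b[0, ]
  out <- project_fingerprint(model, empty)
  expect_equal(nrow(out), 0)

  wrong <- b
  names(wrong)[2] <- "whoops"
  expect_error(project_fingerprint(model, wrong), "mismatch")

  # determinism: identical inputs give identical predictions
  expect_identical(project_fingerprint(model, b), resub)
})

test_that("risk stratification merges calls and validates ids", {
  lo <- tibble::tibble(sample_id = c("a", "b"), predicted = c("early", "early"))
  pr <- tibble::tibble(sample_id = c("c"), predicted = c("metastatic"))
  out <- stratify_risk(lo, pr)
  expect_equal(out$risk, c("low", "low", "high"))
  expect_equal(out$source, c("loocv", "loocv", "projection"))

  one <- stratify_risk(lo[0, ], pr)
  expect_equal(one$risk, "high")

  expect_error(stratify_risk(lo, tibble::tibble(sample_id = "a",
                                                predicted = "early")),
               "duplicate")
})
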