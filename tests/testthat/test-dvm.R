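# Discriminative Vector Machine: neighbour graph, Welsch weighting, the
# closed-form solve, the half-quadratic loop, and classification.

test_that("find_neighbors matches an exhaustive distance sort", {
  withr::with_seed(11, {
    for (i in 1:10) {
      X <- matrix(rnorm(10 * 4), 10, 4)
      y <- rnorm(4)
      fit <- dvm(X, rep(1:2, 5), dvm_params(k = 5))
      nb <- find_neighbors(fit, y, 5)
      d2 <- apply(X, 1, function(r) sum((r - y)^2))
      expect_identical(nb$idx, order(d2, seq_along(d2))[1:5])
    }
  })
})

test_that("the neighbour graph Laplacian satisfies its identities", {
  withr::with_seed(12, {
    X <- matrix(rnorm(20 * 6), 20, 6)
    fit <- dvm(X, rep(1:2, 10), dvm_params(k = 8))
    nb <- find_neighbors(fit, rnorm(6))
    expect_true(isSymmetric(nb$W))
    expect_true(all(nb$W >= 0 & nb$W <= 1))
    expect_equal(nb$L, nb$D - nb$W)
    expect_equal(unname(rowSums(nb$L)), rep(0, 8))
    expect_gt(min(eigen(nb$L, symmetric = TRUE)$values), -1e-10)

    # quadratic form equals the pairwise double sum over the similarity graph
    beta <- rnorm(8)
    dbl <- 0
    for (p in 1:8) for (q in 1:8) {
      dbl <- dbl + nb$W[p, q] * (beta[p] - beta[q])^2
    }
    expect_equal(drop(t(beta) %*% nb$L %*% beta), dbl / 2)
  })
})

test_that("a query equal to a training row is its own sole neighbour", {
  X <- matrix(rnorm(12), 6, 2)
  fit <- dvm(X, rep(1:2, 3), dvm_params(k = 1))
  nb <- find_neighbors(fit, X[3, ], 1)
  expect_identical(nb$idx, 3L)
  expect_equal(nb$W, matrix(1, 1, 1))
  expect_equal(nb$L, matrix(0, 1, 1))
})

test_that("welsch weights follow the kernel-size convention", {
  expect_equal(welsch_weights(rep(0, 5))$p, rep(1, 5))
  w <- welsch_weights(c(2, -2, 2, -2), theta = 1)
  expect_equal(w$sigma, 2)
  expect_equal(w$p, rep(exp(-1), 4))
  withr::with_seed(13, {
    r <- rnorm(10)
    p <- welsch_weights(r)$p
    expect_true(all(p > 0 & p <= 1))
    expect_identical(which.min(p), which.max(abs(r)))
  })
})

test_that("solve_beta matches the scalar closed form at k=1", {
  y <- c(1, 2, 3)
  Xk <- matrix(y, 1, 3)   # single neighbour equal to y
  delta <- 1e-3
  beta <- solve_beta(y, Xk, rep(1, 3), matrix(0, 1, 1), delta, 0)
  expect_equal(beta, sum(y^2) / (sum(y^2) + delta))
  tiny <- solve_beta(y, Xk, rep(1, 3), matrix(0, 1, 1), 1e-12, 0)
  expect_equal(tiny, 1, tolerance = 1e-9)
})

test_that("solve_beta is the stationary point of the fixed-P objective", {
  withr::with_seed(14, {
    for (i in 1:20) {
      k <- sample(2:6, 1); d <- sample(3:8, 1)
      Xk <- matrix(rnorm(k * d), k, d)
      y <- rnorm(d)
      p <- runif(d, 0.1, 1)
      W <- matrix(runif(k * k), k, k); W <- (W + t(W)) / 2; diag(W) <- 1
      L <- diag(rowSums(W)) - W
      delta <- 10^runif(1, -4, -1); gamma <- 10^runif(1, -5, -2)
      beta <- solve_beta(y, Xk, p, L, delta, gamma)
      ref <- oracle_minimize_beta(y, Xk, p, L, delta, gamma)
      expect_equal(beta, ref, tolerance = 1e-5)
    }
  })
})

test_that("ridge dominance shrinks the coefficients to zero", {
  withr::with_seed(15, {
    Xk <- matrix(rnorm(20), 4, 5)
    beta <- solve_beta(rnorm(5), Xk, rep(1, 5), matrix(0, 4, 4), 1e8, 0)
    expect_lt(max(abs(beta)), 1e-6)
  })
})

test_that("each half-quadratic solve does not increase its fixed-P objective", {
  withr::with_seed(16, {
    for (i in 1:20) {
      n <- 12; d <- 6
      X <- matrix(rnorm(n * d), n, d)
      fit <- dvm(X, rep(1:2, n / 2), dvm_params(k = 8))
      y <- rnorm(d)
      sol <- predict_one(fit, y, trace = TRUE)
      nb <- sol$neighbors
      prm <- fit$params
      expect_gte(length(sol$trace), 2)
      for (it in 2:length(sol$trace)) {
        p_it <- sol$trace[[it]]$p
        obj_new <- oracle_objective(sol$trace[[it]]$beta, y, nb$Xk, p_it,
                                    nb$L, prm$delta, prm$gamma)
        obj_old <- oracle_objective(sol$trace[[it - 1]]$beta, y, nb$Xk, p_it,
                                    nb$L, prm$delta, prm$gamma)
        expect_lte(obj_new, obj_old + 1e-9)
      }
    }
  })
})

test_that("memorised samples are classified with near-zero residual", {
  withr::with_seed(17, {
    X <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 8), 5, 2))
    fit <- dvm(X, rep(1:2, each = 5), dvm_params(k = 6))
    sol <- predict_one(fit, X[7, ])
    expect_identical(sol$predicted, 2L)
    # own-class reconstruction dwarfs the other class
    expect_lt(sol$residuals[2], 0.1 * sol$residuals[1])

    # with the query as its sole neighbour the fit is exact up to the
    # ridge shrinkage delta / (||y||^2 + delta)
    fit1 <- dvm(X, rep(1:2, each = 5), dvm_params(k = 1))
    sol1 <- predict_one(fit1, X[7, ])
    expect_identical(sol1$predicted, 2L)
    expect_lt(sol1$residuals[2], 1e-3)
  })
})

test_that("DVM separates well-separated Gaussian classes", {
  task <- make_gaussian_task(seed = 21)
  fit <- dvm(task$train_x, task$train_y, dvm_params(k = 20))
  pred <- predict(fit, task$test_x)
  acc <- mean(as.integer(as.character(pred$.pred_class)) == task$test_y)
  expect_gte(acc, 0.98)
})

test_that("predictions are invariant to training-sample order", {
  task <- make_gaussian_task(n_train = 30, n_test = 10, seed = 22)
  fit <- dvm(task$train_x, task$train_y, dvm_params(k = 10))
  base <- predict(fit, task$test_x)$.pred_class
  withr::with_seed(23, {
    for (i in 1:10) {
      perm <- sample(nrow(task$train_x))
      fitp <- dvm(task$train_x[perm, ], task$train_y[perm],
                  dvm_params(k = 10))
      expect_identical(predict(fitp, task$test_x)$.pred_class, base)
    }
  })
})

test_that("batch prediction equals looped single-query prediction", {
  task <- make_gaussian_task(n_train = 20, n_test = 6, seed = 24)
  fit <- dvm(task$train_x, task$train_y, dvm_params(k = 8))
  batch <- predict(fit, task$test_x)
  loop <- t(vapply(seq_len(nrow(task$test_x)),
                   function(i) predict_one(fit, task$test_x[i, ])$residuals,
                   numeric(2)))
  expect_equal(unname(cbind(batch$residual_1, batch$residual_2)),
               unname(loop))

  empty <- predict(fit, matrix(numeric(0), 0, 2))
  expect_identical(nrow(empty), 0L)
})

test_that("classes absent from the neighbourhood get the empty-fit residual", {
  X <- rbind(matrix(0.1, 5, 3), matrix(50, 5, 3))
  fit <- dvm(X, rep(1:2, each = 5), dvm_params(k = 3))
  y <- c(0.1, 0.1, 0.1)
  sol <- predict_one(fit, y)
  expect_true(all(sol$neighbors$labels == 1))
  expect_equal(sol$residuals[2], sqrt(sum(y^2)))
})

test_that("the residual margin agrees in sign with the predicted label", {
  task <- make_gaussian_task(n_train = 40, n_test = 20, seed = 25)
  fit <- dvm(task$train_x, task$train_y, dvm_params(k = 15))
  pred <- predict(fit, task$test_x)
  expect_identical(pred$.margin > 0,
                   as.character(pred$.pred_class) == "2")
})

test_that("Welsch downweighting resists gross corruption better than ridge", {
  task <- make_gaussian_task(n_train = 60, n_test = 40, sep = 4, d = 6,
                             seed = 26)
  # corrupt one feature column of the training data with gross noise
  corrupted <- task$train_x
  withr::with_seed(27, corrupted[, 3] <- corrupted[, 3] +
                     rnorm(nrow(corrupted), 0, 60))

  fit <- dvm(corrupted, task$train_y, dvm_params(k = 20))
  acc_dvm <- mean(as.integer(as.character(
    predict(fit, task$test_x)$.pred_class)) == task$test_y)

  # plain ridge classifier on the same neighbours: identity weights, no
  # robust reweighting, same residual rule
  ridge_predict <- function(y) {
    nb <- find_neighbors(fit, y, 20)
    beta <- solve_beta(y, nb$Xk, rep(1, length(y)), nb$L,
                       fit$params$delta, fit$params$gamma)
    res <- vapply(1:2, function(ci) {
      sel <- nb$labels == ci
      if (!any(sel)) return(sqrt(sum(y^2)))
      sqrt(sum((y - drop(t(nb$Xk[sel, , drop = FALSE]) %*% beta[sel]))^2))
    }, numeric(1))
    which.min(res)
  }
  acc_ridge <- mean(vapply(seq_len(nrow(task$test_x)),
                           function(i) ridge_predict(task$test_x[i, ]),
                           numeric(1)) == task$test_y)
  expect_gte(acc_dvm, acc_ridge)
})

test_that("model and parameter validation reject bad input", {
  expect_error(dvm(matrix(0, 4, 2), rep(1, 4)), class = "ppidvm_error_domain")
  fit <- dvm(matrix(rnorm(8), 4, 2), rep(1:2, 2), dvm_params(k = 2))
  expect_error(find_neighbors(fit, c(0, 0), k = 9),
               class = "ppidvm_error_domain")
  expect_error(predict(fit, matrix(0, 1, 5)), class = "ppidvm_error_domain")
  expect_error(dvm(matrix(0, 4, 2), rep(1:2, 2), dvm_params(k = 9)),
               class = "ppidvm_error_domain")
})
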