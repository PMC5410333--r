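# Discriminative Vector Machine (DVM).
#
# A per-query representation classifier: the k nearest training samples of
# a query y form a local dictionary X_k (samples as columns, d x k).  The
# coefficient vector beta minimises
#
#   delta * ||beta||_2^2  +  sum_i phi((y - X_k beta)_i)
#                         +  gamma * sum_{p,q} w_pq (beta_p - beta_q)^2
#
# with phi the Welsch M-estimator phi(x) = (1/2)(1 - exp(-x^2)), whose
# influence decays for gross residuals, and w_pq the cosine similarity of
# neighbours p and q (graph-Laplacian smoothness, L = D - W).  Half-
# quadratic minimisation alternates a closed-form weighted ridge solve
#   beta = (X'PX + delta I + gamma L)^{-1} X'Py
# with the Welsch weight update p_i = exp(-r_i^2 / sigma^2),
# sigma^2 = theta * r'r / d.  The query is assigned to the class whose
# neighbour columns reconstruct it with the smallest residual norm.

#' DVM hyperparameters
#'
#' @param delta Ridge weight on the coefficient norm (> 0); default `1e-3`.
#' @param gamma Manifold (graph-Laplacian) regularisation weight (> 0);
#'   default `1e-4`.
#' @param theta Welsch kernel-size constant; fixed at 1 by convention.
#' @param k Neighbourhood size; `NULL` means `min(n_train, 40)` at fit time.
#' @param max_iter Maximum half-quadratic iterations (default 50).
#' @param tol Convergence tolerance on the max-norm change of beta.
#' @param single_step If `TRUE`, perform a single closed-form solve with
#'   identity weights instead of the iterated refinement.
#'
#' @return A list of class `dvm_params`.
#' @export
dvm_params <- function(delta = 1e-3, gamma = 1e-4, theta = 1, k = NULL,
                       max_iter = 50L, tol = 1e-6, single_step = FALSE) {
  stopifnot(delta > 0, gamma > 0, theta > 0, tol > 0, max_iter >= 1)
  if (!is.null(k)) stopifnot(k >= 1)
  structure(list(delta = delta, gamma = gamma, theta = theta, k = k,
                 max_iter = as.integer(max_iter), tol = tol,
                 single_step = single_step),
            class = "dvm_params")
}

#' Fit (store) a DVM model
#'
#' DVM is an instance-based method: fitting stores the training matrix and
#' labels; all computation happens per query at prediction time.
#'
#' @param x Numeric matrix or data frame of training features (rows =
#'   samples).
#' @param y Class labels (factor, character or integer); every class must
#'   have at least one sample.
#' @param params [dvm_params()].
#'
#' @return An object of class `dvm` with elements `x`, `y` (integer codes),
#'   `levels`, and `params` (with `k` resolved).
#' @examples
#' fit <- dvm(matrix(rnorm(40), 20, 2), rep(c("a", "b"), 10))
#' predict(fit, matrix(0, 1, 2))
#' @export
dvm <- function(x, y, params = dvm_params()) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(is.finite(x)))
  yf <- factor(y)
  if (nlevels(yf) < 2) {
    abort("DVM needs at least two classes in the training labels",
          class = "ppidvm_error_domain")
  }
  if (is.null(params$k)) params$k <- min(nrow(x), 40L)
  if (params$k > nrow(x)) {
    abort(sprintf("k = %d exceeds the %d training samples",
                  params$k, nrow(x)),
          class = "ppidvm_error_domain")
  }
  structure(list(x = x, y = as.integer(yf), levels = levels(yf),
                 params = params),
            class = "dvm")
}

#' @export
print.dvm <- function(x, ...) {
  cat(sprintf(
    "<dvm> %d samples x %d features, %d classes (k=%d, delta=%g, gamma=%g)\n",
    nrow(x$x), ncol(x$x), length(x$levels), x$params$k, x$params$delta,
    x$params$gamma))
  invisible(x)
}

#' Nearest-neighbour dictionary of a query
#'
#' Selects the `k` training samples closest to `y` in Euclidean distance
#' (ties broken by training index) and builds the similarity graph over
#' them: `W` is the pairwise cosine similarity clipped to \[0, 1\] (zero-norm
#' rows get similarity 0), `D` its diagonal degree matrix and `L = D - W`
#' the graph Laplacian.
#'
#' @param model A fitted [dvm()] object.
#' @param y Query vector of length `ncol(model$x)`.
#' @param k Neighbourhood size; defaults to the model's.
#' @return List with `idx`, `Xk` (k x d), `labels`, `W`, `D`, `L`.
#' @export
find_neighbors <- function(model, y, k = model$params$k) {
  X <- model$x
  if (k > nrow(X)) {
    abort("k exceeds the number of training samples",
          class = "ppidvm_error_domain")
  }
  stopifnot(length(y) == ncol(X))
  d2 <- rowSums(X * X) - 2 * drop(X %*% y) + sum(y * y)
  idx <- order(d2, seq_along(d2))[seq_len(k)]
  Xk <- X[idx, , drop = FALSE]
  nrm <- sqrt(rowSums(Xk * Xk))
  Xn <- Xk / ifelse(nrm > 0, nrm, 1)
  Xn[nrm == 0, ] <- 0
  W <- Xn %*% t(Xn)
  W[W < 0] <- 0
  W[W > 1] <- 1
  diag(W) <- as.numeric(nrm > 0)
  Dg <- diag(rowSums(W), nrow = k)
  list(idx = idx, Xk = Xk, labels = model$y[idx], W = W, D = Dg,
       L = Dg - W)
}

#' Welsch M-estimator weights
#'
#' Given the reconstruction residual `r = y - X_k beta` (one entry per
#' feature dimension), the kernel size is `sigma^2 = theta * r'r / d` and
#' each dimension receives weight `p_i = exp(-r_i^2 / sigma^2)`, in (0, 1].
#' A zero residual yields all weights 1 by convention.
#'
#' @param r Residual vector.
#' @param theta Kernel-size constant.
#' @return List with `p` (weights, length `length(r)`) and `sigma`.
#' @export
welsch_weights <- function(r, theta = 1) {
  d <- length(r)
  sig2 <- theta * sum(r * r) / d
  if (sig2 == 0) {
    list(p = rep(1, d), sigma = 0)
  } else {
    list(p = exp(-(r * r) / sig2), sigma = sqrt(sig2))
  }
}

#' Closed-form weighted, doubly regularised solve
#'
#' Solves `(X'PX + delta I + gamma L) beta = X'Py` for the local
#' coefficients, where `X` is the d x k dictionary (neighbours as columns)
#' and `P = diag(p)` the per-dimension Welsch weights.  `delta > 0`
#' guarantees a positive-definite system.
#'
#' @param y Query vector (length d).
#' @param Xk Neighbour matrix, k x d (rows = neighbours, as returned by
#'   [find_neighbors()]).
#' @param p Diagonal of `P`, length d.
#' @param L k x k graph Laplacian.
#' @param delta,gamma Regularisation weights.
#' @return Coefficient vector beta of length k.
#' @export
solve_beta <- function(y, Xk, p, L, delta, gamma) {
  X <- t(Xk)                      # d x k, neighbours as columns
  A <- crossprod(X, p * X) + delta * diag(nrow(Xk)) + gamma * L
  b <- crossprod(X, p * y)
  beta <- tryCatch(
    solve(A, b),
    error = function(e) {
      abort(sprintf(
        "DVM inner system is numerically singular (kappa = %.3g): %s",
        kappa(A), conditionMessage(e)),
        class = "ppidvm_error_solver")
    }
  )
  drop(beta)
}

# Fixed-P objective of the half-quadratic inner problem.
dvm_objective <- function(y, Xk, beta, p, L, delta, gamma) {
  r <- y - drop(t(Xk) %*% beta)
  sum(p * r * r) + delta * sum(beta * beta) +
    gamma * drop(crossprod(beta, L %*% beta))
}

#' Classify a single query with DVM
#'
#' Runs the half-quadratic loop (initial weights P = I; alternate the
#' closed-form solve and the Welsch weight update until the coefficient
#' change falls below `tol` or `max_iter` is reached), then computes one
#' reconstruction residual per class using only that class's neighbour
#' columns.  Classes absent from the neighbourhood get residual `||y||`
#' (the empty-dictionary fit).  Ties in the argmin go to the smaller class
#' id.
#'
#' @param model A fitted [dvm()] object.
#' @param y Query vector.
#' @param trace If `TRUE`, also return the per-iteration `beta`, weights
#'   and objective bookkeeping (used to verify the monotonicity of the
#'   half-quadratic scheme).
#' @return List with `predicted` (integer class id), `residuals` (length
#'   = number of classes), `beta`, `p`, `sigma`, `iterations`, `neighbors`,
#'   and optionally `trace`.
#' @export
predict_one <- function(model, y, trace = FALSE) {
  prm <- model$params
  nb <- find_neighbors(model, y, prm$k)
  d <- length(y)
  p <- rep(1, d)
  beta <- solve_beta(y, nb$Xk, p, nb$L, prm$delta, prm$gamma)
  sigma <- welsch_weights(y - drop(t(nb$Xk) %*% beta), prm$theta)$sigma
  iters <- 1L
  tr <- if (trace) list(list(beta = beta, p = p)) else NULL
  if (!isTRUE(prm$single_step)) {
    for (it in seq_len(prm$max_iter - 1L)) {
      ww <- welsch_weights(y - drop(t(nb$Xk) %*% beta), prm$theta)
      p <- ww$p
      sigma <- ww$sigma
      beta_new <- solve_beta(y, nb$Xk, p, nb$L, prm$delta, prm$gamma)
      iters <- iters + 1L
      if (trace) tr[[iters]] <- list(beta = beta_new, p = p)
      if (max(abs(beta_new - beta)) < prm$tol) {
        beta <- beta_new
        break
      }
      beta <- beta_new
    }
  }
  n_class <- length(model$levels)
  residuals <- vapply(seq_len(n_class), function(ci) {
    sel <- nb$labels == ci
    if (!any(sel)) {
      sqrt(sum(y * y))
    } else {
      r <- y - drop(t(nb$Xk[sel, , drop = FALSE]) %*% beta[sel])
      sqrt(sum(r * r))
    }
  }, numeric(1))
  out <- list(predicted = which.min(residuals), residuals = residuals,
              beta = beta, p = p, sigma = sigma, iterations = iters,
              neighbors = nb)
  if (trace) out$trace <- tr
  out
}

#' Predict with a DVM model
#'
#' @param object A fitted [dvm()] object.
#' @param newdata Matrix or data frame of queries (rows = samples).
#' @param ... Unused.
#' @return A tibble with one row per query: `.pred_class` (factor on the
#'   training levels), one `residual_<level>` column per class, and for
#'   two-class models `.margin`, the normalised residual margin
#'   `(R_1 - R_2) / (R_1 + R_2)` — positive when the second class
#'   reconstructs the query better.
#' @examples
#' fit <- dvm(rbind(matrix(0, 5, 2), matrix(5, 5, 2)), rep(1:2, each = 5),
#'            dvm_params(k = 4))
#' predict(fit, rbind(c(0, 0), c(5, 5)))
#' @export
predict.dvm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) > 0 && ncol(newdata) != ncol(object$x)) {
    abort(sprintf("query has %d features, model expects %d",
                  ncol(newdata), ncol(object$x)),
          class = "ppidvm_error_domain")
  }
  n_class <- length(object$levels)
  if (nrow(newdata) == 0) {
    res <- matrix(numeric(0), 0, n_class)
  } else {
    res <- t(vapply(seq_len(nrow(newdata)),
                    function(i) predict_one(object, newdata[i, ])$residuals,
                    numeric(n_class)))
  }
  pred <- if (nrow(res) == 0) integer(0) else max.col(-res, ties.method = "first")
  out <- tibble::tibble(
    .pred_class = factor(object$levels[pred], levels = object$levels)
  )
  for (ci in seq_len(n_class)) {
    out[[paste0("residual_", object$levels[ci])]] <- res[, ci]
  }
  if (n_class == 2) {
    out$.margin <- (res[, 1] - res[, 2]) / (res[, 1] + res[, 2])
  }
  out
}

#' @method tidy dvm
#' @export
tidy.dvm <- function(x, ...) {
  tibble::tibble(
    class = x$levels,
    n_train = as.integer(table(factor(x$y, levels = seq_along(x$levels))))
  )
}

#' @method glance dvm
#' @export
glance.dvm <- function(x, ...) {
  tibble::tibble(
    n_train = nrow(x$x), n_features = ncol(x$x),
    n_classes = length(x$levels), k = x$params$k,
    delta = x$params$delta, gamma = x$params$gamma, theta = x$params$theta
  )
}
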