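# End-to-end orchestration: PCA reduction, stratified cross-validation of
# the IWLD + DVM pipeline, the RBF-SVM baseline, and transfer evaluation
# across datasets.

#' Fit a PCA feature reducer
#'
#' Mean-centred principal-component projection (no rescaling), fitted on
#' training rows only so that downstream evaluation is leakage-free.
#'
#' @param x Numeric matrix (rows = samples).
#' @param n_comp Number of components to keep; must be at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return An object of class `ppi_pca` with `rotation` (d x n_comp,
#'   orthonormal columns), `center`, and `n_comp`; use `predict()` to
#'   transform new rows.
#' @export
fit_pca <- function(x, n_comp = 200L) {
  x <- as.matrix(x)
  if (n_comp > min(nrow(x) - 1L, ncol(x)) || n_comp < 1) {
    abort(sprintf(
      "n_comp = %d out of range: at most min(n - 1, d) = %d available",
      n_comp, min(nrow(x) - 1L, ncol(x))),
      class = "ppidvm_error_domain")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_comp)
  structure(list(rotation = pr$rotation[, seq_len(n_comp), drop = FALSE],
                 center = pr$center, n_comp = as.integer(n_comp)),
            class = "ppi_pca")
}

#' @export
predict.ppi_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$center) %*% object$rotation
}

#' @export
print.ppi_pca <- function(x, ...) {
  cat(sprintf("<ppi_pca> %d -> %d components\n", nrow(x$rotation), x$n_comp))
  invisible(x)
}

# Components are capped at what the training fold supports; real-scale runs
# keep the full 200.
resolve_n_comp <- function(n_comp, n_train, d) {
  cap <- min(n_train - 1L, d)
  if (n_comp > cap) {
    rlang::inform(sprintf(
      "n_comp reduced from %d to %d (training fold has %d rows, %d features)",
      n_comp, cap, n_train, d))
    cap
  } else {
    as.integer(n_comp)
  }
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin over folds.
stratified_folds <- function(labels, folds, seed) {
  tab <- table(labels)
  if (any(tab < folds)) {
    abort(sprintf("every class needs at least %d members for %d-fold CV",
                  folds, folds),
          class = "ppidvm_error_domain")
  }
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

classify_fold <- function(train_x, train_y, test_x, classifier, dvm_params,
                          svm_cost, svm_gamma) {
  if (classifier == "dvm") {
    fit <- dvm(train_x, factor(train_y, levels = c(0, 1)), dvm_params)
    pred <- predict(fit, test_x)
    tibble::tibble(predicted = as.integer(as.character(pred$.pred_class)),
                   score = pred$.margin)
  } else {
    yf <- factor(train_y, levels = c(0, 1))
    # per-feature standardisation (e1071 default), the usual LIBSVM practice
    fit <- e1071::svm(train_x, yf, kernel = "radial", cost = svm_cost,
                      gamma = svm_gamma, scale = TRUE)
    pred <- predict(fit, test_x, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # e1071 orients the decision value toward the first label of "a/b"
    first <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1]][1]
    score <- if (first == "1") dv else -dv
    tibble::tibble(predicted = as.integer(as.character(pred)), score = score)
  }
}

fold_metrics <- function(truth, predicted, score) {
  cm <- confusion_counts(truth, predicted)
  met <- compute_metrics(cm$tp, cm$fp, cm$tn, cm$fn)
  met$auc <- roc_auc(score, truth)
  met
}

#' Cross-validated evaluation of the PPI pipeline
#'
#' Runs the full method under stratified k-fold cross-validation: IWLD
#' descriptors per protein, concatenated pair features, PCA fitted on each
#' training fold (unless `pca_global`), then the chosen classifier, with
#' accuracy, sensitivity, precision, MCC and ROC-AUC per fold.  The DVM
#' ROC score is the normalised residual margin
#' `(R_neg - R_pos) / (R_neg + R_pos)`; the SVM uses its decision values.
#'
#' @param pairs Pair tibble (`id_a`, `id_b`, `label`) or a feature table
#'   from [featurize_pairs()] (recognised by its `f...` columns, in which
#'   case `pssms` is ignored).
#' @param pssms Named list of [pssm()] objects, required when `pairs` is a
#'   plain pair table.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param iwld_params,dvm_params Descriptor and classifier settings.
#' @param n_comp PCA width (default 200, capped at what the training fold
#'   supports).
#' @param classifier `"dvm"` (default) or `"svm"` (RBF baseline on the same
#'   folds and features).
#' @param svm_cost,svm_gamma SVM baseline hyperparameters (defaults 0.6 and
#'   0.01).
#' @param pca_global If `TRUE`, fit the PCA once on the whole dataset
#'   instead of per training fold (reintroduces a mild transductive
#'   leakage; off by default).
#' @param repeats Number of independent fold repartitions; metrics are
#'   pooled over all `repeats * folds` evaluations.
#'
#' @return An object of class `ppi_cv`: list with `per_fold` (tibble of
#'   fold metrics), `summary` (mean and sample sd per metric), `roc`
#'   (per-fold ROC points), `seed`, and `config`.  `tidy()`, `glance()` and
#'   `autoplot()` methods are provided.
#' @examples
#' \donttest{
#' d <- synth_pair_dataset(40, effect = 3, seed = 1)
#' cv <- cross_validate(d$pairs, d$pssms, seed = 1)
#' glance(cv)
#' }
#' @export
cross_validate <- function(pairs, pssms = NULL, folds = 5L, seed = 1L,
                           iwld_params = ppidvm::iwld_params(),
                           dvm_params = ppidvm::dvm_params(),
                           n_comp = 200L,
                           classifier = c("dvm", "svm"),
                           svm_cost = 0.6, svm_gamma = 0.01,
                           pca_global = FALSE, repeats = 1L) {
  classifier <- match.arg(classifier)
  ft <- if (any(grepl("^f[0-9]+$", names(pairs)))) {
    pairs
  } else {
    featurize_pairs(pairs, pssms, iwld_params)
  }
  feats <- feature_matrix(ft)
  labels <- ft$label

  per_fold <- list()
  roc_list <- list()
  fold_id <- 0L
  for (rep_i in seq_len(repeats)) {
    assign <- stratified_folds(labels, folds, seed + (rep_i - 1L) * 10007L)
    for (f in seq_len(folds)) {
      fold_id <- fold_id + 1L
      tr <- assign != f
      n_comp_f <- resolve_n_comp(n_comp, sum(tr), ncol(feats))
      pca <- if (pca_global) fit_pca(feats, n_comp_f) else
        fit_pca(feats[tr, , drop = FALSE], n_comp_f)
      tr_x <- predict(pca, feats[tr, , drop = FALSE])
      te_x <- predict(pca, feats[!tr, , drop = FALSE])
      pred <- classify_fold(tr_x, labels[tr], te_x, classifier, dvm_params,
                            svm_cost, svm_gamma)
      met <- fold_metrics(labels[!tr], pred$predicted, pred$score)
      per_fold[[fold_id]] <- dplyr::bind_cols(
        tibble::tibble(repeat_ = rep_i, fold = f), met)
      roc_list[[fold_id]] <- dplyr::mutate(
        roc_points(pred$score, labels[!tr]), repeat_ = rep_i, fold = f,
        .before = 1)
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  metric_cols <- c("acc", "sen", "pre", "mcc", "auc")
  summary <- tidyr::pivot_longer(per_fold[, metric_cols],
                                 dplyr::all_of(metric_cols),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary,
                 roc = dplyr::bind_rows(roc_list), seed = seed,
                 config = list(folds = folds, repeats = repeats,
                               n_comp = n_comp, classifier = classifier,
                               iwld_params = iwld_params,
                               dvm_params = dvm_params,
                               svm_cost = svm_cost, svm_gamma = svm_gamma,
                               pca_global = pca_global)),
            class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ppi_cv> %s, %d fold(s) x %d repeat(s), seed %d\n",
              x$config$classifier, x$config$folds, x$config$repeats, x$seed))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `ppi_cv` object.
#' @param ... Unused.
#' @method tidy ppi_cv
#' @export
tidy.ppi_cv <- function(x, ...) x$per_fold

#' @rdname cross_validate
#' @method glance ppi_cv
#' @export
glance.ppi_cv <- function(x, ...) {
  s <- x$summary
  out <- tibble::as_tibble(as.list(stats::setNames(s$mean, s$metric)))
  sds <- tibble::as_tibble(as.list(stats::setNames(s$sd,
                                                   paste0(s$metric, "_sd"))))
  dplyr::bind_cols(out, sds,
                   tibble::tibble(folds = x$config$folds,
                                  repeats = x$config$repeats,
                                  classifier = x$config$classifier,
                                  seed = x$seed))
}

#' @rdname cross_validate
#' @param object A `ppi_cv` object (for `autoplot`).
#' @method autoplot ppi_cv
#' @export
autoplot.ppi_cv <- function(object, ...) {
  df <- dplyr::mutate(object$roc,
                      fold = factor(paste0(.data$repeat_, ".", .data$fold)))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Fold",
                  title = sprintf("ROC, %s (mean AUC %.3f)",
                                  object$config$classifier,
                                  object$summary$mean[
                                    object$summary$metric == "auc"])) +
    ggplot2::theme_minimal()
}

#' RBF-SVM baseline on a fixed train/test split
#'
#' Soft-margin Gaussian-kernel SVM evaluated with the same metric set as
#' the DVM, for head-to-head comparison on identical features and splits.
#'
#' @param train_x,test_x Feature matrices (e.g. PCA-reduced pair features).
#' @param train_y,test_y Binary labels (1 = interacting).
#' @param cost Soft-margin cost C (default 0.6).
#' @param gamma RBF kernel width (default 0.01).
#' @return One-row tibble of fold metrics including `auc`.
#' @export
svm_baseline <- function(train_x, train_y, test_x, test_y,
                         cost = 0.6, gamma = 0.01) {
  if (length(unique(train_y)) < 2) {
    abort("SVM baseline needs both classes in the training labels",
          class = "ppidvm_error_domain")
  }
  pred <- classify_fold(as.matrix(train_x), train_y, as.matrix(test_x),
                        "svm", NULL, cost, gamma)
  fold_metrics(test_y, pred$predicted, pred$score)
}

#' Train on one dataset, evaluate on another
#'
#' Fits the PCA reducer and DVM on the full training dataset and evaluates
#' on an independent test dataset that shares the descriptor parameters —
#' the cross-species protocol.
#'
#' @param train,test Lists with elements `pairs` and `pssms` (as returned
#'   by [synth_pair_dataset()]), or pre-built feature tables.
#' @param iwld_params,dvm_params,n_comp As in [cross_validate()].
#' @return One-row tibble of metrics on the test dataset.
#' @export
cross_species_eval <- function(train, test,
                               iwld_params = ppidvm::iwld_params(),
                               dvm_params = ppidvm::dvm_params(),
                               n_comp = 200L) {
  as_ft <- function(d) {
    if (is.data.frame(d)) d else featurize_pairs(d$pairs, d$pssms,
                                                 iwld_params)
  }
  ft_tr <- as_ft(train)
  ft_te <- as_ft(test)
  x_tr <- feature_matrix(ft_tr)
  x_te <- feature_matrix(ft_te)
  if (ncol(x_tr) != ncol(x_te)) {
    abort("train and test feature dimensions differ",
          class = "ppidvm_error_domain")
  }
  n_comp_f <- resolve_n_comp(n_comp, nrow(x_tr), ncol(x_tr))
  pca <- fit_pca(x_tr, n_comp_f)
  pred <- classify_fold(predict(pca, x_tr), ft_tr$label, predict(pca, x_te),
                        "dvm", dvm_params, NULL, NULL)
  fold_metrics(ft_te$label, pred$predicted, pred$score)
}
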