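#' Principal component analysis with a cumulative-variance retention rule
#'
#' Covariance PCA (column-mean centering, no scaling: bins share units).
#' Components are retained up to the smallest count whose cumulative
#' explained-variance fraction reaches `var_threshold`.
#'
#' @param X Numeric samples-by-features matrix (n >= 2).
#' @param var_threshold Cumulative variance fraction to retain
#'   (default 0.999).
#' @return List with `center`, `basis` (features x retained_m, orthonormal,
#'   descending eigenvalue), `retained_m`, `explained_variance` (all
#'   eigenvalues).
#' @export
fit_pca <- function(X, var_threshold = 0.999) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) stop("zero total variance", call. = FALSE)
  cumfrac <- cumsum(ev) / sum(ev)
  m <- which(cumfrac >= var_threshold)[1]
  if (is.na(m)) m <- length(ev)
  list(center = pc$center, basis = pc$rotation[, seq_len(m), drop = FALSE],
       retained_m = m, explained_variance = ev)
}

#' Canonical (Fisher discriminant) axis in PCA-score space
#'
#' Computes the leading eigenvector of `W^-1 B` (W = pooled within-class
#' scatter, B = between-class scatter). For two classes this is the single
#' Fisher direction `W^-1 (mu_met - mu_early)`, normalized to unit pooled
#' within-class variance and signed so the metastatic class mean is
#' positive.
#'
#' @param scores n x m matrix of PCA scores.
#' @param labels Factor/character vector; must contain both classes. The
#'   class named `"metastatic"` (or the second factor level) is the
#'   positive class.
#' @return List with `axis` (length m), `class_means` (CA-score means per
#'   class), `positive_class`.
#' @export
fit_ca <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stop("canonical analysis here requires exactly 2 classes", call. = FALSE)
  pos <- if ("metastatic" %in% classes) "metastatic" else classes[2]
  neg <- setdiff(classes, pos)
  x1 <- scores[labels == pos, , drop = FALSE]
  x0 <- scores[labels == neg, , drop = FALSE]
  if (nrow(x1) < 2 || nrow(x0) < 2)
    stop("each class needs at least 2 samples", call. = FALSE)
  W <- crossprod(sweep(x1, 2, colMeans(x1))) +
       crossprod(sweep(x0, 2, colMeans(x0)))
  d <- colMeans(x1) - colMeans(x0)
  a <- tryCatch(solve(W, d), error = function(e)
    stop("within-class scatter is singular; lower `var_threshold`",
         call. = FALSE))
  wvar <- drop(crossprod(a, W %*% a)) / (nrow(scores) - 2)
  if (wvar <= 0)
    stop("within-class scatter is singular; lower `var_threshold`",
         call. = FALSE)
  a <- a / sqrt(wvar)
  if (sum(d * a) < 0) a <- -a
  mu <- c(mean(x0 %*% a), mean(x1 %*% a))
  names(mu) <- c(neg, pos)
  list(axis = as.numeric(a), class_means = mu, positive_class = pos)
}

#' k-nearest-neighbour prediction in canonical-score space
#'
#' Euclidean distance, majority vote among the `k` nearest training scores.
#' With odd `k` and two classes no vote tie is possible; distance ties are
#' broken deterministically by the smaller training index.
#'
#' @param train_scores Numeric vector/matrix of training CA scores.
#' @param train_labels Training labels.
#' @param query_scores Query CA scores.
#' @param k Neighbourhood size (odd, `<= n_train`).
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_scores, train_labels, query_scores, k = 9) {
  train_scores <- as.matrix(train_scores)
  query_scores <- as.matrix(query_scores)
  n <- nrow(train_scores)
  if (k > n) stop("k = ", k, " exceeds the ", n, " training samples",
                  call. = FALSE)
  train_labels <- as.character(train_labels)
  apply(query_scores, 1, function(q) {
    d <- sqrt(colSums((t(train_scores) - q)^2))
    nb <- order(d, seq_len(n))[seq_len(k)]
    votes <- table(train_labels[nb])
    names(votes)[which.max(votes)]
  })
}

#' Fit the PCA-CA-kNN fingerprint classifier
#'
#' The training chain: PQN against a reference estimated from the training
#' matrix, column-mean centering, covariance PCA retaining the components
#' that explain `var_threshold` of the variance, a Fisher canonical axis in
#' PCA-score space, and a k-nearest-neighbour rule (k = 9 by default) on the
#' canonical scores. All fitted quantities (PQN reference, center, basis,
#' axis, training scores) are stored so new samples can be projected without
#' refitting.
#'
#' @param binned A `binned_spectra` tibble of training samples.
#' @param labels Training labels (`"early"` / `"metastatic"`).
#' @param k Neighbourhood size (odd).
#' @param var_threshold PCA retention rule.
#' @param normalize Apply PQN (default TRUE).
#' @return A `fingerprint_model`.
#' @export
fit_fingerprint <- function(binned, labels, k = 9, var_threshold = 0.999,
                            normalize = TRUE) {
  if (k %% 2 == 0) stop("`k` must be odd", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(binned))
    stop("`labels` must match the rows of `binned`", call. = FALSE)
  if (normalize) {
    pq <- pqn_normalize(binned)
    Xn <- bin_values(pq$normalized)
    reference <- pq$report$reference
  } else {
    Xn <- bin_values(binned)
    reference <- NULL
  }
  pca <- fit_pca(Xn, var_threshold)
  scores <- sweep(Xn, 2, pca$center) %*% pca$basis
  ca <- fit_ca(scores, labels)
  train_ca <- drop(scores %*% ca$axis)
  structure(list(
    normalization_reference = reference,
    center = pca$center, pca_basis = pca$basis,
    retained_m = pca$retained_m,
    explained_variance = pca$explained_variance,
    ca_axis = ca$axis, positive_class = ca$positive_class,
    train_scores = train_ca, train_labels = labels,
    train_ids = binned$sample_id, k = k,
    var_threshold = var_threshold,
    bin_names = setdiff(names(binned), "sample_id")
  ), class = "fingerprint_model")
}

#' @export
print.fingerprint_model <- function(x, ...) {
  cat("<fingerprint_model> ", length(x$train_labels), " training samples; ",
      x$retained_m, " PCs (", x$var_threshold * 100,
      "% variance), 1 canonical axis, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Project new samples through a fitted fingerprint model
#'
#' Applies the stored PQN reference, centering, PCA basis and canonical
#' axis, then the kNN rule. Nothing is refit.
#'
#' @param model A `fingerprint_model`.
#' @param binned New samples on the identical bin grid.
#' @return Tibble: `sample_id`, `ca_score`, `predicted`.
#' @export
project_fingerprint <- function(model, binned) {
  stopifnot(inherits(model, "fingerprint_model"))
  if (nrow(binned) == 0)
    return(tibble::tibble(sample_id = character(), ca_score = numeric(),
                          predicted = character()))
  cols <- setdiff(names(binned), "sample_id")
  if (!identical(cols, model$bin_names))
    stop("bin grid mismatch between model and new samples", call. = FALSE)
  X <- bin_values(binned)
  if (!is.null(model$normalization_reference))
    X <- bin_values(pqn_normalize(binned,
      reference = model$normalization_reference)$normalized)
  scores <- sweep(X, 2, model$center) %*% model$pca_basis
  ca <- drop(scores %*% model$ca_axis)
  pred <- knn_predict(model$train_scores, model$train_labels, ca, model$k)
  tibble::tibble(sample_id = binned$sample_id, ca_score = as.numeric(ca),
                 predicted = unname(pred))
}

# label-independent part of every LOOCV fold: PQN reference, centering and
# PCA refit on the n-1 retained samples, held-out sample scored
loocv_folds <- function(binned, var_threshold = 0.999, normalize = TRUE) {
  X <- bin_values(binned)
  n <- nrow(X)
  lapply(seq_len(n), function(i) {
    tr <- binned[-i, , drop = FALSE]
    te <- binned[i, , drop = FALSE]
    if (normalize) {
      pq <- pqn_normalize(tr)
      Xtr <- bin_values(pq$normalized)
      Xte <- bin_values(pqn_normalize(te, reference = pq$report$reference)$normalized)
    } else {
      Xtr <- bin_values(tr); Xte <- bin_values(te)
    }
    pca <- fit_pca(Xtr, var_threshold)
    list(train_scores = sweep(Xtr, 2, pca$center) %*% pca$basis,
         test_score = sweep(Xte, 2, pca$center) %*% pca$basis)
  })
}

# supervised part of LOOCV given per-fold PCA scores
loocv_predict_labels <- function(folds, labels, k = 9) {
  n <- length(folds)
  vapply(seq_len(n), function(i) {
    tr_lab <- labels[-i]
    if (length(unique(tr_lab)) < 2)
      stop("a fold lost one class entirely", call. = FALSE)
    ca <- fit_ca(folds[[i]]$train_scores, tr_lab)
    tr_ca <- drop(folds[[i]]$train_scores %*% ca$axis)
    te_ca <- drop(folds[[i]]$test_score %*% ca$axis)
    knn_predict(tr_ca, tr_lab, te_ca, k)
  }, "")
}

classification_metrics <- function(truth, predicted,
                                   positive = "metastatic") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  tp <- sum(truth == positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  list(confusion = matrix(c(tp, fn, fp, tn), 2, 2,
         dimnames = list(truth = c(positive, "other"),
                         predicted = c(positive, "other"))),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(truth))
}

#' Leave-one-out cross-validation of the fingerprint classifier
#'
#' For every held-out sample the entire chain (PQN reference, centering,
#' PCA, canonical axis) is refit on the remaining n - 1 samples, so the
#' held-out sample never influences its own fold's model. Metrics use the
#' metastatic class as positive: sensitivity = correctly called metastatic /
#' all metastatic; specificity = correctly called early / all early.
#'
#' @inheritParams fit_fingerprint
#' @return A `loocv_result`: `predictions` tibble (`sample_id`, `truth`,
#'   `predicted`, `fold`), `confusion`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
loocv_evaluate <- function(binned, labels, k = 9, var_threshold = 0.999,
                           normalize = TRUE) {
  labels <- as.character(labels)
  n <- nrow(binned)
  if (length(labels) != n)
    stop("`labels` must match the rows of `binned`", call. = FALSE)
  if (n < k + 1) stop("need at least k + 1 samples per fold", call. = FALSE)
  folds <- loocv_folds(binned, var_threshold, normalize)
  pred <- loocv_predict_labels(folds, labels, k)
  m <- classification_metrics(labels, pred)
  structure(list(
    predictions = tibble::tibble(sample_id = binned$sample_id,
                                 truth = labels, predicted = unname(pred),
                                 fold = seq_len(n)),
    confusion = m$confusion, sensitivity = m$sensitivity,
    specificity = m$specificity, accuracy = m$accuracy,
    k = k, var_threshold = var_threshold
  ), class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf(
    "<loocv_result> n = %d | accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%%\n",
    nrow(x$predictions), 100 * x$accuracy, 100 * x$sensitivity,
    100 * x$specificity))
  invisible(x)
}

#' Permutation null of the LOOCV accuracy
#'
#' Re-runs the supervised half of the LOOCV under label permutation. The
#' label-independent fold models (PQN, PCA) are computed once; only the
#' canonical axis and kNN vote are refit per permutation, which is
#' identical to a full refit because those stages never see the labels.
#'
#' @inheritParams loocv_evaluate
#' @param n_perm Number of label permutations.
#' @return Numeric vector of permuted-label accuracies.
#' @export
loocv_permutation_null <- function(binned, labels, n_perm = 200, k = 9,
                                   var_threshold = 0.999, normalize = TRUE) {
  labels <- as.character(labels)
  folds <- loocv_folds(binned, var_threshold, normalize)
  vapply(seq_len(n_perm), function(p) {
    lab <- sample(labels)
    mean(loocv_predict_labels(folds, lab, k) == lab)
  }, 0)
}

#' Merge LOOCV and projection calls into a metabolomic risk label
#'
#' Early-stage patients predicted metastatic get a high metabolomic risk
#' label, those predicted early a low one. Training (non-relapsed) patients
#' contribute their cross-validated prediction; relapsed patients their
#' projection.
#'
#' @param loocv_predictions Tibble (`sample_id`, `predicted`) of
#'   cross-validated calls for the non-relapsed early patients.
#' @param projected_predictions Tibble (`sample_id`, `predicted`) of
#'   projected calls for the relapsed patients.
#' @return Tibble: `sample_id`, `predicted`, `risk` (`"high"`/`"low"`),
#'   `source` (`"loocv"`/`"projection"`).
#' @export
stratify_risk <- function(loocv_predictions, projected_predictions) {
  a <- dplyr::select(tibble::as_tibble(loocv_predictions),
                     "sample_id", "predicted")
  b <- dplyr::select(tibble::as_tibble(projected_predictions),
                     "sample_id", "predicted")
  out <- dplyr::bind_rows(dplyr::mutate(a, source = "loocv"),
                          dplyr::mutate(b, source = "projection"))
  dup <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup))
    stop("duplicate patient id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(is.na(out$sample_id)) || any(!nzchar(out$sample_id)))
    stop("missing patient id", call. = FALSE)
  dplyr::mutate(out,
    risk = ifelse(.data$predicted == "metastatic", "high", "low"))
}

#' @importFrom generics tidy
#' @export
tidy.loocv_result <- function(x, ...) x$predictions

#' @importFrom generics glance
#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(n = nrow(x$predictions), accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 k = x$k, var_threshold = x$var_threshold)
}

#' @export
tidy.fingerprint_model <- function(x, ...) {
  tibble::tibble(sample_id = x$train_ids, label = x$train_labels,
                 ca_score = x$train_scores)
}

#' @export
glance.fingerprint_model <- function(x, ...) {
  tibble::tibble(n_train = length(x$train_labels),
                 retained_m = x$retained_m, k = x$k,
                 var_threshold = x$var_threshold)
}

#' Canonical score plot of a fitted fingerprint model
#'
#' One-dimensional canonical scores per class, optionally with projected
#' samples overlaid.
#'
#' @param object A `fingerprint_model`.
#' @param projected Optional projection tibble from [project_fingerprint()].
#' @param ... Unused.
#' @export
autoplot.fingerprint_model <- function(object, projected = NULL, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ca_score,
                                       fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::labs(x = "canonical score (CA1)", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(projected) && nrow(projected))
    p <- p + ggplot2::geom_rug(
      data = projected,
      mapping = ggplot2::aes(x = .data$ca_score),
      inherit.aes = FALSE)
  p
}
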