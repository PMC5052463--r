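# Passive depression detection: binary classification of clinically
# relevant PHQ-9 (>= 11) from 120-dimensional feature vectors, evaluated
# with leave-one-subject-out cross-validation.  Folds are subjects, so no
# subject ever appears in its own training set; imputation and
# standardization statistics come from training folds only.

#' Assemble a cohort dataset for classification
#'
#' @param dataset a data.frame from [build_dataset()], or a list of
#'   `feature_vector`s.
#' @param cutoff clinical PHQ-9 threshold for the positive class.
#' @return a `cohort_dataset`: list with `X` (n x 120 numeric matrix,
#'   `NA` for masked entries), `y` (0/1), `groups` (subject id per row),
#'   `scores` (raw PHQ-9).
#' @export
assemble_dataset <- function(dataset, cutoff = 11) {
  if (is.list(dataset) && !is.data.frame(dataset) && length(dataset) &&
      inherits(dataset[[1]], "feature_vector")) {
    X <- do.call(rbind, lapply(dataset, `[[`, "values"))
    groups <- vapply(dataset, `[[`, character(1), "subject_id")
    scores <- vapply(dataset, `[[`, numeric(1), "score")
  } else if (is.data.frame(dataset) && nrow(dataset) > 0) {
    feat_cols <- feature_vector_names()
    missing_cols <- setdiff(feat_cols, names(dataset))
    if (length(missing_cols))
      stop("dataset lacks feature columns, e.g. ", missing_cols[1],
           call. = FALSE)
    X <- as.matrix(dataset[feat_cols])
    groups <- as.character(dataset$subject_id)
    scores <- dataset$score
  } else {
    stop("empty dataset", call. = FALSE)
  }
  y <- as.integer(scores >= cutoff)
  if (length(unique(y)) < 2)
    stop("dataset contains a single class; metrics undefined",
         call. = FALSE)
  structure(list(X = X, y = y, groups = groups, scores = scores),
            class = "cohort_dataset")
}

#' Accuracy, sensitivity and specificity
#'
#' Accuracy is the fraction of correctly classified samples over both
#' classes; sensitivity the fraction of true positives among the
#' positive (PHQ-9 >= 11) class; specificity the fraction of true
#' negatives among the negative class.  All on the 0-100 percent scale.
#'
#' @param y_true,y_pred equal-length 0/1 vectors; `y_true` must contain
#'   both classes.
#' @return named numeric: accuracy, sensitivity, specificity (percent).
#' @export
classification_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(unique(y_true)) < 2)
    stop("both classes must be present in y_true", call. = FALSE)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  c(accuracy = 100 * (tp + tn) / length(y_true),
    sensitivity = 100 * tp / sum(y_true == 1),
    specificity = 100 * tn / sum(y_true == 0))
}

# train-fold imputation + standardization; returns transformed matrices
.fit_transform <- function(Xtr, Xte) {
  med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(Xtr))) {
    Xtr[is.na(Xtr[, j]), j] <- med[j]
    Xte[is.na(Xte[, j]), j] <- med[j]
  }
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(Xtr = scale(Xtr, mu, sdv), Xte = scale(Xte, mu, sdv),
       center = mu, scale = sdv, median = med)
}

# inner grouped-CV accuracy of an RBF SVM at (C, gamma); the Nelder-Mead
# objective is 1 - this value
.svm_inner_cv_acc <- function(X, y, groups, C, gamma, n_folds, seed) {
  subs <- unique(groups)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(min(n_folds, length(subs))),
                            length(subs)))
  names(fold_of) <- subs
  correct <- 0L; total <- 0L
  for (f in unique(fold_of)) {
    te <- groups %in% subs[fold_of == f]
    if (length(unique(y[!te])) < 2) next
    dec <- .svm_fit_predict_cpp(X[!te, , drop = FALSE],
                                as.integer(y[!te]),
                                X[te, , drop = FALSE],
                                C, gamma, 1e-3, 5L, seed)
    correct <- correct + sum((dec > 0) == (y[te] == 1))
    total <- total + sum(te)
  }
  if (total == 0) return(0.5)
  correct / total
}

#' Leave-one-subject-out cross-validation
#'
#' Splits the data into as many folds as subjects; all rows of the
#' held-out subject are tested together on a model fitted to everyone
#' else.  Per fold, masked entries are imputed with training-fold column
#' medians and columns are standardized with training-fold statistics.
#' The random forest grows `ntrees` fully-grown CART trees (default 450)
#' on bootstrap samples with random feature subsets; the SVM uses an RBF
#' kernel with cost and kernel width optimized per fold by Nelder-Mead
#' simplex over log-scale parameters, the objective being inner grouped
#' cross-validated accuracy on the training folds.  Metrics are pooled
#' over all held-out predictions.
#'
#' @param data a `cohort_dataset` from [assemble_dataset()].
#' @param model "random_forest" or "svm_rbf".
#' @param seed integer seed controlling every stochastic element.
#' @param ntrees forest size.
#' @param mtry features per split (`NULL` = floor(sqrt(p))).
#' @param nm_maxit Nelder-Mead iteration budget per fold (SVM only).
#' @param inner_folds inner grouped folds for the SVM objective.
#' @param keep_fold_stats also return the per-fold preprocessing
#'   statistics (training medians/means/sds), mainly for leakage audits.
#' @return a `cv_report`: per-row predictions, pooled metrics (percent),
#'   model spec, seed, and ids of skipped folds (single-class training
#'   sets).
#' @export
loso_cv <- function(data, model = c("random_forest", "svm_rbf"),
                    seed = 1L, ntrees = 450L, mtry = NULL,
                    nm_maxit = 40L, inner_folds = 5L,
                    keep_fold_stats = FALSE) {
  stopifnot(inherits(data, "cohort_dataset"))
  model <- match.arg(model)
  if (length(unique(data$groups)) < 3)
    stop("need at least 3 subjects", call. = FALSE)
  if (length(unique(data$y)) < 2)
    stop("both classes must be present", call. = FALSE)

  # canonicalize row order (subject, then feature values) and key every
  # fold's seed to the subject id, so results do not depend on the order
  # rows happened to arrive in
  ord <- do.call(order, c(list(data$groups),
                          as.data.frame(data$X), list(data$y)))
  inv <- order(ord)
  data <- structure(list(X = data$X[ord, , drop = FALSE],
                         y = data$y[ord], groups = data$groups[ord],
                         scores = data$scores[ord]),
                    class = "cohort_dataset")
  subs <- sort(unique(data$groups))
  fold_seeds <- vapply(subs, function(id)
    (as.integer(seed) +
       strtoi(config_hash(id), 16L)) %% 2147483646L + 1L, numeric(1))
  if (is.null(mtry)) mtry <- -1L

  pred <- rep(NA_integer_, length(data$y))
  score <- rep(NA_real_, length(data$y))
  skipped <- character(0)
  hyper <- list()
  fold_stats <- list()

  for (i in seq_along(subs)) {
    te <- data$groups == subs[i]
    ytr <- data$y[!te]
    if (length(unique(ytr)) < 2) {
      warning("fold '", subs[i], "' skipped: single-class training set")
      skipped <- c(skipped, subs[i])
      next
    }
    tr <- .fit_transform(data$X[!te, , drop = FALSE],
                         data$X[te, , drop = FALSE])
    if (keep_fold_stats)
      fold_stats[[subs[i]]] <- list(median = tr$median, center = tr$center,
                                    scale = tr$scale)
    if (model == "random_forest") {
      prob <- .rf_fit_predict_cpp(tr$Xtr, as.integer(ytr), tr$Xte,
                                  as.integer(ntrees), as.integer(mtry),
                                  2L, fold_seeds[i])
      score[te] <- prob
      pred[te] <- as.integer(prob > 0.5)
    } else {
      obj <- function(par) {
        1 - .svm_inner_cv_acc(tr$Xtr, ytr, data$groups[!te],
                              C = 10^par[1], gamma = 10^par[2],
                              n_folds = inner_folds, seed = fold_seeds[i])
      }
      opt <- stats::optim(c(0, log10(1 / ncol(tr$Xtr))), obj,
                          method = "Nelder-Mead",
                          control = list(maxit = nm_maxit))
      hyper[[subs[i]]] <- c(C = 10^opt$par[1], gamma = 10^opt$par[2])
      dec <- .svm_fit_predict_cpp(tr$Xtr, as.integer(ytr), tr$Xte,
                                  10^opt$par[1], 10^opt$par[2],
                                  1e-3, 10L, fold_seeds[i])
      score[te] <- dec
      pred[te] <- as.integer(dec > 0)
    }
  }

  keep <- !is.na(pred)
  metrics <- if (length(unique(data$y[keep])) == 2)
    classification_metrics(data$y[keep], pred[keep])
  else {
    warning("metrics undefined: skipped folds removed a class")
    c(accuracy = NA_real_, sensitivity = NA_real_,
      specificity = NA_real_)
  }
  predictions <- data.frame(subject_id = data$groups, truth = data$y,
                            pred = pred, score = score)[inv, ]
  rownames(predictions) <- NULL
  structure(list(
    predictions = predictions,
    accuracy = metrics[["accuracy"]],
    sensitivity = metrics[["sensitivity"]],
    specificity = metrics[["specificity"]],
    model = model,
    hyperparameters = if (model == "random_forest")
      list(ntrees = as.integer(ntrees), mtry = mtry) else hyper,
    seed = as.integer(seed), skipped_folds = skipped,
    fold_stats = if (keep_fold_stats) fold_stats else NULL),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, leave-one-subject-out (%d rows, %d subjects)\n",
              x$model, nrow(x$predictions),
              length(unique(x$predictions$subject_id))))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  if (length(x$skipped_folds))
    cat("  skipped folds:", paste(x$skipped_folds, collapse = ", "), "\n")
  invisible(x)
}
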