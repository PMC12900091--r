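#' Repeated random hold-out split protocol
#'
#' @param train_fraction Fraction of cases used for training; default 0.7.
#' @param n_reps Number of independent repetitions; default 10.
#' @param seed Integer seed; the same seed reproduces the same split list, and
#'   one split list is shared across all feature sets and classifiers of an
#'   experiment.
#' @return An object of class `split_protocol`.
#' @export
split_protocol <- function(train_fraction = 0.7, n_reps = 10, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (n_reps < 1) stop("n_reps must be >= 1")
  structure(list(train_fraction = train_fraction, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "split_protocol")
}

#' Generate the train/test index pairs
#'
#' Each repetition is an unstratified random partition with
#' `round(train_fraction * n)` training cases and the rest for testing;
#' deterministic given the protocol seed.
#'
#' @param n_cases Number of cases, >= 4.
#' @param protocol A [split_protocol].
#' @return List of `n_reps` lists with integer `train` and `test` indices.
#' @export
make_splits <- function(n_cases, protocol = split_protocol()) {
  if (n_cases < 4) stop("need at least 4 cases to split")
  n_train <- round(protocol$train_fraction * n_cases)
  set.seed(protocol$seed)
  lapply(seq_len(protocol$n_reps), function(r) {
    perm <- sample.int(n_cases)
    list(train = sort(perm[seq_len(n_train)]),
         test = sort(perm[(n_train + 1):n_cases]))
  })
}

std_params <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

std_apply <- function(X, p) sweep(sweep(X, 2, p$mu), 2, p$sd, "/")

#' Train a classifier on one split and predict the test labels
#'
#' Four classical classifiers are supported: Nearest Centroid (`"nc"`,
#' nearest class mean in Euclidean distance), Gaussian Naive Bayes (`"gnb"`,
#' via \pkg{e1071}, class priors from training frequencies), and the
#' RBF-kernel SVM family (`"svm"` C-classification with cost 1, `"nusvc"`
#' nu-classification with nu = 0.5, both via \pkg{e1071}). The margin methods
#' are scale-sensitive, so their features are standardized with the training
#' set's mean/sd inside the split (no test leakage) and gamma defaults to
#' `1 / (d * var(X_train))`; NC and GNB receive raw features.
#'
#' @param table Feature table (data frame with `case_id`, `label`, features).
#' @param split List with `train` and `test` integer indices.
#' @param classifier One of `"nc"`, `"gnb"`, `"svm"`, `"nusvc"`.
#' @param hyperparams Optional overrides: `cost`, `nu`, `gamma`.
#' @return Character vector of predicted labels for the test cases.
#' @export
train_predict <- function(table, split,
                          classifier = c("nc", "gnb", "svm", "nusvc"),
                          hyperparams = list()) {
  classifier <- match.arg(classifier)
  feat <- setdiff(names(table), c("case_id", "label"))
  X <- as.matrix(table[feat])
  y <- table$label
  tr <- split$train; te <- split$test
  if (length(unique(y[tr])) < 2L)
    stop("training set contains a single class")
  if (classifier == "nc") {
    cls <- unique(y[tr])
    cents <- t(vapply(cls, function(cl)
      colMeans(X[tr[y[tr] == cl], , drop = FALSE]), numeric(length(feat))))
    d2 <- vapply(seq_len(nrow(cents)), function(i)
      rowSums(sweep(X[te, , drop = FALSE], 2, cents[i, ])^2),
      numeric(length(te)))
    return(cls[max.col(-matrix(d2, nrow = length(te)), ties.method = "first")])
  }
  if (classifier == "gnb") {
    fit <- e1071::naiveBayes(X[tr, , drop = FALSE], factor(y[tr]))
    return(as.character(predict(fit, X[te, , drop = FALSE])))
  }
  p <- std_params(X[tr, , drop = FALSE])
  Xtr <- std_apply(X[tr, , drop = FALSE], p)
  Xte <- std_apply(X[te, , drop = FALSE], p)
  gamma <- hyperparams$gamma
  if (is.null(gamma)) {
    v <- mean((Xtr - mean(Xtr))^2)
    gamma <- 1 / (ncol(Xtr) * max(v, .Machine$double.eps))
  }
  fit <- if (classifier == "svm") {
    e1071::svm(Xtr, factor(y[tr]), type = "C-classification",
               kernel = "radial",
               cost = if (is.null(hyperparams$cost)) 1 else hyperparams$cost,
               gamma = gamma, scale = FALSE)
  } else {
    e1071::svm(Xtr, factor(y[tr]), type = "nu-classification",
               kernel = "radial",
               nu = if (is.null(hyperparams$nu)) 0.5 else hyperparams$nu,
               gamma = gamma, scale = FALSE)
  }
  as.character(predict(fit, Xte))
}

#' Six classification metrics for one repetition
#'
#' With diseased as the positive class: Overall Accuracy
#' `OA = (TP+TN)/total * 100`, Balanced Accuracy `BA = (TPR+TNR)/2 * 100`,
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `precision = TP/(TP+FP)`, `F1 = 2*prec*sens/(prec+sens)`. Any 0/0 is 0 by
#' convention (with a warning).
#'
#' @param y_true,y_pred Character vectors of `"healthy"`/`"diseased"` labels.
#' @param positive Positive-class label; default `"diseased"`.
#' @return Named numeric vector `c(OA, BA, specificity, sensitivity,
#'   precision, F1)`.
#' @export
compute_metrics <- function(y_true, y_pred, positive = "diseased") {
  if (!length(y_true)) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      if (num != 0) stop("impossible confusion counts")
      warning(sprintf("0/0 in %s set to 0 by convention", what))
      return(0)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f1 <- if (prec + sens == 0) {
    warning("0/0 in F1 set to 0 by convention")
    0
  } else 2 * prec * sens / (prec + sens)
  c(OA = (tp + tn) / (tp + tn + fp + fn) * 100,
    BA = (sens + spec) / 2 * 100,
    specificity = spec, sensitivity = sens, precision = prec, F1 = f1)
}

#' Evaluate a classifier under the repeated hold-out protocol
#'
#' Trains and tests on each of the protocol's splits and reports the six
#' metrics per repetition plus their unweighted means.
#'
#' @param table Feature table (see [train_predict()]).
#' @param protocol A [split_protocol], or a precomputed split list from
#'   [make_splits()] (so one split list can be shared across experiments).
#' @param classifier Classifier kind, see [train_predict()].
#' @param hyperparams Passed to [train_predict()].
#' @return A `classification_report`: list with `per_rep` (data frame, one
#'   row per repetition) and `mean` (named numeric vector).
#' @export
evaluate <- function(table, protocol = split_protocol(),
                     classifier = "nusvc", hyperparams = list()) {
  splits <- if (inherits(protocol, "split_protocol"))
    make_splits(nrow(table), protocol)
  else protocol
  per_rep <- t(vapply(splits, function(sp) {
    pred <- train_predict(table, sp, classifier, hyperparams)
    compute_metrics(table$label[sp$test], pred)
  }, numeric(6)))
  per_rep <- as.data.frame(per_rep)
  structure(list(per_rep = per_rep, mean = colMeans(per_rep),
                 classifier = classifier),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  m <- x$mean
  cat(sprintf(
    "classification_report (%s, %d reps): OA %.0f%% BA %.0f%% spec %.2f sens %.2f prec %.2f F1 %.2f\n",
    x$classifier, nrow(x$per_rep), m["OA"], m["BA"], m["specificity"],
    m["sensitivity"], m["precision"], m["F1"]))
  invisible(x)
}
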