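#' Normalise FoG class labels
#'
#' Coerces a label vector to a factor with levels `c("noFoG", "FoG")`; FoG
#' is the positive class throughout the package.
#'
#' @param labels Character, factor or logical (TRUE = FoG) vector.
#' @return Factor with levels `noFoG`, `FoG`.
#' @export
as_fog_factor <- function(labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "FoG", "noFoG")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("FoG", "noFoG"))
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", ")))
  }
  factor(labels, levels = c("noFoG", "FoG"))
}

#' Stratified train/validation split
#'
#' Splits subjects into train and validation sets preserving class
#' composition: within each class, `floor(train_fraction * n_class + 0.5)`
#' subjects (half-up rounding) go to training, the remainder to validation.
#' The within-class permutation is driven by `seed`, so the same seed always
#' yields the same split.
#'
#' @param labels Per-subject class labels (see [as_fog_factor()]).
#' @param train_fraction Proportion of each class assigned to training
#'   (default 0.7).
#' @param seed Integer seed for the permutation.
#' @return A list with integer index vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1) {
  y <- as_fog_factor(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  counts <- table(y)
  if (length(counts[counts > 0]) < 2) {
    abort("stratification error: both classes must be present.")
  }
  if (any(counts[counts > 0] < 2)) {
    abort("stratification error: every class needs at least 2 members.")
  }
  set.seed(seed)
  train <- integer()
  for (cls in levels(y)) {
    idx <- which(y == cls)
    if (length(idx) == 0) next
    n_tr <- floor(train_fraction * length(idx) + 0.5)
    n_tr <- min(max(n_tr, 1), length(idx) - 1)
    train <- c(train, sample(idx)[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(y), train))
}

#' Train a FoG classifier
#'
#' Fits one of four classifiers on a feature matrix: RBF-kernel support
#' vector machine, k-nearest neighbours, decision tree or Gaussian naive
#' Bayes. Feature columns are standardised by training statistics inside
#' the model, which records them and applies them to new data at
#' prediction time.
#'
#' Default hyperparameters are conventional: the SVM uses unit
#' regularisation cost and kernel width `1 / n_features` on standardised
#' features; k-NN uses `k = 5` with Euclidean distance; the decision tree
#' splits on Gini impurity with no depth limit; naive Bayes assumes
#' Gaussian densities. All can be overridden via `hyperparams`.
#'
#' @param features Data frame or matrix of numeric feature columns (e.g. a
#'   `fog_augmented` table); non-feature columns `subject_id`/`label` are
#'   dropped automatically.
#' @param labels Class labels, one per row (FoG positive).
#' @param kind One of `"svm_rbf"`, `"knn"`, `"dt"`, `"nb"`.
#' @param hyperparams Named list of overrides: `cost`, `gamma` (svm_rbf);
#'   `k` (knn); `minsplit`, `cp`, `maxdepth` (dt).
#' @param seed Integer seed (fits are deterministic given data and seed).
#' @return An object of class `fog_model`.
#' @export
train_classifier <- function(features, labels,
                             kind = c("svm_rbf", "knn", "dt", "nb"),
                             hyperparams = list(), seed = 1) {
  if (!kind[1] %in% c("svm_rbf", "knn", "dt", "nb")) {
    abort(paste0("parameter error: unknown classifier kind '", kind[1], "'."))
  }
  kind <- match.arg(kind)
  x <- .numeric_feature_matrix(features)
  y <- as_fog_factor(labels)
  if (nrow(x) != length(y)) abort("feature rows and labels differ in length.")
  if (length(unique(y)) < 2) {
    abort("degenerate training set: only one class present.")
  }
  if (any(table(y) < 2)) {
    abort("need at least 2 subjects per class in training.")
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1   # constant columns carry no information; leave centred
  z <- scale(x, center = ctr, scale = scl)
  set.seed(seed)
  fit <- if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    # all-identical rows: degenerate majority-class model
    tab <- table(y)
    list(majority = names(tab)[which.max(tab)])
  } else {
    switch(kind,
      svm_rbf = e1071::svm(
        z, y, kernel = "radial",
        cost = hyperparams$cost %||% 1,
        gamma = hyperparams$gamma %||% (1 / ncol(z)),
        scale = FALSE
      ),
      knn = list(train = z, y = y, k = hyperparams$k %||% 5),
      dt = {
        df <- as.data.frame(z)
        df$.y <- y
        rpart::rpart(
          .y ~ ., data = df, method = "class",
          parms = list(split = "gini"),
          control = rpart::rpart.control(
            minsplit = hyperparams$minsplit %||% 2,
            cp = hyperparams$cp %||% 0,
            maxdepth = hyperparams$maxdepth %||% 30,
            xval = 0
          )
        )
      },
      nb = e1071::naiveBayes(as.data.frame(z), y)
    )
  }
  structure(
    list(kind = kind, fit = fit, center = ctr, scale = scl,
         levels = levels(y), seed = seed),
    class = "fog_model"
  )
}

#' @export
predict.fog_model <- function(object, newdata, ...) {
  x <- .numeric_feature_matrix(newdata)
  z <- scale(x[, names(object$center), drop = FALSE],
             center = object$center, scale = object$scale)
  fit <- object$fit
  if (is.list(fit) && !is.null(fit$majority)) {
    return(factor(rep(fit$majority, nrow(z)), levels = object$levels))
  }
  out <- switch(object$kind,
    svm_rbf = predict(fit, z),
    knn = class::knn(fit$train, z, fit$y, k = fit$k),
    dt = predict(fit, as.data.frame(z), type = "class"),
    nb = predict(fit, as.data.frame(z))
  )
  factor(as.character(out), levels = object$levels)
}

.numeric_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    storage.mode(features) <- "double"
    if (is.null(colnames(features))) {
      colnames(features) <- paste0("f", seq_len(ncol(features)))
    }
    return(features)
  }
  df <- as.data.frame(features)
  df <- df[setdiff(names(df), c("subject_id", "label", "side"))]
  keep <- vapply(df, is.numeric, logical(1))
  as.matrix(df[keep])
}

#' Evaluate a classifier on labelled subjects
#'
#' Predicts the evaluation rows and returns the confusion matrix (FoG
#' positive) plus accuracy, sensitivity and specificity in percent:
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, `sensitivity = TP / (TP +
#' FN)`, `specificity = TN / (TN + FP)`, each times 100. A metric with a
#' zero denominator is reported as `NA` (undefined), never as 0.
#'
#' @param model A `fog_model`.
#' @param features Feature rows to evaluate.
#' @param labels True labels for those rows.
#' @return A list of class `fog_eval` with `confusion` (named counts TP,
#'   FN, TN, FP), `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate <- function(model, features, labels) {
  y <- as_fog_factor(labels)
  if (length(y) == 0) abort("empty evaluation set.")
  pred <- predict(model, features)
  tp <- sum(pred == "FoG" & y == "FoG")
  fn <- sum(pred == "noFoG" & y == "FoG")
  tn <- sum(pred == "noFoG" & y == "noFoG")
  fp <- sum(pred == "FoG" & y == "noFoG")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(
      confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
      accuracy = pct(tp + tn, tp + tn + fp + fn),
      sensitivity = pct(tp, tp + fn),
      specificity = pct(tn, tn + fp)
    ),
    class = "fog_eval"
  )
}

#' Build a classification report from per-simulation metrics
#'
#' Aggregates per-simulation accuracy/sensitivity/specificity into their
#' arithmetic means. Used both by [run_simulations()] and directly when
#' only the per-simulation metric lists are available.
#'
#' @param classifier_kind Classifier name.
#' @param per_simulation Tibble (or data frame) with columns `accuracy`,
#'   `sensitivity`, `specificity` in percent, one row per simulation.
#' @return A list of class `fog_report` with `classifier_kind`,
#'   `per_simulation`, `mean_accuracy`, `mean_sensitivity`,
#'   `mean_specificity`.
#' @export
classification_report <- function(classifier_kind, per_simulation) {
  ps <- as_tibble(per_simulation)
  need <- c("accuracy", "sensitivity", "specificity")
  if (!all(need %in% names(ps))) {
    abort("`per_simulation` needs accuracy, sensitivity and specificity columns.")
  }
  structure(
    list(
      classifier_kind = classifier_kind,
      per_simulation = ps,
      mean_accuracy = mean(ps$accuracy, na.rm = TRUE),
      mean_sensitivity = mean(ps$sensitivity, na.rm = TRUE),
      mean_specificity = mean(ps$specificity, na.rm = TRUE)
    ),
    class = "fog_report"
  )
}

#' @export
print.fog_report <- function(x, ...) {
  cat("FoG classification report -", x$classifier_kind, "\n")
  cat(sprintf("  simulations: %d\n", nrow(x$per_simulation)))
  cat(sprintf("  mean accuracy:    %.3f %%\n", x$mean_accuracy))
  cat(sprintf("  mean sensitivity: %.3f %%\n", x$mean_sensitivity))
  cat(sprintf("  mean specificity: %.3f %%\n", x$mean_specificity))
  invisible(x)
}

#' Repeated stratified train/validation simulations
#'
#' Runs the full classification protocol: for simulation `s` (seeded
#' `base_seed + s`), the subjects are split 70:30 stratified by class, the
#' 14-feature PCA augmentation is fitted on the training fold only and
#' applied to both folds, each requested classifier is trained on the
#' training fold and evaluated on the validation fold. Per-simulation
#' metrics and their means are returned per classifier.
#'
#' @param features Per-subject feature table containing the 14
#'   [feature_names] columns (when `augment = TRUE`) or an already
#'   augmented numeric feature table (`augment = FALSE`).
#' @param labels Per-subject class labels (FoG positive).
#' @param kinds Classifiers to run (default all four).
#' @param n_simulations Number of repeated splits (default 10).
#' @param base_seed Base seed; simulation `s` uses `base_seed + s`.
#' @param train_fraction Training proportion per class (default 0.7).
#' @param augment Fit [pca_augment()] inside each simulation (default TRUE).
#' @param hyperparams Named list of per-kind hyperparameter overrides, e.g.
#'   `list(knn = list(k = 3))`.
#' @return A named list of `fog_report` objects, one per classifier, with
#'   class `fog_report_set`.
#' @export
run_simulations <- function(features, labels,
                            kinds = c("svm_rbf", "knn", "dt", "nb"),
                            n_simulations = 10, base_seed = 1,
                            train_fraction = 0.7, augment = TRUE,
                            hyperparams = list()) {
  if (n_simulations < 1) abort("parameter error: `n_simulations` must be >= 1.")
  y <- as_fog_factor(labels)
  rows <- purrr::map_dfr(seq_len(n_simulations), function(s) {
    seed_s <- base_seed + s
    split <- stratified_split(y, train_fraction = train_fraction, seed = seed_s)
    if (augment) {
      tr <- pca_augment(features[split$train, , drop = FALSE])
      va <- pca_augment(features[split$train, , drop = FALSE],
                        features[split$validation, , drop = FALSE])
    } else {
      tr <- features[split$train, , drop = FALSE]
      va <- features[split$validation, , drop = FALSE]
    }
    purrr::map_dfr(kinds, function(kind) {
      model <- train_classifier(tr, y[split$train], kind = kind,
                                hyperparams = hyperparams[[kind]] %||% list(),
                                seed = seed_s)
      ev <- evaluate(model, va, y[split$validation])
      tibble(
        classifier_kind = kind, simulation = s, seed = seed_s,
        accuracy = ev$accuracy, sensitivity = ev$sensitivity,
        specificity = ev$specificity,
        TP = ev$confusion[["TP"]], FN = ev$confusion[["FN"]],
        TN = ev$confusion[["TN"]], FP = ev$confusion[["FP"]]
      )
    })
  })
  reports <- lapply(kinds, function(kind) {
    classification_report(kind, rows[rows$classifier_kind == kind, ])
  })
  names(reports) <- kinds
  structure(reports, class = "fog_report_set")
}
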