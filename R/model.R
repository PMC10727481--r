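#' Stratified train/test split
#'
#' Splits a feature table into training and test sets, preserving the class
#' mix: each class contributes `round(`(1 - train_fraction)`* class size)`
#' test patients (half-up rounding), adjusted by largest remainder so the
#' totals match the overall split. On a 37-patient cohort with 15
#' upward-linear and 22 S-shape patients the default 80:20 split yields 30
#' training and 7 test patients (3 upward-linear, 4 S-shape).
#'
#' @param table Feature table with a `label` column.
#' @param train_fraction Fraction of patients assigned to training.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with `train` and `test` data frames; attribute `"manifest"`
#'   records the patient ids per partition.
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1) {
  labs <- table$label
  sizes <- table(labs)
  if (any(sizes < 2)) stop("every class needs at least 2 members", call. = FALSE)
  n <- nrow(table)
  total_test <- n - round_half_up(train_fraction * n)
  test_per_class <- round_half_up((1 - train_fraction) * as.numeric(sizes))
  diffn <- total_test - sum(test_per_class)
  if (diffn != 0) {
    frac <- (1 - train_fraction) * as.numeric(sizes) - test_per_class
    idx <- order(frac * sign(diffn), decreasing = TRUE)[seq_len(abs(diffn))]
    test_per_class[idx] <- test_per_class[idx] + sign(diffn)
  }
  test_per_class <- pmin(pmax(test_per_class, 1), as.numeric(sizes) - 1)

  set.seed(seed)
  test_idx <- integer(0)
  for (ci in seq_along(sizes)) {
    members <- which(labs == names(sizes)[ci])
    test_idx <- c(test_idx, sample(members, test_per_class[ci]))
  }
  out <- list(train = table[-test_idx, , drop = FALSE],
              test = table[test_idx, , drop = FALSE])
  attr(out, "manifest") <- list(
    seed = seed,
    train_ids = table$patient_id[-test_idx],
    test_ids = table$patient_id[test_idx])
  out
}

#' Cosine distance between feature vectors
#'
#' \eqn{d(x, y) = 1 - x \cdot y / (\lVert x \rVert \lVert y \rVert)}:
#' 0 for identical directions, 1 for orthogonal vectors, 2 for opposite
#' ones. A zero vector has no direction; by convention it is assigned
#' distance 1 to any vector.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Distance value.
#' @export
#' @examples
#' cosine_distance(c(1, 0), c(0, 1))
cosine_distance <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(1)
  1 - sum(x * y) / (nx * ny)
}

#' Default classifier grid
#'
#' The suite of classifier presets evaluated by [train_suite()], mirroring a
#' point-and-click classification-learner toolbox at comparable presets:
#' fine/medium decision trees, linear and quadratic discriminant analysis,
#' logistic regression, linear and RBF support vector machines, k-nearest
#' neighbours with k in \{1, 5, 10\} under Euclidean and cosine distance,
#' and bagged/boosted tree ensembles. The list order (trees, discriminants,
#' logistic, SVMs, nearest neighbours, ensembles) is also the deterministic
#' tie-break order for cross-validation winners.
#'
#' @return Named list of classifier specs (`family` plus preset parameters).
#' @export
classifier_grid <- function() {
  list(
    tree_fine = list(family = "tree", minsplit = 4, cp = 1e-4),
    tree_medium = list(family = "tree", minsplit = 10, cp = 0.01),
    lda = list(family = "lda"),
    qda = list(family = "qda"),
    logistic = list(family = "logistic"),
    svm_linear = list(family = "svm", kernel = "linear"),
    svm_rbf = list(family = "svm", kernel = "radial"),
    knn_euclidean_k1 = list(family = "knn", metric = "euclidean", k = 1),
    knn_euclidean_k5 = list(family = "knn", metric = "euclidean", k = 5),
    knn_euclidean_k10 = list(family = "knn", metric = "euclidean", k = 10),
    knn_cosine_k1 = list(family = "knn", metric = "cosine", k = 1),
    knn_cosine_k5 = list(family = "knn", metric = "cosine", k = 5),
    knn_cosine_k10 = list(family = "knn", metric = "cosine", k = 10),
    bagged_trees = list(family = "bagged", ntree = 200),
    boosted_trees = list(family = "boosted", nrounds = 50, max_depth = 3)
  )
}

fit_classifier <- function(spec, x, y) {
  x <- as.matrix(x)
  switch(spec$family,
    tree = {
      d <- data.frame(x, .y = y, check.names = FALSE)
      rpart::rpart(.y ~ ., data = d, method = "class",
                   minsplit = spec$minsplit, cp = spec$cp)
    },
    lda = MASS::lda(x, grouping = y),
    qda = MASS::qda(x, grouping = y),
    logistic = {
      d <- data.frame(x, .y = y, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
    },
    svm = e1071::svm(x, y, kernel = spec$kernel, cost = 1),
    knn = list(x = x, y = y, k = spec$k, metric = spec$metric),
    bagged = randomForest::randomForest(x, y, ntree = spec$ntree),
    boosted = xgboost::xgboost(x = x, y = y, nrounds = spec$nrounds,
                               max_depth = spec$max_depth,
                               verbosity = 0, nthreads = 1),
    stop("unknown classifier family: ", spec$family, call. = FALSE)
  )
}

predict_classifier <- function(spec, fit, newx, levels) {
  newx <- as.matrix(newx)
  out <- switch(spec$family,
    tree = as.character(predict(fit, data.frame(newx, check.names = FALSE),
                                type = "class")),
    lda = ,
    qda = as.character(predict(fit, newx)$class),
    logistic = {
      p <- suppressWarnings(
        predict(fit, data.frame(newx, check.names = FALSE), type = "response"))
      ifelse(p > 0.5, levels[2], levels[1])
    },
    svm = as.character(predict(fit, newx)),
    knn = knn_predict(fit, newx),
    bagged = as.character(predict(fit, newx)),
    boosted = as.character(predict(fit, newx, type = "class"))
  )
  factor(out, levels = levels)
}

# k-nearest-neighbour prediction with euclidean or cosine distance.
# Vote ties (possible for even k) go to the class of the single nearest
# neighbour; distance ties keep training order.
knn_predict <- function(fit, newx) {
  apply(newx, 1, function(row) {
    d <- switch(fit$metric,
      euclidean = sqrt(colSums((t(fit$x) - row)^2)),
      cosine = apply(fit$x, 1, cosine_distance, y = row))
    nn <- order(d)[seq_len(min(fit$k, nrow(fit$x)))]
    votes <- table(as.character(fit$y[nn]))
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) > 1) as.character(fit$y[nn[1]]) else winners
  })
}

#' Train the classifier suite with stratified cross-validation
#'
#' Trains every classifier in the grid on the selected features and scores
#' it by stratified k-fold cross-validated accuracy; the classifier with the
#' highest accuracy wins (ties broken by grid order). The winner is refitted
#' on the full training set. A classifier that fails on a fold (e.g. QDA
#' with a singular within-class covariance) falls back to predicting that
#' fold's majority class. If a class has fewer members than `folds`, the
#' fold count is reduced with a warning.
#'
#' @param train Training feature table with a `label` column.
#' @param selected_features Character vector of feature columns to use.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   classifier (bagging); fixed seed means identical results.
#' @param grid Classifier grid, see [classifier_grid()].
#' @return An object of class `cv_result`: list with `table` (data frame
#'   `model, cv_accuracy` in grid order), `winner` (model name), `model`
#'   (the refitted winner, class `pattern_model`), `folds`, `seed`.
#' @export
train_suite <- function(train, selected_features, folds = 5, seed = 1,
                        grid = classifier_grid()) {
  if (!length(selected_features)) stop("'selected_features' is empty", call. = FALSE)
  missing_f <- setdiff(selected_features, names(train))
  if (length(missing_f)) {
    stop("features not in table: ", paste(missing_f, collapse = ", "), call. = FALSE)
  }
  y <- factor(train$label)
  min_class <- min(table(y))
  if (folds > min_class) {
    warning("reducing folds from ", folds, " to ", min_class,
            " (smallest class size)", call. = FALSE)
    folds <- min_class
  }
  x <- as.matrix(train[, selected_features, drop = FALSE])

  # stratified fold assignment
  set.seed(seed)
  fold_id <- integer(nrow(train))
  for (cl in levels(y)) {
    members <- which(y == cl)
    fold_id[members] <- sample(rep_len(seq_len(folds), length(members)))
  }

  acc <- vapply(seq_along(grid), function(gi) {
    spec <- grid[[gi]]
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      set.seed(seed + 1000L * gi + f)
      # collinear features make lda/qda chatter; failures fall back below
      fit <- tryCatch(
        suppressWarnings(fit_classifier(spec, x[tr, , drop = FALSE],
                                        droplevels(y[tr]))),
        error = function(e) NULL)
      pred <- if (is.null(fit)) {
        maj <- names(which.max(table(y[tr])))
        factor(rep(maj, sum(!tr)), levels = levels(y))
      } else {
        suppressWarnings(predict_classifier(spec, fit, x[!tr, , drop = FALSE],
                                            levels(droplevels(y[tr]))))
      }
      correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    }
    correct / nrow(train)
  }, numeric(1))

  winner_idx <- which.max(acc)  # first maximum = grid order tie-break
  winner <- names(grid)[winner_idx]
  set.seed(seed + 999L)
  final_fit <- suppressWarnings(fit_classifier(grid[[winner_idx]], x, y))
  model <- structure(list(name = winner, spec = grid[[winner_idx]],
                          fit = final_fit, features = selected_features,
                          levels = levels(y), cv_accuracy = acc[winner_idx]),
                     class = "pattern_model")
  structure(list(table = data.frame(model = names(grid), cv_accuracy = acc,
                                    stringsAsFactors = FALSE),
                 winner = winner, model = model, folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$folds, "-fold CV; winner:", x$winner,
      sprintf("(accuracy %.3f)\n", x$model$cv_accuracy))
  tab <- x$table[order(-x$table$cv_accuracy), ]
  print(utils::head(tab, 5), row.names = FALSE)
  invisible(x)
}

#' Predict pattern labels for new patients
#'
#' @param object A `pattern_model` from [train_suite()].
#' @param newdata Feature table normalised with the *training* min-max
#'   constants; must contain the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted pattern labels.
#' @export
predict.pattern_model <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f)) {
    stop("newdata lacks feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  suppressWarnings(
    predict_classifier(object$spec, object$fit,
                       as.matrix(newdata[, object$features, drop = FALSE]),
                       object$levels))
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("<pattern_model>", x$name, "on",
      length(x$features), "feature(s):",
      paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
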