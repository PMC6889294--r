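cn_levels <- c("CNL", "CNH")

check_training_set <- function(data, features) {
  data <- as_tibble(data)
  stopifnot_cols(data, c(features, "label"), "Training set")
  if (!all(unlist(data[features]) %in% c(0, 1))) {
    abort("Feature columns must be strictly binary (0/1).")
  }
  bad <- setdiff(unique(data$label), cn_levels)
  if (length(bad) > 0) {
    abort(sprintf("Labels must be CNL/CNH; found: %s", paste(bad, collapse = ", ")))
  }
  if (length(unique(data$label)) < 2) abort("Both labels must be present.")
  data
}

#' Stratified train/validation split
#'
#' Randomly splits a labeled set into training and validation parts while
#' preserving the label proportions (within one sample per class, by
#' largest-remainder apportionment). With the published TCGA-like set of 148
#' copy-number cases and `n_train = 62`, this yields the 62/86 protocol.
#' Deterministic for a given seed.
#'
#' @param data Tibble with a `label` column (`"CNL"`/`"CNH"`).
#' @param n_train Number of training rows (`< nrow(data)`).
#' @param seed Integer seed.
#' @return List with `train` and `validation` tibbles (disjoint, exhaustive).
#' @export
stratified_split <- function(data, n_train, seed) {
  data <- as_tibble(data)
  stopifnot_cols(data, "label", "Split input")
  if (n_train >= nrow(data) || n_train < 1) {
    abort("`n_train` must lie strictly between 0 and nrow(data).")
  }
  classes <- sort(unique(data$label))
  sizes <- table(data$label)[classes]
  take <- apportion(n_train, as.numeric(sizes))
  if (any(take == 0) || any(take == sizes)) {
    abort("`n_train` leaves a class empty in one of the parts.")
  }
  idx <- with_seed(seed, {
    unlist(purrr::map2(classes, take, function(cl, k) {
      pool <- which(data$label == cl)
      sort(sample(pool, k))
    }))
  })
  idx <- sort(idx)
  list(train = data[idx, , drop = FALSE],
       validation = data[-idx, , drop = FALSE])
}

# Stratified fold ids 1..folds, deterministic per seed.
stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      pool <- sample(which(labels == cl))
      fold[pool] <- rep_len(seq_len(folds), length(pool))
    }
  })
  fold
}

#' Tune mtry by stratified 5-fold cross-validation
#'
#' Grows a bagged forest for each candidate number of variables per split and
#' scores it by mean cross-validated accuracy; ties are broken toward the
#' smaller mtry. The fold assignment is stratified so no fold loses a class.
#'
#' @param train Training tibble (binary features + `label`).
#' @param grid Candidate mtry values within `[1, n_features]` (default all).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed (folds and forests).
#' @param n_trees Trees per CV forest (default 1000).
#' @param features Feature columns (default the 12 RF panel genes).
#' @return List with `best_mtry` and `trace` (tibble `mtry`, `cv_accuracy`).
#' @export
tune_mtry <- function(train, grid = NULL, folds = 5, seed = 1,
                      n_trees = 1000, features = gene_panel()$rf_genes) {
  train <- check_training_set(train, features)
  grid <- sort(unique(grid %||% seq_along(features)))
  if (any(grid < 1 | grid > length(features))) {
    abort("`grid` values must lie in [1, n_features].")
  }
  fold <- stratified_folds(train$label, folds, seed)
  if (any(tapply(train$label, fold, function(x) length(unique(x))) < 2)) {
    abort("A fold ended up with a single class; reduce `folds`.")
  }
  x <- as.data.frame(train[features])
  y <- factor(train$label, levels = cn_levels)
  trace <- purrr::map_dfr(grid, function(m) {
    acc <- vapply(seq_len(folds), function(f) {
      hold <- fold == f
      fit <- with_seed(seed + 1000L * m + f, {
        randomForest::randomForest(x = x[!hold, , drop = FALSE],
                                   y = y[!hold], mtry = m, ntree = n_trees)
      })
      mean(stats::predict(fit, x[hold, , drop = FALSE]) == y[hold])
    }, numeric(1))
    tibble(mtry = m, cv_accuracy = mean(acc))
  })
  list(best_mtry = trace$mtry[which.max(trace$cv_accuracy)], trace = trace)
}

#' Train the CNL/CNH random-forest surrogate
#'
#' Grows `n_trees` classification trees (default 1000, the empirically chosen
#' forest size), each on a uniform bootstrap resample with `mtry` candidate
#' features per split; prediction is by majority vote with the vote fraction
#' exposed. Reproducible for a given seed.
#'
#' @param train Training tibble (binary features + `label`).
#' @param mtry Features per split (typically from [tune_mtry()]).
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed.
#' @param features Feature columns, in the order the model will require at
#'   prediction time (default the 12 RF panel genes).
#' @return An `ec_rf` object.
#' @export
train_rf <- function(train, mtry, n_trees = 1000, seed = 1,
                     features = gene_panel()$rf_genes) {
  train <- check_training_set(train, features)
  if (mtry < 1 || mtry > length(features)) abort("`mtry` out of range.")
  x <- as.data.frame(train[features])
  y <- factor(train$label, levels = cn_levels)
  forest <- with_seed(seed, {
    randomForest::randomForest(x = x, y = y, mtry = mtry, ntree = n_trees,
                               importance = FALSE)
  })
  structure(
    list(forest = forest, mtry = mtry, n_trees = n_trees, seed = seed,
         features = features,
         fingerprint = sprintf("n=%d;pos=%d;colsums=%s", nrow(x), sum(y == "CNH"),
                               paste(colSums(x), collapse = ",")),
         oob_accuracy = mean(forest$predicted == y)),
    class = "ec_rf"
  )
}

#' @export
print.ec_rf <- function(x, ...) {
  cat(sprintf("<ec_rf> %d trees, mtry = %d, seed = %d\n",
              x$n_trees, x$mtry, x$seed))
  cat(sprintf("Features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("Out-of-bag accuracy: %.4f\n", x$oob_accuracy))
  invisible(x)
}

#' Predict CNL/CNH for new samples
#'
#' @param object An `ec_rf` model.
#' @param newdata Tibble containing the model's feature columns (0/1).
#' @param ... Unused.
#' @return Tibble `label` (predicted class) and `vote_fraction` (share of
#'   trees voting for the predicted class).
#' @export
predict.ec_rf <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("Prediction data lacks model feature(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x <- as.data.frame(newdata[object$features])
  votes <- stats::predict(object$forest, x, type = "vote", norm.votes = TRUE)
  label <- cn_levels[max.col(votes[, cn_levels, drop = FALSE], ties.method = "first")]
  tibble(label = label,
         vote_fraction = votes[cbind(seq_len(nrow(votes)), label)])
}

#' Gini variable importance
#'
#' Mean decrease in Gini impurity attributed to each feature's splits,
#' averaged over the forest's trees and sorted descending. A feature never
#' selected in any split scores 0.
#'
#' @param model An `ec_rf` model.
#' @return Tibble `gene`, `gini`, sorted by decreasing importance.
#' @export
gini_importance <- function(model) {
  if (!inherits(model, "ec_rf")) abort("`model` must be a trained ec_rf.")
  imp <- randomForest::importance(model$forest, type = 2)
  tibble(gene = rownames(imp), gini = as.numeric(imp[, 1])) |>
    arrange(desc(.data$gini))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname gini_importance
#' @param x An `ec_rf` model.
#' @param ... Unused.
#' @export
tidy.ec_rf <- function(x, ...) gini_importance(x)

#' @rdname train_rf
#' @param x An `ec_rf` model.
#' @param ... Unused.
#' @return For `glance()`: a one-row tibble with `n_trees`, `mtry`, `seed`
#'   and `oob_accuracy`.
#' @export
glance.ec_rf <- function(x, ...) {
  tibble(n_trees = x$n_trees, mtry = x$mtry, seed = x$seed,
         oob_accuracy = x$oob_accuracy)
}
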