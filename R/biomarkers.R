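#' Stratified train/test split
#'
#' Allocates samples to a test partition per class in proportion to
#' \code{test_fraction} (rounded, at least one test sample per class), so
#' every class appears in both partitions.
#'
#' @param labels Factor or character vector of class labels.
#' @param test_fraction Fraction of each class held out (default 0.25).
#' @param seed Optional integer seed; \code{NULL} uses the current RNG
#'   stream (for use inside already-seeded loops).
#' @return List of integer index vectors \code{train} and \code{test}.
#' @export
stratified_split <- function(labels, test_fraction = 0.25, seed = NULL) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("singleton class cannot be split: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  test <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_test <- max(1L, round(length(idx) * test_fraction))
    n_test <- min(n_test, length(idx) - 1L)          # keep >= 1 training sample
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Upsample minority classes of a training set
#'
#' Every class smaller than the majority class is topped up by sampling its
#' own rows with replacement until all classes match the majority count; the
#' majority class and already-balanced sets are left untouched, and every
#' added row is an exact copy of an original training row. The test set is
#' never upsampled.
#'
#' @param x Training matrix. @param labels Training labels.
#' @param seed Optional integer seed.
#' @return List \code{x}, \code{labels} of the balanced training set.
#' @export
upsample_minority <- function(x, labels, seed = NULL) {
  x <- unclass(x); labels <- factor(labels)
  if (!is.null(seed)) set.seed(seed)
  sizes <- table(labels)
  n_max <- max(sizes)
  extra <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < n_max)
      extra <- c(extra, sample(idx, n_max - length(idx), replace = TRUE))
  }
  keep <- c(seq_along(labels), extra)
  list(x = x[keep, , drop = FALSE], labels = droplevels(labels[keep]))
}

# Stratified cross-validation fold ids (1..k per sample), each fold holding a
# proportional share of every class where possible.
stratified_folds <- function(labels, k) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# Fit the configured tree ensemble. Bagged CART is a random forest whose
# trees see every feature at every split (mtry = p).
fit_estimator <- function(x, y, estimator, ntree, mtry = NULL) {
  p <- ncol(x)
  mtry <- if (!is.null(mtry)) min(mtry, p)
          else if (estimator == "bagged_trees") p
          else max(1, floor(sqrt(p)))
  randomForest::randomForest(x = as.data.frame(x), y = y,
                             ntree = ntree, mtry = mtry)
}

estimator_importance <- function(fit) {
  imp <- randomForest::importance(fit)[, 1]
  # total order: importance descending, ties by column (first-appearance) order
  names(imp)[order(-imp, seq_along(imp))]
}

#' Recursive feature elimination with a tree-ensemble wrapper
#'
#' For every cross-validation fold the estimator is fitted on the fold's
#' training part with all features, features are ranked by impurity
#' importance, and the set is cut down the subset-size grid, refitting and
#' re-ranking at each size while recording held-out accuracy. The optimal
#' subset size is the grid value with the highest mean CV accuracy (ties to
#' the smaller size); the final ranking aggregates the per-fold rankings at
#' the optimal size by mean rank (features absent from a fold's subset rank
#' below it), ties broken by first appearance.
#'
#' @param x Training matrix (already balanced). @param y Training labels.
#' @param estimator "random_forest" or "bagged_trees".
#' @param subset_grid Candidate subset sizes; defaults to
#'   \{5, 10, 15, 20, 30, 50, p\} clamped to the feature count.
#' @param cv_folds Folds (default 10). @param seed Integer seed.
#' @param ntree Trees per fit (default 200).
#' @return List: \code{optimal_size}, \code{ranking} (all features, best
#'   first), \code{top15}, \code{cv_accuracy} (per grid size),
#'   \code{grid}.
#' @export
rfe_wrapper <- function(x, y, estimator = c("random_forest", "bagged_trees"),
                        subset_grid = NULL, cv_folds = 10, seed = 1L,
                        ntree = 200) {
  estimator <- match.arg(estimator)
  x <- unclass(x); y <- factor(y)
  p <- ncol(x)
  if (is.null(subset_grid)) subset_grid <- c(5, 10, 15, 20, 30, 50, p)
  if (any(subset_grid > p)) {
    warning("subset grid clamped to the number of features (", p, ")")
    subset_grid <- pmin(subset_grid, p)
  }
  grid <- sort(unique(as.integer(subset_grid)), decreasing = TRUE)
  set.seed(seed)
  fold <- stratified_folds(y, cv_folds)
  acc <- matrix(NA_real_, cv_folds, length(grid),
                dimnames = list(NULL, grid))
  rank_mat <- matrix(NA_real_, cv_folds * length(grid), p,
                     dimnames = list(NULL, colnames(x)))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    fit <- fit_estimator(x[tr, , drop = FALSE], y[tr], estimator, ntree)
    for (gi in seq_along(grid)) {
      s <- grid[gi]
      ranked <- estimator_importance(fit)
      feats <- ranked[seq_len(min(s, length(ranked)))]
      if (length(feats) < length(ranked))
        fit <- fit_estimator(x[tr, feats, drop = FALSE], y[tr], estimator, ntree)
      pred <- predict(fit, as.data.frame(x[te, feats, drop = FALSE]))
      acc[f, gi] <- mean(pred == y[te])
      rk <- rep(length(feats) + 1, p)
      names(rk) <- colnames(x)
      rk[feats] <- seq_along(feats)
      rank_mat[(gi - 1L) * cv_folds + f, ] <- rk
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  best_gi <- which(mean_acc == max(mean_acc))
  optimal <- min(grid[best_gi])                       # tie -> smaller size
  opt_rows <- (which(grid == optimal) - 1L) * cv_folds + seq_len(cv_folds)
  mean_rank <- colMeans(rank_mat[opt_rows, , drop = FALSE], na.rm = TRUE)
  ranking <- colnames(x)[order(mean_rank, seq_len(p))] # ties by first appearance
  list(optimal_size = optimal, ranking = ranking,
       top15 = head(ranking, min(15, p)),
       cv_accuracy = rev(mean_acc), grid = rev(grid))
}

#' Embedded random-forest ranking with tuned features-per-split
#'
#' Tunes the forest's features-per-split parameter (mtry) on a grid of
#' \code{tune_grid_length} values by stratified 10-fold CV accuracy (ties to
#' the smaller mtry), refits on the full training set, and ranks all
#' predictors by impurity importance.
#'
#' @inheritParams rfe_wrapper
#' @param tune_grid_length Number of mtry values tried (default 5).
#' @return List: \code{best_mtry}, \code{ranking}, \code{top15},
#'   \code{cv_accuracy} (per mtry), \code{fit}.
#' @export
embedded_rf <- function(x, y, tune_grid_length = 5, cv_folds = 10, seed = 1L,
                        ntree = 200) {
  x <- unclass(x); y <- factor(y)
  p <- ncol(x)
  mtry_grid <- unique(pmax(1, round(seq(sqrt(p) / 2, p / 2,
                                        length.out = tune_grid_length))))
  set.seed(seed)
  fold <- stratified_folds(y, cv_folds)
  acc <- matrix(NA_real_, cv_folds, length(mtry_grid))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    for (mi in seq_along(mtry_grid)) {
      fit <- fit_estimator(x[tr, , drop = FALSE], y[tr], "random_forest",
                           ntree, mtry = mtry_grid[mi])
      acc[f, mi] <- mean(predict(fit, as.data.frame(x[te, , drop = FALSE])) == y[te])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  best <- mtry_grid[min(which(mean_acc == max(mean_acc)))]
  fit <- fit_estimator(x, y, "random_forest", ntree, mtry = best)
  ranking <- estimator_importance(fit)
  list(best_mtry = best, ranking = ranking, top15 = head(ranking, min(15, p)),
       cv_accuracy = setNames(mean_acc, mtry_grid), fit = fit)
}

#' Final model on the selected predictors
#'
#' Refits the estimator on the balanced training set restricted to the
#' selected predictors and evaluates it once on the untouched test set:
#' overall accuracy, per-class sensitivity (recall; \code{NA} for a class
#' with no test samples), and a one-sided exact binomial p-value of the
#' accuracy against the no-information rate (the largest class prevalence
#' in the test set).
#'
#' @param train_x,train_y Balanced training data. @param test_x,test_y Test
#'   data (never used for selection or tuning).
#' @param predictors Character vector of selected feature names.
#' @param seed Integer seed. @param estimator,ntree Passed to the fit.
#' @return List: \code{accuracy}, \code{sensitivity} (named per class),
#'   \code{p_value}, \code{nir}, \code{confusion}.
#' @export
finalize_model <- function(train_x, train_y, test_x, test_y, predictors,
                           seed = 1L, estimator = "random_forest", ntree = 500) {
  train_x <- unclass(train_x); test_x <- unclass(test_x)
  miss <- setdiff(predictors, intersect(colnames(train_x), colnames(test_x)))
  if (length(miss)) stop("predictors absent from data: ", paste(miss, collapse = ", "))
  train_y <- factor(train_y); test_y <- factor(test_y, levels = levels(train_y))
  set.seed(seed)
  fit <- fit_estimator(train_x[, predictors, drop = FALSE], train_y, estimator, ntree)
  pred <- predict(fit, as.data.frame(test_x[, predictors, drop = FALSE]))
  conf <- table(truth = test_y, predicted = pred)
  accuracy <- mean(pred == test_y)
  sens <- vapply(levels(train_y), function(lv) {
    n_lv <- sum(test_y == lv)
    if (n_lv == 0) NA_real_ else sum(pred == lv & test_y == lv) / n_lv
  }, numeric(1))
  nir <- max(table(test_y)) / length(test_y)
  pv <- binom.test(sum(pred == test_y), length(test_y), p = nir,
                   alternative = "greater")$p.value
  list(accuracy = accuracy, sensitivity = sens, p_value = pv, nir = nir,
       confusion = conf)
}

#' Consensus biomarkers across the three models
#'
#' Models with test accuracy below 0.80 or an insignificant accuracy p-value
#' (>= 0.05) are excluded; the consensus set is the intersection of the
#' surviving models' top-15 predictor sets, ordered by the mean of their
#' per-model ranks. Aggregated metrics are the arithmetic means of the
#' surviving models' accuracy, per-class sensitivity and p-value.
#'
#' @param models Named list of model results, each with \code{top15},
#'   \code{ranking}, \code{accuracy}, \code{sensitivity}, \code{p_value}.
#' @param accuracy_min Inclusion bar (default 0.80).
#' @param alpha Significance bar on the accuracy p-value (default 0.05).
#' @return List: \code{consensus} (data frame predictor/mean_rank),
#'   \code{passing_models}, \code{mean_accuracy}, \code{mean_sensitivity},
#'   \code{mean_p_value}, \code{note}.
#' @export
consensus_biomarkers <- function(models, accuracy_min = 0.80, alpha = 0.05) {
  if (!length(models)) stop("at least one model result required")
  pass <- vapply(models, function(m)
    m$accuracy >= accuracy_min && m$p_value < alpha, logical(1))
  surviving <- models[pass]
  note <- if (sum(pass) < 3)
    sprintf("only %d of %d models passed the accuracy/significance bar",
            sum(pass), length(models)) else NA_character_
  if (!length(surviving))
    return(list(consensus = data.frame(predictor = character(0),
                                       mean_rank = numeric(0)),
                passing_models = character(0), mean_accuracy = NA_real_,
                mean_sensitivity = NULL, mean_p_value = NA_real_,
                note = "no model passed the accuracy/significance bar"))
  shared <- Reduce(intersect, lapply(surviving, `[[`, "top15"))
  ranks <- vapply(shared, function(f)
    mean(vapply(surviving, function(m) match(f, m$ranking), numeric(1))),
    numeric(1))
  o <- order(ranks, seq_along(shared))
  sens_mat <- do.call(rbind, lapply(surviving, `[[`, "sensitivity"))
  list(consensus = data.frame(predictor = shared[o], mean_rank = unname(ranks[o]),
                              stringsAsFactors = FALSE),
       passing_models = names(surviving),
       mean_accuracy = mean(vapply(surviving, `[[`, numeric(1), "accuracy")),
       mean_sensitivity = colMeans(sens_mat),
       mean_p_value = mean(vapply(surviving, `[[`, numeric(1), "p_value")),
       note = note)
}

#' Run the full biomarker-discovery procedure for one task
#'
#' One classification task = one label column on one platform. The data are
#' split 75/25 stratified; the training part is balanced by upsampling; two
#' RFE wrappers (random forest and bagged CART) and one embedded tuned
#' random forest are run on the balanced training data only; each model's
#' top-15 predictors are finalised on the untouched test set; the consensus
#' is formed from the models passing the 80\%-accuracy / significance bar.
#'
#' @param matrix An \code{emission_matrix} (single platform).
#' @param annotation A \code{species_annotation}.
#' @param label Annotation column to predict.
#' @param seed Integer seed driving split, folds, and fits.
#' @param test_fraction,cv_folds,ntree,subset_grid Tuning knobs; see the
#'   individual operations.
#' @return A \code{biomarker_report}: per-model results (with
#'   \code{top15}, \code{accuracy}, \code{sensitivity}, \code{p_value}),
#'   the consensus block, and the z-scored emission table of the consensus
#'   biomarkers (for Fig.-style reporting).
#' @export
run_biomarker_task <- function(matrix, annotation, label, seed = 1L,
                               test_fraction = 0.25, cv_folds = 10,
                               ntree = 200, subset_grid = NULL) {
  st <- sample_table(matrix)
  labels <- effective_labels(annotation, label)[st$species_id]
  ok <- !is.na(labels)
  x <- unclass(matrix)[ok, , drop = FALSE]
  y <- factor(labels[ok])
  sp <- stratified_split(y, test_fraction, seed = stage_seed(seed, "split"))
  train_x <- x[sp$train, , drop = FALSE]; train_y <- y[sp$train]
  test_x  <- x[sp$test, , drop = FALSE];  test_y  <- y[sp$test]
  bal <- upsample_minority(train_x, train_y, seed = stage_seed(seed, "upsample"))

  sel <- list(
    rf_rfe = rfe_wrapper(bal$x, bal$labels, "random_forest", subset_grid,
                         cv_folds, seed = stage_seed(seed, "rf_rfe"), ntree = ntree),
    bagged_rfe = rfe_wrapper(bal$x, bal$labels, "bagged_trees", subset_grid,
                             cv_folds, seed = stage_seed(seed, "bagged_rfe"),
                             ntree = ntree),
    rf_embedded = embedded_rf(bal$x, bal$labels, cv_folds = cv_folds,
                              seed = stage_seed(seed, "rf_embedded"),
                              ntree = ntree))
  models <- lapply(names(sel), function(id) {
    est <- if (id == "bagged_rfe") "bagged_trees" else "random_forest"
    fin <- finalize_model(bal$x, bal$labels, test_x, test_y, sel[[id]]$top15,
                          seed = stage_seed(seed, paste0("final_", id)),
                          estimator = est, ntree = max(ntree, 500))
    c(sel[[id]][c("ranking", "top15")], fin,
      list(model_id = id,
           optimal_subset_size = sel[[id]]$optimal_size,
           passed = fin$accuracy >= 0.80 && fin$p_value < 0.05))
  })
  names(models) <- names(sel)
  cons <- consensus_biomarkers(models)
  ztab <- if (nrow(cons$consensus) > 0)
    scale(x[, cons$consensus$predictor, drop = FALSE]) else NULL
  structure(list(label = label, platform = attr(matrix, "platform"),
                 models = models, consensus = cons, zscores = ztab,
                 n_train = length(sp$train), n_test = length(sp$test)),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat(sprintf("biomarker_report: %s on %s; %d/%d models passed; %d consensus biomarkers\n",
              x$label, x$platform,
              sum(vapply(x$models, `[[`, logical(1), "passed")), length(x$models),
              nrow(x$consensus$consensus)))
  invisible(x)
}
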