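#' Fit a discriminant analysis of principal components (DAPC)
#'
#' Columns are centered and scaled to unit variance (so the two measurement
#' platforms weigh equally in a merged table), reduced by PCA via singular
#' value decomposition to \code{m} components, and a linear discriminant
#' analysis (between/within scatter eigenproblem, via \code{MASS::lda}) is
#' fitted on the retained PC scores. The model stores the full transform
#' chain so new samples can be projected and assigned.
#'
#' @param x Numeric matrix, samples x features (an \code{emission_matrix}
#'   works directly).
#' @param grouping Factor or character vector of group labels, one per row.
#' @param m Number of principal components to retain (clamped to the matrix
#'   rank with a warning if larger).
#' @return A \code{dapc_model}: centering/scaling vectors, kept columns, PC
#'   rotation, \code{MASS::lda} fit, group centroids in discriminant space,
#'   discriminant eigenvalues, \code{m} and \code{k}.
#' @export
fit_dapc <- function(x, grouping, m) {
  x <- unclass(x)
  grouping <- factor(grouping)
  if (length(grouping) != nrow(x)) stop("one label per sample required")
  if (any(table(grouping) < 2))
    stop("every group needs >= 2 samples; offending: ",
         paste(names(which(table(grouping) < 2)), collapse = ", "))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance column(s) dropped before DAPC")
  xs <- scale(x[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (m > rank) {
    warning(sprintf("m = %d exceeds matrix rank %d; clamped", m, rank))
    m <- rank
  }
  if (m < 1) stop("m must be >= 1")
  scores <- pc$x[, seq_len(m), drop = FALSE]
  ld <- MASS::lda(scores, grouping = grouping)
  coords <- predict(ld, as.data.frame(scores))$x
  centroids <- apply(coords, 2, function(a) tapply(a, grouping, mean))
  centroids <- matrix(centroids, nrow = nlevels(grouping),
                      dimnames = list(levels(grouping), colnames(coords)))
  structure(list(center = ctr, scale = scl, keep = keep,
                 rotation = pc$rotation[, seq_len(m), drop = FALSE],
                 lda = ld, centroids = centroids,
                 eigenvalues = ld$svd^2, m = m, k = nlevels(grouping),
                 features = colnames(x), levels = levels(grouping)),
            class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d PCs -> %d groups, %d discriminant axes\n",
              x$m, x$k, length(x$eigenvalues)))
  invisible(x)
}

#' Project and assign new samples with a DAPC model
#'
#' New samples are passed through the stored center/scale/PCA/LDA chain and
#' assigned to the nearest group centroid in discriminant space. Scores are
#' a softmin of squared centroid distances - a heuristic posterior that
#' ranks groups identically to the assignment. Exact centroid-distance ties
#' are broken by group order and flagged.
#'
#' @param model A \code{dapc_model}. @param x New samples x features matrix
#'   with the training feature names.
#' @return List: \code{assignment} (factor), \code{coords} (discriminant
#'   coordinates), \code{scores} (samples x groups), \code{tied} (logical).
#' @export
predict_dapc <- function(model, x) {
  x <- unclass(x)
  miss <- setdiff(model$features, colnames(x))
  if (length(miss))
    stop("missing features: ", paste(head(miss, 10), collapse = ", "))
  x <- x[, model$features, drop = FALSE]
  xs <- scale(x[, model$keep, drop = FALSE],
              center = model$center[model$keep], scale = model$scale[model$keep])
  scores <- xs %*% model$rotation
  coords <- predict(model$lda, as.data.frame(scores))$x
  d2 <- t(apply(coords, 1, function(z)
    colSums((t(model$centroids) - z)^2)))
  d2 <- matrix(d2, ncol = nrow(model$centroids),
               dimnames = list(rownames(x), rownames(model$centroids)))
  best <- apply(d2, 1, which.min)                     # ties -> first group order
  tied <- apply(d2, 1, function(v) sum(v == min(v)) > 1)
  w <- exp(-0.5 * (d2 - apply(d2, 1, min)))
  scores_out <- w / rowSums(w)
  list(assignment = factor(model$levels[best], levels = model$levels),
       coords = coords, scores = scores_out, tied = tied)
}

#' Cross-validated selection of the number of retained PCs
#'
#' For each candidate \code{m} and each replicate, samples are split into a
#' stratified training fraction and a held-out remainder, a DAPC is fitted
#' on the training part, and the held-out assignment success is recorded.
#' The root-mean-squared error per \code{m} is \code{sqrt(mean((1 -
#' success)^2))}; the chosen \code{m} attains the minimum RMSE, ties going
#' to the smaller \code{m} (fewer components means more stable assignments).
#'
#' @param x Samples x features matrix. @param grouping Labels per row.
#' @param grid Integer vector of candidate \code{m} values; default 10
#'   roughly even values from \code{k} to \code{min(n - k, rank)}.
#' @param training_fraction Fraction used for training (default 0.9).
#' @param n_rep Replicates per grid value (default 30).
#' @param seed Integer seed making the whole procedure deterministic.
#' @return An \code{xval_result} list: \code{grid}, \code{mean_success},
#'   \code{rmse}, \code{chosen_m}.
#' @export
xval_select_m <- function(x, grouping, grid = NULL, training_fraction = 0.9,
                          n_rep = 30, seed = 1L) {
  x <- unclass(x); grouping <- factor(grouping)
  n <- nrow(x); k <- nlevels(grouping)
  if (is.null(grid)) {
    upper <- max(k, min(n - k, qr(scale(x))$rank))
    grid <- unique(pmax(1, round(seq(k, upper, length.out = 10))))
  }
  grid <- sort(unique(as.integer(grid)))
  if (!length(grid)) stop("empty grid of candidate m values")
  set.seed(seed)
  succ <- matrix(NA_real_, n_rep, length(grid))
  for (r in seq_len(n_rep)) {
    sp <- stratified_split(grouping, test_fraction = 1 - training_fraction)
    for (gi in seq_along(grid)) {
      fit <- suppressWarnings(
        fit_dapc(x[sp$train, , drop = FALSE], grouping[sp$train], grid[gi]))
      pred <- predict_dapc(fit, x[sp$test, , drop = FALSE])
      succ[r, gi] <- mean(pred$assignment == grouping[sp$test])
    }
  }
  mean_success <- colMeans(succ)
  rmse <- sqrt(colMeans((1 - succ)^2))
  chosen <- grid[which.min(rmse)]                     # which.min: first = smallest m
  structure(list(grid = grid, mean_success = mean_success, rmse = rmse,
                 chosen_m = chosen, n_rep = n_rep,
                 training_fraction = training_fraction),
            class = "xval_result")
}

#' @export
print.xval_result <- function(x, ...) {
  cat("xval_result: chosen m =", x$chosen_m, "\n")
  print(data.frame(m = x$grid, mean_success = round(x$mean_success, 3),
                   rmse = round(x$rmse, 4)))
  invisible(x)
}
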