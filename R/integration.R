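#' Raw phenotypic integration index
#'
#' The degree of covariation among compounds, measured as the variance of
#' the eigenvalues of their Pearson correlation matrix. Since the mean
#' eigenvalue of a correlation matrix is exactly 1, the population variance
#' \eqn{\sum_i (\lambda_i - 1)^2 / p} is used, which ranges from 0
#' (independent compounds) to \eqn{p - 1} (all compounds perfectly
#' correlated). Constant columns are removed first with a warning.
#'
#' @param x Numeric matrix, n samples x p compounds (n >= 3, p >= 2 after
#'   removing constant columns).
#' @return List: \code{raw} (the index), \code{eigenvalues}, \code{p},
#'   \code{n}; or \code{NULL}-valued result with a \code{reason} when fewer
#'   than 2 usable compounds remain.
#' @export
integration_index <- function(x) {
  x <- unclass(x)
  if (nrow(x) < 3) stop("integration index needs >= 3 samples")
  keep <- apply(x, 2, function(v) sd(v) > 0)
  if (!all(keep)) warning(sum(!keep), " constant column(s) removed")
  x <- x[, keep, drop = FALSE]
  p <- ncol(x)
  if (p < 2)
    return(list(raw = NULL, eigenvalues = NULL, p = p, n = nrow(x),
                reason = "fewer than 2 non-constant compounds"))
  R <- cor(x)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  list(raw = sum((ev - 1)^2) / p, eigenvalues = ev, p = p, n = nrow(x))
}

# Fast equivalent used inside null loops: var of eigenvalues of cor(x)
# equals (sum(R^2) - p)/p because trace(R^2) = p + sum of squared
# off-diagonal correlations. Tested against integration_index().
.pi_raw_fast <- function(x) {
  R <- cor(x)
  p <- ncol(R)
  (sum(R * R) - p) / p
}

#' Sample-size correction and relative scaling of the integration index
#'
#' The raw index is corrected by subtracting its expectation under random
#' covariation, \code{(p - 1) / n} (p = number of compounds emitted, n =
#' number of samples), and expressed as a percentage of the maximum
#' attainable index \code{p - 1}: \code{relative = 100 * corrected / (p - 1)}.
#'
#' @param raw Raw index from [integration_index()].
#' @param p Number of compounds. @param n Number of samples.
#' @return List: \code{corrected}, \code{relative_pct}.
#' @export
corrected_relative_pi <- function(raw, p, n) {
  corrected <- raw - (p - 1) / n
  list(corrected = corrected, relative_pct = 100 * corrected / (p - 1))
}

#' Permutation / resampling null for the integration index
#'
#' Calibrates the observed relative integration against chance. Two null
#' models are available: \code{"permute"} (default) independently permutes
#' each compound's values across samples, destroying covariation while
#' preserving every marginal distribution; \code{"subset"} draws random
#' compound sets of the same size p from a larger compound pool over the
#' same samples (the alternative reading of drawing randomly from the data
#' set). Each draw yields a relative PI; the observed value is significant
#' when it exceeds the 95\% empirical quantile of the null, and the p-value
#' is \code{(1 + #\{null >= observed\}) / (1 + n_null)}.
#'
#' @param x n x p matrix of the subset under test.
#' @param n_null Number of null draws (default 10000; < 100 warns).
#' @param mode "permute" or "subset".
#' @param pool Full compound matrix over the same samples (required for
#'   \code{mode = "subset"}).
#' @param seed Integer seed.
#' @return List: \code{observed_relative}, \code{null} (vector of null
#'   relative PIs), \code{q95}, \code{p_value}, \code{significant}.
#' @export
pi_null <- function(x, n_null = 10000, mode = c("permute", "subset"),
                    pool = NULL, seed = 1L) {
  mode <- match.arg(mode)
  x <- unclass(x)
  keep <- apply(x, 2, function(v) sd(v) > 0)
  x <- x[, keep, drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (p < 2 || n < 3) stop("subset not computable (need p >= 2, n >= 3)")
  if (n_null < 100) warning("n_null < 100: the 95% quantile is unstable")
  obs <- corrected_relative_pi(.pi_raw_fast(x), p, n)$relative_pct
  if (mode == "subset") {
    if (is.null(pool)) stop("mode = 'subset' requires a compound pool")
    pool <- unclass(pool)
    pool <- pool[, apply(pool, 2, function(v) sd(v) > 0), drop = FALSE]
    if (ncol(pool) < p) stop("pool smaller than the subset size")
  }
  set.seed(seed)
  null <- numeric(n_null)
  for (i in seq_len(n_null)) {
    xn <- if (mode == "permute") apply(x, 2, sample)
          else pool[, sample(ncol(pool), p), drop = FALSE]
    null[i] <- corrected_relative_pi(.pi_raw_fast(xn), p, n)$relative_pct
  }
  q95 <- as.numeric(quantile(null, 0.95, names = FALSE))
  list(observed_relative = obs, null = null, q95 = q95,
       p_value = (1 + sum(null >= obs)) / (1 + n_null),
       significant = obs > q95)
}

#' Integration panel over trophic modes and structural classes
#'
#' Computes the corrected, relative integration index with its permutation
#' null for every (trophic mode, structural class) cell, plus "all" rows
#' pooling modes and/or classes. Samples are the species replicates within
#' the selected guild; compounds are the columns of the selected class that
#' are positive and non-constant within the subset. Incomputable cells
#' (p < 2 or n < 3 after filtering) are reported with a reason; cells at
#' the n = 3 boundary are flagged low-n.
#'
#' @param matrix An \code{emission_matrix} (typically the merged table).
#' @param annotation A \code{species_annotation} table.
#' @param classes Named character vector compound_id -> structural class.
#' @param n_null Null draws per cell (default 10000).
#' @param mode Null mode, see [pi_null()].
#' @param seed Integer seed (each cell uses a seed derived from it).
#' @return Data frame, one row per cell: \code{trophic_mode},
#'   \code{structural_class}, \code{n}, \code{p_compounds}, \code{raw},
#'   \code{corrected}, \code{relative_pct}, \code{q95}, \code{p_value},
#'   \code{significant}, \code{low_n}, \code{reason}.
#' @export
pi_panel <- function(matrix, annotation, classes, n_null = 10000,
                     mode = "permute", seed = 1L) {
  st <- sample_table(matrix)
  modes <- c("all", .TROPHIC_MODES)
  cls <- c("all", sort(unique(classes[colnames(matrix)])))
  out <- list()
  cell_i <- 0L
  for (mo in modes) {
    rows <- if (mo == "all") seq_len(nrow(matrix))
            else which(st$species_id %in%
                       annotation$species_id[annotation$trophic_mode == mo])
    for (cl in cls) {
      cell_i <- cell_i + 1L
      cols <- if (cl == "all") colnames(matrix)
              else names(classes)[classes == cl]
      cols <- intersect(cols, colnames(matrix))
      rec <- list(trophic_mode = mo, structural_class = cl,
                  n = length(rows), p_compounds = NA_integer_,
                  raw = NA_real_, corrected = NA_real_,
                  relative_pct = NA_real_, q95 = NA_real_,
                  p_value = NA_real_, significant = NA, low_n = NA,
                  reason = NA_character_)
      if (length(rows) < 3) {
        rec$reason <- "fewer than 3 samples"
      } else if (length(cols) < 2) {
        rec$reason <- "fewer than 2 compounds"
      } else {
        sub <- unclass(matrix)[rows, cols, drop = FALSE]
        sub <- sub[, apply(sub, 2, function(v) sd(v) > 0), drop = FALSE]
        if (ncol(sub) < 2) {
          rec$reason <- "fewer than 2 non-constant compounds in subset"
        } else {
          ii <- integration_index(sub)
          cr <- corrected_relative_pi(ii$raw, ii$p, ii$n)
          nl <- pi_null(sub, n_null = n_null, mode = mode,
                        pool = unclass(matrix)[rows, , drop = FALSE],
                        seed = stage_seed(seed, paste(mo, cl)))
          rec$p_compounds <- ii$p
          rec$raw <- ii$raw; rec$corrected <- cr$corrected
          rec$relative_pct <- cr$relative_pct
          rec$q95 <- nl$q95; rec$p_value <- nl$p_value
          rec$significant <- nl$significant
          rec$low_n <- ii$n <= 3
        }
      }
      out[[cell_i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
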