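#' Pielou evenness of an emission profile
#'
#' Shannon entropy of the relative abundances of the positive entries,
#' divided by the log of their count: \code{J = H / log(p)}, so \code{J = 1}
#' when all emitted compounds have equal abundance and \code{J -> 0} when one
#' compound dominates. Zeros (non-detections) are excluded before computing
#' relative abundances. Natural log is used throughout; J itself is
#' base-invariant.
#'
#' @param emissions Nonnegative numeric vector.
#' @return A scalar in \[0, 1\], or \code{NA} with a warning when fewer than
#'   two positive entries are present (evenness is undefined then).
#' @export
pielou_evenness <- function(emissions) {
  if (any(emissions < 0, na.rm = TRUE)) stop("emissions must be nonnegative")
  e <- emissions[emissions > 0]
  if (length(e) < 2) {
    warning("fewer than 2 positive entries; evenness undefined")
    return(NA_real_)
  }
  shannon_entropy(e) / log(length(e))
}

#' @rdname pielou_evenness
#' @export
shannon_entropy <- function(emissions) {
  e <- emissions[emissions > 0]
  q <- e / sum(e)
  -sum(q * log(q))
}

#' Per-species chemical-diversity summaries
#'
#' For each species the replicate profiles are averaged into one emission
#' vector (one evenness value per species, matching how such profiles are
#' usually reported), from which Shannon entropy H, Pielou evenness J, the
#' number of emitted compounds, and the total emission are computed.
#'
#' @param matrix An \code{emission_matrix}.
#' @return Data frame with one row per species: \code{species_id},
#'   \code{platform}, \code{n_compounds}, \code{total_emission}, \code{H},
#'   \code{J}.
#' @export
species_summaries <- function(matrix) {
  st <- sample_table(matrix)
  sp <- unique(st$species_id)
  means <- t(vapply(sp, function(s)
    colMeans(unclass(matrix)[st$species_id == s, , drop = FALSE]),
    numeric(ncol(matrix))))
  data.frame(
    species_id = sp,
    platform = attr(matrix, "platform"),
    n_compounds = apply(means, 1, function(v) sum(v > 0)),
    total_emission = rowSums(means),
    H = apply(means, 1, function(v) if (any(v > 0)) shannon_entropy(v) else NA_real_),
    J = apply(means, 1, function(v)
      if (sum(v > 0) >= 2) shannon_entropy(v[v > 0]) / log(sum(v > 0)) else NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
}
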