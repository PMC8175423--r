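#' Normalise raw PTR counts to reagent ions
#'
#' Counts per second are scaled to 1e6 reagent-ion counts to remove the
#' effect of varying primary-ion intensity (e.g. humidity differences
#' between cuvettes): \code{ncps = cps * 1e6 / reagent_counts}.
#'
#' @param cps Numeric vector of counts per second.
#' @param reagent_counts Positive scalar, reagent-ion counts.
#' @return ncps vector of the same length.
#' @export
normalize_reagent_ions <- function(cps, reagent_counts) {
  if (!is.numeric(reagent_counts) || length(reagent_counts) != 1 ||
      !is.finite(reagent_counts) || reagent_counts <= 0)
    stop("reagent_counts must be a single positive number")
  cps * 1e6 / reagent_counts
}

#' Subtract an interpolated background series
#'
#' A natural cubic spline is laid through the averaged background signal
#' (signals from blank measurements over the run), evaluated at the sample
#' timestamps, and subtracted; negative corrected values are clipped to 0
#' since downstream correlation and evenness statistics require nonnegative
#' abundances.
#'
#' @param sample_times,sample_values Timestamps and signals of the sample.
#' @param bg_times,bg_values Timestamps and signals of the background series;
#'   duplicate timestamps are averaged. At least 4 distinct background time
#'   points are required for the cubic spline.
#' @param method \code{"spline"} (natural cubic, default) or \code{"linear"}
#'   (fallback usable with fewer background points).
#' @return Corrected sample values, nonnegative.
#' @export
subtract_background <- function(sample_times, sample_values,
                                bg_times, bg_values,
                                method = c("spline", "linear")) {
  method <- match.arg(method)
  stopifnot(length(sample_times) == length(sample_values),
            length(bg_times) == length(bg_values))
  avg <- tapply(bg_values, bg_times, mean)
  t0 <- as.numeric(names(avg))
  o <- order(t0)
  t0 <- t0[o]; avg <- as.numeric(avg)[o]
  if (method == "spline" && length(t0) < 4)
    stop("cubic-spline background needs >= 4 distinct background time points; ",
         "use method = \"linear\" as a fallback")
  if (any(sample_times < min(t0)) || any(sample_times > max(t0)))
    stop("sample timestamps outside the background time span")
  bg_at <- if (method == "spline")
    splinefun(t0, avg, method = "natural")(sample_times)
  else
    stats::approx(t0, avg, xout = sample_times)$y
  pmax(sample_values - bg_at, 0)
}

#' Normalise a signal to mycelium area and accumulation time
#'
#' Emission rate = signal / (area x time). The PTR platform accumulates for
#' about 70 min, the GC sorptive collection for 16 h (960 min).
#'
#' @param signal Numeric vector. @param area_cm2 Mycelium area (cm2).
#' @param accumulation_minutes Accumulation time; defaults per platform via
#'   [default_accumulation_minutes()].
#' @return Normalised emission vector.
#' @export
area_time_normalize <- function(signal, area_cm2, accumulation_minutes) {
  if (area_cm2 <= 0 || accumulation_minutes <= 0)
    stop("area and accumulation time must be positive")
  signal / (area_cm2 * accumulation_minutes)
}

#' @rdname area_time_normalize
#' @param platform "PTR" or "GC".
#' @export
default_accumulation_minutes <- function(platform = c("PTR", "GC")) {
  switch(match.arg(platform), PTR = 70, GC = 960)
}

#' Convert ncps to pmol cm-2 h-1 via compound sensitivities
#'
#' Compounds with a known calibration sensitivity (ncps per ppbv) are
#' converted by the linear map \code{ncps / sensitivity * conversion_constant};
#' the constant absorbs flow and molar-volume terms of the full conversion,
#' which depend on the instrument configuration, and defaults to identity.
#' Compounds without a sensitivity are left in ncps and flagged, never
#' dropped.
#'
#' @param ncps Named numeric vector (names = compound ids).
#' @param sensitivities Named numeric vector of positive sensitivities; may
#'   cover only a subset of compounds.
#' @param conversion_constant Positive scalar of the linear map.
#' @return List with \code{values} (converted where possible) and
#'   \code{unconverted} (character vector of compound ids left in ncps).
#' @export
ncps_to_pmol <- function(ncps, sensitivities, conversion_constant = 1) {
  if (any(sensitivities <= 0)) stop("sensitivities must be positive")
  if (conversion_constant <= 0) stop("conversion_constant must be positive")
  out <- ncps
  have <- names(ncps) %in% names(sensitivities)
  out[have] <- ncps[have] / sensitivities[names(ncps)[have]] * conversion_constant
  list(values = out, unconverted = names(ncps)[!have])
}

#' Flag isotopologue mass features
#'
#' A PTR feature F2 is flagged as an isotopologue of F1 when their mass
#' difference matches the 13C (+1.00336 Da) or 18O (+2.00425 Da) spacing
#' within tolerance AND the mean intensity ratio F2/F1 falls inside a window
#' around the natural-abundance expectation. The expectation uses a
#' carbon-count heuristic for protonated oxygenated skeletons,
#' n_C = round((m/z - 18)/14) (overridable via \code{carbon_counts}), with
#' 1.1\% abundance per carbon for 13C and 0.205\% per oxygen (one assumed)
#' for 18O. The ratio check avoids removing genuine compounds at
#' coincidental mass spacing and can be disabled.
#'
#' @param compounds Compound record table (PTR rows carry \code{mz}).
#' @param matrix An \code{emission_matrix} whose columns match
#'   \code{compounds$compound_id} (used for mean intensities).
#' @param mass_tol_mDa Mass tolerance in mDa (default 2).
#' @param abundance_window Multiplicative window \[lo, hi\] around the
#'   expected ratio (default c(0.2, 5)); \code{NULL} disables the ratio check.
#' @param carbon_counts Optional named integer vector of carbon counts per
#'   compound id, overriding the heuristic.
#' @return The compound table with \code{is_isotopologue} updated.
#' @export
flag_isotopologues <- function(compounds, matrix, mass_tol_mDa = 2,
                               abundance_window = c(0.2, 5),
                               carbon_counts = NULL) {
  ptr <- which(compounds$platform == "PTR" & !is.na(compounds$mz))
  if (!length(ptr)) return(compounds)
  mz <- compounds$mz[ptr]
  ids <- compounds$compound_id[ptr]
  mean_int <- colMeans(unclass(matrix))[ids]
  n_c <- if (is.null(carbon_counts)) pmax(1, round((mz - 18) / 14))
         else as.numeric(carbon_counts[ids])
  tol <- mass_tol_mDa / 1000
  spacings <- c(C13 = 1.00336, O18 = 2.00425)
  flagged <- rep(FALSE, length(ptr))
  for (i2 in seq_along(ptr)) {
    for (i1 in seq_along(ptr)) {
      if (i1 == i2) next
      dm <- mz[i2] - mz[i1]
      for (k in seq_along(spacings)) {
        if (abs(dm - spacings[k]) > tol) next
        if (is.null(abundance_window)) { flagged[i2] <- TRUE; next }
        expected <- if (k == 1) n_c[i1] * 0.011 else 0.00205
        if (!is.finite(mean_int[i1]) || mean_int[i1] <= 0) next
        ratio <- mean_int[i2] / mean_int[i1]
        if (ratio >= abundance_window[1] * expected &&
            ratio <= abundance_window[2] * expected)
          flagged[i2] <- TRUE
      }
    }
  }
  compounds$is_isotopologue[ptr] <- flagged
  compounds
}

#' Remove flagged isotopologue columns from a matrix
#'
#' @param matrix An \code{emission_matrix}.
#' @param compounds Compound table with \code{is_isotopologue} set.
#' @return The matrix without isotopologue columns.
#' @export
drop_isotopologues <- function(matrix, compounds) {
  iso <- compounds$compound_id[compounds$is_isotopologue]
  keep <- setdiff(colnames(matrix), iso)
  matrix[, keep, drop = FALSE]
}

#' Group probable fragments by correlation
#'
#' Mass features originating as fragments of the same compound track each
#' other across samples. Features are connected when their squared Pearson
#' correlation exceeds \code{r2_threshold}; connected components of that
#' graph become fragment groups (component semantics: transitivity through
#' shared members is intended). Groups are annotated, not collapsed, by
#' default; \code{collapse = TRUE} sums members into the group head.
#'
#' @param matrix An \code{emission_matrix} with >= 3 samples.
#' @param r2_threshold Squared-correlation threshold (default 0.9).
#' @param collapse Sum grouped columns into one per group?
#' @return List with \code{groups} (named character vector compound ->
#'   group key; singletons get \code{NA}) and \code{matrix} (collapsed or
#'   original).
#' @export
group_fragments <- function(matrix, r2_threshold = 0.9, collapse = FALSE) {
  if (nrow(matrix) < 3) stop("fragment grouping needs >= 3 samples")
  v <- unclass(matrix)
  r <- suppressWarnings(cor(v))
  r[!is.finite(r)] <- 0                 # constant columns: correlation undefined -> 0
  adj <- (r * r > r2_threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  tab <- table(comp)
  groups <- setNames(rep(NA_character_, ncol(v)), colnames(v))
  for (cid in names(tab)[tab > 1]) {
    members <- colnames(v)[comp == as.integer(cid)]
    groups[members] <- paste0("frag_", members[1])
  }
  out <- matrix
  if (collapse) {
    keys <- ifelse(is.na(groups), names(groups), groups)
    collapsed <- sapply(unique(keys), function(k)
      rowSums(v[, keys == k, drop = FALSE]))
    out <- emission_matrix(collapsed, attr(matrix, "platform"), attr(matrix, "units"))
  }
  list(groups = groups, matrix = out)
}

#' Kovats-style retention index (temperature-programmed, linear)
#'
#' Retention times are expressed on the n-alkane scale via the van den
#' Dool-Kratz linear interpolation appropriate for temperature-programmed
#' chromatography: \code{RI = 100 * (n + (rt - rt_n) / (rt_{n+1} - rt_n))}
#' for the bracketing alkanes C_n, C_{n+1}. No extrapolation outside the
#' alkane span.
#'
#' @param rt_minutes Retention time(s) in minutes.
#' @param alkane_rts Named numeric vector: names are carbon numbers (e.g.
#'   9..25), values their retention times, strictly increasing.
#' @return Retention index (vectorised over \code{rt_minutes}).
#' @export
kovats_ri <- function(rt_minutes, alkane_rts) {
  n <- as.integer(names(alkane_rts))
  o <- order(n); n <- n[o]; rts <- as.numeric(alkane_rts)[o]
  if (any(diff(rts) <= 0))
    stop("alkane retention times must be strictly increasing in carbon number")
  if (any(rt_minutes < rts[1] | rt_minutes > rts[length(rts)]))
    stop(sprintf("retention time outside the alkane span [%g, %g] min; no extrapolation",
                 rts[1], rts[length(rts)]))
  idx <- findInterval(rt_minutes, rts, rightmost.closed = TRUE)
  100 * (n[idx] + (rt_minutes - rts[idx]) / (rts[idx + 1] - rts[idx]) *
           (n[idx + 1] - n[idx]))
}

#' Invert a retention index back to retention time
#'
#' @rdname kovats_ri
#' @param ri Retention index value(s).
#' @export
kovats_rt <- function(ri, alkane_rts) {
  n <- as.integer(names(alkane_rts))
  o <- order(n); n <- n[o]; rts <- as.numeric(alkane_rts)[o]
  scale <- 100 * n
  if (any(ri < scale[1] | ri > scale[length(scale)]))
    stop("retention index outside the alkane span")
  idx <- findInterval(ri, scale, rightmost.closed = TRUE)
  rts[idx] + (ri - scale[idx]) / (scale[idx + 1] - scale[idx]) *
    (rts[idx + 1] - rts[idx])
}

#' Internal-standard normalisation of GC peak areas
#'
#' Corrects drifting instrument sensitivity by scaling all peak areas so the
#' internal standard (a spiked monoterpene) matches its reference area:
#' \code{areas * is_reference_area / is_area}.
#'
#' @param areas Peak areas. @param is_area Internal-standard area (> 0).
#' @param is_reference_area Reference area of the internal standard (> 0).
#' @return Corrected areas.
#' @export
internal_standard_normalize <- function(areas, is_area, is_reference_area) {
  if (is_area <= 0 || is_reference_area <= 0)
    stop("internal-standard areas must be positive")
  areas * is_reference_area / is_area
}
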