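#' Construct an emission matrix
#'
#' The central container of the package: a nonnegative numeric matrix of
#' emission rates with samples (one fungal replicate each) as rows and
#' compounds as columns. Zeros encode non-detection; there is no separate
#' missing code. Row names are sample keys of the form
#' \code{"<species_id>:<replicate>"}; column names are compound ids.
#'
#' @param values Numeric matrix, samples x compounds, nonnegative, no NA.
#'   Must carry unique row and column names.
#' @param platform One of \code{"PTR"}, \code{"GC"}, \code{"combined"}.
#' @param units One of \code{"ncps_cm2_s"}, \code{"pmol_cm2_h"},
#'   \code{"mixed"} (the latter only for merged matrices).
#' @return An object of class \code{"emission_matrix"}: the matrix with
#'   \code{platform} and \code{units} attributes.
#' @export
emission_matrix <- function(values, platform, units) {
  platform <- match.arg(platform, .PLATFORMS)
  units    <- match.arg(units, .UNITS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (sample keys) and column names (compound ids)")
  if (anyNA(values))
    stop("NaN/NA forbidden in an emission matrix; zeros encode non-detection")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative emission at sample '%s', compound '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample keys: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate compound ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad_key <- !grepl("^[^:]+:[0-9]+$", rownames(values))
  if (any(bad_key))
    stop("malformed sample keys (expected 'species:replicate'): ",
         paste(head(rownames(values)[bad_key], 5), collapse = ", "))
  structure(values, platform = platform, units = units,
            class = c("emission_matrix", "matrix", "array"))
}

#' @export
print.emission_matrix <- function(x, ...) {
  cat(sprintf("emission_matrix: %d samples x %d compounds [%s, %s]\n",
              nrow(x), ncol(x), attr(x, "platform"), attr(x, "units")))
  invisible(x)
}

#' Sample keys of an emission matrix split into species and replicate
#'
#' @param x An \code{emission_matrix}.
#' @return Data frame with columns \code{sample_key}, \code{species_id},
#'   \code{replicate} in row order of \code{x}.
#' @export
sample_table <- function(x) {
  keys <- rownames(x)
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(sample_key = keys,
             species_id = vapply(parts, `[`, "", 1L),
             replicate  = as.integer(vapply(parts, function(p) p[length(p)], "")),
             stringsAsFactors = FALSE)
}

# Subset rows/columns while keeping class and attributes.
#' @export
`[.emission_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, platform = attr(x, "platform"), units = attr(x, "units"),
                     class = c("emission_matrix", "matrix", "array"))
  out
}

#' Merge PTR and GC emission matrices column-wise
#'
#' Concatenates the two platform tables over an identical sample set (GC rows
#' are reordered to the PTR row order if needed). Columns keep their platform
#' prefixes; the combined column order is all PTR columns followed by all GC
#' columns. No standardisation is applied here - the DAPC stage centers and
#' scales to unit variance so both platforms weigh equally.
#'
#' @param ptr,gc \code{emission_matrix} objects with platforms "PTR" and "GC".
#' @return A combined \code{emission_matrix} with platform \code{"combined"}
#'   and units \code{"mixed"}, plus a \code{col_platform} attribute.
#' @export
merge_platforms <- function(ptr, gc) {
  stopifnot(inherits(ptr, "emission_matrix"), inherits(gc, "emission_matrix"))
  if (attr(ptr, "platform") != "PTR" || attr(gc, "platform") != "GC")
    stop("merge_platforms expects a PTR matrix and a GC matrix, in that order")
  if (!setequal(rownames(ptr), rownames(gc))) {
    d1 <- setdiff(rownames(ptr), rownames(gc))
    d2 <- setdiff(rownames(gc), rownames(ptr))
    stop("sample sets differ; PTR-only: {", paste(d1, collapse = ", "),
         "}; GC-only: {", paste(d2, collapse = ", "), "}")
  }
  gc <- gc[rownames(ptr), , drop = FALSE]
  vals <- cbind(unclass(ptr), unclass(gc))
  out <- emission_matrix(vals, "combined", "mixed")
  attr(out, "col_platform") <- c(rep("PTR", ncol(ptr)), rep("GC", ncol(gc)))
  out
}

#' Read an emission matrix from TSV
#'
#' The format is tab-separated text with two mandatory pragma lines
#' (\code{#platform=} and \code{#units=}) before a header row of compound
#' ids; the first column holds sample keys \code{"species:replicate"}.
#'
#' @param path File path.
#' @param platform Optional platform to require; an error is raised if the
#'   file's pragma disagrees.
#' @return An \code{emission_matrix}.
#' @export
read_emission_matrix <- function(path, platform = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  prag <- grep("^#", lines, value = TRUE)
  get_pragma <- function(key) {
    hit <- grep(paste0("^#", key, "="), prag, value = TRUE)
    if (length(hit) != 1)
      stop("missing or duplicated mandatory pragma '#", key, "=' in ", path)
    sub(paste0("^#", key, "="), "", hit)
  }
  file_platform <- get_pragma("platform")
  file_units    <- get_pragma("units")
  if (!is.null(platform) && !identical(platform, file_platform))
    stop(sprintf("file %s declares platform '%s' but '%s' was requested",
                 path, file_platform, platform))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1]))
    stop("ragged rows in ", path, " (lines ",
         paste(which(ncols != ncols[1]) + length(prag), collapse = ", "), ")")
  header <- fields[[1]][-1]
  rows <- fields[-1]
  keys <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) stop("non-numeric value in row '", r[1], "' of ", path)
    v
  }, numeric(length(header))))
  if (length(header) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(keys, header)
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative value at sample '%s', compound '%s' in %s",
                 keys[neg[1, 1]], header[neg[1, 2]], path))
  emission_matrix(vals, file_platform, file_units)
}

#' Write an emission matrix to TSV
#'
#' Values are serialised with 12 significant digits (\code{\%.12g}), so a
#' read/write round trip is lossless at that precision and byte-stable.
#'
#' @param x An \code{emission_matrix}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_emission_matrix <- function(x, path) {
  stopifnot(inherits(x, "emission_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(s) writeBin(charToRaw(paste0(s, "\n")), con)
  emit(paste0("#platform=", attr(x, "platform")))
  emit(paste0("#units=", attr(x, "units")))
  emit(paste(c("sample", colnames(x)), collapse = "\t"))
  for (i in seq_len(nrow(x)))
    emit(paste(c(rownames(x)[i], sprintf("%.12g", x[i, ])), collapse = "\t"))
  invisible(path)
}
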