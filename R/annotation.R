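#' Validate a species annotation table
#'
#' A species annotation table holds taxonomy (phylum/class/order/family) and
#' ecological guild labels per species: trophic mode, an optional alternative
#' trophic mode (some species plausibly belong to two guilds), lifestyle,
#' substrate, host type, and the mean mycelium area used for emission-rate
#' normalisation. All categorical fields come from closed vocabularies
#' (see [voctrait_vocab()]).
#'
#' @param ann Data frame with columns \code{species_id}, \code{phylum},
#'   \code{class_}, \code{order_}, \code{family}, \code{trophic_mode},
#'   \code{alt_trophic_mode} (may be \code{NA}), \code{lifestyle},
#'   \code{substrate}, \code{host_type} (may be \code{NA}),
#'   \code{mycelium_area_cm2}.
#' @return The validated data frame, invisibly classed
#'   \code{"species_annotation"}.
#' @export
validate_species_annotation <- function(ann) {
  need <- c("species_id", "phylum", "class_", "order_", "family",
            "trophic_mode", "alt_trophic_mode", "lifestyle", "substrate",
            "host_type", "mycelium_area_cm2")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$species_id))
    stop("duplicate species_id: ",
         paste(unique(ann$species_id[duplicated(ann$species_id)]), collapse = ", "))
  check_enum <- function(col, allowed, optional = FALSE) {
    v <- ann[[col]]
    if (optional) v <- v[!is.na(v) & nzchar(v)]
    bad <- setdiff(unique(v), allowed)
    if (length(bad))
      stop(sprintf("unknown %s value(s) %s; allowed: %s", col,
                   paste(sQuote(bad), collapse = ", "),
                   paste(allowed, collapse = ", ")))
  }
  check_enum("phylum", .PHYLA)
  check_enum("trophic_mode", .TROPHIC_MODES)
  check_enum("alt_trophic_mode", .TROPHIC_MODES, optional = TRUE)
  check_enum("lifestyle", .LIFESTYLES)
  check_enum("substrate", .SUBSTRATES)
  check_enum("host_type", .HOST_TYPES, optional = TRUE)
  if (any(!is.finite(ann$mycelium_area_cm2) | ann$mycelium_area_cm2 <= 0))
    stop("mycelium_area_cm2 must be > 0 for every species")
  ann$alt_trophic_mode[!is.na(ann$alt_trophic_mode) & !nzchar(ann$alt_trophic_mode)] <- NA
  class(ann) <- c("species_annotation", "data.frame")
  invisible(ann)
}

#' Read a species annotation TSV
#'
#' Empty strings in \code{alt_trophic_mode} and \code{host_type} are read as
#' absent (\code{NA}). Unknown vocabulary tokens raise an error listing the
#' allowed values.
#'
#' @param path File path of a tab-separated annotation table.
#' @return A validated \code{species_annotation} data frame.
#' @export
read_species_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_species_annotation(ann)
}

#' Write a species annotation table to TSV
#'
#' @param ann A \code{species_annotation} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_species_annotation <- function(ann, path) {
  out <- as.data.frame(ann)
  out[is.na(out)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a compound record table
#'
#' One row per measured feature: PTR mass features carry an m/z, GC compounds
#' a Kovats retention index (exactly one of the two), a structural class from
#' the closed vocabulary, and optional isotopologue / fragment-group /
#' cluster-letter annotations filled in by later stages.
#'
#' @param cmp Data frame with columns \code{compound_id}, \code{platform},
#'   \code{mz}, \code{retention_index}, \code{annotation},
#'   \code{structural_class}, \code{cluster_letter}, \code{is_isotopologue},
#'   \code{fragment_group}.
#' @param classes Allowed structural-class vocabulary (configurable).
#' @return The validated data frame, invisibly.
#' @export
validate_compound_records <- function(cmp, classes = .STRUCT_CLASSES) {
  need <- c("compound_id", "platform", "mz", "retention_index", "annotation",
            "structural_class", "cluster_letter", "is_isotopologue", "fragment_group")
  miss <- setdiff(need, names(cmp))
  if (length(miss)) stop("compound table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cmp$compound_id)) stop("duplicate compound_id values")
  bad <- setdiff(unique(cmp$structural_class), classes)
  if (length(bad))
    stop("unknown structural_class value(s): ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(classes, collapse = ", "))
  is_ptr <- cmp$platform == "PTR"
  if (any(is_ptr & (is.na(cmp$mz) | !is.na(cmp$retention_index))))
    stop("PTR compounds must have mz set and retention_index empty")
  if (any(!is_ptr & (is.na(cmp$retention_index) | !is.na(cmp$mz))))
    stop("GC compounds must have retention_index set and mz empty")
  if (any(!is.na(cmp$mz) & cmp$mz <= 0) ||
      any(!is.na(cmp$retention_index) & cmp$retention_index <= 0))
    stop("mz and retention_index must be positive where present")
  invisible(cmp)
}

#' Read / write a compound record table (TSV)
#'
#' @param path File path.
#' @return \code{read_compound_records}: validated data frame.
#' @export
read_compound_records <- function(path) {
  cmp <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  cmp$is_isotopologue <- as.logical(cmp$is_isotopologue)
  validate_compound_records(cmp)
}

#' @rdname read_compound_records
#' @param cmp Compound record data frame.
#' @export
write_compound_records <- function(cmp, path) {
  out <- as.data.frame(cmp)
  out[is.na(out)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
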