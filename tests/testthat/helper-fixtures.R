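# Shared fixture builders; everything is generated in code.

# Small emission matrix with valid "species:replicate" keys.
toy_matrix <- function(values, platform = "PTR", units = "ncps_cm2_s",
                       n_rep = 1) {
  n <- nrow(values)
  sp <- rep(sprintf("sp%02d", seq_len(ceiling(n / n_rep))), each = n_rep)[1:n]
  reps <- as.integer(ave(seq_len(n), sp, FUN = seq_along))
  rownames(values) <- paste0(sp, ":", reps)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s_%03d", platform, seq_len(ncol(values)))
  emission_matrix(values, platform, units)
}

# One-factor block data: p columns sharing a latent factor with the given
# loading, unit total variance per column.
one_factor_block <- function(n, p, loading) {
  f <- rnorm(n)
  loading * matrix(f, n, p) + sqrt(1 - loading^2) * matrix(rnorm(n * p), n, p)
}

# Minimal valid species annotation for a set of species ids.
toy_annotation <- function(species, trophic = NULL) {
  n <- length(species)
  if (is.null(trophic)) trophic <- rep(voctrait_vocab()$trophic_mode, length.out = n)
  validate_species_annotation(data.frame(
    species_id = species, phylum = rep(voctrait_vocab()$phylum, length.out = n),
    class_ = "c1", order_ = "o1", family = "f1",
    trophic_mode = trophic, alt_trophic_mode = NA_character_,
    lifestyle = rep(voctrait_vocab()$lifestyle, length.out = n),
    substrate = rep(voctrait_vocab()$substrate, length.out = n),
    host_type = rep(voctrait_vocab()$host_type, length.out = n),
    mycelium_area_cm2 = 10, stringsAsFactors = FALSE))
}
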