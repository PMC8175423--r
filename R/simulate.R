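#' Define a synthetic volatilome scenario
#'
#' The generator emulates the structure of a dual-platform fungal volatilome
#' study: a PTR-ToF-MS-like table of mass features and a GC-MS-like table of
#' annotated compounds over the same species x replicate design, with
#' log-normal emissions, heavy species-level sparsity, structural-class
#' covariation blocks within trophic modes, and planted group-specific
#' biomarkers that give every downstream stage a ground truth.
#'
#' The generative model for the log emission of compound \eqn{j} in species
#' \eqn{s}, replicate \eqn{r} is
#' \deqn{x = \mu_0 + a_j + b_{g(s),j} + \lambda_{c(j)} f_{s,c(j)} + \epsilon,}
#' with compound offset \eqn{a_j \sim N(0, 0.5)} (sd), planted biomarker
#' effect \eqn{b = \delta \sigma_0} when species \eqn{s} carries the label
#' value targeted by a biomarker entry naming \eqn{j} (else 0), a per-species
#' latent factor \eqn{f_{s,c} \sim N(0,1)} shared by all compounds of
#' structural class \eqn{c} for species of the covariation entry's trophic
#' mode (loading \eqn{\lambda}, else 0), and residual
#' \eqn{\epsilon \sim N(0, \sigma_0)}. The emission is \eqn{\exp(x)}, masked
#' to 0 with probability \eqn{\pi} per (species, compound) pair - a species
#' either emits a compound in all replicates or in none. Planted biomarker
#' compounds are never masked in species of their target group (a biomarker
#' is defined by reliable presence). GC compounds use dispersion scaled by
#' \code{gc_dispersion} (default 0.6) on both \eqn{a_j} and \eqn{\epsilon},
#' so GC profiles are more even than PTR profiles.
#'
#' @param n_species,n_replicates Design size (defaults 43 species x 3).
#' @param n_ptr_compounds,n_gc_compounds Features per platform (200 / 60).
#' @param mu0 Base log-mean emission. @param sigma0 Residual log-sd.
#' @param a_sd Sd of the per-compound offset.
#' @param gc_dispersion Multiplier on GC log-scale dispersion.
#' @param sparsity Probability \eqn{\pi} that a species never emits a compound.
#' @param biomarker_spec Data frame with columns \code{label} (annotation
#'   column), \code{class_value}, \code{compound_id}, \code{delta} (log-effect
#'   in \eqn{\sigma_0} units). Default plants 6 PTR trophic-mode biomarkers
#'   (2/2/1/1 over the four modes) at \eqn{\delta = 3}.
#' @param covariation_spec Data frame with columns \code{trophic_mode},
#'   \code{structural_class}, \code{loading} in \[0,1\]. Default plants one
#'   block: (saprotrophic, carboxylic_acid) at loading 0.8.
#' @param alt_fraction Fraction of species given an alternative trophic mode.
#' @param balanced If \code{TRUE} (default) guild labels are balanced across
#'   their levels; \code{FALSE} gives an unbalanced preset in which
#'   mycoparasites are a single rare class, exercising the upsampling path.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the scenario including this seed.
#' @return A \code{sim_scenario} list.
#' @export
simulation_scenario <- function(n_species = 43, n_replicates = 3,
                                n_ptr_compounds = 200, n_gc_compounds = 60,
                                mu0 = 2, sigma0 = 1, a_sd = 0.5,
                                gc_dispersion = 0.6, sparsity = 0.4,
                                biomarker_spec = NULL, covariation_spec = NULL,
                                alt_fraction = 0.25, balanced = TRUE,
                                seed = 1L) {
  if (is.null(biomarker_spec)) {
    biomarker_spec <- data.frame(
      label = "trophic_mode",
      class_value = c("saprotrophic", "saprotrophic", "mycorrhizal",
                      "mycorrhizal", "phytopathogenic", "mycoparasitic"),
      compound_id = sprintf("PTR_%03d", 1:6),
      delta = 3,
      stringsAsFactors = FALSE)
  }
  if (is.null(covariation_spec)) {
    covariation_spec <- data.frame(trophic_mode = "saprotrophic",
                                   structural_class = "carboxylic_acid",
                                   loading = 0.8, stringsAsFactors = FALSE)
  }
  sc <- list(n_species = n_species, n_replicates = n_replicates,
             n_ptr_compounds = n_ptr_compounds, n_gc_compounds = n_gc_compounds,
             mu0 = mu0, sigma0 = sigma0, a_sd = a_sd,
             gc_dispersion = gc_dispersion, sparsity = sparsity,
             biomarker_spec = biomarker_spec, covariation_spec = covariation_spec,
             alt_fraction = alt_fraction, balanced = balanced,
             seed = as.integer(seed))
  class(sc) <- "sim_scenario"
  validate_scenario(sc)
  sc
}

#' @rdname simulation_scenario
#' @param sc A \code{sim_scenario}.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  with(sc, {
    if (n_species < 8 || n_replicates < 2)
      stop("need n_species >= 8 (so every guild level is covered at least twice) and n_replicates >= 2")
    if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)")
    if (sigma0 <= 0 || a_sd < 0 || gc_dispersion <= 0) stop("dispersions must be positive")
    if (any(sc$biomarker_spec$delta < 0)) stop("biomarker delta must be >= 0")
    if (any(sc$covariation_spec$loading < 0 | sc$covariation_spec$loading > 1))
      stop("covariation loadings must lie in [0, 1]")
    ids <- c(sprintf("PTR_%03d", seq_len(n_ptr_compounds)),
             sprintf("GC_%03d", seq_len(n_gc_compounds)))
    bad <- setdiff(sc$biomarker_spec$compound_id, ids)
    if (length(bad)) stop("biomarker_spec names unknown compounds: ",
                          paste(bad, collapse = ", "))
    bad_cl <- setdiff(sc$covariation_spec$structural_class, .STRUCT_CLASSES)
    if (length(bad_cl)) stop("unknown structural class in covariation_spec: ",
                             paste(bad_cl, collapse = ", "))
  })
  invisible(sc)
}

# Balanced label vector over `levels`, permuted with the current RNG.
balanced_labels <- function(levels, n) {
  sample(rep(levels, length.out = n))
}

#' Simulate a dual-platform volatilome data set
#'
#' Runs the generative model of [simulation_scenario()] and returns both
#' platform matrices, the species annotation, the compound table, and the
#' planted ground truth. Deterministic for a fixed scenario (including its
#' seed): the same scenario always yields byte-identical tables.
#'
#' @param scenario A \code{sim_scenario}.
#' @return List with elements \code{ptr}, \code{gc} (emission matrices),
#'   \code{annotation} (\code{species_annotation}), \code{compounds}
#'   (compound record table) and \code{truth} (planted biomarkers,
#'   covariation blocks, per-compound class).
#' @export
simulate_volatilome <- function(scenario) {
  validate_scenario(scenario)
  sc <- scenario
  set.seed(sc$seed)
  ns <- sc$n_species; nr <- sc$n_replicates

  species <- sprintf("sp%02d", seq_len(ns))

  # --- guild labels -----------------------------------------------------
  if (sc$balanced) {
    trophic <- balanced_labels(.TROPHIC_MODES, ns)
  } else {
    # unbalanced preset: mycoparasites rare (2 species), saprotrophs dominant
    pool <- c(rep("mycoparasitic", 2),
              rep("mycorrhizal", max(2, round(ns * 0.2))),
              rep("phytopathogenic", max(2, round(ns * 0.25))))
    pool <- c(pool, rep("saprotrophic", ns - length(pool)))
    trophic <- sample(pool)
  }
  phylum    <- balanced_labels(.PHYLA, ns)
  lifestyle <- balanced_labels(.LIFESTYLES, ns)
  substrate <- balanced_labels(.SUBSTRATES, ns)
  host      <- balanced_labels(.HOST_TYPES, ns)

  n_alt <- round(sc$alt_fraction * ns)
  alt <- rep(NA_character_, ns)
  if (n_alt > 0) {
    idx <- sample(ns, n_alt)
    alt[idx] <- vapply(idx, function(i)
      sample(setdiff(.TROPHIC_MODES, trophic[i]), 1), "")
  }

  ann <- data.frame(
    species_id = species, phylum = phylum,
    class_  = paste0(substr(phylum, 1, 4), "_class", (seq_len(ns) %% 3) + 1),
    order_  = paste0(substr(phylum, 1, 4), "_order", (seq_len(ns) %% 5) + 1),
    family  = paste0(substr(phylum, 1, 4), "_fam",   (seq_len(ns) %% 7) + 1),
    trophic_mode = trophic, alt_trophic_mode = alt,
    lifestyle = lifestyle, substrate = substrate, host_type = host,
    mycelium_area_cm2 = exp(rnorm(ns, log(10), 0.3)),
    stringsAsFactors = FALSE)
  ann <- validate_species_annotation(ann)

  # --- compound table ---------------------------------------------------
  np <- sc$n_ptr_compounds; ng <- sc$n_gc_compounds
  mz <- sort(round(runif(np, 31, 250), 3))
  mz <- mz + cumsum(duplicated(mz)) * 1e-3            # force uniqueness
  ri <- sort(round(runif(ng, 900, 2400)))
  ri <- ri + cumsum(duplicated(ri))
  cls_ptr <- rep(.STRUCT_CLASSES, length.out = np)
  cls_gc  <- rep(.STRUCT_CLASSES, length.out = ng)
  compounds <- data.frame(
    compound_id = c(sprintf("PTR_%03d", seq_len(np)), sprintf("GC_%03d", seq_len(ng))),
    platform = c(rep("PTR", np), rep("GC", ng)),
    mz = c(mz, rep(NA_real_, ng)),
    retention_index = c(rep(NA_real_, np), ri),
    annotation = c(sprintf("m/z %.3f", mz), sprintf("compound RI %d", ri)),
    structural_class = c(cls_ptr, cls_gc),
    cluster_letter = NA_character_, is_isotopologue = FALSE,
    fragment_group = NA_character_, stringsAsFactors = FALSE)
  validate_compound_records(compounds)

  # --- latent factors and effects --------------------------------------
  cov_spec <- sc$covariation_spec
  f <- matrix(rnorm(ns * nrow(cov_spec)), ns, max(1, nrow(cov_spec)))

  gen_platform <- function(prefix, n_comp, classes, disp) {
    a <- rnorm(n_comp, 0, sc$a_sd * disp)
    ids <- sprintf(paste0(prefix, "_%03d"), seq_len(n_comp))
    b <- matrix(0, ns, n_comp, dimnames = list(species, ids))
    bm <- sc$biomarker_spec[sc$biomarker_spec$compound_id %in% ids, , drop = FALSE]
    if (nrow(bm)) for (k in seq_len(nrow(bm))) {
      j <- match(bm$compound_id[k], ids)
      hit <- ann[[bm$label[k]]] == bm$class_value[k]
      hit[is.na(hit)] <- FALSE
      b[hit, j] <- b[hit, j] + bm$delta[k] * sc$sigma0
    }
    lam <- matrix(0, ns, n_comp)
    for (e in seq_len(nrow(cov_spec))) {
      in_mode  <- ann$trophic_mode == cov_spec$trophic_mode[e]
      in_class <- classes == cov_spec$structural_class[e]
      lam[in_mode, in_class] <- lam[in_mode, in_class] +
        cov_spec$loading[e] * f[in_mode, e]
    }
    keep <- matrix(rbinom(ns * n_comp, 1, 1 - sc$sparsity), ns, n_comp)
    if (nrow(bm)) for (k in seq_len(nrow(bm))) {     # biomarkers present in target group
      j <- match(bm$compound_id[k], ids)
      hit <- ann[[bm$label[k]]] == bm$class_value[k]
      hit[is.na(hit)] <- FALSE
      keep[hit, j] <- 1
    }
    rows <- as.vector(t(outer(species, seq_len(nr), paste, sep = ":")))
    x <- matrix(0, ns * nr, n_comp, dimnames = list(rows, ids))
    eps <- matrix(rnorm(ns * nr * n_comp, 0, sc$sigma0 * disp), ns * nr, n_comp)
    for (s in seq_len(ns)) {
      rr <- ((s - 1) * nr + 1):(s * nr)
      mu <- sc$mu0 + a + b[s, ] + lam[s, ]
      x[rr, ] <- sweep(eps[rr, , drop = FALSE], 2, mu, `+`)
      x[rr, keep[s, ] == 0] <- -Inf                  # masked: never emitted
    }
    exp(x)
  }

  ptr <- emission_matrix(gen_platform("PTR", np, cls_ptr, 1), "PTR", "ncps_cm2_s")
  gc  <- emission_matrix(gen_platform("GC", ng, cls_gc, sc$gc_dispersion),
                         "GC", "pmol_cm2_h")

  truth <- list(biomarkers = sc$biomarker_spec,
                covariation = cov_spec,
                classes = setNames(compounds$structural_class, compounds$compound_id))
  list(ptr = ptr, gc = gc, annotation = ann, compounds = compounds, truth = truth)
}

#' Effective labels for a grouping column
#'
#' For the alternative-trophic-mode grouping, species without an alternative
#' mode keep their primary trophic mode; other columns are returned as-is.
#'
#' @param ann A \code{species_annotation} table.
#' @param label Annotation column name.
#' @return Named character vector over \code{species_id}.
#' @export
effective_labels <- function(ann, label) {
  v <- ann[[label]]
  if (is.null(v)) stop("no annotation column '", label, "'")
  if (label == "alt_trophic_mode") v <- ifelse(is.na(v), ann$trophic_mode, v)
  setNames(v, ann$species_id)
}
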