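#' Build a validated pipeline configuration
#'
#' The pipeline is configured by a nested list (or a JSON file with the same
#' shape). Unknown keys anywhere in the structure are rejected, so typos
#' cannot silently fall back to defaults. A single global seed
#' deterministically derives per-stage seeds (a small hash of the stage
#' name folded into the seed), so rerunning one stage reproduces exactly
#' what the full pipeline computed.
#'
#' @param config A list, a path to a JSON config file, or \code{NULL} for
#'   all defaults.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    seed = 1L,
    scenario = list(n_species = 43, n_replicates = 3, n_ptr_compounds = 200,
                    n_gc_compounds = 60, mu0 = 2, sigma0 = 1, a_sd = 0.5,
                    gc_dispersion = 0.6, sparsity = 0.4, alt_fraction = 0.25,
                    balanced = TRUE),
    stages = list(preprocess = TRUE, diversity = TRUE, clustering = TRUE,
                  dapc = TRUE, pi = TRUE, biomarkers = TRUE),
    clustering = list(k = 17, linkage = "average"),
    dapc = list(labels = c("trophic_mode", "alt_trophic_mode", "phylum"),
                n_rep = 10, training_fraction = 0.9, grid = NULL,
                log_transform = TRUE),
    pi = list(n_null = 1000, mode = "permute"),
    biomarkers = list(tasks = "trophic_mode", platforms = c("PTR", "GC"),
                      ntree = 200, cv_folds = 10, test_fraction = 0.25,
                      subset_grid = NULL)
  )
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config)) config <- list()
  merged <- merge_config(defaults, config, path = "config")
  class(merged) <- "pipeline_config"
  merged
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s) under ", path, ": ",
         paste(unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], as.list(user[[k]]), paste0(path, "$", k))
    else user[[k]]
  }
  defaults
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes, in dependency order: data simulation, feature-table annotation
#' (isotopologue flags, fragment groups), per-platform diversity summaries,
#' compound clustering, DAPC per label scheme (with cross-validated PC
#' selection), the phenotypic-integration panel, and the biomarker ensemble
#' per task and platform, writing every artifact plus a run manifest to
#' \code{out_dir}. Outputs contain no timestamps, so a rerun under the same
#' config is byte-identical.
#'
#' @param config A \code{pipeline_config}, raw list, or JSON path.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(out_dir, ...)
  seeds <- list()
  results <- list()

  # -- simulate ----------------------------------------------------------
  seeds$simulate <- stage_seed(cfg$seed, "simulate")
  scen_args <- cfg$scenario
  scen_args$seed <- seeds$simulate
  scenario <- do.call(simulation_scenario, scen_args)
  sim <- simulate_volatilome(scenario)
  write_emission_matrix(sim$ptr, out("ptr.tsv"))
  write_emission_matrix(sim$gc, out("gc.tsv"))
  write_species_annotation(sim$annotation, out("species.tsv"))
  results$sim <- sim

  compounds <- sim$compounds
  merged <- merge_platforms(sim$ptr, sim$gc)

  # -- preprocess annotations -------------------------------------------
  if (isTRUE(cfg$stages$preprocess)) {
    compounds <- flag_isotopologues(compounds, sim$ptr)
    fg <- group_fragments(sim$ptr)
    compounds$fragment_group[match(names(fg$groups), compounds$compound_id)] <-
      unname(fg$groups)
  }

  # -- diversity ---------------------------------------------------------
  if (isTRUE(cfg$stages$diversity)) {
    div <- rbind(species_summaries(sim$ptr), species_summaries(sim$gc))
    write.table(format(div, digits = 12, trim = TRUE), out("diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$diversity <- div
  }

  # -- clustering --------------------------------------------------------
  if (isTRUE(cfg$stages$clustering)) {
    d <- spearman_distance_matrix(merged)
    k <- min(cfg$clustering$k, ncol(merged))
    ca <- cluster_compounds(d, k = k, linkage = cfg$clustering$linkage)
    compounds$cluster_letter <- unname(ca$letters[compounds$compound_id])
    write_json_out(list(merge = ca$tree$merge, height = ca$tree$height,
                        order = ca$tree$order, labels = ca$tree$labels,
                        k = k), out("cluster_tree.json"))
    results$clusters <- ca
  }
  write_compound_records(compounds, out("compounds.tsv"))
  results$compounds <- compounds

  # -- dapc --------------------------------------------------------------
  if (isTRUE(cfg$stages$dapc)) {
    results$dapc <- list()
    dapc_x <- if (isTRUE(cfg$dapc$log_transform)) log1p(unclass(merged))
              else unclass(merged)
    for (label in cfg$dapc$labels) {
      seeds[[paste0("dapc_", label)]] <- stage_seed(cfg$seed, paste0("dapc_", label))
      lab <- effective_labels(sim$annotation, label)[sample_table(merged)$species_id]
      xv <- suppressWarnings(
        xval_select_m(dapc_x, lab, grid = cfg$dapc$grid,
                      training_fraction = cfg$dapc$training_fraction,
                      n_rep = cfg$dapc$n_rep,
                      seed = seeds[[paste0("dapc_", label)]]))
      fit <- suppressWarnings(fit_dapc(dapc_x, lab, xv$chosen_m))
      pred <- predict_dapc(fit, dapc_x)
      write_json_out(list(label = label, chosen_m = xv$chosen_m,
                          grid = xv$grid, rmse = xv$rmse,
                          mean_success = xv$mean_success,
                          eigenvalues = fit$eigenvalues,
                          coords = as.data.frame(pred$coords),
                          assignment = data.frame(
                            sample = rownames(merged), truth = unname(lab),
                            assigned = as.character(pred$assignment))),
                     out(paste0("dapc_", label, ".json")))
      results$dapc[[label]] <- list(xval = xv, model = fit, pred = pred)
    }
  }

  # -- phenotypic integration -------------------------------------------
  if (isTRUE(cfg$stages$pi)) {
    seeds$pi <- stage_seed(cfg$seed, "pi")
    classes <- setNames(compounds$structural_class, compounds$compound_id)
    panel <- suppressWarnings(
      pi_panel(merged, sim$annotation, classes, n_null = cfg$pi$n_null,
               mode = cfg$pi$mode, seed = seeds$pi))
    write_json_out(panel, out("pi_panel.json"))
    results$pi <- panel
  }

  # -- biomarkers --------------------------------------------------------
  if (isTRUE(cfg$stages$biomarkers)) {
    results$biomarkers <- list()
    for (pf in cfg$biomarkers$platforms) {
      mat <- if (pf == "PTR") sim$ptr else sim$gc
      for (task in cfg$biomarkers$tasks) {
        id <- paste0("biomarkers_", pf, "_", task)
        seeds[[id]] <- stage_seed(cfg$seed, id)
        rep <- run_biomarker_task(mat, sim$annotation, task,
                                  seed = seeds[[id]],
                                  test_fraction = cfg$biomarkers$test_fraction,
                                  cv_folds = cfg$biomarkers$cv_folds,
                                  ntree = cfg$biomarkers$ntree,
                                  subset_grid = cfg$biomarkers$subset_grid)
        write_json_out(biomarker_report_json(rep), out(paste0(id, ".json")))
        results$biomarkers[[id]] <- rep
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("voctrait")),
    seed = cfg$seed, stage_seeds = seeds,
    stages_run = names(Filter(isTRUE, cfg$stages)),
    stages_skipped = names(Filter(Negate(isTRUE), cfg$stages)),
    config = unclass(cfg))
  write_json_out(manifest, out("manifest.json"))
  invisible(c(results, list(manifest = manifest)))
}

# JSON-serialisable view of a biomarker report (drops the fitted forests).
biomarker_report_json <- function(rep) {
  list(label = rep$label, platform = rep$platform,
       n_train = rep$n_train, n_test = rep$n_test,
       models = lapply(rep$models, function(m)
         list(model_id = m$model_id,
              optimal_subset_size = m$optimal_subset_size,
              top15 = m$top15, accuracy = m$accuracy,
              sensitivity = as.list(m$sensitivity),
              p_value = m$p_value, nir = m$nir, passed = m$passed)),
       consensus = list(
         predictors = rep$consensus$consensus$predictor,
         mean_rank = rep$consensus$consensus$mean_rank,
         passing_models = rep$consensus$passing_models,
         mean_accuracy = rep$consensus$mean_accuracy,
         mean_sensitivity = as.list(rep$consensus$mean_sensitivity),
         mean_p_value = rep$consensus$mean_p_value,
         note = rep$consensus$note))
}
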