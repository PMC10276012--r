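## Default trait set carried into the comparative stages, mirroring the
## size-normalized variables of the swimming analyses.
default_pipeline_traits <- c("f_mean", "u_mean", "Re_mean", "P_freq", "P_time",
                             "P_dist", "C_time", "C_dist", "R_time", "R_dist",
                             "I_time", "I_dist", "PER")

write_csv_precise <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the full-run configuration.  A run's
#' configuration is echoed into its output directory as `config.yaml`, and
#' every option is serializable.
#'
#' @param output_dir directory for the output bundle (created if absent).
#' @param trajectories named list of [trajectory()] objects, or a directory
#'   of trajectory CSVs (schema of [write_trajectory_csv()]).
#' @param metrics_csv optional cached per-sequence metrics CSV from a
#'   previous run; when set, the trajectory/kinematics/segmentation stages
#'   are skipped and downstream stages start from this intermediate.
#' @param tree optional `phylo`, Newick string or Newick file path; enables
#'   the phylogenetic-signal and ancestral-state stages.
#' @param traits trait columns entering normalization, correlation, PCA
#'   and phylogenetic stages (default [default_pipeline_traits]).
#' @param viscosity,smooth_window,resample_dt,detect_smooth_window,
#'   prominence,min_separation sequence-analysis options, see
#'   [analyze_sequence()].
#' @param families scaling families, see [fit_models()].
#' @param standardize_pca correlation-matrix PCA if `TRUE`.
#' @param n_perm,seed randomization-test options.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(output_dir,
                            trajectories = NULL,
                            metrics_csv = NULL,
                            tree = NULL,
                            traits = default_pipeline_traits,
                            viscosity = NULL,
                            smooth_window = NULL,
                            resample_dt = NULL,
                            detect_smooth_window = NULL,
                            prominence = 0.25,
                            min_separation = NULL,
                            families = ontogeny_families,
                            standardize_pca = TRUE,
                            n_perm = 1000,
                            seed = 1) {
  cfg <- structure(list(output_dir = output_dir, trajectories = trajectories,
                        metrics_csv = metrics_csv, tree = tree, traits = traits,
                        viscosity = viscosity, smooth_window = smooth_window,
                        resample_dt = resample_dt,
                        detect_smooth_window = detect_smooth_window,
                        prominence = prominence, min_separation = min_separation,
                        families = families, standardize_pca = standardize_pca,
                        n_perm = n_perm, seed = seed),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

## All input validation happens before any compute.
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$output_dir) || !is.character(cfg$output_dir))
    stop_invalid("config: output_dir is required")
  if (is.null(cfg$trajectories) && is.null(cfg$metrics_csv))
    stop_invalid("config: provide trajectories or a cached metrics_csv")
  if (!is.null(cfg$metrics_csv) && !file.exists(cfg$metrics_csv))
    stop_invalid("config: metrics_csv not found: ", cfg$metrics_csv)
  if (is.character(cfg$trajectories) && !dir.exists(cfg$trajectories))
    stop_invalid("config: trajectory directory not found: ", cfg$trajectories)
  if (is.list(cfg$trajectories) &&
      !all(vapply(cfg$trajectories, inherits, logical(1), "trajectory")))
    stop_invalid("config: trajectories must all be trajectory objects")
  if (!is.null(cfg$tree) && is.character(cfg$tree) && !grepl("\\(", cfg$tree) &&
      !file.exists(cfg$tree))
    stop_invalid("config: tree file not found: ", cfg$tree)
  assert_scalar_num(cfg$n_perm, "n_perm", positive = TRUE)
  assert_scalar_num(cfg$seed, "seed")
  invisible(cfg)
}

## Serializable echo of the configuration (objects replaced by summaries).
config_echo <- function(cfg) {
  out <- unclass(cfg)
  if (is.list(out$trajectories)) out$trajectories <- names(out$trajectories)
  if (inherits(out$tree, "phylo")) out$tree <- ape::write.tree(out$tree)
  out[!vapply(out, is.null, logical(1))]
}

#' Run the full swimming-kinematics pipeline
#'
#' Executes trajectories -> kinematics -> cycle segmentation ->
#' per-sequence metrics -> ontogenetic scaling fits -> size-normalized
#' species trait table -> Pearson correlations and PCA -> phylogenetic
#' signal and ancestral states (when a tree is configured).  Every stage's
#' output is written as plain CSV/TSV under `output_dir`, together with a
#' `config.yaml` echo, a `log.txt` of per-sequence diagnostics, and a
#' `manifest.csv` of file checksums.  All randomness derives from
#' `config$seed`, so a rerun with the same config is bit-identical; a run
#' started from a cached `metrics_csv` reproduces all downstream outputs.
#' A failing stage halts with a stage-tagged error, preserving the outputs
#' already written.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `metrics`, `cycles`, `fits`,
#'   `species_traits`, `correlations`, `pca`, `phylo_signal`, `ancestral`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_add <- function(...) log_lines <<- c(log_lines, paste0(...))
  outfile <- function(name) file.path(cfg$output_dir, name)
  written <- character()
  emit <- function(df, name, sep = ",") {
    write_csv_precise(df, outfile(name), sep = sep)
    written <<- c(written, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, outfile("log.txt"))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  yaml::write_yaml(config_echo(cfg), outfile("config.yaml"))
  written <- c(written, "config.yaml")

  cycles_all <- NULL
  if (!is.null(cfg$metrics_csv)) {
    metrics <- stage("load_metrics", utils::read.csv(cfg$metrics_csv))
    log_add("metrics loaded from cache: ", cfg$metrics_csv,
            " (", nrow(metrics), " sequences)")
  } else {
    trajs <- stage("load_trajectories", {
      if (is.character(cfg$trajectories)) {
        files <- sort(list.files(cfg$trajectories, pattern = "\\.csv$",
                                 full.names = TRUE))
        if (!length(files)) stop_invalid("no trajectory CSVs found")
        stats::setNames(lapply(files, read_trajectory_csv),
                        sub("\\.csv$", "", basename(files)))
      } else cfg$trajectories
    })
    res <- stage("kinematics_segmentation", {
      rows <- list(); cyc <- list()
      for (id in names(trajs)) {
        a <- analyze_sequence(trajs[[id]], viscosity = cfg$viscosity,
                              smooth_window = cfg$smooth_window,
                              resample_dt = cfg$resample_dt,
                              detect_smooth_window = cfg$detect_smooth_window,
                              prominence = cfg$prominence,
                              min_separation = cfg$min_separation)
        mt <- a$metrics
        mt$sequence_id <- id
        mt$species <- trajs[[id]]$species
        mt$individual <- trajs[[id]]$individual
        mt$diameter_cm <- mt$reference_diameter
        rows[[id]] <- mt
        if (nrow(a$cycles)) cyc[[id]] <- cbind(sequence_id = id, a$cycles)
        log_add(sprintf("sequence %s: %d cycles detected%s", id, mt$n_pulses,
                        if (isTRUE(mt$fallback_segmentation))
                          " [velocity-only segmentation fallback]" else ""))
      }
      list(metrics = do.call(rbind, rows),
           cycles = if (length(cyc)) do.call(rbind, cyc) else NULL)
    })
    metrics <- res$metrics
    cycles_all <- res$cycles
    rownames(metrics) <- NULL
    emit(metrics, "sequence_metrics.csv")
    if (!is.null(cycles_all)) {
      rownames(cycles_all) <- NULL
      emit(cycles_all, "cycle_diagnostics.csv")
    }
  }

  traits <- intersect(cfg$traits, names(metrics))
  usable <- metrics[metrics$n_pulses >= 1 & is.finite(metrics$diameter_cm), ]
  sptab <- stage("ontogeny", {
    keep <- traits[vapply(traits, function(tr)
      sum(is.finite(usable[[tr]])) >= 4, logical(1))]
    if (length(keep) < 2L) stop_invalid("fewer than 2 usable traits")
    tab <- species_trait_table(usable, keep, diameter = "diameter_cm",
                               species = "species", families = cfg$families)
    fits <- attr(tab, "fits")
    fit_rows <- do.call(rbind, lapply(names(fits), function(tr)
      cbind(trait = tr, fits[[tr]]$table,
            selected = fits[[tr]]$table$family == fits[[tr]]$best$family)))
    emit(fit_rows, "model_fits.tsv", sep = "\t")
    emit(cbind(species = rownames(tab), tab), "species_traits.csv")
    log_add("ontogeny: ", length(keep), " traits normalized over ",
            nrow(tab), " species")
    tab
  })

  corr <- stage("correlations", {
    cm <- pearson_matrix(sptab)
    emit(data.frame(trait = rownames(cm$r), cm$r, check.names = FALSE),
         "correlations.csv")
    cm
  })

  pca <- stage("pca", {
    complete_traits <- colnames(sptab)[colSums(is.na(sptab)) == 0]
    p <- pca_traits(sptab, standardize = cfg$standardize_pca,
                    columns = complete_traits)
    emit(data.frame(trait = rownames(p$loadings), p$loadings, check.names = FALSE),
         "pca_loadings.csv")
    emit(data.frame(species = rownames(p$scores), p$scores, check.names = FALSE),
         "pca_scores.csv")
    emit(data.frame(component = colnames(p$loadings),
                    explained_fraction = p$explained), "pca_variance.csv")
    log_add(sprintf("pca: PC1 = %.1f%%, PC2 = %.1f%%", 100 * p$explained[1],
                    100 * p$explained[2]))
    p
  })

  physig <- ancestral <- NULL
  if (!is.null(cfg$tree)) {
    tree <- stage("load_tree", {
      tr <- if (inherits(cfg$tree, "phylo")) cfg$tree else read_newick(cfg$tree)
      as_phylo_checked(tr)
    })
    physig <- stage("phylo_signal", {
      tab <- phylo_signal_table(tree, sptab, n_perm = cfg$n_perm, seed = cfg$seed)
      emit(tab, "phylo_signal.tsv", sep = "\t")
      tab
    })
    ancestral <- stage("ancestral_states", {
      common <- intersect(tree$tip.label, rownames(sptab))
      tr <- if (length(common) < length(tree$tip.label))
        prune_to_taxa(tree, common) else tree
      maps <- list()
      rows <- list()
      for (v in colnames(sptab)) {
        x <- stats::setNames(sptab[common, v], common)
        if (anyNA(x)) next
        am <- ancestral_states_ml(tr, x)
        maps[[v]] <- am
        rows[[v]] <- data.frame(variable = v,
                                node = as.integer(names(am$node_states)),
                                state = unname(am$node_states))
      }
      emit(do.call(rbind, rows), "ancestral_states.tsv", sep = "\t")
      maps
    })
  }

  writeLines(log_lines, outfile("log.txt"))
  manifest <- data.frame(file = written,
                         md5 = unname(tools::md5sum(file.path(cfg$output_dir, written))))
  utils::write.csv(manifest, outfile("manifest.csv"), row.names = FALSE)
  invisible(list(metrics = metrics, cycles = cycles_all,
                 species_traits = sptab, correlations = corr, pca = pca,
                 phylo_signal = physig, ancestral = ancestral,
                 manifest = manifest))
}
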