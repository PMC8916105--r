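#' Pipeline run configuration
#'
#' Assembles and checks the settings for [run_pipeline()]. Either
#' `simulate = TRUE` (a synthetic cohort is generated) or paths to a
#' cohort CSV plus lesion-mask maps must be supplied for the stages that
#' need them.
#'
#' @param out_dir output directory (created if absent).
#' @param simulate generate a synthetic cohort (default TRUE).
#' @param sim_params a [simulation_params()] object (when simulating).
#' @param mesh_subdivisions icosphere refinement for the simulated
#'   template.
#' @param n_regions parcels for the simulated parcellation.
#' @param stages character vector of analysis stages to run, any of
#'   `"atlas"`, `"stability"`, `"vertexwise"`, `"spin"`, `"outcome"`,
#'   `"pairwise"`.
#' @param n_perm,n_rotations,cv_folds,min_coverage numeric settings
#'   passed to the respective stages.
#' @param stability_sizes subset sizes for [bootstrap_stability()];
#'   defaults to a spread below `ref_size`.
#' @param ref_size reference subset size for the stability analysis.
#' @param stability_threshold learning-curve stability target.
#' @param seed master RNG seed; stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, simulate = TRUE,
                       sim_params = simulation_params(),
                       mesh_subdivisions = 3, n_regions = 24,
                       stages = c("atlas", "stability", "vertexwise",
                                  "spin", "outcome", "pairwise"),
                       n_perm = 1000, n_rotations = 1000, cv_folds = 10,
                       min_coverage = 5, stability_sizes = NULL,
                       ref_size = NULL, stability_threshold = 0.95,
                       seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!simulate)
    stop("running on external data requires simulate = TRUE in this ",
         "release; read your data with read_cohort_csv()/read_vertex_map()",
         " and call the stage functions directly")
  structure(list(out_dir = out_dir, simulate = simulate,
                 sim_params = sim_params,
                 mesh_subdivisions = mesh_subdivisions,
                 n_regions = n_regions, stages = stages, n_perm = n_perm,
                 n_rotations = n_rotations, cv_folds = cv_folds,
                 min_coverage = min_coverage,
                 stability_sizes = stability_sizes, ref_size = ref_size,
                 stability_threshold = stability_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full lesion-mapping pipeline
#'
#' Executes the enabled stages in dependency order on a (simulated)
#' cohort: lesion features and frequency/likelihood atlas, bootstrap
#' stability with a fitted learning curve, vertexwise permutation
#' inference, spin-test correlation of the onset map against the surrogate
#' cortical axis, patient-level outcome models with cross-validation, and
#' the pairwise association grid. All outputs are written under
#' `config$out_dir` (plain-text vertex maps, CSVs, JSON summaries) along
#' with a JSON run report recording seeds, sizes and verdicts. A fixed
#' config and seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return the run report, invisibly (a list; also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list())
  wpath <- function(...) file.path(config$out_dir, ...)

  mesh <- make_sphere_mesh(config$mesh_subdivisions)
  parc <- make_parcellation(mesh, config$n_regions,
                            seed = config$seed)
  sim <- config$sim_params
  sim$seed <- config$seed
  cohort_masks <- sample_cohort(mesh, parc, sim)
  cohort <- cohort_masks$cohort
  masks <- cohort_masks$masks
  write_cohort_csv(cohort, wpath("cohort.csv"))
  report$n_patients <- nrow(cohort)
  report$n_vertices <- n_vertices(mesh)

  if ("atlas" %in% config$stages) {
    freq <- frequency_map(pool_to_left(masks))
    atlas <- likelihood_atlas(freq)
    write_vertex_map(freq$counts, wpath("frequency_map.txt"))
    write_vertex_map(atlas, wpath("likelihood_atlas.txt"))
    affine <- diag(c(2, 2, 2, 1)); affine[1:3, 4] <- -64
    atlas_to_volume(atlas, mesh$vertex_coords * 50, c(64, 64, 64),
                    affine, path = wpath("likelihood_atlas.nii.gz"))
    report$stages$atlas <- list(max_count = max(freq$counts))
  }
  if ("stability" %in% config$stages) {
    n <- length(masks)
    ref_size <- config$ref_size %||% floor(n / 2)
    sizes <- config$stability_sizes %||%
      unique(pmax(5, floor(ref_size * c(0.1, 0.2, 0.4, 0.7, 1))))
    tab <- bootstrap_stability(masks, sizes, n_reps = 100,
                               ref_size = ref_size,
                               seed = config$seed + 1L)
    lc <- fit_learning_curve(tab, config$stability_threshold)
    write.csv(tab, wpath("stability.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(params = as.list(lc$params), threshold = lc$threshold,
           reachable = lc$reachable, required_n = lc$required_n),
      wpath("learning_curve.json"), auto_unbox = TRUE, digits = NA)
    report$stages$stability <- list(required_n = lc$required_n,
                                    reachable = lc$reachable)
  }
  if ("vertexwise" %in% config$stages) {
    vw <- vertexwise_inference(cohort, masks, factor_spec(),
                               n_perm = config$n_perm,
                               seed = config$seed + 2L,
                               min_coverage = config$min_coverage)
    for (f in vw$fit$factors) {
      fullmap <- rep(NA_real_, n_vertices(mesh))
      fullmap[vw$fit$included_vertices] <- vw$fit$coef[f, ]
      write_vertex_map(fullmap, wpath(paste0("coef_", f, ".txt")))
    }
    write.csv(vw$map_level, wpath("vertexwise_verdicts.csv"),
              row.names = FALSE)
    report$stages$vertexwise <-
      list(n_included = length(vw$fit$included_vertices),
           significant = vw$map_level$factor[vw$map_level$significant])
  }
  if ("spin" %in% config$stages) {
    onset_map <- mean_value_map(cohort, masks, "age_at_onset")
    covered <- !is.na(onset_map$mean)
    filled <- onset_map$mean
    filled[!covered] <- mean(onset_map$mean[covered])
    st <- spin_correlation_test(filled, axis_map(mesh), mesh,
                                n_rotations = config$n_rotations,
                                seed = config$seed + 3L)
    jsonlite::write_json(
      list(r_rank = st$r_rank, p_spin = st$p_spin,
           n_rotations = st$n_rotations, seed = st$seed),
      wpath("spin_test.json"), auto_unbox = TRUE, digits = NA)
    report$stages$spin <- list(r_rank = st$r_rank, p_spin = st$p_spin)
  }
  if ("outcome" %in% config$stages) {
    spec <- outcome_model_spec("presurgical", cv_folds = config$cv_folds)
    fit <- fit_outcome_model(cohort, spec)
    perm <- outcome_permutation_significance(cohort, spec,
                                             n_perm = config$n_perm,
                                             seed = config$seed + 4L)
    cv <- crossvalidate(cohort, spec, seed = config$seed + 5L)
    vx <- vertexwise_outcome_model(cohort, masks,
                                   min_coverage = config$min_coverage)
    write_vertex_map(vx$percent_map$percent,
                     wpath("percent_seizure_free.txt"))
    jsonlite::write_json(
      list(coefficients = as.list(fit$coefficients),
           permutation = perm, cv_metrics = as.list(cv$metrics)),
      wpath("outcome_model.json"), auto_unbox = TRUE, digits = NA)
    report$stages$outcome <- list(cv_metrics = as.list(cv$metrics))
  }
  if ("pairwise" %in% config$stages) {
    vars <- c("sex", "age_at_onset", "age_at_scan", "duration",
              "ever_mri_negative", "scanner", "histopathology",
              "operated", "seizure_free", "lesion_size_pct", "lobe",
              "lesion_hemisphere")
    grid <- pairwise_grid(cohort, vars)
    write.csv(grid, wpath("pairwise_grid.csv"), row.names = FALSE)
    report$stages$pairwise <-
      list(n_pairs = nrow(grid),
           n_significant = sum(grid$fdr_significant))
  }
  jsonlite::write_json(report, wpath("run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
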