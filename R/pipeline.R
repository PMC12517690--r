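#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the standard
#' protocol: row-wise top 10 percent sparsification, diffusion anisotropy
#' `alpha = 0.5`, 1000 surrogates per null distribution, k-means sweep over
#' `k = 2..30`, and 100 split-half iterations. Serializes losslessly to JSON
#' via [jsonlite::toJSON()].
#'
#' @param n_voxels,n_parcels,k,snr,n_subjects,n_timepoints,n_tracers
#'   Synthetic-study dimensions (see [simulate_study()]).
#' @param sparsity Row-wise retained fraction for functional connectomes.
#' @param alpha Diffusion-map density-normalization exponent.
#' @param n_components Gradients computed per embedding.
#' @param n_surrogates Surrogates per null distribution.
#' @param k_range Candidate cluster counts.
#' @param n_iterations Split-half iterations.
#' @param seed Master seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_voxels = 600, n_parcels = 100, k = 2,
                            snr = 10, n_subjects = 10, n_timepoints = 200,
                            n_tracers = 15, sparsity = 0.10, alpha = 0.5,
                            n_components = 5, n_surrogates = 1000,
                            k_range = 2:30, n_iterations = 100, seed = 1) {
  structure(
    list(n_voxels = n_voxels, n_parcels = n_parcels, k = k, snr = snr,
         n_subjects = n_subjects, n_timepoints = n_timepoints,
         n_tracers = n_tracers, sparsity = sparsity, alpha = alpha,
         n_components = n_components, n_surrogates = n_surrogates,
         k_range = as.integer(k_range), n_iterations = n_iterations,
         seed = seed),
    class = c("pipeline_config", "list")
  )
}

#' Simulate a full multimodal gradient study
#'
#' Generates every input the pipeline consumes, with planted ground truth:
#' a bilateral voxel domain with contiguous nuclei, a cortical parcel set
#' with planted cortico-cortical gradients, voxel-to-parcel functional
#' connectivity mirroring those gradients along spatial axes, subject-level
#' BOLD-like time series, overdispersed streamline counts, and receptor
#' density maps loading on the planted axes.
#'
#' @param config A [pipeline_config()] (its synthetic-study fields and seed
#'   are used).
#' @return A list: `domain`, `parcels`, `cortical` (connectome + gradients),
#'   `pulvinar` (connectivity + planted axes), `subject_ts` (list of
#'   voxel/parcel series per subject), `subject_counts`, `receptors`, and
#'   `ground_truth` (`planted_axes`, `planted_cortical_gradients`,
#'   `planted_labels`, `seed`).
#' @export
simulate_study <- function(config = pipeline_config()) {
  cfg <- config
  seed <- cfg$seed
  domain <- make_voxel_domain(cfg$n_voxels, nuclei = 4, voxel_size = 2,
                              seed = seed)
  parcels <- make_parcel_set(cfg$n_parcels, n_networks = 7, seed = seed + 1)
  cort <- plant_cortical_connectivity(parcels, k = cfg$k,
                                      weights = 3 / seq_len(cfg$k),
                                      noise_sd = 0.02, seed = seed + 2)
  axes_dir <- diag(3)[seq_len(cfg$k), , drop = FALSE]
  pulv <- plant_pulvinar_connectivity(domain, parcels,
                                      cort$cortical_gradients, axes_dir,
                                      snr = cfg$snr, seed = seed + 3)
  # feasible correlation targets for the latent-factor series
  target <- pulv$connectivity
  target <- target * (0.9 / sqrt(max(rowSums(target^2))))
  subject_ts <- lapply(seq_len(cfg$n_subjects), function(s) {
    make_timeseries(target, cfg$n_timepoints, noise_sd = 0.1,
                    seed = seed + 100 + s)
  })
  subject_counts <- lapply(seq_len(cfg$n_subjects), function(s) {
    make_structural_counts(pmax(pulv$connectivity, 0), scale = 500,
                           dispersion = 0.2, seed = seed + 200 + s)
  })
  loadings <- with_seed(seed + 300,
                        matrix(rnorm(cfg$n_tracers * cfg$k),
                               cfg$n_tracers, cfg$k))
  receptors <- make_receptor_maps(
    domain, cfg$n_tracers, pulv$planted_axes, loadings,
    noise_sd = sd(pulv$planted_axes %*% t(loadings)) / cfg$snr,
    seed = seed + 301
  )
  list(
    domain = domain, parcels = parcels, cortical = cort, pulvinar = pulv,
    subject_ts = subject_ts, subject_counts = subject_counts,
    receptors = receptors,
    ground_truth = list(
      planted_axes = pulv$planted_axes,
      planted_cortical_gradients = cort$cortical_gradients,
      planted_labels = as.integer(domain$nucleus),
      seed = seed
    )
  )
}

#' Run the full gradient-mapping pipeline on a synthetic study
#'
#' End-to-end composition of the stages in protocol order: feature matrices
#' (functional, structural, coexpression) -> cosine affinities ->
#' diffusion-map gradients -> gradient-weighted cortical projections and
#' cross-modal correlations with SA-corrected p-values -> gradient-space
#' k-means clustering with Dice overlap against the synthetic nuclei ->
#' split-half stability. All tables are written as delimited text with a
#' JSON sidecar carrying the configuration, its hash, and the seed; reruns
#' with an equal configuration produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return A list of stage results (`study`, `features`, `gradients`,
#'   `projection`, `stats`, `clustering`, `reliability`), invisibly
#'   returning paths in `files` when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_study(config)

  # --- features ----------------------------------------------------------
  fc_subj <- lapply(study$subject_ts, function(ts) {
    fisher_z(sparsify(functional_connectome(ts$voxel_ts, ts$parcel_ts),
                      config$sparsity))
  })
  fc_group <- group_average(fc_subj)
  fc_raw_group <- group_average(
    lapply(study$subject_ts,
           function(ts) functional_connectome(ts$voxel_ts, ts$parcel_ts))
  )
  sc_group <- structural_density(study$subject_counts)
  rc <- zscore_columns(study$receptors)

  # --- gradients ---------------------------------------------------------
  grads <- list(
    functional = diffusion_embedding(cosine_affinity(fc_group),
                                     alpha = config$alpha,
                                     n_components = config$n_components,
                                     modality = "functional"),
    structural = diffusion_embedding(cosine_affinity(sc_group),
                                     alpha = config$alpha,
                                     n_components = config$n_components,
                                     modality = "structural"),
    coexpression = diffusion_embedding(cosine_affinity(rc),
                                       alpha = config$alpha,
                                       n_components = config$n_components,
                                       modality = "coexpression")
  )
  n_keep <- vapply(grads, function(g) elbow_select(g$explained_variance),
                   integer(1))

  # --- projections & statistics -----------------------------------------
  gwc <- lapply(seq_len(max(1L, n_keep[["functional"]])), function(j) {
    gradient_weighted_map(fc_raw_group, grads$functional$components[, j])
  })
  cortg <- study$ground_truth$planted_cortical_gradients
  proj_cor <- purrr::map_dfr(seq_along(gwc), function(j) {
    tibble::tibble(
      gradient = j,
      cortical_gradient = seq_len(ncol(cortg)),
      r = vapply(seq_len(ncol(cortg)),
                 function(c) map_correlation(gwc[[j]], cortg[, c]),
                 numeric(1))
    )
  })
  coords <- as.matrix(study$domain[, c("x", "y", "z")])
  xmod <- cross_modal_correlation(grads, coords = coords,
                                  n_surrogates = config$n_surrogates,
                                  seed = config$seed + 7)
  rec_cor <- receptor_correlates(grads$coexpression$components[, 1], rc)

  # --- clustering --------------------------------------------------------
  space <- minmax_concat(grads, selection = pmax(n_keep, 1L))
  sweep_res <- kmeans_sweep(space, k_range = config$k_range,
                            seed = config$seed + 11)
  best <- select_k(sweep_res)
  dice <- dice_overlap(best$labels, study$domain$nucleus)

  # --- reliability -------------------------------------------------------
  stability <- split_half_stability(
    lapply(study$subject_ts,
           function(ts) functional_connectome(ts$voxel_ts, ts$parcel_ts)),
    n_iterations = config$n_iterations,
    config = embed_config(sparsity = config$sparsity, alpha = config$alpha,
                          n_components = min(config$n_components, 3)),
    seed = config$seed + 13
  )

  res <- list(
    study = study,
    features = list(functional = fc_group, functional_raw = fc_raw_group,
                    structural = sc_group, coexpression = rc),
    gradients = grads,
    n_selected = n_keep,
    projection = list(maps = gwc, cortical_correlation = proj_cor,
                      receptor_correlates = rec_cor),
    stats = xmod,
    clustering = list(sweep = sweep_res, best = best, dice = dice),
    reliability = stability
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      gradients_functional = file.path(out_dir, "gradients_functional.csv"),
      gradients_structural = file.path(out_dir, "gradients_structural.csv"),
      gradients_coexpression = file.path(out_dir,
                                         "gradients_coexpression.csv"),
      cross_modal = file.path(out_dir, "cross_modal_correlations.csv"),
      projection = file.path(out_dir, "cortical_projection_correlations.csv"),
      silhouette = file.path(out_dir, "silhouette_curve.csv"),
      clusters = file.path(out_dir, "cluster_labels.csv"),
      dice = file.path(out_dir, "dice_overlap.csv"),
      stability = file.path(out_dir, "split_half_stability.csv"),
      sidecar = file.path(out_dir, "run_config.json")
    )
    for (m in names(grads)) {
      write_matrix_table(grads[[m]]$components,
                         files[[paste0("gradients_", m)]],
                         ids = study$domain$voxel_id)
    }
    readr::write_csv(xmod, files[["cross_modal"]])
    readr::write_csv(proj_cor, files[["projection"]])
    readr::write_csv(
      tibble::tibble(k = vapply(sweep_res, `[[`, integer(1), "k"),
                     silhouette = vapply(sweep_res, `[[`, numeric(1),
                                         "silhouette")),
      files[["silhouette"]]
    )
    readr::write_csv(tibble::tibble(voxel_id = study$domain$voxel_id,
                                    cluster = best$labels),
                     files[["clusters"]])
    readr::write_csv(dice$max_dice, files[["dice"]])
    readr::write_csv(tibble::as_tibble(stability), files[["stability"]])
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA)
    jsonlite::write_json(
      list(config = unclass(config),
           config_hash = rlang::hash(cfg_json),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("pulvigrad"))),
      files[["sidecar"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    res$files <- files
  }
  res
}
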