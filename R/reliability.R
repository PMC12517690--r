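# Shared embedding route used by the reliability analyses: feature matrix ->
# (optional sparsify/Fisher) -> cosine affinity -> diffusion embedding.
embed_features <- function(m, config = embed_config()) {
  fm <- if (inherits(m, "feature_matrix")) m else {
    feature_matrix(m, config$modality %||% "functional", "group_mean")
  }
  if (isTRUE(config$sparsify) && fm_modality(fm) == "functional") {
    fm <- feature_matrix(unclass(fm), fm_modality(fm), "raw",
                         attr(fm, "hemisphere"), colnames(fm))
    fm <- sparsify(fm, config$sparsity)
    fm <- fisher_z(fm)
  }
  a <- cosine_affinity(fm)
  diffusion_embedding(a, alpha = config$alpha,
                      n_components = config$n_components,
                      diffusion_time = config$diffusion_time,
                      modality = fm_modality(fm))
}

#' Embedding configuration for reliability analyses
#'
#' Bundles the processing choices applied before each embedding in
#' [split_half_stability()] and [test_retest()]: whether functional matrices
#' are sparsified and Fisher-transformed, and the diffusion-embedding
#' parameters.
#'
#' @param sparsify Apply row-wise thresholding + Fisher z to functional
#'   matrices (default `TRUE`, the standard functional route).
#' @param sparsity Row-wise retained fraction (default 0.10).
#' @param alpha Diffusion anisotropy exponent (default 0.5).
#' @param n_components Gradients computed per embedding (default 5).
#' @param diffusion_time Diffusion time (default 0).
#' @param modality Modality tag for plain-matrix inputs.
#' @return A named list of class `embed_config`.
#' @export
embed_config <- function(sparsify = TRUE, sparsity = 0.10, alpha = 0.5,
                         n_components = 5, diffusion_time = 0,
                         modality = "functional") {
  structure(list(sparsify = sparsify, sparsity = sparsity, alpha = alpha,
                 n_components = n_components, diffusion_time = diffusion_time,
                 modality = modality),
            class = c("embed_config", "list"))
}

#' Split-half stability of gradients
#'
#' Repeatedly splits the subject list into two disjoint halves, group-
#' averages and embeds each half, Procrustes-aligns the second embedding to
#' the first, and records the per-gradient Pearson correlation. The median
#' and IQR (and the mean) across iterations summarize how stable each
#' gradient is under resampling of the cohort.
#'
#' @param subject_matrices List of subject-level voxel x feature matrices
#'   (>= 4 subjects).
#' @param n_iterations Number of random splits (default 100).
#' @param config An [embed_config()].
#' @param seed Integer seed.
#' @return A `stability_report`: tibble with `gradient`, `median_r`, `iqr_r`,
#'   `mean_r`, plus attributes `n_iterations`, `seed`, and the full
#'   iteration-level correlations in attribute `draws`.
#' @export
split_half_stability <- function(subject_matrices, n_iterations = 100,
                                 config = embed_config(), seed = 1) {
  if (!is.list(subject_matrices) || length(subject_matrices) < 4) {
    abort("at least 4 subject matrices are required.")
  }
  n_iterations <- assert_count(n_iterations, "n_iterations")
  ns <- length(subject_matrices)
  if (ns %% 2 == 1) {
    warn("odd number of subjects: one subject left out of each split")
  }
  half <- ns %/% 2
  draws <- with_seed(seed, {
    purrr::map(seq_len(n_iterations), function(it) {
      idx <- sample.int(ns)
      g1 <- embed_features(group_average(subject_matrices[idx[seq_len(half)]]),
                           config)
      g2 <- embed_features(
        group_average(subject_matrices[idx[half + seq_len(half)]]), config
      )
      g2 <- procrustes_align(g1, g2)
      abs(gradient_correlation(g1, g2))
    })
  })
  dm <- do.call(rbind, draws)
  out <- tibble::tibble(
    gradient = seq_len(ncol(dm)),
    median_r = apply(dm, 2, median),
    iqr_r = apply(dm, 2, IQR),
    mean_r = colMeans(dm)
  )
  class(out) <- c("stability_report", class(out))
  attr(out, "n_iterations") <- n_iterations
  attr(out, "seed") <- seed
  attr(out, "draws") <- dm
  out
}

#' Test-retest gradient similarity
#'
#' Embeds the test and retest dense connectomes, Procrustes-aligns the retest
#' gradients to the test gradients, and reports the per-gradient Pearson
#' correlation.
#'
#' @param test_connectome,retest_connectome Voxel x feature matrices of the
#'   same shape (any modality).
#' @param config An [embed_config()].
#' @return A tibble with `gradient` and `r`.
#' @export
test_retest <- function(test_connectome, retest_connectome,
                        config = embed_config()) {
  if (!all(dim(as.matrix(test_connectome)) ==
             dim(as.matrix(retest_connectome)))) {
    abort("test and retest connectomes must share shape.")
  }
  g1 <- embed_features(test_connectome, config)
  g2 <- embed_features(retest_connectome, config)
  g2 <- procrustes_align(g1, g2)
  tibble::tibble(gradient = seq_len(config$n_components),
                 r = gradient_correlation(g1, g2))
}

#' Association between SNR maps and gradients
#'
#' Spatial correlation of each gradient with a voxel-wise SNR map, with
#' significance from spatial-autocorrelation-preserving surrogates of the
#' SNR map and Benjamini-Hochberg correction across gradients. A strong
#' association would flag a gradient as potentially noise-driven.
#'
#' @param snr An [snr_map()] tibble (undefined voxels are excluded pairwise
#'   with a warning).
#' @param gradients A `gradient_set`.
#' @param d Voxel distance matrix matching the gradient voxels.
#' @param n_surrogates Number of surrogates (default 1000).
#' @param seed Integer seed.
#' @return A tibble with `gradient`, `r`, `p`, `q`.
#' @export
snr_gradient_association <- function(snr, gradients, d,
                                     n_surrogates = 1000, seed = 1) {
  comp <- ref_components(gradients)
  if (nrow(snr) != nrow(comp)) abort("SNR map and gradients share voxels.")
  ok <- snr$defined
  if (!all(ok)) {
    warn(sprintf("%d voxel(s) with undefined SNR excluded pairwise",
                 sum(!ok)))
  }
  vals <- snr$value[ok]
  if (sd(vals) == 0) abort("constant SNR map: correlation undefined.")
  comp <- comp[ok, , drop = FALSE]
  dd <- d[ok, ok, drop = FALSE]
  ens <- generate_surrogates(vals, dd, n_surrogates = n_surrogates,
                             seed = seed)
  res <- purrr::map_dfr(seq_len(ncol(comp)), function(j) {
    t <- sa_permutation_pvalue(vals, comp[, j], ens)
    tibble::tibble(gradient = j, r = t$observed_r, p = t$p)
  })
  res$q <- bh_fdr(res$p)
  res
}
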