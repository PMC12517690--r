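#' Min-max normalize and concatenate gradient components
#'
#' Scales each selected gradient component to \[0, 1\] and binds the columns
#' into the feature space used for gradient-space clustering, optionally
#' pooling components across modalities for combined clustering.
#'
#' @param gradients List of `gradient_set`s (or matrices) over a shared
#'   voxel set.
#' @param selection Integer vector: number of leading components to take
#'   from each set (recycled; defaults to all).
#' @return Voxel x m numeric matrix with columns in \[0, 1\].
#' @export
minmax_concat <- function(gradients, selection = NULL) {
  if (!is.list(gradients)) gradients <- list(gradients)
  mats <- lapply(gradients, ref_components)
  nv <- vapply(mats, nrow, integer(1))
  if (length(unique(nv)) != 1) abort("gradient sets must share voxels.")
  if (is.null(selection)) selection <- vapply(mats, ncol, integer(1))
  selection <- rep_len(selection, length(mats))
  cols <- purrr::map2(mats, selection, function(m, k) {
    k <- min(k, ncol(m))
    apply(m[, seq_len(k), drop = FALSE], 2, minmax)
  })
  out <- do.call(cbind, cols)
  unname(as.matrix(out))
}

#' k-means sweep over gradient space with silhouette scores
#'
#' Runs k-means (Euclidean, best of `n_init` starts by within-cluster sum of
#' squares) for each candidate `k` and records the mean silhouette width of
#' every solution, the model-selection criterion for the number of discrete
#' gradient-space clusters.
#'
#' @param x Voxel x m matrix (typically from [minmax_concat()]).
#' @param k_range Candidate cluster counts (default `2:30`).
#' @param n_init Random starts per k (default 10).
#' @param seed Integer seed.
#' @return A list of `cluster_solution`s: each has `labels`, `k`,
#'   `silhouette`, `seed`.
#' @export
kmeans_sweep <- function(x, k_range = 2:30, n_init = 10, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || max(k_range) >= n) {
    abort("`k_range` must lie in [1, n_voxels - 1].")
  }
  n_init <- assert_count(n_init, "n_init")
  dx <- dist(x)
  with_seed(seed, {
    lapply(k_range, function(k) {
      km <- suppressWarnings(
        kmeans(x, centers = k, nstart = n_init, iter.max = 100)
      )
      sil <- if (k > 1) {
        mean(cluster::silhouette(km$cluster, dx)[, "sil_width"])
      } else NA_real_
      structure(
        list(labels = km$cluster, k = k, silhouette = sil,
             tot_withinss = km$tot.withinss, seed = seed),
        class = "cluster_solution"
      )
    })
  })
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, mean silhouette = %.3f\n",
              x$k, x$silhouette))
  invisible(x)
}

#' Select the clustering with maximum silhouette
#'
#' @param solutions List of `cluster_solution`s from [kmeans_sweep()].
#' @return The solution with maximum mean silhouette; ties break to the
#'   smallest k.
#' @export
select_k <- function(solutions) {
  if (length(solutions) == 0) abort("no candidate solutions.")
  sil <- vapply(solutions, function(s) s$silhouette, numeric(1))
  ks <- vapply(solutions, function(s) as.numeric(s$k), numeric(1))
  if (all(is.na(sil))) return(solutions[[which.min(ks)]])
  best <- max(sil, na.rm = TRUE)
  cand <- which(!is.na(sil) & abs(sil - best) < 1e-12)
  solutions[[cand[which.min(ks[cand])]]]
}

#' Dice overlap between two partitions
#'
#' `Dice(A, B) = 2|A intersect B| / (|A| + |B|)` for every pair of a cluster
#' from `labels_a` and a group (e.g. atlas nucleus) from `labels_b`, plus the
#' maximum Dice across clusters for each group -- the conventional summary of
#' how well any data-driven cluster captures each anatomical nucleus.
#'
#' @param labels_a,labels_b Two labelings of the same voxels.
#' @return A list with `dice` (tibble: `cluster`, `group`, `dice`) and
#'   `max_dice` (tibble: `group`, `dice`, `cluster` achieving it).
#' @export
dice_overlap <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("partitions must label the same voxels.")
  }
  if (length(labels_a) == 0) abort("empty partitions.")
  a <- as.factor(labels_a)
  b <- as.factor(labels_b)
  tab <- table(a, b)
  na <- rowSums(tab)
  nb <- colSums(tab)
  dice <- 2 * tab / outer(na, nb, `+`)
  long <- tibble::tibble(
    cluster = rep(rownames(tab), times = ncol(tab)),
    group = rep(colnames(tab), each = nrow(tab)),
    dice = as.vector(dice)
  )
  max_dice <- long |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$dice, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("group", "dice", "cluster")
  list(dice = long, max_dice = max_dice)
}
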