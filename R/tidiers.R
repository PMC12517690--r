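#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gradient set
#'
#' @param x A `gradient_set`.
#' @param ... Unused.
#' @return A long tibble with `voxel`, `gradient`, `value`.
#' @method tidy gradient_set
#' @export
tidy.gradient_set <- function(x, ...) {
  m <- x$components
  tibble::tibble(
    voxel = rep(seq_len(nrow(m)), times = ncol(m)),
    gradient = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' One-row summary of a gradient set
#'
#' @param x A `gradient_set`.
#' @param ... Unused.
#' @return A tibble with voxel/gradient counts, alpha, leading eigenvalue
#'   and leading explained-variance fraction.
#' @method glance gradient_set
#' @export
glance.gradient_set <- function(x, ...) {
  tibble::tibble(
    n_voxels = nrow(x$components),
    n_gradients = ncol(x$components),
    alpha = x$alpha,
    lambda_1 = x$eigenvalues[1],
    explained_variance_1 = x$explained_variance[1],
    modality = x$modality %||% NA_character_
  )
}

#' Tidy a cluster solution
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return A tibble with `voxel` and `cluster`.
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$labels),
                 cluster = as.integer(x$labels))
}

#' One-row summary of a cluster solution
#'
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @return A tibble with `k`, `silhouette`, `tot_withinss`.
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(k = x$k, silhouette = x$silhouette,
                 tot_withinss = x$tot_withinss)
}

#' Tidy an SA permutation test
#'
#' @param x An `sa_permutation_test`.
#' @param ... Unused.
#' @return A tibble of the null correlations, one row per surrogate.
#' @method tidy sa_permutation_test
#' @export
tidy.sa_permutation_test <- function(x, ...) {
  tibble::tibble(surrogate = seq_along(x$null_rs), null_r = x$null_rs)
}

#' One-row summary of an SA permutation test
#'
#' @param x An `sa_permutation_test`.
#' @param ... Unused.
#' @return A tibble with `observed_r`, `p`, `n_surrogates`.
#' @method glance sa_permutation_test
#' @export
glance.sa_permutation_test <- function(x, ...) {
  tibble::tibble(observed_r = x$observed_r, p = x$p,
                 n_surrogates = length(x$null_rs))
}
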