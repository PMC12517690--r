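#' Gradient-weighted connectivity map
#'
#' Projects a voxel gradient onto the cortex: each parcel's value is the
#' average over voxels of gradient value times voxel-to-parcel connectivity,
#' i.e. the mean dot product of the gradient with the connectivity columns.
#' By default the raw (un-thresholded, pre-Fisher) group connectome is the
#' natural weighting; any stage can be supplied.
#'
#' @param f Voxel x parcel connectivity (`feature_matrix` or matrix).
#' @param g Voxel gradient vector (same voxel index as `f`).
#' @param normalize Min-max normalize the map to \[0, 1\] for display;
#'   statistics should use unnormalized values (default `FALSE`).
#' @return A tibble with `parcel` and `value` (plus attribute `normalized`).
#' @export
gradient_weighted_map <- function(f, g, normalize = FALSE) {
  v <- unclass(as.matrix(f))
  g <- as.numeric(g)
  if (length(g) != nrow(v)) {
    abort("gradient length must equal the number of voxels in `f`.")
  }
  val <- as.numeric(crossprod(v, g)) / length(g)
  if (normalize) val <- minmax(val)
  out <- tibble::tibble(parcel = seq_len(ncol(v)), value = val)
  attr(out, "normalized") <- normalize
  out
}

#' Average left and right gradient-weighted maps
#'
#' Combines hemispheric gradient-weighted maps either elementwise
#' (`mode = "plain"`, appropriate for near-symmetric functional maps) or
#' after re-indexing the right map through a mirror correspondence
#' (`mode = "xflip"`, appropriate for ipsilaterally biased structural maps,
#' mirroring the right-hemisphere projection onto the left).
#'
#' @param left_map,right_map Tibbles from [gradient_weighted_map()].
#' @param mirror Integer vector mapping each parcel to its mirror parcel
#'   (identity by default); used only for `mode = "xflip"`.
#' @param mode `"plain"` or `"xflip"`.
#' @return A tibble with `parcel` and the averaged `value`.
#' @export
hemiflip_average <- function(left_map, right_map, mirror = NULL,
                             mode = c("plain", "xflip")) {
  mode <- match.arg(mode)
  if (nrow(left_map) != nrow(right_map)) {
    abort("left and right maps must cover the same parcels.")
  }
  rv <- right_map$value
  if (mode == "xflip") {
    if (is.null(mirror)) mirror <- seq_len(nrow(right_map))
    if (length(mirror) != nrow(right_map) || anyNA(mirror) ||
        !setequal(mirror, seq_len(nrow(right_map)))) {
      abort("`mirror` must be a permutation covering every parcel.")
    }
    rv <- rv[mirror]
  }
  tibble::tibble(parcel = left_map$parcel,
                 value = (left_map$value + rv) / 2)
}

#' Group values by anatomical or network labels
#'
#' Partitions per-item values (gradient values by nucleus, gradient-weighted
#' connectivity by network) into labelled distributions, optionally min-max
#' normalized across all items first, for violin-style summaries.
#'
#' @param values Numeric vector.
#' @param labels Factor/character labels, same length.
#' @param normalize Min-max normalize values across items first.
#' @return A tibble of class `labeled_summary` with `label` and `value`
#'   columns, one row per item; empty groups are retained as factor levels
#'   with a warning.
#' @export
labeled_summary <- function(values, labels, normalize = FALSE) {
  if (length(values) != length(labels)) {
    abort("`values` and `labels` must have the same length.")
  }
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) {
    warn("empty group(s) retained with no members")
  }
  if (normalize) values <- minmax(values)
  out <- tibble::tibble(label = labels, value = as.numeric(values))
  class(out) <- c("labeled_summary", class(out))
  out
}

#' Pearson correlation between two parcel maps
#'
#' @param a,b Numeric parcel vectors (or tibbles with a `value` column) of
#'   equal length >= 3 and nonzero variance.
#' @return Pearson correlation coefficient.
#' @export
map_correlation <- function(a, b) {
  a <- if (is.data.frame(a)) a$value else as.numeric(a)
  b <- if (is.data.frame(b)) b$value else as.numeric(b)
  if (length(a) != length(b)) abort("maps must have equal length.")
  if (length(a) < 3) abort("at least 3 parcels are required.")
  if (sd(a) == 0 || sd(b) == 0) abort("constant map: correlation undefined.")
  pearson(a, b)
}

#' Rank tracers by correlation with a gradient
#'
#' Correlates a voxel gradient with each z-scored tracer density column and
#' returns the tracers ranked by absolute correlation, by default the five
#' strongest molecular correlates of the gradient.
#'
#' @param g Voxel gradient vector.
#' @param r Voxel x tracer `feature_matrix` (stage `"zscored"`).
#' @param top_n Number of top tracers to return (default 5).
#' @return A tibble with `tracer`, `r`, `rank`, ordered by `|r|` descending.
#' @export
receptor_correlates <- function(g, r, top_n = 5) {
  v <- unclass(as.matrix(r))
  g <- as.numeric(g)
  if (length(g) != nrow(v)) abort("gradient and tracer maps share voxels.")
  top_n <- assert_count(top_n, "top_n")
  sds <- col_sds(v)
  if (any(sds == 0)) {
    warn(sprintf("skipping zero-variance tracer(s): %s",
                 paste(colnames(v)[sds == 0], collapse = ", ")))
    v <- v[, sds > 0, drop = FALSE]
  }
  rs <- as.numeric(cor(g, v))
  ord <- order(abs(rs), decreasing = TRUE)
  tibble::tibble(
    tracer = colnames(v)[ord],
    r = rs[ord],
    rank = seq_along(ord)
  )[seq_len(min(top_n, length(ord))), ]
}

#' Cross-modal gradient correlation matrix
#'
#' All pairwise absolute Pearson correlations between components of gradient
#' sets from different modalities over a common voxel set. Absolute values
#' are reported because gradient sign is indeterminate. Spatial-
#' autocorrelation-corrected p-values can be attached by passing voxel
#' coordinates: surrogates of the first member of each pair feed
#' [sa_permutation_pvalue()].
#'
#' @param gradients Named list of `gradient_set`s over the same voxels.
#' @param coords Optional voxel coordinate matrix; if supplied, SA-corrected
#'   permutational p-values and Benjamini-Hochberg q-values are added.
#' @param n_surrogates Surrogates per null distribution (default 1000).
#' @param seed Seed for surrogate generation.
#' @return A tibble with `modality_a`, `component_a`, `modality_b`,
#'   `component_b`, `abs_r`, and (with `coords`) `p` and `q`.
#' @export
cross_modal_correlation <- function(gradients, coords = NULL,
                                    n_surrogates = 1000, seed = 1) {
  stopifnot(is.list(gradients), length(gradients) >= 2)
  if (is.null(names(gradients))) {
    names(gradients) <- paste0("mod", seq_along(gradients))
  }
  nv <- vapply(gradients, function(g) nrow(ref_components(g)), integer(1))
  if (length(unique(nv)) != 1) abort("gradient sets must share voxels.")

  pairs <- utils::combn(names(gradients), 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    ca <- ref_components(gradients[[pr[1]]])
    cb <- ref_components(gradients[[pr[2]]])
    tidyr::expand_grid(component_a = seq_len(ncol(ca)),
                       component_b = seq_len(ncol(cb))) |>
      dplyr::mutate(
        modality_a = pr[1], modality_b = pr[2],
        abs_r = purrr::map2_dbl(.data$component_a, .data$component_b,
                                function(i, j) abs(pearson(ca[, i],
                                                           cb[, j])))
      )
  })
  rows <- dplyr::select(rows, "modality_a", "component_a",
                        "modality_b", "component_b", "abs_r")
  if (!is.null(coords)) {
    dmat <- distance_matrix(coords)
    cache <- new.env()
    ps <- purrr::pmap_dbl(rows, function(modality_a, component_a,
                                         modality_b, component_b, abs_r) {
      key <- paste(modality_a, component_a, sep = "_")
      x <- ref_components(gradients[[modality_a]])[, component_a]
      if (is.null(cache[[key]])) {
        cache[[key]] <- generate_surrogates(
          x, dmat, n_surrogates = n_surrogates,
          seed = seed + component_a * 131 + match(modality_a,
                                                  names(gradients))
        )
      }
      y <- ref_components(gradients[[modality_b]])[, component_b]
      sa_permutation_pvalue(x, y, cache[[key]])$p
    })
    rows$p <- ps
    rows$q <- bh_fdr(ps)
  }
  rows
}
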