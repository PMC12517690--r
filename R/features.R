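#' Construct a feature matrix
#'
#' Light S3 wrapper around a voxel-by-feature numeric matrix carrying the
#' modality, processing stage and hemisphere tags that downstream stages
#' check. Most users never call this directly; the stage functions
#' ([functional_connectome()], [sparsify()], [fisher_z()], ...) construct and
#' propagate it.
#'
#' @param values Numeric voxel x feature matrix, all values finite.
#' @param modality One of `"functional"`, `"structural"`, `"coexpression"`.
#' @param stage Processing stage tag.
#' @param hemisphere Optional hemisphere tag.
#' @param feature_ids Optional feature identifiers (defaults to column names
#'   or `f1..fP`).
#' @return A `feature_matrix` object (a matrix with metadata attributes).
#' @export
feature_matrix <- function(values,
                           modality = c("functional", "structural",
                                        "coexpression"),
                           stage = c("raw", "thresholded", "fisher_z",
                                     "group_mean", "zscored"),
                           hemisphere = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) abort("feature values must all be finite.")
  modality <- match.arg(modality)
  stage <- match.arg(stage)
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  stopifnot(length(feature_ids) == ncol(values))
  colnames(values) <- feature_ids
  structure(values, class = c("feature_matrix", "matrix", "array"),
            modality = modality, stage = stage, hemisphere = hemisphere)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fm_modality <- function(x) attr(x, "modality")
fm_stage <- function(x) attr(x, "stage")

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d voxels x %d features | modality: %s | stage: %s\n",
              nrow(x), ncol(x), fm_modality(x), fm_stage(x)))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 4))
  invisible(x)
}

#' Voxel-to-parcel functional connectome
#'
#' Pearson correlation of each voxel's time series with each parcel's average
#' time series, giving the raw voxel-by-parcel functional connectivity
#' matrix.
#'
#' @param voxel_ts Voxel x T time-series matrix.
#' @param parcel_ts Parcel x T time-series matrix (same T).
#' @param hemisphere Optional hemisphere tag carried on the result.
#' @return A `feature_matrix` (modality `"functional"`, stage `"raw"`) with
#'   values in \[-1, 1\].
#' @export
functional_connectome <- function(voxel_ts, parcel_ts, hemisphere = NULL) {
  voxel_ts <- as.matrix(voxel_ts)
  parcel_ts <- as.matrix(parcel_ts)
  if (ncol(voxel_ts) != ncol(parcel_ts)) {
    abort("voxel and parcel series must share the time axis.")
  }
  if (ncol(voxel_ts) < 3) abort("at least 3 time points are required.")
  vs <- row_sds(voxel_ts)
  ps <- row_sds(parcel_ts)
  if (any(vs == 0)) {
    abort(sprintf("constant time series for voxel(s): %s",
                  paste(which(vs == 0), collapse = ", ")))
  }
  if (any(ps == 0)) {
    abort(sprintf("constant time series for parcel(s): %s",
                  paste(which(ps == 0), collapse = ", ")))
  }
  r <- cor(t(voxel_ts), t(parcel_ts))
  feature_matrix(r, "functional", "raw", hemisphere,
                 feature_ids = rownames(parcel_ts))
}

#' Row-wise sparsity thresholding of a functional connectome
#'
#' Zeroes negative correlations, then zeroes every value strictly below its
#' row's `100 * (1 - sparsity)` percentile, keeping the top `sparsity`
#' fraction of each voxel's cortical connections (ties at the threshold are
#' kept). The percentile is the linear-interpolation quantile computed on the
#' row after negatives are zeroed.
#'
#' @param m A functional `feature_matrix` (stage `"raw"`).
#' @param sparsity Fraction of connections retained per row, in (0, 1\];
#'   default 0.10 (row-wise top 10 percent).
#' @return A `feature_matrix` at stage `"thresholded"`, values >= 0.
#' @export
sparsify <- function(m, sparsity = 0.10) {
  if (!inherits(m, "feature_matrix") || fm_modality(m) != "functional") {
    abort("`sparsify` applies to functional feature matrices only.")
  }
  if (!is.numeric(sparsity) || length(sparsity) != 1 ||
      is.na(sparsity) || sparsity <= 0 || sparsity > 1) {
    abort("`sparsity` must lie in (0, 1].")
  }
  v <- unclass(m)
  v[v < 0] <- 0
  thr <- apply(v, 1, quantile, probs = 1 - sparsity, names = FALSE)
  v[v < thr] <- 0   # thr recycles down columns: row i compared to thr[i]
  feature_matrix(v, fm_modality(m), "thresholded", attr(m, "hemisphere"),
                 colnames(m))
}

#' Fisher r-to-z transformation
#'
#' Elementwise `atanh`; zeros map to zeros so the sparsity pattern is
#' preserved. Values with `|r| >= 1` are clamped to `1 - 1e-7` in magnitude
#' with a warning, which only arises on degenerate (noise-free synthetic)
#' data.
#'
#' @param m A `feature_matrix` of correlations.
#' @return A `feature_matrix` at stage `"fisher_z"`.
#' @export
fisher_z <- function(m) {
  v <- unclass(as.matrix(m))
  if (any(abs(v) >= 1)) {
    warn("correlations with |r| >= 1 clamped to 1 - 1e-7 before atanh")
    v[v >= 1] <- 1 - 1e-7
    v[v <= -1] <- -(1 - 1e-7)
  }
  z <- atanh(v)
  if (inherits(m, "feature_matrix")) {
    feature_matrix(z, fm_modality(m), "fisher_z", attr(m, "hemisphere"),
                   colnames(m))
  } else z
}

#' Average feature matrices across subjects
#'
#' Elementwise mean of a list of identically shaped subject-level feature
#' matrices, producing the group-level dense connectome.
#'
#' @param ms List of `feature_matrix` objects (or plain matrices) with
#'   identical shape.
#' @return A `feature_matrix` at stage `"group_mean"`.
#' @export
group_average <- function(ms) {
  if (!is.list(ms) || length(ms) == 0) abort("`ms` must be a nonempty list.")
  dims <- vapply(ms, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all subject matrices must share the same shape.")
  }
  first <- ms[[1]]
  avg <- Reduce(`+`, lapply(ms, function(m) unclass(as.matrix(m)))) /
    length(ms)
  modality <- if (inherits(first, "feature_matrix")) fm_modality(first)
              else "functional"
  feature_matrix(avg, modality, "group_mean", attr(first, "hemisphere"),
                 colnames(as.matrix(first)))
}

#' Group-level tract-density matrix
#'
#' Elementwise mean of subject-level nonnegative streamline-count matrices.
#' Structural matrices are neither thresholded nor Fisher-transformed; those
#' steps apply to functional correlations only.
#'
#' @param counts List of voxel x parcel count matrices, all nonnegative.
#' @return A `feature_matrix` (modality `"structural"`, stage
#'   `"group_mean"`).
#' @export
structural_density <- function(counts) {
  if (!is.list(counts) || length(counts) == 0) {
    abort("`counts` must be a nonempty list.")
  }
  if (any(vapply(counts, function(m) any(m < 0), logical(1)))) {
    abort("streamline counts must be nonnegative.")
  }
  m <- group_average(lapply(counts, as.matrix))
  feature_matrix(unclass(m), "structural", "group_mean", NULL, colnames(m))
}

#' Column-wise z-scoring of receptor density maps
#'
#' Standardizes each tracer column to mean 0, sample sd 1 over the supplied
#' mask voxels (by default all rows), producing the coexpression matrix fed
#' to the molecular-gradient embedding.
#'
#' @param m Voxel x tracer matrix.
#' @param mask Optional logical/integer index of rows defining the analysis
#'   mask; statistics and output rows are restricted to it.
#' @return A `feature_matrix` (modality `"coexpression"`, stage `"zscored"`).
#' @export
zscore_columns <- function(m, mask = NULL) {
  v <- unclass(as.matrix(m))
  if (!is.null(mask)) v <- v[mask, , drop = FALSE]
  sds <- col_sds(v)
  if (any(sds == 0)) {
    bad <- colnames(v)[sds == 0] %||% which(sds == 0)
    abort(sprintf("zero-variance tracer column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  z <- scale(v)   # sample-sd convention
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  feature_matrix(z, "coexpression", "zscored", NULL, colnames(v))
}

#' Voxel-wise signal-to-noise ratio map
#'
#' Per-voxel mean divided by sample standard deviation along the series axis:
#' the temporal SNR for BOLD series (`kind = "tsnr"`) or the b0-volume SNR
#' for diffusion data (`kind = "b0_snr"`). Voxels with zero standard
#' deviation are flagged undefined (`NA` value, `defined = FALSE`), never
#' silently zeroed.
#'
#' @param series Voxel x n matrix of signal values (n >= 2 volumes).
#' @param kind `"tsnr"` or `"b0_snr"` (tag only; same formula).
#' @return A tibble with `voxel`, `value`, `defined`, and a `kind` attribute.
#' @export
snr_map <- function(series, kind = c("tsnr", "b0_snr")) {
  kind <- match.arg(kind)
  series <- as.matrix(series)
  if (ncol(series) < 2) abort("at least 2 volumes are required.")
  mu <- rowMeans(series)
  s <- row_sds(series)
  out <- tibble::tibble(
    voxel = seq_len(nrow(series)),
    value = ifelse(s > 0, mu / s, NA_real_),
    defined = s > 0
  )
  attr(out, "kind") <- kind
  out
}
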