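#' Pairwise Euclidean distance matrix
#'
#' @param coords n x d coordinate matrix (millimetres) or a data frame with
#'   `x`, `y`, `z` columns.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
distance_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    cols <- intersect(c("x", "y", "z"), names(coords))
    coords <- as.matrix(coords[, cols])
  }
  as.matrix(dist(as.matrix(coords)))
}

# Precompute pair indices, bins and bin centres for fast repeated variogram
# evaluation on a fixed distance matrix.
vario_setup <- function(d, n_bins = 25, max_frac = 0.5) {
  n <- nrow(d)
  if (n < 2) abort("at least 2 points are required.")
  ut <- which(upper.tri(d))
  pd <- d[ut]
  cutoff <- max_frac * max(pd)
  keep <- pd <= cutoff & pd > 0
  ut <- ut[keep]
  pd <- pd[keep]
  if (length(pd) == 0) abort("no pairs within the distance cutoff.")
  breaks <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(pd, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, n_bins)
  empty <- counts == 0
  if (any(empty)) {
    warn(sprintf("%d empty variogram bin(s) merged with neighbours",
                 sum(empty)))
  }
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  # sort pairs by bin once so per-map bin sums are a single cumsum pass
  ord <- order(bin)
  i <- i[ord]
  j <- j[ord]
  pd <- pd[ord]
  nz <- counts[counts > 0]
  bounds <- cumsum(nz)
  sums_d <- cumsum(pd)[bounds]
  centres <- diff(c(0, sums_d)) / nz
  list(i = i, j = j, counts = nz, bounds = bounds, centres = centres,
       bins_used = which(counts > 0), cutoff = cutoff)
}

vario_gamma <- function(y, setup) {
  cs <- cumsum((y[setup$i] - y[setup$j])^2)[setup$bounds]
  0.5 * diff(c(0, cs)) / setup$counts
}

#' Empirical variogram of a spatial map
#'
#' Half the mean squared difference between values of pairs falling in each
#' distance bin: `gamma(h) = 0.5 * mean((y_i - y_j)^2)` over pairs with
#' distance in bin `h`. Pairs beyond `max_frac` of the maximum pairwise
#' distance are excluded; empty bins are merged with neighbours with a
#' warning.
#'
#' @param y Numeric map of length n.
#' @param d n x n distance matrix (see [distance_matrix()]).
#' @param n_bins Number of equal-width distance bins (default 25).
#' @param max_frac Fraction of the maximum distance to use (default 0.5).
#' @return A tibble with `lag` (mean pair distance per bin), `gamma`, and
#'   `n_pairs`.
#' @export
empirical_variogram <- function(y, d, n_bins = 25, max_frac = 0.5) {
  y <- as.numeric(y)
  if (length(y) < 10) abort("at least 10 points are required.")
  if (length(y) != nrow(d)) abort("`y` and `d` must match in size.")
  su <- vario_setup(d, n_bins, max_frac)
  tibble::tibble(lag = su$centres, gamma = vario_gamma(y, su),
                 n_pairs = su$counts)
}

#' Variogram-matched spatially autocorrelated surrogate maps
#'
#' Generates permutation nulls that preserve the spatial autocorrelation of
#' the input map. Each surrogate starts as a random permutation of `y`,
#' is smoothed with a Gaussian distance-decaying kernel over the `knn`
#' nearest neighbours at each of several candidate bandwidths, and the
#' affine recombination of smoothed map and white noise whose variogram best
#' matches the target variogram (least squares over bins) is kept. With
#' `resample = TRUE` the original values are rank-mapped onto the surrogate,
#' so every order statistic of `y` is preserved exactly.
#'
#' @param y Numeric map of length n (n >= 20).
#' @param d n x n Euclidean distance matrix.
#' @param n_surrogates Number of surrogate maps (default 1000).
#' @param bandwidths Candidate kernel bandwidths in distance units; default
#'   8 values log-spaced over the variogram bin range.
#' @param resample Rank-map original values onto each surrogate (default
#'   `TRUE`).
#' @param seed Integer seed.
#' @param n_bins,max_frac Variogram binning (see [empirical_variogram()]).
#' @param knn Neighbourhood size for kernel smoothing (default
#'   `min(n - 1, 100)`).
#' @return A `surrogate_ensemble`: list with `maps`
#'   (n_surrogates x n), `resampled`, `seed`, `variogram_fit` (per-surrogate
#'   SSE of the matched variogram), and `params`.
#' @export
generate_surrogates <- function(y, d, n_surrogates = 1000,
                                bandwidths = NULL, resample = TRUE,
                                seed = 1, n_bins = 25, max_frac = 0.5,
                                knn = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 20) abort("at least 20 points are required.")
  if (n != nrow(d)) abort("`y` and `d` must match in size.")
  offdiag <- d[upper.tri(d)]
  if (max(offdiag) - min(offdiag) < 1e-12) {
    abort("degenerate distance matrix: all pairwise distances equal.")
  }
  n_surrogates <- assert_count(n_surrogates, "n_surrogates")
  if (is.null(knn)) knn <- min(n - 1L, 100L)
  knn <- min(assert_count(knn, "knn"), n - 1L)

  su <- vario_setup(d, n_bins, max_frac)
  gamma_t <- vario_gamma(y, su)

  if (is.null(bandwidths)) {
    bandwidths <- exp(seq(log(su$cutoff / n_bins), log(su$cutoff),
                          length.out = 8))
  }

  # k-nearest-neighbour index and per-bandwidth smoothing operators; the
  # Gaussian kernel over each voxel's knn neighbourhood is a linear map, so
  # all surrogates are smoothed with one matrix product per bandwidth
  nn_idx <- matrix(0L, n, knn)
  nn_d <- matrix(0, n, knn)
  for (v in seq_len(n)) {
    ord <- order(d[v, ])[-1][seq_len(knn)]
    nn_idx[v, ] <- ord
    nn_d[v, ] <- d[v, ord]
  }
  kernels <- lapply(bandwidths, function(b) {
    w <- exp(-nn_d^2 / (2 * b^2))
    w <- w / rowSums(w)
    k_op <- matrix(0, n, n)
    k_op[cbind(rep(seq_len(n), knn), as.vector(nn_idx))] <- as.vector(w)
    k_op
  })

  ys <- sort(y)
  with_seed(seed, {
    perms <- matrix(0, n_surrogates, n)
    for (s in seq_len(n_surrogates)) perms[s, ] <- y[sample.int(n)]
    smooth_all <- lapply(kernels, function(k_op) tcrossprod(perms, k_op))
    maps <- matrix(0, n_surrogates, n)
    fit_sse <- numeric(n_surrogates)
    for (s in seq_len(n_surrogates)) {
      best <- NULL
      for (b in seq_along(kernels)) {
        sm <- smooth_all[[b]][s, ]
        g_sm <- vario_gamma(sm, su)
        # gamma of a*sm + b*white = a^2 gamma_sm + b^2; nonneg least squares
        xm <- cbind(g_sm, 1)
        beta <- tryCatch(qr.solve(xm, gamma_t), error = function(e) c(0, 0))
        beta <- pmax(beta, 0)
        sse <- sum((gamma_t - xm %*% beta)^2)
        if (is.null(best) || sse < best$sse) {
          best <- list(sse = sse, sm = sm, beta = beta)
        }
      }
      surr <- sqrt(best$beta[1]) * (best$sm - mean(best$sm)) +
        sqrt(best$beta[2]) * rnorm(n)
      if (resample) {
        surr <- ys[rank(surr, ties.method = "first")]
      }
      maps[s, ] <- surr
      fit_sse[s] <- best$sse
    }
    structure(
      list(maps = maps, resampled = resample, seed = seed,
           variogram_fit = fit_sse,
           params = list(n_bins = n_bins, max_frac = max_frac,
                         bandwidths = bandwidths, knn = knn)),
      class = "surrogate_ensemble"
    )
  })
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "<surrogate_ensemble> %d surrogates x %d locations (resampled: %s)\n",
    nrow(x$maps), ncol(x$maps), x$resampled
  ))
  invisible(x)
}

#' SA-corrected permutational correlation test
#'
#' Tests the spatial correlation between maps `x` and `y` against the null
#' distribution of correlations between `y` and spatial-autocorrelation-
#' preserving surrogates of `x`. Two-sided on `|r|` (gradient signs are
#' indeterminate), with the add-one permutation p-value, so `p` is never 0
#' and never below `1 / (n_surrogates + 1)`.
#'
#' @param x Map from which the surrogates were built.
#' @param y Map tested against it (same locations).
#' @param surrogates A `surrogate_ensemble` built from `x`.
#' @return An `sa_permutation_test` list: `observed_r`, `null_rs`, `p`.
#' @export
sa_permutation_pvalue <- function(x, y, surrogates) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!inherits(surrogates, "surrogate_ensemble")) {
    abort("`surrogates` must be a surrogate_ensemble.")
  }
  if (length(x) != length(y) || length(y) != ncol(surrogates$maps)) {
    abort("`x`, `y` and the surrogate maps must share locations.")
  }
  observed <- pearson(x, y)
  null_rs <- as.numeric(cor(t(surrogates$maps), y))
  p <- (sum(abs(null_rs) >= abs(observed)) + 1) / (length(null_rs) + 1)
  structure(list(observed_r = observed, null_rs = null_rs, p = p),
            class = "sa_permutation_test")
}

#' @export
print.sa_permutation_test <- function(x, ...) {
  cat(sprintf("<sa_permutation_test> r = %.3f, p = %.4g (%d surrogates)\n",
              x$observed_r, x$p, length(x$null_rs)))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values, monotone in sorted order and capped at 1.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}
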