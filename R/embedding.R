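#' Cosine-similarity affinity matrix
#'
#' Converts a voxel-by-feature matrix to the symmetric voxel-by-voxel
#' affinity `1 - cosine distance` (i.e. the cosine similarity of feature
#' rows). Negative similarities -- possible when features are z-scored
#' receptor densities -- are rectified to 0 so the result is a valid
#' nonnegative affinity for the diffusion operator; the diagonal is exactly
#' 1.
#'
#' @param f Voxel x feature matrix (or `feature_matrix`); no all-zero rows.
#' @param rectify Set negative similarities to 0 (default `TRUE`).
#' @return An `affinity_matrix`: symmetric matrix, values in \[0, 1\],
#'   unit diagonal.
#' @export
cosine_affinity <- function(f, rectify = TRUE) {
  v <- unclass(as.matrix(f))
  norms <- sqrt(rowSums(v^2))
  if (any(norms == 0)) {
    abort(sprintf("all-zero feature row(s) for voxel(s): %s",
                  paste(which(norms == 0), collapse = ", ")))
  }
  u <- v / norms
  a <- tcrossprod(u)
  if (rectify) a[a < 0] <- 0
  a <- (a + t(a)) / 2
  diag(a) <- 1
  structure(a, class = c("affinity_matrix", "matrix", "array"),
            kernel = "cosine")
}

# connected components of the graph induced by A > 0 (simple BFS)
graph_components <- function(a) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- which(colSums(a[frontier, , drop = FALSE] > 0) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Anisotropic diffusion-map embedding
#'
#' Computes connectopic gradients from a nonnegative symmetric affinity
#' matrix via the anisotropic diffusion operator. With density-normalization
#' exponent `alpha` (default 0.5, robust to sampling-density noise), degrees
#' `q_i = sum_j A_ij` give the kernel `A_ij / (q_i^alpha q_j^alpha)`; the
#' row-stochastic Markov matrix built from it is diagonalized through its
#' symmetric conjugate. The trivial constant eigenvector (eigenvalue 1) is
#' dropped; component k is scaled by `lambda_k / (1 - lambda_k)` when
#' `diffusion_time = 0` and by `lambda_k^t` otherwise. Explained variance is
#' each retained eigenvalue over the sum of all positive non-trivial
#' eigenvalues.
#'
#' @param a An `affinity_matrix` (or symmetric nonnegative matrix) whose
#'   induced graph is connected.
#' @param alpha Density-normalization exponent in \[0, 1\].
#' @param n_components Number of non-trivial gradients to return.
#' @param diffusion_time Diffusion time `t`; 0 selects the
#'   `lambda / (1 - lambda)` multiscale scaling.
#' @param modality,hemisphere Optional tags carried on the result.
#' @return A `gradient_set`: list with `components` (voxel x k),
#'   `eigenvalues`, `explained_variance`, `alpha`, `diffusion_time`,
#'   `modality`, `hemisphere`.
#' @export
diffusion_embedding <- function(a, alpha = 0.5, n_components = 10,
                                diffusion_time = 0, modality = NULL,
                                hemisphere = NULL) {
  a <- unclass(as.matrix(a))
  n <- nrow(a)
  if (n != ncol(a) || max(abs(a - t(a))) > 1e-8) {
    abort("affinity must be a symmetric square matrix.")
  }
  if (any(a < 0)) abort("affinity must be nonnegative.")
  n_components <- assert_count(n_components, "n_components")
  if (n_components >= n) abort("`n_components` must be smaller than n.")
  comp <- graph_components(a)
  if (max(comp) > 1) {
    sizes <- table(comp)
    abort(sprintf(
      "affinity graph is disconnected: %d components of sizes %s",
      max(comp), paste(sizes, collapse = ", ")
    ))
  }

  q <- rowSums(a)
  w <- a / outer(q^alpha, q^alpha)
  d <- rowSums(w)
  s <- w / sqrt(outer(d, d))           # symmetric conjugate of the Markov op
  e <- eigen(s, symmetric = TRUE)
  lambda <- e$values
  psi <- e$vectors / sqrt(d)           # right eigenvectors of the Markov op

  ord <- order(lambda, decreasing = TRUE)
  lambda <- lambda[ord]
  psi <- psi[, ord, drop = FALSE]
  # normalize against the stationary trivial eigenvector so psi_0 == 1
  psi <- psi / psi[, 1]

  lam_nt <- lambda[-1]
  if (max(abs(lam_nt)) < 1e-12) {
    warn("degenerate embedding: all non-trivial eigenvalues are ~0")
  }
  keep <- seq_len(n_components) + 1L
  scaling <- if (diffusion_time == 0) {
    lambda[keep] / (1 - lambda[keep])
  } else {
    lambda[keep]^diffusion_time
  }
  comp_mat <- psi[, keep, drop = FALSE] * rep(scaling, each = n)
  # deterministic sign convention: first non-negligible loading positive
  for (j in seq_len(ncol(comp_mat))) {
    nz <- which(abs(comp_mat[, j]) > 1e-10)
    if (length(nz) > 0 && comp_mat[nz[1], j] < 0) {
      comp_mat[, j] <- -comp_mat[, j]
    }
  }
  pos <- lam_nt[lam_nt > 0]
  ev <- lambda[keep] / sum(pos)

  new_gradient_set(
    components = unname(comp_mat),
    eigenvalues = lambda[keep],
    explained_variance = ev,
    alpha = alpha, diffusion_time = diffusion_time,
    modality = modality, hemisphere = hemisphere
  )
}

new_gradient_set <- function(components, eigenvalues, explained_variance,
                             alpha = NA_real_, diffusion_time = 0,
                             modality = NULL, hemisphere = NULL) {
  structure(
    list(components = as.matrix(components),
         eigenvalues = as.numeric(eigenvalues),
         explained_variance = as.numeric(explained_variance),
         alpha = alpha, diffusion_time = diffusion_time,
         modality = modality, hemisphere = hemisphere),
    class = "gradient_set"
  )
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf(
    "<gradient_set> %d voxels x %d gradients (alpha = %s%s)\n",
    nrow(x$components), ncol(x$components), format(x$alpha),
    if (!is.null(x$modality)) paste0(", ", x$modality) else ""
  ))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "),
      "\n")
  invisible(x)
}

#' Select the number of gradients from a scree of explained variance
#'
#' Automated elbow rule: on the cumulative explained-variance curve, returns
#' the index with maximum distance to the chord joining the first and last
#' points -- the point where adding further gradients stops paying. With
#' fewer than 3 values all components are kept; an exactly straight
#' (degenerate) scree returns 1 with a warning.
#'
#' @param explained_variance Descending positive fractions.
#' @return Integer count of gradients to retain (always >= 1).
#' @export
elbow_select <- function(explained_variance) {
  ev <- as.numeric(explained_variance)
  k <- length(ev)
  if (k == 0) abort("empty explained-variance vector.")
  if (any(ev <= 0)) abort("`explained_variance` must be positive.")
  if (any(diff(ev) > 1e-12)) {
    abort("`explained_variance` must be non-increasing.")
  }
  if (k < 3) return(k)
  cum <- cumsum(ev)
  xs <- (seq_len(k) - 1) / (k - 1)
  ys <- (cum - cum[1]) / if (cum[k] > cum[1]) (cum[k] - cum[1]) else 1
  dist_chord <- ys - xs                 # signed vertical gap to the chord
  if (max(abs(dist_chord)) < 1e-12) {
    warn("degenerate scree: explained variance decreases linearly; keeping 1")
    return(1L)
  }
  as.integer(which.max(dist_chord))
}

#' Align gradient signs to a reference
#'
#' Gradients are defined up to sign. Flips each target component whose
#' Pearson correlation with the corresponding reference component is
#' negative, e.g. to align right-hemisphere gradients with their
#' left-hemisphere counterparts through a voxel correspondence.
#'
#' @param reference,target `gradient_set`s with matching component counts
#'   over corresponding voxels.
#' @return The target `gradient_set` with sign-aligned components.
#' @export
align_signs <- function(reference, target) {
  rc <- ref_components(reference)
  tc <- ref_components(target)
  if (ncol(rc) != ncol(tc) || nrow(rc) != nrow(tc)) {
    abort("reference and target gradients must have matching shape.")
  }
  if (any(col_sds(tc) == 0) || any(col_sds(rc) == 0)) {
    abort("zero-variance gradient component.")
  }
  flips <- vapply(seq_len(ncol(tc)),
                  function(j) sign(cor(rc[, j], tc[, j])), numeric(1))
  flips[flips == 0] <- 1
  set_components(target, sweep(tc, 2, flips, `*`))
}

ref_components <- function(x) {
  if (inherits(x, "gradient_set")) x$components else as.matrix(x)
}

set_components <- function(x, m) {
  if (inherits(x, "gradient_set")) {
    x$components <- m
    x
  } else m
}

#' Procrustes alignment of gradient sets
#'
#' Finds the orthogonal transform (rotation/reflection, no scaling) that best
#' maps the target components onto the reference in least squares, resolving
#' the rotational and sign indeterminacy of separately computed embeddings
#' before they are correlated.
#'
#' @param reference,target `gradient_set`s (or matrices) over the same
#'   voxels with the same number of components.
#' @return The target with components replaced by their aligned version; the
#'   transform is stored in the `rotation` attribute.
#' @export
procrustes_align <- function(reference, target) {
  rc <- ref_components(reference)
  tc <- ref_components(target)
  if (!all(dim(rc) == dim(tc))) {
    abort("reference and target must share voxels and component count.")
  }
  m <- crossprod(tc, rc)
  sv <- svd(m)
  if (min(sv$d) < 1e-12 * max(sv$d)) {
    warn("rank-deficient target: Procrustes transform is not unique")
  }
  rot <- sv$u %*% t(sv$v)
  out <- set_components(target, tc %*% rot)
  attr(out, "rotation") <- rot
  out
}

#' Per-component correlation between two gradient sets
#'
#' @param a,b `gradient_set`s or matrices over the same voxels.
#' @return Numeric vector of Pearson correlations, one per component.
#' @export
gradient_correlation <- function(a, b) {
  ma <- ref_components(a)
  mb <- ref_components(b)
  vapply(seq_len(ncol(ma)), function(j) pearson(ma[, j], mb[, j]),
         numeric(1))
}
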