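#' Build a synthetic bilateral voxel domain
#'
#' Constructs an ellipsoidal blob of voxel centres per hemisphere, mirrored
#' across the mid-sagittal plane (x -> -x), and partitions each blob into
#' spatially contiguous nucleus labels. The blob is a stand-in for a
#' subcortical mask such as the pulvinar: it has realistic millimetric
#' coordinates and contiguous anatomical subdivisions, but no real anatomy.
#'
#' @param n_voxels_target Approximate total number of voxels across both
#'   hemispheres. Each hemisphere receives `floor(n/2)` voxels (the exact
#'   count); `n_voxels_target = 1` yields a single left-hemisphere voxel.
#' @param nuclei Number of contiguous nucleus labels per hemisphere.
#' @param voxel_size Isotropic voxel edge length in millimetres.
#' @param seed Integer seed; the function is deterministic given its inputs.
#'
#' @return A tibble with one row per voxel: `voxel_id`, `x`, `y`, `z`
#'   (millimetres, voxel centres), `hemisphere` (`"left"`/`"right"`) and
#'   `nucleus` (factor). The voxel size is stored in the `voxel_size`
#'   attribute.
#' @export
#' @examples
#' dom <- make_voxel_domain(200, nuclei = 4, voxel_size = 2, seed = 1)
#' dplyr::count(dom, hemisphere, nucleus)
make_voxel_domain <- function(n_voxels_target, nuclei = 4, voxel_size = 2,
                              seed = 1) {
  n_voxels_target <- assert_count(n_voxels_target, "n_voxels_target")
  nuclei <- assert_count(nuclei, "nuclei")
  voxel_size <- assert_scalar(voxel_size, "voxel_size", 0, strict = TRUE)
  if (nuclei > n_voxels_target) {
    abort("`nuclei` cannot exceed `n_voxels_target`.")
  }

  n_half <- max(1L, n_voxels_target %/% 2L)
  if (n_voxels_target == 1L) n_half <- 1L

  with_seed(seed, {
    # grid large enough to contain an ellipsoid of n_half voxels
    semi <- c(1, 1.4, 0.9)                       # pulvinar-like aspect ratio
    r <- (3 * n_half * voxel_size^3 / (4 * pi * prod(semi)))^(1 / 3)
    half_extent <- ceiling(1.6 * r * max(semi) / voxel_size) + 1L
    ax <- seq(-half_extent, half_extent) * voxel_size
    grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    # take exactly n_half grid points closest to the ellipsoid centre
    en <- sqrt((grid[, 1] / semi[1])^2 + (grid[, 2] / semi[2])^2 +
                 (grid[, 3] / semi[3])^2)
    left <- grid[order(en)[seq_len(n_half)], , drop = FALSE]
    # place left blob lateral to the midline, then mirror
    offset <- max(abs(left[, 1])) + voxel_size * 2
    left[, 1] <- left[, 1] - offset
    left <- left + matrix(rep(c(0, -25, 8), each = n_half), ncol = 3)

    # contiguous nucleus partition: Voronoi cells of k-means centroids
    km <- suppressWarnings(
      kmeans(left, centers = min(nuclei, n_half), nstart = 5, iter.max = 50)
    )
    lab <- km$cluster

    nuc_names <- c("MED", "LAT", "ANT", "INF",
                   paste0("N", seq_len(max(0, nuclei - 4)) + 4L))
    nuc_names <- nuc_names[seq_len(nuclei)]

    mirror <- n_voxels_target > 1L
    coords <- left
    hemi <- rep("left", n_half)
    labels <- lab
    if (mirror) {
      right <- left
      right[, 1] <- -right[, 1]
      coords <- rbind(left, right)
      hemi <- c(hemi, rep("right", n_half))
      labels <- c(lab, lab)
    }

    out <- tibble::tibble(
      voxel_id = seq_len(nrow(coords)),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      hemisphere = factor(hemi, levels = c("left", "right")),
      nucleus = factor(nuc_names[labels], levels = nuc_names)
    )
    attr(out, "voxel_size") <- voxel_size
    out
  })
}

#' Build a synthetic cortical parcel set
#'
#' Samples parcel centroids on a sphere-like cortical shell and assigns each
#' parcel to one of `n_networks` intrinsic-connectivity networks defined as
#' contiguous angular sectors, mimicking a 400-area cortical parcellation
#' with a 7-network assignment.
#'
#' @param n_parcels Number of parcels.
#' @param n_networks Number of network labels (each guaranteed nonempty).
#' @param seed Integer seed.
#' @return A tibble with `parcel_id`, centroid `x`, `y`, `z` (mm),
#'   `hemisphere` and `network` (factor).
#' @export
make_parcel_set <- function(n_parcels = 100, n_networks = 7, seed = 1) {
  n_parcels <- assert_count(n_parcels, "n_parcels")
  n_networks <- assert_count(n_networks, "n_networks")
  if (n_networks > n_parcels) abort("`n_networks` cannot exceed `n_parcels`.")

  with_seed(seed, {
    # Fibonacci lattice + jitter: quasi-uniform shell coverage
    i <- seq_len(n_parcels) - 0.5
    phi <- acos(1 - 2 * i / n_parcels)
    theta <- pi * (1 + sqrt(5)) * i + rnorm(n_parcels, sd = 0.05)
    radius <- 70 + rnorm(n_parcels, sd = 2)
    xyz <- cbind(
      x = radius * sin(phi) * cos(theta),
      y = radius * sin(phi) * sin(theta),
      z = radius * cos(phi) * 0.8 + 20
    )
    net_names <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic",
                   "Cont", "Default",
                   paste0("Net", seq_len(max(0, n_networks - 7)) + 7L))
    net_names <- net_names[seq_len(n_networks)]
    # contiguous angular sectors with balanced, nonempty membership
    azimuth <- atan2(xyz[, "y"], xyz[, "x"])
    sector <- ceiling(rank(azimuth, ties.method = "first") *
                        n_networks / n_parcels)

    tibble::tibble(
      parcel_id = seq_len(n_parcels),
      x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"],
      hemisphere = factor(ifelse(xyz[, "x"] < 0, "left", "right"),
                          levels = c("left", "right")),
      network = factor(net_names[sector], levels = net_names)
    )
  })
}

# smooth orthonormal parcel/voxel functions: low-order polynomials of the
# coordinates, centred and Gram-Schmidt-orthonormalized
smooth_basis <- function(coords, k) {
  x <- scale(coords[, 1]); y <- scale(coords[, 2]); z <- scale(coords[, 3])
  raw <- cbind(x, y, z, x * y, x * z, y * z, x^2 - y^2, 2 * z^2 - x^2 - y^2,
               x * y * z, x^3)
  if (k > ncol(raw)) abort(sprintf("at most %d planted axes supported",
                                   ncol(raw)))
  gram_schmidt(raw[, seq_len(k), drop = FALSE])
}

#' Plant a cortico-cortical connectivity matrix with known gradients
#'
#' Builds `k` smooth orthonormal functions of the parcel centroids and returns
#' the low-rank symmetric connectome `C = sum_j w_j g_j g_j' + noise` with
#' unit diagonal, together with the planted cortical gradients, so that
#' embedding `C` has a known spectral target.
#'
#' @param parcels A parcel set from [make_parcel_set()].
#' @param k Number of planted gradients (`k < n_parcels`).
#' @param weights Strictly decreasing positive weights, length `k`.
#' @param noise_sd Standard deviation of the symmetric Gaussian noise.
#' @param seed Integer seed.
#' @return A list with `connectome` (parcel x parcel, symmetric, unit
#'   diagonal) and `cortical_gradients` (parcel x k orthonormal columns).
#' @export
plant_cortical_connectivity <- function(parcels, k = 2,
                                        weights = 3 / seq_len(k),
                                        noise_sd = 0, seed = 1) {
  k <- assert_count(k, "k")
  p <- nrow(parcels)
  if (k >= p) abort("`k` must be smaller than the number of parcels.")
  if (length(weights) != k || any(weights <= 0) ||
      (k > 1 && any(diff(weights) >= 0))) {
    abort("`weights` must be strictly decreasing and positive.")
  }
  noise_sd <- assert_scalar(noise_sd, "noise_sd", 0)

  g <- smooth_basis(as.matrix(parcels[, c("x", "y", "z")]), k)
  C <- g %*% (weights * t(g))
  if (noise_sd > 0) {
    e <- with_seed(seed, matrix(rnorm(p * p, sd = noise_sd), p, p))
    C <- C + (e + t(e)) / 2
  }
  diag(C) <- 1
  list(connectome = unname(C), cortical_gradients = g)
}

#' Plant voxel-to-parcel connectivity mirroring cortical gradients
#'
#' Generates a voxel-by-parcel connectivity matrix in which each voxel's
#' cortical profile is a baseline plus a mixture of the planted cortical
#' gradients, weighted by a monotone function of the voxel's position along
#' the corresponding spatial axis. Embedding the result should recover one
#' voxel gradient per planted axis, and projecting each recovered gradient
#' back onto the cortex should reproduce the generating cortical gradient --
#' the synthetic analogue of cortically mirrored subcortical connectopy.
#'
#' @param domain Voxel domain from [make_voxel_domain()].
#' @param parcels Parcel set (used only for dimension checks).
#' @param cortical_gradients Parcel x k matrix of planted cortical gradients.
#' @param axis_directions k x 3 matrix of linearly independent unit vectors;
#'   voxel scores for axis j are linear in the coordinate along row j.
#' @param snr Signal-to-noise ratio: sd(signal) / sd(noise). Use `Inf` for a
#'   noise-free instance.
#' @param seed Integer seed.
#' @return A list with `connectivity` (voxel x parcel, values in \[-1, 1\])
#'   and `planted_axes` (voxel x k, centred orthonormal columns).
#' @export
plant_pulvinar_connectivity <- function(domain, parcels, cortical_gradients,
                                        axis_directions, snr = 10, seed = 1) {
  if (!is.matrix(axis_directions)) {
    axis_directions <- matrix(axis_directions, ncol = 3, byrow = TRUE)
  }
  k <- nrow(axis_directions)
  if (ncol(cortical_gradients) != k) {
    abort("`cortical_gradients` must have one column per axis direction.")
  }
  if (qr(axis_directions)$rank < k) {
    abort("`axis_directions` must be linearly independent.")
  }
  if (!is.numeric(snr) || length(snr) != 1 || is.na(snr) || snr <= 0) {
    abort("`snr` must be a positive scalar (Inf allowed).")
  }

  coords <- as.matrix(domain[, c("x", "y", "z")])
  scores <- coords %*% t(axis_directions)          # monotone along each axis
  axes <- gram_schmidt(scores)                     # centred, orthonormal
  n <- nrow(coords)

  # decreasing per-axis amplitude so axis 1 dominates the embedding spectrum
  amp <- 0.6^(seq_len(k) - 1)
  s <- sweep(axes, 2, amp * sqrt(n), `*`)          # unit-variance-ish scores
  signal <- s %*% t(cortical_gradients)
  signal <- signal * (0.45 / max(abs(signal)))
  w <- 0.5 + signal
  if (is.finite(snr)) {
    noise_sd <- sd(as.vector(signal)) / snr
    w <- w + with_seed(seed, matrix(rnorm(length(w), sd = noise_sd), n))
  }
  w[w > 1] <- 1
  w[w < -1] <- -1
  list(connectivity = unname(w), planted_axes = axes)
}

#' Simulate BOLD-like time series matching a target voxel-parcel connectome
#'
#' Latent-factor construction: parcel time series are independent unit-normal
#' factors and each voxel series is the target-weighted factor combination
#' plus idiosyncratic noise, so empirical voxel-to-parcel correlations
#' converge to the target as `T` grows and `noise_sd` shrinks. Orthonormal
#' factors bound the attainable correlation vector: target rows with squared
#' norm above 1 are rescaled with a warning.
#'
#' @param connectome Target voxel x parcel correlation matrix.
#' @param n_timepoints Number of time points (`>= 10` recommended, `>= 2`
#'   required).
#' @param noise_sd Extra idiosyncratic noise standard deviation.
#' @param seed Integer seed.
#' @return List with `voxel_ts` (voxel x T) and `parcel_ts` (parcel x T).
#' @export
make_timeseries <- function(connectome, n_timepoints = 200, noise_sd = 0.1,
                            seed = 1) {
  n_timepoints <- assert_count(n_timepoints, "n_timepoints", min = 2L)
  noise_sd <- assert_scalar(noise_sd, "noise_sd", 0)
  C <- as.matrix(connectome)
  rn <- rowSums(C^2)
  if (any(rn > 1)) {
    warn("target rows with squared norm > 1 rescaled to the attainable range")
    bad <- rn > 1
    C[bad, ] <- C[bad, ] * sqrt(0.99 / rn[bad])
    rn <- rowSums(C^2)
  }
  with_seed(seed, {
    y <- matrix(rnorm(ncol(C) * n_timepoints), ncol(C), n_timepoints)
    eps <- matrix(rnorm(nrow(C) * n_timepoints), nrow(C), n_timepoints)
    x <- C %*% y + sqrt(pmax(0, 1 - rn)) * eps
    if (noise_sd > 0) {
      x <- x + matrix(rnorm(nrow(C) * n_timepoints, sd = noise_sd),
                      nrow(C), n_timepoints)
    }
    list(voxel_ts = x, parcel_ts = y)
  })
}

#' Simulate overdispersed streamline-count matrices
#'
#' Draws nonnegative integer counts with mean `scale * weights` from a
#' negative-binomial law (Poisson in the `dispersion -> 0` limit), emulating
#' tract-density matrices from probabilistic tractography, whose counts are
#' overdispersed relative to Poisson.
#'
#' @param weights Nonnegative voxel x parcel weight matrix.
#' @param scale Expected count at weight 1.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); `0` gives Poisson draws.
#' @param seed Integer seed.
#' @return Integer matrix, same shape as `weights`; zero weights map to zero
#'   counts.
#' @export
make_structural_counts <- function(weights, scale = 1000, dispersion = 0.2,
                                   seed = 1) {
  w <- as.matrix(weights)
  if (any(w < 0)) abort("`weights` must be nonnegative.")
  scale <- assert_scalar(scale, "scale", 0, strict = TRUE)
  dispersion <- assert_scalar(dispersion, "dispersion", 0)
  mu <- scale * w
  with_seed(seed, {
    cnt <- if (dispersion < 1e-12) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    matrix(as.integer(cnt), nrow(w), ncol(w))
  })
}

canonical_tracers <- c(
  "5HT1A", "5HT1B", "5HT2A", "5HT4", "5HT6", "5HTT", "A4B2", "CB1", "D1",
  "D2", "DAT", "GABAa", "H3", "M1", "mGluR5", "MOR", "NET", "NMDA", "VAChT"
)

#' Simulate receptor density maps with planted coexpression structure
#'
#' Each tracer map is a linear combination of the planted spatial axes plus
#' Gaussian noise, so the voxel-by-tracer matrix has smooth coexpression
#' structure whose leading molecular gradient is a planted axis.
#'
#' @param domain Voxel domain (provides the voxel count).
#' @param n_tracers Number of tracer maps.
#' @param planted_axes Voxel x k matrix of spatial axes.
#' @param loading_matrix Tracer x k loading matrix.
#' @param noise_sd Noise standard deviation on the scale of unit-norm axes.
#' @param seed Integer seed.
#' @return Voxel x tracer numeric matrix with tracer names as column names.
#' @export
make_receptor_maps <- function(domain, n_tracers, planted_axes,
                               loading_matrix, noise_sd = 0.1, seed = 1) {
  n_tracers <- assert_count(n_tracers, "n_tracers")
  planted_axes <- as.matrix(planted_axes)
  loading_matrix <- as.matrix(loading_matrix)
  if (nrow(loading_matrix) != n_tracers ||
      ncol(loading_matrix) != ncol(planted_axes)) {
    abort("`loading_matrix` must be n_tracers x k, matching `planted_axes`.")
  }
  if (nrow(planted_axes) != nrow(domain)) {
    abort("`planted_axes` must have one row per domain voxel.")
  }
  noise_sd <- assert_scalar(noise_sd, "noise_sd", 0)
  zero_load <- rowSums(abs(loading_matrix)) == 0
  if (noise_sd == 0 && any(zero_load)) {
    abort(sprintf(
      "tracer(s) %s have all-zero loadings and no noise: constant map",
      paste(which(zero_load), collapse = ", ")
    ))
  }
  n <- nrow(planted_axes)
  r <- planted_axes %*% t(loading_matrix)
  if (noise_sd > 0) {
    r <- r + with_seed(seed, matrix(rnorm(n * n_tracers, sd = noise_sd), n))
  }
  nm <- c(canonical_tracers,
          paste0("tracer", seq_len(max(0, n_tracers - 19)) + 19L))
  colnames(r) <- nm[seq_len(n_tracers)]
  r
}

#' Simulate a spatially autocorrelated Gaussian field
#'
#' Draws one realisation of a zero-mean Gaussian random field with squared-
#' exponential covariance `exp(-d^2 / (2 * correlation_length^2))` and unit
#' sill, used as a test map with known spatial autocorrelation for the
#' surrogate null machinery.
#'
#' @param coords n x 3 coordinate matrix (millimetres).
#' @param correlation_length Correlation length in millimetres (`> 0`).
#' @param seed Integer seed.
#' @return Numeric vector of length n.
#' @export
make_sa_field <- function(coords, correlation_length, seed = 1) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) abort("at least 2 points are required.")
  correlation_length <- assert_scalar(correlation_length,
                                      "correlation_length", 0, strict = TRUE)
  d <- as.matrix(dist(coords))
  K <- exp(-d^2 / (2 * correlation_length^2))
  diag(K) <- diag(K) + 1e-8
  L <- chol(K)
  with_seed(seed, as.vector(crossprod(L, rnorm(nrow(coords)))))
}

#' Plant clustered gradient-space data
#'
#' Generates voxel coordinates in gradient space drawn from `k` well-separated
#' Gaussian blobs (or, with `clustered = FALSE`, from a continuous gradient
#' with no cluster structure), with ground-truth labels, for validating
#' gradient-space clustering.
#'
#' @param n_voxels Number of voxels.
#' @param k_clusters Number of planted clusters.
#' @param n_dims Gradient-space dimensionality.
#' @param separation Distance between blob centres in units of within-blob sd.
#' @param clustered If `FALSE`, values are drawn along a continuous gradient
#'   and labels are contiguous slices of it (no density gaps).
#' @param seed Integer seed.
#' @return List with `values` (voxel x n_dims) and `labels` (integer vector).
#' @export
plant_gradient_clusters <- function(n_voxels = 300, k_clusters = 4,
                                    n_dims = 2, separation = 8,
                                    clustered = TRUE, seed = 1) {
  n_voxels <- assert_count(n_voxels, "n_voxels")
  k_clusters <- assert_count(k_clusters, "k_clusters")
  n_dims <- assert_count(n_dims, "n_dims")
  with_seed(seed, {
    if (clustered) {
      # centres on a circle with minimum pairwise distance = separation
      # (in units of the unit within-cluster sd), jittered slightly
      ang <- 2 * pi * (seq_len(k_clusters) - 1) / k_clusters
      radius <- if (k_clusters > 1) separation / (2 * sin(pi / k_clusters))
                else 0
      centers <- matrix(0, k_clusters, n_dims)
      centers[, 1] <- radius * cos(ang)
      if (n_dims > 1) centers[, 2] <- radius * sin(ang)
      centers <- centers + matrix(rnorm(k_clusters * n_dims, sd = 0.5),
                                  k_clusters)
      labels <- sort(rep_len(seq_len(k_clusters), n_voxels))
      values <- centers[labels, , drop = FALSE] +
        matrix(rnorm(n_voxels * n_dims), n_voxels)
    } else {
      t <- sort(runif(n_voxels))
      dirs <- matrix(rnorm(n_dims), 1)
      values <- t %*% dirs * separation +
        matrix(rnorm(n_voxels * n_dims), n_voxels)
      labels <- ceiling(t * k_clusters)
      labels[labels < 1] <- 1L
    }
    list(values = unname(values), labels = as.integer(labels))
  })
}
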