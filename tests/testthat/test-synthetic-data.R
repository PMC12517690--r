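test_that("voxel domains are mirrored, partitioned and deterministic", {
  dom <- make_voxel_domain(200, nuclei = 4, voxel_size = 2, seed = 1)
  expect_equal(nlevels(dom$nucleus), 4)
  expect_true(all(table(dom$nucleus) > 0))
  # mirrored: right-hemisphere coordinates are the left ones with x negated
  left <- dplyr::filter(dom, hemisphere == "left")
  right <- dplyr::filter(dom, hemisphere == "right")
  expect_equal(nrow(left), nrow(right))
  expect_equal(right$x, -left$x)
  expect_equal(right$y, left$y)
  expect_equal(right$nucleus, left$nucleus)
  # coordinates unique, one hemisphere and nucleus per voxel
  expect_equal(anyDuplicated(dom[, c("x", "y", "z")]), 0)
  expect_false(anyNA(dom$nucleus))
  # nuclei are spatially contiguous: each voxel's nearest neighbours are
  # dominated by its own nucleus
  d <- as.matrix(dist(left[, c("x", "y", "z")]))
  frac_same <- vapply(seq_len(nrow(left)), function(v) {
    nb <- order(d[v, ])[2:5]
    mean(left$nucleus[nb] == left$nucleus[v])
  }, numeric(1))
  expect_gt(mean(frac_same), 0.7)
  expect_identical(dom, make_voxel_domain(200, 4, 2, seed = 1))
})

test_that("degenerate and invalid voxel domains are handled", {
  dom1 <- make_voxel_domain(1, nuclei = 1, voxel_size = 2, seed = 0)
  expect_equal(nrow(dom1), 1)
  expect_equal(nlevels(droplevels(dom1$nucleus)), 1)
  expect_error(make_voxel_domain(0, 1, 2, 1), "integer")
  expect_error(make_voxel_domain(10, -1, 2, 1), "integer")
  expect_error(make_voxel_domain(4, 8, 2, 1), "exceed")
})

test_that("parcel sets cover all networks and are deterministic", {
  p <- make_parcel_set(400, 7, seed = 1)
  expect_equal(nrow(p), 400)
  expect_equal(nlevels(p$network), 7)
  expect_true(all(table(p$network) > 0))
  tiny <- make_parcel_set(7, 7, seed = 2)
  expect_true(all(table(tiny$network) == 1))
  expect_identical(p, make_parcel_set(400, 7, seed = 1))
  expect_error(make_parcel_set(5, 7, seed = 1), "exceed")
})

test_that("planted cortical connectomes have the planted spectrum", {
  par <- make_parcel_set(100, 7, seed = 3)
  # rank-1 noise-free: leading eigenvector is the planted gradient
  c1 <- plant_cortical_connectivity(par, k = 1, weights = 3, noise_sd = 0,
                                    seed = 1)
  e1 <- eigen(c1$connectome, symmetric = TRUE)
  expect_gt(abs(cor(e1$vectors[, 1], c1$cortical_gradients[, 1])), 0.999)
  # top-2 eigenvectors span {g1, g2} (dense eigendecomposition oracle)
  c2 <- plant_cortical_connectivity(par, k = 2, weights = c(3, 1),
                                    noise_sd = 0, seed = 1)
  e2 <- eigen(c2$connectome, symmetric = TRUE)
  v <- e2$vectors[, 1:2]
  for (j in 1:2) {
    g <- c2$cortical_gradients[, j]
    resid <- g - v %*% crossprod(v, g)
    expect_lt(sqrt(sum(resid^2)), 0.05)
  }
  expect_equal(max(abs(c2$connectome - t(c2$connectome))), 0)
  expect_equal(unname(diag(c2$connectome)), rep(1, 100))
  expect_error(plant_cortical_connectivity(par, k = 2, weights = c(1, 2)),
               "decreasing")
  expect_error(plant_cortical_connectivity(par, k = 100), "smaller")
})

test_that("planted voxel-parcel connectivity is recoverable by embedding", {
  st <- tiny_planted_study(n_voxels = 200, n_parcels = 60, k = 1, snr = Inf)
  g <- embed_connectome(st$pulvinar$connectivity, n_components = 3)
  expect_gt(abs(cor(g$components[, 1], st$pulvinar$planted_axes[, 1])), 0.99)

  st2 <- tiny_planted_study(n_voxels = 200, n_parcels = 60, k = 2, snr = Inf)
  g2 <- embed_connectome(st2$pulvinar$connectivity, n_components = 4)
  m <- match_axes(g2$components, st2$pulvinar$planted_axes)
  expect_equal(m$gradient, 1:2)
  expect_true(all(m$abs_r > 0.99))
  # planted axes are centred and orthonormal
  ax <- st2$pulvinar$planted_axes
  expect_lt(max(abs(colMeans(ax))), 1e-10)
  expect_equal(crossprod(ax), diag(2), tolerance = 1e-8)
  expect_error(
    plant_pulvinar_connectivity(st2$domain, st2$parcels,
                                st2$cortical$cortical_gradients,
                                diag(3)[1:2, ], snr = 0),
    "positive"
  )
})

test_that("voxels at identical coordinates get identical noise-free profiles", {
  st <- tiny_planted_study(n_voxels = 50, n_parcels = 30, k = 2, snr = Inf)
  dom <- st$domain
  dom[2, c("x", "y", "z")] <- dom[1, c("x", "y", "z")]
  pulv <- plant_pulvinar_connectivity(dom, st$parcels,
                                      st$cortical$cortical_gradients,
                                      diag(3)[1:2, ], snr = Inf, seed = 1)
  expect_equal(pulv$connectivity[1, ], pulv$connectivity[2, ])
})

test_that("simulated time series converge to the target connectome", {
  set.seed(11)
  target <- matrix(runif(30 * 5, -0.3, 0.3), 30, 5)
  ts <- make_timeseries(target, n_timepoints = 10000, noise_sd = 0, seed = 4)
  emp <- cor(t(ts$voxel_ts), t(ts$parcel_ts))
  expect_lt(max(abs(emp - target)), 0.05)
  # zero target: correlations scattered around zero
  ts0 <- make_timeseries(matrix(0, 20, 4), 2000, noise_sd = 0, seed = 5)
  expect_lt(max(abs(cor(t(ts0$voxel_ts), t(ts0$parcel_ts)))), 0.1)
  expect_identical(make_timeseries(target, 50, 0.1, seed = 9),
                   make_timeseries(target, 50, 0.1, seed = 9))
  expect_error(make_timeseries(target, 1), ">= 2")
  expect_warning(make_timeseries(matrix(1, 2, 4), 20, seed = 1), "rescaled")
})

test_that("structural counts are overdispersed draws with the right mean", {
  w <- matrix(runif(50 * 10, 0.1, 1), 50, 10)
  cnt <- make_structural_counts(w, scale = 5000, dispersion = 0, seed = 2)
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))
  expect_lt(mean(abs(cnt / (5000 * w) - 1)), 0.05)
  w0 <- w
  w0[3, ] <- 0
  cnt0 <- make_structural_counts(w0, scale = 100, dispersion = 0.3, seed = 2)
  expect_true(all(cnt0[3, ] == 0))
  # overdispersion: negative-binomial variance exceeds Poisson at the same mu
  flat <- matrix(0.5, 200, 5)
  nb <- make_structural_counts(flat, 1000, dispersion = 0.5, seed = 3)
  expect_gt(var(as.vector(nb)), 2 * 500)
  expect_error(make_structural_counts(-w), "nonnegative")
})

test_that("receptor maps encode the planted coexpression axes", {
  dom <- make_voxel_domain(300, 4, 2, seed = 6)
  ax <- pulvigrad:::gram_schmidt(as.matrix(dom[, c("x", "y", "z")])[, 1:2])
  # two tracers with opposite loadings on one axis are perfectly anticorrelated
  r2 <- make_receptor_maps(dom, 2, ax[, 1, drop = FALSE],
                           matrix(c(1, -1), 2, 1), noise_sd = 0, seed = 1)
  expect_equal(cor(r2[, 1], r2[, 2]), -1)
  # coexpression gradient recovers the planted axis at snr 10
  set.seed(8)
  loads <- matrix(rnorm(12 * 2), 12, 2)
  noise_sd <- sd(ax %*% t(loads)) / 10
  rmap <- make_receptor_maps(dom, 12, ax, loads, noise_sd = noise_sd,
                             seed = 2)
  g <- diffusion_embedding(cosine_affinity(zscore_columns(rmap)),
                           n_components = 4)
  expect_gt(max(abs(cor(g$components, ax[, 1]))), 0.95)
  expect_identical(rmap, make_receptor_maps(dom, 12, ax, loads,
                                            noise_sd = noise_sd, seed = 2))
  expect_error(make_receptor_maps(dom, 2, ax[, 1, drop = FALSE],
                                  matrix(c(1, 0), 2, 1), noise_sd = 0),
               "all-zero")
})

test_that("spatially autocorrelated fields have the planted variogram shape", {
  set.seed(13)
  coords <- matrix(runif(500 * 3, 0, 60), 500)
  d <- distance_matrix(coords)
  smooth <- make_sa_field(coords, correlation_length = 15, seed = 1)
  vg <- empirical_variogram(smooth, d)
  # rises over the first bins and approaches the unit sill
  expect_true(all(diff(vg$gamma[1:8]) > -0.02))
  expect_gt(vg$gamma[nrow(vg)], 0.5)
  expect_lt(vg$gamma[1], 0.3)
  # near-white field: variogram flat near the sill everywhere
  white <- make_sa_field(coords, correlation_length = 0.1, seed = 2)
  vw <- empirical_variogram(white, d)
  expect_lt(max(vw$gamma) - min(vw$gamma), 0.4 * mean(vw$gamma))
  # near-constant field: variogram ~0 at short lags
  flat <- make_sa_field(coords, correlation_length = 500, seed = 3)
  vf <- empirical_variogram(flat, d)
  expect_lt(vf$gamma[1], 0.01)
  expect_error(make_sa_field(coords[1, , drop = FALSE], 10), "2 points")
})

test_that("planted gradient-space clusters carry usable ground truth", {
  pl <- plant_gradient_clusters(200, k_clusters = 4, n_dims = 2,
                                separation = 8, seed = 3)
  expect_equal(sort(unique(pl$labels)), 1:4)
  expect_equal(nrow(pl$values), 200)
  cont <- plant_gradient_clusters(200, 4, 2, clustered = FALSE, seed = 3)
  expect_equal(sort(unique(cont$labels)), 1:4)
  expect_identical(pl, plant_gradient_clusters(200, 4, 2, 8, TRUE, seed = 3))
})
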