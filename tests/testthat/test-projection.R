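test_that("gradient-weighted maps are mean dot products and linear in g", {
  f <- matrix(c(3, 4, 1, 2), 2, 2)
  gw <- gradient_weighted_map(f, c(1, 2))
  expect_equal(gw$value[1], (1 * 3 + 2 * 4) / 2)
  expect_equal(gradient_weighted_map(f, c(1, 1))$value, colMeans(f))
  expect_equal(gradient_weighted_map(f, c(0, 0))$value, c(0, 0))
  # linearity
  set.seed(3)
  fm <- matrix(rnorm(50 * 8), 50)
  g1 <- rnorm(50)
  g2 <- rnorm(50)
  lhs <- gradient_weighted_map(fm, 2 * g1 - 3 * g2)$value
  rhs <- 2 * gradient_weighted_map(fm, g1)$value -
    3 * gradient_weighted_map(fm, g2)$value
  expect_equal(lhs, rhs)
  expect_error(gradient_weighted_map(fm, g1[-1]), "length")
  norm <- gradient_weighted_map(fm, g1, normalize = TRUE)
  expect_equal(range(norm$value), c(0, 1))
})

test_that("hemispheric averaging honours the mirror correspondence", {
  l <- tibble::tibble(parcel = 1:4, value = c(1, 2, 3, 4))
  r <- tibble::tibble(parcel = 1:4, value = c(4, 3, 2, 1))
  plain <- hemiflip_average(l, r, mode = "plain")
  expect_equal(plain$value, rep(2.5, 4))
  expect_equal(hemiflip_average(r, l, mode = "plain")$value, plain$value)
  expect_equal(hemiflip_average(l, l, mode = "plain")$value, l$value)
  # identity mirror equals plain; a true mirror re-indexes
  expect_equal(hemiflip_average(l, r, mirror = 1:4, mode = "xflip")$value,
               plain$value)
  expect_equal(hemiflip_average(l, r, mirror = 4:1, mode = "xflip")$value,
               c(1, 2, 3, 4))
  expect_error(hemiflip_average(l, r, mirror = c(1, 1, 2, 3),
                                mode = "xflip"),
               "permutation")
})

test_that("labelled summaries partition values by group", {
  ls <- labeled_summary(c(1, 2, 3, 5), c("a", "a", "b", "b"))
  means <- dplyr::summarise(dplyr::group_by(ls, label),
                            m = mean(value))
  expect_equal(means$m, c(1.5, 4))
  one <- labeled_summary(1:5, rep("x", 5))
  expect_equal(nlevels(one$label), 1)
  singletons <- labeled_summary(1:3, c("a", "b", "c"))
  expect_equal(table(singletons$label), table(c("a", "b", "c")),
               ignore_attr = TRUE)
  expect_warning(labeled_summary(1:3, factor(c("a", "a", "b"),
                                             levels = c("a", "b", "c"))),
                 "empty")
  expect_error(labeled_summary(1:3, c("a", "b")), "length")
})

test_that("map correlation is Pearson r with guards", {
  expect_equal(map_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  a <- rnorm(10)
  expect_equal(map_correlation(a, a), 1)
  expect_equal(map_correlation(a, -a), -1)
  expect_error(map_correlation(a, rep(1, 10)), "constant")
  expect_error(map_correlation(a[1:2], a[1:2]), "3 parcels")
  # tibble inputs from gradient_weighted_map work directly
  expect_equal(map_correlation(tibble::tibble(value = a),
                               tibble::tibble(value = a)), 1)
})

test_that("receptor correlates rank tracers by absolute correlation", {
  set.seed(41)
  g <- rnorm(300)
  maps <- cbind(planted = g + rnorm(300, sd = 0.2),
                noise1 = rnorm(300), noise2 = rnorm(300),
                anti = -g + rnorm(300, sd = 0.2))
  rc <- receptor_correlates(g, zscore_columns(maps), top_n = 4)
  expect_equal(rc$rank, 1:4)
  expect_true(all(c("planted", "anti") %in% rc$tracer[1:2]))
  expect_true(all(diff(abs(rc$r)) <= 0))          # sorted by |r|
  # ranking invariant to tracer ordering
  rc2 <- receptor_correlates(g, zscore_columns(maps[, c(3, 1, 4, 2)]),
                             top_n = 4)
  expect_equal(sort(rc$tracer), sort(rc2$tracer))
  expect_equal(rc$r[rc$tracer == "planted"], rc2$r[rc2$tracer == "planted"])
  # exact self-correlation tops the list
  self <- receptor_correlates(g, cbind(self = g, noise = rnorm(300)))
  expect_equal(self$tracer[1], "self")
  expect_equal(self$r[1], 1)
})

test_that("cross-modal correlations honour sign indeterminacy", {
  set.seed(43)
  comp <- matrix(rnorm(60 * 2), 60)
  ga <- pulvigrad:::new_gradient_set(comp, c(0.5, 0.3), c(0.6, 0.4))
  gb <- pulvigrad:::new_gradient_set(-comp, c(0.5, 0.3), c(0.6, 0.4))
  out <- cross_modal_correlation(list(fc = ga, rc = gb))
  expect_equal(nrow(out), 4)
  same <- dplyr::filter(out, component_a == component_b)
  expect_equal(same$abs_r, c(1, 1))               # negation: |r| = 1
  expect_true(all(out$abs_r >= 0 & out$abs_r <= 1))
  expect_error(
    cross_modal_correlation(list(
      a = ga,
      b = pulvigrad:::new_gradient_set(comp[1:10, ], 0.5, 0.6)
    )),
    "share voxels"
  )
})

test_that("shared planted axes produce high cross-modal correlation", {
  st <- tiny_planted_study(n_voxels = 200, n_parcels = 60, k = 2, snr = 10)
  g_fc <- embed_connectome(st$pulvinar$connectivity, n_components = 2)
  set.seed(4)
  loads <- matrix(rnorm(20), 10, 2)
  rmap <- make_receptor_maps(st$domain, 10, st$pulvinar$planted_axes,
                             loads,
                             noise_sd = sd(st$pulvinar$planted_axes %*%
                                             t(loads)) / 10,
                             seed = 5)
  g_rc <- diffusion_embedding(cosine_affinity(zscore_columns(rmap)),
                              n_components = 2)
  out <- cross_modal_correlation(list(functional = g_fc,
                                      coexpression = g_rc))
  expect_gt(max(out$abs_r), 0.9)
})
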