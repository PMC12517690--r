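test_that("functional connectome entries are Pearson correlations", {
  t3 <- rbind(c(1, 2, 3))
  p3 <- rbind(a = c(1, 3, 2))
  fc <- functional_connectome(t3, p3)
  expect_equal(as.numeric(fc), 0.5)          # hand computation
  expect_s3_class(fc, "feature_matrix")
  expect_equal(attr(fc, "stage"), "raw")

  ts <- matrix(rnorm(5 * 20), 5, 20)
  same <- functional_connectome(ts, ts[2, , drop = FALSE])
  expect_equal(unname(same[2, 1]), 1)
  neg <- functional_connectome(ts, -ts[2, , drop = FALSE])
  expect_equal(unname(neg[2, 1]), -1)
  expect_true(all(abs(unclass(functional_connectome(ts, ts))) <= 1))

  bad <- ts
  bad[3, ] <- 7
  expect_error(functional_connectome(bad, ts), "voxel.*3")
  expect_error(functional_connectome(ts[, 1:2], ts[, 1:2]), "3 time points")
})

test_that("sparsify keeps the row-wise top fraction with ties at threshold", {
  row400 <- matrix(sample(seq_len(400)) / 400, 1)
  fm <- feature_matrix(row400, "functional", "raw")
  sp <- sparsify(fm)
  expect_equal(sum(sp > 0), 40)              # exactly 10% of 400 distinct
  # survivors are the 40 largest values (brute-force rank oracle)
  expect_setequal(unclass(sp)[sp > 0], sort(row400, decreasing = TRUE)[1:40])

  row10 <- matrix(seq(0.1, 1, by = 0.1), 1)
  sp10 <- sparsify(feature_matrix(row10, "functional", "raw"))
  expect_equal(sum(sp10 > 0), 1)             # only the maximum survives
  expect_equal(max(sp10), 1)

  allneg <- feature_matrix(matrix(-runif(20), 2), "functional", "raw")
  expect_true(all(sparsify(allneg) == 0))

  expect_error(sparsify(fm, sparsity = 0), "0, 1")
  expect_error(sparsify(fm, sparsity = 1.5), "0, 1")
  expect_error(sparsify(feature_matrix(matrix(1, 2, 2), "structural",
                                       "raw")),
               "functional")
})

test_that("sparsify is idempotent and its zero pattern survives fisher_z", {
  set.seed(21)
  for (rep in 1:5) {
    m <- feature_matrix(matrix(runif(40 * 50, -0.99, 0.99), 40),
                        "functional", "raw")
    s1 <- sparsify(m)
    s2 <- sparsify(feature_matrix(unclass(s1), "functional", "raw"))
    expect_equal(unclass(s2), unclass(s1))
    z <- fisher_z(s1)
    expect_identical(unclass(z) == 0, unclass(s1) == 0)
  }
})

test_that("fisher_z is atanh with clamping at |r| = 1", {
  m <- feature_matrix(matrix(c(0, 0.5, -0.3, 0.9), 2), "functional", "raw")
  z <- fisher_z(m)
  expect_equal(unname(unclass(z)[1, 1]), 0)
  expect_equal(unname(unclass(z)[2, 1]), 0.5493, tolerance = 1e-4)
  expect_equal(unclass(z), atanh(unclass(m)), ignore_attr = TRUE)
  # monotone
  r <- sort(runif(50, -0.99, 0.99))
  zz <- fisher_z(matrix(r, 1))
  expect_true(all(diff(as.numeric(zz)) > 0))
  expect_warning(
    out <- fisher_z(feature_matrix(matrix(c(1, 0.2), 1), "functional",
                                   "raw")),
    "clamped"
  )
  expect_true(all(is.finite(unclass(out))))
})

test_that("group averaging is the elementwise mean and order-invariant", {
  set.seed(31)
  ms <- lapply(1:4, function(i) {
    feature_matrix(matrix(rnorm(12), 3), "functional", "raw")
  })
  avg <- group_average(ms)
  expect_equal(attr(avg, "stage"), "group_mean")
  expect_equal(unclass(group_average(ms[1])), unclass(ms[[1]]),
               ignore_attr = TRUE)
  expect_equal(unclass(group_average(rev(ms))), unclass(avg))
  m <- ms[[1]]
  zero <- group_average(list(m, feature_matrix(-unclass(m), "functional",
                                               "raw")))
  expect_equal(max(abs(unclass(zero))), 0)
  expect_error(group_average(list()), "nonempty")
  expect_error(group_average(list(m, matrix(0, 2, 2))), "shape")
})

test_that("structural density is the untransformed mean of counts", {
  a <- matrix(2, 3, 4)
  b <- matrix(4, 3, 4)
  sd3 <- structural_density(list(a, b))
  expect_true(all(unclass(sd3) == 3))
  expect_equal(attr(sd3, "modality"), "structural")
  expect_true(all(unclass(structural_density(list(a, a))) == 2))
  expect_true(all(unclass(structural_density(list(a * 0, b * 0))) == 0))
  expect_error(structural_density(list(a, -b)), "nonnegative")
})

test_that("z-scored columns have exact moments under the sample-sd convention", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), 3, dimnames = list(NULL, c("A", "B")))
  z <- zscore_columns(m)
  expect_equal(unname(unclass(z)[, 1]), c(-1, 0, 1))
  expect_equal(attr(z, "stage"), "zscored")
  # idempotence and location invariance
  expect_equal(unclass(zscore_columns(unclass(z))), unclass(z),
               tolerance = 1e-12)
  expect_equal(unclass(zscore_columns(m + 100)), unclass(z))
  # moment invariants
  set.seed(5)
  big <- matrix(rnorm(200 * 6, 5, 3), 200)
  zb <- unclass(zscore_columns(big))
  expect_lt(max(abs(colMeans(zb))), 1e-10)
  expect_lt(max(abs(apply(zb, 2, sd) - 1)), 1e-10)
  const <- cbind(m, C = 7)
  expect_error(zscore_columns(const), "C")
})

test_that("SNR maps divide mean by sample sd and flag undefined voxels", {
  s <- rbind(c(1, 2, 3), c(10, 10, 10), c(2, 4, 6))
  snr <- snr_map(s, "tsnr")
  expect_equal(snr$value[1], 2)              # mean 2 / sample sd 1
  expect_false(snr$defined[2])
  expect_true(is.na(snr$value[2]))
  expect_equal(snr$value[3], snr$value[1])   # scale invariance
  expect_error(snr_map(s[, 1, drop = FALSE]), "2 volumes")
})
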