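test_that("diattenuation reads the first row and clips at 1", {
  expect_equal(diattenuation(diag(3))$D, 0)
  expect_equal(diattenuation(gbm_M)$D, sqrt(0.02^2 + 0.01^2))
  M <- diag(3); M[1, 2] <- 0.6; M[1, 3] <- 0.8
  expect_equal(diattenuation(M)$D, 1)
})

test_that("strip_diattenuation removes the diattenuator factor", {
  expect_equal(strip_diattenuation(diag(3)), diag(3))
  expect_matrix_equal(strip_diattenuation(make_diattenuator(0.3, 0.4)),
                      diag(3), tol = 1e-12)
  # reference non-GBM matrix strips to nearly the pure backscatter depolarizer
  Mp <- strip_diattenuation(non_gbm_M)
  expect_matrix_equal(Mp, diag(c(1, 0.09, -0.09)), tol = 2e-3)
  M <- diag(3); M[1, 2] <- 1
  expect_error(strip_diattenuation(M), "singular")
})

test_that("mmpd recovers depolarization and retardance worked examples", {
  r <- mmpd(diag(c(1, 0.09, -0.09)))
  expect_equal(r$delta_dep, 0.09, tolerance = 1e-12)
  expect_equal(r$one_minus_delta, 0.91, tolerance = 1e-12)
  expect_equal(r$delta_ret, 0)
  expect_equal(r$eigenvalues, c(0.0081, 0.0081), tolerance = 1e-12)

  r <- mmpd(diag(3))
  expect_equal(r$delta_dep, 1)
  expect_equal(r$one_minus_delta, 0)
  expect_equal(r$delta_ret, 0)

  r <- mmpd(make_linear_retarder(pi / 3, 0))
  expect_equal(r$delta_dep, 1, tolerance = 1e-12)
  expect_equal(r$delta_ret, pi / 3, tolerance = 1e-12)
})

test_that("mmpd on the reference tissue matrices gives the published scale", {
  expect_equal(mmpd(non_gbm_M)$one_minus_delta, 0.91, tolerance = 0.005)
  # the GBM average matrix decomposes to ~0.67; the published per-pixel
  # average is 0.65 (mean of a nonlinear map vs map of the mean)
  expect_lt(abs(mmpd(gbm_M)$one_minus_delta - 0.65), 0.03)
})

test_that("parameter recovery is exact for composed depolarizer-retarder-diattenuator", {
  for (dep in seq(0.1, 0.9, by = 0.2)) {
    for (ret in c(0, pi / 6, pi / 3)) {
      for (dvec in list(c(0, 0), c(0.2, -0.1), c(-0.15, 0.25))) {
        M <- composed_sample(dep, ret, theta = 0.35, dvec[1], dvec[2])
        r <- mmpd(M)
        expect_equal(r$delta_dep, dep, tolerance = 1e-8)
        expect_equal(r$delta_ret, ret, tolerance = 1e-7)
        expect_equal(r$D, sqrt(sum(dvec^2)), tolerance = 1e-8)
      }
    }
  }
})

test_that("mmt_t reproduces the worked tissue examples and identity", {
  expect_equal(mmt_t(gbm_M)$t, 0.325)
  expect_equal(mmt_t(non_gbm_M)$t, 0.09)
  expect_equal(mmt_t(diag(3))$t, 0)
  # both variants coincide when m23 = m32 = 0
  expect_equal(mmt_t(gbm_M, "plus")$t, mmt_t(gbm_M, "minus")$t)
})

test_that("t-plus is rotation invariant; t-minus on a rotated retarder follows |cos 4phi|", {
  set.seed(21)
  for (k in 1:6) {
    M <- composed_sample(runif(1, 0.2, 1), runif(1, 0, pi), runif(1, 0, pi),
                         runif(1, -0.3, 0.3), runif(1, -0.3, 0.3))
    phi <- runif(1, 0, pi)
    expect_equal(mmt_t(rotate_sample(M, phi), "plus")$t, mmt_t(M, "plus")$t,
                 tolerance = 1e-10)
  }
  d <- 1.2
  for (phi in c(0, 0.2, 0.6, 1.1)) {
    Mr <- rotate_sample(make_linear_retarder(d, 0), phi)
    expect_equal(mmt_t(Mr, "minus")$t, abs(cos(4 * phi)) * (1 - cos(d)) / 2,
                 tolerance = 1e-10)
  }
})

test_that("backscatter depolarizer ties t to the depolarization coefficient", {
  for (dep in c(0.09, 0.33, 0.7)) {
    M <- make_depolarizer(dep, backscatter = TRUE)
    expect_equal(mmt_t(M)$t, dep)
    expect_equal(mmpd(M)$one_minus_delta, 1 - mmt_t(M)$t, tolerance = 1e-12)
  }
})

test_that("isotropic depolarization strictly decreases the recovered Delta", {
  M <- composed_sample(0.9, pi / 5, 0.2)
  deltas <- vapply(c(1, 0.8, 0.6, 0.4), function(k) {
    Mk <- M
    Mk[2:3, 2:3] <- k * Mk[2:3, 2:3]
    mmpd(Mk)$delta_dep
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
})

test_that("decompose_image agrees pixel-for-pixel with the single-matrix path", {
  set.seed(31)
  mats <- list(gbm_M, non_gbm_M, composed_sample(0.5, 0.9, 0.3, 0.1, -0.05),
               diag(3))
  m <- array(NA_real_, c(2, 2, 9))
  for (i in 1:2) for (j in 1:2) {
    m[i, j, ] <- as.vector(t(mats[[(i - 1) * 2 + j]]))
  }
  img <- mueller_image(m)
  maps <- decompose_image(img)
  for (i in 1:2) for (j in 1:2) {
    M <- mats[[(i - 1) * 2 + j]]
    r <- mmpd(M)
    expect_equal(maps$D[i, j], r$D, tolerance = 1e-10)
    expect_equal(maps$one_minus_delta[i, j], r$one_minus_delta,
                 tolerance = 1e-10)
    expect_equal(maps$delta_ret[i, j], r$delta_ret, tolerance = 1e-10)
    expect_equal(maps$t[i, j], mmt_t(M)$t, tolerance = 1e-12)
    expect_equal(maps$t_plus[i, j], mmt_t(M, "plus")$t, tolerance = 1e-12)
  }
})

test_that("uniform images give constant parameter maps at the published values", {
  img <- uniform_mueller_image(non_gbm_M, 8, 8)
  maps <- decompose_image(img)
  expect_equal(unique(round(as.vector(maps$one_minus_delta), 6)),
               round(mmpd(non_gbm_M)$one_minus_delta, 6))
  maps_id <- decompose_image(uniform_mueller_image(diag(3), 4, 4))
  expect_true(all(maps_id$one_minus_delta == 0))
  expect_true(all(maps_id$t == 0))
})

test_that("invalid pixels propagate through decomposition", {
  img <- uniform_mueller_image(gbm_M, 3, 3)
  img$valid[1, 2] <- FALSE
  maps <- decompose_image(img)
  expect_false(maps$valid[1, 2])
  expect_true(is.na(maps$t[1, 2]))
  img$valid[] <- FALSE
  expect_error(decompose_image(img), "invalid")
})
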