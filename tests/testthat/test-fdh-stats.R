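fdh_area <- function(h) sum(h$heights * diff(h$bin_edges))

test_that("FDH is density-normalized with exact unit area", {
  h <- fdh(rep(0.5, 1000), bins = 10, range = c(0, 1))
  expect_equal(max(h$heights), 10)
  expect_equal(sum(h$heights != 0), 1)
  expect_equal(fdh_area(h), 1, tolerance = 1e-15)

  set.seed(5)
  for (k in 1:5) {
    v <- switch(k, rnorm(100), runif(3), rexp(1000), rnorm(10, 50, 10), 0.3)
    h <- fdh(v, bins = sample(1:300, 1))
    expect_equal(fdh_area(h), 1, tolerance = 1e-12)
    expect_equal(h$peak_h, max(h$heights))
  }
})

test_that("out-of-range values are clipped into edge bins, preserving area", {
  h <- fdh(c(-10, 0.5, 20), bins = 4, range = c(0, 1))
  expect_equal(fdh_area(h), 1, tolerance = 1e-15)
  expect_equal(h$heights, c(4, 0, 4, 4) / 3)
  expect_error(fdh(numeric(0)), "empty")
  expect_error(fdh(1, range = c(2, 2)), "lo < hi")
})

test_that("Gaussian FDH peak approaches the density maximum", {
  set.seed(1234)
  h <- fdh(rnorm(1e5), bins = 100, range = c(-5, 5))
  expect_equal(h$peak_h, 1 / sqrt(2 * pi), tolerance = 0.05)
})

test_that("central moment coefficients match closed-form cases", {
  v <- rep(c(-1, 1), 500)
  m <- cmc(v)
  expect_equal(m$P1, 0)
  expect_equal(m$P2, 1)
  expect_equal(m$P3, 0)
  expect_equal(m$P4, 1)

  set.seed(77)
  g <- cmc(rnorm(1e6))
  expect_equal(g$P1, 0, tolerance = 0.01)
  expect_equal(g$P2, 1, tolerance = 0.01)
  expect_equal(g$P3, 0, tolerance = 0.01)
  expect_equal(g$P4, 3, tolerance = 0.02)
})

test_that("constant samples report an explicit undefined sentinel", {
  m <- cmc(rep(0.32, 50))
  expect_equal(m$P2, 0)
  expect_false(m$defined)
  expect_true(is.na(m$P3) && is.na(m$P4))
  expect_error(cmc(1), "at least 2")
})

test_that("moments are permutation invariant and affine equivariant", {
  set.seed(8)
  v <- rexp(500)
  m1 <- cmc(v)
  m2 <- cmc(sample(v))
  expect_equal(m1[c("P1", "P2", "P3", "P4")], m2[c("P1", "P2", "P3", "P4")])
  # positive affine map: P3, P4 unchanged
  ma <- cmc(3 * v + 10)
  expect_equal(ma$P3, m1$P3, tolerance = 1e-12)
  expect_equal(ma$P4, m1$P4, tolerance = 1e-12)
  # negative scale flips the skewness sign only
  mn <- cmc(-2 * v)
  expect_equal(mn$P3, -m1$P3, tolerance = 1e-12)
  expect_equal(mn$P4, m1$P4, tolerance = 1e-12)
  # P4 >= P3^2 + 1 for any sample
  expect_gte(m1$P4, m1$P3^2 + 1)
})

test_that("binned moments converge to raw moments as bins grow", {
  set.seed(15)
  v <- rnorm(20000)
  raw <- cmc(v)
  errs <- vapply(c(10, 100, 1000), function(b) {
    w <- cmc(v, weighted_by_fdh = TRUE, bins = b)
    max(abs(c(w$P1 - raw$P1, w$P2 - raw$P2, w$P3 - raw$P3, w$P4 - raw$P4)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("fdh_report tabulates per element per ROI with recorded settings", {
  ph <- make_phantom(size = c(16, 16), noise_sd = 0)
  img <- reconstruct_mueller(ph$frames)
  rep <- fdh_report(img, ph$rois)
  expect_equal(nrow(rep), 16)
  expect_equal(unique(rep$element),
               c("m12", "m13", "m21", "m22", "m23", "m31", "m32", "m33"))
  g22 <- rep[rep$roi == "GBM" & rep$element == "m22", ]
  expect_equal(g22$P1, 0.32, tolerance = 1e-8)
  expect_equal(g22$P2, 0)        # constant region: undefined higher moments
  expect_true(is.na(g22$P3))
  expect_equal(g22$bins, 256)
  expect_error(fdh_report(img, list(empty = matrix(FALSE, 16, 16))), "empty")
})

test_that("injected element noise is recovered in P2", {
  set.seed(40)
  img <- uniform_mueller_image(non_gbm_M, 60, 60)
  img$m[, , 5] <- img$m[, , 5] + rnorm(3600, sd = 0.05)
  rep <- fdh_report(img, matrix(TRUE, 60, 60), elements = "m22")
  expect_equal(rep$P2, 0.0025, tolerance = 0.15)
})

test_that("rotation-insensitive parameters keep their CMCs under global rotation", {
  set.seed(55)
  h <- 12; w <- 12
  m <- array(NA_real_, c(h, w, 9))
  mr <- array(NA_real_, c(h, w, 9))
  phi <- 0.7
  for (i in seq_len(h)) for (j in seq_len(w)) {
    M <- composed_sample(runif(1, 0.3, 0.9), runif(1, 0.2, 1.4),
                         theta = runif(1, 0, pi))
    m[i, j, ] <- as.vector(t(M))
    mr[i, j, ] <- as.vector(t(rotate_sample(M, phi)))
  }
  maps <- decompose_image(mueller_image(m))
  maps_r <- decompose_image(mueller_image(mr))
  for (p in c("one_minus_delta", "t_plus")) {
    a <- cmc(maps[[p]][maps$valid])
    b <- cmc(maps_r[[p]][maps_r$valid])
    expect_equal(b$P1, a$P1, tolerance = 1e-9)
    expect_equal(b$P2, a$P2, tolerance = 1e-9)
    expect_equal(b$P3, a$P3, tolerance = 1e-6)
    expect_equal(b$P4, a$P4, tolerance = 1e-6)
  }
})
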