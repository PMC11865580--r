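test_that("least-squares sphere fit is exact on symmetric points", {
  p6 <- rbind(c(10, 0, 0), c(-10, 0, 0), c(0, 10, 0),
              c(0, -10, 0), c(0, 0, 10), c(0, 0, -10))
  f <- fit_sphere_lsq(p6)
  expect_equal(f$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(f$radius, 10, tolerance = 1e-12)

  f2 <- fit_sphere_lsq(sweep(p6, 2, c(5, -3, 2), `+`))
  expect_equal(f2$center, c(5, -3, 2), tolerance = 1e-9)
  expect_equal(f2$radius, 10, tolerance = 1e-9)
})

test_that("degenerate geometry raises errors", {
  set.seed(1)
  flat <- cbind(rnorm(6), rnorm(6), 0)
  expect_error(fit_sphere_lsq(flat), "degenerate")
  expect_error(fit_sphere_lsq(matrix(rnorm(9), 3, 3)), "degenerate")
  expect_error(fit_sphere_ransac(matrix(rnorm(9), 3, 3)), "degenerate")
  expect_error(fit_sphere_ransac(flat, max_iterations = 200),
               "no valid 4-point sample")
})

test_that("RANSAC recovers an exact sphere with full consensus", {
  set.seed(2)
  pts <- sphere_cloud(100, r = 10)
  f <- fit_sphere_ransac(pts, seed = 1)
  expect_equal(f$radius, 10, tolerance = 1e-6)
  expect_equal(length(f$inlier_indices), 100)
  expect_lt(f$inlier_rmse, 1e-6)
})

test_that("RANSAC separates noisy signal from outliers", {
  set.seed(3)
  pts <- sphere_cloud(80, r = 10, noise = 0.5, n_outliers = 20,
                      outlier_shift = 5)
  f <- fit_sphere_ransac(pts, threshold = 1.0, seed = 7)
  expect_gt(f$radius, 9.5)
  expect_lt(f$radius, 10.5)
  expect_setequal(f$inlier_indices, 1:80)
  expect_lte(f$inlier_rmse, 1.0)
})

test_that("RANSAC agrees with exhaustive 4-subset enumeration", {
  for (s in 1:4) {
    set.seed(s)
    signal <- sphere_cloud(8, r = 10)                # exact inliers
    clutter <- matrix(rnorm(12, sd = 2), 4, 3) +
      matrix(c(0, 0, 16), 4, 3, byrow = TRUE)        # > 3 A off-sphere
    pts <- rbind(signal, clutter)
    oracle <- brute_force_sphere_inliers(pts, threshold = 1.0)
    f <- fit_sphere_ransac(pts, threshold = 1.0,
                           max_iterations = 100000, seed = s)
    expect_setequal(f$inlier_indices, oracle$inl)
    expect_setequal(f$inlier_indices, 1:8)
  }
})

test_that("identical seeds give bit-identical fits", {
  set.seed(4)
  pts <- sphere_cloud(60, r = 15, noise = 0.4, n_outliers = 10)
  f1 <- fit_sphere_ransac(pts, seed = 42)
  f2 <- fit_sphere_ransac(pts, seed = 42)
  expect_identical(f1$center, f2$center)
  expect_identical(f1$radius, f2$radius)
  expect_identical(f1$inlier_indices, f2$inlier_indices)
})

test_that("fits are rigid-motion invariant and scale with similarity", {
  set.seed(5)
  pts <- sphere_cloud(50, r = 12, noise = 0.3, n_outliers = 8)
  f <- fit_sphere_ransac(pts, seed = 9)
  moved <- pts %*% t(rot_xyz(0.4, 1.0, -0.7)) +
    matrix(c(3, -8, 1), nrow(pts), 3, byrow = TRUE)
  fm <- fit_sphere_ransac(moved, seed = 9)
  expect_equal(fm$radius, f$radius, tolerance = 1e-6)
  expect_setequal(fm$inlier_indices, f$inlier_indices)

  fs <- fit_sphere_ransac(pts * 2, threshold = 2.0, seed = 9)
  expect_equal(fs$radius, 2 * f$radius, tolerance = 1e-6)
})

test_that("the inner-product sign test separates pockets from bulges", {
  set.seed(6)
  # pocket: patch on the inner wall of a shell; the body sits beyond the
  # patch, the fitted center on the opposite (open) side
  patch <- sphere_cloud(40, r = 10, cap_angle = 60)    # cap around +z
  body <- matrix(rnorm(150, sd = 3), 50, 3)
  body[, 3] <- body[, 3] + 16                          # body above the patch
  f <- fit_sphere_lsq(patch)
  sg <- surface_sign(body, patch, f$center)
  expect_equal(sg$sign, -1L)

  # mirrored: the patch bulges outward toward the body's far side
  body2 <- body; body2[, 3] <- -body2[, 3] + 4
  sg2 <- surface_sign(body2, patch, f$center)
  expect_equal(sg2$sign, 1L)

  expect_error(surface_sign(patch, patch, f$center), "indeterminate")
})

test_that("signed convexity is the signed reciprocal radius", {
  set.seed(7)
  patch <- sphere_cloud(60, r = 20, cap_angle = 55, noise = 0.1)
  body <- matrix(rnorm(240, sd = 4), 80, 3)
  body[, 3] <- body[, 3] + 30
  m <- mk_model(rbind(patch, body), chain = "A")
  cv <- signed_convexity(m, "A", seq_len(nrow(patch)), seed = 1)
  expect_equal(cv$sign, -1L)
  expect_equal(abs(cv$signed_convexity), 1 / cv$radius)
  expect_equal(cv$signed_convexity, -0.05, tolerance = 0.15)

  # similarity scaling halves the convexity
  m2 <- mk_model(rbind(patch, body) * 2, chain = "A")
  cv2 <- signed_convexity(m2, "A", seq_len(nrow(patch)), threshold = 2,
                          seed = 1)
  expect_equal(cv2$signed_convexity, cv$signed_convexity / 2,
               tolerance = 0.02)
})

test_that("noisy patches recover the generating curvature within 10%", {
  radii <- c(10, 15, 25, 40)
  n_trials <- 50
  hits <- 0; total <- 0
  for (r in radii) {
    for (s in seq_len(n_trials)) {
      set.seed(1000 * r + s)
      pts <- sphere_cloud(60, r = r, noise = 0.3, cap_angle = 70)
      f <- fit_sphere_ransac(pts, seed = s, max_iterations = 2000)
      total <- total + 1
      if (abs(1 / f$radius - 1 / r) <= 0.1 / r) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("interface profiling reports signs, areas and counts in one record", {
  bs <- make_ball_socket()
  prof <- profile_interface(bs, "A", "B", ransac_iterations = 20000,
                            seed = 1)
  expect_s3_class(prof, "interface_profile")
  expect_equal(prof$sign_a, -1L)  # socket is concave
  expect_equal(prof$sign_b, 1L)   # ball is convex
  expect_equal(prof$radius_a, 10, tolerance = 0.05)
  expect_equal(prof$radius_b, 6, tolerance = 0.05)
  expect_gt(prof$buried_total, 0)
  expect_equal(prof$buried_total, prof$buried_polar + prof$buried_apolar,
               tolerance = 1e-9)

  path <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  tab <- read.delim(path)
  expect_equal(tab$convexity_a, prof$convexity_a, tolerance = 1e-9)
})

test_that("partners with too few interfacial atoms yield NA convexity", {
  m <- mk_model(matrix(c(0, 0, 0, 25, 0, 0), 2, 3, byrow = TRUE),
                chain = c("A", "B"))
  w <- capture_warnings(prof <- profile_interface(m, "A", "B"))
  expect_length(w, 2)
  expect_match(w, "fewer than 4", all = TRUE)
  expect_true(is.na(prof$convexity_a))
  expect_true(is.na(prof$convexity_b))
  expect_equal(prof$n_interfacial_a, 0)
})
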