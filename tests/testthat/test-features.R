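test_that("sampling a sphere mesh gives near-constant ray lengths", {
  sph <- build_hemisphere(12)
  s <- sample_mesh(icosphere_mesh(16, radius = 70), sph, subject_id = "ball",
                   class_label = "healthy")
  expect_length(s$lengths, 751L)
  expect_false(s$mirrored)
  expect_lt(max(abs(s$lengths - 70) / 70), 0.005)
})

test_that("miss policies: error aborts with the ray index, fill averages neighbors, na passes through", {
  sph <- build_hemisphere(4)
  mesh <- icosphere_mesh(8, radius = 40)
  # carve away the top cap so upward rays miss
  keep_v <- mesh$vertices[, 3] < 35
  keep <- keep_v[mesh$faces[, 1]] & keep_v[mesh$faces[, 2]] & keep_v[mesh$faces[, 3]]
  holed <- triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
  expect_error(sample_mesh(holed, sph, miss = "error"), "missed the mesh at index")
  s_na <- sample_mesh(holed, sph, miss = "na")
  expect_true(anyNA(s_na$lengths))
  s_fill <- sample_mesh(holed, sph, miss = "fill")
  expect_false(anyNA(s_fill$lengths))
  # filled rays are plausible (between the polar cut radius and the sphere)
  filled <- which(is.na(s_na$lengths))
  expect_true(all(s_fill$lengths[filled] > 30 & s_fill$lengths[filled] < 41))
})

test_that("mirroring is a linked involution", {
  sph <- build_hemisphere(12)
  s <- sample_mesh(icosphere_mesh(8, radius = 55), sph, subject_id = "S42",
                   class_label = "trigonocephaly")
  m <- mirror_sample(s, sph)
  expect_true(m$mirrored)
  expect_identical(m$subject_id, "S42")
  expect_identical(m$class_label, "trigonocephaly")
  back <- mirror_sample(m, sph)
  expect_identical(back$lengths, s$lengths)
  expect_false(back$mirrored)
  short <- shape_sample("x", "healthy", s$lengths[1:10])
  expect_error(mirror_sample(short, sph), "751")
})

test_that("the scaler standardizes its own fitting set to mean 0 / sd 1", {
  set.seed(8)
  X <- matrix(rexp(20 * 50) + 1, 20)
  sc <- fit_scaler(X)
  Z <- apply_scaler(X, sc)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  pop_sd <- sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2))
  expect_lt(max(abs(pop_sd - 1)), 1e-9)
  # two-point case: mean 15, population sd 5
  sc2 <- fit_scaler(rbind(rep(10, 5), rep(20, 5)))
  expect_equal(unname(sc2$mean), rep(15, 5))
  expect_equal(unname(sc2$sd), rep(5, 5))
  # the mean vector maps to zero; mean + sd maps to one
  expect_equal(unname(apply_scaler(sc$mean, sc)), rep(0, 50))
  expect_equal(unname(apply_scaler(sc$mean + sc$sd, sc)), rep(1, 50))
})

test_that("scaler degenerate and error cases", {
  expect_error(fit_scaler(matrix(1, 1, 3)), "at least 2")
  expect_warning(sc <- fit_scaler(rbind(c(1, 5), c(1, 9))), "clamped")
  expect_equal(sc$sd[1], 1e-12)
  sc2 <- suppressWarnings(fit_scaler(rbind(c(1, 5), c(1, 9))))
  expect_error(apply_scaler(matrix(0, 2, 3), sc2), "does not match")
})

test_that("standardization is affine-invertible", {
  set.seed(3)
  X <- matrix(runif(10 * 30, 40, 90), 10)
  sc <- fit_scaler(X)
  expect_lt(max(abs(invert_scaler(apply_scaler(X, sc), sc) - X)), 1e-9)
})

test_that("fitting on a size-varying population removes global scale", {
  # scaler fitted on same-shape heads of varying size, so the per-ray spread
  # is size-driven; the same head at two sizes then standardizes to nearly
  # identical vectors
  sph <- build_hemisphere(12)
  scales <- seq(55, 75, length.out = 12)
  pop <- t(vapply(seq_along(scales), function(i) {
    m <- generate_head(subtype_params("healthy", 0, scale_mm = scales[i],
                                      seed = 500 + i, frequency = 8))
    sample_mesh(m, sph)$lengths
  }, numeric(751)))
  sc <- fit_scaler(pop)
  p_small <- subtype_params("scaphocephaly", 0.8, scale_mm = 56, seed = 999,
                            frequency = 8)
  p_large <- subtype_params("scaphocephaly", 0.8, scale_mm = 74, seed = 999,
                            frequency = 8)
  z1 <- apply_scaler(sample_mesh(generate_head(p_small), sph)$lengths, sc)
  z2 <- apply_scaler(sample_mesh(generate_head(p_large), sph)$lengths, sc)
  expect_gt(cor(z1, z2), 0.99)
})

test_that("cohort feature tables round-trip through CSV", {
  fix <- local_small_cohort()
  feats <- fix$features
  expect_equal(nrow(feats$lengths), 2L * nrow(fix$cohort$manifest))
  expect_true(all(table(feats$subject_id) == 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(feats, path)
  back <- read_features(path)
  expect_equal(unname(back$lengths), unname(feats$lengths), tolerance = 1e-12)
  expect_identical(back$subject_id, feats$subject_id)
  expect_identical(back$mirrored, feats$mirrored)
})

test_that("scaler statistics round-trip through JSON", {
  sc <- fit_scaler(matrix(runif(6 * 20, 40, 90), 6))
  path <- withr::local_tempfile(fileext = ".json")
  write_scaler(sc, path)
  back <- read_scaler(path)
  expect_equal(back$mean, unname(sc$mean))
  expect_equal(back$sd, unname(sc$sd))
})
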