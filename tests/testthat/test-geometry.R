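test_that("geodesic hemisphere has the expected direction counts", {
  # full sphere 10 f^2 + 2, equator ring 5 f -> hemisphere 5 f^2 + 5 f / 2 + 1
  sph12 <- build_hemisphere(12)
  expect_equal(sph12$n, 751L)
  expect_equal(nrow(sph12$directions), 751L)
  sph2 <- build_hemisphere(2)
  expect_equal(sph2$n, 26L)
  for (f in c(2L, 4L, 6L)) {
    expect_equal(build_hemisphere(f)$n, 5L * f^2 + 5L * f %/% 2L + 1L)
  }
  expect_error(build_hemisphere(11), "equatorial ring")
  expect_error(build_hemisphere(12, n_expected = 750), "750")
})

test_that("hemisphere directions are unit norm on the closed upper hemisphere", {
  for (f in c(2L, 6L, 12L)) {
    sph <- build_hemisphere(f)
    expect_lt(max(abs(sqrt(rowSums(sph$directions^2)) - 1)), 1e-9)
    expect_true(all(sph$directions[, 3] >= -1e-9))
    # equatorial ring present: exactly 5 f directions with z ~ 0
    expect_equal(sum(abs(sph$directions[, 3]) < 1e-9), 5L * f)
  }
})

test_that("hemisphere construction is deterministic and canonically ordered", {
  a <- build_hemisphere(12)
  b <- build_hemisphere(12)
  expect_identical(a$directions, b$directions)
  expect_identical(a$mirror_perm, b$mirror_perm)
  # z non-increasing; azimuth increasing within equal-z runs
  z <- a$directions[, 3]
  expect_true(all(diff(z) <= 1e-12))
})

test_that("mirror permutation is an involution matching x-negation", {
  for (f in c(2L, 12L)) {
    sph <- build_hemisphere(f)
    p <- sph$mirror_perm
    expect_identical(p[p], seq_len(sph$n))
    refl <- sph$directions
    refl[, 1] <- -refl[, 1]
    expect_lt(max(abs(refl - sph$directions[p, ])), 1e-9)
  }
})

test_that("frequency-12 hemisphere has 25 directions on the mid-sagittal plane", {
  # brute-force oracle: count directions with |x| < 1e-6, then check the
  # permutation's fixed points agree
  sph <- build_hemisphere(12)
  n_plane <- sum(abs(sph$directions[, 1]) < 1e-6)
  expect_equal(n_plane, 25L)
  expect_equal(sum(sph$mirror_perm == seq_len(sph$n)), n_plane)
})

test_that("mirror permutation handles simple direction sets and bad input", {
  expect_equal(compute_mirror_permutation(matrix(c(0, 0, 1), 1)), 1L)
  d <- rbind(c(0.6, 0, 0.8), c(-0.6, 0, 0.8))
  expect_equal(compute_mirror_permutation(d), c(2L, 1L))
  bad <- rbind(c(0.6, 0, 0.8), c(0, 0, 1))
  expect_error(compute_mirror_permutation(bad), "mirror partner")
})

test_that("raycast matches closed-form sphere and ellipsoid distances", {
  sph <- build_hemisphere(12)
  mesh <- icosphere_mesh(16, radius = 50)
  lens <- sample_mesh(mesh, sph)$lengths
  expect_lt(max(abs(lens - 50) / 50), 0.005)

  ab <- c(60, 80, 55)
  emesh <- ellipsoid_mesh(ab[1], ab[2], ab[3], frequency = 16)
  elens <- sample_mesh(emesh, sph)$lengths
  oracle <- apply(sph$directions, 1, ellipsoid_ray_length,
                  a = ab[1], b = ab[2], c_ = ab[3])
  expect_lt(max(abs(elens - oracle) / oracle), 0.005)
  # the ray nearest +y sees the b semi-axis
  iy <- which.max(sph$directions[, 2])
  expect_equal(elens[iy], 80, tolerance = 0.005)
})

test_that("single-ray intersection returns the farthest hit and NA on a miss", {
  mesh <- icosphere_mesh(8, radius = 30)
  # origin inside, one crossing
  expect_equal(ray_mesh_intersect(mesh, c(0, 0, 0), c(0, 0, 1)), 30, tolerance = 0.01)
  # origin outside looking through the sphere: farthest crossing is the back wall
  t_far <- ray_mesh_intersect(mesh, c(0, 0, -100), c(0, 0, 1))
  expect_equal(t_far, 130, tolerance = 0.01)
  # open half-mesh with a hole at the pole
  keep <- mesh$vertices[mesh$faces[, 1], 3] < 25 &
    mesh$vertices[mesh$faces[, 2], 3] < 25 &
    mesh$vertices[mesh$faces[, 3], 3] < 25
  open_mesh <- triangle_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
  expect_true(is.na(ray_mesh_intersect(open_mesh, c(0, 0, 0), c(0, 0, 1))))
  expect_error(ray_mesh_intersect(mesh, c(0, 0, 0), c(0, 0, 2)), "unit")
})

test_that("degenerate triangles are skipped, not fatal", {
  mesh <- icosphere_mesh(4, radius = 10)
  v <- rbind(mesh$vertices, c(0, 0, 20), c(0, 0, 20))
  nv <- nrow(v)
  f <- rbind(mesh$faces, c(nv - 1L, nv, nv - 1L))  # zero-area triangle
  degen <- triangle_mesh(v, f)
  expect_equal(ray_mesh_intersect(degen, c(0, 0, 0), c(0, 0, 1)), 10,
               tolerance = 0.02)
})

test_that("ray lengths of an x-symmetric mesh are invariant under the mirror permutation", {
  sph <- build_hemisphere(12)
  emesh <- ellipsoid_mesh(60, 80, 55, frequency = 16)   # symmetric about x = 0
  lens <- sample_mesh(emesh, sph)$lengths
  expect_lt(max(abs(lens - lens[sph$mirror_perm])), 1e-6)
})
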