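test_that("severity 0 reproduces the healthy shape for every class", {
  base <- generate_head(subtype_params("healthy", 0, scale_mm = 62, seed = 5,
                                       frequency = 8))
  for (cl in setdiff(cranio_classes(), "healthy")) {
    m <- generate_head(subtype_params(cl, 0, scale_mm = 62, seed = 5,
                                      frequency = 8))
    expect_identical(m$vertices, base$vertices)
    expect_identical(m$faces, base$faces)
  }
})

test_that("scaphocephaly lowers the cephalic index", {
  ci <- function(m) diff(range(m$vertices[, 1])) / diff(range(m$vertices[, 2]))
  m0 <- generate_head(subtype_params("scaphocephaly", 0, scale_mm = 65,
                                     seed = 9, frequency = 8))
  m1 <- generate_head(subtype_params("scaphocephaly", 1, scale_mm = 65,
                                     seed = 9, frequency = 8))
  expect_lt(ci(m1), ci(m0))
  # healthy near 0.80; full severity scales width by 0.85 and length by 1.25,
  # so the index drops to about 0.8 * 0.85 / 1.25 = 0.544
  expect_equal(ci(m0), 0.80, tolerance = 0.05)
  expect_gt(ci(m1), 0.50)
  expect_lt(ci(m1), 0.60)
})

test_that("plagiocephaly flattens the anterior-right octant", {
  sph <- build_hemisphere(12)
  right <- sph$directions[, 1] > 0.05 & sph$directions[, 2] > 0.05 &
    sph$directions[, 3] > 0.05
  octant_vols <- function(mesh) {
    v <- sample_mesh(mesh, sph)$lengths
    c(right = sum(v[right]^3), left = sum(v[sph$mirror_perm][right]^3))
  }
  plag <- octant_vols(generate_head(subtype_params("plagiocephaly", 1,
                                                   scale_mm = 65, seed = 13)))
  heal <- octant_vols(generate_head(subtype_params("healthy", 0,
                                                   scale_mm = 65, seed = 13)))
  expect_lt(plag["right"], plag["left"] * 0.9)
  expect_lt(abs(heal["right"] - heal["left"]) / heal["left"], 0.02)
})

test_that("plagiocephaly at severity >= 0.5 breaks mirror symmetry well above the noise floor", {
  sph <- build_hemisphere(12)
  asym <- function(cl, s, seed) {
    v <- sample_mesh(generate_head(subtype_params(cl, s, scale_mm = 65,
                                                  seed = seed)), sph)$lengths
    sqrt(sum((v - v[sph$mirror_perm])^2))
  }
  noise_floor <- mean(vapply(21:24, function(sd) asym("healthy", 0, sd), 1))
  plag <- vapply(21:24, function(sd) asym("plagiocephaly", 0.5, sd), 1)
  expect_true(all(plag >= 3 * noise_floor))
})

test_that("generated heads are watertight and contain the origin", {
  dirs <- rbind(c(0.0480, 0.1443, 0.9884), c(-0.0480, -0.1443, -0.9884),
                c(0.7071, 0.7071, 0), c(0, -0.6, 0.8))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (cl in cranio_classes()) {
    m <- generate_head(subtype_params(cl, 0.8, scale_mm = 60, seed = 31,
                                      frequency = 8))
    hits <- craniorays:::raycast_all(m, dirs)$hits
    # odd crossing parity in every direction => closed surface, origin inside
    expect_true(all(hits %% 2 == 1), info = cl)
  }
})

test_that("cohorts are deterministic with the documented per-subject seed scheme", {
  spec <- cohort_spec(counts = c(2, 2, 2, 2), seed = 77, frequency = 4)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$meshes, b$meshes)
  expect_equal(a$manifest$seed, 77 * 10000 + seq_len(8))
  expect_equal(nrow(a$manifest), 8L)
  expect_equal(as.vector(table(factor(a$manifest$class,
                                      levels = cranio_classes()))),
               c(2L, 2L, 2L, 2L))
  expect_false(any(duplicated(a$manifest$subject_id)))
  # a single subject regenerated in isolation matches the cohort mesh
  i <- 5L
  solo <- generate_head(subtype_params(a$manifest$class[i],
                                       severity = a$manifest$severity[i],
                                       scale_mm = a$manifest$scale_mm[i],
                                       seed = a$manifest$seed[i],
                                       frequency = 4))
  expect_identical(solo$vertices, a$meshes[[i]]$vertices)
})

test_that("the default cohort specification matches the study composition", {
  spec <- cohort_spec()
  expect_equal(sum(spec$counts), 196L)
  expect_equal(unname(spec$counts), c(53L, 76L, 40L, 27L))
  manifest <- generate_cohort(spec, meshes = FALSE)$manifest
  expect_equal(nrow(manifest), 196L)
  expect_true(all(manifest$severity[manifest$class == "healthy"] == 0))
  pat <- manifest$severity[manifest$class != "healthy"]
  expect_true(all(pat >= 0.5 & pat <= 1))
})
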