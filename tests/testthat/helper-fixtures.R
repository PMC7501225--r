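# Shared fixtures, built in code.

# unit tetrahedron: 4 vertices, 4 faces, outward-wound
tetrahedron_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# axis-aligned ellipsoid mesh by scaling a geodesic sphere
ellipsoid_mesh <- function(a, b, c_, frequency = 16) {
  m <- icosphere_mesh(frequency)
  m$vertices <- m$vertices %*% diag(c(a, b, c_))
  m
}

# closed-form distance from the origin to an ellipsoid surface along `dir`
ellipsoid_ray_length <- function(dir, a, b, c_) {
  1 / sqrt((dir[1] / a)^2 + (dir[2] / b)^2 + (dir[3] / c_)^2)
}

# small cohort + features, memoised across test files (built on first use)
local_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(counts = c(healthy = 6, scaphocephaly = 6,
                                     trigonocephaly = 6, plagiocephaly = 6),
                          seed = 2024, frequency = 8)
      cohort <- generate_cohort(spec)
      sphere <- build_hemisphere(12)
      cache <<- list(cohort = cohort, sphere = sphere,
                     features = cohort_features(cohort, sphere))
    }
    cache
  }
})
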