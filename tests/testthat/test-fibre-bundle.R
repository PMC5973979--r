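test_that("lattice generation is deterministic, dense and collision-free", {
  lat1 <- generate_fibre_lattice(1000, 100, jitter_frac = 0.3, seed = 7)
  lat2 <- generate_fibre_lattice(1000, 100, jitter_frac = 0.3, seed = 7)
  expect_identical(lat1$positions, lat2$positions)
  # count within +/-5% of the target, all inside the disc, no collisions
  expect_lt(abs(lat1$n_fibres - 1000), 50)
  d <- sqrt((lat1$positions[, 1] - lat1$fov_center[1])^2 +
            (lat1$positions[, 2] - lat1$fov_center[2])^2)
  expect_true(all(d <= lat1$fov_radius))
  expect_gt(min(dist(lat1$positions)), 0)
  lat3 <- generate_fibre_lattice(1000, 100, jitter_frac = 0.3, seed = 8)
  expect_false(identical(lat1$positions, lat3$positions))
})

test_that("zero-jitter lattice is a clean hexagonal packing", {
  lat <- generate_fibre_lattice(3, 10, jitter_frac = 0, seed = 1)
  expect_gte(lat$n_fibres, 3L)
  d <- sqrt((lat$positions[, 1] - lat$fov_center[1])^2 +
            (lat$positions[, 2] - lat$fov_center[2])^2)
  expect_true(all(d <= 10))
  # neighbour spacing equals the hexagonal pitch
  lat2 <- generate_fibre_lattice(200, 60, jitter_frac = 0, seed = 1)
  nn <- apply(as.matrix(dist(lat2$positions)) +
                diag(Inf, lat2$n_fibres), 1, min)
  expect_equal(unname(nn), rep(lat2$generator_params$pitch, lat2$n_fibres),
               tolerance = 1e-6)
})

test_that("lattice argument validation", {
  expect_error(generate_fibre_lattice(2, 10), "at least 3")
  expect_error(generate_fibre_lattice(10, 10, jitter_frac = 0.7), "jitter_frac")
  expect_error(generate_fibre_lattice(10, -1), "positive")
  expect_error(fibre_lattice(rbind(c(1, 1), c(1, 1), c(2, 2)), c(1, 1), 5),
               "distinct")
})

test_that("nearest-fibre map is the perpendicular-bisector split for 2+1 fibres", {
  # two fibres on a horizontal line; a third far away, outside the grid's FoV
  # influence, to satisfy the 3-fibre minimum
  lat <- fibre_lattice(rbind(c(10, 4), c(10, 16), c(19.8, 10)), c(10, 10), 10)
  pa <- nearest_fibre_map(lat, c(20, 20))
  idx <- pa$index
  inside <- !is.na(idx)
  # columns strictly left of the bisector at col 10 belong to fibre 1
  for (r in 1:20) for (c in 1:20) {
    if (!inside[r, c]) next
    d <- c((r - 10)^2 + (c - 4)^2, (r - 10)^2 + (c - 16)^2, (r - 19.8)^2 + (c - 10)^2)
    expect_identical(idx[r, c], which(d == min(d))[1])
  }
})

test_that("nearest-fibre map matches the exhaustive oracle and partitions the FoV", {
  for (seed in 1:3) {
    lat <- random_lattice(50, 28, seed)
    pa <- nearest_fibre_map(lat, c(64, 64))
    expect_identical(pa$index, bf_nearest_map(lat, c(64, 64)))
    # partition: in-FoV pixels all assigned, assignments within range
    m <- fov_mask(lat, c(64, 64))
    expect_identical(!is.na(pa$index), m)
    expect_true(all(pa$index[m] >= 1L & pa$index[m] <= lat$n_fibres))
  }
})

test_that("triangulation handles canonical small cases", {
  lat3 <- fibre_lattice(rbind(c(2, 2), c(2, 8), c(8, 5)), c(5, 5), 6)
  tri <- triangulate(lat3)
  expect_identical(dim(tri$simplices), c(1L, 3L))
  expect_setequal(as.integer(tri$simplices), 1:3)
  # square: two simplices sharing one diagonal
  lat4 <- fibre_lattice(rbind(c(2, 2), c(2, 8), c(8, 8), c(8, 2)), c(5, 5), 6)
  tri4 <- triangulate(lat4)
  expect_identical(nrow(tri4$simplices), 2L)
  shared <- intersect(tri4$simplices[1, ], tri4$simplices[2, ])
  expect_length(shared, 2L)
  # collinear input is degenerate
  latc <- fibre_lattice(cbind(c(2, 5, 8), c(2, 5, 8)), c(5, 5), 6)
  expect_error(triangulate(latc), "collinear|degenerate")
})

test_that("every Delaunay simplex has an empty circumcircle", {
  lat <- random_lattice(200, 80, seed = 42)
  tri <- triangulate(lat)
  expect_true(bf_delaunay_ok(lat$positions, tri$simplices, tol = 1e-8))
  # and on a perturbed-hexagonal lattice with co-circular tendencies
  lat2 <- generate_fibre_lattice(300, 70, jitter_frac = 0.05, seed = 5)
  tri2 <- triangulate(lat2)
  expect_true(bf_delaunay_ok(lat2$positions, tri2$simplices, tol = 1e-7))
})

test_that("fov_mask matches the analytic disc", {
  lat <- generate_fibre_lattice(100, 1000, fov_center = c(16, 16), seed = 1)
  expect_true(all(fov_mask(lat, c(32, 32))))  # radius exceeds the grid
  lat2 <- fibre_lattice(rbind(c(250, 250), c(250, 270), c(270, 250)),
                        c(256.5, 256.5), 0.4 * 512)
  m <- fov_mask(lat2, c(512, 512))
  expect_lt(abs(sum(m) - pi * (0.4 * 512)^2) / (pi * (0.4 * 512)^2), 0.01)
  # pixel at the center is inside
  expect_true(m[256, 256])
})

test_that("lattice JSON serialization round-trips exactly", {
  lat <- generate_fibre_lattice(150, 40, jitter_frac = 0.25, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_lattice(lat, f)
  lat2 <- read_lattice(f)
  expect_identical(lat2$positions, unname(lat$positions))
  expect_identical(lat2$fov_radius, lat$fov_radius)
  expect_identical(lat2$fov_center, lat$fov_center)
  expect_identical(lat2$seed, lat$seed)
})
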