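test_that("radial_vector normalizes the center-to-location direction", {
  model <- toy_model()
  expect_equal(radial_vector(c(0, 0, 50), model), c(0, 0, 1))
  expect_equal(radial_vector(c(3, 4, 0), model), c(0.6, 0.8, 0))
  set.seed(1)
  for (i in 1:20) {
    loc <- rnorm(3, sd = 40)
    expect_equal(sqrt(sum(radial_vector(loc, model)^2)), 1, tolerance = 1e-12)
  }
  expect_error(radial_vector(c(0, 0, 0), model), "center")
})

test_that("nearest interface point matches a brute-force vertex scan", {
  model <- toy_model()
  v <- model$gw_mesh$vertices
  # a location coincident with a vertex is its own nearest point
  hit <- nearest_interface_point(v[17, ], model)
  expect_equal(hit$index, 17L)
  expect_equal(hit$dist, 0)
  set.seed(7)
  locs <- matrix(rnorm(3 * 60, sd = 45), ncol = 3)
  got <- nearest_interface_point(locs, model)
  for (i in seq_len(nrow(locs))) {
    oracle <- brute_nearest(locs[i, ], v)
    expect_equal(got$index[i], oracle$index)
    expect_equal(got$dist[i], oracle$dist, tolerance = 1e-9)
  }
})

test_that("nearest-vertex ties break to the lowest vertex index", {
  mesh <- trimesh(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 3, 4), c(2, 3, 4), c(1, 2, 3), c(1, 2, 4)))
  regions <- data.frame(region_id = 1L, name = "r", hemisphere = "midline",
                        tissue = "subcortical", volume_mm3 = 1,
                        paired_region_id = NA_integer_)
  model <- brain_model(regions, mesh, mesh, exclusion_radius = 0)
  # the origin is equidistant from all four vertices
  expect_equal(nearest_interface_point(c(0, 0, 0), model)$index, 1L)
})

test_that("vertex normals of a sphere are radial and unit length", {
  s <- icosphere(2)
  lens <- sqrt(rowSums(s$normals^2))
  expect_equal(lens, rep(1, nrow(s$normals)), tolerance = 1e-12)
  # for a sphere mesh the area-weighted normal is parallel to the vertex
  cosang <- rowSums(s$normals * s$vertices)
  expect_true(all(cosang > 0.99))
})

test_that("feature geometry: trivial parallel and tangent cases", {
  model <- toy_model()
  v <- model$gw_mesh$vertices
  n <- model$gw_mesh$normals
  # event on the interface with direction parallel to the local normal
  ev <- data.frame(x_mm = v[5, 1], y_mm = v[5, 2], z_mm = v[5, 3],
                   dx = n[5, 1], dy = n[5, 2], dz = n[5, 3])
  f <- compute_features(ev, model)
  expect_equal(f$f1, 1, tolerance = 1e-9)
  expect_equal(f$f3, 0)
  # perfect sphere: radial normal, so a tangent direction gives f1 = 0, f2 = 1
  s <- icosphere(2)
  sphere <- trimesh(60 * s$vertices, s$faces)
  regions <- model$regions
  smodel <- brain_model(regions, sphere, trimesh(63 * s$vertices, s$faces))
  u <- unit(sphere$vertices[40, ])        # query at a mesh vertex
  tang <- unit(cross3(u, c(0, 0, 1)))     # orthogonal to u
  loc <- 60 * u
  ev2 <- data.frame(x_mm = loc[1], y_mm = loc[2], z_mm = loc[3],
                    dx = tang[1], dy = tang[2], dz = tang[3])
  f2 <- compute_features(ev2, smodel)
  nv <- smodel$gw_mesh$normals[40, ]
  expect_equal(f2$f1, sum(tang * nv), tolerance = 1e-9)
  expect_lt(abs(f2$f1), 0.05)       # tangent to a (faceted) sphere
  expect_gt(f2$f2, 0.99)            # radial normal
  expect_error(compute_features(
    data.frame(x_mm = 0, y_mm = 0, z_mm = 0, dx = 1, dy = 0, dz = 0), model),
    "sphere center")
})

test_that("all four features match brute-force recomputation from vertices", {
  model <- toy_model()
  set.seed(21)
  sim <- small_cohort()
  ev <- sim$events[sample(nrow(sim$events), 40), ]
  f <- compute_features(ev, model)
  gw <- model$gw_mesh$vertices
  pial <- model$pial_mesh$vertices
  for (i in seq_len(nrow(ev))) {
    p <- as.numeric(ev[i, c("x_mm", "y_mm", "z_mm")])
    d <- as.numeric(ev[i, c("dx", "dy", "dz")])
    near <- brute_nearest(p, gw)
    nv <- model$gw_mesh$normals[near$index, ]
    expect_equal(f$f1[i], sum(d * nv), tolerance = 1e-9)
    expect_equal(f$f2[i], sum(unit(p) * nv), tolerance = 1e-9)
    expect_equal(f$f3[i], near$dist, tolerance = 1e-9)
    expect_equal(f$f4[i], brute_nearest(gw[near$index, ], pial)$dist,
                 tolerance = 1e-9)
  }
})

test_that("f1 and f2 are invariant under joint rigid rotation", {
  model <- toy_model()
  sim <- small_cohort()
  set.seed(3)
  ev <- sim$events[sample(nrow(sim$events), 25), ]
  f0 <- compute_features(ev, model)
  rot <- rotation_matrix(c(1, -2, 0.5), 0.83)
  rmesh <- function(m) trimesh(m$vertices %*% t(rot), m$faces)
  rmodel <- brain_model(model$regions, rmesh(model$gw_mesh),
                        rmesh(model$pial_mesh))
  loc <- as.matrix(ev[, c("x_mm", "y_mm", "z_mm")]) %*% t(rot)
  dir <- as.matrix(ev[, c("dx", "dy", "dz")]) %*% t(rot)
  rev_ <- data.frame(x_mm = loc[, 1], y_mm = loc[, 2], z_mm = loc[, 3],
                     dx = dir[, 1], dy = dir[, 2], dz = dir[, 3])
  f1 <- compute_features(rev_, rmodel)
  expect_equal(f1$f1, f0$f1, tolerance = 1e-6)
  expect_equal(f1$f2, f0$f2, tolerance = 1e-6)
  expect_equal(f1$f3, f0$f3, tolerance = 1e-6)
  expect_equal(f1$f4, f0$f4, tolerance = 1e-6)
})

test_that("parcellation validation enforces pairing and volume invariants", {
  regions <- toy_model()$regions
  expect_silent(validate_parcellation(regions))
  bad <- regions
  bad$volume_mm3[1] <- -5
  expect_error(validate_parcellation(bad), "volume")
  bad <- regions
  bad$paired_region_id[1] <- bad$region_id[2]  # cortex paired to cortex
  expect_error(validate_parcellation(bad))
  bad <- regions
  bad$region_id[2] <- bad$region_id[1]
  expect_error(validate_parcellation(bad), "unique")
})

test_that("OFF and PLY round-trips preserve mesh geometry", {
  m <- toy_model()$gw_mesh
  off <- tempfile(fileext = ".off")
  ply <- tempfile(fileext = ".ply")
  write_off(m, off)
  write_ply(m, ply)
  m_off <- read_mesh(off)
  m_ply <- read_mesh(ply)
  expect_equal(m_off$vertices, m$vertices, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(m_off$faces, m$faces, ignore_attr = TRUE)
  expect_equal(m_ply$vertices, m$vertices, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(m_ply$faces, m$faces, ignore_attr = TRUE)
  # hand-built minimal OFF fixture
  tf <- tempfile(fileext = ".off")
  writeLines(c("OFF", "3 1 0", "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), tf)
  tri <- read_off(tf)
  expect_equal(nrow(tri$vertices), 3)
  expect_equal(tri$faces, matrix(c(1L, 2L, 3L), 1), ignore_attr = TRUE)
})
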