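test_that("hull volume matches closed forms on polytopes", {
  h <- compute_hull(cube_cloud())
  expect_equal(h$volume, 1)
  expect_equal(h$hull_vertex_count, 8L)
  expect_equal(compute_hull(tetra_cloud())$volume, 1 / (6 * sqrt(2)),
               tolerance = 1e-12)
})

test_that("interior points change neither volume nor hull vertices", {
  inter <- withr::with_seed(1, matrix(runif(300, 0.01, 0.99), ncol = 3))
  h <- compute_hull(pointcloud(rbind(cube_cloud()$points, inter)))
  expect_equal(h$volume, 1)
  expect_equal(h$hull_vertex_count, 8L)
})

test_that("hull volume agrees with an independent qhull oracle on small clouds", {
  # reference volumes computed once with scipy.spatial.ConvexHull on the
  # identical fixed-seed clouds
  oracle <- c(0.816103654337, 2.167258303605, 7.309593894557,
              13.106598626109, 9.104154833291, 4.151790492874)
  clouds <- withr::with_seed(424242,
    lapply(1:6, function(i) matrix(rnorm(3 * (i + 5)), ncol = 3)))
  vols <- vapply(clouds, function(m) compute_hull(pointcloud(m))$volume, 0)
  expect_equal(vols, oracle, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with their rank", {
  expect_error(compute_hull(pointcloud(rbind(c(0, 0, 0), c(1, 1, 1)))),
               "need >= 4")
  line <- pointcloud(cbind(1:5, 2 * (1:5), 3 * (1:5)))
  expect_error(compute_hull(line), "rank 1.*collinear")
  plane <- pointcloud(cbind(runif(10), runif(10), 0))
  expect_error(compute_hull(plane), "rank 2.*coplanar")
})

test_that("hull volume is rigid-motion invariant and cube-law equivariant", {
  for (s in 1:5) {
    m <- withr::with_seed(s, matrix(rnorm(90), ncol = 3))
    v0 <- compute_hull(pointcloud(m))$volume
    R <- rot3(0.3 * s, 0.8 - 0.1 * s)
    v1 <- compute_hull(pointcloud(m %*% R + 50))$volume
    expect_equal(v1, v0, tolerance = 1e-9)
    k <- 1.7
    expect_equal(compute_hull(pointcloud(k * m))$volume, k^3 * v0,
                 tolerance = 1e-9)
  }
})

test_that("hull volume is monotone under point insertion", {
  m <- withr::with_seed(9, matrix(rnorm(45), ncol = 3))
  v <- compute_hull(pointcloud(m))$volume
  extra <- withr::with_seed(10, matrix(rnorm(60, sd = 1.5), ncol = 3))
  for (i in seq_len(nrow(extra))) {
    v2 <- compute_hull(pointcloud(rbind(m, extra[i, ])))$volume
    expect_gte(v2 + 1e-12, v)
  }
})

test_that("hull facets close up: surface integral of the identity recovers volume", {
  cl <- sphere_surface_cloud(500, seed = 21)
  h <- compute_hull(cl)
  # divergence theorem with div(F)=3 for F=x: sum of face-normal fluxes / 3
  p <- cl$points
  flux <- 0
  for (i in seq_len(nrow(h$faces))) {
    tri <- p[h$faces[i, ], ]
    nrm <- crossprod_vec(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    flux <- flux + sum(nrm * tri[1, ]) / 2
  }
  expect_equal(flux / 3, h$volume, tolerance = 1e-9)
})

test_that("interior-uniform ball clouds converge to the ball volume from below", {
  pts <- withr::with_seed(11, {
    z <- matrix(runif(3 * 120000, -1, 1), ncol = 3)
    z[rowSums(z^2) <= 1, ][1:50000, ]
  })
  v <- compute_hull(pointcloud(pts))$volume
  expect_lte(v, 4 * pi / 3)
  expect_equal(v, 4 * pi / 3, tolerance = 0.02)
})

test_that("total skeleton volume is the exact sum of segment hulls", {
  c1 <- cube_cloud("a")
  c2 <- pointcloud(cube_cloud()$points + 10, label = "b")
  sk <- skeleton_model(list(segment("a", c1), segment("b", c2)))
  tv <- total_volume(sk)
  expect_equal(tv$total, 2)
  expect_equal(sum(tv$breakdown$volume), tv$total)
  single <- total_volume(skeleton_model(segment("a", c1)))
  expect_equal(single$total, compute_hull(c1)$volume)

  flat <- segment("flat", pointcloud(cbind(runif(9), runif(9), 0)))
  expect_error(total_volume(skeleton_model(list(segment("a", c1), flat))),
               "segment 'flat'")
})

test_that("segment bookkeeping rejects duplicates and bad parts", {
  expect_error(segment("s", cube_cloud(), part_index = 0), "part_index")
  expect_error(
    skeleton_model(list(segment("a", cube_cloud()),
                        segment("a", cube_cloud()))),
    "duplicate segment")
})

test_that("subdividing a straight cylinder conserves summed hull volume", {
  cy <- generate_segment_cloud("cylinder", n_points = 20000, seed = 2,
                               radius = 0.1, length = 1)
  sg <- segment("cyl", cy$cloud)
  expect_identical(subdivide_segment(sg, 1)[[1]], sg)
  unsplit <- compute_hull(cy$cloud)$volume
  parts <- subdivide_segment(sg, 2)
  expect_equal(length(parts), 2L)
  expect_equal(sum(vapply(parts, function(s) npoints(s$cloud), 0L)),
               npoints(cy$cloud))
  split_sum <- sum(vapply(parts, function(s) compute_hull(s$cloud)$volume, 0))
  expect_equal(split_sum, unsplit, tolerance = 0.01)
})

test_that("subdividing a curved tube strictly reduces summed hull volume", {
  ct <- generate_segment_cloud("curved_tube", n_points = 20000, seed = 3,
                               radius = 0.1, length = 1, arc_angle_deg = 90,
                               reference_points = 2e5)
  sg <- segment("neck", ct$cloud)
  unsplit <- compute_hull(ct$cloud)$volume
  split_sum <- sum(vapply(subdivide_segment(sg, 2),
                          function(s) compute_hull(s$cloud)$volume, 0))
  expect_lt(split_sum, unsplit * 0.99)
})

test_that("subdivision refuses to create degenerate parts", {
  tiny <- segment("t", pointcloud(rbind(cube_cloud()$points,
                                        cube_cloud()$points[1, , drop = FALSE])))
  expect_error(subdivide_segment(tiny, 4), "fewer parts")
})

test_that("subsampling is a uniform, seeded, hull-shrinking operation", {
  cl <- sphere_surface_cloud(5000, seed = 4)
  same <- subsample_pointcloud(cl, npoints(cl), seed = 1)
  expect_equal(dim(same$points), dim(cl$points))
  # same multiset of points (order may differ)
  expect_equal(same$points[order(same$points[, 1]), ],
               cl$points[order(cl$points[, 1]), ])
  expect_error(subsample_pointcloud(cl, 0, seed = 1), "between 1 and")
  expect_error(subsample_pointcloud(cl, 5001, seed = 1), "between 1 and")

  v_full <- compute_hull(cl)$volume
  for (s in 1:4) {
    sub <- subsample_pointcloud(cl, 500, seed = s)
    expect_lte(compute_hull(sub)$volume, v_full + 1e-12)
  }
  expect_identical(subsample_pointcloud(cl, 100, seed = 5)$points,
                   subsample_pointcloud(cl, 100, seed = 5)$points)
})

test_that("hull OBJ export re-imports as the hull vertex set", {
  cl <- sphere_surface_cloud(200, seed = 6)
  h <- compute_hull(cl)
  path <- withr::local_tempfile(fileext = ".obj")
  write_hull_obj(h, cl, path)
  back <- read_pointcloud(path)
  expect_equal(npoints(back), h$hull_vertex_count)
  expect_equal(compute_hull(back)$volume, h$volume, tolerance = 1e-12)
})
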