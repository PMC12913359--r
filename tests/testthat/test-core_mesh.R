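test_that("signed volume follows the triple-product formula", {
  expect_equal(signed_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(0, 0, 1))), 1 / 6)
  # coplanar points are degenerate
  expect_equal(signed_volume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                   c(1, 1, 0))), 0)
  # swapping two vertices negates the volume
  tet <- matrix(rnorm(12), 4L, 3L)
  expect_equal(signed_volume(tet[c(2, 1, 3, 4), ]), -signed_volume(tet))
})

test_that("construction enforces positive orientation", {
  m <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                matrix(c(2L, 1L, 3L, 4L), 1L)) # negatively oriented input
  expect_gt(vesselmesh:::cpp_signed_volumes(m$vertices, m$tets)[1L], 0)
  expect_error(tet_mesh(diag(3), matrix(c(1L, 2L, 3L, 4L), 1L)),
               "out of range")
})

test_that("adjacency identifies neighbors and boundary faces", {
  m1 <- unit_tet_mesh()
  a1 <- build_adjacency(m1)
  expect_equal(nrow(a1$boundary_faces), 4L)
  expect_true(all(a1$neighbors == 0L))

  m2 <- two_tet_mesh()
  a2 <- build_adjacency(m2)
  expect_equal(nrow(a2$boundary_faces), 6L)
  expect_equal(sum(a2$neighbors[1L, ] > 0L), 1L)
  expect_equal(sum(a2$neighbors[2L, ] > 0L), 1L)

  # a duplicated tet is rejected outright
  m3 <- two_tet_mesh()
  m3$tets <- rbind(m3$tets, m3$tets[1L, ])
  expect_error(build_adjacency(m3), "duplicate")
  # three distinct tets sharing one face: non-manifold
  m4 <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                       c(1, 1, 1), c(-1, -1, 1)),
                 rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L),
                       c(2L, 3L, 4L, 6L)))
  expect_error(build_adjacency(m4), "non-manifold")
})

test_that("validator passes sound meshes and flags defects", {
  sph <- small_sphere_phantom()
  m <- bcc_lattice_mesh(sph, bcc_config(cell_size = 2))
  v <- validate_mesh(m)
  expect_true(v$orientation_ok)
  expect_true(v$conformity_ok)
  expect_true(v$boundary_closed)
  expect_true(v$ok)
  expect_gt(v$min_volume, 0)

  # inverted element
  mi <- m
  mi$tets[1L, 1:2] <- mi$tets[1L, 2:1]
  expect_false(validate_mesh(mi)$orientation_ok)

  # hanging vertex in the middle of a boundary face
  vh <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              c(1 / 3, 1 / 3, 0), c(1 / 3, 1 / 3, -1))
  mh <- tet_mesh(vh, rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 5L, 6L)))
  expect_false(validate_mesh(mh)$conformity_ok)
})

test_that("extract_surface produces a closed oriented boundary", {
  s1 <- extract_surface(unit_tet_mesh())
  expect_equal(nrow(s1$triangles), 4L)

  s2 <- extract_surface(two_tet_mesh())
  expect_equal(nrow(s2$triangles), 6L) # shared face excluded

  sph <- small_sphere_phantom()
  m <- bcc_lattice_mesh(sph, bcc_config(cell_size = 2))
  s <- extract_surface(m)
  tri <- s$triangles
  ea <- c(tri[, 1L], tri[, 1L], tri[, 2L])
  eb <- c(tri[, 2L], tri[, 3L], tri[, 3L])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  expect_true(all(table(key) == 2L)) # closed 2-manifold
  n_edges <- length(unique(key))
  expect_equal(nrow(s$vertices) - n_edges + nrow(tri), 2L) # Euler: sphere

  # outward orientation: the divergence-theorem volume of the oriented
  # surface equals the summed tet volume
  p1 <- s$vertices[tri[, 1L], ]; p2 <- s$vertices[tri[, 2L], ]
  p3 <- s$vertices[tri[, 3L], ]
  cr <- cbind(p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L],
              p2[, 3L] * p3[, 1L] - p2[, 1L] * p3[, 3L],
              p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])
  surf_vol <- sum(rowSums(p1 * cr)) / 6
  mesh_vol <- sum(vesselmesh:::cpp_signed_volumes(m$vertices, m$tets))
  expect_equal(surf_vol, mesh_vol, tolerance = 1e-9)
})

test_that("bucket partition is contiguous, disjoint and round-robin", {
  sph <- small_sphere_phantom()
  m <- bcc_lattice_mesh(sph, bcc_config(cell_size = 2))
  m10 <- m
  m10$tets <- m$tets[1:10, ]
  m10$labels <- m$labels[1:10]
  p <- partition_buckets(m10, n_workers = 2L, bucket_size = 4L)
  expect_equal(p$buckets, list(1:4, 5:8, 9:10))
  expect_equal(p$owner, c(1L, 2L, 1L))

  p1 <- partition_buckets(m, n_workers = 1L, bucket_size = 100L)
  expect_true(all(p1$owner == 1L))
  all_ids <- unlist(p1$buckets)
  expect_equal(sort(all_ids), seq_len(nrow(m$tets))) # disjoint cover
})
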