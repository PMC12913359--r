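# a small well-shaped block mesh for pass-level tests
block_mesh <- function(n = 4L) {
  img <- list(image = array(1L, c(n, n, n) * 2L), spacing = c(1, 1, 1),
              origin = c(0, 0, 0))
  bcc_lattice_mesh(img, bcc_config(cell_size = 2))
}

test_that("refine splits long edges at midpoints and conserves volume", {
  m <- block_mesh()
  f <- uniform_metric(nrow(m$vertices), h = 4) # BCC edges ~2: all short
  r0 <- refine_pass(m, f, adapt_config())
  expect_equal(r0$inserted, 0L) # nothing above L_max

  f2 <- uniform_metric(nrow(m$vertices), h = 1) # edges ~2 in metric: long
  vol0 <- sum(vesselmesh:::cpp_signed_volumes(m$vertices, m$tets))
  r <- refine_pass(m, f2, adapt_config())
  expect_gt(r$inserted, 0L)
  vol1 <- sum(vesselmesh:::cpp_signed_volumes(r$mesh$vertices, r$mesh$tets))
  expect_lt(abs(vol1 - vol0) / vol0, 1e-9)
  expect_true(validate_mesh(r$mesh)$ok)
  # field grew with the mesh
  expect_equal(nrow(r$field$tensors), nrow(r$mesh$vertices))
})

test_that("collapse removes short interior edges, never boundary vertices", {
  m <- block_mesh()
  # refine first so interior short edges exist, then ask for coarse h
  f_fine <- uniform_metric(nrow(m$vertices), h = 1)
  r <- refine_pass(m, f_fine, adapt_config())
  m2 <- r$mesh
  f_coarse <- uniform_metric(nrow(m2$vertices), h = 4)
  adj0 <- build_adjacency(m2)
  cl <- collapse_pass(m2, f_coarse, adapt_config())
  expect_gt(cl$collapsed, 0L)
  expect_true(validate_mesh(cl$mesh)$ok)
  # all original boundary vertex coordinates still present and unmoved
  bc0 <- m2$vertices[adj0$boundary_vertices, , drop = FALSE]
  keys0 <- apply(bc0, 1L, paste, collapse = ",")
  keys1 <- apply(cl$mesh$vertices, 1L, paste, collapse = ",")
  expect_true(all(keys0 %in% keys1))
  # no short edges: nothing to collapse
  cl0 <- collapse_pass(m, uniform_metric(nrow(m$vertices), h = 2),
                       adapt_config())
  expect_equal(cl0$collapsed, 0L)
})

test_that("2-3 flip fires on a poor bipyramid and conserves volume", {
  m <- bipyramid_mesh(squash = 0.15) # flat bipyramid: 2 bad tets
  f <- uniform_metric(5L, h = 1)
  vol0 <- sum(vesselmesh:::cpp_signed_volumes(m$vertices, m$tets))
  q0 <- min(mean_ratio(m, f))
  lr <- local_reconnection_pass(m, f, adapt_state(2L), mode = "naive")
  expect_equal(lr$applied, 1)
  expect_equal(nrow(lr$mesh$tets), 3L) # 2-3 flip
  vol1 <- sum(vesselmesh:::cpp_signed_volumes(lr$mesh$vertices, lr$mesh$tets))
  expect_lt(abs(vol1 - vol0), 1e-12)
  expect_gt(min(mean_ratio(lr$mesh, f)), q0)
  expect_true(validate_mesh(lr$mesh)$ok)
  # the reverse 3-2 flip is not re-applied (no improvement available)
  lr2 <- local_reconnection_pass(lr$mesh, f, adapt_state(3L), mode = "naive")
  expect_equal(lr2$applied, 0)
})

test_that("optimized reconnection skips converged work and is re-triggered", {
  m <- bipyramid_mesh(squash = 0.15)
  f <- uniform_metric(5L, h = 1)
  st <- adapt_state(nrow(m$tets))
  lr1 <- local_reconnection_pass(m, f, st, mode = "optimized")
  expect_equal(lr1$applied, 1)
  # freshly created tets are attempted once more, without further flips
  lr2 <- local_reconnection_pass(lr1$mesh, f, lr1$state, mode = "optimized")
  expect_equal(lr2$applied, 0)
  expect_equal(lr2$attempts, 3)
  # after convergence a repeated optimized pass skips every candidate
  lr2b <- local_reconnection_pass(lr2$mesh, f, lr2$state, mode = "optimized")
  expect_equal(lr2b$attempts, 0)
  expect_equal(lr2b$skipped, 3)
  # a lock failure forces a retry of that element
  st3 <- lr2b$state
  st3$lockfail[1L] <- 1L
  lr3 <- local_reconnection_pass(lr2b$mesh, f, st3, mode = "optimized")
  expect_equal(lr3$attempts, 1)
  # naive mode never skips
  lr4 <- local_reconnection_pass(lr2b$mesh, f, adapt_state(3L), mode = "naive")
  expect_equal(lr4$attempts, 3)
})

test_that("smoothing fixes boundary, keeps quality, finds the centroid", {
  # perturb an interior vertex of a block; smoothing must not lower the
  # local minimum quality and must leave the boundary bit-identical
  m <- block_mesh()
  adj <- build_adjacency(m)
  interior <- setdiff(seq_len(nrow(m$vertices)), adj$boundary_vertices)
  set.seed(2)
  i <- interior[1L]
  m$vertices[i, ] <- m$vertices[i, ] + c(0.3, -0.2, 0.25)
  f <- uniform_metric(nrow(m$vertices), h = 2)
  q0 <- min(mean_ratio(m, f))
  sm <- smooth_pass(m, f, adapt_config())
  expect_gt(sm$moved, 0L)
  expect_gte(min(mean_ratio(sm$mesh, f)), q0)
  bnd <- adj$boundary_vertices
  expect_identical(sm$mesh$vertices[bnd, ], m$vertices[bnd, ])
  # a symmetric configuration is a fixed point for its center vertex
  sm2 <- smooth_pass(sm$mesh, f, adapt_config())
  d <- max(abs(sm2$mesh$vertices[i, ] - sm$mesh$vertices[i, ]))
  expect_lt(d, max(abs(m$vertices[i, ] - sm$mesh$vertices[i, ])) + 1e-12)
})

test_that("adapt on an already-conforming mesh is a topological fixed point", {
  m <- block_mesh()
  # metric set to the block's own BCC edge scale: nothing long or short
  f <- uniform_metric(nrow(m$vertices), h = 2)
  res <- adapt(m, f, adapt_config(max_ma_iters = 3L, max_qi_iters = 2L))
  expect_equal(sum(res$log$inserted), 0L)
  expect_equal(sum(res$log$collapsed), 0L)
  expect_true(validate_mesh(res$mesh)$ok)
  expect_error(adapt(m, uniform_metric(3L), adapt_config()), "vertex count")
})

test_that("adapt freezes the boundary and stays valid on the tube phantom", {
  ph <- small_tube_phantom()
  m0 <- bcc_lattice_mesh(ph, bcc_config(cell_size = 2))
  mesh <- snap_surface(m0, ph, bcc_config(cell_size = 2))
  f <- build_metric_from_landmarks(mesh, ph$centerline, k = 8,
                                   h_min = 1, h_max = 8)
  f <- scale_to_complexity(mesh, f, 250)
  adj0 <- build_adjacency(mesh)
  frozen <- mesh$vertices[adj0$boundary_vertices, , drop = FALSE]
  res <- adapt(mesh, f, adapt_config(max_ma_iters = 8L), mode = "optimized")
  expect_true(validate_mesh(res$mesh)$ok)
  # every frozen coordinate survives bit-identically
  k0 <- apply(frozen, 1L, paste, collapse = ",")
  k1 <- apply(res$mesh$vertices, 1L, paste, collapse = ",")
  expect_true(all(k0 %in% k1))
  # determinism: bit-identical rerun
  res2 <- adapt(mesh, f, adapt_config(max_ma_iters = 8L), mode = "optimized")
  expect_identical(res$mesh$vertices, res2$mesh$vertices)
  expect_identical(res$mesh$tets, res2$mesh$tets)
})
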