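test_that("mvee recovers known ellipsoids and covers all points", {
  # regular unit-edge tetrahedron: MVEE is the circumscribed ball of
  # radius sqrt(3/8), so E = (8/3) I
  ell <- mvee(regular_tet_coords())
  expect_equal(ell$shape, diag(8 / 3, 3L), tolerance = 1e-4)
  expect_equal(ell$center, colMeans(regular_tet_coords()), tolerance = 1e-5)

  # +-e_i on the axes: the unit ball
  ell2 <- mvee(rbind(diag(3), -diag(3)))
  expect_equal(ell2$shape, diag(3L), tolerance = 1e-5)

  # every input point satisfies (x-c)' E (x-c) <= 1 + 10 tol
  set.seed(11)
  for (rep in 1:5) {
    P <- matrix(rnorm(30), 10L, 3L)
    e <- mvee(P, tol = 1e-7)
    D <- sweep(P, 2L, e$center)
    vals <- rowSums((D %*% e$shape) * D)
    expect_true(all(vals <= 1 + 1e-5))
  }

  # collinear points regularize to a thin ellipsoid with the floor
  # half-axis eps_reg
  P <- cbind(seq(0, 5, length.out = 6L), 0, 0)
  e <- mvee(P, eps_reg = 1e-3)
  ev <- eigen(e$shape, symmetric = TRUE, only.values = TRUE)$values
  # transverse half-axis floored at eps_reg (cover renormalization can
  # loosen it slightly, never tighten it)
  expect_lte(max(ev), 1 / (1e-3)^2 * (1 + 1e-9))
  expect_gt(max(ev), 0.8 / (1e-3)^2)
  # the long direction still spans the points: half-axis at least the
  # half-extent of the segment, not wildly larger
  expect_gte(1 / sqrt(min(ev)), 2.5 - 1e-9)
  expect_lt(1 / sqrt(min(ev)), 5)
  expect_error(mvee(matrix(numeric(), 0L, 3L)), "at least one")
})

test_that("mvee agrees with a brute-force grid-search ball oracle", {
  # for point sets whose MVEE is a ball (symmetric sets), the shape is
  # (1/r^2) I with r the circumradius from a direct search over centers
  P <- regular_tet_coords()
  grid <- seq(-0.2, 0.2, by = 0.02)
  ctr0 <- colMeans(P)
  best <- Inf
  for (dx in grid) for (dy in grid) for (dz in grid) {
    r <- max(sqrt(rowSums(sweep(P, 2L, ctr0 + c(dx, dy, dz))^2)))
    if (r < best) best <- r
  }
  e <- mvee(P)
  r_mvee <- 1 / sqrt(min(eigen(e$shape, symmetric = TRUE,
                               only.values = TRUE)$values))
  expect_equal(r_mvee, best, tolerance = 0.01)
})

test_that("landmark metric elongates along the centerline", {
  ph <- small_tube_phantom()
  m <- bcc_lattice_mesh(ph, bcc_config(cell_size = 2))
  f <- build_metric_from_landmarks(m, ph$centerline, k = 8,
                                   h_min = 0.5, h_max = 8)
  expect_s3_class(f, "metric_field")
  expect_equal(nrow(f$tensors), nrow(m$vertices))
  # vertex closest to the centerline midpoint: weakest eigen-direction
  # (longest allowed edge) within 10 degrees of the tube axis (x)
  mid <- ph$centerline[nrow(ph$centerline) %/% 2L, ]
  d2 <- rowSums(sweep(m$vertices, 2L, mid)^2)
  i <- which.min(d2)
  M <- vesselmesh:::.sym6_to_mat(f$tensors[i, ])
  eg <- eigen(M, symmetric = TRUE)
  dir_weak <- eg$vectors[, which.min(eg$values)]
  ang <- acos(min(1, abs(dir_weak[1L]))) * 180 / pi
  expect_lt(ang, 10)
  # k beyond landmark count falls back to all landmarks
  f2 <- build_metric_from_landmarks(m, ph$centerline[1:5, ], k = 50,
                                    h_min = 0.5, h_max = 8)
  expect_equal(nrow(f2$tensors), nrow(m$vertices))
  # result independent of vertex processing order
  ord <- rev(seq_len(nrow(m$vertices)))
  m_r <- m
  m_r$vertices <- m$vertices[ord, , drop = FALSE]
  f_r <- build_metric_from_landmarks(m_r, ph$centerline, k = 8,
                                     h_min = 0.5, h_max = 8)
  expect_equal(f_r$tensors[order(ord), ], f$tensors, tolerance = 1e-12)
})

test_that("velocity metric stretches along the flow and handles edge cases", {
  ph <- small_tube_phantom()
  ph <- make_streamlines(ph, n_samples = 300L, seed = 3, u_max = 500)
  m <- bcc_lattice_mesh(ph, bcc_config(cell_size = 2))
  f <- build_metric_from_velocity(m, ph$velocity_samples, h0 = 1,
                                  stretch_coeff = 1, s_max = 4)
  # allowed edge length along the tube axis >= transverse at interior
  # vertices (flow is axial)
  adj <- build_adjacency(m)
  interior <- setdiff(seq_len(nrow(m$vertices)), adj$boundary_vertices)
  ok <- vapply(interior, function(i) {
    M <- vesselmesh:::.sym6_to_mat(f$tensors[i, ])
    lx <- 1 / sqrt(c(1, 0, 0) %*% M %*% c(1, 0, 0))
    lt <- 1 / sqrt(c(0, 1, 0) %*% M %*% c(0, 1, 0))
    lx >= lt - 1e-9
  }, logical(1))
  expect_true(all(ok))

  # uniform velocity field: zero gradient, isotropic tensor (1/h0^2) I
  uni <- data.frame(x = runif(10, 0, 20), y = runif(10, -2, 2),
                    z = runif(10, -2, 2), u = 100, v = 0, w = 0)
  fu <- build_metric_from_velocity(m, uni, h0 = 2)
  expect_equal(fu$tensors[1L, ], c(0.25, 0, 0, 0.25, 0, 0.25),
               tolerance = 1e-9)
  # s_max = 1 disables stretching entirely
  f1 <- build_metric_from_velocity(m, ph$velocity_samples, h0 = 1, s_max = 1)
  iso <- matrix(rep(c(1, 0, 0, 1, 0, 1), each = nrow(m$vertices)),
                ncol = 6L)
  expect_equal(f1$tensors, iso, tolerance = 1e-9)
  expect_error(build_metric_from_velocity(m, uni[1:2, ]), "fewer")
})

test_that("isotropic sizing metric follows h(d) = clamp(h_min + g d)", {
  lms <- rbind(c(0, 0, 0))
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c((8 - 1) / 0.5, 0, 0), c(100, 0, 0))
  f <- isotropic_sizing_metric(pts, lms, h_min = 1, g = 0.5, h_max = 8)
  expect_equal(f$tensors[1L, 1L], 1)            # on the landmark: 1/h_min^2
  expect_equal(f$tensors[2L, 1L], 1 / 2^2)      # h = 1 + 0.5*2 = 2
  expect_equal(f$tensors[3L, 1L], 1 / 64)       # d = (h_max-h_min)/g
  expect_equal(f$tensors[4L, 1L], 1 / 64)       # clamped at h_max
  f0 <- isotropic_sizing_metric(pts, lms, h_min = 2, g = 0, h_max = 8)
  expect_true(all(f0$tensors[, 1L] == 0.25))    # g = 0: uniform
  expect_error(isotropic_sizing_metric(pts, lms, h_min = 0), "positive")
})

test_that("edge metric length follows the log-mean with 0.001 threshold", {
  I3 <- diag(3)
  # L_a = L_b = 1: mean branch
  e1 <- edge_metric_length(c(0, 0, 0), c(1, 0, 0), I3, I3)
  expect_equal(e1$L_e, 1)
  # L_a = 2, L_b = 1 -> 1/ln 2
  e2 <- edge_metric_length(c(0, 0, 0), c(2, 0, 0), I3, I3 / 4)
  expect_equal(e2$L_a, 2)
  expect_equal(e2$L_b, 1)
  expect_equal(e2$L_e, 1 / log(2))
  # just inside the threshold: arithmetic mean branch
  Ma <- diag(1.0005^2, 3L)
  e3 <- edge_metric_length(c(0, 0, 0), c(1, 0, 0), Ma, I3)
  expect_equal(e3$L_e, (1.0005 + 1) / 2)
  expect_error(edge_metric_length(c(0, 0, 0), c(1, 0, 0), -I3, I3), "SPD")
})

test_that("the two length branches agree across the switching threshold", {
  # continuity: as L_a -> L_b the log-mean tends to the arithmetic mean
  for (eps in c(0.0009, 0.0011, 0.002)) {
    la <- 1 + eps
    logmean <- (la - 1) / log(la / 1)
    arith <- (la + 1) / 2
    expect_lt(abs(logmean - arith) / arith, 1e-3)
  }
})

test_that("tensor interpolation is the arithmetic mean and preserves SPD", {
  M <- crossprod(matrix(rnorm(9), 3L)) + diag(3L)
  expect_equal(interpolate_edge_tensor(M, M), M)
  expect_equal(interpolate_edge_tensor(diag(3L), diag(3, 3L)), diag(2, 3L))
  set.seed(5)
  for (i in 1:20) {
    A <- crossprod(matrix(rnorm(9), 3L)) + diag(0.1, 3L)
    B <- crossprod(matrix(rnorm(9), 3L)) + diag(0.1, 3L)
    ev <- eigen(interpolate_edge_tensor(A, B), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("mean ratio normalizes to 1 for the regular tet and 0 when flat", {
  reg <- tet_mesh(regular_tet_coords(), matrix(1:4, 1L))
  expect_equal(mean_ratio(reg), 1, tolerance = 1e-9)
  rc <- unit_tet_mesh()
  expect_equal(mean_ratio(rc), 4 / 108^(1 / 3), tolerance = 1e-12)
  flat <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                   matrix(1:4, 1L), fix_orientation = FALSE)
  expect_equal(mean_ratio(flat), 0)
  null_m <- tet_mesh(matrix(0, 4L, 3L), matrix(1:4, 1L),
                     fix_orientation = FALSE)
  expect_error(mean_ratio(null_m), "null")
})

test_that("mean ratio is invariant under rigid motion with rotated tensors", {
  set.seed(21)
  for (i in 1:10) {
    tet <- matrix(rnorm(12), 4L, 3L)
    t6 <- random_spd6(4L)
    m1 <- tet_mesh(tet, matrix(1:4, 1L), fix_orientation = FALSE)
    f1 <- metric_field(t6, clamp = FALSE)
    q1 <- mean_ratio(m1, f1)
    # random rotation + translation
    qr_ <- qr.Q(qr(matrix(rnorm(9), 3L)))
    if (det(qr_) < 0) qr_[, 1L] <- -qr_[, 1L]
    shift <- rnorm(3)
    tet2 <- tet %*% t(qr_) + rep(shift, each = 4L)
    t6r <- t(vapply(1:4, function(k) {
      M <- vesselmesh:::.sym6_to_mat(t6[k, ])
      vesselmesh:::.mat_to_sym6(qr_ %*% M %*% t(qr_))
    }, numeric(6)))
    m2 <- tet_mesh(tet2, matrix(1:4, 1L), fix_orientation = FALSE)
    q2 <- mean_ratio(m2, metric_field(t6r, clamp = FALSE))
    expect_equal(q2, q1, tolerance = 1e-9)
  }
})

test_that("complexity uses barycentric dual volumes that sum to the volume", {
  sph <- small_sphere_phantom()
  m <- bcc_lattice_mesh(sph, bcc_config(cell_size = 2))
  cc <- complexity(m)
  vol <- sum(vesselmesh:::cpp_signed_volumes(m$vertices, m$tets))
  expect_equal(sum(cc$V), vol)           # duals partition the volume
  expect_equal(cc$C, vol)                # identity metric: C = volume
  # single tet with all tensors 4I: C = sqrt(det 4I) * V = 8 V
  ut <- unit_tet_mesh()
  f4 <- metric_field(matrix(rep(c(4, 0, 0, 4, 0, 4), each = 4L), 4L),
                     clamp = FALSE)
  expect_equal(complexity(ut, f4)$C, 8 / 6)
  empty <- tet_mesh(matrix(numeric(), 0L, 3L), matrix(integer(), 0L, 4L))
  expect_equal(complexity(empty)$C, 0)
})

test_that("complexity is additive and scales with exponent 3/2", {
  set.seed(31)
  m <- two_tet_mesh()
  f <- metric_field(random_spd6(5L), clamp = FALSE)
  c_all <- complexity(m, f)$C
  m1 <- m; m1$tets <- m$tets[1L, , drop = FALSE]; m1$labels <- 1L
  m2 <- m; m2$tets <- m$tets[2L, , drop = FALSE]; m2$labels <- 1L
  expect_equal(complexity(m1, f)$C + complexity(m2, f)$C, c_all)
  fa <- f; fa$tensors <- f$tensors * 3
  expect_equal(complexity(m, fa)$C, c_all * 3^(3 / 2))
})

test_that("scale_to_complexity hits the target exactly on random fields", {
  set.seed(41)
  sph <- small_sphere_phantom()
  m <- bcc_lattice_mesh(sph, bcc_config(cell_size = 2))
  for (i in 1:10) {
    f <- metric_field(random_spd6(nrow(m$vertices),
                                  scale = runif(1, 0.1, 5)),
                      clamp = FALSE)
    Cr <- runif(1, 1, 1e4)
    f2 <- scale_to_complexity(m, f, Cr)
    expect_lt(abs(complexity(m, f2)$C - Cr) / Cr, 1e-10)
    # invertibility
    f3 <- scale_to_complexity(m, f2, complexity(m, f)$C)
    expect_equal(f3$tensors, f$tensors, tolerance = 1e-12)
  }
  expect_error(scale_to_complexity(m, uniform_metric(nrow(m$vertices)), -1),
               "positive")
})

test_that("refinement predicate flags any over-threshold edge", {
  ut <- unit_tet_mesh() # edges 1 and sqrt(2)
  f <- uniform_metric(4L, h = 1)
  expect_true(refinement_predicate(ut, f, 1L, tau = 1.2))   # sqrt(2) > 1.2
  expect_false(refinement_predicate(ut, f, 1L, tau = 1.5))  # all <= 1.5
  expect_false(refinement_predicate(ut, f, 1L, tau = 1e9))
  expect_error(refinement_predicate(ut, f, 1L, tau = 0), "positive")
})
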