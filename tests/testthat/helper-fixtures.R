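# small meshes and fields used across tests; everything built in code

unit_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1L))
}

regular_tet_coords <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
        c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
}

two_tet_mesh <- function() {
  # two tets sharing face (2,3,4)
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1)),
           rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L)))
}

# convex bipyramid over triangle (p, q, r) with poles a (top) and b
# (bottom), triangulated as two tets sharing the triangle face -- the
# canonical 2-3 flip configuration
bipyramid_mesh <- function(squash = 1) {
  V <- rbind(c(0, 0, squash),              # a
             c(0, 0, -squash),             # b
             c(1, 0, 0), c(-0.5, 0.9, 0), c(-0.5, -0.9, 0)) # p q r
  tet_mesh(V, rbind(c(1L, 3L, 4L, 5L), c(2L, 3L, 5L, 4L)))
}

small_sphere_phantom <- function(radius = 6, spacing = 1) {
  make_primitive_image("sphere", list(radius = radius, spacing = spacing))
}

small_tube_phantom <- function(seed = 1L) {
  make_vessel_image(list(tube_radius = 3, length = 20, spacing = 1,
                         bulge_radius = 0), seed = seed)
}

random_spd6 <- function(n, scale = 1) {
  t(vapply(seq_len(n), function(i) {
    A <- matrix(rnorm(9), 3L)
    M <- crossprod(A) + diag(0.5, 3L)
    M <- M * scale
    c(M[1, 1], M[1, 2], M[1, 3], M[2, 2], M[2, 3], M[3, 3])
  }, numeric(6)))
}
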