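#' Tetrahedral mesh container
#'
#' Builds a `tet_mesh` from a vertex matrix and a tet connectivity matrix.
#' Tets are stored with positive signed volume (right-handed vertex order);
#' negatively oriented input tets are repaired by swapping their first two
#' vertices. Per-tet modification counters (`tet_version`) and a global
#' `mesh_version` support the change-tracking used by the optimized local
#' reconnection pass.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param tets integer matrix (m x 4), 1-based vertex indices.
#' @param labels integer material label per tet (default 1).
#' @param fix_orientation repair negatively oriented tets (default TRUE).
#' @return an object of class `tet_mesh` with elements `vertices`, `tets`,
#'   `labels`, `tet_version`, `mesh_version`.
#' @export
tet_mesh <- function(vertices, tets, labels = NULL, fix_orientation = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (nrow(tets) > 0L) {
    if (ncol(tets) != 4L) stop("tets must be an m x 4 matrix")
    if (max(tets) > nrow(vertices) || min(tets) < 1L)
      stop("tet vertex index out of range")
    if (fix_orientation) {
      vol <- cpp_signed_volumes(vertices, tets)
      neg <- which(vol < 0)
      if (length(neg)) tets[neg, 1:2] <- tets[neg, 2:1]
    }
  }
  if (is.null(labels)) labels <- rep.int(1L, nrow(tets))
  structure(list(
    vertices = vertices,
    tets = tets,
    labels = as.integer(labels),
    tet_version = integer(nrow(tets)),
    mesh_version = 0L
  ), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$vertices), "vertices,", nrow(x$tets), "tets\n")
  if (nrow(x$tets) > 0L) {
    vol <- cpp_signed_volumes(x$vertices, x$tets)
    cat(sprintf("  total volume %.4g mm^3, min tet volume %.4g mm^3\n",
                sum(vol), min(vol)))
  }
  invisible(x)
}

#' @export
summary.tet_mesh <- function(object, ...) {
  adj <- build_adjacency(object)
  vol <- cpp_signed_volumes(object$vertices, object$tets)
  out <- list(
    n_vertices = nrow(object$vertices),
    n_tets = nrow(object$tets),
    n_boundary_faces = nrow(adj$boundary_faces),
    total_volume = sum(vol),
    min_volume = if (length(vol)) min(vol) else NA_real_
  )
  class(out) <- "summary.tet_mesh"
  out
}

#' @export
print.summary.tet_mesh <- function(x, ...) {
  cat(sprintf(
    "tet_mesh: %d vertices, %d tets, %d boundary faces\n  volume %.4g mm^3 (min tet %.4g)\n",
    x$n_vertices, x$n_tets, x$n_boundary_faces, x$total_volume, x$min_volume))
  invisible(x)
}

#' Signed volume of a tetrahedron
#'
#' One sixth of the scalar triple product of the edge vectors emanating from
#' the first vertex. Positive for right-handed vertex order; zero for
#' degenerate (coplanar) input.
#'
#' @param tet a 4 x 3 matrix of vertex coordinates.
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(tet) {
  tet <- as.matrix(tet)
  if (!all(dim(tet) == c(4L, 3L))) stop("tet must be a 4 x 3 matrix")
  u <- tet[2L, ] - tet[1L, ]
  v <- tet[3L, ] - tet[1L, ]
  w <- tet[4L, ] - tet[1L, ]
  (u[1L] * (v[2L] * w[3L] - v[3L] * w[2L]) -
   u[2L] * (v[1L] * w[3L] - v[3L] * w[1L]) +
   u[3L] * (v[1L] * w[2L] - v[2L] * w[1L])) / 6
}

# per-tet face table: row f gives local vertex indices of the face opposite
# local vertex f, ordered so the face normal points outward for a positively
# oriented tet
.tet_faces <- matrix(c(2L, 3L, 4L,
                       1L, 4L, 3L,
                       1L, 2L, 4L,
                       1L, 3L, 2L), nrow = 4L, byrow = TRUE)

.tet_edges <- matrix(c(1L, 2L, 1L, 3L, 1L, 4L, 2L, 3L, 2L, 4L, 3L, 4L),
                     ncol = 2L, byrow = TRUE)

# all 4m oriented faces; returns list(tet = tet id, a,b,c sorted vertex ids,
# oa,ob,oc oriented ids)
.all_faces <- function(tets) {
  m <- nrow(tets)
  tid <- rep(seq_len(m), times = 4L)
  oa <- c(tets[, 2L], tets[, 1L], tets[, 1L], tets[, 1L])
  ob <- c(tets[, 3L], tets[, 4L], tets[, 2L], tets[, 3L])
  oc <- c(tets[, 4L], tets[, 3L], tets[, 4L], tets[, 2L])
  s1 <- pmin(oa, ob, oc)
  s3 <- pmax(oa, ob, oc)
  s2 <- oa + ob + oc - s1 - s3
  list(tet = tid, a = s1, b = s2, c = s3, oa = oa, ob = ob, oc = oc)
}

#' Face and neighbor adjacency of a tetrahedral mesh
#'
#' Face keys are sorted vertex triples, which makes the adjacency
#' deterministic. Interior faces must be shared by exactly two tets; a face
#' with more than two incident tets is a structural (non-manifold) error.
#'
#' @param mesh a `tet_mesh`.
#' @return list with `neighbors` (m x 4 integer matrix, 0 where the face
#'   opposite local vertex k is on the boundary), `boundary_faces` (sorted
#'   vertex triples, one row per boundary face), `boundary_vertices`
#'   (integer ids), and `face_count` (faces in the mesh).
#' @export
build_adjacency <- function(mesh) {
  tets <- mesh$tets
  m <- nrow(tets)
  if (m == 0L)
    return(list(neighbors = matrix(integer(), 0L, 4L),
                boundary_faces = matrix(integer(), 0L, 3L),
                boundary_vertices = integer(), face_count = 0L))
  if (anyDuplicated(.tet_keys(tets)))
    stop("duplicate tets in mesh")
  fc <- .all_faces(tets)
  ord <- order(fc$a, fc$b, fc$c)
  a <- fc$a[ord]; b <- fc$b[ord]; c3 <- fc$c[ord]; tid <- fc$tet[ord]
  new_grp <- c(TRUE, a[-1L] != a[-length(a)] | b[-1L] != b[-length(b)] |
                 c3[-1L] != c3[-length(c3)])
  grp <- cumsum(new_grp)
  cnt <- tabulate(grp)
  if (any(cnt > 2L)) {
    bad <- which(grp == which(cnt > 2L)[1L])[1L]
    stop(sprintf("non-manifold face (%d, %d, %d): more than 2 incident tets",
                 a[bad], b[bad], c3[bad]))
  }
  # local face slot: which local face of tid is this (recover from position)
  slot <- rep(rep(1:4, each = 1L), length.out = 0L) # filled below
  slot <- ((ord - 1L) %/% m) + 1L
  neighbors <- matrix(0L, m, 4L)
  paired <- which(cnt == 2L)
  firsts <- which(new_grp)
  i1 <- firsts[paired]
  i2 <- i1 + 1L
  neighbors[cbind(tid[i1], slot[i1])] <- tid[i2]
  neighbors[cbind(tid[i2], slot[i2])] <- tid[i1]
  single <- firsts[cnt == 1L]
  boundary_faces <- cbind(a[single], b[single], c3[single])
  colnames(boundary_faces) <- c("v1", "v2", "v3")
  list(neighbors = neighbors,
       boundary_faces = boundary_faces,
       boundary_vertices = sort(unique(as.integer(boundary_faces))),
       face_count = length(cnt))
}

#' Validate a tetrahedral mesh
#'
#' Checks orientation (all signed volumes positive), structural conformity
#' (no face with more than two incident tets, no vertex hanging on a face of
#' another tet), and closure of the boundary surface (every boundary edge in
#' exactly two boundary faces). Failures are reported, not raised.
#'
#' @param mesh a `tet_mesh`.
#' @param check_hanging run the geometric hanging-vertex scan (default TRUE;
#'   O(boundary faces x boundary vertices), prefiltered by bounding box).
#' @param tol geometric tolerance for the hanging-vertex test (mm).
#' @return list with `min_volume`, `orientation_ok`, `conformity_ok`,
#'   `boundary_closed`, and overall `ok`.
#' @export
validate_mesh <- function(mesh, check_hanging = TRUE, tol = 1e-8) {
  m <- nrow(mesh$tets)
  if (m == 0L)
    return(list(min_volume = NA_real_, orientation_ok = TRUE,
                conformity_ok = TRUE, boundary_closed = TRUE, ok = TRUE))
  vol <- cpp_signed_volumes(mesh$vertices, mesh$tets)
  orientation_ok <- all(vol > 0)
  conformity_ok <- TRUE
  boundary_closed <- TRUE
  adj <- tryCatch(build_adjacency(mesh), error = function(e) NULL)
  if (is.null(adj)) {
    conformity_ok <- FALSE
  } else {
    bf <- adj$boundary_faces
    if (nrow(bf) > 0L) {
      ea <- c(bf[, 1L], bf[, 1L], bf[, 2L])
      eb <- c(bf[, 2L], bf[, 3L], bf[, 3L])
      key <- paste(pmin(ea, eb), pmax(ea, eb))
      cnt <- table(key)
      # closed: every boundary edge bounds an even number (>= 2) of
      # boundary faces; counts of 4+ are pinched (non-manifold but
      # watertight) edges, as voxel-derived shapes can produce
      if (any(cnt %% 2L != 0L)) boundary_closed <- FALSE
    }
    if (check_hanging && nrow(bf) > 0L && conformity_ok) {
      conformity_ok <- !.has_hanging_vertex(mesh$vertices, bf,
                                            adj$boundary_vertices, tol)
    }
  }
  ok <- orientation_ok && conformity_ok && boundary_closed
  list(min_volume = min(vol), orientation_ok = orientation_ok,
       conformity_ok = conformity_ok, boundary_closed = boundary_closed,
       ok = ok)
}

# TRUE if any boundary vertex lies strictly inside a boundary face it does
# not belong to (tell-tale of a non-conforming split)
.has_hanging_vertex <- function(V, faces, bverts, tol) {
  P <- V[bverts, , drop = FALSE]
  for (i in seq_len(nrow(faces))) {
    f <- faces[i, ]
    p1 <- V[f[1L], ]; p2 <- V[f[2L], ]; p3 <- V[f[3L], ]
    lo <- pmin(p1, p2, p3) - tol
    hi <- pmax(p1, p2, p3) + tol
    cand <- which(P[, 1L] >= lo[1L] & P[, 1L] <= hi[1L] &
                  P[, 2L] >= lo[2L] & P[, 2L] <= hi[2L] &
                  P[, 3L] >= lo[3L] & P[, 3L] <= hi[3L] &
                  !(bverts %in% f))
    if (!length(cand)) next
    u <- p2 - p1; w <- p3 - p1
    nrm <- c(u[2L] * w[3L] - u[3L] * w[2L],
             u[3L] * w[1L] - u[1L] * w[3L],
             u[1L] * w[2L] - u[2L] * w[1L])
    nn <- sqrt(sum(nrm^2))
    if (nn == 0) next
    nrm <- nrm / nn
    D <- sweep(P[cand, , drop = FALSE], 2L, p1)
    dist <- abs(D %*% nrm)
    onplane <- which(dist < tol)
    if (!length(onplane)) next
    # barycentric coordinates in the triangle plane
    uu <- sum(u * u); vv <- sum(w * w); uv <- sum(u * w)
    den <- uu * vv - uv * uv
    if (den <= 0) next
    for (j in onplane) {
      d <- D[j, ]
      du <- sum(d * u); dv <- sum(d * w)
      s <- (vv * du - uv * dv) / den
      t <- (uu * dv - uv * du) / den
      eps <- 1e-6
      if (s > eps && t > eps && s + t < 1 - eps) return(TRUE)
    }
  }
  FALSE
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' Collects all faces incident to exactly one tet, oriented outward, and
#' reindexes them over the boundary vertex set.
#'
#' @param mesh a `tet_mesh`.
#' @return an object of class `tri_surface`: `vertices` (k x 3),
#'   `triangles` (f x 3, outward-oriented, 1-based into `vertices`), and
#'   `orig_ids` mapping surface vertices back to mesh vertex ids.
#' @export
extract_surface <- function(mesh) {
  fc <- .all_faces(mesh$tets)
  key <- paste(fc$a, fc$b, fc$c)
  cnt <- table(key)
  bnd <- which(key %in% names(cnt)[cnt == 1L])
  tri <- cbind(fc$oa[bnd], fc$ob[bnd], fc$oc[bnd])
  ids <- sort(unique(as.integer(tri)))
  remap <- integer(nrow(mesh$vertices))
  remap[ids] <- seq_along(ids)
  tri2 <- matrix(remap[tri], ncol = 3L)
  structure(list(vertices = mesh$vertices[ids, , drop = FALSE],
                 triangles = tri2, orig_ids = ids),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  v <- nrow(x$vertices); f <- nrow(x$triangles)
  ek <- unique(paste(pmin(x$triangles[, c(1, 1, 2)], x$triangles[, c(2, 3, 3)]),
                     pmax(x$triangles[, c(1, 1, 2)], x$triangles[, c(2, 3, 3)])))
  cat(sprintf("tri_surface: %d vertices, %d edges, %d triangles (V-E+F = %d)\n",
              v, length(ek), f, v - length(ek) + f))
  invisible(x)
}

#' Partition tets into contiguous buckets dealt round-robin to workers
#'
#' Tetrahedra are chunked into contiguous id ranges of `bucket_size` and the
#' buckets are dealt round-robin to `n_workers` workers, forming the unit of
#' work for the load-balancing scheduler.
#'
#' @param mesh a `tet_mesh`.
#' @param n_workers number of workers (>= 1).
#' @param bucket_size tets per bucket (default 256).
#' @return object of class `bucket_partition`: `buckets` (list of integer
#'   tet-id vectors) and `owner` (worker id per bucket, 1-based).
#' @export
partition_buckets <- function(mesh, n_workers = 1L, bucket_size = 256L) {
  stopifnot(n_workers >= 1L, bucket_size >= 1L)
  m <- nrow(mesh$tets)
  if (m == 0L)
    return(structure(list(buckets = list(), owner = integer()),
                     class = "bucket_partition"))
  starts <- seq.int(1L, m, by = bucket_size)
  buckets <- lapply(starts, function(s) seq.int(s, min(s + bucket_size - 1L, m)))
  owner <- ((seq_along(buckets) - 1L) %% n_workers) + 1L
  structure(list(buckets = buckets, owner = owner), class = "bucket_partition")
}

# internal: order-independent key per tet (sorted vertex ids packed into a
# string pair of doubles); vectorized 4-element sorting network
.tet_keys <- function(tets) {
  if (nrow(tets) == 0L) return(character())
  a <- tets[, 1L]; b <- tets[, 2L]; c3 <- tets[, 3L]; d <- tets[, 4L]
  lo1 <- pmin(a, b); hi1 <- pmax(a, b)
  lo2 <- pmin(c3, d); hi2 <- pmax(c3, d)
  s1 <- pmin(lo1, lo2); s4 <- pmax(hi1, hi2)
  m1 <- pmax(lo1, lo2); m2 <- pmin(hi1, hi2)
  s2 <- pmin(m1, m2); s3 <- pmax(m1, m2)
  paste(s1 * 2^26 + s2, s3 * 2^26 + s4)
}

# internal: unique undirected edges of a mesh as a 2-column matrix (a < b)
.mesh_edges <- function(tets) {
  if (nrow(tets) == 0L) return(matrix(integer(), 0L, 2L))
  a <- as.integer(tets[, .tet_edges[, 1L]])
  b <- as.integer(tets[, .tet_edges[, 2L]])
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(lo * (2^26) + hi)
  cbind(lo[keep], hi[keep])
}
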