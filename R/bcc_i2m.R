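#' BCC lattice configuration
#'
#' @param cell_size lattice spacing in mm (> 0).
#' @param snap_iters surface-snapping iterations (default 20).
#' @param snap_step fraction of the signed distance moved per iteration
#'   (in (0, 1], default 0.5).
#' @param min_quality_accept mean-ratio floor (identity metric) below which
#'   a snapping move is rejected (default 0.1).
#' @return a `bcc_config` list.
#' @export
bcc_config <- function(cell_size = 1, snap_iters = 20L, snap_step = 0.5,
                       min_quality_accept = 0.1) {
  stopifnot(cell_size > 0, snap_step > 0, snap_step <= 1)
  structure(list(cell_size = cell_size, snap_iters = as.integer(snap_iters),
                 snap_step = snap_step,
                 min_quality_accept = min_quality_accept),
            class = "bcc_config")
}

#' Body-centered-cubic lattice tetrahedralization of a labelled image
#'
#' Lays a cubic lattice of cell size `cell_size` over the image (one cell
#' of margin on every side), places nodes at cell corners and cell centers,
#' and creates four congruent tetrahedra per interior cube face, each
#' joining the two adjacent cell centers with one edge of the shared face.
#' Tets whose centroid falls in the selected label are kept; unused
#' vertices are dropped.
#'
#' @param image either a 3-D integer array or a list with `image`,
#'   `spacing`, `origin` (as produced by the phantom generators or
#'   [read_image()]).
#' @param config a `bcc_config` (or a cell size).
#' @param label label value to mesh (default 1).
#' @param spacing,origin used when `image` is a bare array.
#' @return a `tet_mesh`.
#' @export
bcc_lattice_mesh <- function(image, config = bcc_config(), label = 1L,
                             spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.numeric(config)) config <- bcc_config(cell_size = config)
  img <- image
  if (is.list(image)) {
    img <- image$image
    spacing <- image$spacing
    origin <- image$origin
  }
  if (!any(img == label)) stop("selected label is empty in the image")
  h <- config$cell_size
  dims <- dim(img)
  lo <- origin - spacing / 2 - h
  hi <- origin + (dims - 1L) * spacing + spacing / 2 + h
  nc <- pmax(as.integer(ceiling((hi - lo) / h)), 2L)
  nx <- nc[1L]; ny <- nc[2L]; nz <- nc[3L]

  # corner grid (nx+1, ny+1, nz+1) then center grid (nx, ny, nz)
  n_corner <- (nx + 1L) * (ny + 1L) * (nz + 1L)
  corner_id <- function(i, j, k)
    i + (j - 1L) * (nx + 1L) + (k - 1L) * (nx + 1L) * (ny + 1L)
  center_id <- function(i, j, k)
    n_corner + i + (j - 1L) * nx + (k - 1L) * nx * ny

  # 4 tets per interior face in each axis direction; faces enumerated
  # vectorized as (i, j, k) = lower cell index
  tet_blocks <- vector("list", 3L)
  for (ax in 1:3) {
    if (ax == 1L) {
      g <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny), k = seq_len(nz))
      c1 <- center_id(g$i, g$j, g$k)
      c2 <- center_id(g$i + 1L, g$j, g$k)
      # shared face corners at x-plane i+1: (j..j+1, k..k+1)
      p00 <- corner_id(g$i + 1L, g$j,      g$k)
      p10 <- corner_id(g$i + 1L, g$j + 1L, g$k)
      p11 <- corner_id(g$i + 1L, g$j + 1L, g$k + 1L)
      p01 <- corner_id(g$i + 1L, g$j,      g$k + 1L)
    } else if (ax == 2L) {
      g <- expand.grid(i = seq_len(nx), j = seq_len(ny - 1L), k = seq_len(nz))
      c1 <- center_id(g$i, g$j, g$k)
      c2 <- center_id(g$i, g$j + 1L, g$k)
      p00 <- corner_id(g$i,      g$j + 1L, g$k)
      p10 <- corner_id(g$i + 1L, g$j + 1L, g$k)
      p11 <- corner_id(g$i + 1L, g$j + 1L, g$k + 1L)
      p01 <- corner_id(g$i,      g$j + 1L, g$k + 1L)
    } else {
      g <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz - 1L))
      c1 <- center_id(g$i, g$j, g$k)
      c2 <- center_id(g$i, g$j, g$k + 1L)
      p00 <- corner_id(g$i,      g$j,      g$k + 1L)
      p10 <- corner_id(g$i + 1L, g$j,      g$k + 1L)
      p11 <- corner_id(g$i + 1L, g$j + 1L, g$k + 1L)
      p01 <- corner_id(g$i,      g$j + 1L, g$k + 1L)
    }
    tet_blocks[[ax]] <- rbind(cbind(c1, c2, p00, p10),
                              cbind(c1, c2, p10, p11),
                              cbind(c1, c2, p11, p01),
                              cbind(c1, c2, p01, p00))
  }
  tets <- do.call(rbind, tet_blocks)
  storage.mode(tets) <- "integer"

  # node coordinates, corners then centers
  cx <- lo[1L] + (0:nx) * h; cy <- lo[2L] + (0:ny) * h; cz <- lo[3L] + (0:nz) * h
  corners <- cbind(rep(cx, times = (ny + 1L) * (nz + 1L)),
                   rep(rep(cy, each = nx + 1L), times = nz + 1L),
                   rep(cz, each = (nx + 1L) * (ny + 1L)))
  mx <- lo[1L] + (seq_len(nx) - 0.5) * h
  my <- lo[2L] + (seq_len(ny) - 0.5) * h
  mz <- lo[3L] + (seq_len(nz) - 0.5) * h
  centers <- cbind(rep(mx, times = ny * nz),
                   rep(rep(my, each = nx), times = nz),
                   rep(mz, each = nx * ny))
  verts <- rbind(corners, centers)

  # keep tets whose centroid samples the selected label
  cen <- (verts[tets[, 1L], ] + verts[tets[, 2L], ] +
          verts[tets[, 3L], ] + verts[tets[, 4L], ]) / 4
  keep <- .sample_label(img, spacing, origin, cen) == label
  tets <- tets[keep, , drop = FALSE]
  if (nrow(tets) == 0L) stop("no tets inside the selected label at this cell size")

  used <- sort(unique(as.integer(tets)))
  remap <- integer(nrow(verts))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  tet_mesh(verts[used, , drop = FALSE], tets)
}

# nearest-voxel label lookup; points outside the grid sample 0
.sample_label <- function(img, spacing, origin, pts) {
  dims <- dim(img)
  i <- round((pts[, 1L] - origin[1L]) / spacing[1L]) + 1L
  j <- round((pts[, 2L] - origin[2L]) / spacing[2L]) + 1L
  k <- round((pts[, 3L] - origin[3L]) / spacing[3L]) + 1L
  ok <- i >= 1L & i <= dims[1L] & j >= 1L & j <= dims[2L] & k >= 1L & k <= dims[3L]
  out <- integer(nrow(pts))
  out[ok] <- img[cbind(i[ok], j[ok], k[ok])]
  out
}

#' Signed distance field of a labelled image
#'
#' Exact Euclidean distance transform on the voxel grid (negative inside
#' the label, positive outside), with trilinear interpolation off-grid.
#'
#' @param img 3-D integer array.
#' @param spacing,origin grid geometry (mm).
#' @param label label value (default 1).
#' @return list with `phi` (array), `spacing`, `origin`, and
#'   `interp(points)` evaluating the field at arbitrary positions.
#' @export
signed_distance_field <- function(img, spacing, origin, label = 1L) {
  mask <- array(as.integer(img == label), dim = dim(img))
  d_in <- sqrt(cpp_edt_sq(as.integer(mask), dim(img), as.numeric(spacing)))
  d_out <- sqrt(cpp_edt_sq(as.integer(1L - mask), dim(img), as.numeric(spacing)))
  phi <- array(d_in - d_out, dim = dim(img)) # negative inside the label
  interp <- function(pts) .trilinear(phi, spacing, origin, pts)
  list(phi = phi, spacing = spacing, origin = origin, interp = interp)
}

.trilinear <- function(arr, spacing, origin, pts) {
  dims <- dim(arr)
  gx <- (pts[, 1L] - origin[1L]) / spacing[1L]
  gy <- (pts[, 2L] - origin[2L]) / spacing[2L]
  gz <- (pts[, 3L] - origin[3L]) / spacing[3L]
  i0 <- pmin(pmax(floor(gx), 0), dims[1L] - 2L)
  j0 <- pmin(pmax(floor(gy), 0), dims[2L] - 2L)
  k0 <- pmin(pmax(floor(gz), 0), dims[3L] - 2L)
  fx <- pmin(pmax(gx - i0, 0), 1); fy <- pmin(pmax(gy - j0, 0), 1)
  fz <- pmin(pmax(gz - k0, 0), 1)
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L; k0 <- as.integer(k0) + 1L
  v000 <- arr[cbind(i0, j0, k0)];         v100 <- arr[cbind(i0 + 1L, j0, k0)]
  v010 <- arr[cbind(i0, j0 + 1L, k0)];    v110 <- arr[cbind(i0 + 1L, j0 + 1L, k0)]
  v001 <- arr[cbind(i0, j0, k0 + 1L)];    v101 <- arr[cbind(i0 + 1L, j0, k0 + 1L)]
  v011 <- arr[cbind(i0, j0 + 1L, k0 + 1L)]; v111 <- arr[cbind(i0 + 1L, j0 + 1L, k0 + 1L)]
  (v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
   v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
   v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
   v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz)
}

#' Snap the mesh surface toward the image boundary
#'
#' Boundary vertices descend the signed distance field (step
#' `snap_step * phi` along the normalized gradient) for up to `snap_iters`
#' iterations. A move is rejected when any incident tet would invert or
#' its identity-metric mean ratio would drop below `min_quality_accept`.
#' Interior vertices are untouched, so the output surface stays watertight
#' (C0) though possibly sharp.
#'
#' @param mesh a `tet_mesh` from [bcc_lattice_mesh()].
#' @param image array or list (see [bcc_lattice_mesh()]).
#' @param config a `bcc_config`.
#' @param label label value (default 1).
#' @param spacing,origin used when `image` is a bare array.
#' @return the snapped `tet_mesh` (with attribute `snap_log`: moves
#'   accepted / rejected per iteration).
#' @export
snap_surface <- function(mesh, image, config = bcc_config(), label = 1L,
                         spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  img <- image
  if (is.list(image)) {
    img <- image$image
    spacing <- image$spacing
    origin <- image$origin
  }
  sdf <- signed_distance_field(img, spacing, origin, label)
  adj <- build_adjacency(mesh)
  bv <- adj$boundary_vertices
  if (!length(bv)) return(mesh)
  V <- mesh$vertices
  T <- mesh$tets
  n <- nrow(V)
  Mid <- matrix(rep(c(1, 0, 0, 1, 0, 1), each = n), n, 6L)
  # vertex -> incident tets
  star <- split(rep(seq_len(nrow(T)), times = 4L),
                factor(as.integer(T), levels = seq_len(n)))
  eps <- min(spacing) * 0.25
  log_acc <- integer(config$snap_iters)
  log_rej <- integer(config$snap_iters)
  for (it in seq_len(config$snap_iters)) {
    P <- V[bv, , drop = FALSE]
    phi <- sdf$interp(P)
    act <- which(abs(phi) > 1e-9)
    if (!length(act)) break
    gx <- (sdf$interp(P + rep(c(eps, 0, 0), each = nrow(P))) -
           sdf$interp(P - rep(c(eps, 0, 0), each = nrow(P)))) / (2 * eps)
    gy <- (sdf$interp(P + rep(c(0, eps, 0), each = nrow(P))) -
           sdf$interp(P - rep(c(0, eps, 0), each = nrow(P)))) / (2 * eps)
    gz <- (sdf$interp(P + rep(c(0, 0, eps), each = nrow(P))) -
           sdf$interp(P - rep(c(0, 0, eps), each = nrow(P)))) / (2 * eps)
    gn2 <- gx^2 + gy^2 + gz^2
    for (ii in act) {
      if (gn2[ii] < 1e-12) next
      v <- bv[ii]
      prop <- V[v, ] - config$snap_step * phi[ii] *
        c(gx[ii], gy[ii], gz[ii]) / gn2[ii]
      tt <- star[[v]]
      Ts <- T[tt, , drop = FALSE]
      old <- V[v, ]
      V[v, ] <- prop
      vols <- cpp_signed_volumes(V, Ts)
      if (any(vols <= 0) ||
          min(cpp_mean_ratio(V, Ts, Mid)) < config$min_quality_accept) {
        V[v, ] <- old
        log_rej[it] <- log_rej[it] + 1L
      } else {
        log_acc[it] <- log_acc[it] + 1L
      }
    }
  }
  out <- mesh
  out$vertices <- V
  attr(out, "snap_log") <- data.frame(iter = seq_along(log_acc),
                                      accepted = log_acc, rejected = log_rej)
  out
}
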