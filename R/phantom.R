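#' Synthetic vessel phantom: tube with a saccular bulge
#'
#' Generates a binary labelled voxel grid emulating a segmented vascular
#' scan: a cylindrical tube of radius `tube_radius` swept along an analytic
#' cubic centerline, plus an optional spherical saccular bulge (aneurysm
#' stand-in) attached to the side of the tube. The ground-truth centerline
#' is returned sampled at arc-length steps no larger than the voxel spacing.
#'
#' @param params list overriding any of: `tube_radius` (mm, default 4),
#'   `length` (mm, default 40), `spacing` (mm/voxel, default 1),
#'   `bulge_radius` (mm, default 6; 0 disables the bulge),
#'   `bulge_center_t` (arc parameter in [0,1], default 0.5),
#'   `bulge_offset` (mm from centerline to bulge center, default
#'   `tube_radius`), `curvature` (mm of lateral bow of the cubic
#'   centerline, default 0).
#' @param seed integer seed recorded in the output; the geometry itself is
#'   deterministic, the seed feeds downstream sampling.
#' @return object of class `vessel_phantom`: `image` (3-D integer array,
#'   0/1), `spacing`, `origin` (mm, voxel-center convention), `centerline`
#'   (k x 3 mm), `params`.
#' @export
make_vessel_image <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(list(tube_radius = 4, length = 40, spacing = 1,
                              bulge_radius = 6, bulge_center_t = 0.5,
                              bulge_offset = NULL, curvature = 0), params)
  if (is.null(p$bulge_offset)) p$bulge_offset <- p$tube_radius
  if (p$tube_radius < 2 * p$spacing)
    stop("tube_radius must be at least 2 * spacing")
  cl <- .centerline_points(p)
  bulge_c <- .bulge_center(p, cl)
  margin <- p$tube_radius + 2 * p$spacing
  lo <- pmin(apply(cl, 2L, min) - margin,
             if (p$bulge_radius > 0) bulge_c - p$bulge_radius - 2 * p$spacing
             else rep(Inf, 3L))
  hi <- pmax(apply(cl, 2L, max) + margin,
             if (p$bulge_radius > 0) bulge_c + p$bulge_radius + 2 * p$spacing
             else rep(-Inf, 3L))
  if (p$bulge_radius > 0) {
    span <- apply(cl, 2L, range)
    if (any(bulge_c - p$bulge_radius < span[1L, ] - 4 * margin) ||
        any(bulge_c + p$bulge_radius > span[2L, ] + 4 * margin))
      stop("bulge lies outside the phantom grid")
  }
  dims <- as.integer(ceiling((hi - lo) / p$spacing)) + 1L
  origin <- unname(lo)
  img <- .label_voxels(dims, origin, p$spacing, cl, p$tube_radius,
                       bulge_c, p$bulge_radius)
  if (!any(img != 0L)) stop("phantom produced an empty label")
  structure(list(image = img, spacing = rep(p$spacing, 3L), origin = origin,
                 centerline = cl, velocity_samples = NULL,
                 params = c(p, list(seed = as.integer(seed),
                                    bulge_center = bulge_c))),
            class = "vessel_phantom")
}

# analytic cubic centerline: x runs along the tube, lateral bow in y
.centerline_curve <- function(p, t) {
  cbind(t * p$length,
        p$curvature * 6.75 * t^2 * (1 - t),
        0)
}

.centerline_points <- function(p) {
  # sample densely, then resample at <= spacing arc-length steps
  t0 <- seq(0, 1, length.out = 512L)
  pts <- .centerline_curve(p, t0)
  seglen <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seglen))
  n <- max(2L, ceiling(arc[length(arc)] / p$spacing) + 1L)
  s <- seq(0, arc[length(arc)], length.out = n)
  out <- cbind(stats::approx(arc, pts[, 1L], xout = s)$y,
               stats::approx(arc, pts[, 2L], xout = s)$y,
               stats::approx(arc, pts[, 3L], xout = s)$y)
  colnames(out) <- c("x", "y", "z")
  out
}

.bulge_center <- function(p, cl) {
  i <- max(1L, min(nrow(cl), round(p$bulge_center_t * (nrow(cl) - 1L)) + 1L))
  cl[i, ] + c(0, p$bulge_offset + ifelse(p$bulge_radius > 0, p$bulge_radius * 0.4, 0), 0)
}

.label_voxels <- function(dims, origin, spacing, cl, r_tube, bulge_c, r_bulge) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  xs <- origin[1L] + (seq_len(nx) - 1L) * spacing
  ys <- origin[2L] + (seq_len(ny) - 1L) * spacing
  zs <- origin[3L] + (seq_len(nz) - 1L) * spacing
  img <- array(0L, dim = dims)
  # chunk by z-slab to bound memory of the point-to-centerline distances
  P <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  for (k in seq_len(nz)) {
    d2 <- .min_dist2_to_polyline(cbind(P, zs[k]), cl)
    inside <- d2 <= r_tube^2
    if (r_bulge > 0) {
      db <- (P[, 1L] - bulge_c[1L])^2 + (P[, 2L] - bulge_c[2L])^2 +
        (zs[k] - bulge_c[3L])^2
      inside <- inside | db <= r_bulge^2
    }
    img[, , k] <- as.integer(inside)
  }
  img
}

# squared distance from each point to the densely sampled polyline
.min_dist2_to_polyline <- function(pts, cl) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  for (j in seq_len(nrow(cl))) {
    d2 <- (pts[, 1L] - cl[j, 1L])^2 + (pts[, 2L] - cl[j, 2L])^2 +
      (pts[, 3L] - cl[j, 3L])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
  }
  best
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf(
    "vessel_phantom: %s voxel grid (spacing %.3g mm), %d label voxels\n",
    paste(dim(x$image), collapse = " x "), x$spacing[1L], sum(x$image != 0L)))
  cat(sprintf("  centerline: %d points, tube radius %.3g mm, bulge radius %.3g mm\n",
              nrow(x$centerline), x$params$tube_radius, x$params$bulge_radius))
  if (!is.null(x$velocity_samples))
    cat(sprintf("  %d velocity samples\n", nrow(x$velocity_samples)))
  invisible(x)
}

#' Analytic velocity field of a vessel phantom
#'
#' Poiseuille profile along the local centerline tangent:
#' `u(rho) = u_max * (1 - rho^2 / r^2)` where `rho` is the distance to the
#' centerline and `r` the tube radius. Inside the bulge (outside the tube)
#' the flow is stagnant except for an optional recirculation fraction.
#'
#' @param phantom a `vessel_phantom`.
#' @param positions k x 3 matrix of query positions (mm).
#' @param u_max peak axial speed (mm/s, default 500 -- a typical cerebral
#'   artery systolic peak).
#' @param recirc_fraction fraction of `u_max` for the tangential
#'   recirculation speed inside the bulge (default 0).
#' @return k x 3 matrix of velocities (mm/s).
#' @export
phantom_velocity <- function(phantom, positions, u_max = 500,
                             recirc_fraction = 0) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  cl <- phantom$centerline
  p <- phantom$params
  k <- nrow(positions)
  vel <- matrix(0, k, 3L)
  # nearest centerline sample + tangent there
  tang <- rbind(cl[2L, ] - cl[1L, ],
                (cl[-(1:2), , drop = FALSE] - cl[seq_len(nrow(cl) - 2L), , drop = FALSE]) / 2,
                cl[nrow(cl), ] - cl[nrow(cl) - 1L, ])
  tang <- tang / sqrt(rowSums(tang^2))
  for (i in seq_len(k)) {
    d2 <- (cl[, 1L] - positions[i, 1L])^2 + (cl[, 2L] - positions[i, 2L])^2 +
      (cl[, 3L] - positions[i, 3L])^2
    j <- which.min(d2)
    rho2 <- d2[j]
    if (rho2 <= p$tube_radius^2) {
      speed <- u_max * (1 - rho2 / p$tube_radius^2)
      vel[i, ] <- speed * tang[j, ]
    } else if (p$bulge_radius > 0) {
      db2 <- sum((positions[i, ] - p$bulge_center)^2)
      if (db2 <= p$bulge_radius^2 && recirc_fraction > 0) {
        # weak swirl around the bulge axis (z)
        rvec <- positions[i, ] - p$bulge_center
        sw <- c(-rvec[2L], rvec[1L], 0)
        ns <- sqrt(sum(sw^2))
        if (ns > 0) vel[i, ] <- recirc_fraction * u_max * sw / ns
      }
    }
  }
  vel
}

#' Streamline velocity samples inside a vessel phantom
#'
#' Draws `n_samples` positions uniformly inside the labelled region
#' (rejection sampling over the label bounding box) and evaluates the
#' analytic Poiseuille field there. Optional isotropic Gaussian noise on the
#' velocity vectors lets metric construction be exercised under noise.
#'
#' @param phantom a `vessel_phantom`.
#' @param n_samples number of samples (> 0).
#' @param seed integer seed.
#' @param u_max,recirc_fraction passed to [phantom_velocity()].
#' @param noise_sd standard deviation of Gaussian velocity noise (mm/s,
#'   default 0).
#' @return the phantom with `velocity_samples` set: a data.frame with
#'   columns x, y, z (mm) and u, v, w (mm/s).
#' @export
make_streamlines <- function(phantom, n_samples = 200L, seed = 1L,
                             u_max = 500, recirc_fraction = 0,
                             noise_sd = 0) {
  if (n_samples <= 0L) stop("n_samples must be positive")
  p <- phantom$params
  cl <- phantom$centerline
  set.seed(seed)
  lo <- apply(cl, 2L, min) - p$tube_radius
  hi <- apply(cl, 2L, max) + p$tube_radius
  if (p$bulge_radius > 0) {
    lo <- pmin(lo, p$bulge_center - p$bulge_radius)
    hi <- pmax(hi, p$bulge_center + p$bulge_radius)
  }
  acc <- matrix(numeric(), 0L, 3L)
  while (nrow(acc) < n_samples) {
    cand <- cbind(stats::runif(4L * n_samples, lo[1L], hi[1L]),
                  stats::runif(4L * n_samples, lo[2L], hi[2L]),
                  stats::runif(4L * n_samples, lo[3L], hi[3L]))
    d2 <- .min_dist2_to_polyline(cand, cl)
    keep <- d2 <= p$tube_radius^2
    if (p$bulge_radius > 0) {
      db2 <- (cand[, 1L] - p$bulge_center[1L])^2 +
        (cand[, 2L] - p$bulge_center[2L])^2 +
        (cand[, 3L] - p$bulge_center[3L])^2
      keep <- keep | db2 <= p$bulge_radius^2
    }
    acc <- rbind(acc, cand[keep, , drop = FALSE])
  }
  pos <- acc[seq_len(n_samples), , drop = FALSE]
  vel <- phantom_velocity(phantom, pos, u_max = u_max,
                          recirc_fraction = recirc_fraction)
  if (noise_sd > 0)
    vel <- vel + matrix(stats::rnorm(3L * n_samples, sd = noise_sd), ncol = 3L)
  out <- data.frame(x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                    u = vel[, 1L], v = vel[, 2L], w = vel[, 3L])
  phantom$velocity_samples <- out
  phantom$params$streamline_seed <- as.integer(seed)
  phantom
}

#' Analytic primitive label images (sphere, torus)
#'
#' @param shape "sphere" or "torus".
#' @param params for a sphere: `radius` (mm), `spacing`; for a torus:
#'   `major_radius`, `minor_radius`, `spacing`. A margin of 2 voxels is
#'   added around the shape.
#' @return list with `image` (0/1 integer array), `spacing`, `origin`.
#' @export
make_primitive_image <- function(shape = c("sphere", "torus"), params = list()) {
  shape <- match.arg(shape)
  p <- utils::modifyList(list(radius = 10, major_radius = 10,
                              minor_radius = 3, spacing = 1), params)
  sp <- p$spacing
  if (shape == "sphere") {
    if (p$radius < sp) stop("sphere radius below spacing yields an empty label")
    ext <- p$radius + 2 * sp
  } else {
    if (p$minor_radius <= 0) stop("torus minor_radius must be positive")
    if (p$minor_radius < sp) stop("torus minor radius below spacing yields an empty label")
    ext <- p$major_radius + p$minor_radius + 2 * sp
  }
  n <- as.integer(2L * ceiling(ext / sp) + 1L)
  origin <- rep(-(n - 1L) / 2 * sp, 3L)
  ax <- origin[1L] + (seq_len(n) - 1L) * sp
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax, each = n * n), dim = c(n, n, n))
  if (shape == "sphere") {
    img <- (X^2 + Y^2 + Z^2 <= p$radius^2)
  } else {
    img <- ((sqrt(X^2 + Y^2) - p$major_radius)^2 + Z^2 <= p$minor_radius^2)
  }
  img <- array(as.integer(img), dim = dim(img))
  if (!any(img != 0L)) stop("primitive produced an empty label")
  list(image = img, spacing = rep(sp, 3L), origin = origin)
}
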