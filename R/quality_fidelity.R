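#' Dihedral angle statistics
#'
#' Computes the six dihedral angles (degrees) of every tet from its
#' face-normal pairs. Degenerate tets are flagged and excluded from the
#' histogram.
#'
#' @param mesh a `tet_mesh`.
#' @param breaks histogram breaks in degrees (default every 10 degrees).
#' @return list with `angles` (m x 6), `min`, `max`, `per_tet_min`,
#'   `per_tet_max`, `histogram`, `degenerate` (tet ids).
#' @export
dihedral_angles <- function(mesh, breaks = seq(0, 180, by = 10)) {
  A <- cpp_dihedral_angles(mesh$vertices, mesh$tets)
  bad <- which(apply(A, 1L, function(r) any(!is.finite(r))))
  ok <- if (length(bad)) A[-bad, , drop = FALSE] else A
  h <- hist(as.numeric(ok), breaks = breaks, plot = FALSE)
  list(angles = A,
       min = if (length(ok)) min(ok) else NA_real_,
       max = if (length(ok)) max(ok) else NA_real_,
       per_tet_min = apply(A, 1L, min),
       per_tet_max = apply(A, 1L, max),
       histogram = h,
       degenerate = bad)
}

#' Two-sided Hausdorff distance between point sets
#'
#' `HD_A->B = max_a min_b ||a - b||` and `HD = max(HD_A->B, HD_B->A)`,
#' computed exactly (identical to the O(n^2) definition).
#'
#' @param points_a,points_b non-empty k x 3 matrices (mm).
#' @return list with `HD`, `HD_ab`, `HD_ba`.
#' @export
hausdorff <- function(points_a, points_b) {
  A <- matrix(as.numeric(points_a), ncol = 3L)
  B <- matrix(as.numeric(points_b), ncol = 3L)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("point sets must be non-empty")
  ab <- cpp_directed_hausdorff(A, B)
  ba <- cpp_directed_hausdorff(B, A)
  list(HD = max(ab, ba), HD_ab = ab, HD_ba = ba)
}

#' Boundary voxel centers of a labelled image
#'
#' Centers (world mm, voxel-center convention: origin + index * spacing
#' with 0-based indices) of label voxels having at least one six-connected
#' neighbor outside the label; voxels on the grid border count as
#' boundary.
#'
#' @param image 3-D integer array or a list with `image`, `spacing`,
#'   `origin`.
#' @param label label value (default 1).
#' @param spacing,origin used when `image` is a bare array.
#' @return k x 3 matrix of boundary voxel centers.
#' @export
boundary_voxels <- function(image, label = 1L, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  img <- image
  if (is.list(image)) {
    img <- image$image
    spacing <- image$spacing
    origin <- image$origin
  }
  if (!any(img == label)) stop("label absent from image")
  m <- img == label
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- m
  slab <- function(i, j, k) array(pad[i, j, k], d)
  core <- slab(2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L))
  nb_all <- slab(1:d[1L], 2:(d[2L] + 1L), 2:(d[3L] + 1L)) &
    slab(3:(d[1L] + 2L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)) &
    slab(2:(d[1L] + 1L), 1:d[2L], 2:(d[3L] + 1L)) &
    slab(2:(d[1L] + 1L), 3:(d[2L] + 2L), 2:(d[3L] + 1L)) &
    slab(2:(d[1L] + 1L), 2:(d[2L] + 1L), 1:d[3L]) &
    slab(2:(d[1L] + 1L), 2:(d[2L] + 1L), 3:(d[3L] + 2L))
  bnd <- which(core & !nb_all, arr.ind = TRUE)
  if (!is.matrix(bnd)) bnd <- matrix(bnd, ncol = 3L)
  cbind(origin[1L] + (bnd[, 1L] - 1L) * spacing[1L],
        origin[2L] + (bnd[, 2L] - 1L) * spacing[2L],
        origin[3L] + (bnd[, 3L] - 1L) * spacing[3L])
}

#' Metric conformity report
#'
#' Mean-ratio quality per tet and metric edge length per edge, with the
#' histograms used for conformity plots: 16 uniform bins on [0, 1] for
#' `Q_k` and logarithmic bins for `L_e`.
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field` (NULL for identity).
#' @return object of class `quality_report` with `Q`, `L_e`, `q_hist`
#'   (16-bin counts), `l_hist` (log2 bins), and summary quantiles.
#' @export
conformity_report <- function(mesh, field = NULL) {
  Q <- mean_ratio(mesh, field)
  le <- edge_lengths(mesh, field)$L_e
  q_breaks <- seq(0, 1, length.out = 17L)
  q_hist <- hist(pmin(pmax(Q, 0), 1), breaks = q_breaks, plot = FALSE)$counts
  l_breaks <- 2^seq(-5, 5, by = 0.5)
  lh <- hist(pmin(pmax(le, min(l_breaks)), max(l_breaks)),
             breaks = l_breaks, plot = FALSE)$counts
  structure(list(
    Q = Q, L_e = le,
    q_hist = q_hist, q_breaks = q_breaks,
    l_hist = lh, l_breaks = l_breaks,
    q_quantiles = stats::quantile(Q, c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)),
    l_quantiles = stats::quantile(le, c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)),
    unit_fraction = mean(le >= 1 / sqrt(2) & le <= sqrt(2))),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "quality_report: %d tets, %d edges\n  mean Q = %.3f (min %.3f), median L_e = %.3f\n  %.1f%% of edges in [1/sqrt2, sqrt2]\n",
    length(x$Q), length(x$L_e), mean(x$Q), min(x$Q),
    stats::median(x$L_e), 100 * x$unit_fraction))
  invisible(x)
}

#' @export
plot.quality_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(pmax(x$q_hist, 0.5), log = "y",
                    names.arg = sprintf("%.2f", utils::head(x$q_breaks, -1L)),
                    las = 2, main = "mean ratio Q", ylab = "count (log)")
  graphics::barplot(pmax(x$l_hist, 0.5), log = "y",
                    names.arg = sprintf("%.2g", utils::head(x$l_breaks, -1L)),
                    las = 2, main = "metric edge length", ylab = "count (log)")
  invisible(x)
}

#' Full quality and fidelity report
#'
#' @param mesh a `tet_mesh`.
#' @param field optional `metric_field` for conformity statistics.
#' @param image optional labelled image (list with `image`, `spacing`,
#'   `origin`) for the Hausdorff fidelity check against the boundary
#'   voxels.
#' @param label image label (default 1).
#' @return list with `dihedral`, `conformity`, and (if an image is given)
#'   `HD`, `HD_im`, `HD_mi` (image-to-mesh and mesh-to-image directed
#'   values, mm).
#' @export
quality_report <- function(mesh, field = NULL, image = NULL, label = 1L) {
  out <- list(dihedral = dihedral_angles(mesh),
              conformity = conformity_report(mesh, field))
  if (!is.null(image)) {
    surf <- extract_surface(mesh)
    bv <- boundary_voxels(image, label)
    h <- hausdorff(bv, surf$vertices)
    out$HD <- h$HD
    out$HD_im <- h$HD_ab
    out$HD_mi <- h$HD_ba
  }
  out
}
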