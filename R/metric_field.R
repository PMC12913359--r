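# symmetric tensors are stored packed per vertex as the 6-vector
# (xx, xy, xz, yy, yz, zz) in mm^-2

.sym6_to_mat <- function(s) {
  matrix(c(s[1L], s[2L], s[3L],
           s[2L], s[4L], s[5L],
           s[3L], s[5L], s[6L]), 3L, 3L)
}

.mat_to_sym6 <- function(M) {
  c(M[1L, 1L], M[1L, 2L], M[1L, 3L], M[2L, 2L], M[2L, 3L], M[3L, 3L])
}

# clamp eigenvalues of a symmetric 3x3 into [lo, hi]; keeps SPD and bounds
# anisotropy
.clamp_eig <- function(M, lo, hi) {
  e <- eigen(M, symmetric = TRUE)
  v <- pmin(pmax(e$values, lo), hi)
  e$vectors %*% (v * t(e$vectors))
}

.is_spd <- function(M, tol = 0) {
  isTRUE(all(abs(M - t(M)) < 1e-8 * (1 + max(abs(M))))) &&
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > tol
}

#' Per-vertex metric tensor field
#'
#' A metric field prescribes, at every mesh vertex, a symmetric positive
#' definite 3x3 tensor `M_i` whose unit ball is the set of ideal edge
#' vectors: an edge `v` has metric length `sqrt(v' M v)`, and a conforming
#' mesh has all edges at metric length 1. Eigenvalues are clamped into
#' `[1/h_max^2, 1/h_min^2]` so allowed edge lengths stay in
#' `[h_min, h_max]`.
#'
#' @param tensors n x 6 matrix of packed tensors (xx, xy, xz, yy, yz, zz)
#'   or a list of n symmetric 3x3 matrices.
#' @param h_min,h_max edge-length bounds in mm.
#' @param provenance one of "landmark", "velocity", "isotropic", "file".
#' @param clamp apply eigenvalue clamping (default TRUE).
#' @return object of class `metric_field`.
#' @export
metric_field <- function(tensors, h_min = 0.1, h_max = 100,
                         provenance = "file", clamp = TRUE) {
  if (is.list(tensors))
    tensors <- do.call(rbind, lapply(tensors, .mat_to_sym6))
  tensors <- as.matrix(tensors)
  if (ncol(tensors) != 6L) stop("tensors must be n x 6 (packed symmetric)")
  storage.mode(tensors) <- "double"
  if (h_min <= 0 || h_max <= h_min) stop("need 0 < h_min < h_max")
  lo <- 1 / h_max^2
  hi <- 1 / h_min^2
  if (clamp && nrow(tensors) > 0L) {
    for (i in seq_len(nrow(tensors))) {
      M <- .sym6_to_mat(tensors[i, ])
      e <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      if (min(e) < lo || max(e) > hi)
        tensors[i, ] <- .mat_to_sym6(.clamp_eig(M, lo, hi))
    }
  }
  structure(list(tensors = tensors, h_min = h_min, h_max = h_max,
                 provenance = provenance),
            class = "metric_field")
}

#' @export
print.metric_field <- function(x, ...) {
  n <- nrow(x$tensors)
  cat(sprintf("metric_field (%s): %d vertex tensors, h in [%.3g, %.3g] mm\n",
              x$provenance, n, x$h_min, x$h_max))
  invisible(x)
}

#' Uniform isotropic metric field
#'
#' @param n number of vertices.
#' @param h target edge length (mm).
#' @return a `metric_field` with every tensor `(1/h^2) I`.
#' @export
uniform_metric <- function(n, h = 1) {
  t6 <- matrix(rep(c(1 / h^2, 0, 0, 1 / h^2, 0, 1 / h^2), each = n), n, 6L)
  metric_field(t6, h_min = h / 1e3, h_max = h * 1e3,
               provenance = "isotropic", clamp = FALSE)
}

# ---- minimum-volume enclosing ellipsoid ----------------------------------

#' Minimum-volume enclosing ellipsoid (Khachiyan iteration)
#'
#' Finds the smallest ellipsoid `(x - c)' E (x - c) <= 1` containing all
#' points. Affinely degenerate point sets are handled by ridge
#' regularization of the normal matrix and by clamping the shape matrix so
#' the smallest half-axis is `eps_reg` (a ball of radius `eps_reg` around
#' each input point is effectively included).
#'
#' @param points k x 3 matrix (k >= 1).
#' @param tol relative convergence tolerance of the Khachiyan update
#'   (default 1e-7).
#' @param eps_reg regularization half-axis; default `1e-6 *` the
#'   bounding-box diagonal (floored at 1e-9 for single points).
#' @param max_iter iteration cap.
#' @return object of class `ellipsoid` with `center` (length 3) and
#'   `shape` (SPD 3x3 matrix E).
#' @export
mvee <- function(points, tol = 1e-7, eps_reg = NULL, max_iter = 1000L) {
  points <- matrix(as.numeric(points), ncol = 3L)
  k <- nrow(points)
  if (k < 1L) stop("mvee needs at least one point")
  bbd <- sqrt(sum((apply(points, 2L, max) - apply(points, 2L, min))^2))
  if (is.null(eps_reg)) eps_reg <- max(1e-6 * bbd, 1e-9)
  if (k == 1L) {
    return(structure(list(center = points[1L, ],
                          shape = diag(3L) / eps_reg^2),
                     class = "ellipsoid"))
  }
  Q <- rbind(t(points), 1)              # 4 x k lifted points
  u <- rep(1 / k, k)
  d <- 3
  ridge <- 1e-12 * (1 + bbd^2)
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q)) + diag(ridge, 4L)
    Minv <- tryCatch(solve(X, Q), error = function(e) NULL)
    if (is.null(Minv)) {
      ridge <- ridge * 100
      next
    }
    w <- colSums(Q * Minv)              # Mahalanobis weights
    j <- which.max(w)
    err <- w[j] / (d + 1) - 1           # optimality gap of the dual iterate
    if (!is.finite(err) || err < tol) break
    step <- (w[j] - d - 1) / ((d + 1) * (w[j] - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  ctr <- as.numeric(t(points) %*% u)
  S <- t(points) %*% (u * points) - tcrossprod(ctr)
  S <- (S + t(S)) / 2
  # half-axes a_i = sqrt(d * lambda_i(S)), floored at eps_reg so
  # affinely degenerate sets yield a thin but valid ellipsoid
  eS <- eigen(S, symmetric = TRUE)
  a <- pmax(sqrt(d * pmax(eS$values, 0)), eps_reg)
  E <- eS$vectors %*% ((1 / a^2) * t(eS$vectors))
  # enforce the cover exactly (Khachiyan stops at a small dual gap)
  D <- sweep(points, 2L, ctr)
  maxv <- max(rowSums((D %*% E) * D))
  if (is.finite(maxv) && maxv > 1) E <- E / maxv
  structure(list(center = ctr, shape = E), class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  hax <- 1 / sqrt(rev(eigen(x$shape, symmetric = TRUE, only.values = TRUE)$values))
  cat(sprintf("ellipsoid: center (%.4g, %.4g, %.4g), half-axes %.4g %.4g %.4g\n",
              x$center[1L], x$center[2L], x$center[3L], hax[1L], hax[2L], hax[3L]))
  invisible(x)
}

# ---- metric construction -------------------------------------------------

#' Landmark (centerline) ellipsoid metric
#'
#' For each mesh vertex, the minimum-volume enclosing ellipsoid of the
#' vertex together with its `k` nearest landmarks (e.g. centerline / medial
#' axis points) is computed; its shape matrix, eigenvalue-clamped into
#' `[1/h_max^2, 1/h_min^2]`, is the vertex tensor. Vertices are processed
#' independently, so the result does not depend on processing order.
#'
#' @param mesh a `tet_mesh`.
#' @param landmarks l x 3 matrix of landmark points (mm).
#' @param k number of nearest landmarks per vertex (default 8; capped at
#'   the landmark count).
#' @param h_min,h_max allowed edge-length bounds (mm).
#' @param alpha scalar multiplier applied to each ellipsoid shape matrix
#'   before clamping (default 1): half-axes map directly to allowed edge
#'   lengths.
#' @return a `metric_field` with provenance "landmark".
#' @export
build_metric_from_landmarks <- function(mesh, landmarks, k = 8L,
                                        h_min = 1, h_max = 8,
                                        alpha = 1) {
  landmarks <- matrix(as.numeric(landmarks), ncol = 3L)
  if (nrow(landmarks) < 1L) stop("no landmarks supplied")
  k <- min(as.integer(k), nrow(landmarks))
  V <- mesh$vertices
  n <- nrow(V)
  t6 <- matrix(0, n, 6L)
  lo <- 1 / h_max^2
  hi <- 1 / h_min^2
  for (i in seq_len(n)) {
    d2 <- (landmarks[, 1L] - V[i, 1L])^2 + (landmarks[, 2L] - V[i, 2L])^2 +
      (landmarks[, 3L] - V[i, 3L])^2
    nn <- order(d2)[seq_len(k)]
    ell <- mvee(rbind(V[i, , drop = FALSE], landmarks[nn, , drop = FALSE]))
    t6[i, ] <- .mat_to_sym6(.clamp_eig(alpha * ell$shape, lo, hi))
  }
  metric_field(t6, h_min = h_min, h_max = h_max,
               provenance = "landmark", clamp = FALSE)
}

#' Velocity-gradient metric from streamline samples
#'
#' For each vertex, the `n_nearest` streamline samples provide a
#' ridge-regularized least-squares velocity gradient `G` (from the samples'
#' position and velocity differences about their mean). The largest
#' absolute eigenvalue of the symmetric part of `G` sets a stretching
#' factor `s = min(1 + stretch_coeff * lambda_max / lambda_ref, s_max)`,
#' and the tensor allows edge length `h0 * s` along the mean flow direction
#' and `h0` transversally, so elements stretch along the dominant velocity
#' direction. `lambda_ref` defaults to the median `lambda_max` over all
#' vertices. A vertex with zero mean sample velocity gets the isotropic
#' tensor `(1/h0^2) I`.
#'
#' @param mesh a `tet_mesh`.
#' @param velocity_samples data.frame with columns x, y, z, u, v, w (or a
#'   k x 6 matrix).
#' @param n_nearest samples used per vertex (default 3).
#' @param stretch_coeff gain of the stretching factor (default 1).
#' @param s_max stretching cap (default 4).
#' @param h0 transverse target edge length (mm).
#' @param lambda_ref reference shear rate; NULL (default) uses the median.
#' @return a `metric_field` with provenance "velocity".
#' @export
build_metric_from_velocity <- function(mesh, velocity_samples, n_nearest = 3L,
                                       stretch_coeff = 1, s_max = 4,
                                       h0 = 1, lambda_ref = NULL) {
  S <- as.matrix(velocity_samples)
  if (ncol(S) != 6L) stop("velocity_samples must have 6 columns (x,y,z,u,v,w)")
  if (nrow(S) < n_nearest) stop("fewer velocity samples than n_nearest")
  V <- mesh$vertices
  n <- nrow(V)
  lam <- numeric(n)
  dirs <- matrix(0, n, 3L)
  scale2 <- mean(rowSums(S[, 1:3, drop = FALSE]^2))
  ridge <- 1e-8 * (1 + scale2)
  for (i in seq_len(n)) {
    d2 <- (S[, 1L] - V[i, 1L])^2 + (S[, 2L] - V[i, 2L])^2 +
      (S[, 3L] - V[i, 3L])^2
    nn <- order(d2)[seq_len(n_nearest)]
    P <- S[nn, 1:3, drop = FALSE]
    W <- S[nn, 4:6, drop = FALSE]
    dP <- sweep(P, 2L, colMeans(P))
    dW <- sweep(W, 2L, colMeans(W))
    G <- solve(crossprod(dP) + diag(ridge, 3L), crossprod(dP, dW))
    Sg <- (G + t(G)) / 2
    lam[i] <- max(abs(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values))
    mv <- colMeans(W)
    nm <- sqrt(sum(mv^2))
    if (nm > 0) dirs[i, ] <- mv / nm
  }
  if (is.null(lambda_ref)) lambda_ref <- stats::median(lam[lam > 0])
  if (!is.finite(lambda_ref) || lambda_ref <= 0) lambda_ref <- 1
  t6 <- matrix(0, n, 6L)
  iso6 <- c(1 / h0^2, 0, 0, 1 / h0^2, 0, 1 / h0^2)
  for (i in seq_len(n)) {
    d1 <- dirs[i, ]
    if (sum(d1^2) == 0) {
      t6[i, ] <- iso6
      next
    }
    s <- min(1 + stretch_coeff * lam[i] / lambda_ref, s_max)
    # orthonormal frame with first axis along the flow
    a <- if (abs(d1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    d2v <- a - sum(a * d1) * d1
    d2v <- d2v / sqrt(sum(d2v^2))
    d3v <- c(d1[2L] * d2v[3L] - d1[3L] * d2v[2L],
             d1[3L] * d2v[1L] - d1[1L] * d2v[3L],
             d1[1L] * d2v[2L] - d1[2L] * d2v[1L])
    R <- rbind(d1, d2v, d3v)
    M <- t(R) %*% (c(1 / (h0 * s)^2, 1 / h0^2, 1 / h0^2) * R)
    t6[i, ] <- .mat_to_sym6((M + t(M)) / 2)
  }
  metric_field(t6, h_min = h0 / 2, h_max = h0 * s_max * 2,
               provenance = "velocity", clamp = FALSE)
}

#' Isotropic distance-to-landmark sizing metric
#'
#' Allowed edge length grows linearly with the distance to the nearest
#' landmark: `h(d) = clamp(h_min + g * d, h_min, h_max)`; the tensor is
#' `(1/h^2) I`.
#'
#' @param points n x 3 matrix of evaluation points, or a `tet_mesh` (its
#'   vertices are used).
#' @param landmarks l x 3 matrix.
#' @param h_min size on a landmark (mm, > 0).
#' @param g linear growth rate (mm per mm).
#' @param h_max size cap (mm).
#' @return a `metric_field` with provenance "isotropic".
#' @export
isotropic_sizing_metric <- function(points, landmarks, h_min = 1, g = 0.5,
                                    h_max = 8) {
  if (inherits(points, "tet_mesh")) points <- points$vertices
  if (h_min <= 0) stop("h_min must be positive")
  landmarks <- matrix(as.numeric(landmarks), ncol = 3L)
  if (nrow(landmarks) < 1L) stop("no landmarks supplied")
  points <- matrix(as.numeric(points), ncol = 3L)
  d <- sqrt(.min_dist2_to_polyline(points, landmarks))
  h <- pmin(pmax(h_min + g * d, h_min), h_max)
  n <- nrow(points)
  t6 <- cbind(1 / h^2, 0, 0, 1 / h^2, 0, 1 / h^2)
  metric_field(t6, h_min = h_min, h_max = h_max,
               provenance = "isotropic", clamp = FALSE)
}

# ---- edge and element measures -------------------------------------------

#' Metric length of an edge
#'
#' Endpoint lengths `L_a = sqrt(v' M_a v)` and `L_b = sqrt(v' M_b v)` are
#' combined by the log-mean `(L_a - L_b) / log(L_a / L_b)` when they differ
#' by more than 0.001, and by the arithmetic mean otherwise.
#'
#' @param p_a,p_b edge endpoints (length-3 numeric).
#' @param M_a,M_b SPD 3x3 tensors at the endpoints.
#' @return list with `v_e` (edge vector), `L_a`, `L_b`, `L_e`.
#' @export
edge_metric_length <- function(p_a, p_b, M_a, M_b) {
  if (!.is_spd(M_a) || !.is_spd(M_b)) stop("endpoint tensors must be SPD")
  v <- as.numeric(p_b) - as.numeric(p_a)
  L_a <- sqrt(max(0, sum(v * (M_a %*% v))))
  L_b <- sqrt(max(0, sum(v * (M_b %*% v))))
  L_e <- if (abs(L_a - L_b) > 0.001) (L_a - L_b) / log(L_a / L_b)
         else (L_a + L_b) / 2
  list(v_e = v, L_a = L_a, L_b = L_b, L_e = L_e)
}

#' Arithmetic-mean edge tensor interpolation
#'
#' @param M_a,M_b SPD 3x3 tensors.
#' @param mode "arithmetic" (default) or "log_euclidean".
#' @return interpolated SPD 3x3 tensor.
#' @export
interpolate_edge_tensor <- function(M_a, M_b, mode = c("arithmetic", "log_euclidean")) {
  mode <- match.arg(mode)
  if (mode == "arithmetic") return((M_a + M_b) / 2)
  ea <- eigen(M_a, symmetric = TRUE)
  eb <- eigen(M_b, symmetric = TRUE)
  la <- ea$vectors %*% (log(ea$values) * t(ea$vectors))
  lb <- eb$vectors %*% (log(eb$values) * t(eb$vectors))
  em <- eigen((la + lb) / 2, symmetric = TRUE)
  em$vectors %*% (exp(em$values) * t(em$vectors))
}

#' Metric mean-ratio shape quality
#'
#' For each tet `k`, the tensor `M_mean` is the arithmetic mean of the four
#' vertex tensors (the interpolated tensor at the element centroid) and
#' `Q_k = (36 / 3^(1/3)) * (|k| sqrt(det M_mean))^(2/3) /
#' sum_e v_e' M_mean v_e` over the six edges, clamped to `[0, 1]`. One is
#' the quality of an equilateral element in the metric; degenerate
#' (zero-volume) tets score 0.
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field` on its vertices (NULL for the identity
#'   metric).
#' @param which optional tet indices (default all).
#' @return numeric vector of `Q_k`.
#' @export
mean_ratio <- function(mesh, field = NULL, which = NULL) {
  T <- mesh$tets
  if (!is.null(which)) T <- T[which, , drop = FALSE]
  if (nrow(T) == 0L) return(numeric())
  V <- mesh$vertices
  spread <- pmax(
    rowSums(abs(V[T[, 2L], , drop = FALSE] - V[T[, 1L], , drop = FALSE])),
    rowSums(abs(V[T[, 3L], , drop = FALSE] - V[T[, 1L], , drop = FALSE])),
    rowSums(abs(V[T[, 4L], , drop = FALSE] - V[T[, 1L], , drop = FALSE])))
  if (any(spread == 0))
    stop("element with all edges null (coincident vertices)")
  M <- .field_tensors(field, nrow(mesh$vertices))
  cpp_mean_ratio(mesh$vertices, T, M)
}

.field_tensors <- function(field, n) {
  if (is.null(field)) {
    M <- matrix(rep(c(1, 0, 0, 1, 0, 1), each = n), n, 6L)
  } else {
    M <- field$tensors
    if (nrow(M) != n) stop("metric field does not match mesh vertex count")
  }
  M
}

#' Metric lengths of all mesh edges
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field` (NULL for identity).
#' @return list with `edges` (e x 2) and `L_e` (numeric).
#' @export
edge_lengths <- function(mesh, field = NULL) {
  E <- .mesh_edges(mesh$tets)
  M <- .field_tensors(field, nrow(mesh$vertices))
  list(edges = E, L_e = if (nrow(E)) cpp_edge_metric_lengths(mesh$vertices, E, M)
                        else numeric())
}

#' Discrete metric complexity
#'
#' `C(M) = sum_i sqrt(det M_i) V_i` where `V_i` is the barycentric dual
#' volume of vertex i (one quarter of each incident tet volume), so the
#' dual volumes sum exactly to the mesh volume. The complexity is
#' proportional to the number of vertices/tets a metric-conforming mesh
#' needs.
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field` (NULL for identity, in which case C equals
#'   the mesh volume).
#' @return list with `C` (scalar) and `V` (per-vertex dual volumes).
#' @export
complexity <- function(mesh, field = NULL) {
  n <- nrow(mesh$vertices)
  if (nrow(mesh$tets) == 0L) return(list(C = 0, V = numeric(n)))
  vol <- cpp_signed_volumes(mesh$vertices, mesh$tets)
  Vdual <- numeric(n)
  for (k in 1:4) {
    agg <- rowsum(vol / 4, group = mesh$tets[, k])
    idx <- as.integer(rownames(agg))
    Vdual[idx] <- Vdual[idx] + agg[, 1L]
  }
  M <- .field_tensors(field, n)
  det6 <- M[, 1L] * (M[, 4L] * M[, 6L] - M[, 5L]^2) -
    M[, 2L] * (M[, 2L] * M[, 6L] - M[, 5L] * M[, 3L]) +
    M[, 3L] * (M[, 2L] * M[, 5L] - M[, 4L] * M[, 3L])
  list(C = sum(sqrt(pmax(det6, 0)) * Vdual), V = Vdual)
}

#' Scale a metric field to a target complexity
#'
#' Multiplies every tensor by `(C_r / C(M))^(2/3)`, which scales the
#' complexity exactly to `C_r` (determinants scale by the cube of the
#' factor, their square roots by its 3/2 power).
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field`.
#' @param C_r target complexity (> 0).
#' @return the rescaled `metric_field` (clamping bounds rescaled too).
#' @export
scale_to_complexity <- function(mesh, field, C_r) {
  if (C_r <= 0) stop("target complexity must be positive")
  C0 <- complexity(mesh, field)$C
  if (C0 <= 0) stop("field has zero complexity")
  f <- (C_r / C0)^(2 / 3)
  out <- field
  out$tensors <- field$tensors * f
  out$h_min <- field$h_min / sqrt(f)
  out$h_max <- field$h_max / sqrt(f)
  out
}

#' PODM-style refinement predicate
#'
#' TRUE iff any edge of the element has metric length above the threshold
#' `tau`, where the edge tensor is the arithmetic mean of the endpoint
#' tensors and the length is `sqrt(v' M v)`.
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field`.
#' @param element tet index.
#' @param tau threshold (> 0, default sqrt(2)).
#' @return logical.
#' @export
refinement_predicate <- function(mesh, field, element, tau = sqrt(2)) {
  if (tau <= 0) stop("tau must be positive")
  t <- mesh$tets[element, ]
  M <- .field_tensors(field, nrow(mesh$vertices))
  for (e in seq_len(6L)) {
    a <- t[.tet_edges[e, 1L]]
    b <- t[.tet_edges[e, 2L]]
    v <- mesh$vertices[b, ] - mesh$vertices[a, ]
    Mb <- (.sym6_to_mat(M[a, ]) + .sym6_to_mat(M[b, ])) / 2
    if (sqrt(max(0, sum(v * (Mb %*% v)))) > tau) return(TRUE)
  }
  FALSE
}
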