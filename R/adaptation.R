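#' Adaptation configuration
#'
#' Thresholds follow the unit-mesh convention: edges are ideal at metric
#' length 1, refined above `L_max = sqrt(2)` and collapsed below
#' `L_min = 1/sqrt(2)`.
#'
#' @param L_max refine threshold (metric length).
#' @param L_min collapse threshold (must satisfy L_min < 1 < L_max).
#' @param q_accept strict improvement margin for flips and the tolerance
#'   for collapse quality loss (default 1e-4; prevents flip cycling).
#' @param max_ma_iters,max_qi_iters iteration caps of the mesh-adaptation
#'   and quality-improvement phases.
#' @param point_tol MA terminates when a pass inserts fewer than
#'   `point_tol * n_vertices` points (default 0.01).
#' @param qi_tol QI terminates when the mean mean-ratio improves by less
#'   (default 1e-3).
#' @param freeze_surface keep boundary vertices and faces bit-identical
#'   (default TRUE).
#' @param seed recorded for reproducibility metadata.
#' @return an `adapt_config` list.
#' @export
adapt_config <- function(L_max = sqrt(2), L_min = 1 / sqrt(2),
                         q_accept = 1e-4, max_ma_iters = 15L,
                         max_qi_iters = 10L, point_tol = 0.01,
                         qi_tol = 1e-3, freeze_surface = TRUE, seed = 1L) {
  stopifnot(L_min < 1, L_max > 1, q_accept >= 0)
  structure(list(L_max = L_max, L_min = L_min, q_accept = q_accept,
                 max_ma_iters = as.integer(max_ma_iters),
                 max_qi_iters = as.integer(max_qi_iters),
                 point_tol = point_tol, qi_tol = qi_tol,
                 freeze_surface = isTRUE(freeze_surface),
                 seed = as.integer(seed)),
            class = "adapt_config")
}

#' Flip-attempt tracking state
#'
#' Per-tet flags driving the optimized local reconnection: whether a flip
#' has been attempted, the mesh version at the last attempt, and whether a
#' speculative lock failure forces a retry.
#'
#' @param n_tets number of tets.
#' @return an `adapt_state` list of integer vectors.
#' @export
adapt_state <- function(n_tets) {
  structure(list(attempted = integer(n_tets), stamp = integer(n_tets),
                 lockfail = integer(n_tets)),
            class = "adapt_state")
}

# edge incidence: unique undirected edges plus the (edge, tet) occurrence
# table; numeric keys keep grouping deterministic
.edge_incidence <- function(tets) {
  m <- nrow(tets)
  a <- as.integer(tets[, .tet_edges[, 1L]])
  b <- as.integer(tets[, .tet_edges[, 2L]])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- lo * 2^26 + hi
  ukey <- sort(unique(key))
  eid <- match(key, ukey)
  edges <- cbind(as.integer(ukey %/% 2^26), as.integer(ukey %% 2^26))
  occ_tet <- rep(seq_len(m), times = 6L)
  list(edges = edges, occ_edge = eid, occ_tet = occ_tet)
}

# boundary edge keys (numeric lo*2^26+hi) from the boundary face set
.boundary_edge_keys <- function(boundary_faces) {
  if (nrow(boundary_faces) == 0L) return(numeric())
  ea <- c(boundary_faces[, 1L], boundary_faces[, 1L], boundary_faces[, 2L])
  eb <- c(boundary_faces[, 2L], boundary_faces[, 3L], boundary_faces[, 3L])
  unique(pmin(ea, eb) * 2^26 + pmax(ea, eb))
}

#' Edge refinement pass
#'
#' One bisection sweep: selects a maximal tet-disjoint set of edges with
#' metric length above `L_max`, in descending metric length (ties by
#' vertex ids), and splits each at its geometric midpoint, bisecting every
#' incident tet; the new vertex receives the arithmetic mean of the
#' endpoint tensors. Edges sharing a tet with an already-selected edge are
#' picked up by the next mesh-adaptation iteration, which interleaves
#' refinement with collapse, reconnection and smoothing (pure bisection
#' without reconnection degrades and over-refines anisotropic meshes).
#' Boundary edges are never split while the surface is frozen.
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field` on its vertices.
#' @param config an `adapt_config`.
#' @param sweeps number of bisection sweeps in this pass (default 1).
#' @return list `mesh`, `field`, `inserted`.
#' @export
refine_pass <- function(mesh, field, config = adapt_config(), sweeps = 1L) {
  inserted <- 0L
  bnd_keys <- if (config$freeze_surface)
    .boundary_edge_keys(build_adjacency(mesh)$boundary_faces) else numeric()
  for (sweep in seq_len(sweeps)) {
    V <- mesh$vertices
    T <- mesh$tets
    M <- .field_tensors(field, nrow(V))
    inc <- .edge_incidence(T)
    L <- cpp_edge_metric_lengths(V, inc$edges, M)
    ekey <- inc$edges[, 1L] * 2^26 + inc$edges[, 2L]
    long <- which(L > config$L_max & !(ekey %in% bnd_keys))
    if (!length(long)) break
    long <- long[order(-L[long], inc$edges[long, 1L], inc$edges[long, 2L])]
    edge_tets <- split(inc$occ_tet, inc$occ_edge)
    claimed <- logical(nrow(T))
    sel <- integer(0)
    for (e in long) {
      tt <- edge_tets[[e]]
      if (any(claimed[tt])) next
      claimed[tt] <- TRUE
      sel <- c(sel, e)
    }
    if (!length(sel)) break
    a <- inc$edges[sel, 1L]; b <- inc$edges[sel, 2L]
    mid <- (V[a, , drop = FALSE] + V[b, , drop = FALSE]) / 2
    newids <- nrow(V) + seq_along(sel)
    V2 <- rbind(V, mid)
    M2 <- rbind(M, (M[a, , drop = FALSE] + M[b, , drop = FALSE]) / 2)
    # all occurrences of selected edges: one per incident tet
    hit <- inc$occ_edge %in% sel
    occ_t <- inc$occ_tet[hit]
    occ_e <- inc$occ_edge[hit]
    pos <- match(occ_e, sel)
    k <- length(occ_t)
    Told <- T[occ_t, , drop = FALSE]
    A <- matrix(a[pos], k, 4L); B <- matrix(b[pos], k, 4L)
    MId <- matrix(newids[pos], k, 4L)
    child1 <- Told; child1[Told == A] <- MId[Told == A]
    child2 <- Told; child2[Told == B] <- MId[Told == B]
    storage.mode(child1) <- "integer"; storage.mode(child2) <- "integer"
    v1 <- cpp_signed_volumes(V2, child1)
    v2 <- cpp_signed_volumes(V2, child2)
    bad_e <- unique(occ_e[v1 <= 0 | v2 <= 0]) # skipped splits (logged)
    keep_occ <- !(occ_e %in% bad_e)
    if (any(!keep_occ)) {
      drop_new <- newids[match(bad_e, sel)]
      child1 <- child1[keep_occ, , drop = FALSE]
      child2 <- child2[keep_occ, , drop = FALSE]
      occ_t <- occ_t[keep_occ]
      occ_e2 <- occ_e[keep_occ]
    } else occ_e2 <- occ_e
    labs <- mesh$labels[occ_t]
    ver <- mesh$mesh_version + 1L
    keep_tets <- setdiff(seq_len(nrow(T)), occ_t)
    mesh$tets <- rbind(T[keep_tets, , drop = FALSE], child1, child2)
    mesh$labels <- c(mesh$labels[keep_tets], labs, labs)
    mesh$tet_version <- c(mesh$tet_version[keep_tets],
                          rep.int(ver, 2L * nrow(child1)))
    mesh$mesh_version <- ver
    mesh$vertices <- V2
    field$tensors <- M2
    n_new <- length(unique(occ_e2))
    inserted <- inserted + n_new
    if (n_new == 0L) break
  }
  list(mesh = mesh, field = field, inserted = inserted)
}

#' Edge collapse pass
#'
#' Collapses edges with metric length below `L_min` by merging one
#' endpoint into the other (interior endpoints are removed first; with a
#' frozen surface an edge between two boundary vertices is never
#' collapsed). A collapse is rejected when a tet would invert, the vertex
#' link condition fails (which would break conformity), a duplicate tet
#' would appear, or the local minimum mean ratio would drop by more than
#' `q_accept`. Edges are processed in ascending metric length; vertex
#' stars are updated incrementally (collapses move no vertex, so the
#' precomputed edge lengths stay valid throughout the pass).
#'
#' @inheritParams refine_pass
#' @return list `mesh`, `field`, `collapsed`.
#' @export
collapse_pass <- function(mesh, field, config = adapt_config()) {
  V <- mesh$vertices
  T <- mesh$tets
  n <- nrow(V)
  M <- .field_tensors(field, n)
  adj <- build_adjacency(mesh)
  is_bnd <- logical(n)
  is_bnd[adj$boundary_vertices] <- TRUE
  inc <- .edge_incidence(T)
  L <- cpp_edge_metric_lengths(V, inc$edges, M)
  short <- which(L < config$L_min)
  if (!length(short))
    return(list(mesh = mesh, field = field, collapsed = 0L))
  short <- short[order(L[short], inc$edges[short, 1L], inc$edges[short, 2L])]
  star <- split(rep(seq_len(nrow(T)), times = 4L),
                factor(as.integer(T), levels = seq_len(n)))
  alive <- rep(TRUE, nrow(T))
  touched_any <- logical(n)
  collapsed <- 0L
  for (e in short) {
    a <- inc$edges[e, 1L]; b <- inc$edges[e, 2L]
    if (config$freeze_surface && is_bnd[a] && is_bnd[b]) next
    rem <- if (is_bnd[a]) b else if (is_bnd[b]) a else max(a, b)
    keep <- if (rem == a) b else a
    sa <- star[[a]]; sb <- star[[b]]
    sa <- sa[alive[sa]]; sb <- sb[alive[sb]]
    if (!length(sa) || !length(sb)) next
    srem <- if (rem == a) sa else sb
    skeep <- if (rem == a) sb else sa
    shared <- intersect(sa, sb)          # tets containing the edge
    if (!length(shared)) next
    # vertex link condition: common neighbors must lie on the edge ring
    nbr_a <- setdiff(unique(as.integer(T[sa, ])), a)
    nbr_b <- setdiff(unique(as.integer(T[sb, ])), b)
    ring <- setdiff(unique(as.integer(T[shared, ])), c(a, b))
    if (!all(intersect(nbr_a, nbr_b) %in% ring)) next
    surv <- setdiff(srem, shared)
    Told <- T[surv, , drop = FALSE]
    Tnew <- Told
    Tnew[Tnew == rem] <- keep
    if (nrow(Tnew)) {
      vols <- cpp_signed_volumes(V, Tnew)
      if (any(vols <= 0)) next
      q_old <- min(cpp_mean_ratio(V, T[srem, , drop = FALSE], M))
      q_new <- min(cpp_mean_ratio(V, Tnew, M))
      if (q_new < q_old - config$q_accept) next
      kk <- .tet_keys(rbind(Tnew, T[setdiff(skeep, shared), , drop = FALSE]))
      if (anyDuplicated(kk)) next
    }
    # commit: retire the edge tets, rewrite the survivors in place, and
    # hand the survivors to the kept vertex's star
    T[surv, ] <- Tnew
    alive[shared] <- FALSE
    star[[keep]] <- c(skeep, surv)
    star[[rem]] <- integer()
    touched_any[unique(as.integer(T[c(surv, shared), , drop = FALSE]))] <- TRUE
    collapsed <- collapsed + 1L
  }
  if (collapsed > 0L) {
    ver <- mesh$mesh_version + 1L
    touched <- touched_any[T[, 1L]] | touched_any[T[, 2L]] |
      touched_any[T[, 3L]] | touched_any[T[, 4L]]
    mesh$tets <- T[alive, , drop = FALSE]
    mesh$labels <- mesh$labels[alive]
    tv <- mesh$tet_version
    tv[touched] <- ver
    mesh$tet_version <- tv[alive]
    mesh$mesh_version <- ver
  }
  list(mesh = mesh, field = field, collapsed = collapsed)
}

#' Local reconnection pass (2-3 and 3-2 flips)
#'
#' Sweeps the tets in id order and applies, per candidate, the first flip
#' (2-3 across each interior face, then 3-2 around each 3-tet interior
#' edge) that raises the minimum mean ratio of the replaced set by more
#' than `q_accept` without inverting an element. In `optimized` mode a tet
#' is skipped when a flip was already attempted and neither it nor any
#' face neighbor has been modified since (the change-tracking
#' optimization); a recorded speculative lock failure forces a retry.
#' Boundary faces are never flipped.
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field`.
#' @param state an `adapt_state` aligned with the tets.
#' @param mode "naive" or "optimized".
#' @param q_accept improvement margin.
#' @return list `mesh`, `state`, `attempts`, `applied`, `skipped`.
#' @export
local_reconnection_pass <- function(mesh, field, state = NULL,
                                    mode = c("naive", "optimized"),
                                    q_accept = 1e-4) {
  mode <- match.arg(mode)
  if (is.null(state)) state <- adapt_state(nrow(mesh$tets))
  M <- .field_tensors(field, nrow(mesh$vertices))
  res <- cpp_reconnection_pass(mesh$vertices, mesh$tets, M,
                               mesh$tet_version, state$stamp,
                               state$attempted, state$lockfail,
                               mesh$mesh_version,
                               if (mode == "optimized") 1L else 0L,
                               q_accept)
  lab <- if (length(mesh$labels)) mesh$labels[1L] else 1L
  mesh$tets <- res$tets
  mesh$labels <- rep.int(lab, nrow(res$tets))
  mesh$tet_version <- res$version
  mesh$mesh_version <- res$mesh_version
  state$attempted <- res$attempted
  state$stamp <- res$stamp
  state$lockfail <- res$lockfail
  list(mesh = mesh, state = state, attempts = res$attempts,
       applied = res$applied, skipped = res$skipped)
}

#' Metric-weighted vertex smoothing pass
#'
#' Proposes each interior vertex at the metric-length-weighted average of
#' its edge neighbors; the move is kept only if the minimum mean ratio
#' over the vertex star does not decrease and no incident tet inverts.
#' Boundary vertices never move.
#'
#' @inheritParams refine_pass
#' @return list `mesh`, `moved`.
#' @export
smooth_pass <- function(mesh, field, config = adapt_config()) {
  n <- nrow(mesh$vertices)
  M <- .field_tensors(field, n)
  adj <- build_adjacency(mesh)
  bnd <- logical(n)
  bnd[adj$boundary_vertices] <- TRUE
  res <- cpp_smooth_pass(mesh$vertices, mesh$tets, M, bnd)
  if (res$n_moved > 0L) {
    mesh$vertices <- res$vertices
    moved <- res$moved
    touched <- moved[mesh$tets[, 1L]] | moved[mesh$tets[, 2L]] |
      moved[mesh$tets[, 3L]] | moved[mesh$tets[, 4L]]
    ver <- mesh$mesh_version + 1L
    mesh$tet_version[touched] <- ver
    mesh$mesh_version <- ver
  }
  list(mesh = mesh, moved = res$n_moved)
}

#' Two-phase metric-conforming mesh adaptation
#'
#' Mesh-adaptation (MA) phase: refine, collapse, local reconnection
#' (always naive over the freshly created elements), smoothing -- until a
#' pass inserts fewer than `point_tol * n_vertices` points or
#' `max_ma_iters` is reached. Quality-improvement (QI) phase: local
#' reconnection (naive or optimized change-tracking) plus smoothing until
#' the mean mean-ratio improves by less than `qi_tol` or `max_qi_iters`.
#' The boundary surface is frozen throughout by default. Unreferenced
#' vertices are compacted away at the end.
#'
#' @param mesh a `tet_mesh`.
#' @param field a `metric_field` on its vertices.
#' @param config an `adapt_config`.
#' @param mode reconnection mode for the QI phase ("optimized" or
#'   "naive").
#' @return an `adapt_result`: `mesh`, `field`, `state`, and `log` (a
#'   data.frame of per-pass counters with a `phase` column).
#' @export
adapt <- function(mesh, field, config = adapt_config(),
                  mode = c("optimized", "naive")) {
  mode <- match.arg(mode)
  if (nrow(field$tensors) != nrow(mesh$vertices))
    stop("metric field does not match mesh vertex count")
  log <- list()
  if (config$freeze_surface) {
    adj0 <- build_adjacency(mesh)
    frozen <- mesh$vertices[adj0$boundary_vertices, , drop = FALSE]
    frozen_ids <- adj0$boundary_vertices
  }
  # ---- mesh adaptation ----
  for (it in seq_len(config$max_ma_iters)) {
    r <- refine_pass(mesh, field, config)
    mesh <- r$mesh; field <- r$field
    cl <- collapse_pass(mesh, field, config)
    mesh <- cl$mesh
    lr <- local_reconnection_pass(mesh, field, adapt_state(nrow(mesh$tets)),
                                  mode = "naive", q_accept = config$q_accept)
    mesh <- lr$mesh
    sm <- smooth_pass(mesh, field, config)
    mesh <- sm$mesh
    log[[length(log) + 1L]] <- data.frame(
      phase = "MA", iter = it, inserted = r$inserted,
      collapsed = cl$collapsed, flip_attempts = lr$attempts,
      flips = lr$applied, flip_skipped = lr$skipped, moved = sm$moved)
    if (r$inserted < config$point_tol * nrow(mesh$vertices)) break
  }
  # ---- quality improvement ----
  state <- adapt_state(nrow(mesh$tets))
  prev_q <- mean(mean_ratio(mesh, field))
  for (it in seq_len(config$max_qi_iters)) {
    lr <- local_reconnection_pass(mesh, field, state, mode = mode,
                                  q_accept = config$q_accept)
    mesh <- lr$mesh; state <- lr$state
    sm <- smooth_pass(mesh, field, config)
    mesh <- sm$mesh
    q <- mean(mean_ratio(mesh, field))
    log[[length(log) + 1L]] <- data.frame(
      phase = "QI", iter = it, inserted = 0L, collapsed = 0L,
      flip_attempts = lr$attempts, flips = lr$applied,
      flip_skipped = lr$skipped, moved = sm$moved)
    if (q - prev_q < config$qi_tol) { prev_q <- q; break }
    prev_q <- q
  }
  # ---- compact unreferenced vertices ----
  used <- sort(unique(as.integer(mesh$tets)))
  if (length(used) < nrow(mesh$vertices)) {
    remap <- integer(nrow(mesh$vertices))
    remap[used] <- seq_along(used)
    mesh$tets <- matrix(remap[mesh$tets], ncol = 4L)
    storage.mode(mesh$tets) <- "integer"
    mesh$vertices <- mesh$vertices[used, , drop = FALSE]
    field$tensors <- field$tensors[used, , drop = FALSE]
    if (config$freeze_surface) frozen_ids <- remap[frozen_ids]
  }
  if (config$freeze_surface &&
      !identical(mesh$vertices[frozen_ids, , drop = FALSE], frozen))
    warning("frozen boundary vertices moved during adaptation")
  structure(list(mesh = mesh, field = field, state = state,
                 log = do.call(rbind, log)),
            class = "adapt_result")
}

#' @export
print.adapt_result <- function(x, ...) {
  q <- mean_ratio(x$mesh, x$field)
  le <- edge_lengths(x$mesh, x$field)$L_e
  cat(sprintf(
    "adapt_result: %d tets, %d vertices; mean Q = %.3f, %.1f%% edges in [1/sqrt2, sqrt2]\n",
    nrow(x$mesh$tets), nrow(x$mesh$vertices), mean(q),
    100 * mean(le >= 1 / sqrt(2) & le <= sqrt(2))))
  print(x$log)
  invisible(x)
}
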