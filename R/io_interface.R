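#' Read a labelled 3-D image (NIfTI or MetaImage)
#'
#' @param path file ending in .nii / .nii.gz / .mha.
#' @param cast allow non-integer voxel data to be rounded to integers
#'   (default FALSE: such data is an error).
#' @return list with `image` (integer array), `spacing`, `origin` (mm).
#' @export
read_image <- function(path, cast = FALSE) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return(.read_mha(path))
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (!cast && any(abs(arr - round(arr)) > 1e-9))
    stop("image contains non-integer labels; pass cast = TRUE to round")
  x <- RNifti::xform(im)
  list(image = array(as.integer(round(arr)), dim = dim(arr)),
       spacing = as.numeric(RNifti::pixdim(im))[1:3],
       origin = as.numeric(x[1:3, 4L]))
}

#' Write a labelled 3-D image
#'
#' Format chosen by extension: .nii / .nii.gz (NIfTI) or .mha (MetaImage,
#' local raw block).
#'
#' @param image list with `image`, `spacing`, `origin` (or a
#'   `vessel_phantom`).
#' @param path output path.
#' @export
write_image <- function(image, path) {
  arr <- image$image
  spacing <- image$spacing
  origin <- image$origin
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    .write_mha(arr, spacing, origin, path)
    return(invisible(path))
  }
  im <- RNifti::asNifti(array(as.integer(arr), dim = dim(arr)))
  RNifti::pixdim(im) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4L] <- origin
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

.write_mha <- function(arr, spacing, origin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "ObjectType = Image\n",
    "NDims = 3\n",
    "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "DimSize = ", paste(dim(arr), collapse = " "), "\n",
    "ElementSpacing = ", paste(spacing, collapse = " "), "\n",
    "Offset = ", paste(origin, collapse = " "), "\n",
    "ElementType = MET_SHORT\n",
    "ElementDataFile = LOCAL\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.integer(arr), con, size = 2L, endian = "little")
}

.read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    kv <- strsplit(line, " = ", fixed = TRUE)[[1L]]
    hdr[[kv[1L]]] <- kv[2L]
    if (kv[1L] == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage data blocks are supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], " ")[[1L]])
  type <- hdr[["ElementType"]]
  size <- switch(type, MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                 MET_USHORT = 2L, MET_INT = 4L,
                 stop("unsupported MetaImage element type: ", type))
  vals <- readBin(con, "integer", n = prod(dims), size = size,
                  endian = "little", signed = size > 1L)
  list(image = array(as.integer(vals), dim = dims),
       spacing = as.numeric(strsplit(hdr[["ElementSpacing"]], " ")[[1L]]),
       origin = as.numeric(strsplit(hdr[["Offset"]], " ")[[1L]]))
}

#' Write a tetrahedral mesh as VTK legacy unstructured grid (ASCII)
#'
#' One fixed dialect: legacy 4.2 header, POINTS double, CELLS with
#' 0-based connectivity, CELL_TYPES 10. Labels go to CELL_DATA; an
#' optional metric field goes to POINT_DATA as a 9-component row-major
#' TENSORS array named "metric".
#'
#' @param mesh a `tet_mesh`.
#' @param path output .vtk path.
#' @param field optional `metric_field` written alongside.
#' @export
write_mesh <- function(mesh, path, field = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$vertices); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 4.2",
               "vesselmesh tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep.int(10L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m), "SCALARS label int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$labels), con)
  if (!is.null(field)) {
    writeLines(c(sprintf("POINT_DATA %d", n), "TENSORS metric double"), con)
    t6 <- field$tensors
    t9 <- cbind(t6[, 1L], t6[, 2L], t6[, 3L],
                t6[, 2L], t6[, 4L], t6[, 5L],
                t6[, 3L], t6[, 5L], t6[, 6L])
    utils::write.table(format(t9, digits = 17, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a VTK legacy unstructured grid of tetrahedra
#'
#' @param path .vtk path (the dialect written by [write_mesh()]).
#' @return list with `mesh` (a `tet_mesh`) and `field` (a `metric_field`
#'   or NULL).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1L]]
  ip <- grep("^POINTS", lines)[1L]
  n <- as.integer(toks(lines[ip])[2L])
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(ip + 1L):(ip + n)]), "\\s+")))
  pts <- matrix(vals[seq_len(3L * n)], ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1L]
  m <- as.integer(toks(lines[ic])[2L])
  cellvals <- as.integer(unlist(strsplit(trimws(
    lines[(ic + 1L):(ic + m)]), "\\s+")))
  cellmat <- matrix(cellvals, ncol = 5L, byrow = TRUE)
  if (any(cellmat[, 1L] != 4L)) stop("unsupported (non-tet) cells in file")
  it <- grep("^CELL_TYPES", lines)[1L]
  types <- as.integer(unlist(strsplit(trimws(
    lines[(it + 1L):(it + m)]), "\\s+")))
  if (any(types != 10L)) stop("mixed cell types are not supported")
  labels <- NULL
  il <- grep("^SCALARS label", lines)
  if (length(il)) {
    labels <- as.integer(unlist(strsplit(trimws(
      lines[(il[1L] + 2L):(il[1L] + 1L + m)]), "\\s+")))
  }
  field <- NULL
  im <- grep("^TENSORS metric", lines)
  if (length(im)) {
    tvals <- as.numeric(unlist(strsplit(trimws(
      lines[(im[1L] + 1L):(im[1L] + n)]), "\\s+")))
    t9 <- matrix(tvals, ncol = 9L, byrow = TRUE)
    t6 <- cbind(t9[, 1L], t9[, 2L], t9[, 3L], t9[, 5L], t9[, 6L], t9[, 9L])
    field <- metric_field(t6, clamp = FALSE)
  }
  mesh <- tet_mesh(pts, cellmat[, 2:5] + 1L, labels = labels,
                   fix_orientation = FALSE)
  list(mesh = mesh, field = field)
}

#' Write a triangle surface as binary STL
#'
#' @param surface a `tri_surface` from [extract_surface()].
#' @param path output .stl path.
#' @export
write_stl <- function(surface, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(formatC("vesselmesh surface", width = -80))
  writeBin(hdr[1:80], con)
  tri <- surface$triangles
  V <- surface$vertices
  writeBin(as.integer(nrow(tri)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(tri))) {
    p1 <- V[tri[i, 1L], ]; p2 <- V[tri[i, 2L], ]; p3 <- V[tri[i, 3L], ]
    u <- p2 - p1; w <- p3 - p1
    nrm <- c(u[2L] * w[3L] - u[3L] * w[2L],
             u[3L] * w[1L] - u[1L] * w[3L],
             u[1L] * w[2L] - u[2L] * w[1L])
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, p1, p2, p3)), con, size = 4L,
             endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL surface
#'
#' @param path .stl path.
#' @return a `tri_surface` (vertices merged exactly on coordinates).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nt <- readBin(con, "integer", size = 4L, endian = "little")
  tris <- matrix(0L, nt, 3L)
  coords <- matrix(0, 3L * nt, 3L)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    invisible(readBin(con, "integer", n = 1L, size = 2L, endian = "little"))
    coords[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
  }
  key <- apply(coords, 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  V <- coords[uk, , drop = FALSE]
  tris <- matrix(ids, ncol = 3L, byrow = TRUE)
  structure(list(vertices = V, triangles = tris,
                 orig_ids = seq_len(nrow(V))),
            class = "tri_surface")
}

#' Write / read a centerline as CSV (x,y,z per row, mm)
#' @param centerline k x 3 matrix.
#' @param path csv path.
#' @export
write_centerline_csv <- function(centerline, path) {
  utils::write.csv(data.frame(x = centerline[, 1L], y = centerline[, 2L],
                              z = centerline[, 3L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @export
read_centerline_csv <- function(path) {
  as.matrix(utils::read.csv(path))[, 1:3, drop = FALSE]
}

#' Write / read velocity samples as CSV (x,y,z,u,v,w)
#' @param samples data.frame with columns x,y,z,u,v,w.
#' @param path csv path.
#' @export
write_velocity_csv <- function(samples, path) {
  utils::write.csv(samples[, c("x", "y", "z", "u", "v", "w")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_csv
#' @export
read_velocity_csv <- function(path) {
  utils::read.csv(path)[, c("x", "y", "z", "u", "v", "w")]
}

#' Write a metric field as 6-component CSV (xx,xy,xz,yy,yz,zz)
#' @param field a `metric_field`.
#' @param path csv path.
#' @export
write_tensor_csv <- function(field, path) {
  t6 <- field$tensors
  colnames(t6) <- c("xx", "xy", "xz", "yy", "yz", "zz")
  utils::write.csv(as.data.frame(t6), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tensor_csv
#' @export
read_tensor_csv <- function(path) {
  metric_field(as.matrix(utils::read.csv(path)), clamp = FALSE)
}

# ---- pipeline configuration ----------------------------------------------

.default_config <- function() {
  list(
    seed = 1L,
    phantom = list(tube_radius = 4, length = 40, spacing = 1,
                   bulge_radius = 6, bulge_center_t = 0.5, curvature = 0),
    bcc = list(cell_size = 2, snap_iters = 20L, snap_step = 0.5,
               min_quality_accept = 0.1),
    metric = list(mode = "landmarks", k = 8L, h_min = 1, h_max = 8,
                  target_complexity = NULL),
    adapt = list(L_max = sqrt(2), L_min = 1 / sqrt(2), q_accept = 1e-4,
                 max_ma_iters = 10L, max_qi_iters = 10L, point_tol = 0.01,
                 qi_tol = 1e-3, freeze_surface = TRUE, mode = "optimized"),
    output_dir = "."
  )
}

#' Read a pipeline configuration (YAML)
#'
#' Unknown top-level or per-section keys are rejected so typos surface
#' early.
#'
#' @param path YAML file; NULL returns the defaults.
#' @return a validated config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- .default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
      badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(badk))
        stop("unknown config keys in '", sec, "': ",
             paste(badk, collapse = ", "))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  cfg
}

#' Run the full image-to-mesh pipeline
#'
#' phantom (or supplied image) -> BCC lattice mesh -> surface snap ->
#' metric construction -> optional complexity scaling -> two-phase
#' adaptation -> quality/fidelity report. Artifacts and a JSON run log are
#' written to `config$output_dir`.
#'
#' @param config list from [read_config()].
#' @param image optional pre-loaded image list (skips the phantom stage).
#' @param write_artifacts write mesh/metric/report files (default TRUE).
#' @return list with `phantom`, `bcc_mesh`, `snapped`, `field`, `result`
#'   (an `adapt_result`), `report`, `log_path`.
#' @export
pipeline <- function(config = read_config(), image = NULL,
                     write_artifacts = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  phantom <- NULL
  if (is.null(image)) {
    phantom <- stage("phantom",
      make_vessel_image(config$phantom, seed = config$seed))
    image <- phantom
  }
  bcfg <- bcc_config(cell_size = config$bcc$cell_size,
                     snap_iters = config$bcc$snap_iters,
                     snap_step = config$bcc$snap_step,
                     min_quality_accept = config$bcc$min_quality_accept)
  mesh0 <- stage("i2m", bcc_lattice_mesh(image, bcfg))
  snapped <- stage("snap", snap_surface(mesh0, image, bcfg))
  mcfg <- config$metric
  field <- stage("build-metric", {
    if (mcfg$mode == "landmarks") {
      if (is.null(phantom)) stop("landmark metric needs a phantom centerline")
      build_metric_from_landmarks(snapped, phantom$centerline, k = mcfg$k,
                                  h_min = mcfg$h_min, h_max = mcfg$h_max)
    } else if (mcfg$mode == "velocity") {
      ph <- make_streamlines(phantom, n_samples = 400L, seed = config$seed)
      build_metric_from_velocity(snapped, ph$velocity_samples,
                                 h0 = mcfg$h_min * 2)
    } else {
      if (is.null(phantom)) stop("isotropic metric needs a phantom centerline")
      isotropic_sizing_metric(snapped, phantom$centerline,
                              h_min = mcfg$h_min, h_max = mcfg$h_max)
    }
  })
  if (!is.null(mcfg$target_complexity))
    field <- stage("scale-metric",
                   scale_to_complexity(snapped, field, mcfg$target_complexity))
  acfg <- adapt_config(L_max = config$adapt$L_max, L_min = config$adapt$L_min,
                       q_accept = config$adapt$q_accept,
                       max_ma_iters = config$adapt$max_ma_iters,
                       max_qi_iters = config$adapt$max_qi_iters,
                       point_tol = config$adapt$point_tol,
                       qi_tol = config$adapt$qi_tol,
                       freeze_surface = config$adapt$freeze_surface,
                       seed = config$seed)
  result <- stage("adapt", adapt(snapped, field, acfg,
                                 mode = config$adapt$mode))
  report <- stage("quality",
                  quality_report(result$mesh, result$field, image = image))
  log_path <- NULL
  if (write_artifacts) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output_dir, f)
    write_mesh(snapped, out("background.vtk"), field = field)
    write_mesh(result$mesh, out("adapted.vtk"), field = result$field)
    write_stl(extract_surface(result$mesh), out("surface.stl"))
    if (!is.null(phantom)) {
      write_image(phantom, out("phantom.nii.gz"))
      write_centerline_csv(phantom$centerline, out("centerline.csv"))
    }
    log_path <- out("run_log.json")
    jsonlite::write_json(list(
      seed = config$seed,
      stages = c("phantom", "i2m", "snap", "build-metric", "adapt", "quality"),
      n_tets = nrow(result$mesh$tets),
      n_vertices = nrow(result$mesh$vertices),
      mean_q = mean(report$conformity$Q),
      unit_fraction = report$conformity$unit_fraction,
      hd = report$HD,
      counters = result$log
    ), log_path, auto_unbox = TRUE, digits = NA)
  }
  list(phantom = phantom, bcc_mesh = mesh0, snapped = snapped,
       field = field, result = result, report = report, log_path = log_path)
}
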