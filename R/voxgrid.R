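# Core data types and I/O.
#
# Coordinate conventions used throughout the package:
#  * volumes are 3D arrays with dims (n1, n2, n3); axis 1 is the
#    anatomical/scan longitudinal axis (the "z" axis of the VOI protocol);
#  * voxel indices are 1-based in R; world coordinates are voxel CENTRES,
#    world(i,j,k) = origin + (i-1, j-1, k-1) * spacing, in mm, with point
#    components ordered like the array axes;
#  * all physical outputs are mm, mm^2, mm^3.

#' Voxel volume
#'
#' A 3D scalar image with anisotropic voxel spacing. Axis 1 of the array is
#' the longitudinal (scan) axis; world coordinates are voxel centres in mm,
#' component order matching the array axes.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin world coordinate (mm) of the centre of voxel (1,1,1).
#' @return An object of class `voxel_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_bad("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop_bad("`spacing` must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop_bad("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' Binary mask on a voxel grid
#'
#' @param data 3D logical array.
#' @inheritParams voxel_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop_bad("`data` must be a 3D logical array")
  v <- voxel_volume(array(0, dim(data)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "binary_mask")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, spacing %s mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d foreground (%.3g mm^3)\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$data), volume_mm3(x)))
  invisible(x)
}

#' Index/world coordinate maps
#'
#' Voxel indices are 1-based; world coordinates are voxel centres (mm).
#' The two maps are exact inverses.
#'
#' @param x a `voxel_volume` or `binary_mask`.
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix.
#' @export
world_from_index <- function(x, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, x$spacing, `*`), 2, x$origin, `+`)
}

#' @rdname world_from_index
#' @export
index_from_world <- function(x, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, x$origin, `-`), 2, x$spacing, `/`) + 1
}

#' Voxel and mask volume
#'
#' @param x a `voxel_volume` or `binary_mask`.
#' @return `voxel_size_mm3`: volume of one voxel (mm^3). `volume_mm3`:
#'   foreground voxel count times voxel volume.
#' @export
voxel_size_mm3 <- function(x) prod(x$spacing)

#' @rdname voxel_size_mm3
#' @export
volume_mm3 <- function(x) {
  stopifnot(inherits(x, "binary_mask"))
  sum(x$data) * voxel_size_mm3(x)
}

#' Ordered 3D polyline
#'
#' @param points n x 3 matrix of world coordinates (mm), n >= 2.
#' @param closed whether the final point connects back to the first.
#' @return An object of class `polyline3d`.
#' @export
polyline3d <- function(points, closed = FALSE) {
  points <- rbind(points)
  if (nrow(points) < 2L) stop_bad("a polyline needs at least 2 points")
  if (!all(is.finite(points))) stop_bad("polyline coordinates must be finite")
  if (ncol(points) == 2L) points <- cbind(points, 0)
  if (ncol(points) != 3L) stop_bad("points must have 2 or 3 columns")
  structure(list(points = unname(points), closed = isTRUE(closed)),
            class = "polyline3d")
}

#' Polyline length
#'
#' Sum of consecutive Euclidean segment lengths, plus the closing segment
#' for closed polylines.
#'
#' @param line a `polyline3d`.
#' @return length in mm.
#' @export
polyline_length <- function(line) {
  p <- line$points
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  len <- sum(seg)
  if (line$closed) len <- len + sqrt(sum((p[1, ] - p[nrow(p), ])^2))
  len
}

#' @export
print.polyline3d <- function(x, ...) {
  cat(sprintf("<polyline3d> %d points, %s, length %.4f mm\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              polyline_length(x)))
  invisible(x)
}

#' Triangulated surface mesh
#'
#' Vertex coordinates are world mm. Degenerate (near-zero-area) faces are
#' dropped at construction; face indices are validated.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param area_tol faces with area below this (mm^2) are discarded.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, area_tol = 1e-12) {
  vertices <- rbind(vertices)
  faces <- rbind(faces)
  storage.mode(faces) <- "integer"
  if (nrow(vertices) == 0L || nrow(faces) == 0L)
    stop_bad("mesh must have at least one vertex and one face")
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop_bad("vertices must be n x 3 and faces m x 3")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop_bad("face indices out of range")
  a <- face_areas(vertices, faces)
  keep <- a > area_tol & faces[, 1] != faces[, 2] &
    faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  if (nrow(faces) == 0L) stop_bad("all faces degenerate")
  structure(list(vertices = unname(vertices), faces = unname(faces)),
            class = "surface_mesh")
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' Total mesh surface area
#'
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, area %.4f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Landmark set
#'
#' Named 2D or 3D world points (mm). All points in a set must share
#' dimensionality and labels must be unique.
#'
#' @param points named list of numeric vectors (length 2 or 3).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  if (length(points) == 0L || is.null(names(points)) ||
      any(names(points) == "") || anyDuplicated(names(points)))
    stop_bad("landmarks must have unique non-empty labels")
  dims <- vapply(points, length, 1L)
  if (!all(dims %in% c(2L, 3L)) || length(unique(dims)) != 1L)
    stop_bad("all landmarks must be 2D or all 3D")
  if (!all(vapply(points, function(p) all(is.finite(p)), TRUE)))
    stop_bad("landmark coordinates must be finite")
  structure(lapply(points, as.numeric), class = "landmark_set")
}

#' Read/write landmark JSON
#'
#' JSON files map labels to coordinate arrays, e.g.
#' `{"nasal_tip": [0, 12.5]}`; coordinate component order matches the
#' volume axis order.
#'
#' @param path file path.
#' @param landmarks a `landmark_set`.
#' @return `read_landmarks` returns a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  landmark_set(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(unclass(landmarks), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Volume I/O

#' Read a volumetric image
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and multi-page TIFF stacks. NIfTI
#' axes (x, y, z) are reordered so that the slice axis becomes array axis 1,
#' matching the package convention. TIFF stacks carry no 3D spacing, so
#' `spacing` must be supplied; a missing spacing is an error, never a
#' silent 1.0.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"nifti"` or `"tiff_stack"`.
#' @param spacing optional spacing override, mm (required for TIFF).
#' @param origin world coordinate of the first voxel centre.
#' @return a `voxel_volume`.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff_stack"),
                        spacing = NULL, origin = c(0, 0, 0)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_bad("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
      "nifti" else "tiff_stack"
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    dat <- aperm(array(as.numeric(img), dim(img)), 3:1)
    if (is.null(spacing)) {
      pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
      spacing <- rev(abs(pd[1:3]))
      if (!all(is.finite(spacing)) || any(spacing <= 0))
        stop_bad("NIfTI header has no usable spacing; pass `spacing`")
    }
    voxel_volume(dat, spacing, origin)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (is.null(spacing))
      stop_bad("TIFF stacks carry no 3D spacing; pass `spacing` explicitly")
    d <- dim(pages[[1]])
    if (length(d) != 2L)
      stop_bad("only single-channel (grayscale) TIFF stacks are supported")
    dat <- array(0, c(length(pages), d[1], d[2]))
    for (k in seq_along(pages)) {
      if (!identical(dim(pages[[k]]), d))
        stop_bad("TIFF pages have inconsistent dimensions")
      dat[k, , ] <- pages[[k]]
    }
    voxel_volume(dat, spacing, origin)
  }
}

#' Write a volume as NIfTI-1
#'
#' Inverse of [read_volume()] for NIfTI: array axes are reordered back to
#' (x, y, z) and the spacing stored in the header.
#'
#' @param vol a `voxel_volume` or `binary_mask` (written as 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim(dat))
  arr <- aperm(dat, 3:1)
  attr(arr, "pixdim") <- rev(vol$spacing)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Write / read a surface mesh (ASCII STL or PLY)
#'
#' PLY preserves vertex sharing; STL stores a triangle soup and re-reading
#' merges exactly coincident vertices. Coordinates are preserved to better
#' than 1e-5 mm.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format `"auto"` (by extension), `"stl"` or `"ply"`.
#' @return `read_mesh` returns a `surface_mesh`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (!inherits(mesh, "surface_mesh")) stop_bad("`mesh` must be a surface_mesh")
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "stl"
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.10g", x)
  if (format == "stl") {
    n <- face_normals(v, f)
    writeLines("solid mesh", con)
    for (t in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %s %s %s", num(n[t,1]), num(n[t,2]), num(n[t,3])),
        "    outer loop",
        sprintf("      vertex %s %s %s",
                num(v[f[t, ], 1]), num(v[f[t, ], 2]), num(v[f[t, ], 3])),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%s %s %s", num(v[,1]), num(v[,2]), num(v[,3])), con)
    writeLines(sprintf("3 %d %d %d", f[,1] - 1L, f[,2] - 1L, f[,3] - 1L), con)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "stl"
  lines <- readLines(path)
  if (format == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    if (is.null(coords) || nrow(coords) %% 3L != 0L)
      stop_bad("malformed STL: vertex count not a multiple of 3")
    key <- apply(coords, 1, paste, collapse = ",")
    uid <- match(key, unique(key))
    verts <- coords[!duplicated(key), , drop = FALSE]
    faces <- matrix(uid, ncol = 3, byrow = TRUE)
    surface_mesh(verts, faces)
  } else {
    hdr_end <- match("end_header", trimws(lines))
    nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                         grep("element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                         grep("element face", lines, value = TRUE)[1]))
    vl <- lines[(hdr_end + 1):(hdr_end + nv)]
    fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
    verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[1:3])))
    faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x)
      as.integer(x[2:4]) + 1L))
    surface_mesh(verts, faces)
  }
}

# ---------------------------------------------------------------------------
# Study tables

#' Per-animal study table
#'
#' Long-format records of one measurement per animal per age. The key
#' (animal_id, measurement_name, age_weeks) must be unique and all values
#' finite.
#'
#' @param df data.frame with columns `animal_id`, `genotype` (WT/Ach),
#'   `sex`, `age_weeks`, `measurement_name`, `value`.
#' @return the validated data.frame with class `study_table`.
#' @export
study_table <- function(df) {
  need <- c("animal_id", "genotype", "sex", "age_weeks",
            "measurement_name", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_bad("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (!all(is.finite(df$value))) stop_bad("all values must be finite")
  key <- paste(df$animal_id, df$measurement_name, df$age_weeks, sep = "\r")
  if (anyDuplicated(key))
    stop_bad("duplicate (animal_id, measurement_name, age_weeks) rows")
  class(df) <- c("study_table", "data.frame")
  df
}

#' Write / read study result tables (CSV)
#'
#' Columns in stable order; numeric values round-trip to at least 12
#' significant digits. Writing a table with non-finite values is an error.
#'
#' @param table a `study_table`.
#' @param path CSV path.
#' @export
write_results <- function(table, path) {
  table <- study_table(table)
  tab <- table
  tab$value <- sprintf("%.15g", tab$value)
  write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  study_table(df)
}
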