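#' Triangle mesh constructor
#'
#' A triangle mesh holds vertex coordinates in millimetres, 1-based face
#' indices and an optional per-face region label (used to exclude bent or
#' adjusted implant regions from registration). On construction duplicate
#' vertices are welded (tolerance `weld_tol` mm) and degenerate faces
#' (area below `1e-12` mm^2) are dropped.
#'
#' @param vertices numeric `n x 3` matrix, mm.
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param labels optional character/factor vector of length `m` with a
#'   region label per face.
#' @param weld_tol welding tolerance in mm; `0` disables welding.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, labels = NULL, weld_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (!all(is.finite(vertices))) stop("triangle_mesh: non-finite vertex coordinates")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("triangle_mesh: face index out of range")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    stopifnot(length(labels) == nrow(faces))
  }
  m <- structure(list(vertices = vertices, faces = faces, labels = labels),
                 class = "triangle_mesh")
  if (weld_tol > 0) m <- weld_vertices(m, tol = weld_tol)
  drop_degenerate_faces(m)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$labels)) {
    cat(sprintf(" (labels: %s)", paste(unique(x$labels), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# Merge vertices closer than tol (mm) and remap faces.
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  if (nrow(v) == 0) return(mesh)
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  mesh$vertices <- v[first, , drop = FALSE]
  mesh$faces[] <- remap[mesh$faces]
  mesh
}

drop_degenerate_faces <- function(mesh, min_area = 1e-12) {
  f <- mesh$faces
  if (nrow(f) == 0) return(mesh)
  distinct <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  keep <- distinct
  keep[distinct] <- face_areas(mesh)[distinct] > min_area
  mesh$faces <- f[keep, , drop = FALSE]
  if (!is.null(mesh$labels)) mesh$labels <- mesh$labels[keep]
  mesh
}

#' Mesh surface measures
#'
#' `face_areas()` returns the area of every triangle (mm^2), `mesh_area()`
#' their sum, and `mesh_volume()` the enclosed volume (mm^3) of a closed
#' mesh via the divergence theorem (absolute value of the summed signed
#' tetrahedron volumes).
#'
#' @param mesh a `triangle_mesh`.
#' @return Numeric vector or scalar.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' @rdname face_areas
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cx <- p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]
  cy <- p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]
  cz <- p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]
  abs(sum(p1[, 1] * cx + p1[, 2] * cy + p1[, 3] * cz) / 6)
}

#' Read an STL file
#'
#' Reads binary or ASCII STL (dialect auto-detected). STL stores one
#' coordinate triple per triangle corner; vertices are welded on read
#' (tolerance `1e-6` mm) and degenerate triangles dropped. Coordinates are
#' interpreted as millimetres.
#'
#' @param path path to an `.stl` file.
#' @return A `triangle_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop(sprintf("STL file not found: %s", path))
  size <- file.info(path)$size
  if (size < 15) stop(sprintf("malformed STL '%s': only %d bytes", path, size))
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 512))
  # inspect only printable ASCII so binary headers do not trip encoding
  printable <- (head >= as.raw(0x20) & head <= as.raw(0x7e)) |
    head == as.raw(0x09) | head == as.raw(0x0a) | head == as.raw(0x0d)
  head_txt <- rawToChar(head[printable])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, fixed = TRUE, useBytes = TRUE)
  if (!is_ascii && size >= 84) {
    # binary: 80-byte header, uint32 count, 50 bytes per triangle
    seek(con, 80)
    n_tri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    expected <- 84 + 50 * as.numeric(n_tri)
    if (n_tri < 0 || expected > size) {
      stop(sprintf("malformed binary STL '%s': triangle count %d implies %0.f bytes, file has %0.f (error at byte offset 80)",
                   path, n_tri, expected, size))
    }
    rec <- readBin(con, "raw", n = 50 * n_tri)
    if (length(rec) < 50 * n_tri) {
      stop(sprintf("truncated binary STL '%s' at byte offset %d", path, 84 + length(rec)))
    }
    # each record: 12 floats (normal + 3 vertices) + uint16 attribute
    dim(rec) <- c(50, n_tri)
    flo <- readBin(as.vector(rec[1:48, ]), "double", size = 4, n = 12 * n_tri, endian = "little")
    flo <- matrix(flo, nrow = 12)
    tri <- flo[4:12, , drop = FALSE]  # drop normals; 9 x n (v1 v2 v3 per col)
    verts <- matrix(as.vector(tri), ncol = 3, byrow = TRUE)
  } else if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      stop(sprintf("malformed ASCII STL '%s': %d vertex lines (not a multiple of 3)", path, length(vl)))
    }
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
    verts <- do.call(rbind, nums)
    if (any(!is.finite(verts))) stop(sprintf("malformed ASCII STL '%s': non-numeric vertex", path))
  } else {
    stop(sprintf("malformed STL '%s': not binary (size %0.f < 84) and no ASCII facets (error at byte offset 0)", path, size))
  }
  n_tri <- nrow(verts) / 3
  faces <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' Write an STL file
#'
#' Writes a mesh as binary (default) or ASCII STL. Binary STL stores
#' float32 coordinates, so a write/read round trip is exact at float32
#' precision; the binary file size is exactly `84 + 50 * nrow(faces)`
#' bytes.
#'
#' @param mesh a `triangle_mesh` with at least one face.
#' @param path output path.
#' @param ascii logical; write the ASCII dialect instead of binary.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0) stop("write_stl: mesh has no faces")
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (ascii) {
    con <- try(file(path, "w"), silent = TRUE)
    if (inherits(con, "try-error")) stop(sprintf("cannot open '%s' for writing", path))
    on.exit(close(con))
    writeLines("solid oipf", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p3[i, 1], p3[i, 2], p3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid oipf", con)
  } else {
    con <- try(file(path, "wb"), silent = TRUE)
    if (inherits(con, "try-error")) stop(sprintf("cannot open '%s' for writing", path))
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 per triangle as float32 + uint16 attr
    flo <- rbind(t(n), t(p1), t(p2), t(p3))  # 12 x m
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(flo[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Sample points uniformly on a mesh surface
#'
#' Area-weighted uniform surface sampling: faces are drawn with
#' probability proportional to their area, then a point is placed at
#' uniform barycentric coordinates. Deterministic given `seed`. Faces with
#' labels in `exclude_labels`, or listed in `exclude_faces`, are skipped —
#' this is how bent or screw-ring regions are kept out of registration.
#'
#' @param mesh a `triangle_mesh` with at least one face.
#' @param n number of points (default 20000, a density that stabilizes ICP
#'   well below 0.1 mm on implant-sized surfaces).
#' @param seed integer RNG seed.
#' @param exclude_labels character vector of face labels to skip.
#' @param exclude_faces integer vector of 1-based face indices to skip.
#' @return An object of class `surface_sample`: list with `points`
#'   (`n x 3`, mm), `face` (source face index per point) and `seed`.
#' @export
sample_surface <- function(mesh, n = 20000, seed = 1L,
                           exclude_labels = NULL, exclude_faces = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), n >= 1)
  keep <- rep(TRUE, nrow(mesh$faces))
  if (!is.null(exclude_labels) && !is.null(mesh$labels)) {
    keep <- keep & !(mesh$labels %in% exclude_labels)
  }
  if (!is.null(exclude_faces)) keep[exclude_faces] <- FALSE
  fidx <- which(keep)
  if (length(fidx) == 0) stop("sample_surface: all faces excluded")
  areas <- face_areas(mesh)[fidx]
  v <- mesh$vertices; f <- mesh$faces
  with_seed(seed, {
    pick <- fidx[sample.int(length(fidx), n, replace = TRUE, prob = areas)]
    r1 <- stats::runif(n); r2 <- stats::runif(n)
    flip <- r1 + r2 > 1
    r1[flip] <- 1 - r1[flip]; r2[flip] <- 1 - r2[flip]
    p <- (1 - r1 - r2) * v[f[pick, 1], , drop = FALSE] +
      r1 * v[f[pick, 2], , drop = FALSE] +
      r2 * v[f[pick, 3], , drop = FALSE]
    structure(list(points = p, face = pick, seed = seed), class = "surface_sample")
  })
}

#' @export
print.surface_sample <- function(x, ...) {
  cat(sprintf("surface sample: %d points (seed %d)\n", nrow(x$points), x$seed))
  invisible(x)
}

# Evaluate code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
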