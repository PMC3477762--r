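#' @useDynLib kneedea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

DEGENERATE_AREA <- 1e-12  # mm^2; faces below this carry no load and break normals
DEDUP_TOL <- 1e-6         # mm; vertices closer than this are merged at load

#' Triangulated bone surface
#'
#' Container for one bone surface: an `n x 3` vertex matrix (mm) and an
#' `m x 3` integer face matrix (1-based, counter-clockwise when viewed from
#' outside). Face normals and areas are derived quantities, available via
#' [surface_geometry()].
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param label bone identity, typically `"femur"` or `"tibia"`.
#' @param validate check invariants (index range, finiteness, degeneracy).
#' @return An object of class `triangle_surface`.
#' @export
triangle_surface <- function(vertices, faces, label = "bone", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (validate) {
    if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
    if (nrow(faces) > 0 &&
        (min(faces) < 1L || max(faces) > nrow(vertices)))
      stop("face index out of range")
  }
  s <- structure(list(vertices = vertices, faces = faces, label = label),
                 class = "triangle_surface")
  if (validate && nrow(faces) > 0) {
    a <- face_areas(s)
    if (any(a < DEGENERATE_AREA))
      stop("degenerate (zero-area) faces present; use load_surface() or drop them")
  }
  s
}

#' @export
print.triangle_surface <- function(x, ...) {
  cat(sprintf("triangle_surface '%s': %d vertices, %d faces, area %.2f mm^2\n",
              x$label, nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

face_cross <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

face_areas <- function(surface) {
  cr <- face_cross(surface)
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-face centroids, unit normals and areas
#'
#' @param surface a [triangle_surface()].
#' @return List with `centroids` (m x 3, mm), `normals` (m x 3, unit),
#'   `areas` (mm^2).
#' @export
surface_geometry <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  centroids <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
                  v[f[, 3], , drop = FALSE]) / 3
  cr <- face_cross(surface)
  nrm <- sqrt(rowSums(cr^2))
  list(centroids = centroids, normals = cr / nrm, areas = 0.5 * nrm)
}

#' Total surface area in mm^2
#' @param surface a [triangle_surface()].
#' @export
surface_area <- function(surface) sum(face_areas(surface))

#' Vertex centroid (unweighted mean of vertices)
#' @param surface a [triangle_surface()].
#' @export
surface_centroid <- function(surface) colMeans(surface$vertices)

#' Signed enclosed volume (positive for closed, outward-wound surfaces)
#' @param surface a [triangle_surface()].
#' @export
signed_volume <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# unique undirected edges with adjacent faces: matrix v1, v2, f1, f2 (f2 = 0
# for boundary edges); cached on the surface via attribute
surface_edges <- function(surface) {
  cached <- attr(surface, "edge_table")
  if (!is.null(cached)) return(cached)
  f <- surface$faces
  m <- nrow(f)
  ev <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep.int(seq_len(m), 3)
  key_lo <- pmin(ev[, 1], ev[, 2])
  key_hi <- pmax(ev[, 1], ev[, 2])
  ord <- order(key_lo, key_hi)
  key_lo <- key_lo[ord]; key_hi <- key_hi[ord]; fid <- fid[ord]
  new_edge <- c(TRUE, key_lo[-1] != key_lo[-length(key_lo)] |
                  key_hi[-1] != key_hi[-length(key_hi)])
  grp <- cumsum(new_edge)
  n_edges <- grp[length(grp)]
  counts <- tabulate(grp, n_edges)
  if (any(counts > 2))
    stop("non-manifold edges present (more than two adjacent faces)")
  e <- matrix(0L, n_edges, 4)
  first <- which(new_edge)
  e[, 1] <- key_lo[first]
  e[, 2] <- key_hi[first]
  e[, 3] <- fid[first]
  second <- setdiff(seq_along(grp), first)
  e[grp[second], 4] <- fid[second]
  e
}

# merge vertices closer than tol (grid snap), drop degenerate faces
clean_mesh <- function(vertices, faces, tol = DEDUP_TOL) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces <- matrix(map[faces], ncol = 3)
  # drop collapsed / degenerate faces
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  tmp <- structure(list(vertices = vertices, faces = faces),
                   class = "triangle_surface")
  keep2 <- face_areas(tmp) >= DEGENERATE_AREA
  n_dropped <- sum(!keep) + sum(!keep2)
  list(vertices = vertices, faces = faces[keep2, , drop = FALSE],
       n_dropped = n_dropped)
}

#' Load a triangulated surface from STL, PLY or OBJ
#'
#' Duplicate vertices (within 1e-6 mm) are merged and zero-area faces dropped,
#' with a message reporting the count. Coordinates are millimetres,
#' right-handed.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"`, `"obj"`, or `NULL` to infer from the
#'   extension.
#' @param label bone identity stored on the surface.
#' @param max_nonmanifold_frac maximum tolerated fraction of non-manifold
#'   edges before loading fails.
#' @return A [triangle_surface()].
#' @export
load_surface <- function(path, format = NULL, label = NULL,
                         max_nonmanifold_frac = 0) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  raw <- switch(format,
                stl = read_stl(path),
                ply = read_ply(path),
                obj = read_obj(path),
                stop("unsupported format '", format, "'"))
  cl <- clean_mesh(raw$vertices, raw$faces)
  if (cl$n_dropped > 0)
    message(cl$n_dropped, " degenerate/collapsed faces dropped at load")
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  s <- triangle_surface(cl$vertices, cl$faces, label = label)
  # non-manifold check: count edges used by >2 faces
  f <- s$faces
  ev <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ev[, 1], ev[, 2]), pmax(ev[, 1], ev[, 2]))
  tab <- table(key)
  bad <- names(tab)[tab > 2]
  if (length(bad) / max(1, length(tab)) > max_nonmanifold_frac)
    stop("non-manifold edges beyond tolerated fraction: ",
         paste(utils::head(bad, 5), collapse = "; "))
  s
}

#' Save a triangulated surface to STL, PLY or OBJ
#'
#' @param surface a [triangle_surface()].
#' @param path output path.
#' @param format `"stl"`, `"ply"`, `"obj"`, or `NULL` to infer from the
#'   extension.
#' @param binary for STL, write the binary dialect (default ASCII).
#' @export
save_surface <- function(surface, path, format = NULL, binary = FALSE) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         stl = write_stl(surface, path, binary = binary),
         ply = write_ply(surface, path),
         obj = write_obj(surface, path),
         stop("unsupported format '", format, "'"))
  invisible(path)
}

# ---- STL ------------------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.size(path)
  is_binary <- length(ntri) == 1 && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    tri <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("cannot parse '", path, "' as STL")
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(p) as.numeric(p[2:4]), numeric(3)))
    tri <- nums
  }
  n <- nrow(tri)
  list(vertices = tri, faces = matrix(seq_len(n), ncol = 3, byrow = TRUE))
}

write_stl <- function(surface, path, binary = FALSE) {
  v <- surface$vertices
  f <- surface$faces
  g <- surface_geometry(surface)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(g$normals[i, ], t(v[f[i, ], ]))), con,
               size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", surface$label), con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                           g$normals[i, 1], g$normals[i, 2], g$normals[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", surface$label), con)
  }
  invisible(path)
}

# ---- PLY (ASCII) ----------------------------------------------------------

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || txt[1] != "ply") stop("cannot parse '", path, "' as PLY")
  endh <- match("end_header", txt)
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", txt, value = TRUE)[1]))
  vlines <- txt[(endh + 1):(endh + nv)]
  flines <- txt[(endh + nv + 1):(endh + nv + nf)]
  vertices <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                       function(p) as.numeric(p[1:3]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(flines), "\\s+"),
                    function(p) as.integer(p[2:4]) + 1L, integer(3)))
  list(vertices = vertices, faces = faces)
}

write_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices
  f <- surface$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

# ---- OBJ ------------------------------------------------------------------

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0) stop("cannot parse '", path, "' as OBJ")
  vertices <- t(vapply(strsplit(trimws(vl), "\\s+"),
                       function(p) as.numeric(p[2:4]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(fl), "\\s+"), function(p) {
    as.integer(sub("/.*", "", p[2:4]))
  }, integer(3)))
  list(vertices = vertices, faces = faces)
}

write_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices
  f <- surface$faces
  writeLines(sprintf("v %.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}
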