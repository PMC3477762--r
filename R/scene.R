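#' Virtual radiographic scene
#'
#' Reconstructs the acquisition geometry of a posterior-anterior fixed-flexion
#' knee radiograph: a point X-ray source at the source-detector distance
#' (default 72 in = 1828.8 mm) above a flat detector, with the central beam
#' tilted caudally by 5, 10 or 15 degrees about the detector's horizontal
#' axis. The detector lies in the plane z = 0 with in-plane axes
#' u = (1, 0, 0) (horizontal, medial-lateral on the film) and v = (0, 1, 0)
#' (vertical); the source sits at (0, 0, SDD) so an object at
#' object-to-detector distance d is magnified by SDD / (SDD - d). The caudal
#' angle is realised by tilting the central axis, keeping the source-detector
#' distance fixed; the detector rectangle is centred on the central-axis
#' intersection and represented as two adjacent coplanar polygons.
#'
#' @param source_detector_distance source to detector distance, mm.
#' @param caudal_angle caudal beam tilt, degrees; one of 5, 10, 15 unless
#'   `allow_any_angle`.
#' @param pixel_spacing detector pixel size, mm/pixel.
#' @param image_size integer `c(nrow, ncol)` detector raster size, pixels.
#' @param object_detector_distance nominal knee-to-detector distance, mm.
#' @param allow_any_angle permit caudal angles outside the protocol set.
#' @return An object of class `radiographic_scene`.
#' @export
build_scene <- function(source_detector_distance = 1828.8,
                        caudal_angle = 10,
                        pixel_spacing = 0.2,
                        image_size = c(896L, 1024L),
                        object_detector_distance = 100,
                        allow_any_angle = FALSE) {
  if (source_detector_distance <= 0 || object_detector_distance <= 0)
    stop("distances must be positive")
  if (pixel_spacing <= 0 || any(image_size <= 0))
    stop("pixel spacing and image size must be positive")
  if (!allow_any_angle && !caudal_angle %in% c(5, 10, 15))
    stop("caudal angle must be 5, 10 or 15 degrees (or set allow_any_angle)")
  th <- caudal_angle * pi / 180
  sdd <- source_detector_distance
  source <- c(0, 0, sdd)
  central_axis <- c(0, -sin(th), -cos(th))
  det_center <- c(0, -sdd * tan(th), 0)
  axis_u <- c(1, 0, 0)
  axis_v <- c(0, 1, 0)
  w_mm <- image_size[2] * pixel_spacing
  h_mm <- image_size[1] * pixel_spacing
  det_origin <- det_center - (w_mm / 2) * axis_u - (h_mm / 2) * axis_v
  odd <- object_detector_distance
  nominal_point <- c(0, -(sdd - odd) * tan(th), odd)
  # detector rectangle as two adjacent coplanar polygons (left/right halves)
  corner <- function(du, dv) det_origin + du * axis_u + dv * axis_v
  polygons <- list(
    left = rbind(corner(0, 0), corner(w_mm / 2, 0),
                 corner(w_mm / 2, h_mm), corner(0, h_mm)),
    right = rbind(corner(w_mm / 2, 0), corner(w_mm, 0),
                  corner(w_mm, h_mm), corner(w_mm / 2, h_mm)))
  structure(list(
    source = source,
    source_detector_distance = sdd,
    caudal_angle = caudal_angle,
    central_axis = central_axis,
    det_center = det_center,
    det_origin = det_origin,
    axis_u = axis_u,
    axis_v = axis_v,
    normal = c(0, 0, 1),
    pixel_spacing = pixel_spacing,
    image_size = as.integer(image_size),
    object_detector_distance = odd,
    nominal_point = nominal_point,
    detector_polygons = polygons
  ), class = "radiographic_scene")
}

#' @export
print.radiographic_scene <- function(x, ...) {
  cat(sprintf(paste0("radiographic_scene: SDD %.1f mm, caudal angle %g deg, ",
                     "%d x %d px @ %.3g mm/px\n"),
              x$source_detector_distance, x$caudal_angle,
              x$image_size[1], x$image_size[2], x$pixel_spacing))
  invisible(x)
}

#' Binary bone-edge raster
#'
#' @param pixels integer/logical matrix; nonzero marks edge pixels.
#' @param pixel_spacing mm per pixel.
#' @param origin_mm in-plane mm coordinates of the (1,1) pixel corner,
#'   relative to the detector centre.
#' @param provenance `"radiograph tracing"` or `"ray-cast projection"`.
#' @return An object of class `edge_image`.
#' @export
edge_image <- function(pixels, pixel_spacing, origin_mm = c(0, 0),
                       provenance = "radiograph tracing") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (!all(pixels %in% c(0L, 1L))) pixels <- (pixels != 0L) * 1L
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 origin_mm = origin_mm, provenance = provenance),
            class = "edge_image")
}

#' @export
print.edge_image <- function(x, ...) {
  cat(sprintf("edge_image (%s): %d x %d px @ %.3g mm/px, %d foreground\n",
              x$provenance, nrow(x$pixels), ncol(x$pixels), x$pixel_spacing,
              sum(x$pixels)))
  invisible(x)
}

#' Write / read a binary edge image (PNG or TIFF + JSON sidecar)
#'
#' The raster is stored single-channel with foreground 255; pixel spacing,
#' origin and provenance go to `<path>.json`.
#'
#' @param img an [edge_image()].
#' @param path output path ending in `.png` or `.tif`/`.tiff`.
#' @export
write_edge_image <- function(img, path) {
  arr <- img$pixels * 1.0
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path)
  } else stop("unsupported edge image format '", ext, "'")
  jsonlite::write_json(
    list(pixel_spacing_mm = img$pixel_spacing, origin_mm = img$origin_mm,
         provenance = img$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_edge_image
#' @export
read_edge_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported edge image format '", ext, "'")
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edge_image(arr > 0.5, meta$pixel_spacing_mm, unlist(meta$origin_mm),
             meta$provenance)
}

#' Silhouette edges of a surface as seen from a point source
#'
#' A mesh edge belongs to the silhouette when its two adjacent faces face
#' opposite ways relative to the ray from the source to the face (the
#' signed dot product of face normal with centroid-minus-source changes
#' sign), and every boundary edge is always included.
#'
#' @param surface a [triangle_surface()] with consistent winding.
#' @param source_point 3-vector, mm.
#' @return Integer matrix with columns `v1`, `v2` (vertex indices).
#' @export
extract_silhouette_edges <- function(surface, source_point) {
  if (nrow(surface$faces) == 0) stop("empty surface")
  g <- surface_geometry(surface)
  s <- rowSums(g$normals * sweep(g$centroids, 2, source_point)) > 0
  e <- surface_edges(surface)
  boundary <- e[, 4] == 0L
  f2 <- ifelse(boundary, e[, 3], e[, 4])
  sil <- boundary | s[e[, 3]] != s[f2]
  out <- e[sil, 1:2, drop = FALSE]
  colnames(out) <- c("v1", "v2")
  out
}

#' Project 3D points onto the detector plane
#'
#' Each point is carried along the ray from the source through it to the
#' detector plane; the intersection is returned in detector in-plane
#' coordinates (mm, relative to the detector centre). Rays parallel to the
#' detector plane are flagged `NA` with a warning.
#'
#' @param points n x 3 matrix, mm.
#' @param scene a [build_scene()] scene.
#' @return n x 2 matrix of (u, v) mm.
#' @export
project_to_detector <- function(points, scene) {
  points <- matrix(points, ncol = 3)
  d <- sweep(points, 2, scene$source)
  if (any(rowSums(d^2) == 0)) stop("point coincident with the source")
  denom <- d %*% scene$normal
  num <- sum((scene$det_center - scene$source) * scene$normal)
  par <- abs(denom) < 1e-12
  tpar <- num / denom
  X <- sweep(d * as.vector(tpar), 2, scene$source, `+`)
  rel <- sweep(X, 2, scene$det_center)
  out <- cbind(u = rel %*% scene$axis_u, v = rel %*% scene$axis_v)
  colnames(out) <- c("u", "v")
  if (any(par)) {
    warning(sum(par), " points on rays parallel to the detector excluded")
    out[par, ] <- NA_real_
  }
  out
}

# (u, v) mm relative to detector centre -> 0-based pixel coordinates
mm_to_px0 <- function(points2d, scene) {
  w_mm <- scene$image_size[2] * scene$pixel_spacing
  h_mm <- scene$image_size[1] * scene$pixel_spacing
  cbind(floor((points2d[, 1] + w_mm / 2) / scene$pixel_spacing),
        floor((points2d[, 2] + h_mm / 2) / scene$pixel_spacing))
}

#' Rasterise an ordered contour into a binary edge image
#'
#' Consecutive points are joined with Bresenham segments, yielding an
#' 8-connected pixel contour on the scene's detector raster.
#'
#' @param points2d ordered n x 2 matrix of detector coordinates (mm,
#'   relative to the detector centre).
#' @param scene a [build_scene()] scene.
#' @param close join the last point back to the first.
#' @return An [edge_image()] with provenance `"ray-cast projection"`.
#' @export
rasterize_contour <- function(points2d, scene, close = FALSE) {
  points2d <- matrix(points2d, ncol = 2)
  points2d <- points2d[stats::complete.cases(points2d), , drop = FALSE]
  if (nrow(points2d) < 1) stop("need at least one finite point")
  px <- mm_to_px0(points2d, scene)
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  inside <- px[, 1] >= 0 & px[, 1] < nc & px[, 2] >= 0 & px[, 2] < nr
  if (!any(inside))
    stop(sprintf("all points fall outside the %d x %d px image", nr, nc))
  if (nrow(px) == 1) {
    segs <- cbind(px, px)
  } else {
    i0 <- seq_len(nrow(px) - 1)
    segs <- cbind(px[i0, , drop = FALSE], px[i0 + 1, , drop = FALSE])
    if (close) segs <- rbind(segs, c(px[nrow(px), ], px[1, ]))
  }
  storage.mode(segs) <- "integer"
  img <- raster_segments_cpp(segs, nr, nc)
  w_mm <- nc * scene$pixel_spacing; h_mm <- nr * scene$pixel_spacing
  edge_image(img, scene$pixel_spacing, origin_mm = c(-w_mm / 2, -h_mm / 2),
             provenance = "ray-cast projection")
}

#' Symmetric contour distance cost
#'
#' Mean over model-contour pixels of the Euclidean distance transform of the
#' reference edge image, averaged with the symmetric term (reference pixels
#' against the model contour's distance transform), in mm. Zero if and only
#' if the two foreground sets coincide; symmetric in its arguments.
#'
#' @param model_edges,radiograph_edges [edge_image()] objects on the same
#'   pixel grid.
#' @return Nonnegative scalar cost, mm.
#' @export
contour_cost <- function(model_edges, radiograph_edges) {
  a <- model_edges$pixels; b <- radiograph_edges$pixels
  if (!all(dim(a) == dim(b)))
    stop("edge images are on different pixel grids")
  if (model_edges$pixel_spacing != radiograph_edges$pixel_spacing)
    stop("edge images have different pixel spacing")
  if (sum(a) == 0 || sum(b) == 0) stop("empty edge image")
  dt_a <- edt_cpp(a)
  dt_b <- edt_cpp(b)
  0.5 * (mean(dt_b[a == 1L]) + mean(dt_a[b == 1L])) * model_edges$pixel_spacing
}

# render the ray-cast silhouette of a surface (optionally posed) as an
# edge_image on the scene raster; shared by registration and the phantom
render_silhouette <- function(surface, scene, pose = rigid_pose(),
                              center = surface_centroid(surface)) {
  e <- surface_edges(surface)
  R <- rotation_matrix(pose$rx, pose$ry, pose$rz)
  img <- render_silhouette_cpp(
    surface$vertices, surface$faces, e, R,
    c(pose$tx, pose$ty, pose$tz), center, scene$source, scene$det_origin,
    scene$axis_u, scene$axis_v, scene$pixel_spacing,
    scene$image_size[1], scene$image_size[2])
  w_mm <- scene$image_size[2] * scene$pixel_spacing
  h_mm <- scene$image_size[1] * scene$pixel_spacing
  edge_image(img, scene$pixel_spacing, origin_mm = c(-w_mm / 2, -h_mm / 2),
             provenance = "ray-cast projection")
}
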