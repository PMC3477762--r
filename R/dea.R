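#' DEA cartilage material parameters
#'
#' Linear-elastic cartilage represented as a bed of independent compressive
#' springs (Winkler foundation). Defaults: elastic modulus 12 MPa, Poisson's
#' ratio 0.42, combined tibiofemoral thickness 6 mm, vertical load 1000 N.
#'
#' @param E cartilage elastic modulus, MPa.
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param t combined cartilage thickness, mm.
#' @param load applied vertical force, N.
#' @export
dea_params <- function(E = 12, nu = 0.42, t = 6, load = 1000) {
  if (nu <= 0 || nu >= 0.5)
    stop("Poisson's ratio must lie in (0, 0.5); the confined-compression law is singular at 0.5")
  if (E <= 0 || t <= 0 || load <= 0) stop("E, t and load must be positive")
  structure(list(E = E, nu = nu, t = t, load = load), class = "dea_params")
}

#' Confined-compression (aggregate) modulus, MPa
#' @param params a [dea_params()].
#' @export
confined_modulus <- function(params) {
  params$E * (1 - params$nu) / ((1 + params$nu) * (1 - 2 * params$nu))
}

#' Nearest-facet contact pairs between apposed surfaces
#'
#' For every tibial facet, the nearest femoral facet (centroid distance)
#' within `search_radius`, found with a uniform spatial grid; results are
#' identical to an exhaustive all-pairs search.
#'
#' @param tibia,femur [triangle_surface()] objects posed in a common frame.
#' @param search_radius pairing cutoff, mm.
#' @param tibia_geom,femur_geom optional precomputed [surface_geometry()]s.
#' @return Data frame with columns `tibial`, `femoral` (facet indices) and
#'   `dist` (mm), one row per paired tibial facet.
#' @export
find_contact_pairs <- function(tibia, femur, search_radius,
                               tibia_geom = surface_geometry(tibia),
                               femur_geom = surface_geometry(femur)) {
  if (nrow(tibia$faces) == 0 || nrow(femur$faces) == 0)
    stop("empty surface")
  nn <- nearest_within_cpp(tibia_geom$centroids, femur_geom$centroids,
                           search_radius)
  hit <- nn$idx > 0L
  data.frame(tibial = which(hit), femoral = nn$idx[hit], dist = nn$dist[hit])
}

#' Compressive spring deformation from intersurface separation
#'
#' `d = max(0, t - s)`: springs only engage once the separation `s` along
#' the tibial facet normal falls below the combined cartilage thickness;
#' tension is never modelled, and bone-on-bone overlap (negative `s`) simply
#' yields `d > t`.
#'
#' @param separation separations `s`, mm (may be negative for overlap).
#' @param t combined cartilage thickness, mm.
#' @export
spring_deformation <- function(separation, t) pmax(0, t - separation)

#' Winkler spring stress from deformation
#'
#' Linear-elastic confined-column law:
#' `stress = E (1 - nu) / ((1 + nu)(1 - 2 nu)) * d / t`, in MPa.
#' The deformation-to-stress relation is pluggable at the [solve_equilibrium()]
#' level, this law being the default.
#'
#' @param d spring deformations, mm (>= 0).
#' @param params a [dea_params()].
#' @export
spring_stress <- function(d, params) {
  if (any(d < 0)) stop("negative spring deformation")
  confined_modulus(params) * d / params$t
}

#' Net contact force from a spring set
#'
#' Vector sum of per-facet normal forces, `stress_i * area_i * direction_i`;
#' 1 MPa mm^2 = 1 N.
#'
#' @param springs list with `directions` (n x 3 unit vectors) and `areas`
#'   (mm^2), as in the `springs` element of a [solve_equilibrium()] field.
#' @param stresses per-spring stress, MPa.
#' @return Force 3-vector, N.
#' @export
contact_force <- function(springs, stresses) {
  if (length(stresses) == 0) return(c(0, 0, 0))
  colSums(springs$directions * (stresses * springs$areas))
}

# separation along the tibial facet normal to the paired femoral facet
# (the facet plane, accepted only where the normal ray actually meets the
# facet's extent, with a half-facet barycentric margin). Pairs whose
# normals do not oppose are discarded (side walls, back faces).
facet_separations <- function(pairs, tg, fg, fem_vertices, fem_faces,
                              fem_shift = c(0, 0, 0), margin = 0.5) {
  nt <- tg$normals[pairs$tibial, , drop = FALSE]
  nf <- fg$normals[pairs$femoral, , drop = FALSE]
  ct <- tg$centroids[pairs$tibial, , drop = FALSE]
  cf <- fg$centroids[pairs$femoral, , drop = FALSE]
  opp <- rowSums(nt * nf)
  s <- rowSums((cf - ct) * nf) / opp
  s[opp > -0.2] <- Inf  # not facing each other: no spring
  # barycentric extent check of the intersection point on the facet plane
  fi <- fem_faces[pairs$femoral, , drop = FALSE]
  A <- sweep(fem_vertices[fi[, 1], , drop = FALSE], 2, fem_shift, `+`)
  B <- sweep(fem_vertices[fi[, 2], , drop = FALSE], 2, fem_shift, `+`)
  C <- sweep(fem_vertices[fi[, 3], , drop = FALSE], 2, fem_shift, `+`)
  p <- ct + nt * ifelse(is.finite(s), s, 0)
  v0 <- B - A; v1 <- C - A; v2 <- p - A
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01^2
  alpha <- (d11 * d20 - d01 * d21) / den
  beta <- (d00 * d21 - d01 * d20) / den
  outside <- alpha < -margin | beta < -margin | alpha + beta > 1 + margin
  s[outside] <- Inf
  s
}

#' Solve the DEA contact problem to vertical load equilibrium
#'
#' Rigid femur on a compressive-only spring bed over the tibial facets.
#' Load control: the femur's translation along the (vertical) load axis is
#' the single equilibrium unknown, found by bracketing and bisection until
#' the vertical contact force matches the applied load within `tol`
#' (default 0.5%). Deterministic.
#'
#' @param femur,tibia [triangle_surface()] objects posed in a common frame
#'   (femur above the tibia along `load_axis`).
#' @param params a [dea_params()].
#' @param load_axis unit 3-vector of the applied load (vertical), pointing
#'   from tibia towards femur.
#' @param search_radius facet pairing cutoff, mm (default `2 t`).
#' @param tol relative force tolerance.
#' @param max_iter bisection iteration cap.
#' @param travel_bound maximum femoral travel in either direction, mm.
#' @param stress_law function `(d, params) -> MPa` (default [spring_stress()]).
#' @return A `contact_stress_field`: per-tibial-facet `stress` (MPa, zero
#'   off contact), `springs` (pair table with deformations, directions,
#'   areas), `offset` (equilibrium femoral translation along the load axis,
#'   mm; negative = pressed towards the tibia), `force` (converged vertical
#'   force, N), `converged`, plus the inputs needed by
#'   [compartment_metrics()].
#' @export
solve_equilibrium <- function(femur, tibia, params = dea_params(),
                              load_axis = c(0, 0, 1), search_radius = NULL,
                              tol = 0.005, max_iter = 100, travel_bound = 10,
                              stress_law = spring_stress) {
  if (is.null(search_radius)) search_radius <- 2 * params$t
  load_axis <- load_axis / sqrt(sum(load_axis^2))
  tg <- surface_geometry(tibia)
  fg <- surface_geometry(femur)

  # vertical contact force for a femoral offset u along load_axis
  force_at <- function(u) {
    fgu <- fg
    fgu$centroids <- sweep(fg$centroids, 2, u * load_axis, `+`)
    pairs <- find_contact_pairs(tibia, femur, search_radius,
                                tibia_geom = tg, femur_geom = fgu)
    if (nrow(pairs) == 0)
      return(list(fz = 0, pairs = pairs, d = numeric(0), s = numeric(0)))
    s <- facet_separations(pairs, tg, fgu, femur$vertices, femur$faces,
                           fem_shift = u * load_axis)
    d <- spring_deformation(s, params$t)
    sig <- stress_law(d, params)
    nt <- tg$normals[pairs$tibial, , drop = FALSE]
    fz <- sum(sig * tg$areas[pairs$tibial] * (nt %*% load_axis))
    list(fz = fz, pairs = pairs, d = d, s = s)
  }

  target <- params$load
  f0 <- force_at(0)
  # bracket the equilibrium offset: pressing = negative u (femur moves
  # towards the tibia along -load_axis)
  lo <- hi <- 0
  f_lo <- f_hi <- f0$fz
  step <- 0.5
  if (f0$fz < target) {
    while (f_lo < target) {
      lo <- lo - step
      if (-lo > travel_bound)
        stop(sprintf(paste0("no contact equilibrium within the %.1f mm travel ",
                            "bound (force %.1f N short of %.0f N)"),
                     travel_bound, target - f_lo, target))
      f_lo <- force_at(lo)$fz
    }
    hi <- lo + step
    f_hi <- force_at(hi)$fz
  } else {
    while (f_hi > target) {
      hi <- hi + step
      if (hi > travel_bound)
        stop(sprintf(paste0("cannot unload to %.0f N within the %.1f mm ",
                            "travel bound (excess force %.1f N)"),
                     target, travel_bound, f_hi - target))
      f_hi <- force_at(hi)$fz
    }
    lo <- hi - step
    f_lo <- force_at(lo)$fz
  }

  u <- (lo + hi) / 2
  fu <- force_at(u)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (abs(fu$fz - target) <= tol * target) {
      converged <- TRUE
      break
    }
    if (fu$fz < target) hi <- u else lo <- u
    u <- (lo + hi) / 2
    fu <- force_at(u)
  }
  if (!converged && abs(fu$fz - target) > tol * target)
    stop(sprintf("equilibrium not reached in %d iterations (force gap %.2f N)",
                 max_iter, fu$fz - target))

  stress <- numeric(nrow(tibia$faces))
  sig <- stress_law(fu$d, params)
  stress[fu$pairs$tibial] <- sig
  active <- sig > 0
  springs <- list(
    tibial = fu$pairs$tibial[active],
    femoral = fu$pairs$femoral[active],
    deformations = fu$d[active],
    directions = tg$normals[fu$pairs$tibial[active], , drop = FALSE],
    areas = tg$areas[fu$pairs$tibial[active]])
  structure(list(stress = stress, springs = springs, offset = u,
                 force = fu$fz, converged = converged, iterations = iter,
                 load_axis = load_axis, params = params,
                 tibia_geom = tg), class = "contact_stress_field")
}

#' @export
print.contact_stress_field <- function(x, ...) {
  cat(sprintf(paste0("contact_stress_field: %d active springs, peak %.3f MPa, ",
                     "offset %.3f mm, force %.1f N (%s)\n"),
              length(x$springs$tibial), max(x$stress), x$offset, x$force,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Peak and mean contact stress per tibiofemoral compartment
#'
#' Facets are split into medial and lateral by the sign of their centroid
#' coordinate along the medial-lateral axis relative to the tibial surface
#' centroid (a sagittal midline plane). Peak is the maximum facet stress;
#' mean is the area-weighted mean over facets in contact (nonzero stress).
#' An empty compartment reports zeros with a warning.
#'
#' @param field a [solve_equilibrium()] result.
#' @param ml_axis unit 3-vector of the medial-lateral direction; medial is
#'   the negative side.
#' @param midline_offset scalar shift of the midline plane along `ml_axis`
#'   from the tibial centroid, mm.
#' @return List `peak_medial`, `mean_medial`, `peak_lateral`, `mean_lateral`
#'   (MPa) plus per-facet `compartment` labels.
#' @export
compartment_metrics <- function(field, ml_axis = c(1, 0, 0),
                                midline_offset = 0) {
  cen <- field$tibia_geom$centroids
  mid <- sum(colMeans(cen) * ml_axis) + midline_offset
  coord <- as.numeric(cen %*% ml_axis) - mid
  compartment <- ifelse(coord < 0, "medial", "lateral")
  one <- function(side) {
    sel <- compartment == side & field$stress > 0
    if (!any(sel)) {
      warning("no contact in the ", side, " compartment; metrics are 0")
      return(c(peak = 0, mean = 0))
    }
    a <- field$tibia_geom$areas[sel]
    c(peak = max(field$stress[sel]),
      mean = sum(field$stress[sel] * a) / sum(a))
  }
  med <- one("medial")
  lat <- one("lateral")
  list(peak_medial = med[["peak"]], mean_medial = med[["mean"]],
       peak_lateral = lat[["peak"]], mean_lateral = lat[["mean"]],
       compartment = compartment)
}
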