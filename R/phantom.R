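#' Synthetic knee phantom specification
#'
#' Parametric stand-in for MRI-derived femur/tibia surfaces: the femur is a
#' pair of spherical condyles (unequal radii, so the silhouette identifies
#' left from right) bridged by a shaft stub; the tibia is a plateau slab
#' carrying two conforming spherical sockets whose rims limit the contact
#' patch. In the assembled (ground-truth) configuration each condyle centre
#' coincides with its socket's sphere centre, leaving a uniform radial
#' clearance equal to `socket_clearance`.
#'
#' @param condyle_radii two femoral condyle radii, mm (medial, lateral).
#' @param intercondylar_spacing distance between condyle centres, mm; must
#'   exceed the radius sum (non-overlapping condyles) and twice the rim.
#' @param socket_clearance socket sphere radius minus condyle radius, mm.
#' @param rim_radius socket rim (contact patch limit), mm.
#' @param refinement icosphere subdivision level / plateau grid halvings.
#' @param femur_refinement optional finer subdivision level for the femoral
#'   condyles (defaults to `refinement`); contact-stress work benefits from
#'   a femoral mesh whose chord error is small against the spring
#'   deformations.
#' @param seed stored for provenance (the generator itself is
#'   deterministic).
#' @export
phantom_spec <- function(condyle_radii = c(40, 36),
                         intercondylar_spacing = 80,
                         socket_clearance = 0.5,
                         rim_radius = 15,
                         refinement = 3,
                         femur_refinement = refinement,
                         seed = 1) {
  if (length(condyle_radii) != 2 || any(condyle_radii <= 0))
    stop("need two positive condyle radii")
  if (intercondylar_spacing < sum(condyle_radii))
    stop("infeasible spec: condyle spheres overlap (spacing ",
         intercondylar_spacing, " < radius sum ", sum(condyle_radii), ")")
  if (intercondylar_spacing < 2 * rim_radius)
    stop("infeasible spec: sockets overlap")
  if (socket_clearance < 0) stop("socket clearance must be nonnegative")
  if (rim_radius >= min(condyle_radii))
    stop("rim radius must be smaller than the condyle radii")
  structure(list(condyle_radii = condyle_radii,
                 intercondylar_spacing = intercondylar_spacing,
                 socket_clearance = socket_clearance,
                 rim_radius = rim_radius,
                 refinement = refinement,
                 femur_refinement = femur_refinement, seed = seed),
            class = "phantom_spec")
}

#' Conforming symmetric phantom used for DEA sensitivity work
#'
#' Equal 40 mm condyles in 40.5 mm sockets with a 15 mm rim: contact is
#' rim-limited and near-uniform, emulating conforming tibiofemoral contact.
#' @param refinement subdivision level.
#' @export
conforming_phantom_spec <- function(refinement = 3) {
  phantom_spec(condyle_radii = c(40, 40), intercondylar_spacing = 82,
               socket_clearance = 0.5, rim_radius = 15,
               refinement = refinement, femur_refinement = refinement + 2)
}

# ---- mesh primitives ------------------------------------------------------

#' Icosphere mesh
#' @param radius sphere radius, mm.
#' @param center centre, mm.
#' @param subdivisions subdivision level (0 = icosahedron, each level
#'   quadruples the face count).
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      id <- mids[[k]]
      if (is.null(id)) {
        m <- (v[a, ] + v[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        newv[[length(newv) + 1]] <<- m
        id <- nv + length(newv)
        mids[[k]] <- id
      }
      id
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  v <- sweep(v * radius, 2, center, `+`)
  triangle_surface(v, f, label = "sphere")
}

#' Axis-aligned closed box mesh
#' @param lo,hi opposite corners, mm.
#' @export
box_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertices indexed: 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+)
  # 7:(-++) 8:(+++); outward-wound quads split into triangles
  quads <- rbind(
    c(1, 3, 4, 2),  # z = lo (viewed from below: CCW)
    c(5, 6, 8, 7),  # z = hi
    c(1, 2, 6, 5),  # y = lo
    c(3, 7, 8, 4),  # y = hi
    c(1, 5, 7, 3),  # x = lo
    c(2, 4, 8, 6))  # x = hi
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  triangle_surface(v, f, label = "box")
}

# closed solid under a heightfield z = f(x, y): top follows the surface,
# flat bottom, vertical side walls; outward winding throughout
heightfield_solid <- function(xs, ys, zfun, z_bottom, label = "slab") {
  nx <- length(xs); ny <- length(ys)
  g <- as.matrix(expand.grid(x = xs, y = ys))  # x varies fastest
  zt <- zfun(g[, 1], g[, 2])
  top <- cbind(g, zt)
  bot <- cbind(g, z_bottom)
  v <- rbind(top, bot)
  id <- function(i, j) (j - 1L) * nx + i          # top vertex index
  bid <- function(i, j) nx * ny + (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- id(i, j); b <- id(i + 1, j); c_ <- id(i + 1, j + 1); d <- id(i, j + 1)
  top_f <- rbind(cbind(a, b, c_), cbind(a, c_, d))          # +z outward
  ab <- bid(i, j); bb <- bid(i + 1, j); cb <- bid(i + 1, j + 1)
  db <- bid(i, j + 1)
  bot_f <- rbind(cbind(ab, cb, bb), cbind(ab, db, cb))      # -z outward
  side <- function(t1, t2, b1, b2) rbind(cbind(t1, b2, b1), cbind(t1, t2, b2))
  iy <- seq_len(ny - 1)
  ix <- seq_len(nx - 1)
  s1 <- side(id(1, iy), id(1, iy + 1), bid(1, iy), bid(1, iy + 1))       # x = min
  s2 <- side(id(nx, iy + 1), id(nx, iy), bid(nx, iy + 1), bid(nx, iy))   # x = max
  s3 <- side(id(ix + 1, 1), id(ix, 1), bid(ix + 1, 1), bid(ix, 1))       # y = min
  s4 <- side(id(ix, ny), id(ix + 1, ny), bid(ix, ny), bid(ix + 1, ny))   # y = max
  triangle_surface(v, rbind(top_f, bot_f, s1, s2, s3, s4), label = label)
}

# merge several closed surfaces into one (disjoint union)
merge_surfaces <- function(surfaces, label = "merged") {
  offs <- 0L
  vs <- list(); fs <- list()
  for (s in surfaces) {
    vs[[length(vs) + 1]] <- s$vertices
    fs[[length(fs) + 1]] <- s$faces + offs
    offs <- offs + nrow(s$vertices)
  }
  triangle_surface(do.call(rbind, vs), do.call(rbind, fs), label = label)
}

# ---- phantom generation ---------------------------------------------------

#' Generate a synthetic knee phantom
#'
#' Builds femur and tibia surfaces in the knee frame (x medial-lateral,
#' y anterior-posterior, z superior) in the assembled ground-truth
#' configuration: condyle centres at `(+/- spacing/2, 0, 0)`, each socket
#' sphere concentric with its condyle so that the radial tibiofemoral gap
#' equals `socket_clearance` over the whole socket. The relative
#' ground-truth pose is therefore the identity.
#'
#' @param spec a [phantom_spec()].
#' @return List with `femur`, `tibia` ([triangle_surface()]s),
#'   `truth_pose` (identity [rigid_pose()]), `condyle_centers`,
#'   and `spec`.
#' @export
generate_knee_phantom <- function(spec = phantom_spec()) {
  r <- spec$condyle_radii
  half <- spec$intercondylar_spacing / 2
  centers <- rbind(medial = c(-half, 0, 0), lateral = c(half, 0, 0))
  ref <- spec$refinement

  fref <- if (is.null(spec$femur_refinement)) ref else spec$femur_refinement
  cond1 <- icosphere(r[1], centers[1, ], subdivisions = fref)
  cond2 <- icosphere(r[2], centers[2, ], subdivisions = fref)
  shaft <- box_mesh(c(-15, -12, 20), c(15, 12, 70))
  femur <- merge_surfaces(list(cond1, cond2, shaft), label = "femur")

  rs <- r + spec$socket_clearance
  rim <- spec$rim_radius
  # plateau sits well clear of the condyles beyond the socket rims, so the
  # contact patch is rim-limited for any cartilage thickness up to 8 mm
  z_sphere_rim <- -sqrt(r^2 - rim^2)
  zp <- min(z_sphere_rim) - 10.5
  zfun <- function(x, y) {
    z <- rep(zp, length(x))
    for (k in 1:2) {
      rho2 <- (x - centers[k, 1])^2 + y^2
      inside <- rho2 <= rim^2
      z[inside] <- -sqrt(rs[k]^2 - rho2[inside])
    }
    z
  }
  xmax <- half + rim + 10
  ymax <- 30
  nx <- 16 * 2^ref + 1
  ny <- 8 * 2^ref + 1
  tibia <- heightfield_solid(seq(-xmax, xmax, length.out = nx),
                             seq(-ymax, ymax, length.out = ny),
                             zfun, z_bottom = zp - 25, label = "tibia")

  list(femur = femur, tibia = tibia, truth_pose = rigid_pose(),
       condyle_centers = centers, spec = spec)
}

#' Place knee-frame surfaces into the radiographic scene
#'
#' Rotates the knee frame (x medial-lateral, y anterior-posterior,
#' z superior) into the scene frame (x detector horizontal, y detector
#' vertical, z towards the source) for a posterior-anterior view, then
#' translates the combined bounding-box centre to the scene's nominal
#' object point between source and detector (centring the knee in the
#' field of view).
#'
#' @param surfaces a single [triangle_surface()] or a (named) list of them.
#' @param scene a [build_scene()] scene.
#' @return List with `surfaces` (same shape as the input), `rotation`
#'   (3 x 3) and `translation` applied.
#' @export
place_in_scene <- function(surfaces, scene) {
  single <- inherits(surfaces, "triangle_surface")
  lst <- if (single) list(surfaces) else surfaces
  R <- matrix(c(1, 0, 0,
                0, 0, 1,
                0, -1, 0), 3, 3, byrow = TRUE)  # knee -> scene (PA view)
  allv <- do.call(rbind, lapply(lst, `[[`, "vertices")) %*% t(R)
  cen <- (apply(allv, 2, min) + apply(allv, 2, max)) / 2  # bounding-box centre
  tr <- scene$nominal_point - cen
  out <- lapply(lst, function(s) {
    s2 <- s
    s2$vertices <- sweep(s$vertices %*% t(R), 2, tr, `+`)
    attr(s2, "edge_table") <- attr(s, "edge_table")
    s2
  })
  if (single) out <- out[[1]]
  list(surfaces = out, rotation = R, translation = tr)
}

#' Render ground-truth radiograph edge images for placed surfaces
#'
#' Forward-renders each surface's ray-cast silhouette at the given pose with
#' the pipeline's own projector, so model-image mismatch is exactly zero at
#' the ground-truth pose.
#'
#' @param surfaces a [triangle_surface()] or list of them, already placed
#'   in scene coordinates.
#' @param scene a [build_scene()] scene.
#' @param pose pose at which to render (default identity = ground truth).
#' @return An [edge_image()] per surface (same shape as the input).
#' @export
synthesize_radiograph_edges <- function(surfaces, scene,
                                        pose = rigid_pose()) {
  single <- inherits(surfaces, "triangle_surface")
  lst <- if (single) list(surfaces) else surfaces
  out <- lapply(lst, render_silhouette, scene = scene, pose = pose)
  if (single) out[[1]] else out
}

# area-weighted vertex normals
vertex_normals <- function(surface) {
  g <- surface_geometry(surface)
  n <- matrix(0, nrow(surface$vertices), 3)
  w <- g$normals * g$areas
  for (k in 1:3) {
    idx <- surface$faces[, k]
    for (d in 1:3) {
      acc <- rowsum(w[, d], idx)
      n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Segmentation-like surface perturbation
#'
#' Displaces vertices along their normals by smooth, spatially correlated
#' zero-mean noise: white per-vertex noise is averaged over the mesh
#' neighbourhood graph until its correlation length matches the request,
#' then rescaled so the RMS displacement equals `amplitude`. Topology is
#' unchanged; deterministic given `seed`.
#'
#' @param surface a [triangle_surface()].
#' @param amplitude RMS vertex displacement, mm.
#' @param correlation_length smoothing length scale, mm.
#' @param seed integer seed.
#' @return Perturbed [triangle_surface()].
#' @export
perturb_segmentation <- function(surface, amplitude, correlation_length = 10,
                                 seed = 1) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (amplitude == 0) return(surface)
  e <- surface_edges(surface)
  el <- sqrt(rowSums((surface$vertices[e[, 1], , drop = FALSE] -
                        surface$vertices[e[, 2], , drop = FALSE])^2))
  h <- mean(el)
  n_iter <- max(1L, as.integer(round((correlation_length / h)^2)))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  nv <- nrow(surface$vertices)
  noise <- rnorm(nv)
  both <- c(e[, 1], e[, 2])
  nbr <- c(e[, 2], e[, 1])
  deg <- tabulate(both, nv)
  deg[deg == 0] <- 1
  for (it in seq_len(n_iter)) {
    s <- rowsum(noise[nbr], both)
    acc <- numeric(nv)
    acc[as.integer(rownames(s))] <- s
    noise <- (noise + acc) / (1 + deg)
  }
  noise <- noise - mean(noise)
  rms <- sqrt(mean(noise^2))
  if (rms == 0) stop("degenerate noise field")
  noise <- noise * (amplitude / rms)
  minr <- min(sqrt(rowSums(sweep(surface$vertices, 2,
                                 surface_centroid(surface))^2)))
  if (amplitude > 0.1 * minr)
    warning("amplitude exceeds 10% of the minimum radius; ",
            "surface may self-intersect")
  out <- surface
  out$vertices <- surface$vertices + vertex_normals(surface) * noise
  attr(out, "edge_table") <- attr(surface, "edge_table")
  out
}

#' Simulate a two-way random-effects ratings table
#'
#' `value(i, j, d) = mu + a_i + b_j + e_ijd` with independent zero-mean
#' normal target, rater and error effects at the stated variances — the
#' generative model under which ICC(2,1) estimates
#' `sigma2_target / (sigma2_target + sigma2_rater + sigma2_error)`.
#'
#' @param n_targets number of knees.
#' @param k_raters number of raters.
#' @param n_days number of rating occasions.
#' @param variance_components numeric `c(target, rater, error)` variances.
#' @param grand_mean mean rating, MPa.
#' @param seed integer seed.
#' @param metric,compartment labels attached to the output.
#' @return Long data frame with columns `knee_id`, `rater_id`, `day`,
#'   `metric`, `compartment`, `value_mpa`; attribute `population_icc`.
#' @export
simulate_ratings <- function(n_targets, k_raters = 3, n_days = 2,
                             variance_components = c(9, 0.5, 0.5),
                             grand_mean = 3, seed = 1,
                             metric = "peak", compartment = "medial") {
  if (n_targets < 2) stop("need at least 2 targets")
  if (any(variance_components < 0)) stop("variances must be nonnegative")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  a <- rnorm(n_targets, 0, sqrt(variance_components[1]))
  b <- rnorm(k_raters, 0, sqrt(variance_components[2]))
  grid <- expand.grid(knee_id = seq_len(n_targets),
                      rater_id = seq_len(k_raters),
                      day = seq_len(n_days))
  e <- rnorm(nrow(grid), 0, sqrt(variance_components[3]))
  out <- data.frame(grid,
                    metric = metric, compartment = compartment,
                    value_mpa = grand_mean + a[grid$knee_id] +
                      b[grid$rater_id] + e)
  attr(out, "population_icc") <-
    variance_components[1] / sum(variance_components)
  out
}

#' Simulate a full four-metric reliability study
#'
#' One [simulate_ratings()] draw per metric x compartment combination, with
#' seeds offset so the four tables are independent.
#'
#' @inheritParams simulate_ratings
#' @export
simulate_ratings_study <- function(n_targets = 10, k_raters = 3, n_days = 2,
                                   variance_components = c(9, 0.5, 0.5),
                                   grand_mean = 3, seed = 1) {
  combos <- expand.grid(metric = c("peak", "mean"),
                        compartment = c("medial", "lateral"),
                        stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    simulate_ratings(n_targets, k_raters, n_days, variance_components,
                     grand_mean, seed = seed + i - 1,
                     metric = combos$metric[i],
                     compartment = combos$compartment[i])
  }))
}
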