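#' Default CMA-ES scales for the 6-DOF pose search
#'
#' 5 mm for the two in-plane translations, 10 mm for the out-of-plane
#' (depth) translation — matching the weaker depth observability of a single
#' projection — and 3 degrees for each rotation.
#' @export
default_pose_scales <- function() c(5, 5, 10, 3, 3, 3)

# fast silhouette cost closure for one bone against a fixed target image;
# rotation centre fixed at optimisation start
make_silhouette_cost <- function(surface, edges, scene, center) {
  e_tab <- surface_edges(surface)
  dt <- edt_cpp(edges$pixels)
  tpx <- which(edges$pixels == 1L, arr.ind = TRUE) - 1L  # 0-based (row, col)
  force(center)
  function(x) {
    R <- rotation_matrix(x[4], x[5], x[6])
    silhouette_cost_cpp(surface$vertices, surface$faces, e_tab, R, x[1:3],
                        center, scene$source, scene$det_origin, scene$axis_u,
                        scene$axis_v, scene$pixel_spacing,
                        scene$image_size[1], scene$image_size[2], dt, tpx)
  }
}

#' Register one bone surface to a radiograph edge image
#'
#' Minimises the symmetric silhouette [contour_cost()] between the ray-cast
#' model silhouette and the traced radiograph edges over a 6-DOF pose, using
#' CMA-ES. Because the cost landscape is highly nonconvex, `n_runs`
#' independent seeded runs are executed and the lowest-cost run wins (ties
#' broken by run order).
#'
#' @param surface a [triangle_surface()] already placed at its nominal
#'   position between source and detector (see [place_in_scene()]).
#' @param edges target [edge_image()] (binary bone-edge tracing).
#' @param scene a [build_scene()] scene.
#' @param init_pose initial pose estimate (search centre).
#' @param n_runs independent optimizer runs (default 3).
#' @param seed base seed; run `i` uses `seed + i - 1`.
#' @param popsize,max_evals CMA-ES population size and per-run budget.
#' @param sigma0 per-parameter search scales (mm, mm, mm, deg, deg, deg).
#' @param extra_cost optional function of a [rigid_pose()] added to the
#'   silhouette cost (used for the tibial proximity penalty).
#' @return A `registration_result`: `best_pose`, `best_cost`, `center`
#'   (rotation centre used), `per_run` (pose, cost, evaluations, seed,
#'   converged for each run), `converged`.
#' @export
register_bone <- function(surface, edges, scene,
                          init_pose = rigid_pose(), n_runs = 3, seed = 1,
                          popsize = 70, max_evals = 8000,
                          sigma0 = default_pose_scales(),
                          extra_cost = NULL) {
  center <- surface_centroid(surface)
  cost_sil <- make_silhouette_cost(surface, edges, scene, center)
  cost_fn <- if (is.null(extra_cost)) cost_sil else {
    function(x) cost_sil(x) + extra_cost(pose_from_vector(x))
  }
  x0 <- pose_to_vector(init_pose)
  c0 <- cost_fn(x0)
  if (!is.finite(c0))
    stop("silhouette projects fully outside the image at the initial pose; ",
         "re-center the model (see place_in_scene)")
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    r <- cma_es_minimize(cost_fn, x0, sigma0, popsize = popsize,
                         max_evals = max_evals, seed = seed + i - 1)
    runs[[i]] <- list(pose = pose_from_vector(r$x), cost = r$cost,
                      evaluations = r$evaluations, seed = r$seed,
                      converged = r$converged)
  }
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  best <- which.min(costs)   # ties -> lowest run index
  structure(list(best_pose = runs[[best]]$pose, best_cost = costs[best],
                 center = center, per_run = runs,
                 converged = runs[[best]]$converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: best cost %.4g mm over %d runs%s\n",
              x$best_cost, length(x$per_run),
              if (x$converged) " (converged)" else ""))
  print(x$best_pose)
  invisible(x)
}

#' Tibiofemoral proximity penalty
#'
#' Penalises tibial candidate poses that pull the tibia away from the
#' already-aligned femur: `weight * max(0, gap - gap_threshold)` where `gap`
#' is the minimum distance between the two vertex sets (mm). Zero while the
#' bones stay within the threshold (default 6 mm, the combined cartilage
#' thickness).
#'
#' @param femur_posed,tibia_posed surfaces posed in scene coordinates.
#' @param weight penalty slope, cost-mm per mm of excess gap.
#' @param gap_threshold allowed tibiofemoral gap, mm.
#' @return Nonnegative scalar.
#' @export
tibia_penalty <- function(femur_posed, tibia_posed, weight = 1,
                          gap_threshold = 6) {
  gap <- min_surface_distance(tibia_posed$vertices, femur_posed$vertices,
                              r0 = gap_threshold)
  weight * max(0, gap - gap_threshold)
}

# minimum distance between two point sets; grid query with doubling radius
min_surface_distance <- function(a, b, r0 = 6) {
  r <- r0
  for (k in 1:12) {
    nn <- nearest_within_cpp(a, b, r)
    if (any(nn$idx > 0)) return(min(nn$dist, na.rm = TRUE))
    r <- r * 2
  }
  # beyond any plausible gap: fall back to centroid distance
  sqrt(sum((colMeans(a) - colMeans(b))^2))
}

#' Register a knee: femur first, then tibia with a proximity penalty
#'
#' The femur is aligned first; its best transform is then applied to the
#' tibia as the initial pose (the bones travel together), and the tibial
#' cost adds [tibia_penalty()] so the tibia cannot drift away from the
#' femur along the weakly observed depth axis. If the femur registration
#' fails the tibia is not attempted.
#'
#' @param femur,tibia [triangle_surface()] objects placed in the scene.
#' @param femur_edges,tibia_edges target [edge_image()]s.
#' @param scene a [build_scene()] scene.
#' @param seed base seed (femur uses `seed`, tibia `seed + 100`).
#' @param penalty_weight,gap_threshold see [tibia_penalty()].
#' @param ... passed to [register_bone()] (`n_runs`, `popsize`, `max_evals`,
#'   `sigma0`, `init_pose` for the femur).
#' @return List with elements `femur` and `tibia` (registration results)
#'   and `tibia_init` (the tibial initial pose derived from the femur).
#' @export
register_knee <- function(femur, tibia, femur_edges, tibia_edges, scene,
                          seed = 1, penalty_weight = 1, gap_threshold = 6,
                          ...) {
  fem_res <- tryCatch(
    register_bone(femur, femur_edges, scene, seed = seed, ...),
    error = function(e) e)
  if (inherits(fem_res, "error"))
    stop("femur registration failed; tibia not attempted: ",
         conditionMessage(fem_res))
  # carry the tibia along with the femur's best transform (the same rigid
  # map, re-expressed about the tibia's own centroid, which is the rotation
  # centre register_bone optimises about)
  M <- pose_to_matrix(fem_res$best_pose, fem_res$center)
  tib_center <- surface_centroid(tibia)
  tibia_init <- matrix_to_pose(M, tib_center)
  femur_posed <- apply_pose(femur, fem_res$best_pose, center = fem_res$center)
  penalty <- function(pose) {
    tibia_posed <- apply_pose(tibia, pose, center = tib_center)
    tibia_penalty(femur_posed, tibia_posed, weight = penalty_weight,
                  gap_threshold = gap_threshold)
  }
  dots <- list(...)
  dots$init_pose <- NULL
  tib_res <- do.call(register_bone, c(
    list(surface = tibia, edges = tibia_edges, scene = scene,
         init_pose = tibia_init, seed = seed + 100, extra_cost = penalty),
    dots))
  list(femur = fem_res, tibia = tib_res, tibia_init = tibia_init)
}
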