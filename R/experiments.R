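#' Registration recovery experiment on a self-rendered phantom radiograph
#'
#' Renders the phantom femur's edge image at a known ground-truth pose,
#' perturbs the initial pose by uniform +/- `perturb_mm` / `perturb_deg` on
#' every component, runs best-of-`n_runs` CMA-ES registration, and reports
#' the in-plane translation error (detector u/v components) and the
#' rotation error about the beam axis of the best run, averaged over
#' `n_reps` seeded repetitions.
#'
#' @param n_reps number of seeded repetitions.
#' @param seed base seed.
#' @param spec a [phantom_spec()].
#' @param scene a [build_scene()] scene.
#' @param n_runs,popsize,max_evals CMA-ES settings per repetition.
#' @param perturb_mm,perturb_deg initialization perturbation half-widths.
#' @return List with `mean_inplane_mm`, `mean_rotation_deg`,
#'   `mean_outofplane_mm` (recorded, not bounded) and the per-repetition
#'   table `reps`.
#' @export
registration_recovery <- function(n_reps = 10, seed = 1,
                                  spec = phantom_spec(),
                                  scene = build_scene(),
                                  n_runs = 3, popsize = 70,
                                  max_evals = 8000,
                                  perturb_mm = 5, perturb_deg = 5) {
  ph <- generate_knee_phantom(spec)
  femur <- place_in_scene(ph$femur, scene)$surfaces
  edges <- synthesize_radiograph_edges(femur, scene)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  rows <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    set.seed(seed + 1000 * rep)
    init <- pose_from_vector(c(runif(3, -perturb_mm, perturb_mm),
                               runif(3, -perturb_deg, perturb_deg)))
    res <- register_bone(femur, edges, scene, init_pose = init,
                         n_runs = n_runs, seed = seed + 1000 * rep,
                         popsize = popsize, max_evals = max_evals)
    err <- pose_to_vector(res$best_pose)  # ground truth is the zero pose
    rows[[rep]] <- data.frame(
      rep = rep,
      inplane_mm = sqrt(err[1]^2 + err[2]^2),
      outofplane_mm = abs(err[3]),
      rotation_deg = abs(err[6]),
      best_cost = res$best_cost,
      evaluations = sum(vapply(res$per_run, `[[`, numeric(1), "evaluations")))
  }
  reps <- do.call(rbind, rows)
  list(mean_inplane_mm = mean(reps$inplane_mm),
       mean_rotation_deg = mean(reps$rotation_deg),
       mean_outofplane_mm = mean(reps$outofplane_mm),
       reps = reps)
}

#' Peak-stress sensitivity to the combined cartilage thickness
#'
#' Solves the conforming phantom to 1000 N vertical equilibrium at each
#' thickness and reports the maximum relative change in peak contact stress
#' against the reference thickness.
#'
#' @param thicknesses thicknesses to compare, mm.
#' @param reference reference thickness, mm.
#' @param spec a [phantom_spec()]; default the conforming phantom.
#' @param E,nu,load material and load settings.
#' @return List with `peaks` (named MPa vector), `max_rel_change_pct`,
#'   and `n_facets`.
#' @export
thickness_sensitivity <- function(thicknesses = c(4, 8), reference = 6,
                                  spec = conforming_phantom_spec(),
                                  E = 12, nu = 0.42, load = 1000) {
  ph <- generate_knee_phantom(spec)
  all_t <- c(reference, thicknesses)
  peaks <- vapply(all_t, function(t) {
    field <- solve_equilibrium(ph$femur, ph$tibia,
                               dea_params(E = E, nu = nu, t = t, load = load))
    max(field$stress)
  }, numeric(1))
  names(peaks) <- paste0("t", all_t)
  ref_peak <- peaks[1]
  rel <- abs(peaks[-1] - ref_peak) / ref_peak * 100
  list(peaks = peaks, max_rel_change_pct = max(rel),
       n_facets = nrow(ph$tibia$faces))
}

#' Winkler sphere-on-plane analytic benchmark
#'
#' A rigid sphere pressed into a flat compressive spring bed has the closed
#' form peak pressure `p0 = sqrt(k P / (pi R))` with foundation modulus
#' `k = E (1 - nu) / (t (1 + nu)(1 - 2 nu))`. The DEA peak stress is
#' compared against this at the given mesh refinement.
#'
#' @param radius sphere radius, mm.
#' @param sphere_subdivisions icosphere level.
#' @param plate_spacing plate facet pitch, mm.
#' @param params a [dea_params()].
#' @return List with `peak_dea`, `p0_analytic` (MPa), `rel_error_pct`,
#'   `contact_radius_mm` and mesh sizes.
#' @export
winkler_benchmark <- function(radius = 40, sphere_subdivisions = 4,
                              plate_spacing = 0.75,
                              params = dea_params()) {
  k <- confined_modulus(params) / params$t
  p0 <- sqrt(k * params$load / (pi * radius))
  delta <- p0 / k
  a_contact <- sqrt(2 * radius * delta)
  half <- ceiling(a_contact * 1.8)
  sphere <- icosphere(radius, c(0, 0, radius + params$t),
                      subdivisions = sphere_subdivisions)
  xs <- seq(-half, half, by = plate_spacing)
  plate <- heightfield_solid(xs, xs, function(x, y) rep(0, length(x)),
                             z_bottom = -10, label = "plate")
  field <- solve_equilibrium(sphere, plate, params)
  peak <- max(field$stress)
  list(peak_dea = peak, p0_analytic = p0,
       rel_error_pct = abs(peak - p0) / p0 * 100,
       contact_radius_mm = a_contact,
       n_sphere_facets = nrow(sphere$faces),
       n_plate_facets = nrow(plate$faces))
}

#' End-to-end phantom pipeline in a temporary directory
#'
#' Generates a phantom knee, writes surfaces and ground-truth edge images to
#' disk, builds a batch config and runs [run_pipeline()] — the full chain
#' phantom -> render -> register -> DEA -> metrics under one seed.
#'
#' @param dir working directory (created if needed).
#' @param seed integer seed.
#' @param spec a [phantom_spec()].
#' @param scene a [build_scene()] scene.
#' @param n_knees number of phantom knees in the batch.
#' @param ... registration settings forwarded in the config (e.g. `popsize`,
#'   `max_evals`, `n_runs`).
#' @return The [run_pipeline()] result.
#' @export
phantom_pipeline <- function(dir = tempfile("kneedea"), seed = 1,
                             spec = phantom_spec(refinement = 2),
                             scene = build_scene(), n_knees = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_knee_phantom(spec)
  placed <- place_in_scene(list(femur = ph$femur, tibia = ph$tibia), scene)
  edges <- synthesize_radiograph_edges(placed$surfaces, scene)
  knees <- lapply(seq_len(n_knees), function(i) {
    fstem <- file.path(dir, paste0("knee", i))
    save_surface(ph$femur, paste0(fstem, "_femur.stl"))
    save_surface(ph$tibia, paste0(fstem, "_tibia.stl"))
    write_edge_image(edges$femur, paste0(fstem, "_femur_edges.png"))
    write_edge_image(edges$tibia, paste0(fstem, "_tibia_edges.png"))
    list(id = paste0("knee", i),
         femur = paste0(fstem, "_femur.stl"),
         tibia = paste0(fstem, "_tibia.stl"),
         femur_edges = paste0(fstem, "_femur_edges.png"),
         tibia_edges = paste0(fstem, "_tibia_edges.png"))
  })
  config <- list(seed = seed,
                 scene = list(caudal_angle = scene$caudal_angle,
                              pixel_spacing = scene$pixel_spacing,
                              image_size = scene$image_size),
                 registration = list(...),
                 knees = knees)
  run_pipeline(config, out_dir = file.path(dir, "out"))
}
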