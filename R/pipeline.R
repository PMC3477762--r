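#' Default quality-control thresholds
#'
#' Registration cost above 1 mm, inter-run in-plane pose spread above
#' 1 mm / 1 degree, equilibrium nonconvergence, an empty compartment, or a
#' peak stress outside (0.5, 30) MPa all raise flags for analyst review.
#' @export
default_qc_thresholds <- function() {
  list(max_cost = 1.0, max_pose_spread_mm = 1.0, max_pose_spread_deg = 1.0,
       stress_band = c(0.5, 30))
}

#' Quality-control flags for one processed knee
#'
#' @param result a per-knee result bundle from [run_pipeline()] (fields
#'   `femur_reg`, `tibia_reg`, `field`, `metrics`; missing pieces are
#'   tolerated).
#' @param thresholds see [default_qc_thresholds()].
#' @return Character vector of flags (empty when the run is clean).
#' @export
qc_flags <- function(result, thresholds = default_qc_thresholds()) {
  flags <- character(0)
  for (bone in c("femur_reg", "tibia_reg")) {
    reg <- result[[bone]]
    if (is.null(reg)) next
    nm <- sub("_reg", "", bone)
    if (reg$best_cost > thresholds$max_cost)
      flags <- c(flags, sprintf("%s registration cost %.3g mm above %.3g mm",
                                nm, reg$best_cost, thresholds$max_cost))
    poses <- t(vapply(reg$per_run, function(r) pose_to_vector(r$pose),
                      numeric(6)))
    spread_mm <- max(apply(poses[, 1:2, drop = FALSE], 2,
                           function(v) diff(range(v))))
    spread_deg <- max(apply(poses[, 4:6, drop = FALSE], 2,
                            function(v) diff(range(v))))
    if (spread_mm > thresholds$max_pose_spread_mm ||
        spread_deg > thresholds$max_pose_spread_deg)
      flags <- c(flags,
                 sprintf("%s inter-run pose spread %.3g mm / %.3g deg", nm,
                         spread_mm, spread_deg))
  }
  if (!is.null(result$field) && !isTRUE(result$field$converged))
    flags <- c(flags, "equilibrium not converged")
  if (is.null(result$field) && !is.null(result$error))
    flags <- c(flags, paste("equilibrium failed:", result$error))
  if (!is.null(result$metrics)) {
    m <- result$metrics
    if (m$peak_medial == 0) flags <- c(flags, "no medial contact")
    if (m$peak_lateral == 0) flags <- c(flags, "no lateral contact")
    pk <- max(m$peak_medial, m$peak_lateral)
    band <- thresholds$stress_band
    if (pk > 0 && (pk < band[1] || pk > band[2]))
      flags <- c(flags, sprintf("peak stress %.3g MPa outside (%g, %g) MPa",
                                pk, band[1], band[2]))
  }
  flags
}

#' Batch pipeline: register, solve DEA and summarise a list of knees
#'
#' The configuration (YAML path or equivalent list) names per-knee surface
#' files and edge images plus scene, registration and DEA settings.
#' Knees are processed independently: a failure is logged on that knee and
#' does not abort the batch. With `ratings` present (a long CSV as in
#' [reliability_report()]) a reliability table is appended. Deterministic
#' given the seeds in the config.
#'
#' @param config YAML file path or a list with elements `knees` (list of
#'   `id`, `femur`, `tibia`, `femur_edges`, `tibia_edges`), optional
#'   `scene`, `dea`, `registration`, `seed`, `ratings`.
#' @param out_dir optional output directory for CSV/JSON results.
#' @return List with `metrics` (one row per knee), `results` (per-knee
#'   bundles incl. `qc`), `reliability` (or `NULL`), `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  } else {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  if (is.null(config$knees)) stop("config$knees is required (schema: knees[].{id,femur,tibia,femur_edges,tibia_edges})")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  scene <- do.call(build_scene, if (is.null(config$scene)) list() else config$scene)
  params <- do.call(dea_params, if (is.null(config$dea)) list() else config$dea)
  reg_cfg <- if (is.null(config$registration)) list() else config$registration

  results <- list()
  rows <- list()
  for (i in seq_along(config$knees)) {
    kn <- config$knees[[i]]
    if (is.null(kn$id)) stop("config$knees[[", i, "]]$id is required")
    res <- tryCatch({
      femur <- load_surface(kn$femur, label = "femur")
      tibia <- load_surface(kn$tibia, label = "tibia")
      placed <- place_in_scene(list(femur = femur, tibia = tibia), scene)
      fe <- read_edge_image(kn$femur_edges)
      te <- read_edge_image(kn$tibia_edges)
      reg <- do.call(register_knee, c(
        list(femur = placed$surfaces$femur, tibia = placed$surfaces$tibia,
             femur_edges = fe, tibia_edges = te, scene = scene,
             seed = seed + 17 * (i - 1)),
        reg_cfg))
      fem_posed <- apply_pose(placed$surfaces$femur, reg$femur$best_pose,
                              center = reg$femur$center)
      tib_posed <- apply_pose(placed$surfaces$tibia, reg$tibia$best_pose,
                              center = reg$tibia$center)
      field <- solve_equilibrium(fem_posed, tib_posed, params,
                                 load_axis = scene$axis_v)
      metrics <- compartment_metrics(field, ml_axis = scene$axis_u)
      list(id = kn$id, femur_reg = reg$femur, tibia_reg = reg$tibia,
           field = field, metrics = metrics)
    }, error = function(e) list(id = kn$id, error = conditionMessage(e)))
    res$qc <- qc_flags(res)
    results[[kn$id]] <- res
    rows[[kn$id]] <- if (is.null(res$error)) {
      data.frame(id = kn$id,
                 peak_medial = res$metrics$peak_medial,
                 mean_medial = res$metrics$mean_medial,
                 peak_lateral = res$metrics$peak_lateral,
                 mean_lateral = res$metrics$mean_lateral,
                 n_flags = length(res$qc), failed = FALSE)
    } else {
      data.frame(id = kn$id, peak_medial = NA_real_, mean_medial = NA_real_,
                 peak_lateral = NA_real_, mean_lateral = NA_real_,
                 n_flags = length(res$qc), failed = TRUE)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  reliability <- NULL
  if (!is.null(config$ratings)) {
    ratings <- read.csv(config$ratings)
    reliability <- reliability_report(ratings)
  }
  provenance <- list(config_hash = cfg_hash, seed = seed,
                     n_knees = length(config$knees))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(provenance = provenance, metrics = metrics,
           qc = lapply(results, `[[`, "qc"),
           reliability = if (is.null(reliability)) NULL else reliability$table),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, results = results, reliability = reliability,
       provenance = provenance)
}
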