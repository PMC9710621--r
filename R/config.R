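# Declarative run configuration (YAML) + command entry points. A single
# document describes the simulation, the render stack, optional fluorescence
# and dataset sections, the emitters to run and the output directory; CLI
# dotted-key overrides (e.g. render.calibration=0.09) take precedence.

default_run_config <- function() {
  list(
    simulation = list(seed = 1L, dt = 1 / 60, duration = 8, n_founders = 1L,
                      emit_every = 30L, shape_kind = "rod", width = 0.9,
                      bend = 0, founder_length = NULL, angle_sd = 0.05,
                      split_sd = 0, fluorescence = 0, verbose = FALSE),
    model = list(kind = "sizer", trigger_mean = 3.6, trigger_cv = 0.1,
                 rate_mean = log(2), rate_cv = 0.1),
    placement = list(overlap_tolerance = 0.01, max_iterations = 1000L,
                     damping = 0.7, rot_strength = 0.3, boundary = NULL),
    render = list(image_size = c(512L, 512L), calibration = 0.09,
                  background_level = 0.7, cell_level = 0.25,
                  halo_sigmas = c(1, 6), halo_weights = c(1, 0.4),
                  illumination_amplitude = 0.05, illumination_scale = 128,
                  illumination_type = "polynomial",
                  noise_additive_sigma = 0.01,
                  noise_multiplicative_sigma = 0.02,
                  output_depth = 16L, n_vertices = 32L),
    fluorescence = list(enabled = FALSE, psf_sigma = 2,
                        background_level = 0.05, shot_noise = FALSE,
                        photons_per_unit = 1e4),
    dataset = list(n_images = 128L, image_size = 512L, calibration = 0.09,
                   cell_count_range = c(0L, 512L), seed = 1L,
                   emitters = c("yolo", "coco", "masks")),
    outputs = c("frames", "masks"),
    output_dir = "colonysim_output"
  )
}

# overlay user values onto defaults, rejecting unknown keys and collecting
# all schema violations before failing
merge_config <- function(defaults, user, prefix = "") {
  errors <- character(0)
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults)) {
      errors <- c(errors, sprintf("unknown key '%s'", full))
      next
    }
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      sub <- merge_config(dv, as.list(uv), full)
      defaults[[key]] <- sub$config
      errors <- c(errors, sub$errors)
    } else {
      defaults[[key]] <- uv
    }
  }
  list(config = defaults, errors = errors)
}

validate_run_config <- function(cfg) {
  errors <- character(0)
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(cfg$simulation$dt > 0, "simulation.dt must be > 0")
  chk(cfg$simulation$duration >= 0, "simulation.duration must be >= 0")
  chk(cfg$simulation$n_founders >= 1, "simulation.n_founders must be >= 1")
  chk(cfg$model$kind %in% c("timer", "sizer"),
      "model.kind must be 'timer' or 'sizer'")
  chk(cfg$model$trigger_mean > 0, "model.trigger_mean must be > 0")
  chk(cfg$model$rate_mean > 0, "model.rate_mean must be > 0")
  chk(cfg$model$trigger_cv >= 0 && cfg$model$rate_cv >= 0,
      "model cv values must be >= 0")
  chk(cfg$render$calibration > 0, "render.calibration must be > 0")
  chk(all(cfg$render$image_size >= 1), "render.image_size must be positive")
  chk(cfg$render$halo_sigmas[2] > cfg$render$halo_sigmas[1],
      "render.halo_sigmas must be increasing")
  chk(cfg$render$noise_additive_sigma >= 0 &&
        cfg$render$noise_multiplicative_sigma >= 0,
      "render noise sigmas must be >= 0")
  chk(cfg$placement$overlap_tolerance >= 0,
      "placement.overlap_tolerance must be >= 0")
  chk(cfg$dataset$n_images >= 1, "dataset.n_images must be >= 1")
  chk(cfg$dataset$cell_count_range[2] >= cfg$dataset$cell_count_range[1],
      "dataset.cell_count_range must be (min, max) with max >= min")
  bad <- setdiff(cfg$outputs,
                 c("frames", "masks", "yolo", "coco", "trackmate", "mesh"))
  chk(length(bad) == 0,
      paste0("unknown emitter(s): ", paste(bad, collapse = ", ")))
  errors
}

#' Load a run configuration
#'
#' Reads a YAML configuration, overlays it onto the documented defaults,
#' applies dotted-key overrides and validates the result. Unknown keys and
#' all schema violations are reported together.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides named list or character vector of `key=value` strings
#'   with dotted keys (e.g. `"render.calibration=0.09"`).
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  res <- merge_config(default_run_config(), user)
  cfg <- res$config
  errors <- res$errors
  if (!is.null(overrides)) {
    if (is.character(overrides)) {
      kv <- strsplit(overrides, "=", fixed = TRUE)
      overrides <- stats::setNames(
        lapply(kv, function(p) yaml::yaml.load(paste(p[-1L], collapse = "="))),
        vapply(kv, `[[`, character(1), 1L))
    }
    for (key in names(overrides)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      node <- cfg
      ok <- TRUE
      for (p in parts[-length(parts)]) {
        if (!p %in% names(node)) { ok <- FALSE; break }
        node <- node[[p]]
      }
      if (!ok || !parts[length(parts)] %in% names(node)) {
        errors <- c(errors, sprintf("unknown key '%s'", key))
        next
      }
      cfg[[parts]] <- overrides[[key]]
    }
  }
  if (length(errors) == 0L) errors <- validate_run_config(cfg)
  else errors <- c(errors, validate_run_config(cfg))
  errors <- unique(errors)
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

# materialize typed config objects from the plain run_config tree
build_objects <- function(cfg) {
  model <- homeostasis_model(kind = cfg$model$kind,
                             trigger_mean = cfg$model$trigger_mean,
                             trigger_cv = cfg$model$trigger_cv,
                             rate_mean = cfg$model$rate_mean,
                             rate_cv = cfg$model$rate_cv)
  pl <- placement_config(overlap_tolerance = cfg$placement$overlap_tolerance,
                         max_iterations = cfg$placement$max_iterations,
                         damping = cfg$placement$damping,
                         rot_strength = cfg$placement$rot_strength,
                         boundary = cfg$placement$boundary)
  sim <- simulation_config(seed = cfg$simulation$seed, dt = cfg$simulation$dt,
                           duration = cfg$simulation$duration,
                           n_founders = cfg$simulation$n_founders,
                           model = model, placement = pl,
                           emit_every = cfg$simulation$emit_every,
                           shape_kind = cfg$simulation$shape_kind,
                           width = cfg$simulation$width,
                           bend = cfg$simulation$bend,
                           founder_length = cfg$simulation$founder_length,
                           angle_sd = cfg$simulation$angle_sd,
                           split_sd = cfg$simulation$split_sd,
                           fluorescence = cfg$simulation$fluorescence,
                           verbose = cfg$simulation$verbose)
  rc <- render_config(image_size = cfg$render$image_size,
                      calibration = cfg$render$calibration,
                      background_level = cfg$render$background_level,
                      cell_level = cfg$render$cell_level,
                      halo_sigmas = cfg$render$halo_sigmas,
                      halo_weights = cfg$render$halo_weights,
                      illumination_amplitude = cfg$render$illumination_amplitude,
                      illumination_scale = cfg$render$illumination_scale,
                      illumination_type = cfg$render$illumination_type,
                      noise_additive_sigma = cfg$render$noise_additive_sigma,
                      noise_multiplicative_sigma = cfg$render$noise_multiplicative_sigma,
                      output_depth = cfg$render$output_depth,
                      n_vertices = cfg$render$n_vertices)
  fl <- fluorescence_config(psf_sigma = cfg$fluorescence$psf_sigma,
                            background_level = cfg$fluorescence$background_level,
                            shot_noise = cfg$fluorescence$shot_noise,
                            photons_per_unit = cfg$fluorescence$photons_per_unit)
  ds <- dataset_spec(n_images = cfg$dataset$n_images,
                     image_size = cfg$dataset$image_size,
                     calibration = cfg$dataset$calibration,
                     cell_count_range = cfg$dataset$cell_count_range,
                     seed = cfg$dataset$seed,
                     emitters = cfg$dataset$emitters)
  list(model = model, placement = pl, simulation = sim, render = rc,
       fluorescence = fl, dataset = ds)
}

#' Run a configured time-lapse simulation
#'
#' Runs [run_simulation()] under a full `run_config`, writing the configured
#' emitters per emitted frame (phase-contrast frames, label masks, YOLO
#' labels) plus the whole-run outputs (COCO JSON, TrackMate XML, STL meshes
#' of the final colony) and a manifest embedding the fully resolved
#' configuration for bit-identical re-runs.
#'
#' @param cfg a `run_config` from [load_config()].
#' @return The output directory, invisibly.
#' @export
run_config_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  obj <- build_objects(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  trajectory <- run_simulation(obj$simulation)
  annotations <- list()
  image_files <- character(0)
  for (f in seq_along(trajectory)) {
    world <- trajectory[[f]]
    idx <- f - 1L
    ann <- annotate(world, obj$render, frame_index = idx)
    annotations[[f]] <- ann
    fname <- sprintf("frame_%06d.tif", idx)
    image_files[f] <- fname
    if ("frames" %in% cfg$outputs) {
      img <- render_phase_contrast(world, obj$render,
                                   seed = derive_seed(obj$simulation$seed,
                                                      1000L + idx))
      write_frame(img, file.path(cfg$output_dir, fname))
      if (isTRUE(cfg$fluorescence$enabled)) {
        fli <- render_fluorescence(world, obj$fluorescence, obj$render,
                                   seed = derive_seed(obj$simulation$seed,
                                                      2000L + idx))
        write_frame(pmin(pmax(fli, 0), 1),
                    file.path(cfg$output_dir,
                              sprintf("fluor_%06d.tif", idx)))
      }
    }
    if ("masks" %in% cfg$outputs)
      write_masks(ann, file.path(cfg$output_dir, sprintf("mask_%06d.tif", idx)))
    if ("yolo" %in% cfg$outputs)
      write_yolo(ann, file.path(cfg$output_dir, sprintf("frame_%06d.txt", idx)))
  }
  if ("coco" %in% cfg$outputs)
    write_coco(annotations, image_files,
               file.path(cfg$output_dir, "annotations.json"))
  if ("trackmate" %in% cfg$outputs)
    write_trackmate(trajectory, file.path(cfg$output_dir, "tracks.xml"))
  if ("mesh" %in% cfg$outputs) {
    mdir <- file.path(cfg$output_dir, "meshes")
    dir.create(mdir, showWarnings = FALSE)
    final <- trajectory[[length(trajectory)]]$agents
    for (i in seq_len(nrow(final)))
      export_mesh(final[i, ], file.path(mdir, sprintf("cell_%06d.stl",
                                                      final$id[i])))
  }
  jsonlite::write_json(list(config = unclass(cfg),
                            n_frames = length(trajectory),
                            final_cell_count =
                              nrow(trajectory[[length(trajectory)]]$agents)),
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(cfg$output_dir)
}

#' Simulate subcommand
#'
#' Loads the configuration, applies overrides and runs
#' [run_config_simulation()]; returns a process exit code (0 on success).
#'
#' @param config_path YAML config path or `NULL` for defaults.
#' @param overrides character vector of dotted `key=value` overrides.
#' @return Integer exit code, invisibly.
#' @export
cmd_simulate <- function(config_path = NULL, overrides = NULL) {
  code <- tryCatch({
    cfg <- load_config(config_path, overrides)
    run_config_simulation(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

#' Dataset subcommand
#'
#' Loads the configuration and delegates to
#' [generate_ground_truth_dataset()] with the configured dataset section.
#'
#' @inheritParams cmd_simulate
#' @return Integer exit code, invisibly.
#' @export
cmd_dataset <- function(config_path = NULL, overrides = NULL) {
  code <- tryCatch({
    cfg <- load_config(config_path, overrides)
    obj <- build_objects(cfg)
    sim <- obj$simulation
    generate_ground_truth_dataset(obj$dataset, model = obj$model,
                                  render = obj$render,
                                  dir = cfg$output_dir, sim_config = sim)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
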