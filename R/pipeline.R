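# Run configuration and the end-to-end pipeline: input stack (holograms
# or phase maps) -> per-frame metrics per condition -> rate constants,
# written as tidy CSVs with unit-bearing column names.

config_blocks <- list(
  optics = c("wavelength_nm", "n_medium", "alpha_m3_per_kg", "pixel_pitch_um"),
  segmentation = c("threshold", "smooth_sigma_px", "close_disc_px",
                   "min_object_um2", "min_hole_um2"),
  geometry = c("axis", "gap_start_um", "gap_end_um"),
  holography = c("carrier", "window_radius"),
  top = c("optics", "segmentation", "geometry", "holography", "conditions",
          "input", "input_type", "output_dir", "frame_interval_min", "seed"),
  condition = c("name", "region", "n_cell", "dm_single_pg")
)

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0) {
    stop_units("unknown configuration key", if (length(unknown) > 1) "s",
               " in ", where, ": ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Validate a pipeline run configuration
#'
#' Accepts a nested list (or a YAML file path) describing one analysis
#' run: the optical configuration, segmentation settings, the wound
#' geometry, the per-condition refractive indices, optional holography
#' settings, the input stack and output directory. Unknown keys anywhere
#' are rejected by name.
#'
#' @param config nested list, or path to a YAML file with the same
#'   structure.
#' @return The validated configuration (class `run_config`) with defaults
#'   filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  check_keys(config, config_blocks$top, "top level")
  check_keys(config$optics %||% list(), config_blocks$optics, "optics")
  check_keys(config$segmentation %||% list(), config_blocks$segmentation,
             "segmentation")
  check_keys(config$geometry %||% list(), config_blocks$geometry, "geometry")
  check_keys(config$holography %||% list(), config_blocks$holography,
             "holography")
  cfg <- do.call(optical_config, config$optics %||% list())
  if (is.null(config$geometry)) {
    stop_units("configuration block `geometry` is required")
  }
  geom <- wound_geometry(config$geometry$axis %||% "x",
                         config$geometry$gap_start_um,
                         config$geometry$gap_end_um)
  conds <- config$conditions %||% list(list(name = "all", region = "all",
                                            n_cell = cfg$n_medium + 0.03))
  for (i in seq_along(conds)) {
    check_keys(conds[[i]], config_blocks$condition,
               paste0("conditions[", i, "]"))
    if (is.null(conds[[i]]$n_cell)) {
      stop_units("conditions[", i, "] needs an n_cell value")
    }
    conds[[i]]$name <- conds[[i]]$name %||% paste0("condition", i)
    conds[[i]]$region <- match.arg(conds[[i]]$region %||% "all",
                                   c("all", "left", "right"))
  }
  structure(
    list(optics = cfg, geometry = geom, conditions = conds,
         segmentation = config$segmentation %||% list(),
         holography = config$holography %||% list(),
         input = config$input, input_type = config$input_type %||% "phase",
         output_dir = config$output_dir,
         frame_interval_min = config$frame_interval_min,
         seed = config$seed %||% 1L),
    class = "run_config"
  )
}

# Split the gap mask into the halves populated from each side.
condition_region <- function(region, geom, dims, pitch) {
  gap <- geometry_mask(geom, dims, pitch)
  if (region == "all" || !is.null(geom$polygon)) return(gap)
  mid <- (geom$gap_start_um + geom$gap_end_um) / 2
  g <- pixel_grid(dims, pitch)
  coord <- if (geom$axis == "x") g$x else g$y
  if (region == "left") gap & coord < mid else gap & coord >= mid
}

#' Run the full wound-assay analysis pipeline
#'
#' Reads the input stack (reconstructing, unwrapping and
#' background-correcting first when it contains holograms), segments each
#' frame, computes per-frame metrics inside the wound gap for every
#' configured condition, regresses the per-minute rate constants, and
#' writes `metrics.csv`, `rates.csv` and `run.log` to the output
#' directory. Deterministic for a given configuration and seed.
#'
#' @param config a [run_config()] (or anything it accepts). Alternatively
#'   pass `frames` to skip reading from disk.
#' @param frames optional list of [phase_image()] frames overriding
#'   `config$input`.
#' @return Invisibly, a list with `metrics`, `rates` (data frames) and
#'   `paths` of the files written (when `output_dir` is set).
#' @export
run_pipeline <- function(config, frames = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  cfg <- config$optics
  log_lines <- c(sprintf("run_pipeline seed=%d input_type=%s",
                         config$seed, config$input_type),
                 sprintf("optics: lambda=%g nm n_medium=%g alpha=%g m3/kg pitch=%g um",
                         cfg$wavelength_nm, cfg$n_medium, cfg$alpha_m3_per_kg,
                         cfg$pixel_pitch_um))
  if (is.null(frames)) {
    if (is.null(config$input)) stop_units("no input stack configured")
    frames <- if (identical(config$input_type, "holograms")) {
      holos <- read_hologram_stack(config$input)
      lapply(seq_along(holos), function(k) {
        rec <- tryCatch(
          reconstruct_phase(holos[[k]],
                            carrier_hint = config$holography$carrier,
                            window_radius = config$holography$window_radius),
          error = function(e) stop_units("stage reconstruct failed at frame ",
                                         k, ": ", conditionMessage(e)))
        u <- unwrap_phase(rec)
        cellfree <- !segment_cells(u)
        out <- if (sum(cellfree) >= 3) background_correct(u, cellfree, 1) else u
        out$time_min <- if (!is.null(config$frame_interval_min)) {
          (k - 1) * config$frame_interval_min
        } else {
          k - 1
        }
        out
      })
    } else {
      read_phase_stack(config$input, interval_min = config$frame_interval_min)
    }
  }
  dims <- dim(frames[[1]]$values)
  seg_args <- config$segmentation
  seg <- lapply(seq_along(frames), function(k) {
    tryCatch(
      do.call(segment_cells, c(list(frames[[k]]), seg_args)),
      error = function(e) stop_units("stage segmentation failed at frame ",
                                     k, ": ", conditionMessage(e)))
  })
  log_lines <- c(log_lines,
                 sprintf("segmentation: %s",
                         if (length(seg_args) == 0) "defaults (auto threshold)"
                         else paste(names(seg_args), unlist(seg_args),
                                    sep = "=", collapse = " ")),
                 sprintf("frames: %d of %dx%d px", length(frames),
                         dims[1], dims[2]))
  metrics <- list()
  rates <- list()
  for (cond in config$conditions) {
    region <- condition_region(cond$region, config$geometry, dims,
                               cfg$pixel_pitch_um)
    rows <- lapply(seq_along(frames), function(k) {
      compute_frame_metrics(frames[[k]], seg[[k]] & region, cond$n_cell,
                            cfg, dm_single_pg = cond$dm_single_pg)
    })
    series <- relative_series(do.call(rbind, rows))
    if (is.null(series$n_cells_est)) series$n_cells_est <- NA_real_
    series <- cbind(condition = cond$name, series)
    r <- estimate_rates(series[, -1])
    r <- cbind(condition = cond$name, as.data.frame(r))
    metrics[[cond$name]] <- series
    rates[[cond$name]] <- r
    log_lines <- c(log_lines,
                   sprintf("condition %s: region=%s n_cell=%g%s",
                           cond$name, cond$region, cond$n_cell,
                           if (is.null(cond$dm_single_pg)) "" else
                             sprintf(" dm_single=%g pg", cond$dm_single_pg)))
  }
  metrics <- do.call(rbind, c(metrics, make.row.names = FALSE))
  rates <- do.call(rbind, c(rates, make.row.names = FALSE))
  paths <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(config$output_dir,
                       c("metrics.csv", "rates.csv", "run.log"))
    utils::write.csv(metrics, paths[1], row.names = FALSE)
    utils::write.csv(rates, paths[2], row.names = FALSE)
    writeLines(log_lines, paths[3])
  }
  message(paste(log_lines, collapse = "\n"))
  invisible(list(metrics = metrics, rates = rates, paths = paths))
}
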