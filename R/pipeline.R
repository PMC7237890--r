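## End-to-end scenario orchestration: simulate -> (render -> detect/link) ->
## metrics / direction / flow / density, with a manifest recording every
## stage, its outputs and the full configuration so a run is self-describing
## and reproducible from its seed.

#' Read a scenario configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml or .json.
#' @return the configuration list.
#' @export
read_scenario_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be YAML or JSON", call. = FALSE)
}

#' Default scenario configuration
#'
#' A ready-to-run scenario: one control-like geometry, one cohort per listed
#' preset, ground-truth metrics and directionality analyses on. The
#' \code{"entry_control"} name gives the strong-bias entry scenario (5 animals
#' x 60 track-guided cells at the default bias).
#'
#' @param name \code{"entry_control"} or \code{"minimal"}.
#' @param seed global seed.
#' @return a scenario configuration list for \code{\link{run_scenario}}.
#' @export
scenario_preset <- function(name = c("entry_control", "minimal"), seed = 1L) {
  name <- match.arg(name)
  if (name == "entry_control") {
    cohorts <- lapply(1:5, function(i)
      list(cohort = paste0("animal", i),
           n_cells = list(track_guided = 60),
           preset = "control", n_frames = 40, frame_interval = 20))
    list(geometry = list(n_tracks = 4), cohorts = cohorts,
         analyses = list(metrics = TRUE, direction = TRUE, flow = FALSE,
                         density = FALSE, detect = FALSE),
         seed = seed)
  } else {
    list(geometry = list(n_tracks = 2),
         cohorts = list(list(cohort = "animal1",
                             n_cells = list(track_guided = 10),
                             preset = "control", n_frames = 31,
                             frame_interval = 20)),
         analyses = list(metrics = TRUE, direction = TRUE, flow = FALSE,
                         density = FALSE, detect = FALSE),
         seed = seed)
  }
}

#' Run a full analysis scenario
#'
#' Executes the toggled stages in order (simulate, optionally render and
#' detect/link, then metrics, directionality, flow, density) and returns a
#' manifest. A stage failure is recorded and downstream stages are skipped.
#' Identical configuration and seed give identical outputs.
#'
#' @param config scenario configuration (see \code{\link{scenario_preset}}).
#' @param out_dir if non-NULL, summary CSVs and fixtures are written here.
#' @return list of class \code{perivax_manifest}: \code{config},
#'   \code{stages} (status per stage), \code{results}, \code{files}.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), length(config$cohorts) >= 1)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  analyses <- config$analyses
  tog <- function(x) isTRUE(analyses[[x]])
  stages <- list()
  results <- list()
  files <- character(0)
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) { stages[[name]] <<- "skipped"; return(NULL) }
    r <- tryCatch(fun(), error = function(e) e)
    if (inherits(r, "error")) {
      stages[[name]] <<- paste0("failed: ", conditionMessage(r))
      failed <<- TRUE
      NULL
    } else {
      stages[[name]] <<- "ok"
      r
    }
  }

  geometry <- run_stage("geometry", function() {
    do.call(build_geometry, c(config$geometry, list(seed = seed)))
  })

  tracks <- run_stage("simulate", function() {
    tabs <- lapply(seq_along(config$cohorts), function(i) {
      cc <- config$cohorts[[i]]
      cc$n_cells <- unlist(cc$n_cells)
      cc$seed <- seed + i
      simulate_cohort(geometry, do.call(cohort_config, cc))
    })
    do.call(rbind, tabs)
  })

  stacks <- NULL
  if (tog("detect") || tog("flow")) {
    stacks <- run_stage("render", function() {
      rp <- config$render
      lapply(split(tracks, tracks$cohort), function(tt)
        do.call(render_stack, c(list(tracks = tt, geometry = geometry,
                                     seed = seed), rp)))
    })
  } else stages$render <- "skipped"

  analysis_tracks <- tracks
  if (tog("detect")) {
    analysis_tracks <- run_stage("detect_link", function() {
      linked <- lapply(names(stacks), function(nm) {
        det <- detect_stack(stacks[[nm]])
        link_tracks(det, frame_interval = attr(stacks[[nm]], "frame_interval"),
                    cohort = nm)
      })
      do.call(rbind, linked)
    })
  } else stages$detect_link <- "skipped"

  if (tog("metrics")) {
    results$metrics <- run_stage("metrics", function() {
      rec <- track_metrics(analysis_tracks)
      list(records = rec, summary = cohort_summary(rec, "mean_velocity"))
    })
  } else stages$metrics <- "skipped"

  if (tog("direction")) {
    results$direction <- run_stage("direction", function() {
      cls <- classify_tracks(analysis_tracks, geometry)
      list(classes = cls, summary = fraction_toward(cls))
    })
  } else stages$direction <- "skipped"

  if (tog("flow")) {
    results$flow <- run_stage("flow", function() {
      lapply(names(stacks), function(nm) {
        st <- stacks[[nm]]
        grid <- partition_superpixels(dim(st)[1:2])
        traj <- advect_superpixels(st, grid)
        br <- lapply(geometry$vessel_masks, branch_axes,
                     t_zone_center = geometry$t_zone_center,
                     pixel_size = geometry$pixel_size)
        fraction_toward_tzone(traj, br, geometry$vessel_masks,
                              pixel_size = geometry$pixel_size)
      })
    })
  } else stages$flow <- "skipped"

  if (tog("density")) {
    results$density <- run_stage("density", function() {
      pos <- as.matrix(analysis_tracks[analysis_tracks$frame == 0,
                                       c("x_um", "y_um")])
      association_fraction(pos, geometry)
    })
  } else stages$density <- "skipped"

  if (!is.null(out_dir) && !failed) {
    run_stage("write", function() {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      f <- file.path(out_dir, "tracks.csv")
      write.csv(tracks, f, row.names = FALSE); files <<- c(files, f)
      if (!is.null(results$metrics)) {
        f <- file.path(out_dir, "track_metrics.csv")
        write.csv(results$metrics$records, f, row.names = FALSE)
        files <<- c(files, f)
      }
      if (!is.null(results$direction)) {
        f <- file.path(out_dir, "direction.csv")
        write.csv(results$direction$classes, f, row.names = FALSE)
        files <<- c(files, f)
      }
      invisible(TRUE)
    })
  }

  structure(list(config = config, seed = seed, stages = stages,
                 results = results, files = files,
                 geometry = geometry, tracks = tracks),
            class = "perivax_manifest")
}

#' @export
print.perivax_manifest <- function(x, ...) {
  cat("perivax run manifest (seed", x$seed, ")\n")
  for (nm in names(x$stages)) cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]))
  invisible(x)
}

#' Compare a metric between two scenario runs
#'
#' @param manifest_a,manifest_b manifests from \code{\link{run_scenario}}
#'   with the metrics stage enabled.
#' @param metric per-track metric column to compare (default mean velocity).
#' @return list with per-manifest means, \code{difference}, \code{ratio}
#'   (b / a) and \code{percent_change} = 100 * (1 - ratio).
#' @export
compare_scenarios <- function(manifest_a, manifest_b,
                              metric = "mean_velocity") {
  get_mean <- function(m) {
    if (is.null(m$results$metrics))
      stop("manifest lacks the metrics stage", call. = FALSE)
    rec <- m$results$metrics$records
    if (!metric %in% names(rec))
      stop("metric '", metric, "' not present", call. = FALSE)
    cohort_summary(rec, metric)$overall$mean
  }
  a <- get_mean(manifest_a); b <- get_mean(manifest_b)
  list(mean_a = a, mean_b = b, difference = b - a, ratio = b / a,
       percent_change = 100 * (1 - b / a))
}
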