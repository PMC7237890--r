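## Renders ground-truth tracks into a calibrated grayscale time-lapse stack:
## each cell is an isotropic Gaussian blob over a uniform background with
## additive Gaussian read noise, mimicking a single projected two-photon
## channel. Intensities are normalized fluorescence in [0, 1].

#' Construct an image stack object
#'
#' @param data H x W x T numeric array (row = y, column = x).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param channel channel label.
#' @return object of class \code{perivax_image_stack}.
#' @export
image_stack <- function(data, pixel_size, frame_interval, channel = "gfp") {
  stopifnot(length(dim(data)) == 3, pixel_size > 0, frame_interval > 0,
            all(is.finite(data)), all(data >= 0))
  structure(data, pixel_size = pixel_size, frame_interval = frame_interval,
            channel = channel, class = "perivax_image_stack")
}

#' @export
print.perivax_image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("perivax image stack: %d x %d px, %d frames, %g um/px, %g s/frame, channel '%s'\n",
              d[1], d[2], d[3], attr(x, "pixel_size"),
              attr(x, "frame_interval"), attr(x, "channel")))
  invisible(x)
}

#' Number of frames of an image stack
#' @param stack a \code{perivax_image_stack}.
#' @export
n_frames <- function(stack) dim(stack)[3]

#' Extract one frame of an image stack as a plain matrix
#' @param stack a \code{perivax_image_stack}.
#' @param t frame index (1-based).
#' @export
get_frame <- function(stack, t) {
  unclass(stack)[, , t]
}

#' Render a track table into a synthetic time-lapse stack
#'
#' @param tracks track table as returned by \code{\link{simulate_cohort}}.
#' @param geometry the matching \code{perivax_geometry}.
#' @param blob_sigma_px Gaussian blob sd in pixels (cell radius ~ 2 sd).
#' @param peak_intensity blob peak amplitude (normalized units).
#' @param background uniform background level.
#' @param noise_sd sd of additive Gaussian read noise; clipped at 0.
#' @param pixel_size um/px of the rendered stack (defaults to the geometry's).
#' @param seed integer seed for the noise; identical seeds give identical
#'   stacks.
#' @param frames frame indices to render; defaults to the frames present in
#'   \code{tracks} (must be given for an empty table).
#' @return a \code{perivax_image_stack}.
#' @export
render_stack <- function(tracks, geometry,
                         blob_sigma_px = 2,
                         peak_intensity = 0.6,
                         background = 0.05,
                         noise_sd = 0.02,
                         pixel_size = geometry$pixel_size,
                         seed = 1L,
                         frames = NULL) {
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (any(tracks$x_um < 0 | tracks$x_um > geometry$field_size[1] |
          tracks$y_um < 0 | tracks$y_um > geometry$field_size[2]))
    stop("track positions outside the field cannot be rendered", call. = FALSE)
  frame_interval <- if (nrow(tracks) >= 2) {
    dt <- diff(sort(unique(tracks$t_s)))
    if (length(dt)) dt[1] else 20
  } else 20

  w_px <- ceiling(geometry$field_size[1] / pixel_size)
  h_px <- ceiling(geometry$field_size[2] / pixel_size)
  if (is.null(frames)) frames <- sort(unique(tracks$frame))
  nf <- length(frames)
  if (nf == 0) stop("no frames to render; supply `frames`", call. = FALSE)
  arr <- array(background, dim = c(h_px, w_px, nf))

  half <- ceiling(4 * blob_sigma_px)
  off <- seq(-half, half)
  kern_template <- off  # offsets reused for every blob
  for (ti in seq_len(nf)) {
    sub <- tracks[tracks$frame == frames[ti], , drop = FALSE]
    fr <- arr[, , ti]
    for (j in seq_len(nrow(sub))) {
      cx <- sub$x_um[j] / pixel_size + 0.5   # pixel-centre coordinates
      cy <- sub$y_um[j] / pixel_size + 0.5
      ix <- round(cx) + kern_template
      iy <- round(cy) + kern_template
      okx <- ix >= 1 & ix <= w_px
      oky <- iy >= 1 & iy <= h_px
      if (!any(okx) || !any(oky)) next
      gx <- exp(-((ix[okx] - cx)^2) / (2 * blob_sigma_px^2))
      gy <- exp(-((iy[oky] - cy)^2) / (2 * blob_sigma_px^2))
      fr[iy[oky], ix[okx]] <- fr[iy[oky], ix[okx]] +
        peak_intensity * outer(gy, gx)
    }
    arr[, , ti] <- fr
  }
  if (noise_sd > 0) {
    old <- local_seed(seed)
    arr <- arr + rnorm(length(arr), 0, noise_sd)
    restore_seed(old)
  }
  arr <- pmin(pmax(arr, 0), 1)
  image_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval)
}

## ---- fixture I/O ------------------------------------------------------------

#' Write a simulation fixture to disk
#'
#' Writes the stack as a multi-page 32-bit float TIFF, the track table as CSV,
#' one mask TIFF per vessel branch plus the T-zone disc mask, a geometry JSON,
#' and a JSON config sidecar sufficient to regenerate the outputs from the
#' same seed.
#'
#' @param geometry a \code{perivax_geometry}.
#' @param tracks the track table.
#' @param stack a \code{perivax_image_stack}.
#' @param out_dir output directory (created if missing).
#' @param config optional \code{perivax_cohort_config} recorded in the sidecar.
#' @return invisibly, a character vector of the files written.
#' @export
write_fixture <- function(geometry, tracks, stack, out_dir, config = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  files <- character(0)

  f <- file.path(out_dir, "stack.tif")
  write_stack_tiff(stack, f); files <- c(files, f)

  f <- file.path(out_dir, "tracks.csv")
  write.csv(tracks, f, row.names = FALSE); files <- c(files, f)

  for (k in seq_along(geometry$vessel_masks)) {
    f <- file.path(out_dir, sprintf("vessel_mask_%02d.tif", k))
    tiff::writeTIFF(geometry$vessel_masks[[k]] * 1, f, bits.per.sample = 8L)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "tzone_mask.tif")
  tiff::writeTIFF(tzone_mask(geometry) * 1, f, bits.per.sample = 8L)
  files <- c(files, f)

  f <- file.path(out_dir, "geometry.json")
  jsonlite::write_json(geometry_to_list(geometry), f, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, f)

  f <- file.path(out_dir, "config.json")
  if (!is.null(config) && !is.null(config$n_cells))
    config$n_cells <- as.list(config$n_cells)   # keep behaviour names in JSON
  sidecar <- list(
    config = if (is.null(config)) NULL else strip_classes(config),
    render = list(pixel_size = attr(stack, "pixel_size"),
                  frame_interval = attr(stack, "frame_interval"),
                  channel = attr(stack, "channel")))
  jsonlite::write_json(sidecar, f, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, f)
  invisible(files)
}

#' Binary raster of the T-zone disc
#' @param geometry a \code{perivax_geometry}.
#' @param pixel_size raster calibration; defaults to the geometry's.
#' @export
tzone_mask <- function(geometry, pixel_size = geometry$pixel_size) {
  w_px <- ceiling(geometry$field_size[1] / pixel_size)
  h_px <- ceiling(geometry$field_size[2] / pixel_size)
  xs <- (seq_len(w_px) - 0.5) * pixel_size
  ys <- (seq_len(h_px) - 0.5) * pixel_size
  outer(ys, xs, function(y, x)
    (x - geometry$t_zone_center[1])^2 + (y - geometry$t_zone_center[2])^2 <=
      geometry$t_zone_radius^2)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

geometry_to_list <- function(geometry) {
  list(t_zone_center = geometry$t_zone_center,
       t_zone_radius = geometry$t_zone_radius,
       tracks = lapply(geometry$tracks, unname),   # row-wise [x, y] pairs
       track_half_width = geometry$track_half_width,
       branch_junctions = if (nrow(geometry$branch_junctions))
         unname(geometry$branch_junctions) else list(),
       field_size = geometry$field_size,
       pixel_size = geometry$pixel_size)
}

#' Write an image stack as a multi-page 32-bit float TIFF
#' @param stack a \code{perivax_image_stack}.
#' @param path output file.
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_len(n_frames(stack)), function(t) get_frame(stack, t))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#' @param path TIFF file.
#' @param pixel_size um/px calibration.
#' @param frame_interval seconds per frame.
#' @param channel channel label.
#' @export
read_stack_tiff <- function(path, pixel_size, frame_interval,
                            channel = "gfp") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  image_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval,
              channel = channel)
}

#' Read a track table CSV
#' @param path CSV file with the standard track-table header.
#' @export
read_track_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(tab)))
    stop("track table lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  tab
}

#' Read a geometry JSON written by \code{\link{write_fixture}}
#' @param path JSON file.
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  ## equal-length polylines may come back as one 3-D array
  tracks <- if (is.array(g$tracks) && length(dim(g$tracks)) == 3) {
    lapply(seq_len(dim(g$tracks)[1]), function(i) g$tracks[i, , ])
  } else {
    lapply(g$tracks, function(p) unname(as.matrix(p)))
  }
  masks <- lapply(tracks, function(p)
    rasterize_tube(p, g$track_half_width, g$field_size, g$pixel_size))
  bj <- if (length(g$branch_junctions)) as.matrix(g$branch_junctions) else
    matrix(numeric(0), ncol = 2)
  structure(list(t_zone_center = as.numeric(g$t_zone_center),
                 t_zone_radius = g$t_zone_radius,
                 tracks = tracks,
                 track_half_width = g$track_half_width,
                 vessel_masks = masks,
                 branch_junctions = bj,
                 field_size = as.numeric(g$field_size),
                 pixel_size = g$pixel_size),
            class = "perivax_geometry")
}
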