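## Spatial model of the imaged splenic field: a central T-zone disc, oriented
## perivascular track polylines radiating into the red pulp, and per-branch
## vessel masks. All coordinates are in micrometres; masks are rasters at
## `pixel_size` um/px with pixel centres at (i - 0.5) * pixel_size.

#' Build the compartment geometry for a simulated imaging field
#'
#' Constructs a T-zone disc with \code{n_tracks} perivascular track polylines
#' radiating outward from its perimeter into the red pulp. Each polyline is
#' ordered from its distal (red-pulp) end to its T-zone end, matching the
#' direction of homing migration. A binary vessel mask raster is generated per
#' track branch, and junction points are recorded wherever two polylines
#' intersect.
#'
#' @param field_size numeric length-2, field width and height in um.
#' @param n_tracks number of track polylines (>= 1).
#' @param t_zone_center centre of the T-zone disc in um; defaults to the field
#'   centre.
#' @param t_zone_radius radius of the T-zone disc in um.
#' @param track_half_width half-width of a track (and its vessel mask) in um.
#' @param pixel_size raster calibration in um/px for the vessel masks.
#' @param n_vertices vertices per track polyline.
#' @param angle_jitter_sd angular wobble (radians) applied to successive
#'   polyline vertices, giving tracks a gently tortuous course.
#' @param seed integer seed; identical seeds give identical geometry.
#'
#' @return An object of class \code{perivax_geometry}: a list with elements
#'   \code{t_zone_center}, \code{t_zone_radius}, \code{tracks} (list of n x 2
#'   vertex matrices, distal end first), \code{track_half_width},
#'   \code{vessel_masks} (list of binary H x W matrices), \code{branch_junctions}
#'   (k x 2 matrix, possibly empty), \code{field_size}, \code{pixel_size}.
#' @export
build_geometry <- function(field_size = c(1000, 1000),
                           n_tracks = 4,
                           t_zone_center = field_size / 2,
                           t_zone_radius = 150,
                           track_half_width = 15,
                           pixel_size = 2,
                           n_vertices = 8,
                           angle_jitter_sd = 0.08,
                           seed = 1L) {
  stopifnot(length(field_size) == 2, all(field_size > 0), n_tracks >= 1,
            t_zone_radius > 0, track_half_width > 0, pixel_size > 0,
            n_vertices >= 2)
  margin <- track_half_width + pixel_size
  ## the disc plus at least one track segment must fit inside the field
  max_inner <- min(t_zone_center[1], t_zone_center[2],
                   field_size[1] - t_zone_center[1],
                   field_size[2] - t_zone_center[2])
  if (max_inner < t_zone_radius + 2 * track_half_width)
    stop("field too small to hold the T-zone disc plus tracks", call. = FALSE)

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  base_angles <- seq(0, 2 * pi, length.out = n_tracks + 1)[seq_len(n_tracks)]
  base_angles <- base_angles + runif(1, 0, 2 * pi / max(n_tracks, 1))
  tracks <- vector("list", n_tracks)
  for (k in seq_len(n_tracks)) {
    ang <- base_angles[k]
    r_max <- ray_exit_radius(t_zone_center, ang, field_size) - margin
    r_max <- max(r_max, t_zone_radius + 2 * track_half_width)
    radii <- seq(r_max, t_zone_radius, length.out = n_vertices)
    angs <- ang + cumsum(c(0, rnorm(n_vertices - 1, 0, angle_jitter_sd)))
    ## walk inward with wobble; keep the end point exactly on the perimeter
    verts <- cbind(t_zone_center[1] + radii * cos(angs),
                   t_zone_center[2] + radii * sin(angs))
    verts[, 1] <- pmin(pmax(verts[, 1], margin), field_size[1] - margin)
    verts[, 2] <- pmin(pmax(verts[, 2], margin), field_size[2] - margin)
    verts[n_vertices, ] <- t_zone_center +
      t_zone_radius * c(cos(angs[n_vertices]), sin(angs[n_vertices]))
    tracks[[k]] <- dedupe_vertices(verts)
  }

  masks <- lapply(tracks, function(p)
    rasterize_tube(p, track_half_width, field_size, pixel_size))
  junctions <- polyline_junctions(tracks)

  geom <- structure(list(
    t_zone_center = as.numeric(t_zone_center),
    t_zone_radius = t_zone_radius,
    tracks = tracks,
    track_half_width = track_half_width,
    vessel_masks = masks,
    branch_junctions = junctions,
    field_size = as.numeric(field_size),
    pixel_size = pixel_size
  ), class = "perivax_geometry")
  validate_geometry(geom)
  geom
}

#' @export
print.perivax_geometry <- function(x, ...) {
  cat("perivax geometry:", length(x$tracks), "track(s),",
      sprintf("T zone r=%g um at (%g, %g),", x$t_zone_radius,
              x$t_zone_center[1], x$t_zone_center[2]),
      sprintf("field %g x %g um @ %g um/px\n", x$field_size[1],
              x$field_size[2], x$pixel_size))
  if (nrow(x$branch_junctions))
    cat("  junctions:", nrow(x$branch_junctions), "\n")
  invisible(x)
}

validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "perivax_geometry"))
  lim <- geom$t_zone_radius + geom$track_half_width
  for (p in geom$tracks) {
    endd <- sqrt(sum((p[nrow(p), ] - geom$t_zone_center)^2))
    if (endd > lim + 1e-9)
      stop("track polyline does not terminate at the T-zone perimeter")
    seg <- diff(p)
    if (any(rowSums(seg^2) <= 0))
      stop("track polyline contains a zero-length segment")
  }
  invisible(TRUE)
}

## distance from the disc centre to the field boundary along direction `ang`
ray_exit_radius <- function(center, ang, field_size) {
  d <- c(cos(ang), sin(ang))
  ts <- c(if (d[1] > 0) (field_size[1] - center[1]) / d[1] else Inf,
          if (d[1] < 0) (0 - center[1]) / d[1] else Inf,
          if (d[2] > 0) (field_size[2] - center[2]) / d[2] else Inf,
          if (d[2] < 0) (0 - center[2]) / d[2] else Inf)
  min(ts)
}

dedupe_vertices <- function(verts, tol = 1e-9) {
  keep <- c(TRUE, rowSums(diff(verts)^2) > tol^2)
  verts[keep, , drop = FALSE]
}

## ---- polyline utilities (shared with the simulator and classifiers) --------

## squared distance from each point (n x 2) to segment a-b
point_segment_dist2 <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap_x <- pts[, 1] - a[1]
  ap_y <- pts[, 2] - a[2]
  t <- if (len2 > 0) pmin(pmax((ap_x * ab[1] + ap_y * ab[2]) / len2, 0), 1) else 0
  dx <- ap_x - t * ab[1]
  dy <- ap_y - t * ab[2]
  dx * dx + dy * dy
}

## minimum distance from points (n x 2) to a polyline (m x 2)
dist_to_polyline <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(poly) - 1)) {
    d2 <- pmin(d2, point_segment_dist2(pts, poly[i, ], poly[i + 1, ]))
  }
  sqrt(d2)
}

## cumulative arc length of polyline vertices (first vertex at 0)
arc_lengths <- function(poly) c(0, cumsum(sqrt(rowSums(diff(poly)^2))))

## point and unit tangent at arc-length position s (clamped to the polyline);
## pass the precomputed cumulative arc lengths `cs` in hot loops
polyline_point <- function(poly, s, cs = arc_lengths(poly)) {
  s <- pmin(pmax(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(poly) - 1L)
  seg <- poly[i + 1, , drop = FALSE] - poly[i, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  tan_u <- seg / len
  frac <- (s - cs[i]) / len
  list(point = poly[i, , drop = FALSE] + seg * frac, tangent = tan_u)
}

## binary raster of pixels whose centres lie within `half_width` of the polyline
rasterize_tube <- function(poly, half_width, field_size, pixel_size) {
  w_px <- ceiling(field_size[1] / pixel_size)
  h_px <- ceiling(field_size[2] / pixel_size)
  mask <- matrix(FALSE, nrow = h_px, ncol = w_px)
  pad <- half_width + pixel_size
  x0 <- max(1L, floor((min(poly[, 1]) - pad) / pixel_size) + 1L)
  x1 <- min(w_px, ceiling((max(poly[, 1]) + pad) / pixel_size))
  y0 <- max(1L, floor((min(poly[, 2]) - pad) / pixel_size) + 1L)
  y1 <- min(h_px, ceiling((max(poly[, 2]) + pad) / pixel_size))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- (seq(x0, x1) - 0.5) * pixel_size
  ys <- (seq(y0, y1) - 0.5) * pixel_size
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  d <- dist_to_polyline(pts, poly)
  sub <- matrix(d <= half_width, nrow = length(ys), ncol = length(xs))
  mask[y0:y1, x0:x1] <- sub
  mask
}

## proper intersection points between segments of distinct polylines
polyline_junctions <- function(tracks) {
  pts <- matrix(numeric(0), ncol = 2)
  n <- length(tracks)
  if (n < 2) return(pts)
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    pa <- tracks[[a]]; pb <- tracks[[b]]
    for (i in seq_len(nrow(pa) - 1)) for (j in seq_len(nrow(pb) - 1)) {
      p <- segment_intersection(pa[i, ], pa[i + 1, ], pb[j, ], pb[j + 1, ])
      if (!is.null(p)) pts <- rbind(pts, p)
    }
  }
  unname(pts)
}

segment_intersection <- function(p1, p2, q1, q2) {
  r <- p2 - p1; s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-12) return(NULL)
  qp <- q1 - p1
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
  p1 + t * r
}

#' Label positions by splenic compartment
#'
#' Assigns each position to \code{"tzone"} (inside the T-zone disc),
#' \code{"track"} (within the track half-width of a polyline) or
#' \code{"redpulp"} (elsewhere).
#'
#' @param pts n x 2 matrix of positions in um.
#' @param geometry a \code{perivax_geometry}.
#' @return character vector of compartment labels.
#' @export
label_compartment <- function(pts, geometry) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  d_center <- sqrt((pts[, 1] - geometry$t_zone_center[1])^2 +
                   (pts[, 2] - geometry$t_zone_center[2])^2)
  lab <- rep("redpulp", nrow(pts))
  d_track <- rep(Inf, nrow(pts))
  for (p in geometry$tracks) d_track <- pmin(d_track, dist_to_polyline(pts, p))
  lab[d_track <= geometry$track_half_width] <- "track"
  lab[d_center <= geometry$t_zone_radius] <- "tzone"
  lab
}

## ---- local RNG scoping ------------------------------------------------------
## set.seed scoped to a block so library code does not clobber the caller's RNG
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
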