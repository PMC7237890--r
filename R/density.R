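## Fixed-ROI cell counting and density per mm^3. ROIs are frozen at a
## reference time and reused verbatim at later timepoints; 2-D counts are
## converted to volumes with a configurable imaging slab depth.

#' Define a fixed region of interest
#'
#' @param polygon n x 2 matrix of vertices in um (closed implicitly), or NULL
#'   when a mask is supplied.
#' @param mask binary matrix alternative to a polygon.
#' @param pixel_size um/px when \code{mask} is used.
#' @param slab_depth imaging slab depth in um used to convert the 2-D area
#'   to a volume; default 60 (mid-range of typical two-photon z-stacks).
#' @param id ROI identifier.
#' @return list of class \code{perivax_roi}: geometry, \code{area_um2},
#'   \code{volume_mm3}.
#' @export
roi_spec <- function(polygon = NULL, mask = NULL, pixel_size = 1,
                     slab_depth = 60, id = "roi1") {
  if (is.null(polygon) == is.null(mask))
    stop("supply exactly one of polygon or mask", call. = FALSE)
  stopifnot(slab_depth > 0)
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
    area <- abs(polygon_area(polygon))
  } else {
    area <- sum(mask > 0) * pixel_size^2
  }
  vol <- area * slab_depth * 1e-9        # um^3 -> mm^3
  if (vol <= 0) stop("ROI has zero volume", call. = FALSE)
  structure(list(polygon = polygon, mask = mask, pixel_size = pixel_size,
                 slab_depth = slab_depth, area_um2 = area,
                 volume_mm3 = vol, id = id),
            class = "perivax_roi")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

## even-odd point-in-polygon; points on an edge count as inside
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  on_edge <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    ## boundary test: point within the segment's span and collinear
    cross <- (pts[, 1] - xi) * (yj - yi) - (pts[, 2] - yi) * (xj - xi)
    within <- pts[, 1] >= pmin(xi, xj) - 1e-9 & pts[, 1] <= pmax(xi, xj) + 1e-9 &
              pts[, 2] >= pmin(yi, yj) - 1e-9 & pts[, 2] <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

roi_contains <- function(roi, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  if (!is.null(roi$polygon)) {
    point_in_polygon(pts, roi$polygon)
  } else {
    col <- ceiling(pts[, 1] / roi$pixel_size)
    row <- ceiling(pts[, 2] / roi$pixel_size)
    ok <- row >= 1 & row <= nrow(roi$mask) & col >= 1 & col <= ncol(roi$mask)
    res <- rep(FALSE, nrow(pts))
    res[ok] <- roi$mask[cbind(row[ok], col[ok])] > 0
    res
  }
}

#' Count cells in an ROI and convert to density per mm^3
#'
#' @param positions n x 2 matrix of cell positions in um (one timepoint).
#' @param roi a \code{\link{roi_spec}}; points on the boundary count as
#'   inside.
#' @param timepoint label stored in the record.
#' @return data.frame row: \code{roi}, \code{timepoint}, \code{count},
#'   \code{density_mm3}.
#' @export
count_in_roi <- function(positions, roi, timepoint = 0) {
  stopifnot(inherits(roi, "perivax_roi"))
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  cnt <- if (nrow(positions)) sum(roi_contains(roi, positions)) else 0L
  data.frame(roi = roi$id, timepoint = timepoint, count = cnt,
             density_mm3 = cnt / roi$volume_mm3, stringsAsFactors = FALSE)
}

#' Density change between two timepoints over matched ROIs
#'
#' @param records_t0,records_t1 data.frames from \code{\link{count_in_roi}}
#'   for the same ROI set at the reference and later timepoint.
#' @return data.frame per ROI: densities, \code{ratio} and
#'   \code{percent_loss} = 100 * (1 - ratio); ROIs empty at t0 get NA with a
#'   flag.
#' @export
density_change <- function(records_t0, records_t1) {
  if (!setequal(records_t0$roi, records_t1$roi) ||
      nrow(records_t0) != nrow(records_t1))
    stop("ROI ids at the two timepoints do not match", call. = FALSE)
  t0 <- records_t0[order(records_t0$roi), ]
  t1 <- records_t1[order(records_t1$roi), ]
  ratio <- ifelse(t0$density_mm3 > 0, t1$density_mm3 / t0$density_mm3,
                  NA_real_)
  data.frame(roi = t0$roi,
             density_t0 = t0$density_mm3, density_t1 = t1$density_mm3,
             ratio = ratio, percent_loss = 100 * (1 - ratio),
             undefined = t0$density_mm3 <= 0, stringsAsFactors = FALSE)
}

#' Fraction of cells associated with perivascular tracks
#'
#' fraction = on-track count / (on-track + red-pulp count); cells in neither
#' region (e.g. inside the T zone) are excluded from the denominator.
#'
#' @param positions n x 2 matrix of cell positions in um.
#' @param geometry a \code{perivax_geometry} supplying track tubes and the
#'   T-zone disc.
#' @return list with \code{n_on_track}, \code{n_red_pulp}, \code{fraction}.
#' @export
association_fraction <- function(positions, geometry) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  lab <- label_compartment(positions, geometry)
  n_track <- sum(lab == "track")
  n_rp <- sum(lab == "redpulp")
  if (n_track + n_rp == 0)
    stop("no cells in either the track or red-pulp region", call. = FALSE)
  list(n_on_track = n_track, n_red_pulp = n_rp,
       fraction = n_track / (n_track + n_rp))
}
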