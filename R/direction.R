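## Binary toward/away-T-zone classification of tracks from their start and
## end distances to the T zone, with a dead band absorbing jitter, exclusion
## of tracks dwelling at vessel branch points, and per-animal fractions.

#' Classify one track as moving toward or away from the T zone
#'
#' Compares the distance to the T-zone reference point at the track's start
#' and end. Tracks whose net radial change is within \code{epsilon} are
#' excluded (dead band); tracks with more than half of their points within
#' \code{branch_radius} of a vessel junction are excluded (cell behaviour at
#' branch points is complex and crowded); tracks shorter than
#' \code{min_duration} are excluded.
#'
#' @param track track-table rows of a single cell (>= 2 points).
#' @param geometry a \code{perivax_geometry} (supplies the T-zone centre and
#'   junctions).
#' @param epsilon dead-band half width in um (~ one cell radius).
#' @param branch_radius exclusion radius around junction points, um.
#' @param min_duration minimum track duration in minutes.
#' @param reference \code{"center"} measures distances to the T-zone centre,
#'   \code{"boundary"} to the disc boundary (identical ordering for tracks
#'   outside the disc).
#' @return data.frame row: \code{cell_id}, \code{d_start}, \code{d_end},
#'   \code{class} (toward/away/excluded), \code{exclusion_reason}
#'   (none/dead_band/branch_point/short_track).
#' @export
classify_track <- function(track, geometry, epsilon = 5, branch_radius = 20,
                           min_duration = 10,
                           reference = c("center", "boundary")) {
  reference <- match.arg(reference)
  if (is.null(geometry$t_zone_center))
    stop("geometry lacks a T-zone center", call. = FALSE)
  stopifnot(nrow(track) >= 2)
  track <- track[order(track$t_s), , drop = FALSE]
  pts <- cbind(track$x_um, track$y_um)
  d <- sqrt((pts[, 1] - geometry$t_zone_center[1])^2 +
            (pts[, 2] - geometry$t_zone_center[2])^2)
  if (reference == "boundary") d <- pmax(d - geometry$t_zone_radius, 0)
  d_start <- d[1]; d_end <- d[length(d)]
  dur <- (max(track$t_s) - min(track$t_s)) / 60

  reason <- "none"
  if (dur < min_duration) {
    reason <- "short_track"
  } else if (nrow(geometry$branch_junctions) > 0) {
    dj <- rep(Inf, nrow(pts))
    for (j in seq_len(nrow(geometry$branch_junctions))) {
      jp <- geometry$branch_junctions[j, ]
      dj <- pmin(dj, sqrt((pts[, 1] - jp[1])^2 + (pts[, 2] - jp[2])^2))
    }
    if (mean(dj <= branch_radius) > 0.5) reason <- "branch_point"
  }
  cls <- "excluded"
  if (reason == "none") {
    if (d_end < d_start - epsilon) cls <- "toward"
    else if (d_end > d_start + epsilon) cls <- "away"
    else reason <- "dead_band"
  }
  data.frame(cell_id = track$cell_id[1], d_start = d_start, d_end = d_end,
             class = cls, exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

#' Classify every track of a track table
#'
#' @param tracks track table.
#' @inheritParams classify_track
#' @return data.frame with one row per track (see \code{\link{classify_track}}),
#'   plus the \code{cohort} column when present.
#' @export
classify_tracks <- function(tracks, geometry, epsilon = 5, branch_radius = 20,
                            min_duration = 10,
                            reference = c("center", "boundary")) {
  reference <- match.arg(reference)
  if (is.null(geometry$t_zone_center))
    stop("geometry lacks a T-zone center", call. = FALSE)
  has_cohort <- "cohort" %in% names(tracks)
  key <- if (has_cohort) paste(tracks$cohort, tracks$cell_id) else
    tracks$cell_id
  o <- order(key, tracks$t_s)
  idx <- split(o, key[o])
  d <- sqrt((tracks$x_um - geometry$t_zone_center[1])^2 +
            (tracks$y_um - geometry$t_zone_center[2])^2)
  if (reference == "boundary") d <- pmax(d - geometry$t_zone_radius, 0)
  near_junction <- rep(FALSE, nrow(tracks))
  if (nrow(geometry$branch_junctions) > 0) {
    dj <- rep(Inf, nrow(tracks))
    for (j in seq_len(nrow(geometry$branch_junctions))) {
      jp <- geometry$branch_junctions[j, ]
      dj <- pmin(dj, sqrt((tracks$x_um - jp[1])^2 + (tracks$y_um - jp[2])^2))
    }
    near_junction <- dj <= branch_radius
  }
  first <- vapply(idx, `[`, 0L, 1L)
  last <- vapply(idx, function(i) i[length(i)], 0L)
  d_start <- d[first]; d_end <- d[last]
  dur <- (tracks$t_s[last] - tracks$t_s[first]) / 60
  frac_junction <- vapply(idx, function(i) mean(near_junction[i]), 0)

  reason <- rep("none", length(idx))
  reason[frac_junction > 0.5] <- "branch_point"
  reason[dur < min_duration] <- "short_track"
  cls <- rep("excluded", length(idx))
  ok <- reason == "none"
  cls[ok & d_end < d_start - epsilon] <- "toward"
  cls[ok & d_end > d_start + epsilon] <- "away"
  reason[ok & cls == "excluded"] <- "dead_band"
  out <- data.frame(cell_id = tracks$cell_id[first], d_start = d_start,
                    d_end = d_end, class = cls, exclusion_reason = reason,
                    stringsAsFactors = FALSE)
  if (has_cohort) out$cohort <- tracks$cohort[first]
  rownames(out) <- NULL
  out
}

#' Per-animal fraction of tracks moving toward the T zone
#'
#' Excluded tracks are omitted from the denominator:
#' fraction = toward / (toward + away) per animal, then the across-animal
#' mean and SD (one value per mouse).
#'
#' @param results classification table from \code{\link{classify_tracks}}.
#' @param group grouping column name (animal id); default \code{"cohort"}.
#' @return list with \code{per_group} (group, n_toward, n_away, fraction)
#'   and \code{overall} (mean, sd, sem, n_groups). Animals with no
#'   classified track are omitted with a warning.
#' @export
fraction_toward <- function(results, group = "cohort") {
  stopifnot(group %in% names(results))
  by_g <- split(results, results[[group]])
  per <- lapply(names(by_g), function(g) {
    r <- by_g[[g]]
    n_t <- sum(r$class == "toward")
    n_a <- sum(r$class == "away")
    if (n_t + n_a == 0) {
      warning("group '", g, "' has no classified tracks; omitted")
      return(NULL)
    }
    data.frame(group = g, n_toward = n_t, n_away = n_a,
               fraction = n_t / (n_t + n_a), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0) {
    warning("no group has classified tracks")
    return(list(per_group = data.frame(), overall = list(
      mean = NA_real_, sd = NA_real_, sem = NA_real_, n_groups = 0L)))
  }
  f <- per$fraction
  list(per_group = per,
       overall = list(mean = mean(f),
                      sd = if (length(f) > 1) sd(f) else 0,
                      sem = if (length(f) > 1) sd(f) / sqrt(length(f)) else 0,
                      n_groups = length(f)))
}
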