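## Per-track motility metrics: mean velocity (path length / duration),
## straightness (net displacement / path length), and the population mean
## displacement versus sqrt(time) curve with its motility coefficient.

#' Motility metrics for the tracks of a track table
#'
#' Tracks shorter than \code{min_duration} are excluded (flagged, not an
#' error), following the convention of analysing only cells tracked for at
#' least 10 minutes.
#'
#' @param tracks track table (\code{cell_id}, \code{t_s}, \code{x_um},
#'   \code{y_um}, optionally \code{cohort}).
#' @param min_duration minimum track duration in minutes.
#' @return data.frame with one row per track: \code{cell_id}, \code{cohort},
#'   \code{duration_min}, \code{path_length_um}, \code{net_displacement_um},
#'   \code{mean_velocity}, \code{straightness}, \code{included}.
#' @export
track_metrics <- function(tracks, min_duration = 10) {
  stopifnot(all(c("cell_id", "t_s", "x_um", "y_um") %in% names(tracks)))
  has_cohort <- "cohort" %in% names(tracks)
  ## cell ids are only unique within a cohort
  key <- if (has_cohort) paste(tracks$cohort, tracks$cell_id) else
    tracks$cell_id
  o <- order(key, tracks$t_s)
  idx <- split(o, key[o])
  x <- tracks$x_um; y <- tracks$y_um; t_s <- tracks$t_s
  stat <- vapply(idx, function(i) {
    dur <- (t_s[i[length(i)]] - t_s[i[1]]) / 60
    path <- sum(sqrt(diff(x[i])^2 + diff(y[i])^2))
    net <- sqrt((x[i[length(i)]] - x[i[1]])^2 + (y[i[length(i)]] - y[i[1]])^2)
    c(dur, path, net)
  }, numeric(3))
  dur <- stat[1, ]; path <- stat[2, ]; net <- stat[3, ]
  out <- data.frame(
    cell_id = tracks$cell_id[vapply(idx, `[`, 0L, 1L)],
    cohort = if (has_cohort) tracks$cohort[vapply(idx, `[`, 0L, 1L)] else
      NA_character_,
    duration_min = dur,
    path_length_um = path,
    net_displacement_um = net,
    mean_velocity = ifelse(dur > 0, path / dur, NA_real_),
    straightness = ifelse(path > 0, net / path, NA_real_),
    included = dur >= min_duration,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean displacement versus square root of time
#'
#' For each lag tau up to \code{horizon}, averages |x(t + tau) - x(t)| over
#' all tracks and all start offsets (overlapping windows), and fits the
#' motility coefficient as the slope of the through-origin least-squares
#' line of mean displacement against sqrt(tau).
#'
#' @param tracks track table with a uniform frame interval.
#' @param horizon maximum lag in minutes.
#' @return list of class \code{perivax_displacement_curve}:
#'   \code{sqrt_t_min} (including 0), \code{mean_displacement_um},
#'   \code{n_pairs}, \code{motility_coefficient} (um/min^0.5).
#' @export
displacement_curve <- function(tracks, horizon = 10) {
  stopifnot(all(c("cell_id", "t_s", "x_um", "y_um") %in% names(tracks)))
  key <- if ("cohort" %in% names(tracks))
    paste(tracks$cohort, tracks$cell_id) else tracks$cell_id
  dts <- unlist(lapply(split(tracks$t_s, key),
                       function(t) diff(sort(t))))
  dt_s <- min(dts)
  if (any(abs(dts - dt_s) > 0.01 * dt_s))
    stop("displacement_curve requires one uniform frame interval")
  max_lag <- floor(horizon * 60 / dt_s)
  if (max_lag < 1) stop("horizon shorter than one frame interval")
  by_cell <- split(tracks[, c("t_s", "x_um", "y_um")], key)
  spans <- vapply(by_cell, function(tr) diff(range(tr$t_s)), 0)
  if (sum(spans >= horizon * 60) == 0)
    stop("no track spans the requested horizon", call. = FALSE)
  disp_sum <- numeric(max_lag)
  disp_n <- integer(max_lag)
  for (tr in by_cell) {
    tr <- tr[order(tr$t_s), ]
    n <- nrow(tr)
    for (lag in seq_len(min(max_lag, n - 1))) {
      i <- seq_len(n - lag)
      d <- sqrt((tr$x_um[i + lag] - tr$x_um[i])^2 +
                (tr$y_um[i + lag] - tr$y_um[i])^2)
      disp_sum[lag] <- disp_sum[lag] + sum(d)
      disp_n[lag] <- disp_n[lag] + length(d)
    }
  }
  keep <- disp_n > 0
  tau_min <- (seq_len(max_lag) * dt_s / 60)[keep]
  md <- (disp_sum / disp_n)[keep]
  sqrt_t <- sqrt(tau_min)
  slope <- sum(sqrt_t * md) / sum(sqrt_t^2)    # through-origin least squares
  structure(list(sqrt_t_min = c(0, sqrt_t),
                 mean_displacement_um = c(0, md),
                 n_pairs = c(0L, disp_n[keep]),
                 motility_coefficient = slope),
            class = "perivax_displacement_curve")
}

#' @export
print.perivax_displacement_curve <- function(x, ...) {
  cat(sprintf("displacement curve: %d lags, motility coefficient %.3g um/min^0.5\n",
              length(x$sqrt_t_min) - 1L, x$motility_coefficient))
  invisible(x)
}

#' Per-animal cohort summary of a metric
#'
#' Computes unweighted per-animal (group) means of a per-track metric, then
#' the across-animal mean, SD and SEM, matching the convention of plotting
#' one point per mouse.
#'
#' @param records per-track data.frame (e.g. from \code{\link{track_metrics}}).
#' @param metric name of the metric column.
#' @param group name of the grouping column (animal id); default
#'   \code{"cohort"}.
#' @param only_included if TRUE (default), use rows with \code{included} TRUE
#'   when that column exists.
#' @return list with \code{per_group} (group, n, mean) and \code{overall}
#'   (mean, sd, sem, n_groups).
#' @export
cohort_summary <- function(records, metric = "mean_velocity",
                           group = "cohort", only_included = TRUE) {
  stopifnot(metric %in% names(records), group %in% names(records))
  if (only_included && "included" %in% names(records))
    records <- records[records$included, , drop = FALSE]
  records <- records[!is.na(records[[metric]]), , drop = FALSE]
  groups <- split(records[[metric]], records[[group]])
  empty <- vapply(groups, length, 0L) == 0
  if (any(empty)) {
    warning("empty group(s) excluded: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  per <- data.frame(group = names(groups),
                    n = vapply(groups, length, 0L),
                    mean = vapply(groups, mean, 0),
                    stringsAsFactors = FALSE)
  m <- per$mean
  list(per_group = per,
       overall = list(mean = mean(m),
                      sd = if (length(m) > 1) sd(m) else 0,
                      sem = if (length(m) > 1) sd(m) / sqrt(length(m)) else 0,
                      n_groups = length(m)))
}
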