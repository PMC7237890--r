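## Superpixel collective-motion analysis: partition the frame into ~equal
## square regions, track their centroids with dense optical flow, summarize
## each superpixel by its mean velocity vector and mean position, orient each
## vessel branch by its image-moment major axis (flipped to point toward the
## T zone), and report the fraction of in-vessel superpixels whose mean
## velocity projects positively onto their branch axis (null expectation 0.5).

#' Partition a frame into equal square superpixels
#'
#' Chooses the square cell side whose resulting region count is closest to
#' \code{target_count}; boundary regions are clipped. A 1000 x 1000 frame at
#' the default target gives exactly 10,000 regions of side 10 px.
#'
#' @param frame_shape integer length-2 (H, W) in pixels.
#' @param target_count desired number of regions (default 10000).
#' @return list of class \code{perivax_superpixel_grid}: \code{side},
#'   \code{n_rows}, \code{n_cols}, \code{n_regions}, \code{centers_x},
#'   \code{centers_y} (0-based px centre coordinates per region, row-major),
#'   and \code{frame_shape}.
#' @export
partition_superpixels <- function(frame_shape, target_count = 10000) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 10))
  if (target_count < 1) stop("target_count must be >= 1", call. = FALSE)
  H <- frame_shape[1]; W <- frame_shape[2]
  sides <- seq_len(min(H, W))
  counts <- ceiling(H / sides) * ceiling(W / sides)
  ideal <- sqrt(H * W / target_count)
  best <- which(abs(counts - target_count) == min(abs(counts - target_count)))
  side <- sides[best[which.min(abs(sides[best] - ideal))]]
  n_rows <- ceiling(H / side); n_cols <- ceiling(W / side)
  ## region centres (clipped boxes keep the full-box nominal centre)
  row_c <- (seq_len(n_rows) - 0.5) * side - 0.5
  col_c <- (seq_len(n_cols) - 0.5) * side - 0.5
  structure(list(side = side, n_rows = n_rows, n_cols = n_cols,
                 n_regions = n_rows * n_cols,
                 centers_x = rep(col_c, times = n_rows),
                 centers_y = rep(row_c, each = n_cols),
                 frame_shape = c(H, W)),
            class = "perivax_superpixel_grid")
}

#' @export
print.perivax_superpixel_grid <- function(x, ...) {
  cat(sprintf("superpixel grid: %d x %d regions of side %d px (%d total)\n",
              x$n_rows, x$n_cols, x$side, x$n_regions))
  invisible(x)
}

#' Dense optical flow between two frames
#'
#' Pyramidal iterative Lucas-Kanade flow. Frames are contrast-normalized to
#' [0, 1] before estimation. For rigid translations of up to ~5 px of a
#' textured scene the mean error is below 0.2 px per component.
#'
#' @param frame_a,frame_b same-shape intensity matrices.
#' @param levels pyramid levels.
#' @param win box window half-size in px.
#' @param iters iterations per level.
#' @return list with \code{dx}, \code{dy} (per-pixel displacement in px,
#'   column/x and row/y components) and \code{low_confidence} (TRUE when a
#'   frame is texture-free).
#' @export
dense_flow <- function(frame_a, frame_b, levels = 3, win = 7, iters = 3) {
  stopifnot(is.matrix(frame_a), all(dim(frame_a) == dim(frame_b)))
  ra <- range(frame_a); rb <- range(frame_b)
  low_conf <- (ra[2] - ra[1]) < 1e-12 || (rb[2] - rb[1]) < 1e-12
  na <- if (ra[2] > ra[1]) (frame_a - ra[1]) / (ra[2] - ra[1]) else frame_a * 0
  nb <- if (rb[2] > rb[1]) (frame_b - rb[1]) / (rb[2] - rb[1]) else frame_b * 0
  fl <- .lk_flow(na, nb, levels = levels, win = win, iters = iters)
  list(dx = fl$dx, dy = fl$dy, low_confidence = low_conf)
}

#' Advect superpixel centroids through a stack
#'
#' Each superpixel centroid is advected frame-to-frame by the mean optical
#' flow over its current square footprint (bilinear sampling, forward
#' Euler). The mean velocity vector (net displacement over total time) and
#' the mean position of each trajectory summarize its average motion.
#'
#' @param stack a \code{perivax_image_stack} with T >= 2 frames.
#' @param grid a \code{\link{partition_superpixels}} grid.
#' @param levels,win,iters passed to \code{\link{dense_flow}}.
#' @return list of class \code{perivax_superpixel_trajectories}:
#'   \code{pos_x_px}, \code{pos_y_px} (n_regions x T, 0-based px),
#'   \code{mean_velocity} (n x 2, um/min), \code{mean_position} (n x 2, um),
#'   \code{frozen} (logical: centroid reached the frame boundary).
#' @export
advect_superpixels <- function(stack, grid, levels = 3, win = 7, iters = 3) {
  T_ <- n_frames(stack)
  stopifnot(T_ >= 2, inherits(grid, "perivax_superpixel_grid"))
  px <- attr(stack, "pixel_size")
  dt_min <- attr(stack, "frame_interval") / 60
  H <- dim(stack)[1]; W <- dim(stack)[2]
  n <- grid$n_regions
  pos_x <- matrix(NA_real_, n, T_)
  pos_y <- matrix(NA_real_, n, T_)
  pos_x[, 1] <- grid$centers_x
  pos_y[, 1] <- grid$centers_y
  frozen <- rep(FALSE, n)
  for (t in seq_len(T_ - 1)) {
    fl <- dense_flow(get_frame(stack, t), get_frame(stack, t + 1),
                     levels = levels, win = win, iters = iters)
    mv <- .footprint_mean_flow(fl$dx, fl$dy, pos_x[, t], pos_y[, t],
                               as.integer(grid$side))
    nx <- pos_x[, t] + ifelse(frozen, 0, mv[, 1])
    ny <- pos_y[, t] + ifelse(frozen, 0, mv[, 2])
    hit <- nx < 0 | nx > (W - 1) | ny < 0 | ny > (H - 1)
    frozen <- frozen | hit
    pos_x[, t + 1] <- pmin(pmax(nx, 0), W - 1)
    pos_y[, t + 1] <- pmin(pmax(ny, 0), H - 1)
  }
  mean_velocity <- cbind((pos_x[, T_] - pos_x[, 1]),
                         (pos_y[, T_] - pos_y[, 1])) * px / ((T_ - 1) * dt_min)
  mean_position <- cbind(rowMeans(pos_x) + 0.5, rowMeans(pos_y) + 0.5) * px
  structure(list(pos_x_px = pos_x, pos_y_px = pos_y,
                 mean_velocity = mean_velocity,
                 mean_position = mean_position, frozen = frozen,
                 pixel_size = px),
            class = "perivax_superpixel_trajectories")
}

#' Oriented principal axes of a vessel-branch mask
#'
#' The major and minor axes are the eigenvectors of the second central
#' image-moment matrix of the mask. The major axis is flipped (multiplied by
#' -1) where needed so it points toward the T-zone centre; the minor axis is
#' set to the +90 degree rotation of the major axis so all branches share one
#' handedness convention.
#'
#' @param vessel_mask binary matrix (row = y, col = x).
#' @param t_zone_center T-zone centre in um.
#' @param pixel_size um/px of the mask raster.
#' @param min_anisotropy minimum eigenvalue ratio; masks more isotropic than
#'   this have no meaningful axis and raise an error.
#' @return list of class \code{perivax_branch_axes}: \code{centroid} (um),
#'   \code{major}, \code{minor} (unit vectors), \code{eigenvalues}.
#' @export
branch_axes <- function(vessel_mask, t_zone_center, pixel_size = 1,
                        min_anisotropy = 1.2) {
  pix <- which(vessel_mask > 0, arr.ind = TRUE)
  if (nrow(pix) == 0) stop("empty vessel mask", call. = FALSE)
  x <- (pix[, 2] - 0.5) * pixel_size
  y <- (pix[, 1] - 0.5) * pixel_size
  centroid <- c(mean(x), mean(y))
  xc <- x - centroid[1]; yc <- y - centroid[2]
  M <- matrix(c(mean(xc^2), mean(xc * yc), mean(xc * yc), mean(yc^2)), 2, 2)
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values
  if (lam[2] <= 0 || lam[1] / lam[2] < min_anisotropy)
    stop("vessel mask too isotropic for a principal axis (ratio ",
         sprintf("%.3g", lam[1] / max(lam[2], .Machine$double.eps)),
         " < ", min_anisotropy, ")", call. = FALSE)
  e1 <- e$vectors[, 1]
  if (sum(e1 * (t_zone_center - centroid)) < 0) e1 <- -e1
  e2 <- c(-e1[2], e1[1])                 # fixed right-handed convention
  structure(list(centroid = centroid, major = e1, minor = e2,
                 eigenvalues = lam),
            class = "perivax_branch_axes")
}

#' Fraction of in-vessel superpixels moving toward the T zone
#'
#' A superpixel belongs to a vessel branch when its mean position falls
#' inside that branch's mask (ties between overlapping masks go to the
#' branch with the nearer centroid). It counts as moving toward the T zone
#' when the projection of its mean velocity vector onto the branch's
#' oriented major axis is strictly positive; a projection of exactly zero
#' has no directionality and is not counted as positive. The expected
#' fraction under isotropic motion is ~0.5.
#'
#' @param trajectories result of \code{\link{advect_superpixels}}.
#' @param branches list of \code{\link{branch_axes}} results, one per mask.
#' @param vessel_masks list of binary masks matching \code{branches}.
#' @param pixel_size um/px of the masks.
#' @return list of class \code{perivax_flow_statistic}: \code{n_in_vessel},
#'   \code{n_positive}, \code{fraction}, \code{null_expectation} (0.5), and
#'   per-superpixel \code{branch} (0 = outside) and \code{projection}
#'   (um/min).
#' @export
fraction_toward_tzone <- function(trajectories, branches, vessel_masks,
                                  pixel_size = trajectories$pixel_size) {
  stopifnot(length(branches) == length(vessel_masks), length(branches) >= 1)
  n <- nrow(trajectories$mean_position)
  pos <- trajectories$mean_position
  branch_of <- integer(n)
  best_d <- rep(Inf, n)
  for (k in seq_along(vessel_masks)) {
    m <- vessel_masks[[k]]
    col <- pmin(pmax(ceiling(pos[, 1] / pixel_size), 1L), ncol(m))
    row <- pmin(pmax(ceiling(pos[, 2] / pixel_size), 1L), nrow(m))
    inside <- m[cbind(row, col)] > 0
    cen <- branches[[k]]$centroid
    d <- sqrt((pos[, 1] - cen[1])^2 + (pos[, 2] - cen[2])^2)
    take <- inside & d < best_d
    branch_of[take] <- k
    best_d[take] <- d[take]
  }
  in_vessel <- branch_of > 0
  if (!any(in_vessel))
    stop("no superpixel lies within a vessel mask", call. = FALSE)
  proj <- rep(NA_real_, n)
  for (k in seq_along(branches)) {
    sel <- branch_of == k
    if (any(sel))
      proj[sel] <- trajectories$mean_velocity[sel, , drop = FALSE] %*%
        branches[[k]]$major
  }
  n_pos <- sum(proj[in_vessel] > 0)
  structure(list(n_in_vessel = sum(in_vessel), n_positive = n_pos,
                 fraction = n_pos / sum(in_vessel), null_expectation = 0.5,
                 branch = branch_of, projection = proj),
            class = "perivax_flow_statistic")
}

#' @export
print.perivax_flow_statistic <- function(x, ...) {
  cat(sprintf("flow statistic: %d / %d in-vessel superpixels toward the T zone (f = %.3f, null 0.5)\n",
              x$n_positive, x$n_in_vessel, x$fraction))
  invisible(x)
}
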