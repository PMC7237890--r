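test_that("superpixel partition yields near-target counts of square regions", {
  g <- partition_superpixels(c(1000, 1000))
  expect_equal(g$side, 10)
  expect_equal(g$n_regions, 10000)
  expect_equal(partition_superpixels(c(10, 10), 1)$n_regions, 1)
  g2 <- partition_superpixels(c(100, 70), 70)
  expect_equal(g2$side, 10)
  expect_equal(g2$n_rows * g2$n_cols, 70)
  expect_error(partition_superpixels(c(100, 100), 0), "target_count")
})

test_that("dense flow meets its identity, translation and rotation contracts", {
  tex <- make_texture(220, seed = 3)
  ## identity
  f0 <- dense_flow(tex, tex)
  expect_lt(mean(abs(f0$dx)) + mean(abs(f0$dy)), 0.05)
  ## integer translations up to 5 px, error measured off the wrap border
  cen <- 61:160
  for (sh in list(c(3, 0), c(-2, 1), c(5, 5))) {
    fl <- dense_flow(tex, shift_image(tex, sh[1], sh[2]))
    expect_lt(abs(mean(fl$dx[cen, cen]) - sh[1]), 0.2)
    expect_lt(abs(mean(fl$dy[cen, cen]) - sh[2]), 0.2)
  }
  ## uniform frames are flagged low-confidence
  expect_true(dense_flow(matrix(0.5, 64, 64),
                         matrix(0.5, 64, 64))$low_confidence)
})

test_that("dense flow recovers a small rigid rotation field", {
  n <- 200; c0 <- (n + 1) / 2; th <- 2 * pi / 180
  set.seed(7)
  xs <- runif(80, 15, n - 15); ys <- runif(80, 15, n - 15)
  draw <- function(xs, ys) {
    img <- matrix(0.05, n, n)
    for (k in seq_along(xs)) {
      ix <- round(xs[k]) + (-6:6); iy <- round(ys[k]) + (-6:6)
      okx <- ix >= 1 & ix <= n; oky <- iy >= 1 & iy <= n
      img[iy[oky], ix[okx]] <- img[iy[oky], ix[okx]] +
        0.6 * outer(exp(-((iy[oky] - ys[k])^2) / 8),
                    exp(-((ix[okx] - xs[k])^2) / 8))
    }
    img
  }
  a <- draw(xs, ys)
  b <- draw(c0 + cos(th) * (xs - c0) - sin(th) * (ys - c0),
            c0 + sin(th) * (xs - c0) + cos(th) * (ys - c0))
  fl <- dense_flow(a, b)
  gx <- matrix(rep(1:n, each = n), n); gy <- matrix(rep(1:n, n), n)
  ex <- cos(th) * (gx - c0) - sin(th) * (gy - c0) + c0 - gx
  ey <- sin(th) * (gx - c0) + cos(th) * (gy - c0) + c0 - gy
  ii <- 76:125   # central half
  expect_lt(mean(abs(fl$dx[ii, ii] - ex[ii, ii])), 0.3)
  expect_lt(mean(abs(fl$dy[ii, ii] - ey[ii, ii])), 0.3)
})

test_that("advected superpixels track global translation and stay put on static stacks", {
  n <- 128; T_ <- 7
  big <- make_texture(n + 2 * T_, seed = 11)
  arr <- array(0, c(n, n, T_))
  for (t in seq_len(T_)) arr[, , t] <- big[1:n + T_, 1:n + t]  # +1 px/frame in x
  st <- image_stack(arr, pixel_size = 2, frame_interval = 30)
  gr <- partition_superpixels(c(n, n), 256)
  tr <- advect_superpixels(st, gr)
  v_exp <- c(-1 * 2 / 0.5, 0)            # content moves -1 px/frame
  inner <- !tr$frozen
  expect_lt(abs(mean(tr$mean_velocity[inner, 1]) - v_exp[1]),
            0.05 * abs(v_exp[1]))
  expect_lt(abs(mean(tr$mean_velocity[inner, 2])), 0.2)
  ## static stack
  arr0 <- array(rep(big[1:n, 1:n], T_), c(n, n, T_))
  tr0 <- advect_superpixels(image_stack(arr0, 2, 30), gr)
  expect_lt(max(abs(tr0$mean_velocity)), 0.05)
})

test_that("branch axes follow image moments and the orientation rule", {
  m <- matrix(FALSE, 240, 240); m[111:130, 21:220] <- TRUE
  b <- branch_axes(m, t_zone_center = c(400, 120))
  expect_equal(b$major, c(1, 0), tolerance = 1e-9)
  expect_equal(sum(b$major * b$minor), 0)
  b2 <- branch_axes(m, t_zone_center = c(10, 120))
  expect_equal(b2$major, c(-1, 0), tolerance = 1e-9)
  ## minor axis keeps the same handedness in both cases
  expect_equal(b$minor, c(0, 1)); expect_equal(b2$minor, c(0, -1))
  ## 30-degree bar: axis within 1 degree of the analytic direction
  th <- 30 * pi / 180
  mm <- outer(1:300, 1:300, function(i, j) {
    u <- cos(th) * (j - 150) + sin(th) * (i - 150)
    v <- -sin(th) * (j - 150) + cos(th) * (i - 150)
    abs(u) <= 100 & abs(v) <= 10
  })
  b3 <- branch_axes(mm, t_zone_center = c(500, 400))
  expect_lt(abs(atan2(b3$major[2], b3$major[1]) - th), pi / 180)
  ## isotropic masks have no meaningful axis
  expect_error(branch_axes(make_square(50), c(500, 400)), "isotropic")
  expect_error(branch_axes(matrix(FALSE, 10, 10), c(1, 1)), "empty")
})

test_that("projection statistic counts positive components only", {
  mask <- matrix(TRUE, 100, 100)
  br <- list(structure(list(centroid = c(50, 50), major = c(1, 0),
                            minor = c(0, 1), eigenvalues = c(2, 1)),
                       class = "perivax_branch_axes"))
  mk_traj <- function(v) {
    structure(list(mean_position = cbind(runif(nrow(v), 10, 90),
                                         runif(nrow(v), 10, 90)),
                   mean_velocity = v, pixel_size = 1),
              class = "perivax_superpixel_trajectories")
  }
  set.seed(2)
  ## all velocities along the axis
  f1 <- fraction_toward_tzone(mk_traj(cbind(rep(2, 20), rnorm(20))), br,
                              list(mask))
  expect_equal(f1$fraction, 1)
  ## 7 of 10 positive
  v <- cbind(c(rep(1, 7), rep(-1, 3)), 0)
  expect_equal(fraction_toward_tzone(mk_traj(v), br, list(mask))$fraction, 0.7)
  ## exact zero projection is not positive
  v0 <- cbind(c(0, 0, 1, -1), c(5, -5, 0, 0))
  expect_equal(fraction_toward_tzone(mk_traj(v0), br, list(mask))$fraction,
               0.25)
  ## isotropic random directions: f near 0.5
  set.seed(9)
  ang <- runif(4000, 0, 2 * pi)
  fr <- fraction_toward_tzone(mk_traj(cbind(cos(ang), sin(ang))), br,
                              list(mask))
  expect_lt(abs(fr$fraction - 0.5), 3 * sqrt(0.25 / 4000))
  ## no in-vessel superpixel is an error
  empty_mask <- matrix(FALSE, 100, 100)
  expect_error(fraction_toward_tzone(mk_traj(v0), br, list(empty_mask)),
               "vessel")
})

test_that("flow statistic flips under time reversal and survives 90-degree rotation", {
  scene <- vessel_scene(field = c(320, 160))
  p <- agent_params("track_guided", bias_q = 1, sigma_lateral = 0)
  cc <- cohort_config(n_cells = c(track_guided = 30),
                      params = list(track_guided = p), seed = 3,
                      n_frames = 10)
  tt <- simulate_cohort(scene, cc)
  st <- render_stack(tt, scene, seed = 4, pixel_size = 1)
  gr <- partition_superpixels(dim(st)[1:2], 800)
  br <- list(branch_axes(scene$vessel_masks[[1]], scene$t_zone_center))
  f_fwd <- fraction_toward_tzone(advect_superpixels(st, gr), br,
                                 scene$vessel_masks)
  ## strongly biased inbound motion dominates the in-vessel superpixels
  expect_gt(f_fwd$fraction, 0.5)

  ## time reversal: f -> 1 - f up to zero-projection ties
  arr_rev <- unclass(st)[, , dim(st)[3]:1]
  st_rev <- image_stack(arr_rev, attr(st, "pixel_size"),
                        attr(st, "frame_interval"))
  f_rev <- fraction_toward_tzone(advect_superpixels(st_rev, gr), br,
                                 scene$vessel_masks)
  ties <- mean(abs(f_fwd$projection[f_fwd$branch > 0]) < 0.05, na.rm = TRUE)
  expect_lt(abs(f_rev$fraction - (1 - f_fwd$fraction)), max(0.05, ties))

  ## rotate stack, mask and T-zone centre together by 90 degrees
  rot90 <- function(m) t(m)[ncol(m):1, ]
  arr_rot <- array(0, c(dim(st)[2], dim(st)[1], dim(st)[3]))
  for (t in seq_len(dim(st)[3])) arr_rot[, , t] <- rot90(get_frame(st, t))
  scene_rot <- scene
  scene_rot$vessel_masks <- list(rot90(scene$vessel_masks[[1]]))
  ## this raster rotation maps (x, y) -> (y, field_width - x) in um
  scene_rot$t_zone_center <- c(scene$t_zone_center[2],
                               scene$field_size[1] - scene$t_zone_center[1])
  st_rot <- image_stack(arr_rot, 1, attr(st, "frame_interval"))
  gr_rot <- partition_superpixels(dim(st_rot)[1:2], 800)
  br_rot <- list(branch_axes(scene_rot$vessel_masks[[1]],
                             scene_rot$t_zone_center))
  f_rot <- fraction_toward_tzone(advect_superpixels(st_rot, gr_rot), br_rot,
                                 scene_rot$vessel_masks)
  n_min <- min(f_rot$n_in_vessel, f_fwd$n_in_vessel)
  expect_lt(abs(f_rot$fraction - f_fwd$fraction), 0.05 + 2 / n_min)
})
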