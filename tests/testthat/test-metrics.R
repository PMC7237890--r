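walk_table <- function(steps_x, steps_y, dt_s = 30, cohort = "a") {
  ## steps matrices: n_walks x n_steps; returns a track table
  n <- nrow(steps_x); k <- ncol(steps_x) + 1
  x <- cbind(0, t(apply(steps_x, 1, cumsum)))
  y <- cbind(0, t(apply(steps_y, 1, cumsum)))
  data.frame(cell_id = rep(seq_len(n), each = k),
             frame = rep(seq_len(k) - 1L, n),
             t_s = rep((seq_len(k) - 1) * dt_s, n),
             x_um = as.vector(t(x)), y_um = as.vector(t(y)),
             cohort = cohort, stringsAsFactors = FALSE)
}

test_that("velocity and straightness follow their definitions", {
  ## 3 collinear points, 10 um per 30 s step
  tr <- data.frame(cell_id = 1, frame = 0:2, t_s = c(0, 30, 60),
                   x_um = c(0, 10, 20), y_um = 0, cohort = "a")
  m <- track_metrics(tr, min_duration = 0)
  expect_equal(m$mean_velocity, 20)
  expect_equal(m$straightness, 1)
  ## a closed loop has straightness 0
  loop <- data.frame(cell_id = 1, frame = 0:4, t_s = (0:4) * 30,
                     x_um = c(0, 10, 10, 0, 0), y_um = c(0, 0, 10, 10, 0),
                     cohort = "a")
  expect_equal(track_metrics(loop, min_duration = 0)$straightness, 0)
  ## short tracks are flagged, not dropped silently
  expect_false(track_metrics(tr, min_duration = 10)$included)
})

test_that("straightness is bounded and time-reversal leaves velocity unchanged", {
  set.seed(5)
  tt <- walk_table(matrix(rnorm(200 * 30), 200), matrix(rnorm(200 * 30), 200))
  m <- track_metrics(tt, min_duration = 0)
  expect_true(all(m$straightness >= 0 & m$straightness <= 1 + 1e-12))
  rev_tt <- tt
  rev_tt$t_s <- ave(tt$t_s, tt$cell_id, FUN = function(t) max(t) - t)
  m2 <- track_metrics(rev_tt, min_duration = 0)
  expect_equal(sort(m2$mean_velocity), sort(m$mean_velocity),
               tolerance = 1e-12)
})

test_that("random-walk mean straightness matches the Monte-Carlo oracle", {
  n_steps <- 40
  ## implementation on 4e4 simulated unbiased 2-D walks
  set.seed(101)
  n1 <- 40000
  ang <- matrix(runif(n1 * n_steps, 0, 2 * pi), n1)
  m <- track_metrics(walk_table(cos(ang), sin(ang)), min_duration = 0)
  ## independent brute-force oracle at larger n, direct arithmetic
  set.seed(202)
  n2 <- 100000
  ang2 <- matrix(runif(n2 * n_steps, 0, 2 * pi), n2)
  net <- sqrt(rowSums(cos(ang2))^2 + rowSums(sin(ang2))^2)
  oracle <- mean(net / n_steps)
  expect_lt(abs(mean(m$straightness) - oracle) / oracle, 0.01)
})

test_that("displacement curve is exact for ballistic and stationary cohorts", {
  v <- 12  # um/min along x, dt = 30 s
  tt <- walk_table(matrix(v / 2, 20, 30), matrix(0, 20, 30))
  dc <- displacement_curve(tt, horizon = 10)
  expect_equal(dc$sqrt_t_min[1], 0)
  expect_equal(dc$mean_displacement_um[1], 0)
  tau <- dc$sqrt_t_min[-1]^2
  expect_equal(dc$mean_displacement_um[-1], v * tau, tolerance = 1e-12)
  ## stationary cohort: identically zero
  tt0 <- walk_table(matrix(0, 15, 30), matrix(0, 15, 30))
  dc0 <- displacement_curve(tt0, horizon = 10)
  expect_true(all(dc0$mean_displacement_um == 0))
  expect_equal(dc0$motility_coefficient, 0)
  expect_error(displacement_curve(tt, horizon = 60), "horizon")
})

test_that("diffusive motility coefficient matches the Monte-Carlo oracle", {
  s <- 3  # per-step per-axis sd, dt = 30 s
  gen <- function(n, seed) {
    set.seed(seed)
    walk_table(matrix(rnorm(n * 40, 0, s), n), matrix(rnorm(n * 40, 0, s), n))
  }
  dc <- displacement_curve(gen(400, 7), horizon = 8)
  ## independent realization, same estimator arithmetic written out longhand
  tt2 <- gen(2000, 8)
  lag_frames <- seq_len(16)
  md <- vapply(lag_frames, function(L) {
    d <- unlist(lapply(split(tt2, tt2$cell_id), function(tr) {
      i <- seq_len(nrow(tr) - L)
      sqrt((tr$x_um[i + L] - tr$x_um[i])^2 + (tr$y_um[i + L] - tr$y_um[i])^2)
    }))
    mean(d)
  }, 0)
  st <- sqrt(lag_frames * 0.5)
  oracle_slope <- sum(st * md) / sum(st^2)
  expect_lt(abs(dc$motility_coefficient - oracle_slope) / oracle_slope, 0.03)
})

test_that("cohort summary averages per animal and its SEM shrinks as 1/sqrt(n)", {
  rec <- data.frame(cohort = c("m1", "m1", "m2"), mean_velocity = c(1, 3, 5),
                    included = TRUE)
  s <- cohort_summary(rec)
  expect_equal(s$per_group$mean, c(2, 5))
  expect_equal(s$overall$mean, 3.5)
  ## identical records: zero dispersion
  rec2 <- data.frame(cohort = "m1", mean_velocity = rep(4, 6), included = TRUE)
  expect_equal(cohort_summary(rec2)$overall$sd, 0)
  ## bootstrap: SEM at 16 animals is about half the SEM at 4 animals
  set.seed(33)
  sems <- vapply(c(4L, 16L), function(k) {
    mean(vapply(1:300, function(i) {
      r <- data.frame(cohort = rep(paste0("m", 1:k), each = 10),
                      mean_velocity = rnorm(10 * k), included = TRUE)
      cohort_summary(r)$overall$sem
    }, 0))
  }, 0)
  expect_lt(abs(sems[2] / sems[1] - 0.5), 0.1)
})
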