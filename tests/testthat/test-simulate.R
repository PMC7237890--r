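test_that("identical seeds and configs give identical track tables", {
  g <- small_geometry()
  cc <- cohort_config(n_cells = c(track_guided = 6, tzone_walker = 4,
                                  redpulp_arrested = 4, flow_flyer = 2),
                      seed = 9, n_frames = 15)
  expect_identical(simulate_cohort(g, cc), simulate_cohort(g, cc))
})

test_that("adding cells does not perturb existing trajectories", {
  g <- small_geometry()
  c1 <- cohort_config(n_cells = c(track_guided = 5), seed = 9, n_frames = 12)
  c2 <- cohort_config(n_cells = c(track_guided = 8), seed = 9, n_frames = 12)
  t1 <- simulate_cohort(g, c1)
  t2 <- simulate_cohort(g, c2)
  expect_identical(t1, t2[t2$cell_id <= 5, ])
})

test_that("fully biased noiseless cells approach the T zone monotonically", {
  g <- straight_geometry()
  p <- agent_params("track_guided", bias_q = 1, sigma_lateral = 0,
                    speed_sd = 0)
  cc <- cohort_config(n_cells = c(track_guided = 10),
                      params = list(track_guided = p),
                      seed = 4, n_frames = 25)
  tt <- simulate_cohort(g, cc)
  for (tr in split(tt, tt$cell_id)) {
    d <- sqrt((tr$x_um - g$t_zone_center[1])^2 +
              (tr$y_um - g$t_zone_center[2])^2)
    expect_true(all(diff(d) <= 1e-9))
  }
})

test_that("zero-speed cells are stationary", {
  g <- small_geometry()
  p <- agent_params("track_guided", speed_mean = 0, speed_sd = 0,
                    sigma_lateral = 0)
  cc <- cohort_config(n_cells = c(track_guided = 5),
                      params = list(track_guided = p), seed = 2, n_frames = 10)
  tt <- simulate_cohort(g, cc)
  for (tr in split(tt, tt$cell_id)) {
    expect_equal(diff(range(tr$x_um)), 0)
    expect_equal(diff(range(tr$y_um)), 0)
  }
})

test_that("biased-walk end positions match the binomial oracle", {
  ## with sigma = 0 and constant speed, the sign of the net arc change is a
  ## (q, 1-q) +/-1 walk; oracle: P(#toward >= 21 of 40) from the binomial law
  g <- straight_geometry()
  q <- 0.8; nf <- 41; n_cells <- 10000
  p <- agent_params("track_guided", bias_q = q, sigma_lateral = 0,
                    speed_sd = 0)
  cc <- cohort_config(n_cells = c(track_guided = n_cells),
                      params = list(track_guided = p), seed = 21,
                      n_frames = nf)
  tt <- simulate_cohort(g, cc)
  d_of <- function(x, y) sqrt((x - g$t_zone_center[1])^2 +
                              (y - g$t_zone_center[2])^2)
  nearer <- vapply(split(tt, tt$cell_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    d_of(tr$x_um[n], tr$y_um[n]) < d_of(tr$x_um[1], tr$y_um[1]) - 1e-9
  }, TRUE)
  p_oracle <- 1 - pbinom(20, 40, q)     # strict majority of 40 steps toward
  se <- sqrt(p_oracle * (1 - p_oracle) / n_cells)
  expect_lt(abs(mean(nearer) - p_oracle), 4 * se)
})

test_that("per-step displacement recovers the programmed speed within 2%", {
  g <- straight_geometry()
  cc <- cohort_config(n_cells = c(track_guided = 250), seed = 31,
                      n_frames = 41)
  tt <- simulate_cohort(g, cc)
  tg <- tt[tt$behavior == "track_guided", ]
  steps <- unlist(lapply(split(tg, tg$cell_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    keep <- diff(tr$frame) == 1            # consecutive track-guided frames
    sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)[keep]
  }))
  expect_gte(length(steps), 1e4)
  v <- mean(steps) / (20 / 60)
  expect_lt(abs(v - 10) / 10, 0.02)
})

test_that("presets transform parameters and behaviours as specified", {
  base <- c(track_guided = 10)
  ## integrin_block halves the programmed speed exactly (parameter contract)
  cb <- cohort_config(n_cells = base, preset = "integrin_block")
  expect_identical(perivax:::apply_preset(cb)$params$track_guided$speed_mean,
                   0.5 * agent_params("track_guided")$speed_mean)
  ## ptx arrests every transferred cell
  cp <- cohort_config(n_cells = c(track_guided = 6, tzone_walker = 4),
                      preset = "ptx")
  expect_true(all(perivax:::apply_preset(cp)$behaviors == "redpulp_arrested"))
  ## ccr7_ko removes the bias and bars T-zone entry
  ck <- cohort_config(n_cells = base, preset = "ccr7_ko")
  pk <- perivax:::apply_preset(ck)$params$track_guided
  expect_equal(pk$bias_q, 0.5)
  expect_true(isTRUE(pk$no_tzone_entry))
  expect_error(cohort_config(n_cells = c(nonsense = 3)), "unknown behavior")
})

test_that("ccr7_ko cells never enter the T zone", {
  g <- straight_geometry()
  cc <- cohort_config(n_cells = c(track_guided = 40), preset = "ccr7_ko",
                      seed = 17, n_frames = 60)
  tt <- simulate_cohort(g, cc)
  d <- sqrt((tt$x_um - g$t_zone_center[1])^2 +
            (tt$y_um - g$t_zone_center[2])^2)
  expect_true(all(d >= g$t_zone_radius - 1e-6))
})

test_that("lps detaches roughly detach_prob of track-guided cells", {
  g <- straight_geometry()
  n <- 400
  cc <- cohort_config(n_cells = c(track_guided = n), preset = "lps",
                      seed = 23, n_frames = 10)
  tt <- simulate_cohort(g, cc)
  first <- tt[tt$frame == 0, ]
  frac <- mean(first$behavior == "redpulp_arrested")
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), 4 * se)
})

test_that("unbiased cohorts show no net radial drift (symmetry null)", {
  g <- straight_geometry()
  p <- agent_params("track_guided", bias_q = 0.5)
  cc <- cohort_config(n_cells = c(track_guided = 10000),
                      params = list(track_guided = p), seed = 41,
                      n_frames = 21)
  tt <- simulate_cohort(g, cc)
  d_of <- function(x, y) sqrt((x - g$t_zone_center[1])^2 +
                              (y - g$t_zone_center[2])^2)
  delta <- vapply(split(tt, tt$cell_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    d_of(tr$x_um[n], tr$y_um[n]) - d_of(tr$x_um[1], tr$y_um[1])
  }, 0)
  sem <- sd(delta) / sqrt(length(delta))
  expect_lt(abs(mean(delta)), 3 * sem)
})
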