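## Agent-based model of T cell migration in the splenic red pulp / white pulp.
## Four behaviours reproduce the phenotypes seen by intravital imaging:
##   track_guided     - latched to a perivascular track polyline, stepping toward
##                      the T zone with probability bias_q per frame
##   tzone_walker     - persistent random walk confined to the T-zone disc
##   redpulp_arrested - rounded, immotile, with occasional fast linear
##                      blood-flow displacements
##   flow_flyer       - very fast intravascular objects crossing the field
## plus "isotropic": track-confined cells with uniformly random step direction,
## used as the null (no-directionality) calibration condition.
##
## Every per-frame step has total length speed * dt exactly; for track-guided
## cells that length is split between a lateral innovation (sd sigma_lateral,
## reflected at the track half-width) and the along-track arc component whose
## sign is Bernoulli(bias_q). This keeps the realized per-step displacement
## equal to the programmed speed, so image-derived speed estimates can be
## compared directly against cohort parameters.

#' Behavioural parameters for one agent class
#'
#' @param behavior one of \code{"track_guided"}, \code{"tzone_walker"},
#'   \code{"redpulp_arrested"}, \code{"flow_flyer"}, \code{"isotropic"}.
#' @param speed_mean,speed_sd per-frame speed draw, um/min (truncated at 0).
#' @param bias_q probability per step of stepping toward the T zone along the
#'   track polyline (track_guided only).
#' @param sigma_lateral sd of the per-step lateral jitter, um (track_guided).
#' @param persistence directional correlation per step in [0, 1]
#'   (tzone_walker); 1 = ballistic, 0 = uncorrelated.
#' @param flow_event_rate rate of fast flow displacements, events/min
#'   (redpulp_arrested).
#' @param flow_speed speed of a flow displacement, um/min.
#' @param jitter_sd residual positional jitter of arrested cells, um/frame.
#' @param detach_prob probability of permanent detachment from a track at
#'   preset onset (used by the lps preset).
#' @return a list of class \code{perivax_agent_params}.
#' @export
agent_params <- function(behavior = c("track_guided", "tzone_walker",
                                      "redpulp_arrested", "flow_flyer",
                                      "isotropic"),
                         speed_mean = NULL, speed_sd = NULL,
                         bias_q = 0.95, sigma_lateral = 2,
                         persistence = 0.6,
                         flow_event_rate = 0.2, flow_speed = 300,
                         jitter_sd = 0.3,
                         detach_prob = 0.5) {
  behavior <- match.arg(behavior)
  if (is.null(speed_mean))
    speed_mean <- switch(behavior, track_guided = 10, tzone_walker = 10,
                         redpulp_arrested = 0, flow_flyer = 600,
                         isotropic = 10)
  if (is.null(speed_sd))
    speed_sd <- switch(behavior, track_guided = 2, tzone_walker = 2,
                       redpulp_arrested = 0, flow_flyer = 50, isotropic = 2)
  stopifnot(bias_q >= 0, bias_q <= 1, speed_mean >= 0, speed_sd >= 0,
            persistence >= 0, persistence <= 1, detach_prob >= 0,
            detach_prob <= 1)
  structure(list(behavior = behavior, speed_mean = speed_mean,
                 speed_sd = speed_sd, bias_q = bias_q,
                 sigma_lateral = sigma_lateral, persistence = persistence,
                 flow_event_rate = flow_event_rate, flow_speed = flow_speed,
                 jitter_sd = jitter_sd, detach_prob = detach_prob),
            class = "perivax_agent_params")
}

#' Cohort configuration
#'
#' Bundles agent counts, behavioural parameters, a perturbation preset, and
#' acquisition settings for one simulated animal/imaging session.
#'
#' Presets encode the experimental perturbations:
#' \describe{
#'   \item{control}{parameters as given.}
#'   \item{ccr7_ko}{track-guided cells lose chemotactic bias (bias_q = 0.5)
#'     and cannot enter the T zone (reflected at the track end).}
#'   \item{ptx}{pertussis toxin: all transferred cells are arrested in the
#'     red pulp.}
#'   \item{integrin_block}{LFA-1/VLA-4 blockade: motile speeds halved.}
#'   \item{lps}{inflammation: bias_q = 0.5 and each track-guided cell detaches
#'     permanently with probability \code{detach_prob} at onset, becoming
#'     red-pulp arrested.}
#' }
#'
#' @param n_cells named integer vector of cells per behaviour, e.g.
#'   \code{c(track_guided = 60)}.
#' @param params named list of \code{\link{agent_params}} overrides per
#'   behaviour; defaults are filled in for behaviours not listed.
#' @param preset perturbation preset name.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames.
#' @param seed integer seed for the cohort's random stream.
#' @param cohort label for this cohort (also used as the animal id).
#' @return a list of class \code{perivax_cohort_config}.
#' @export
cohort_config <- function(n_cells = c(track_guided = 40, tzone_walker = 30,
                                      redpulp_arrested = 30, flow_flyer = 3),
                          params = list(),
                          preset = c("control", "ccr7_ko", "ptx",
                                     "integrin_block", "lps"),
                          n_frames = 30, frame_interval = 20,
                          seed = 1L, cohort = "animal1") {
  preset <- match.arg(preset)
  stopifnot(n_frames >= 2, frame_interval > 0, length(n_cells) >= 1,
            !is.null(names(n_cells)))
  known <- c("track_guided", "tzone_walker", "redpulp_arrested",
             "flow_flyer", "isotropic")
  if (!all(names(n_cells) %in% known))
    stop("unknown behavior in n_cells: ",
         paste(setdiff(names(n_cells), known), collapse = ", "), call. = FALSE)
  full <- list()
  for (b in names(n_cells)) {
    full[[b]] <- if (!is.null(params[[b]])) params[[b]] else
      agent_params(behavior = b)
    stopifnot(inherits(full[[b]], "perivax_agent_params"))
  }
  structure(list(n_cells = n_cells, params = full, preset = preset,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed),
                 cohort = cohort),
            class = "perivax_cohort_config")
}

## preset transformations applied to the (behaviour -> params) assignment of
## individual cells; returns per-cell behaviour and params after onset
apply_preset <- function(config) {
  behaviors <- rep(names(config$n_cells), times = config$n_cells)
  params <- config$params
  assigned <- behaviors
  extra <- list()
  switch(config$preset,
    control = NULL,
    ccr7_ko = {
      if (!is.null(params$track_guided)) {
        params$track_guided$bias_q <- 0.5
        params$track_guided$no_tzone_entry <- TRUE
      }
    },
    ptx = {
      assigned[] <- "redpulp_arrested"
      if (is.null(params$redpulp_arrested))
        params$redpulp_arrested <- agent_params("redpulp_arrested")
    },
    integrin_block = {
      for (b in intersect(names(params),
                          c("track_guided", "tzone_walker", "isotropic")))
        params[[b]]$speed_mean <- params[[b]]$speed_mean * 0.5
    },
    lps = {
      if (!is.null(params$track_guided)) {
        params$track_guided$bias_q <- 0.5
        extra$detach_prob <- params$track_guided$detach_prob
      }
      if (is.null(params$redpulp_arrested))
        params$redpulp_arrested <- agent_params("redpulp_arrested")
    })
  list(behaviors = assigned, params = params, extra = extra)
}

#' Simulate one cohort of migrating cells
#'
#' Runs the agent-based migration model over \code{n_frames} frames and
#' returns a long-format ground-truth track table.
#'
#' @param geometry a \code{\link{build_geometry}} result.
#' @param config a \code{\link{cohort_config}}.
#' @return a \code{data.frame} (the track table) with columns
#'   \code{cell_id}, \code{frame} (0-based), \code{t_s}, \code{x_um},
#'   \code{y_um}, \code{cohort}, \code{behavior}, \code{compartment}.
#' @export
simulate_cohort <- function(geometry, config) {
  stopifnot(inherits(geometry, "perivax_geometry"),
            inherits(config, "perivax_cohort_config"))
  pre <- apply_preset(config)
  n <- length(pre$behaviors)
  dt_min <- config$frame_interval / 60
  nf <- config$n_frames

  out <- vector("list", n)
  for (i in seq_len(n)) {
    b <- pre$behaviors[i]
    p <- pre$params[[b]]
    cs <- cell_seed(config$seed, i)
    old <- local_seed(cs)
    ## lps detachment decided first in the cell's substream so trajectories of
    ## non-detached cells are unchanged relative to control order
    if (config$preset == "lps" && b == "track_guided" &&
        runif(1) < pre$extra$detach_prob) {
      traj <- sim_detached_on_track(geometry, pre$params, i, nf, dt_min)
      b_lab <- rep("redpulp_arrested", nf)
    } else {
      r <- switch(b,
        track_guided = sim_track_guided(geometry, p, i, nf, dt_min),
        tzone_walker = list(pos = sim_tzone_walker(geometry, p, nf, dt_min),
                            behavior = rep("tzone_walker", nf)),
        redpulp_arrested = list(pos = sim_arrested(geometry, p, nf, dt_min),
                                behavior = rep("redpulp_arrested", nf)),
        flow_flyer = list(pos = sim_flyer(geometry, p, nf, dt_min),
                          behavior = rep("flow_flyer", nf)),
        isotropic = list(pos = sim_isotropic(geometry, p, i, nf, dt_min),
                         behavior = rep("isotropic", nf)))
      traj <- r$pos
      b_lab <- r$behavior
    }
    restore_seed(old)
    out[[i]] <- data.frame(
      cell_id = i,
      frame = seq_len(nf) - 1L,
      t_s = (seq_len(nf) - 1L) * config$frame_interval,
      x_um = traj[, 1], y_um = traj[, 2],
      cohort = config$cohort,
      behavior = b_lab,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$compartment <- label_compartment(cbind(tab$x_um, tab$y_um), geometry)
  rownames(tab) <- NULL
  tab
}

## substream per cell: adding cells never perturbs earlier trajectories
cell_seed <- function(seed, cell_id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(cell_id) * 7919) %%
               2147483647)
}

trunc_speed <- function(n, mean, sd) pmax(rnorm(n, mean, sd), 0)

## ---- track-guided cells -----------------------------------------------------

sim_track_guided <- function(geometry, p, cell_index, nf, dt_min) {
  k <- ((cell_index - 1L) %% length(geometry$tracks)) + 1L
  poly <- geometry$tracks[[k]]
  cs <- arc_lengths(poly)
  L <- cs[length(cs)]
  hw <- geometry$track_half_width
  no_entry <- isTRUE(p$no_tzone_entry)

  s <- runif(1, 0.05, 0.60) * L          # start in the distal/red-pulp reach
  l <- reflect_interval(rnorm(1, 0, p$sigma_lateral), -hw, hw)
  pos <- matrix(NA_real_, nf, 2)
  beh <- character(nf)
  walker_state <- NULL                   # set once the cell enters the T zone

  speeds <- trunc_speed(nf, p$speed_mean, p$speed_sd)
  for (t in seq_len(nf)) {
    if (is.null(walker_state)) {
      pp <- polyline_point(poly, s, cs)
      nrm <- c(-pp$tangent[1, 2], pp$tangent[1, 1])
      pos[t, ] <- pp$point[1, ] + nrm * l
      beh[t] <- "track_guided"
    } else {
      pos[t, ] <- walker_state$pos
      beh[t] <- "tzone_walker"
    }
    if (t == nf) break
    step <- speeds[t] * dt_min
    if (is.null(walker_state)) {
      dl <- rnorm(1, 0, p$sigma_lateral)
      dl <- sign(dl) * min(abs(dl), step)
      arc <- sqrt(max(step^2 - dl^2, 0))
      dir <- if (runif(1) < p$bias_q) 1 else -1   # +1 = toward the T zone
      s <- s + dir * arc
      l <- reflect_interval(l + dl, -hw, hw)
      if (s < 0) s <- -s                          # distal end reflects
      if (s > L) {
        if (no_entry) {
          s <- 2 * L - s                          # barred from the T zone
        } else {
          ## crossed into the T zone: continue as a persistent walker
          pp <- polyline_point(poly, L, cs)
          walker_state <- list(pos = pp$point[1, ],
                               heading = atan2(pp$tangent[1, 2],
                                               pp$tangent[1, 1]))
          s <- L
        }
      }
    } else {
      walker_state <- tzone_walk_step(walker_state, geometry, p, step)
    }
  }
  list(pos = pos, behavior = beh)
}

## track-guided cell that detached at lps onset: arrested at its track position
sim_detached_on_track <- function(geometry, params, cell_index, nf, dt_min) {
  k <- ((cell_index - 1L) %% length(geometry$tracks)) + 1L
  poly <- geometry$tracks[[k]]
  L <- max(arc_lengths(poly))
  tg <- params$track_guided
  s <- runif(1, 0.05, 0.60) * L
  hw <- geometry$track_half_width
  l <- reflect_interval(rnorm(1, 0, tg$sigma_lateral), -hw, hw)
  pp <- polyline_point(poly, s)
  nrm <- c(-pp$tangent[1, 2], pp$tangent[1, 1])
  origin <- pp$point[1, ] + nrm * l
  ap <- if (!is.null(params$redpulp_arrested)) params$redpulp_arrested else
    agent_params("redpulp_arrested")
  jit <- matrix(rnorm(nf * 2, 0, ap$jitter_sd), nf, 2)
  jit[1, ] <- 0
  sweep(jit, 2, origin, `+`)
}

## ---- T-zone persistent random walk -----------------------------------------

tzone_walk_step <- function(state, geometry, p, step) {
  turn_sd <- (1 - p$persistence) * pi
  heading <- state$heading + rnorm(1, 0, turn_sd)
  prop <- state$pos + step * c(cos(heading), sin(heading))
  d <- prop - geometry$t_zone_center
  r <- sqrt(sum(d^2))
  if (r > geometry$t_zone_radius) {
    ## fold the radial excess back inside and head inward
    r_new <- max(2 * geometry$t_zone_radius - r, 0)
    prop <- geometry$t_zone_center + d / r * r_new
    heading <- atan2(-d[2], -d[1]) + rnorm(1, 0, 0.5)
  }
  list(pos = prop, heading = heading)
}

sim_tzone_walker <- function(geometry, p, nf, dt_min) {
  r0 <- geometry$t_zone_radius * sqrt(runif(1))
  a0 <- runif(1, 0, 2 * pi)
  state <- list(pos = geometry$t_zone_center + r0 * c(cos(a0), sin(a0)),
                heading = runif(1, 0, 2 * pi))
  pos <- matrix(NA_real_, nf, 2)
  speeds <- trunc_speed(nf, p$speed_mean, p$speed_sd)
  for (t in seq_len(nf)) {
    pos[t, ] <- state$pos
    if (t < nf) state <- tzone_walk_step(state, geometry, p, speeds[t] * dt_min)
  }
  pos
}

## ---- arrested red-pulp cells ------------------------------------------------

sim_arrested <- function(geometry, p, nf, dt_min) {
  pos0 <- sample_redpulp_point(geometry)
  pos <- matrix(NA_real_, nf, 2)
  pos[1, ] <- pos0
  cur <- pos0
  for (t in seq_len(nf - 1)) {
    if (runif(1) < p$flow_event_rate * dt_min) {
      ## caught in blood flow: one sharp linear displacement
      ang <- runif(1, 0, 2 * pi)
      cur <- cur + p$flow_speed * dt_min * c(cos(ang), sin(ang))
    } else {
      cur <- cur + rnorm(2, 0, p$jitter_sd)
    }
    cur <- pmin(pmax(cur, 1), geometry$field_size - 1)
    pos[t + 1, ] <- cur
  }
  pos
}

sample_redpulp_point <- function(geometry, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    pt <- runif(2) * geometry$field_size
    if (label_compartment(pt, geometry) == "redpulp") return(pt)
  }
  stop("could not place a red-pulp cell; geometry leaves no red pulp")
}

## ---- intravascular flyers ---------------------------------------------------

sim_flyer <- function(geometry, p, nf, dt_min) {
  cur <- runif(2) * geometry$field_size
  heading <- runif(1, 0, 2 * pi)
  v <- trunc_speed(1, p$speed_mean, p$speed_sd)
  pos <- matrix(NA_real_, nf, 2)
  for (t in seq_len(nf)) {
    pos[t, ] <- cur
    if (t == nf) break
    prop <- cur + v * dt_min * c(cos(heading), sin(heading))
    ## reflect off field edges
    if (prop[1] < 0 || prop[1] > geometry$field_size[1]) {
      prop[1] <- reflect_interval(prop[1], 0, geometry$field_size[1])
      heading <- pi - heading
    }
    if (prop[2] < 0 || prop[2] > geometry$field_size[2]) {
      prop[2] <- reflect_interval(prop[2], 0, geometry$field_size[2])
      heading <- -heading
    }
    cur <- pmin(pmax(prop, 0), geometry$field_size)
    pos[t + 1, ] <- cur
  }
  pos
}

## ---- isotropic null cells (track-confined, no directional bias) ------------

sim_isotropic <- function(geometry, p, cell_index, nf, dt_min, max_tries = 20) {
  k <- ((cell_index - 1L) %% length(geometry$tracks)) + 1L
  poly <- geometry$tracks[[k]]
  L <- max(arc_lengths(poly))
  hw <- geometry$track_half_width
  s0 <- runif(1, 0.02, 0.98) * L
  pp <- polyline_point(poly, s0)
  nrm <- c(-pp$tangent[1, 2], pp$tangent[1, 1])
  cur <- pp$point[1, ] + nrm * reflect_interval(rnorm(1, 0, hw / 2), -hw, hw)
  pos <- matrix(NA_real_, nf, 2)
  speeds <- trunc_speed(nf, p$speed_mean, p$speed_sd)
  for (t in seq_len(nf)) {
    pos[t, ] <- cur
    if (t == nf) break
    step <- speeds[t] * dt_min
    for (try in seq_len(max_tries)) {
      ang <- runif(1, 0, 2 * pi)
      prop <- cur + step * c(cos(ang), sin(ang))
      if (dist_to_polyline(prop, poly) <= hw) { cur <- prop; break }
    }
    pos[t + 1, ] <- cur
  }
  pos
}

## reflect a scalar into [lo, hi]
reflect_interval <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}
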