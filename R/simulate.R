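#' Roadblock on a DNA substrate
#'
#' A protein obstacle (nucleosome, catalytically dead restriction enzyme, or
#' another diffusing protein) at a fixed position on the DNA. Sliding motion
#' always reflects at a roadblock; only hop landings may cross it, with
#' probability `permeability`. The collision zone used by the event classifier
#' is `position_bp` +/- `zone_halfwidth_bp`; the default halfwidth of 375 bp
#' makes the zone 750 bp wide, i.e. three times the 250 bp localization s.d.
#'
#' @param id Identifier (string or integer).
#' @param position_bp Position on the DNA in bp.
#' @param kind One of `"nucleosome"`, `"restriction-enzyme"`, `"protein"`,
#'   `"other"`.
#' @param permeability Probability that a hop landing beyond the roadblock is
#'   accepted (0 = fully reflecting).
#' @param zone_halfwidth_bp Collision-zone halfwidth in bp.
#' @param axis_id DNA axis the roadblock sits on (for multi-DNA scenes).
#' @return An object of class `roadblock`.
#' @export
roadblock <- function(id, position_bp, kind = "nucleosome", permeability = 0,
                      zone_halfwidth_bp = 375, axis_id = 1L) {
  kind <- match.arg(kind, c("nucleosome", "restriction-enzyme", "protein", "other"))
  if (position_bp < 0) stop("roadblock position_bp must be >= 0")
  if (permeability < 0 || permeability > 1) stop("permeability must be in [0, 1]")
  if (zone_halfwidth_bp <= 0) stop("zone_halfwidth_bp must be positive")
  structure(list(id = id, position_bp = as.numeric(position_bp), kind = kind,
                 permeability = permeability,
                 zone_halfwidth_bp = as.numeric(zone_halfwidth_bp),
                 axis_id = as.integer(axis_id)),
            class = "roadblock")
}

#' Lesion capture site
#'
#' A specific binding site (e.g. a 3'-ssDNA flap 20 kb from the tethered end).
#' When the simulated molecule visits within `capture_radius_bp` of the site it
#' is captured with probability `p_capture_per_visit` per frame; capture
#' freezes the position for the rest of the movie.
#'
#' @param position_bp Site position (bp); default 20,000.
#' @param capture_radius_bp Capture radius (bp).
#' @param p_capture_per_visit Capture probability per visited frame.
#' @return An object of class `lesion_site`.
#' @export
lesion_site <- function(position_bp = 20000, capture_radius_bp = 150,
                        p_capture_per_visit = 1) {
  if (position_bp < 0) stop("lesion position_bp must be >= 0")
  if (capture_radius_bp <= 0) stop("capture_radius_bp must be positive")
  if (p_capture_per_visit < 0 || p_capture_per_visit > 1)
    stop("p_capture_per_visit must be in [0, 1]")
  structure(list(position_bp = as.numeric(position_bp),
                 capture_radius_bp = as.numeric(capture_radius_bp),
                 p_capture_per_visit = p_capture_per_visit),
            class = "lesion_site")
}

#' Configuration of the sliding + hopping simulator
#'
#' Parametrizes 1D facilitated diffusion as continuous Brownian sliding
#' (diffusion coefficient `d_slide_um2_s`) interrupted by Poissonian
#' micro-dissociation events ("hops") at `hop_rate_per_s`. A hop relocates the
#' molecule by a Normal(0, `hop_sigma_bp`) displacement that, unlike sliding,
#' may cross roadblocks; each hop escapes into solution with probability
#' `p_escape_per_hop`. Hops are treated as instantaneous relative to the
#' 200 ms frame. Quantum-dot blinking is a two-state telegraph process.
#'
#' The hop excursion length and rate are free simulator parameters, not
#' quantities estimated from data.
#'
#' @param d_slide_um2_s Sliding diffusion coefficient (um^2/s).
#' @param hop_rate_per_s Poisson rate of hops (1/s).
#' @param hop_sigma_bp S.d. of the landing displacement per hop (bp).
#' @param p_escape_per_hop Probability a hop becomes macroscopic dissociation.
#' @param t_half_s Macroscopic half-life (s); if finite, spontaneous
#'   dissociation occurs at rate ln(2)/`t_half_s` independently of hops.
#' @param roadblocks List of [roadblock()] objects.
#' @param lesion Optional [lesion_site()].
#' @param blink_off_rate_per_s,blink_on_rate_per_s Telegraph rates into and out
#'   of the fluorophore dark state (1/s); 0 off-rate disables blinking.
#' @param loc_sigma_bp Localization noise s.d. (bp); default 250 bp so that
#'   3 s.d. equals the 750 bp collision zone.
#' @param frame_interval_s Frame interval (s); default 0.2.
#' @param n_frames Number of frames in the movie.
#' @param start_bp Initial position (bp); default mid-DNA.
#' @param end_open Length-2 logical: is the (left, right) DNA end open so the
#'   molecule can slide off (single-tether mode)? Default both closed.
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(d_slide_um2_s = 0.03, hop_rate_per_s = 0,
                       hop_sigma_bp = 1000, p_escape_per_hop = 0,
                       t_half_s = Inf, roadblocks = list(), lesion = NULL,
                       blink_off_rate_per_s = 0, blink_on_rate_per_s = 2,
                       loc_sigma_bp = 250, frame_interval_s = 0.2,
                       n_frames = 300L, start_bp = NULL,
                       end_open = c(FALSE, FALSE), seed = NULL) {
  if (d_slide_um2_s < 0) stop("d_slide_um2_s must be >= 0")
  if (hop_rate_per_s < 0) stop("hop_rate_per_s must be >= 0")
  if (hop_sigma_bp < 0) stop("hop_sigma_bp must be >= 0")
  if (p_escape_per_hop < 0 || p_escape_per_hop > 1)
    stop("p_escape_per_hop must be in [0, 1]")
  if (t_half_s <= 0) stop("t_half_s must be positive")
  if (blink_off_rate_per_s < 0 || blink_on_rate_per_s < 0)
    stop("blink rates must be >= 0")
  if (loc_sigma_bp < 0) stop("loc_sigma_bp must be >= 0")
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(lesion) && !inherits(lesion, "lesion_site"))
    stop("lesion must be a lesion_site or NULL")
  for (rb in roadblocks) {
    if (!inherits(rb, "roadblock")) stop("roadblocks must be roadblock objects")
  }
  if (length(end_open) != 2) stop("end_open must have length 2")
  structure(list(d_slide_um2_s = d_slide_um2_s, hop_rate_per_s = hop_rate_per_s,
                 hop_sigma_bp = hop_sigma_bp, p_escape_per_hop = p_escape_per_hop,
                 t_half_s = t_half_s, roadblocks = roadblocks, lesion = lesion,
                 blink_off_rate_per_s = blink_off_rate_per_s,
                 blink_on_rate_per_s = blink_on_rate_per_s,
                 loc_sigma_bp = loc_sigma_bp, frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames), start_bp = start_bp,
                 end_open = as.logical(end_open), seed = seed),
            class = "sim_config")
}

# Fold a proposed position into [lo, hi] by specular reflection.
.reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(lo)
  y <- (x - lo) %% (2 * w)
  if (y > w) y <- 2 * w - y
  lo + y
}

# Core frame-stepping engine shared by simulate_trajectory() and
# make_two_dna_scene(). Returns a ground_truth object. axes_um is NULL for a
# single-DNA scene, otherwise the lateral positions of the parallel DNA axes.
.sim_core <- function(config, geometry, axes_um = NULL, transfer_p = 0,
                      start_axis = 1L) {
  cfg <- config
  geom <- geometry
  L <- geom$length_bp
  dt <- cfg$frame_interval_s
  n <- cfg$n_frames
  bp_per_um <- L / geom$tether_span_um

  if (!is.null(cfg$lesion) && cfg$lesion$position_bp > L)
    stop("lesion position is outside the DNA")
  for (rb in cfg$roadblocks) {
    if (rb$position_bp > L) stop("roadblock position is outside the DNA")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  sigma_step_bp <- sqrt(2 * cfg$d_slide_um2_s * dt) * bp_per_um
  p_spont <- if (is.finite(cfg$t_half_s)) 1 - exp(-log(2) / cfg$t_half_s * dt) else 0
  rb_pos <- vapply(cfg$roadblocks, function(r) r$position_bp, numeric(1))
  rb_perm <- vapply(cfg$roadblocks, function(r) r$permeability, numeric(1))
  rb_ids <- lapply(cfg$roadblocks, function(r) r$id)

  pos <- numeric(n); pos[] <- NA_real_
  state <- character(n)
  axis <- integer(n); axis[] <- NA_integer_
  pos[1] <- if (is.null(cfg$start_bp)) L / 2 else cfg$start_bp
  if (pos[1] < 0 || pos[1] > L) stop("start_bp outside the DNA")
  axis[1] <- start_axis

  log_rb <- list(); n_log <- 0L
  log_tx <- list(); n_tx <- 0L
  dark <- FALSE
  state[1] <- "sliding"
  alive <- TRUE
  captured <- FALSE
  exit_mode <- "none"
  cur <- pos[1]
  cur_axis <- start_axis
  p_off <- 1 - exp(-cfg$blink_off_rate_per_s * dt)
  p_on <- 1 - exp(-cfg$blink_on_rate_per_s * dt)

  # Walls bounding the compartment that contains x (roadblocks + DNA ends).
  compartment <- function(x, ax) {
    walls <- rb_pos[vapply(cfg$roadblocks, function(r) r$axis_id, 1L) == ax]
    lo <- max(c(0, walls[walls <= x]))
    hi <- min(c(L, walls[walls > x]))
    c(lo, hi)
  }

  # Resolve a hop landing across roadblocks: each roadblock strictly between
  # x0 and the landing is crossed with its permeability, otherwise the
  # remaining path reflects back off it. Every attempt is logged.
  resolve_hop <- function(x0, land, ax, t_now) {
    for (guard in 1:64) {
      on_axis <- vapply(cfg$roadblocks, function(r) r$axis_id, 1L) == ax
      between <- on_axis & ((rb_pos - x0) * (rb_pos - land) < 0)
      if (!any(between)) break
      idx <- which(between)
      # nearest roadblock in the direction of travel
      k <- idx[which.min(abs(rb_pos[idx] - x0))]
      crossed <- stats::runif(1) < rb_perm[k]
      n_log <<- n_log + 1L
      log_rb[[n_log]] <<- list(roadblock_id = rb_ids[[k]], time_s = t_now,
                               crossed = crossed, mode = "hop")
      if (crossed) {
        x0 <- rb_pos[k]
      } else {
        land <- 2 * rb_pos[k] - land
        x0 <- rb_pos[k]
      }
    }
    land
  }

  for (i in 2:max(n, 2)) {
    if (n < 2) break
    if (!alive) { state[i] <- "dissociated"; next }
    if (captured) { pos[i] <- cur; axis[i] <- cur_axis; state[i] <- "captured"; next }

    hopped <- FALSE
    # spontaneous (clamp-opening independent) dissociation
    if (p_spont > 0 && stats::runif(1) < p_spont) {
      alive <- FALSE
      exit_mode <- "spontaneous"
      state[i] <- "dissociated"
      next
    }

    # sliding: Brownian step reflected inside the current compartment
    if (sigma_step_bp > 0) {
      prop <- cur + stats::rnorm(1, 0, sigma_step_bp)
      cp <- compartment(cur, cur_axis)
      # sliding off an open DNA end
      if (prop < 0 && cp[1] == 0 && cfg$end_open[1]) {
        alive <- FALSE; exit_mode <- "slide-off-left"; state[i] <- "dissociated"; next
      }
      if (prop > L && cp[2] == L && cfg$end_open[2]) {
        alive <- FALSE; exit_mode <- "slide-off-right"; state[i] <- "dissociated"; next
      }
      if (prop < cp[1] || prop > cp[2]) {
        # log reflections at roadblock walls (not DNA ends)
        wall <- if (prop < cp[1]) cp[1] else cp[2]
        k <- which(rb_pos == wall)
        if (length(k) == 1) {
          n_log <- n_log + 1L
          log_rb[[n_log]] <- list(roadblock_id = rb_ids[[k]],
                                  time_s = (i - 1) * dt, crossed = FALSE,
                                  mode = "slide")
        }
        prop <- .reflect_into(prop, cp[1], cp[2])
      }
      cur <- prop
    }

    # hops: Poisson number of instantaneous micro-dissociations this frame,
    # resolved at sub-frame times drawn uniformly
    n_hops <- if (cfg$hop_rate_per_s > 0) stats::rpois(1, cfg$hop_rate_per_s * dt) else 0L
    if (n_hops > 0) {
      t_subs <- sort(stats::runif(n_hops, (i - 2) * dt, (i - 1) * dt))
      for (h in seq_len(n_hops)) {
        hopped <- TRUE
        if (stats::runif(1) < cfg$p_escape_per_hop) {
          alive <- FALSE
          exit_mode <- "hop-escape"
          break
        }
        if (!is.null(axes_um) && transfer_p > 0 && stats::runif(1) < transfer_p) {
          new_axis <- if (cur_axis == 1L) 2L else 1L
          n_tx <- n_tx + 1L
          log_tx[[n_tx]] <- list(time_s = t_subs[h], from_axis = cur_axis,
                                 to_axis = new_axis)
          cur_axis <- new_axis
        }
        land <- cur + stats::rnorm(1, 0, cfg$hop_sigma_bp)
        land <- resolve_hop(cur, land, cur_axis, t_subs[h])
        if (land < 0 || land > L) {
          if ((land < 0 && cfg$end_open[1]) || (land > L && cfg$end_open[2])) {
            alive <- FALSE
            exit_mode <- if (land < 0) "slide-off-left" else "slide-off-right"
            break
          }
          land <- .reflect_into(land, 0, L)
        }
        cur <- land
      }
      if (!alive) { state[i] <- "dissociated"; next }
    }

    # lesion capture freezes the position
    if (!is.null(cfg$lesion) && is.null(axes_um)) {
      les <- cfg$lesion
      if (abs(cur - les$position_bp) <= les$capture_radius_bp &&
          stats::runif(1) < les$p_capture_per_visit) {
        captured <- TRUE
      }
    }

    # blinking telegraph process
    if (cfg$blink_off_rate_per_s > 0) {
      dark <- if (dark) stats::runif(1) >= p_on else stats::runif(1) < p_off
    }

    pos[i] <- cur
    axis[i] <- cur_axis
    state[i] <- if (captured) "captured" else if (dark) "dark"
                else if (hopped) "hopping" else "sliding"
  }

  crossing_log <- if (n_log > 0) {
    do.call(rbind, lapply(log_rb, function(e)
      data.frame(roadblock_id = e$roadblock_id, time_s = e$time_s,
                 crossed = e$crossed, mode = e$mode,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(roadblock_id = character(0), time_s = numeric(0),
               crossed = logical(0), mode = character(0),
               stringsAsFactors = FALSE)
  }
  transfers <- if (n_tx > 0) {
    do.call(rbind, lapply(log_tx, function(e)
      data.frame(time_s = e$time_s, from_axis = e$from_axis,
                 to_axis = e$to_axis)))
  } else {
    data.frame(time_s = numeric(0), from_axis = integer(0), to_axis = integer(0))
  }

  structure(list(times_s = (seq_len(n) - 1) * dt,
                 true_positions_bp = pos,
                 state = state,
                 axis = axis,
                 exit_mode = exit_mode,
                 crossing_log = crossing_log,
                 transfers = transfers,
                 config = cfg, geometry = geom, axes_um = axes_um),
            class = "ground_truth")
}

#' Simulate a single ground-truth trajectory
#'
#' Runs the sliding + hopping model on an obstacle/lesion-bearing DNA: Euler
#' Brownian steps at the frame interval with variance 2 D dt (converted between
#' um and bp through the curtain geometry), reflecting boundaries at DNA ends
#' (unless flagged open) and at roadblocks, Poissonian instantaneous hops that
#' may cross roadblocks and may escape into solution, optional lesion capture,
#' and two-state fluorophore blinking. Every roadblock encounter outcome is
#' recorded in `crossing_log`.
#'
#' @param config A [sim_config()].
#' @param geometry A [dna_geometry()].
#' @return An object of class `ground_truth` with fields `times_s`,
#'   `true_positions_bp`, `state` (one of sliding/hopping/captured/
#'   dissociated/dark per frame), `crossing_log`, and the echoed config.
#' @examples
#' gt <- simulate_trajectory(sim_config(n_frames = 100, seed = 1), dna_geometry())
#' table(gt$state)
#' @export
simulate_trajectory <- function(config, geometry) {
  stopifnot(inherits(config, "sim_config"), inherits(geometry, "dna_geometry"))
  .sim_core(config, geometry)
}

#' @export
print.ground_truth <- function(x, ...) {
  alive <- sum(!x$state %in% "dissociated")
  cat(sprintf("ground-truth trajectory: %d frames (%d on DNA), %d roadblock encounters\n",
              length(x$times_s), alive, nrow(x$crossing_log)))
  invisible(x)
}

#' Simulate a population of independent trajectories
#'
#' Per-trajectory RNG streams are derived from `config$seed` by a counter, so
#' trajectory k is identical whether the population has n = k or n = 1000
#' members.
#'
#' @param config A [sim_config()] with a non-`NULL` seed for reproducibility.
#' @param n Number of trajectories (>= 1).
#' @param geometry A [dna_geometry()].
#' @return List of `ground_truth` objects.
#' @export
simulate_population <- function(config, n, geometry) {
  stopifnot(inherits(config, "sim_config"))
  if (n < 1) stop("n must be >= 1")
  base <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  lapply(seq_len(n), function(k) {
    cfg <- config
    cfg$seed <- (base * 48271 + k * 16807) %% 2147483647
    .sim_core(cfg, geometry)
  })
}

#' Simulate exponential dwell times with right censoring
#'
#' Draws on-DNA lifetimes from an exponential with rate ln(2)/`t_half_s` (so
#' the distribution median equals the half-life) and right-censors values at
#' `censor_at_s` (e.g. the movie end).
#'
#' @param t_half_s Half-life (s); may be `Inf` for the no-dissociation limit.
#' @param n Number of molecules.
#' @param censor_at_s Censoring time (s); default `Inf` (no censoring).
#' @param seed RNG seed or `NULL`.
#' @return A data frame with columns `dwell_s` and `censored`.
#' @examples
#' d <- simulate_dwell_times(76, 50, seed = 1)
#' median(d$dwell_s)
#' @export
simulate_dwell_times <- function(t_half_s, n, censor_at_s = Inf, seed = NULL) {
  if (t_half_s <= 0) stop("t_half_s must be positive")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rate <- log(2) / t_half_s
  raw <- if (rate == 0) rep(Inf, n) else stats::rexp(n, rate)
  censored <- raw > censor_at_s
  data.frame(dwell_s = pmin(raw, censor_at_s), censored = censored)
}

#' Simulate a two-DNA transfer scene
#'
#' Two parallel DNA molecules laterally separated by `separation_um` (about
#' 1 um between adjacent pedestals). Each hop relocates the molecule to the
#' neighbouring axis with probability `transfer_p_per_hop`; every transfer is
#' logged with its time in the `transfers` field of each trajectory.
#'
#' @param separation_um Lateral separation between the two DNA axes (um).
#' @param transfer_p_per_hop Per-hop transfer probability in `[0, 1]`.
#' @param config A [sim_config()].
#' @param geometry A [dna_geometry()].
#' @param n Number of molecules; each starts on axis 1.
#' @return List of `ground_truth` objects with per-frame `axis` assignment and
#'   `axes_um` attribute giving the lateral positions of the two axes.
#' @export
make_two_dna_scene <- function(separation_um, transfer_p_per_hop, config,
                               geometry, n = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (separation_um <= 0) stop("separation_um must be positive")
  if (transfer_p_per_hop < 0 || transfer_p_per_hop > 1)
    stop("transfer_p_per_hop must be in [0, 1]")
  axes <- c(0, separation_um)
  base <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  lapply(seq_len(n), function(k) {
    cfg <- config
    cfg$seed <- (base * 48271 + k * 16807) %% 2147483647
    .sim_core(cfg, geometry, axes_um = axes, transfer_p = transfer_p_per_hop)
  })
}

#' Convert a ground-truth trajectory into a measured trajectory table
#'
#' Applies Gaussian localization noise (`config$loc_sigma_bp`) to the true
#' positions and marks dark/dissociated frames as undetected, producing the
#' same table the tracker emits. This is the fast path for estimator-recovery
#' studies that do not need the full render-and-track round trip.
#'
#' @param gt A `ground_truth` object.
#' @param molecule_id Identifier stored in the output.
#' @param seed RNG seed or `NULL`.
#' @return A trajectory data frame (see [write_trajectories()] for the schema).
#' @export
measure_trajectory <- function(gt, molecule_id = 1L, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  geom <- gt$geometry
  n <- length(gt$times_s)
  detected <- gt$state %in% c("sliding", "hopping", "captured")
  noise_bp <- stats::rnorm(n, 0, gt$config$loc_sigma_bp)
  pos_bp <- gt$true_positions_bp + noise_bp
  pos_bp[!detected] <- NA_real_
  out <- data.frame(
    molecule_id = molecule_id,
    dna_axis_id = ifelse(is.na(gt$axis), 1L, gt$axis),
    frame = seq_len(n) - 1L,
    time_s = gt$times_s,
    position_bp = pos_bp,
    position_um = bp_to_um(pos_bp, geom),
    detected = as.integer(detected))
  if (!is.null(gt$axes_um)) {
    # lateral coordinate for multi-DNA scenes, with the same localization noise
    lat <- gt$axes_um[ifelse(is.na(gt$axis), 1L, gt$axis)] +
      stats::rnorm(n, 0, bp_to_um(gt$config$loc_sigma_bp, geom))
    lat[!detected] <- NA_real_
    out$lateral_um <- lat
  }
  out
}
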