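#' Score roadblock collisions and bypass events
#'
#' Implements the operational bypass criteria: (a) the protein is initially
#' diffusing on one side of the roadblock, (b) it transiently co-localizes
#' with the roadblock inside a collision zone (roadblock position +/- the
#' zone halfwidth, 750 bp wide by default = 3 x the 250 bp localization
#' s.d.), and (c) it clearly continues diffusing on the opposite side.
#' "Clearly diffusing on a side" requires at least `min_outside_frames`
#' consecutive detections outside the zone on that side, which keeps
#' localization noise at the zone edge from fabricating crossings. Each
#' maximal zone visit between two such confirmed outside runs is one
#' collision: a `bypass` when the sides differ, a `same-side-return`
#' otherwise, and `unresolved-at-track-end` when the track ends in the zone.
#' Two confirmed runs on opposite sides with no intervening detection count
#' as a bypass too (a fast track can span the whole zone within one frame).
#'
#' @param track Trajectory data frame with `time_s` and `position_bp` (or
#'   `position_um` plus `geometry`); undetected rows are ignored.
#' @param roadblocks List of [roadblock()] objects (or a single one).
#' @param geometry Optional [dna_geometry()] for um-to-bp conversion and
#'   clipping zones at DNA ends.
#' @param min_outside_frames Consecutive outside detections required to
#'   confirm which side the protein is diffusing on.
#' @return Data frame of class `collision_events`: `molecule_id`,
#'   `roadblock_id`, `entry_time_s`, `entry_side`, `exit_time_s`,
#'   `exit_side`, `outcome`.
#' @export
score_collisions <- function(track, roadblocks, geometry = NULL,
                             min_outside_frames = 3L) {
  if (inherits(roadblocks, "roadblock")) roadblocks <- list(roadblocks)
  det <- if ("detected" %in% names(track)) track$detected == 1 else rep(TRUE, nrow(track))
  pos <- if ("position_bp" %in% names(track)) track$position_bp
         else if (!is.null(geometry)) um_to_bp(track$position_um, geometry)
         else stop("track needs position_bp, or position_um with a geometry")
  tt <- track$time_s[det & !is.na(pos)]
  pos <- pos[det & !is.na(pos)]
  mol <- if ("molecule_id" %in% names(track)) track$molecule_id[1] else NA
  empty <- data.frame(molecule_id = mol[0], roadblock_id = character(0),
                      entry_time_s = numeric(0), entry_side = character(0),
                      exit_time_s = numeric(0), exit_side = character(0),
                      outcome = character(0), stringsAsFactors = FALSE)
  if (length(pos) < 2) return(structure(empty, class = c("collision_events", "data.frame")))

  out <- list()
  for (rb in roadblocks) {
    lo <- rb$position_bp - rb$zone_halfwidth_bp
    hi <- rb$position_bp + rb$zone_halfwidth_bp
    if (!is.null(geometry) && (lo < 0 || hi > geometry$length_bp)) {
      warning(sprintf("collision zone of roadblock %s clipped at a DNA end", rb$id))
      lo <- max(lo, 0); hi <- min(hi, geometry$length_bp)
    }
    # -1 left of zone, +1 right of zone, 0 inside; short outside runs are
    # demoted to "unconfirmed" so they cannot establish a side on their own
    side <- ifelse(pos < lo, -1L, ifelse(pos > hi, 1L, 0L))
    r <- rle(side)
    confirmed <- r$values != 0L & r$lengths >= min_outside_frames
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    conf_idx <- which(confirmed)
    if (length(conf_idx) >= 1) {
      for (k in seq_len(length(conf_idx) - 1)) {
        a <- conf_idx[k]; b <- conf_idx[k + 1]
        gap_runs <- if (b > a + 1) (a + 1):(b - 1) else integer(0)
        zone_contact <- length(gap_runs) > 0 && any(r$values[gap_runs] == 0L)
        sides_differ <- r$values[a] != r$values[b]
        if (!zone_contact && !sides_differ) next   # no collision
        out[[length(out) + 1L]] <- data.frame(
          molecule_id = mol, roadblock_id = as.character(rb$id),
          entry_time_s = tt[run_end[a]], entry_side = .side_name(r$values[a]),
          exit_time_s = tt[run_start[b]], exit_side = .side_name(r$values[b]),
          outcome = if (sides_differ) "bypass" else "same-side-return",
          stringsAsFactors = FALSE)
      }
      # track ending with zone contact after the last confirmed run
      last <- conf_idx[length(conf_idx)]
      if (last < length(r$values) && any(r$values[(last + 1):length(r$values)] == 0L)) {
        out[[length(out) + 1L]] <- data.frame(
          molecule_id = mol, roadblock_id = as.character(rb$id),
          entry_time_s = tt[run_end[last]], entry_side = .side_name(r$values[last]),
          exit_time_s = tt[length(tt)], exit_side = NA_character_,
          outcome = "unresolved-at-track-end", stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  structure(res, class = c("collision_events", "data.frame"))
}

.side_name <- function(s) c("left", "zone", "right")[s + 2L]

#' Bypass frequency with a Wilson confidence interval
#'
#' Fraction of resolved collisions (bypass or same-side-return) that are
#' bypasses; unresolved episodes are excluded and counted separately.
#'
#' @param events A `collision_events` data frame (rows from one or many
#'   tracks).
#' @param conf_level Confidence level for the Wilson score interval.
#' @return A list: `frequency`, `n_bypass`, `n_collisions`, `n_unresolved`,
#'   `conf_int`.
#' @examples
#' # 53 bypasses out of 115 scored collisions -> 46%
#' @export
bypass_frequency <- function(events, conf_level = 0.95) {
  resolved <- events[events$outcome %in% c("bypass", "same-side-return"), , drop = FALSE]
  n <- nrow(resolved)
  if (n == 0) stop("no resolved collisions")
  k <- sum(resolved$outcome == "bypass")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(frequency = p, n_bypass = k, n_collisions = n,
       n_unresolved = sum(events$outcome == "unresolved-at-track-end"),
       conf_int = c(max(0, centre - half), min(1, centre + half)))
}

#' Score inter-DNA transfer events
#'
#' Transfer criteria: (i) the protein diffuses in register with one DNA for
#' more than `min_dwell_s`, (ii) it shifts to the neighbouring DNA in at most
#' `max_switch_frames` frames (less than one 200 ms frame by default), and
#' (iii) it continues in register with the other DNA for at least
#' `min_dwell_s` more. Each detection is assigned to the nearest DNA axis
#' within `register_tolerance_um`; detections outside tolerance of every axis
#' are unassigned and break a register run.
#'
#' @param track Trajectory data frame with `time_s` and a lateral coordinate
#'   `lateral_um` (or an `axis` column of pre-assigned axis indices).
#' @param axes_um Lateral positions of the DNA axes (um). A single axis
#'   yields zero transfers.
#' @param min_dwell_s Minimum in-register dwell on each side (s).
#' @param max_switch_frames Maximum frames for the switch itself.
#' @param register_tolerance_um Assignment tolerance (um); default is 3 x the
#'   250 bp localization s.d. converted through the standard geometry
#'   (about 0.2 um), mirroring the collision-zone logic.
#' @return Data frame of class `transfer_events`: `molecule_id`,
#'   `source_axis`, `dest_axis`, `switch_time_s`, `dwell_before_s`,
#'   `dwell_after_s`, and the three criteria flags.
#' @export
score_transfers <- function(track, axes_um, min_dwell_s = 4.0,
                            max_switch_frames = 1L,
                            register_tolerance_um = 0.2) {
  empty <- data.frame(molecule_id = integer(0), source_axis = integer(0),
                      dest_axis = integer(0), switch_time_s = numeric(0),
                      dwell_before_s = numeric(0), dwell_after_s = numeric(0),
                      in_register_before = logical(0),
                      single_frame_switch = logical(0),
                      in_register_after = logical(0))
  cls <- function(x) structure(x, class = c("transfer_events", "data.frame"))
  if (length(axes_um) < 2) return(cls(empty))
  det <- if ("detected" %in% names(track)) track$detected == 1 else rep(TRUE, nrow(track))
  tr <- track[det, , drop = FALSE]
  if (nrow(tr) < 2) return(cls(empty))
  mol <- if ("molecule_id" %in% names(tr)) tr$molecule_id[1] else 1L

  if ("axis" %in% names(tr)) {
    assign <- tr$axis
  } else {
    if (!"lateral_um" %in% names(tr))
      stop("track needs a lateral_um or axis column")
    dists <- vapply(axes_um, function(a) abs(tr$lateral_um - a), numeric(nrow(tr)))
    dists <- matrix(dists, nrow = nrow(tr))
    assign <- apply(dists, 1, which.min)
    assign[apply(dists, 1, min) > register_tolerance_um] <- NA_integer_
  }

  # runs of constant axis assignment (NA breaks a run)
  r <- rle(ifelse(is.na(assign), -1L, assign))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(axis = r$values, start = starts, end = ends)
  runs$t0 <- tr$time_s[runs$start]
  runs$t1 <- tr$time_s[runs$end]
  runs <- runs[runs$axis > 0, , drop = FALSE]
  # frame interval, to express the switch duration in frames even when the
  # detected rows skip frames
  dt <- if (nrow(tr) >= 2) min(diff(tr$time_s)) else 0.2

  out <- list()
  if (nrow(runs) >= 2) {
    for (k in seq_len(nrow(runs) - 1)) {
      a <- runs[k, ]; b <- runs[k + 1, ]
      if (a$axis == b$axis) next
      gap_frames <- round((b$t0 - a$t1) / dt)   # 1 = adjacent frames
      dwell_a <- a$t1 - a$t0
      dwell_b <- b$t1 - b$t0
      f_before <- dwell_a > min_dwell_s
      f_switch <- gap_frames <= max_switch_frames
      f_after <- dwell_b >= min_dwell_s
      if (f_before && f_switch && f_after) {
        out[[length(out) + 1L]] <- data.frame(
          molecule_id = mol, source_axis = a$axis, dest_axis = b$axis,
          switch_time_s = tr$time_s[b$start],
          dwell_before_s = dwell_a, dwell_after_s = dwell_b,
          in_register_before = f_before, single_frame_switch = f_switch,
          in_register_after = f_after)
      }
    }
  }
  cls(if (length(out)) do.call(rbind, out) else empty)
}

#' Binding-position histogram with a Gaussian fit
#'
#' Histogram of lesion-binding positions along the DNA with a nonlinear
#' least-squares Gaussian fit to the bin counts, reporting the peak centre,
#' sigma, and amplitude (the peak of such a histogram falls at the lesion
#' position, e.g. 20 kb from the tethered end).
#'
#' @param positions_bp Binding positions (bp).
#' @param bin_width_bp Histogram bin width (bp).
#' @param range_bp Optional length-2 range; defaults to the data range padded
#'   to whole bins.
#' @return A list of class `lesion_histogram`: `breaks_bp`, `counts`,
#'   `fit_ok`, `center_bp`, `sigma_bp`, `amplitude`, `n`.
#' @export
lesion_histogram <- function(positions_bp, bin_width_bp = 500, range_bp = NULL) {
  positions_bp <- positions_bp[is.finite(positions_bp)]
  n <- length(positions_bp)
  if (n < 10) stop("need at least 10 positions to fit the histogram")
  if (is.null(range_bp)) {
    lo <- floor(min(positions_bp) / bin_width_bp) * bin_width_bp
    hi <- ceiling(max(positions_bp) / bin_width_bp) * bin_width_bp
    if (hi <= lo) hi <- lo + bin_width_bp
    range_bp <- c(lo, hi)
  }
  breaks <- seq(range_bp[1], range_bp[2], by = bin_width_bp)
  h <- graphics::hist(positions_bp, breaks = breaks, plot = FALSE)
  mids <- h$mids; counts <- h$counts
  res <- list(breaks_bp = breaks, counts = counts, fit_ok = FALSE,
              center_bp = NA_real_, sigma_bp = NA_real_,
              amplitude = NA_real_, n = n)
  class(res) <- "lesion_histogram"
  if (stats::sd(positions_bp) == 0 || sum(counts > 0) < 3) return(res)
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ A * exp(-(mids - mu)^2 / (2 * s^2)),
                      data = data.frame(mids = mids, counts = counts),
                      start = list(A = max(counts), mu = mids[which.max(counts)],
                                   s = max(stats::sd(positions_bp), bin_width_bp)),
                      lower = c(A = 0, mu = range_bp[1], s = bin_width_bp / 10)),
    error = function(e) NULL)
  if (is.null(fit)) return(res)
  p <- stats::coef(fit)
  # a fit that degenerates to the bin mean (flat data) is flagged non-peaked
  if (p["s"] > diff(range_bp) || p["A"] <= 2 * sqrt(max(mean(counts), 1)))
    return(res)
  res$fit_ok <- TRUE
  res$center_bp <- unname(p["mu"])
  res$sigma_bp <- unname(p["s"])
  res$amplitude <- unname(p["A"])
  res
}

#' Classify the lesion-recognition mode of a trajectory
#'
#' A track that arrests at the lesion (ends within `direct_threshold_bp` of
#' it and is stationary over its last `arrest_frames` frames, displacement
#' below the localization s.d.) is classed `direct-3D` when its first
#' detection is already within `direct_threshold_bp` of the lesion and arrest
#' is immediate; `sliding-1D` when the cumulative pre-arrest excursion is at
#' least `sliding_threshold_bp`; otherwise `ambiguous`. Tracks that do not
#' arrest at the lesion return mode `none`.
#'
#' @param track Trajectory data frame with `position_bp` (or `position_um`
#'   plus `geometry`).
#' @param lesion A [lesion_site()].
#' @param direct_threshold_bp Direct-binding resolution (~300 bp).
#' @param sliding_threshold_bp Minimum 1D search excursion (~1 kb).
#' @param loc_sigma_bp Localization s.d. for the arrest test (bp).
#' @param arrest_frames Frames of stationarity defining arrest.
#' @param geometry Optional [dna_geometry()].
#' @return A list of class `recognition_call`: `mode` (direct-3D /
#'   sliding-1D / ambiguous / none), `pre_arrest_path_bp`,
#'   `first_detection_distance_bp`, `arrest_start_frame`.
#' @export
classify_recognition <- function(track, lesion, direct_threshold_bp = 300,
                                 sliding_threshold_bp = 1000,
                                 loc_sigma_bp = 250, arrest_frames = 10L,
                                 geometry = NULL) {
  stopifnot(inherits(lesion, "lesion_site"))
  det <- if ("detected" %in% names(track)) track$detected == 1 else rep(TRUE, nrow(track))
  pos <- if ("position_bp" %in% names(track)) track$position_bp
         else if (!is.null(geometry)) um_to_bp(track$position_um, geometry)
         else stop("track needs position_bp, or position_um with a geometry")
  pos <- pos[det & !is.na(pos)]
  out <- function(mode, path = NA_real_, first = NA_real_, start = NA_integer_)
    structure(list(mode = mode, pre_arrest_path_bp = path,
                   first_detection_distance_bp = first,
                   arrest_start_frame = start),
              class = "recognition_call")
  m <- length(pos)
  if (m < arrest_frames) return(out("none"))
  if (abs(pos[m] - lesion$position_bp) > direct_threshold_bp) return(out("none"))
  tail_idx <- (m - arrest_frames + 1L):m
  if (max(abs(diff(pos[tail_idx]))) >= loc_sigma_bp) return(out("none"))

  # earliest frame from which the molecule stays continuously arrested
  arrest_start <- tail_idx[1]
  while (arrest_start > 1 &&
         abs(pos[arrest_start - 1] - pos[arrest_start]) < loc_sigma_bp &&
         abs(pos[arrest_start - 1] - lesion$position_bp) <= direct_threshold_bp) {
    arrest_start <- arrest_start - 1L
  }
  pre <- pos[seq_len(arrest_start)]
  path_len <- if (length(pre) > 1) sum(abs(diff(pre))) else 0
  first_dist <- abs(pos[1] - lesion$position_bp)
  immediate <- arrest_start <= 2L
  mode <- if (first_dist <= direct_threshold_bp && immediate) "direct-3D"
          else if (path_len >= sliding_threshold_bp) "sliding-1D"
          else "ambiguous"
  out(mode, path_len, first_dist, arrest_start)
}
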