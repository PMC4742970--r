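#' Fit a 2D Gaussian to an image patch
#'
#' Localizes one diffraction-limited spot with sub-pixel precision by
#' nonlinear least squares over centre, sigma, amplitude, and a constant
#' background. Coordinates are 1-based pixel indices within the window
#' (x = column, y = row). Non-convergence, or a fitted amplitude below
#' `min_snr` times the robust background noise of the window, yields a
#' "no spot" result rather than an error.
#'
#' @param window Numeric matrix, at least 5x5.
#' @param init Optional named list with starting values (`x`, `y`, `sigma`,
#'   `amplitude`, `background`); defaults are estimated from the window.
#' @param min_snr Minimum amplitude-to-noise ratio for an accepted fit.
#' @return A list of class `spot_fit`: `ok`, `x_px`, `y_px`, `sigma_px`,
#'   `amplitude`, `background`, `rss`.
#' @examples
#' w <- outer(1:11, 1:11, function(r, c) 100 * exp(-((c - 5.3)^2 + (r - 7.8)^2) / (2 * 1.2^2)))
#' fit_gaussian_2d(w)
#' @export
fit_gaussian_2d <- function(window, init = NULL, min_snr = 3) {
  if (!is.matrix(window) || nrow(window) < 5 || ncol(window) < 5)
    stop("window must be a matrix of at least 5x5 pixels")
  ny <- nrow(window); nx <- ncol(window)
  df <- data.frame(v = as.vector(window),
                   x = rep(seq_len(nx), each = ny),
                   y = rep(seq_len(ny), nx))
  bg0 <- stats::median(df$v)
  noise <- stats::mad(df$v)
  no_spot <- list(ok = FALSE, x_px = NA_real_, y_px = NA_real_,
                  sigma_px = NA_real_, amplitude = NA_real_,
                  background = bg0, rss = NA_real_)
  class(no_spot) <- "spot_fit"

  excess <- pmax(df$v - bg0, 0)
  if (sum(excess) <= 0) return(no_spot)
  if (is.null(init)) {
    init <- list(x = sum(df$x * excess) / sum(excess),
                 y = sum(df$y * excess) / sum(excess),
                 sigma = 1.5, amplitude = max(df$v) - bg0, background = bg0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
      data = df,
      start = list(x0 = init$x, y0 = init$y, s = init$sigma,
                   A = init$amplitude, b = init$background),
      lower = c(x0 = 0.5, y0 = 0.5, s = 0.3, A = 0, b = -Inf),
      upper = c(x0 = nx + 0.5, y0 = ny + 0.5, s = max(nx, ny), A = Inf, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(no_spot)
  p <- stats::coef(fit)
  if (!is.finite(p["A"]) || p["A"] <= min_snr * max(noise, 1e-12)) return(no_spot)
  structure(list(ok = TRUE, x_px = unname(p["x0"]), y_px = unname(p["y0"]),
                 sigma_px = unname(p["s"]), amplitude = unname(p["A"]),
                 background = unname(p["b"]),
                 rss = sum(stats::resid(fit)^2)),
            class = "spot_fit")
}

#' Detect fluorescent spots in one frame
#'
#' Candidate pixels exceed the frame background (median) by
#' `threshold_sigmas` robust standard deviations (MAD) and are local maxima in
#' their 3x3 neighbourhood; each candidate is refined by [fit_gaussian_2d()]
#' on a window around it. Detections closer than one PSF sigma are merged,
#' keeping the brighter fit: overlapping emitters within one PSF are reported
#' as a single spot (a documented resolution limit).
#'
#' @param frame Numeric matrix (one movie frame).
#' @param threshold_sigmas Detection threshold in robust s.d. units.
#' @param psf_sigma_px Expected PSF sigma (pixels), used for the merge radius.
#' @param window_halfwidth Half-width of the fit window (pixels).
#' @return Data frame with one row per detection: `x_px`, `y_px`, `sigma_px`,
#'   `amplitude`, `background`, `rss`.
#' @export
detect_spots <- function(frame, threshold_sigmas = 5, psf_sigma_px = 1.0,
                         window_halfwidth = 4L) {
  if (threshold_sigmas <= 0) stop("threshold_sigmas must be positive")
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      sigma_px = numeric(0), amplitude = numeric(0),
                      background = numeric(0), rss = numeric(0))
  if (!is.matrix(frame) || length(frame) == 0) return(empty)
  ny <- nrow(frame); nx <- ncol(frame)
  if (ny < 3 || nx < 3) return(empty)
  bg <- stats::median(frame)
  noise <- stats::mad(frame)
  thr <- bg + threshold_sigmas * max(noise, 1e-12)
  cand <- which(frame > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  is_local_max <- function(r, c) {
    rr <- max(1, r - 1):min(ny, r + 1)
    cc <- max(1, c - 1):min(nx, c + 1)
    frame[r, c] >= max(frame[rr, cc])
  }
  keep <- mapply(is_local_max, cand[, 1], cand[, 2])
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  hw <- as.integer(window_halfwidth)
  fits <- list()
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    rr <- max(1, r - hw):min(ny, r + hw)
    cc <- max(1, c - hw):min(nx, c + hw)
    if (length(rr) < 5 || length(cc) < 5) next
    f <- fit_gaussian_2d(frame[rr, cc, drop = FALSE])
    if (!f$ok) next
    fits[[length(fits) + 1L]] <- data.frame(
      x_px = f$x_px + cc[1] - 1, y_px = f$y_px + rr[1] - 1,
      sigma_px = f$sigma_px, amplitude = f$amplitude,
      background = f$background, rss = f$rss)
  }
  if (!length(fits)) return(empty)
  det <- do.call(rbind, fits)
  det <- det[order(-det$amplitude), , drop = FALSE]
  # merge duplicates within one PSF sigma, keeping the brighter fit
  taken <- rep(FALSE, nrow(det))
  out <- list()
  for (k in seq_len(nrow(det))) {
    if (taken[k]) next
    d <- sqrt((det$x_px - det$x_px[k])^2 + (det$y_px - det$y_px[k])^2)
    taken[d < psf_sigma_px] <- TRUE
    out[[length(out) + 1L]] <- det[k, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour linking: at each frame, open tracks claim their
#' closest detection (smallest jump first), provided the jump does not exceed
#' `max_jump_um` and the dark gap does not exceed `max_gap_frames` frames.
#' Equidistant candidates are broken deterministically towards the lower spot
#' index. Unclaimed detections seed new tracks. Gap frames are retained in the
#' output with `detected = 0`.
#'
#' The default `max_jump_um` is 4 x sqrt(2 D_max dt) with D_max = 0.5 um^2/s
#' at 0.2 s frames: wide enough to span blinking jitter without bridging
#' neighbouring molecules.
#'
#' @param detections Data frame with columns `frame` (0-based), `x_px`,
#'   `y_px`, plus any fit columns, time-ordered.
#' @param pixel_size_um Pixel size (um).
#' @param frame_interval_s Frame interval (s).
#' @param max_jump_um Maximum allowed jump between linked detections (um).
#' @param max_gap_frames Maximum number of skipped (dark) frames inside a track.
#' @param axis_origin_px Image row corresponding to DNA position 0 (the
#'   barrier-tethered end); positions along the DNA are
#'   `(y_px - axis_origin_px) * pixel_size_um`.
#' @return List of trajectory data frames with columns `molecule_id`, `frame`,
#'   `time_s`, `x_px`, `y_px`, `position_um`, `detected`, `sigma_px`,
#'   `amplitude`, `background`.
#' @export
link_trajectories <- function(detections, pixel_size_um, frame_interval_s = 0.2,
                              max_jump_um = 4 * sqrt(2 * 0.5 * frame_interval_s),
                              max_gap_frames = 5L, axis_origin_px = 0) {
  need <- c("frame", "x_px", "y_px")
  if (!all(need %in% names(detections)))
    stop("detections must have columns frame, x_px, y_px")
  if (nrow(detections) == 0) return(list())
  max_jump_px <- max_jump_um / pixel_size_um

  tracks <- list()        # each: list(rows = list of det rows, last_frame)
  open_idx <- integer(0)
  frames <- sort(unique(detections$frame))
  for (f in frames) {
    det_f <- detections[detections$frame == f, , drop = FALSE]
    det_f <- det_f[order(seq_len(nrow(det_f))), , drop = FALSE]
    n_det <- nrow(det_f)
    claimed <- rep(FALSE, n_det)

    # drop tracks whose gap is exhausted
    open_idx <- open_idx[vapply(tracks[open_idx], function(tr)
      f - tr$last_frame <= max_gap_frames + 1L, logical(1))]

    if (length(open_idx) && n_det) {
      last_xy <- t(vapply(tracks[open_idx], function(tr) {
        lr <- tr$rows[[length(tr$rows)]]
        c(lr$x_px, lr$y_px)
      }, numeric(2)))
      dmat <- sqrt(outer(last_xy[, 1], det_f$x_px, "-")^2 +
                   outer(last_xy[, 2], det_f$y_px, "-")^2)
      repeat {
        if (!any(is.finite(dmat)) || min(dmat, na.rm = TRUE) > max_jump_px) break
        # smallest distance; ties resolved towards the lower spot index
        best <- which(dmat == min(dmat, na.rm = TRUE), arr.ind = TRUE)
        best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
        ti <- best[1]; di <- best[2]
        tr <- tracks[[open_idx[ti]]]
        tr$rows[[length(tr$rows) + 1L]] <- det_f[di, , drop = FALSE]
        tr$last_frame <- f
        tracks[[open_idx[ti]]] <- tr
        claimed[di] <- TRUE
        dmat[ti, ] <- Inf
        dmat[, di] <- Inf
      }
    }
    for (di in which(!claimed)) {
      tracks[[length(tracks) + 1L]] <- list(rows = list(det_f[di, , drop = FALSE]),
                                            last_frame = f)
      open_idx <- c(open_idx, length(tracks))
    }
    # refresh open set (tracks updated above stay open)
    open_idx <- unique(c(open_idx[vapply(tracks[open_idx], function(tr)
      f - tr$last_frame <= max_gap_frames, logical(1))]))
  }

  lapply(seq_along(tracks), function(m) {
    rows <- do.call(rbind, tracks[[m]]$rows)
    full <- data.frame(frame = rows$frame[1]:rows$frame[nrow(rows)])
    out <- merge(full, rows, by = "frame", all.x = TRUE, sort = TRUE)
    out$detected <- as.integer(!is.na(out$x_px))
    out$molecule_id <- m
    out$time_s <- out$frame * frame_interval_s
    out$position_um <- (out$y_px - axis_origin_px) * pixel_size_um
    cols <- c("molecule_id", "frame", "time_s", "x_px", "y_px", "position_um",
              "detected")
    extra <- setdiff(names(out), c(cols))
    out[, c(cols, extra)]
  })
}

#' Apply the minimum-duration trajectory filter
#'
#' Keeps trajectories with at least `min_frames` detected frames. The default
#' of 50 frames corresponds to 10 s at the 0.2 s frame interval and is
#' inclusive at exactly 50 detected frames.
#'
#' @param tracks List of trajectory data frames (with a `detected` column;
#'   rows without one count as detected).
#' @param min_frames Minimum number of detected frames.
#' @return The kept tracks, with attributes `n_kept` and `n_removed`.
#' @export
filter_trajectories <- function(tracks, min_frames = 50L) {
  n_det <- vapply(tracks, function(tr) {
    if ("detected" %in% names(tr)) sum(tr$detected == 1) else nrow(tr)
  }, numeric(1))
  keep <- n_det >= min_frames
  out <- tracks[keep]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}
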