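#' Optical configuration for the synthetic kymograph renderer
#'
#' Emulates a prism-TIRF microscope with an EMCCD camera: each visible
#' molecule is rendered as a symmetric 2D Gaussian point-spread function and
#' photon shot noise is Poisson. Defaults correspond to a 60x objective with
#' 16 um camera pixels (0.267 um/px).
#'
#' @param pixel_size_um Pixel size in the sample plane (um).
#' @param psf_sigma_px Gaussian PSF sigma (pixels).
#' @param photons_per_frame Expected photons collected per molecule per frame.
#' @param background_photons_per_px Expected background photons per pixel.
#' @param camera_bit_depth Bit depth of the camera output (default 16).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size_um = 0.267, psf_sigma_px = 1.0,
                          photons_per_frame = 2000,
                          background_photons_per_px = 20,
                          camera_bit_depth = 16L) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be positive")
  if (photons_per_frame < 0 || background_photons_per_px < 0)
    stop("photon counts must be >= 0")
  structure(list(pixel_size_um = pixel_size_um, psf_sigma_px = psf_sigma_px,
                 photons_per_frame = photons_per_frame,
                 background_photons_per_px = background_photons_per_px,
                 camera_bit_depth = as.integer(camera_bit_depth)),
            class = "optics_config")
}

#' Render ground-truth trajectories into a synthetic image stack
#'
#' Produces the input the tracker expects: a 16-bit grayscale movie in which
#' every molecule that is not dark (and still on DNA) appears as a 2D Gaussian
#' spot with Poisson shot noise on top of a uniform Poisson background. The
#' DNA axis runs along image rows (y); lateral DNA positions are given in
#' `axes_um` measured from the left image edge. A ground-truth sidecar table
#' of true pixel positions accompanies the stack.
#'
#' @param trajectories List of `ground_truth` objects sharing a frame grid.
#' @param optics An [optics_config()].
#' @param geometry A [dna_geometry()].
#' @param axes_um Lateral position(s) of the DNA axes (um from left edge).
#' @param pad_px Padding rows above and below the DNA span.
#' @param seed RNG seed for the shot noise, or `NULL`.
#' @param path Optional basename; if given, writes `<path>.tif` (uncompressed
#'   16-bit multi-page TIFF) and `<path>.json` (ground-truth sidecar).
#' @return Invisibly, a list with `frames` (ny x nx x n_frames integer array),
#'   `truth` (data frame: molecule, frame, x_px, y_px, visible), `optics`,
#'   `geometry`, `axes_um`, `pad_px`, and `clipped` (count of positions that
#'   fell outside the image and were skipped, with a warning if non-zero).
#' @export
render_kymograph <- function(trajectories, optics, geometry,
                             axes_um = 1.0, pad_px = 4L, seed = NULL,
                             path = NULL) {
  stopifnot(inherits(optics, "optics_config"), inherits(geometry, "dna_geometry"))
  if (!length(trajectories)) stop("no trajectories to render")
  nf <- unique(vapply(trajectories, function(g) length(g$times_s), numeric(1)))
  if (length(nf) != 1) stop("trajectories do not share a frame grid")
  if (!is.null(seed)) set.seed(seed)

  px <- optics$pixel_size_um
  ny <- as.integer(ceiling(geometry$tether_span_um / px)) + 2L * pad_px
  nx <- as.integer(ceiling((max(axes_um) + 1) / px)) + 2L * pad_px
  sig <- optics$psf_sigma_px
  maxval <- 2^optics$camera_bit_depth - 1
  clipped <- 0L

  # true sub-pixel pixel coordinates (1-based, row = along DNA)
  truth <- do.call(rbind, lapply(seq_along(trajectories), function(m) {
    g <- trajectories[[m]]
    ax <- ifelse(is.na(g$axis), 1L, g$axis)
    lateral <- axes_um[pmin(ax, length(axes_um))]
    data.frame(molecule = m, frame = seq_len(nf) - 1L,
               x_px = pad_px + lateral / px + 0.5,
               y_px = pad_px + bp_to_um(g$true_positions_bp, geometry) / px + 0.5,
               visible = g$state %in% c("sliding", "hopping", "captured"))
  }))

  frames <- array(0L, dim = c(ny, nx, nf))
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  amp <- optics$photons_per_frame / (2 * pi * sig^2)
  for (f in seq_len(nf)) {
    lambda <- matrix(optics$background_photons_per_px, ny, nx)
    sub <- truth[truth$frame == f - 1L & truth$visible, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      x0 <- sub$x_px[r]; y0 <- sub$y_px[r]
      if (is.na(y0)) next
      if (y0 < 1 || y0 > ny || x0 < 1 || x0 > nx) { clipped <- clipped + 1L; next }
      lambda <- lambda + amp * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sig^2))
    }
    img <- stats::rpois(ny * nx, lambda)
    frames[, , f] <- as.integer(pmin(img, maxval))
  }
  if (clipped > 0)
    warning(sprintf("%d molecule positions fell outside the image and were skipped",
                    clipped))

  out <- list(frames = frames, truth = truth, optics = optics,
              geometry = geometry, axes_um = axes_um, pad_px = pad_px,
              clipped = clipped)
  class(out) <- "kymo_stack"
  if (!is.null(path)) {
    pages <- lapply(seq_len(nf), function(f) frames[, , f] / maxval)
    tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 16L,
                    compression = "none")
    sidecar <- list(
      optics = unclass(optics),
      geometry = unclass(geometry),
      axes_um = axes_um, pad_px = pad_px,
      configs = lapply(trajectories, function(g) {
        cfg <- unclass(g$config)
        cfg$roadblocks <- lapply(cfg$roadblocks, unclass)
        cfg$lesion <- if (is.null(cfg$lesion)) NULL else unclass(cfg$lesion)
        cfg
      }),
      truth = truth)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(out)
}
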