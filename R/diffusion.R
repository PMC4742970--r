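#' Time-averaged mean squared displacement of a trajectory
#'
#' For a track of N frames, the MSD at lag n dt is the overlapping time
#' average (1/(N - n)) * sum_i (y_{i+n} - y_i)^2 over all start frames i. For
#' gapped tracks, only displacement pairs with both endpoints detected
#' contribute and the denominator is the actual pair count.
#'
#' @param track Either a numeric vector of positions (um) or a trajectory data
#'   frame with columns `position_um` and optionally `detected`.
#' @param dt Frame interval (s); taken from the `time_s` column when `track`
#'   is a data frame.
#' @param n_max Number of lags (default 10, i.e. 0.2-2 s at 0.2 s cadence).
#' @return An object of class `msd_curve`: data frame with columns `lag_s`,
#'   `msd_um2`, `n_pairs`, plus attribute `dt`.
#' @examples
#' compute_msd(c(0, 1, 0, 1, 0, 1), dt = 0.2, n_max = 2)
#' @export
compute_msd <- function(track, dt = 0.2, n_max = 10L) {
  if (is.data.frame(track)) {
    if (!"position_um" %in% names(track))
      stop("track data frame must have a position_um column")
    y <- track$position_um
    det <- if ("detected" %in% names(track)) track$detected == 1 else rep(TRUE, length(y))
    y[!det] <- NA_real_
    if ("time_s" %in% names(track) && nrow(track) >= 2)
      dt <- track$time_s[2] - track$time_s[1]
  } else {
    y <- as.numeric(track)
  }
  N <- length(y)
  if (sum(!is.na(y)) < n_max + 1)
    stop(sprintf("track has fewer than n_max + 1 = %d detected frames", n_max + 1))
  lag <- seq_len(n_max)
  msd <- numeric(n_max)
  npairs <- integer(n_max)
  for (n in lag) {
    d2 <- (y[(1 + n):N] - y[1:(N - n)])^2
    npairs[n] <- sum(!is.na(d2))
    msd[n] <- if (npairs[n] > 0) mean(d2, na.rm = TRUE) else NA_real_
  }
  structure(data.frame(lag_s = lag * dt, msd_um2 = msd, n_pairs = npairs),
            dt = dt, class = c("msd_curve", "data.frame"))
}

#' Fit a 1D diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of MSD against lag time. For 1D Brownian motion
#' MSD = 2 D t, so D is slope/2. The default fit has a free intercept, which
#' absorbs the static localization-noise offset (approximately 2 sigma^2);
#' a through-origin fit is available for sensitivity analysis. Noise-dominated
#' tracks can yield D <= 0; such estimates are flagged, not dropped.
#'
#' @param curve An `msd_curve` (or data frame with `lag_s`, `msd_um2`).
#' @param through_origin Fit without an intercept.
#' @param molecule_id Identifier carried into the result.
#' @return A list of class `diffusion_estimate`: `D_um2_s`, `intercept_um2`,
#'   `rmse_um2`, `n_lags`, `nonpositive` flag, `molecule_id`.
#' @export
fit_diffusion <- function(curve, through_origin = FALSE, molecule_id = NA) {
  if (!all(c("lag_s", "msd_um2") %in% names(curve)))
    stop("curve must have columns lag_s and msd_um2")
  cc <- curve[is.finite(curve$msd_um2), , drop = FALSE]
  if (nrow(cc) < 2) stop("need at least 2 lags to fit a line")
  fit <- if (through_origin) stats::lm(msd_um2 ~ lag_s - 1, data = cc)
         else stats::lm(msd_um2 ~ lag_s, data = cc)
  co <- stats::coef(fit)
  D <- unname(co["lag_s"]) / 2
  structure(list(D_um2_s = D,
                 intercept_um2 = if (through_origin) 0 else unname(co["(Intercept)"]),
                 rmse_um2 = sqrt(mean(stats::resid(fit)^2)),
                 n_lags = nrow(cc),
                 nonpositive = D <= 0,
                 molecule_id = molecule_id),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g um^2/s (intercept %.4g um^2, %d lags)%s\n",
              x$D_um2_s, x$intercept_um2, x$n_lags,
              if (x$nonpositive) " [non-positive]" else ""))
  invisible(x)
}

#' Summarize a population of diffusion coefficients
#'
#' Arithmetic mean and s.d. of per-molecule D, the convention used to report
#' mean +/- s.d. per condition.
#'
#' @param estimates List of `diffusion_estimate` objects or a numeric vector
#'   of D values.
#' @param label Condition label (e.g. nucleotide and NaCl concentration).
#' @return A one-row data frame: `label`, `mean_D`, `sd_D`, `n`, `sd_defined`.
#' @export
summarize_population <- function(estimates, label = "") {
  D <- if (is.numeric(estimates)) estimates
       else vapply(estimates, function(e) e$D_um2_s, numeric(1))
  if (length(D) < 1) stop("need at least one estimate")
  data.frame(label = label, mean_D = mean(D),
             sd_D = if (length(D) > 1) stats::sd(D) else 0,
             n = length(D), sd_defined = length(D) > 1)
}

#' Compare two diffusion-coefficient samples on the log scale
#'
#' Two-tailed two-sample t-test on log10(D), the scale on which
#' diffusion-coefficient populations are approximately normal. Non-positive
#' estimates cannot be log-transformed and are excluded with a reported count.
#' Welch (unequal-variance) degrees of freedom by default; the pooled-variance
#' test is available via `pooled = TRUE`.
#'
#' @param a,b Numeric vectors of diffusion coefficients.
#' @param pooled Use the pooled-variance (classic Student) test.
#' @param conf_level Confidence level for the log10 mean-difference interval.
#' @return A list: `p_value`, `conf_int` (log10 difference), `estimate`
#'   (log10 means), `n_used`, `n_excluded`, `method`.
#' @export
compare_log_d <- function(a, b, pooled = FALSE, conf_level = 0.95) {
  a_ok <- a[is.finite(a) & a > 0]
  b_ok <- b[is.finite(b) & b > 0]
  if (length(a_ok) < 2 || length(b_ok) < 2)
    stop("need at least 2 positive diffusion coefficients per group")
  ht <- stats::t.test(log10(a_ok), log10(b_ok), var.equal = pooled,
                      conf.level = conf_level)
  list(p_value = ht$p.value,
       conf_int = as.numeric(ht$conf.int),
       estimate = as.numeric(ht$estimate),
       n_used = c(length(a_ok), length(b_ok)),
       n_excluded = c(length(a) - length(a_ok), length(b) - length(b_ok)),
       method = if (pooled) "pooled t-test on log10(D)" else "Welch t-test on log10(D)")
}

#' Theoretical speed limit for sliding with rotation along the DNA backbone
#'
#' Upper bound on the 1D diffusion coefficient of a protein that tracks the
#' helical pitch while sliding. The effective friction combines translation
#' of a sphere of radius `protein_radius_nm` with the rotation about the
#' helical axis required to advance one turn (pitch 3.57 nm = 10.5 bp x
#' 0.34 nm) per revolution, following the rotation-coupled sliding model of
#' Schurr (Biophys Chem 1979) as applied by Blainey et al. (Nat Struct Mol
#' Biol 2009):
#'
#'   zeta = 6 pi eta r + (2 pi / pitch)^2 (8 pi eta r^3 + 6 pi eta r R_oc^2)
#'   D_max = kB T / zeta
#'
#' where R_oc is the offset of the protein centre from the helical axis.
#'
#' @param protein_radius_nm Hydrodynamic radius of the protein (nm).
#' @param offset_from_axis_nm Offset of the protein centre of mass from the
#'   DNA helical axis (nm); defaults to the protein radius.
#' @param temperature_K Temperature (K).
#' @param viscosity_Pa_s Solvent viscosity (Pa s); default water at 25 C.
#' @param pitch_nm Helical pitch (nm per turn).
#' @return Maximum diffusion coefficient (um^2/s).
#' @export
rotational_sliding_limit <- function(protein_radius_nm = 5,
                                     offset_from_axis_nm = protein_radius_nm,
                                     temperature_K = 298.15,
                                     viscosity_Pa_s = 8.9e-4,
                                     pitch_nm = 3.57) {
  if (protein_radius_nm <= 0 || temperature_K <= 0 || viscosity_Pa_s <= 0 ||
      pitch_nm <= 0 || offset_from_axis_nm < 0)
    stop("all physical parameters must be positive")
  kB <- 1.380649e-23
  r <- protein_radius_nm * 1e-9
  roc <- offset_from_axis_nm * 1e-9
  pitch <- pitch_nm * 1e-9
  eta <- viscosity_Pa_s
  zeta <- 6 * pi * eta * r +
    (2 * pi / pitch)^2 * (8 * pi * eta * r^3 + 6 * pi * eta * r * roc^2)
  (kB * temperature_K / zeta) * 1e12  # m^2/s -> um^2/s
}
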