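# Independent oracles and small builders shared across tests.

std_geom <- function() dna_geometry()

# Brute-force MSD at one lag: mean of squared displacements, written directly.
brute_msd_lag <- function(y, n) {
  N <- length(y)
  mean((y[(1 + n):N] - y[1:(N - n)])^2, na.rm = TRUE)
}

# Ground-truth zone-crossing count: alternations of the confirmed outside-side
# sequence, computed by direct enumeration (independent of the classifier's
# state machine).
oracle_bypass_count <- function(pos_bp, rb_bp, halfwidth_bp, min_run = 3L) {
  side <- ifelse(pos_bp < rb_bp - halfwidth_bp, -1L,
                 ifelse(pos_bp > rb_bp + halfwidth_bp, 1L, 0L))
  r <- rle(side)
  s <- r$values[r$values != 0L & r$lengths >= min_run]
  if (length(s) < 2) 0L else sum(diff(s) != 0)
}

oracle_collision_count <- function(pos_bp, rb_bp, halfwidth_bp, min_run = 3L) {
  side <- ifelse(pos_bp < rb_bp - halfwidth_bp, -1L,
                 ifelse(pos_bp > rb_bp + halfwidth_bp, 1L, 0L))
  r <- rle(side)
  keep <- r$values != 0L & r$lengths >= min_run
  idx <- which(keep)
  if (length(idx) < 2) return(0L)
  n <- 0L
  for (k in seq_len(length(idx) - 1)) {
    a <- idx[k]; b <- idx[k + 1]
    gap <- if (b > a + 1) (a + 1):(b - 1) else integer(0)
    contact <- length(gap) > 0 && any(r$values[gap] == 0L)
    if (contact || r$values[a] != r$values[b]) n <- n + 1L
  }
  n
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(centre - half, centre + half)
}

# Fit D for every trajectory in a measured population.
fit_population_d <- function(pop, seed_offset = 10000L, n_lags = 10L) {
  vapply(seq_along(pop), function(k) {
    tr <- measure_trajectory(pop[[k]], molecule_id = k, seed = seed_offset + k)
    fit_diffusion(compute_msd(tr, n_max = n_lags))$D_um2_s
  }, numeric(1))
}

# Noiseless rendered Gaussian spot with Poisson noise for localization tests.
noisy_spot <- function(x0, y0, sigma = 1.2, photons = 1000, bg = 10,
                       size = 11L) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)
  ys <- matrix(rep(seq_len(size), size), size, size)
  lambda <- bg + photons / (2 * pi * sigma^2) *
    exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sigma^2))
  matrix(rpois(size * size, lambda), size, size)
}
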