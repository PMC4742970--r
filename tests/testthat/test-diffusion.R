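geom <- std_geom()

test_that("MSD matches hand-computable paths", {
  # constant position
  m0 <- compute_msd(rep(2.5, 30), dt = 0.2, n_max = 5)
  expect_true(all(m0$msd_um2 == 0))
  # alternating 0,1: MSD(1) = 1, MSD(2) = 0 under the overlapping average
  ma <- compute_msd(rep(c(0, 1), 3), dt = 0.2, n_max = 2)
  expect_equal(ma$msd_um2, c(1, 0))
  expect_equal(ma$n_pairs, c(5L, 4L))
  # uniform drift: MSD(n dt) = (v n dt)^2
  v <- 0.3; dt <- 0.2
  y <- v * (0:100) * dt
  md <- compute_msd(y, dt = dt, n_max = 10)
  expect_equal(md$msd_um2, (v * md$lag_s)^2, tolerance = 1e-12)
  expect_error(compute_msd(rep(0, 5), n_max = 10), "fewer than")
})

test_that("lag-1 MSD equals the brute-force mean squared displacement", {
  set.seed(31)
  for (rep_i in 1:20) {
    y <- cumsum(rnorm(200, 0, 0.1))
    m <- compute_msd(y, dt = 0.2, n_max = 10)
    expect_equal(m$msd_um2[1], brute_msd_lag(y, 1), tolerance = 1e-14)
    expect_equal(m$msd_um2[7], brute_msd_lag(y, 7), tolerance = 1e-14)
  }
})

test_that("gapped tracks use only pairs with both endpoints detected", {
  y <- c(0, 1, NA, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  tr <- data.frame(position_um = y, time_s = 0.2 * (0:11),
                   detected = as.integer(!is.na(y)))
  m <- compute_msd(tr, n_max = 2)
  ok1 <- which(!is.na(y[-length(y)]) & !is.na(y[-1]))
  expect_equal(m$n_pairs[1], length(ok1))
  expect_equal(m$msd_um2[1], mean((y[ok1 + 1] - y[ok1])^2))
})

test_that("line fits return D = slope/2 with the intercept absorbing offsets", {
  lag <- 0.2 * (1:10)
  exact <- data.frame(lag_s = lag, msd_um2 = 2 * 0.05 * lag)
  f <- fit_diffusion(exact)
  expect_equal(f$D_um2_s, 0.05, tolerance = 1e-12)
  expect_equal(f$intercept_um2, 0, tolerance = 1e-12)
  offset <- data.frame(lag_s = lag, msd_um2 = 2 * 0.05 * lag + 0.01)
  fo <- fit_diffusion(offset)
  expect_equal(fo$D_um2_s, 0.05, tolerance = 1e-12)
  expect_equal(fo$intercept_um2, 0.01, tolerance = 1e-12)
  ft <- fit_diffusion(exact, through_origin = TRUE)
  expect_equal(ft$D_um2_s, 0.05, tolerance = 1e-12)
  expect_error(fit_diffusion(data.frame(lag_s = 0.2, msd_um2 = 0.02)),
               "at least 2 lags")
})

test_that("localization noise shifts the intercept by ~2 sigma^2, not D", {
  set.seed(8)
  sigma <- 0.067   # um, the 250 bp equivalent
  d_noisy <- replicate(40, {
    y <- cumsum(rnorm(400, 0, sqrt(2 * 0.05 * 0.2)))
    clean <- fit_diffusion(compute_msd(y, dt = 0.2))
    noisy <- fit_diffusion(compute_msd(y + rnorm(400, 0, sigma), dt = 0.2))
    c(noisy$D_um2_s - clean$D_um2_s, noisy$intercept_um2 - clean$intercept_um2)
  })
  expect_lt(abs(mean(d_noisy[1, ])) / 0.05, 0.05)
  expect_equal(mean(d_noisy[2, ]), 2 * sigma^2, tolerance = 0.25)
})

test_that("noiseless Brownian ensembles fit a through-zero MSD line", {
  # ensemble MSD over many exact Brownian paths: the fitted intercept should
  # vanish relative to MSD at the first lag
  set.seed(271)
  n_tracks <- 3000L; n_frames <- 1000L; dt <- 0.2; d_true <- 0.05
  inc <- matrix(rnorm(n_tracks * n_frames, 0, sqrt(2 * d_true * dt)),
                n_frames, n_tracks)
  Y <- apply(inc, 2, cumsum)
  msd_ens <- vapply(1:10, function(n)
    mean((Y[(n + 1):n_frames, ] - Y[1:(n_frames - n), ])^2), numeric(1))
  fit <- fit_diffusion(data.frame(lag_s = dt * (1:10), msd_um2 = msd_ens))
  expect_lt(abs(fit$intercept_um2), 0.01 * msd_ens[1])
  expect_lt(abs(fit$D_um2_s - d_true) / d_true, 0.02)
})

test_that("scale equivariance: positions times c gives D times c^2", {
  set.seed(12)
  y <- cumsum(rnorm(300, 0, 0.05))
  d1 <- fit_diffusion(compute_msd(y, dt = 0.2))$D_um2_s
  d3 <- fit_diffusion(compute_msd(3 * y, dt = 0.2))$D_um2_s
  expect_equal(d3, 9 * d1, tolerance = 1e-10)
})

test_that("estimator is consistent over a simulated Brownian population", {
  cfg <- sim_config(d_slide_um2_s = 0.05, n_frames = 150, seed = 301,
                    loc_sigma_bp = 250)
  pop <- simulate_population(cfg, 200, geom)
  d_hat <- fit_population_d(pop, seed_offset = 40000L)
  expect_lt(abs(mean(d_hat) - 0.05) / 0.05, 0.10)
})

test_that("population summaries report mean, sd, and n", {
  s <- summarize_population(c(0.02, 0.04), label = "ADP")
  expect_equal(s$mean_D, 0.03)
  expect_equal(s$n, 2)
  one <- summarize_population(0.02)
  expect_equal(one$mean_D, 0.02)
  expect_equal(one$sd_D, 0)
  expect_false(one$sd_defined)
})

test_that("AMP-PNP-like population has about twice the ADP-like mean D", {
  mk <- function(d, n, seed) {
    cfg <- sim_config(d_slide_um2_s = d, n_frames = 150, seed = seed)
    fit_population_d(simulate_population(cfg, n, geom), seed_offset = seed * 7L)
  }
  d_adp <- mk(0.025, 72, 51)
  d_pnp <- mk(0.053, 50, 73)
  ratio <- mean(d_pnp) / mean(d_adp)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.8)
})

test_that("log-scale comparison behaves like a t-test should", {
  x <- c(0.02, 0.03, 0.04, 0.05)
  expect_equal(compare_log_d(x, x)$p_value, 1.0)
  expect_error(compare_log_d(x, 0.02), "at least 2")
  # non-positive estimates are excluded with a count
  res <- compare_log_d(c(x, -0.01), x)
  expect_equal(res$n_excluded, c(1L, 0L))
  # Monte-Carlo power at the published effect size and sample sizes
  set.seed(99)
  p <- replicate(20, {
    a <- rlnorm(47, log(0.031), 0.8)
    b <- rlnorm(49, log(0.12), 0.8)
    compare_log_d(a, b)$p_value
  })
  expect_gte(mean(p < 0.001), 0.95)
})

test_that("rotation-coupled sliding limit matches its closed form and is monotone", {
  # independent evaluation of kT / [6 pi eta r + (2 pi/pitch)^2 (8 pi eta r^3
  # + 6 pi eta r r^2)] at r = 5 nm, water, 25 C: 0.270 um^2/s
  expect_equal(rotational_sliding_limit(), 0.270, tolerance = 0.005)
  expect_lt(rotational_sliding_limit(viscosity_Pa_s = 1e3), 1e-6)
  expect_lt(rotational_sliding_limit(protein_radius_nm = 10),
            rotational_sliding_limit(protein_radius_nm = 5))
  expect_error(rotational_sliding_limit(protein_radius_nm = -1), "positive")
})
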