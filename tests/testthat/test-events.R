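geom <- std_geom()

test_that("constructed paths score collisions and bypasses as expected", {
  rb <- roadblock("nuc", 24000)
  # monotone left-to-right crossing: one bypass
  mono <- data.frame(time_s = 0.2 * (0:40), molecule_id = 1,
                     position_bp = seq(22000, 26000, length.out = 41))
  ev <- score_collisions(mono, rb, geom)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$outcome, "bypass")
  expect_equal(ev$entry_side, "left")
  expect_equal(ev$exit_side, "right")
  # entering from the left and returning left: one collision, no bypass
  back <- data.frame(time_s = 0.2 * (0:40), molecule_id = 2,
                     position_bp = c(seq(22000, 23900, length.out = 21),
                                     seq(23900, 22000, length.out = 20)))
  evb <- score_collisions(back, rb, geom)
  expect_equal(nrow(evb), 1)
  expect_equal(evb$outcome, "same-side-return")
  # track ending inside the zone is unresolved
  stuck <- data.frame(time_s = 0.2 * (0:20), molecule_id = 3,
                      position_bp = c(seq(22000, 23900, length.out = 11),
                                      rep(24000, 10)))
  evs <- score_collisions(stuck, rb, geom)
  expect_equal(evs$outcome, "unresolved-at-track-end")
  # spanning the whole zone between consecutive frames still counts
  jumpy <- data.frame(time_s = 0.2 * (0:9), molecule_id = 4,
                      position_bp = c(rep(22000, 5), rep(26000, 5)))
  expect_equal(score_collisions(jumpy, rb, geom)$outcome, "bypass")
})

test_that("zone clipping at a DNA end warns and still scores", {
  rb_edge <- roadblock("edge", 200)
  tr <- data.frame(time_s = 0.2 * (0:30), molecule_id = 1,
                   position_bp = seq(1000, 300, length.out = 31))
  expect_warning(score_collisions(tr, rb_edge, geom), "clipped")
})

test_that("classifier bypass counts equal the enumeration oracle on true paths", {
  rb <- roadblock("n1", 24000, permeability = 0.5)
  total_cl <- 0L; total_or <- 0L; total_coll <- 0L
  for (k in 1:25) {
    cfg <- sim_config(d_slide_um2_s = 0.03, hop_rate_per_s = 0.6,
                      hop_sigma_bp = 1500, roadblocks = list(rb),
                      n_frames = 400, seed = 900 + k, loc_sigma_bp = 0)
    g <- simulate_trajectory(cfg, geom)
    p <- g$true_positions_bp[!is.na(g$true_positions_bp)]
    tr <- data.frame(time_s = 0.2 * (seq_along(p) - 1), position_bp = p,
                     molecule_id = k)
    ev <- score_collisions(tr, rb, geom)
    total_cl <- total_cl + sum(ev$outcome == "bypass")
    total_coll <- total_coll + sum(ev$outcome != "unresolved-at-track-end")
    total_or <- total_or + oracle_bypass_count(p, 24000, 375)
  }
  expect_gt(total_coll, 80)
  expect_identical(total_cl, total_or)
})

test_that("enlarging the collision zone never increases the bypass count", {
  cfg <- sim_config(d_slide_um2_s = 0.04, hop_rate_per_s = 0.6,
                    hop_sigma_bp = 1500,
                    roadblocks = list(roadblock("n1", 24000, permeability = 0.5)),
                    n_frames = 600, seed = 55, loc_sigma_bp = 0)
  pop <- simulate_population(cfg, 15, geom)
  counts <- vapply(c(200, 375, 600, 1000), function(hw) {
    rb <- roadblock("n1", 24000, permeability = 0.5, zone_halfwidth_bp = hw)
    sum(vapply(seq_along(pop), function(k) {
      p <- pop[[k]]$true_positions_bp[!is.na(pop[[k]]$true_positions_bp)]
      tr <- data.frame(time_s = 0.2 * (seq_along(p) - 1), position_bp = p,
                       molecule_id = k)
      sum(score_collisions(tr, rb, geom)$outcome == "bypass")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("bypass frequency reproduces the printed count arithmetic", {
  mk_events <- function(k, n) {
    data.frame(molecule_id = 1, roadblock_id = "rb",
               entry_time_s = seq_len(n), entry_side = "left",
               exit_time_s = seq_len(n) + 1,
               exit_side = rep(c("right", "left"), c(k, n - k)),
               outcome = rep(c("bypass", "same-side-return"), c(k, n - k)))
  }
  unlabelled <- bypass_frequency(mk_events(53, 115))
  expect_equal(round(unlabelled$frequency, 3), 0.461)
  labelled <- bypass_frequency(mk_events(12, 28))
  expect_equal(round(labelled$frequency, 3), 0.429)
  none <- bypass_frequency(mk_events(0, 20))
  expect_equal(none$frequency, 0)
  expect_equal(none$conf_int[1], 0)
  expect_gt(none$conf_int[2], 0)
  expect_error(bypass_frequency(mk_events(0, 20)[0, ]), "no resolved")
})

test_that("noisy classifier stays inside the truth binomial interval across permeabilities", {
  for (perm in c(0, 0.5, 1)) {
    rb <- roadblock("n1", 24000, permeability = perm)
    nb <- 0L; nc <- 0L; ob <- 0L; oc <- 0L
    for (k in 1:30) {
      cfg <- sim_config(d_slide_um2_s = 0.03, hop_rate_per_s = 0.6,
                        hop_sigma_bp = 1500, roadblocks = list(rb),
                        n_frames = 400, seed = 2000 + 400 * perm + k)
      g <- simulate_trajectory(cfg, geom)
      m <- measure_trajectory(g, molecule_id = k, seed = 7000 + k)
      ev <- score_collisions(m, rb, geom)
      nb <- nb + sum(ev$outcome == "bypass")
      nc <- nc + sum(ev$outcome %in% c("bypass", "same-side-return"))
      p <- g$true_positions_bp[!is.na(g$true_positions_bp)]
      ob <- ob + oracle_bypass_count(p, 24000, 375)
      oc <- oc + oracle_collision_count(p, 24000, 375)
    }
    expect_gt(oc, 50)
    if (perm == 0) {
      expect_identical(ob, 0L)
      expect_identical(nb, 0L)
    } else {
      ci <- wilson_interval(ob, oc)
      frac <- nb / nc
      expect_gte(frac, ci[1])
      expect_lte(frac, ci[2])
    }
  }
})

test_that("transfer criteria require 4 s in register on both sides", {
  mk <- function(dwell_a_s, dwell_b_s, gap_frames = 1) {
    na <- round(dwell_a_s / 0.2) + 1
    nb <- round(dwell_b_s / 0.2) + 1
    frames <- c(seq_len(na), na + gap_frames - 1 + seq_len(nb))
    data.frame(molecule_id = 1, time_s = 0.2 * (frames - 1),
               lateral_um = rep(c(0, 1), c(na, nb)) + rnorm(na + nb, 0, 0.03),
               detected = 1L)
  }
  set.seed(14)
  ok <- score_transfers(mk(5, 5), axes_um = c(0, 1))
  expect_equal(nrow(ok), 1)
  expect_true(all(ok$in_register_before, ok$single_frame_switch,
                  ok$in_register_after))
  expect_equal(ok$source_axis, 1)
  expect_equal(ok$dest_axis, 2)
  # criterion iii fails with only 3 s on the destination
  expect_equal(nrow(score_transfers(mk(5, 3), axes_um = c(0, 1))), 0)
  # slow switches fail criterion ii
  expect_equal(nrow(score_transfers(mk(5, 5, gap_frames = 4), axes_um = c(0, 1))), 0)
  # single-axis scenes yield no transfers by construction
  expect_equal(nrow(score_transfers(mk(5, 5), axes_um = 0)), 0)
})

test_that("axis relabelling leaves the transfer count unchanged", {
  cfg <- sim_config(d_slide_um2_s = 0.02, hop_rate_per_s = 0.2,
                    n_frames = 600, seed = 33)
  scene <- make_two_dna_scene(1.0, 0.5, cfg, geom, n = 12)
  n_ab <- 0L; n_ba <- 0L
  for (k in seq_along(scene)) {
    m <- measure_trajectory(scene[[k]], molecule_id = k, seed = 800 + k)
    n_ab <- n_ab + nrow(score_transfers(m, axes_um = c(0, 1)))
    m2 <- m
    m2$lateral_um <- 1 - m$lateral_um
    n_ba <- n_ba + nrow(score_transfers(m2, axes_um = c(0, 1)))
  }
  expect_identical(n_ab, n_ba)
})

test_that("classifier transfers match qualifying ground-truth transfers", {
  cfg <- sim_config(d_slide_um2_s = 0.02, hop_rate_per_s = 0.08,
                    n_frames = 600, seed = 44, loc_sigma_bp = 50)
  scene <- make_two_dna_scene(1.0, 1.0, cfg, geom, n = 15)
  for (g in scene) {
    m <- measure_trajectory(g, molecule_id = 1, seed = 321)
    got <- nrow(score_transfers(m, axes_um = c(0, 1)))
    # qualifying ground-truth transfers: axis runs of > 4 s before and >= 4 s
    # after a single-frame switch
    ax <- g$axis[!is.na(g$axis)]
    tt <- g$times_s[!is.na(g$axis)]
    r <- rle(ax)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    want <- 0L
    if (length(r$lengths) >= 2) {
      for (j in seq_len(length(r$lengths) - 1)) {
        if (tt[run_end[j]] - tt[run_start[j]] > 4 &&
            tt[run_end[j + 1]] - tt[run_start[j + 1]] >= 4)
          want <- want + 1L
      }
    }
    expect_equal(got, want)
  }
})

test_that("binding-position histograms recover a 20 kb lesion peak", {
  set.seed(4)
  pos <- rnorm(503, 20000, 500)
  lh <- lesion_histogram(pos, bin_width_bp = 500)
  expect_true(lh$fit_ok)
  expect_lt(abs(lh$center_bp - 20000), 100)
  expect_equal(sum(lh$counts), 503)
  expect_equal(lh$n, 503)
  # histogram conservation under rebinning
  lh2 <- lesion_histogram(pos, bin_width_bp = 237)
  expect_equal(sum(lh2$counts), 503)
  # degenerate inputs flag the fit instead of failing
  expect_false(lesion_histogram(rep(20000, 50))$fit_ok)
  set.seed(5)
  expect_false(lesion_histogram(runif(400, 0, 48502), bin_width_bp = 2000)$fit_ok)
  expect_error(lesion_histogram(1:5), "at least 10")
})

test_that("recognition calls separate direct binding from 1D search", {
  les <- lesion_site(20000)
  # stationary at the lesion from the first frame: direct 3D collision
  direct <- data.frame(time_s = 0.2 * (0:29), position_bp = rep(20100, 30))
  expect_equal(classify_recognition(direct, les)$mode, "direct-3D")
  # long 1D search ending in arrest: sliding recognition
  search <- data.frame(time_s = 0.2 * (0:59),
                       position_bp = c(seq(25000, 20000, length.out = 30),
                                       rep(20000, 30)))
  call <- classify_recognition(search, les)
  expect_equal(call$mode, "sliding-1D")
  expect_gte(call$pre_arrest_path_bp, 1000)
  # between thresholds: ambiguous
  ambig <- data.frame(time_s = 0.2 * (0:29),
                      position_bp = c(20600, 20300, rep(20100, 28)))
  expect_equal(classify_recognition(ambig, les)$mode, "ambiguous")
  # a track that never arrests at the lesion is not a recognition event
  wander <- data.frame(time_s = 0.2 * (0:29),
                       position_bp = seq(10000, 16000, length.out = 30))
  expect_equal(classify_recognition(wander, les)$mode, "none")
})

test_that("null scenes contain no bypasses and no transfers", {
  # reflecting roadblock, no hopping: bypass frequency exactly zero
  rb <- roadblock("wall", 24000)
  cfg <- sim_config(d_slide_um2_s = 0.05, hop_rate_per_s = 0,
                    roadblocks = list(rb), start_bp = 23000,
                    n_frames = 500, seed = 66)
  pop <- simulate_population(cfg, 20, geom)
  ev <- do.call(rbind, lapply(seq_along(pop), function(k) {
    score_collisions(measure_trajectory(pop[[k]], molecule_id = k,
                                        seed = 450 + k), rb, geom)
  }))
  expect_equal(sum(ev$outcome == "bypass"), 0)
  # zero transfer probability: zero classified transfers
  scene <- make_two_dna_scene(1.0, 0, sim_config(hop_rate_per_s = 0.5,
                                                 n_frames = 300, seed = 67),
                              geom, n = 10)
  n_tx <- sum(vapply(seq_along(scene), function(k)
    nrow(score_transfers(measure_trajectory(scene[[k]], molecule_id = k,
                                            seed = 500 + k),
                         axes_um = c(0, 1))), numeric(1)))
  expect_equal(n_tx, 0)
})
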