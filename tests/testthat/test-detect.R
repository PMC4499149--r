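test_that("smooth_fret is a running median with bounded edge shift", {
  ft <- mk_fret(c(rep(0.2, 10), rep(0.8, 10)))
  expect_equal(smooth_fret(ft, 1)$efret, ft$efret)

  spike <- mk_fret(c(rep(0.3, 10), 1.1, rep(0.3, 10)))
  expect_equal(smooth_fret(spike, 3)$efret, rep(0.3, 21))

  for (w in c(3, 5, 7)) {
    sm <- smooth_fret(ft, w)$efret
    edge <- which(diff(sm > 0.5) != 0)
    expect_lte(abs(edge - 10), floor(w / 2))
  }
  expect_error(smooth_fret(ft, 2), "odd")
})

test_that("reeling detection measures constructed dwell times within two frames", {
  # baseline 0.35, 16-frame ramp to 0.80, 31-frame plateau, 4-frame fall
  ef <- c(rep(0.35, 30), seq(0.35, 0.80, length.out = 17)[-1],
          rep(0.80, 31), seq(0.80, 0.35, length.out = 5)[-1], rep(0.35, 30))
  ev <- detect_reeling_events(mk_fret(ef), cfg_reeling)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "REELING")
  expect_lte(abs(ev$reeling_time - 16 * DT), 2 * DT)
  expect_lte(abs(ev$waiting_time - 31 * DT), 2 * DT)
  expect_true(ev$reached_high)

  # a rise that never reaches the plateau is not a reeling event
  ef2 <- c(rep(0.35, 30), seq(0.35, 0.55, length.out = 9)[-1],
           rep(0.55, 20), rep(0.35, 30))
  expect_equal(nrow(detect_reeling_events(mk_fret(ef2), cfg_reeling)), 0)
})

test_that("a pre-rise binding dip is flagged", {
  ef <- c(rep(0.35, 30), rep(0.27, 5),
          seq(0.27, 0.80, length.out = 13)[-1], rep(0.80, 20),
          rep(0.35, 30))
  ev <- detect_reeling_events(mk_fret(ef), cfg_reeling)
  expect_equal(nrow(ev), 1)
  expect_true(ev$binding_dip_seen)
})

test_that("GQ clusters classify by completion and dip count", {
  ef <- c(rep(0.23, 30), seq(0.23, 0.80, length.out = 13)[-1], rep(0.80, 15),
          rep(0.30, 6), rep(0.80, 15), rep(0.30, 6), rep(0.80, 15),
          rep(0.23, 30))
  ev <- detect_gq_events(mk_fret(ef), cfg_gq)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "GQ_EVENT")
  expect_equal(ev$n_cycles, 2L)

  # completed rise with no dip: unsuccessful (no unfolding seen)
  ef2 <- c(rep(0.23, 30), seq(0.23, 0.80, length.out = 13)[-1],
           rep(0.80, 20), rep(0.23, 30))
  ev2 <- detect_gq_events(mk_fret(ef2), cfg_gq)
  expect_equal(ev2$kind, "UNSUCCESSFUL_ATTEMPT")
  expect_true(ev2$reached_high)

  # sub-threshold rise: unsuccessful attempt
  ef3 <- c(rep(0.23, 30), seq(0.23, 0.55, length.out = 9)[-1],
           rep(0.55, 15), rep(0.23, 30))
  ev3 <- detect_gq_events(mk_fret(ef3), cfg_gq)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$kind, "UNSUCCESSFUL_ATTEMPT")
  expect_false(ev3$reached_high)
})

test_that("unfolding dips honor the cut-off and the nonproductive band", {
  cfgd <- construct_preset("pd-12ThGQ")$det
  ef <- c(rep(0.62, 40), seq(0.62, 0.26, length.out = 8)[-1], rep(0.26, 8),
          rep(0.62, 40))
  ev <- detect_unfolding_dips(mk_fret(ef), cfgd)
  expect_equal(ev$kind, "UNFOLDING_DIP")

  # dip bottoming at 0.45: recorded nonproductive, excluded from statistics
  ef2 <- c(rep(0.62, 40), rep(0.45, 8), rep(0.62, 40))
  ev2 <- detect_unfolding_dips(mk_fret(ef2), cfgd)
  expect_equal(ev2$kind, "UNSUCCESSFUL_ATTEMPT")
  expect_true(ev2$nonproductive)
  expect_equal(sum(ev2$kind == "UNFOLDING_DIP"), 0)

  # dips without recovery above the folded band are not counted
  ef3 <- c(rep(0.62, 40), rep(0.26, 40))
  expect_equal(nrow(detect_unfolding_dips(mk_fret(ef3), cfgd)), 0)
})

test_that("transition times resolve constructed collapse durations", {
  cfgd <- construct_preset("pd-12ThGQ")$det
  # linear drop lasting exactly 6 frames: 5 intermediate values
  ef <- c(rep(0.62, 40), seq(0.62, 0.26, length.out = 7)[-c(1, 7)],
          rep(0.26, 8), rep(0.62, 40))
  ev <- detect_unfolding_dips(mk_fret(ef), cfgd)
  expect_equal(ev$dt_uf[1], 6 * DT)

  # instantaneous drop: one frame, the resolution floor
  ef2 <- c(rep(0.62, 40), rep(0.26, 8), rep(0.62, 40))
  ev2 <- detect_unfolding_dips(mk_fret(ef2), cfgd)
  expect_equal(ev2$dt_uf[1], DT)
})

test_that("timing uncertainty follows the two-data-point convention", {
  u <- timing_uncertainty(0.032)
  expect_equal(u$raw, 0.064)
  expect_equal(u$reported, 0.07)
  u2 <- timing_uncertainty(0.050)
  expect_equal(u2$raw, 0.100)
  expect_equal(u2$reported, 0.10)
  u3 <- timing_uncertainty(0.001)
  expect_equal(u3$raw, 0.002)
  expect_equal(u3$reported, 0.01)
})

test_that("production detectors agree with the generative oracle on noiseless traces", {
  set.seed(101)
  for (mode in c("reeling", "gq")) {
    cfg <- if (mode == "reeling") cfg_reeling else cfg_gq
    for (r in 1:500) {
      tt <- random_noiseless_trace(mode)
      ev <- if (mode == "reeling")
        detect_reeling_events(tt$fret, cfg)
      else detect_gq_events(tt$fret, cfg)
      expect_equal(nrow(ev), nrow(tt$oracle))
      if (nrow(ev) && nrow(ev) == nrow(tt$oracle)) {
        expect_equal(ev$kind, tt$oracle$kind)
        if (mode == "gq") expect_equal(ev$n_cycles, tt$oracle$n_cycles)
        # boundaries agree within the longest inserted transition ramp
        # (band-crossing points are ambiguous by the ramp length)
        expect_true(all(abs(ev$t_start - tt$oracle$t_start) <= 12 * DT))
        expect_true(all(abs(ev$t_end - tt$oracle$t_end) <= 12 * DT))
      }
    }
  }
})

test_that("detected events are time-ordered and non-overlapping", {
  p <- construct_preset("pd-35T")
  set.seed(102)
  for (r in 1:10) {
    path <- simulate_state_path(p$kp, 300, 120)
    tr <- render_trace(path, p$fsm, p$pp)
    fret <- truncate_at_bleach(compute_fret(tr), tr)
    ev <- detect_reeling_events(fret, p$det)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$t_start) > 0))
      expect_true(all(ev$t_start[-1] >= head(ev$t_end, -1)))
    }
    expect_true(all(ev$t_end > ev$t_start))
    expect_true(all(ev$reeling_time <= ev$t_end - ev$t_start + 1e-9,
                    na.rm = TRUE))
  }
})

test_that("raising thresholds never increases event counts", {
  set.seed(103)
  g <- construct_preset("pd-30ThGQ")
  d <- construct_preset("pd-12ThGQ")
  for (r in 1:5) {
    path <- simulate_state_path(g$kp, 100, 100)
    fret <- compute_fret(render_trace(path, g$fsm, g$pp))
    counts <- vapply(c(0.55, 0.60, 0.65, 0.70), function(th) {
      cfg <- g$det; cfg$high_threshold <- th
      sum(detect_gq_events(fret, cfg)$kind == "GQ_EVENT")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))

    path2 <- simulate_state_path(d$kp, 100, 100)
    fret2 <- compute_fret(render_trace(path2, d$fsm, d$pp))
    counts2 <- vapply(c(0.38, 0.35, 0.32, 0.29), function(cut) {
      cfg <- d$det; cfg$unfold_cutoff <- cut
      sum(detect_unfolding_dips(fret2, cfg)$kind == "UNFOLDING_DIP")
    }, numeric(1))
    expect_true(all(diff(counts2) <= 0))
  }
})

test_that("events overlapping the bleach point are discarded", {
  ef <- c(rep(0.35, 50), seq(0.35, 0.8, length.out = 11)[-1], rep(0.8, 200))
  ft <- mk_fret(ef)
  ft$valid_until <- 100L  # bleach mid-plateau
  expect_equal(nrow(detect_reeling_events(ft, cfg_reeling)), 0)
})
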