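kp_polyT <- kinetic_params(event_amp_A = 0.35, event_Keq = 86.2,
                           titrant = "BLM", spacer_length = 35,
                           gq_length = 0)
kp_gq <- kinetic_params(event_amp_A = 0.17, event_Keq = 13.3,
                        titrant = "ATP", spacer_length = 30, gq_length = 23,
                        p_unfold = 0.7, conc_unit = "uM")

ALLOWED <- list(
  UNBOUND_FOLDED = c("BOUND"),
  BOUND = c("REELING", "WAITING_AT_JUNCTION"),
  REELING = c("WAITING_AT_JUNCTION"),
  WAITING_AT_JUNCTION = c("UNFOLDING_COLLAPSE", "RELEASED"),
  UNFOLDING_COLLAPSE = c("UNFOLDED"),
  UNFOLDED = c("POST_UNFOLD_REELING"),
  POST_UNFOLD_REELING = c("WAITING_AT_JUNCTION", "RELEASED"),
  RELEASED = c("UNBOUND_FOLDED", "BOUND"))

legal_path <- function(path) {
  segs <- path$segments
  if (any(segs$t_end <= segs$t_start)) return(FALSE)
  if (nrow(segs) < 2) return(TRUE)
  if (max(abs(segs$t_start[-1] - head(segs$t_end, -1))) > 1e-9)
    return(FALSE)
  from <- segs$state[-nrow(segs)]
  to <- segs$state[-1]
  all(mapply(function(f, t) t %in% ALLOWED[[f]], from, to))
}

test_that("forced outcomes produce exactly one collapse per event", {
  kp <- kp_gq
  kp$p_unfold <- 1; kp$dissociation_prob_per_cycle <- 1
  set.seed(4)
  for (r in 1:20) {
    path <- simulate_state_path(kp, 50, 60)
    ev <- path$events[path$events$complete, ]
    if (!nrow(ev)) next
    expect_true(all(ev$n_cycles == 1L))
    expect_true(all(ev$success))
  }
})

test_that("poly-T mode never unfolds", {
  set.seed(5)
  for (r in 1:20) {
    path <- simulate_state_path(kp_polyT, 300, 100)
    expect_false(any(path$segments$state %in%
                       c("UNFOLDING_COLLAPSE", "UNFOLDED",
                         "POST_UNFOLD_REELING")))
    expect_false(any(path$events$success))
  }
})

test_that("event initiations at c = Keq follow the half-saturation Poisson mean", {
  set.seed(6)
  dur <- 10000
  path <- simulate_state_path(kp_polyT, 86.2, dur)
  n <- nrow(path$events)
  mu <- 0.35 / 2 * dur
  expect_lt(abs(n - mu), 3 * sqrt(mu))
})

test_that("initiation counts in disjoint windows are Poisson", {
  # low-occupancy regime so queueing delays are negligible
  kp <- kp_polyT; kp$event_amp_A <- 0.04
  set.seed(7)
  path <- simulate_state_path(kp, 1e6 * kp$event_Keq, 50000)
  starts <- path$events$t_start
  win <- 100
  counts <- tabulate(pmin(floor(starts / win) + 1, 500), nbins = 500)
  lam <- mean(counts)
  expect_lt(abs(lam - 0.04 * win) / (0.04 * win), 0.1)
  kmax <- max(counts)
  obs <- tabulate(counts + 1, nbins = kmax + 1)
  pr <- dpois(0:kmax, lam)
  pr[kmax + 1] <- 1 - sum(pr[1:kmax])
  keep <- pr * length(counts) >= 1
  gof <- suppressWarnings(
    stats::chisq.test(obs[keep], p = pr[keep] / sum(pr[keep])))
  expect_gt(gof$p.value, 0.01)
})

test_that("state paths respect the transition graph", {
  set.seed(8)
  kp <- kp_gq; kp$event_amp_A <- 0.8
  n_checked <- 0
  for (r in 1:3000) {
    path <- simulate_state_path(kp, 40, 8)
    expect_true(legal_path(path))
    n_checked <- n_checked + nrow(path$segments)
  }
  expect_gt(n_checked, 10000)
})

test_that("the success fraction converges to p_unfold", {
  set.seed(21)
  succ <- integer(0)
  for (r in 1:60) {
    path <- simulate_state_path(kp_gq, 40, 200)
    succ <- c(succ, path$events$success)
  }
  n <- length(succ)
  expect_gt(n, 500)
  ci <- stats::prop.test(sum(succ), n)$conf.int
  expect_true(ci[1] <= 0.7 && 0.7 <= ci[2])
})

test_that("zero reeling velocity with a spacer is a parameter error", {
  kp <- kp_polyT
  kp$reel_velocity_max <- 0
  expect_error(simulate_state_path(kp, 100, 10), "velocity")
})

test_that("zero-noise rendering reproduces the state-map levels exactly", {
  fsm <- fret_state_map(baseline_mean = 0.35, baseline_sigma = 0.06,
                        bound_dip_mean = 0.30, high_mean = 0.80)
  pp <- photophysics_params(noise_sd_floor = 0)
  # idle path renders flat at the baseline
  kp0 <- kp_polyT; kp0$event_amp_A <- 0
  set.seed(10)
  path0 <- simulate_state_path(kp0, 100, 5)
  tr0 <- render_trace(path0, fsm, pp)
  expect_equal(compute_fret(tr0)$efret, rep(0.35, length(tr0)))

  # active path: every constant-state frame sits exactly on its state mean
  set.seed(11)
  path <- simulate_state_path(kp_polyT, 500, 60)
  tr <- render_trace(path, fsm, pp)
  ef <- compute_fret(tr)$efret
  st <- tr$truth_states
  expect_equal(ef[st == "UNBOUND_FOLDED"],
               rep(0.35, sum(st == "UNBOUND_FOLDED")))
  expect_equal(ef[st == "BOUND"], rep(0.30, sum(st == "BOUND")))
  expect_equal(ef[st == "WAITING_AT_JUNCTION"],
               rep(0.80, sum(st == "WAITING_AT_JUNCTION")))
  # reeling frames ramp monotonically between baseline and high
  expect_true(all(ef[st == "REELING"] >= 0.35 - 1e-12 &
                    ef[st == "REELING"] <= 0.80 + 1e-12))
})

test_that("a zero-noise reeling ramp is linear over the segment", {
  fsm <- fret_state_map(baseline_mean = 0.35, high_mean = 0.80)
  pp <- photophysics_params(noise_sd_floor = 0)
  segs <- data.frame(state = c("UNBOUND_FOLDED", "REELING",
                               "WAITING_AT_JUNCTION"),
                     t_start = c(0, 1, 1.5), t_end = c(1, 1.5, 3))
  path <- structure(list(segments = segs,
                         events = data.frame(), duration = 3,
                         concentration = 1, params = kp_polyT),
                    class = "state_path")
  tr <- render_trace(path, fsm, pp)
  ef <- compute_fret(tr)$efret
  ramp <- which(tr$truth_states == "REELING")
  expect_lte(abs(length(ramp) - 0.5 / DT), 1)
  expect_equal(max(abs(diff(diff(ef[ramp])))), 0, tolerance = 1e-10)
  expect_lt(ef[ramp[1]], ef[ramp[length(ramp)]])
})

test_that("rendered noise matches the configured FRET peak width", {
  fsm <- fret_state_map(baseline_mean = 0.35, baseline_sigma = 0.06)
  pp <- photophysics_params(
    noise_sd_floor = noise_floor_for_sigma(fsm, 1000))
  kp0 <- kp_polyT; kp0$event_amp_A <- 0
  set.seed(12)
  path <- simulate_state_path(kp0, 1, 200)
  tr <- render_trace(path, fsm, pp)
  ef <- compute_fret(tr)$efret
  expect_lt(abs(sd(ef) - 0.06) / 0.06, 0.1)
  expect_lt(abs(mean(ef) - 0.35), 0.01)
})

test_that("titration datasets are seed-reproducible and Langmuir-monotone", {
  fsm <- fret_state_map(baseline_mean = 0.35, baseline_sigma = 0.06)
  pp <- photophysics_params(noise_sd_floor = 60)
  concs <- c(10, 30, 90, 270, 810)
  d1 <- simulate_titration(kp_polyT, fsm, pp, concs, n_traces = 4,
                           duration = 40, seed = 99)
  d2 <- simulate_titration(kp_polyT, fsm, pp, concs, n_traces = 4,
                           duration = 40, seed = 99)
  expect_identical(d1$points[[3]]$traces[[2]]$donor,
                   d2$points[[3]]$traces[[2]]$donor)
  expect_identical(d1$points[[5]]$truth_event_counts,
                   d2$points[[5]]$truth_event_counts)

  set.seed(13)
  d3 <- simulate_titration(kp_polyT, fsm, pp, concs, n_traces = 12,
                           duration = 100, seed = 14)
  totals <- vapply(d3$points, function(p) sum(p$truth_event_counts),
                   numeric(1))
  expect_gt(suppressWarnings(cor(concs, totals, method = "spearman")), 0)
})

test_that("the saturation limit recovers the amplitude", {
  set.seed(15)
  n <- 0; Tt <- 0
  for (r in 1:30) {
    path <- simulate_state_path(kp_polyT, 1e6 * kp_polyT$event_Keq, 200)
    n <- n + nrow(path$events)
    Tt <- Tt + 200
  }
  rate <- n / Tt
  se <- sqrt(n) / Tt
  expect_lt(abs(rate - 0.35), 3 * se + 0.35 * 0.02)
})

test_that("expected_event_rate is the closed-form isotherm", {
  expect_equal(expected_event_rate(kp_polyT, 0), 0)
  expect_equal(expected_event_rate(kp_polyT, 86.2), 0.35 / 2)
  kp <- kinetic_params(event_amp_A = 0.17, event_Keq = 15.2,
                       titrant = "ATP", conc_unit = "uM")
  expect_equal(expected_event_rate(kp, 15.2), 0.085)
})
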