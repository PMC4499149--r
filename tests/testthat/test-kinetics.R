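test_that("event rates divide counts by total time including empty traces", {
  ev <- data.frame(kind = rep("REELING", 30),
                   trace_id = rep(1:3, each = 10),
                   nonproductive = FALSE)
  dur <- setNames(rep(50, 4), as.character(1:4))  # trace 4 has no events
  tp <- event_rate(ev, dur, kinds = "REELING")
  expect_equal(tp$rate, 30 / 200)
  expect_equal(tp$n_events, 30)

  # zero events over any time is a zero rate, not an error
  tp0 <- event_rate(ev[0, ], dur)
  expect_equal(tp0$rate, 0)
  expect_error(event_rate(ev, numeric(0)))

  # guard: dropping the zero-event trace from the denominator must change
  # the rate, so the implementation cannot be doing that
  tp3 <- event_rate(ev, dur[1:3], kinds = "REELING")
  expect_false(isTRUE(all.equal(tp$rate, tp3$rate)))
  expect_equal(tp3$rate, 30 / 150)
})

test_that("split errors vanish for identical groups and track Poisson scatter", {
  # 9 identical traces: every partition into 3 gives identical group rates
  ev <- data.frame(kind = "REELING", trace_id = 1:9, nonproductive = FALSE)
  dur <- setNames(rep(10, 9), as.character(1:9))
  expect_equal(split_error(ev, dur, seed = 1), 0)
  expect_error(split_error(ev, dur[1:2]), "splits")

  # Poisson events at rate r: the split error approximates the SD of a
  # group-mean rate, sqrt(r / T_group), on average over replicates
  r <- 0.2; n_tr <- 60; Tt <- 50
  T_group <- n_tr / 3 * Tt
  set.seed(42)
  errs <- replicate(100, {
    counts <- rpois(n_tr, r * Tt)
    evp <- data.frame(kind = rep("REELING", sum(counts)),
                      trace_id = rep(seq_len(n_tr), counts),
                      nonproductive = FALSE)
    split_error(evp, setNames(rep(Tt, n_tr), seq_len(n_tr)),
                seed = sample.int(1e6, 1))
  })
  expect_lt(abs(mean(errs) - sqrt(r / T_group)) / sqrt(r / T_group), 0.5)
})

test_that("split error expectation is stable under repartitioning", {
  set.seed(43)
  counts <- rpois(60, 8)
  ev <- data.frame(kind = rep("REELING", sum(counts)),
                   trace_id = rep(1:60, counts), nonproductive = FALSE)
  dur <- setNames(rep(50, 60), 1:60)
  e1 <- vapply(1:200, function(s) split_error(ev, dur, seed = s), numeric(1))
  e2 <- vapply(201:400, function(s) split_error(ev, dur, seed = s),
               numeric(1))
  expect_false(isTRUE(all.equal(e1[1], e1[2])))  # partitions differ
  expect_lt(abs(mean(e1) - mean(e2)) / mean(c(e1, e2)), 0.1)
})

test_that("the isotherm is half-saturated at Keq, monotone and bounded", {
  expect_equal(langmuir(0, 0.5, 10), 0)
  expect_equal(langmuir(10, 0.5, 10), 0.25)
  expect_equal(langmuir(140.7, 0.48, 140.7), 0.24)
  cc <- seq(0, 5000, by = 25)
  y <- langmuir(cc, 0.48, 140.7)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y <= 0.48))
})

test_that("noiseless isotherm fits recover parameters to numerical tolerance", {
  cc <- 10^seq(log10(5), log10(500), length.out = 7)
  f <- fit_langmuir(data.frame(concentration = cc,
                               rate = langmuir(cc, 0.35, 86.2)))
  expect_lt(abs(f$A / 0.35 - 1), 1e-6)
  expect_lt(abs(f$Keq / 86.2 - 1), 1e-6)
  expect_true(f$identifiable)

  set.seed(44)
  for (r in 1:15) {
    A <- runif(1, 0.01, 10); K <- runif(1, 1, 1000)
    ccs <- K * 10^seq(-1.5, 1.5, length.out = 8)
    fs <- fit_langmuir(data.frame(concentration = ccs,
                                  rate = langmuir(ccs, A, K)))
    expect_lt(abs(fs$A / A - 1), 1e-6)
    expect_lt(abs(fs$Keq / K - 1), 1e-6)
  }
})

test_that("a flat titration is flagged unidentifiable", {
  cc <- 10^seq(0, 3, length.out = 7)
  f <- suppressWarnings(
    fit_langmuir(data.frame(concentration = cc, rate = rep(0.3, 7))))
  expect_false(f$identifiable)
  expect_error(fit_langmuir(data.frame(concentration = 1:2, rate = 1:2)),
               "3 titration points")
})

test_that("fitted parameters cover the truth under Poisson noise", {
  # Poisson counting noise is heteroscedastic, so the calibrated error
  # model is the weighted fit with per-point counting errors
  A <- 0.35; K <- 86.2; Tt <- 5000
  cc <- 10^seq(log10(5), log10(500), length.out = 7)
  set.seed(45)
  hits <- replicate(200, {
    n <- rpois(length(cc), langmuir(cc, A, K) * Tt)
    f <- fit_langmuir(data.frame(concentration = cc, rate = n / Tt,
                                 rate_error = sqrt(pmax(n, 1)) / Tt),
                      weighted = TRUE)
    abs(f$A - A) <= 3 * f$A_err && abs(f$Keq - K) <= 3 * f$Keq_err
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Gaussian peak fits recover single and double peaks", {
  set.seed(46)
  g1 <- fit_gaussians(rnorm(10000, 0.35, 0.06), 1)
  expect_lt(abs(g1$components$mean - 0.35), 0.01)
  expect_lt(abs(g1$components$sigma - 0.06), 0.01)

  x2 <- c(rnorm(5000, 0.46, 0.04), rnorm(5000, 0.62, 0.05))
  g2 <- fit_gaussians(x2, 2)
  expect_equal(nrow(g2$components), 2)
  expect_lt(abs(g2$components$mean[1] - 0.46), 0.02)
  expect_lt(abs(g2$components$mean[2] - 0.62), 0.02)
  expect_equal(sum(g2$components$weight), 1)

  # delta-like histogram: mean at the occupied bin, sigma below bin width
  gd <- suppressWarnings(fit_gaussians(rep(0.5, 30), 1, bin_width = 0.02))
  expect_equal(gd$components$mean, 0.5)
  expect_lte(gd$components$sigma, 0.02)
})

test_that("success fractions are amplitude ratios", {
  expect_equal(unfold_success_fraction(0.12, 0.17), 12 / 17)
  expect_equal(round(unfold_success_fraction(0.12, 0.17), 2), 0.71)
  expect_equal(round(unfold_success_fraction(0.18, 0.35), 2), 0.51)
  expect_equal(unfold_success_fraction(0.2, 0.2), 1.0)
  expect_error(unfold_success_fraction(0.1, 0), "zero")
  f1 <- structure(list(A = 0.12), class = "isotherm_fit")
  f2 <- structure(list(A = 0.17), class = "isotherm_fit")
  expect_equal(unfold_success_fraction(f1, f2), 12 / 17)
})
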