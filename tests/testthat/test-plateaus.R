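test_that("detector finds square pulses with interpolated edges", {
  tr <- square_trace(pulses = list(c(100, 350, 40)))
  segs <- detect_plateaus(tr, threshold = -30, min_duration = 5)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$duration, 250, tolerance = 0.5 / 250)
  expect_false(segs$open_ended)
  expect_equal(segs$V_peak, 40)

  expect_equal(nrow(detect_plateaus(square_trace(pulses = list()))), 0)

  # min_duration filters the 3 ms pulse but keeps the 50 ms one
  tr2 <- square_trace(pulses = list(c(100, 150, 40), c(300, 303, 40)))
  segs2 <- detect_plateaus(tr2, min_duration = 5)
  expect_equal(nrow(segs2), 1)
  expect_equal(segs2$t_on, 100, tolerance = 1)
})

test_that("a segment reaching the trace end is flagged open-ended", {
  tr <- square_trace(t_total = 500, pulses = list(c(100, 600, 40)))
  segs <- detect_plateaus(tr)
  expect_true(segs$open_ended)
  expect_equal(segs$t_off, 500)
})

test_that("measured durations are insensitive to output-grid refinement", {
  p <- model_parameters()
  sched <- feeding_schedule(t_total = 1200, params = p)
  d1 <- detect_plateaus(simulate_model(p, sched, dt_out = 0.5))$duration
  d2 <- detect_plateaus(simulate_model(p, sched, dt_out = 0.25))$duration
  expect_equal(length(d1), length(d2))
  expect_lt(max(abs(d1 - d2)), 1)
})

test_that("mean duration uses closed segments only", {
  segs <- detect_plateaus(square_trace(pulses = list(c(100, 350, 40))))
  expect_equal(mean_plateau_duration(segs)$mean, 250, tolerance = 1e-2)
  expect_equal(mean_plateau_duration(segs)$n, 1)
  empty <- mean_plateau_duration(detect_plateaus(square_trace(pulses = list())))
  expect_true(empty$empty)
  expect_equal(empty$mean, 0)
})

test_that("regime labels: commanded plateaus, unending, two-level, quiescent", {
  p <- model_parameters()
  sched <- feeding_schedule(t_total = 2100, params = p)
  tr <- simulate_model(p, sched)
  expect_equal(classify_regime(tr, sched), "physiological")

  # a trace that never repolarizes after the first EPSP
  tr_un <- square_trace(t_total = 2100, pulses = list(c(100, 2200, 40)))
  expect_equal(classify_regime(tr_un, sched), "unending")

  # constructed two-step plateau: 40 mV for 300 ms, 0 mV for 300 ms, rest
  tt <- seq(0, 1000, 0.5)
  V <- rep(-65, length(tt))
  V[tt >= 100 & tt < 400] <- 40
  V[tt >= 400 & tt < 700] <- 0
  tr_2l <- structure(data.frame(t = tt, V = V), dt_out = 0.5)
  sched1k <- feeding_schedule(t_total = 1000, params = p)
  expect_equal(classify_regime(tr_2l, sched1k), "two_level")

  expect_equal(classify_regime(square_trace(pulses = list()), sched1k),
               "quiescent")
})

test_that("two-level band voltages are recovered from constructed traces", {
  tt <- seq(0, 1000, 0.5)
  V <- rep(-65, length(tt))
  V[tt >= 100 & tt < 400] <- 40
  V[tt >= 400 & tt < 700] <- 0
  tr <- structure(data.frame(t = tt, V = V), dt_out = 0.5)
  seg <- detect_plateaus(tr)[1, ]
  b <- plateau_levels(tr, seg)
  expect_equal(b$upper, 40, tolerance = 1e-6)
  expect_equal(b$lower, 0, tolerance = 1e-6)
  # a single-level plateau has no second band
  tr1 <- square_trace(pulses = list(c(100, 350, 40)))
  b1 <- plateau_levels(tr1, detect_plateaus(tr1)[1, ])
  expect_true(is.na(b1$upper))
})

test_that("wedge depth: constructed dip, absent for monotone relaxation", {
  tt <- seq(0, 400, 0.5)
  V <- rep(-65, length(tt))
  V[tt >= 100 & tt < 300] <- 38
  V[tt >= 100 & tt < 110] <- 40
  V[tt >= 110 & tt < 125] <- 25
  tr <- data.frame(t = tt, V = V)
  seg <- detect_plateaus(tr)[1, ]
  expect_equal(wedge_depth(tr, seg), 15)

  # monotone relaxing plateau (ultrafast shape): no wedge beyond the trend
  p <- model_parameters()
  tru <- quick_protocol(p)
  expect_lt(wedge_depth(tru, detect_plateaus(tru)[2, ]), 2)
})

test_that("wedge depth grows with the inactivation time constant", {
  p <- model_parameters()
  w <- sapply(c(1, 5, 10, 20), function(th) {
    pp <- p; pp$tau_h <- th
    tr <- quick_protocol(pp)
    wedge_depth(tr, detect_plateaus(tr)[2, ])
  })
  expect_true(all(diff(w) >= 0))   # monotone nondecreasing in tau_h
  expect_gt(w[2], 0)               # noticeable wedge from 5 ms up
  expect_gt(w[3], w[2])            # 10 ms wedge exceeds the 5 ms wedge
})
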