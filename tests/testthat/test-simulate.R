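test_that("leak-only relaxation matches the closed form to < 0.01 mV", {
  # gK = gCaT = gCaL = 0, start at 0 mV: V(t) = VL + (V0 - VL) exp(-t gL / C)
  p <- model_parameters(gK = 0, gCaT = 0, gCaL = 0, C = 10)
  tr <- simulate_model(p, event_schedule(t_total = 25), t_total = 25,
                       y0 = state_vector(V = 0), dt_out = 0.5)
  expected <- leak_relaxation(tr$t, 0, -65, 2, 10)
  expect_lt(max(abs(tr$V - expected)), 0.01)
  # tau = C/gL = 5 ms: V(5) = -65 + 65/e
  expect_equal(tr$V[tr$t == 5], -65 + 65 * exp(-1), tolerance = 1e-4)
})

test_that("synaptic conductance decays exponentially after a spike", {
  p <- model_parameters()
  s <- event_schedule(100, "EPSP", 3.0, t_total = 120)
  tr <- simulate_model(p, s, t_total = 120)
  after <- tr$t > 100   # the sample at the event time itself is pre-event
  expected <- 3.0 * exp(-(tr$t[after] - 100) / p$tauE)
  expect_lt(max(abs(tr$gE[after] - expected)), 1e-6)
  expect_equal(tr$gE[tr$t == 101], 3.0 / exp(1), tolerance = 1e-6)
})

test_that("an unstimulated cell stays at rest", {
  p <- model_parameters()
  r <- resting_state(p)
  tr <- simulate_model(p, event_schedule(t_total = 1000), t_total = 1000)
  expect_lt(max(abs(tr$V - r[["V"]])), 0.1)
})

test_that("simulation is deterministic and seeds control noise realizations", {
  p <- model_parameters()
  a <- simulate_reference_protocol(p, noise_config(0.05, seed = 21), 3000)
  b <- simulate_reference_protocol(p, noise_config(0.05, seed = 21), 3000)
  expect_identical(a$V, b$V)
  c2 <- simulate_reference_protocol(p, noise_config(0.05, seed = 22), 3000)
  expect_false(identical(a$V, c2$V))
  # lam = 0 noise is the same trace as no noise at all
  d <- simulate_reference_protocol(p, noise_config(0, seed = 21), 3000)
  e <- simulate_reference_protocol(p, NULL, 3000)
  expect_identical(d$V, e$V)
})

test_that("halving solver tolerances moves V by < 0.1 mV", {
  p <- model_parameters()
  a <- simulate_reference_protocol(p, NULL, 2000, rtol = 1e-6, atol = 1e-9)
  b <- simulate_reference_protocol(p, NULL, 2000, rtol = 5e-7, atol = 5e-10)
  expect_lt(max(abs(a$V - b$V)), 0.1)
})

test_that("chunked integration reproduces the single-call trace", {
  p <- model_parameters()
  noise <- noise_config(0.05, seed = 31)
  a <- simulate_reference_protocol(p, noise, 4000)
  b <- simulate_reference_protocol(p, noise, 4000, chunk_ms = 1000)
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$V - b$V)), 0.01)
})

test_that("gating variables stay in [0, 1] along noisy and noiseless trajectories", {
  for (tau_h in list("instantaneous", 5)) {
    p <- model_parameters(tau_h = tau_h)
    tr <- simulate_reference_protocol(p, noise_config(0.05, seed = 41), 3000)
    g <- as.matrix(tr[, c("w", "h", "mT", "hT", "mL", "hL")])
    expect_true(all(g >= -1e-6 & g <= 1 + 1e-6))
    expect_true(all(tr$gE >= -1e-9 & tr$gI >= -1e-9))
    expect_true(all(is.finite(as.matrix(tr))))
  }
})

test_that("equal-time events are order-stable under the documented tie order", {
  p <- model_parameters()
  # IPSP and noise quantum at the same instant, supplied in either order
  s1 <- event_schedule(c(100, 500, 500), c("EPSP", "IPSP", "NOISE"),
                       c(3, 2.5, 0.45), t_total = 800)
  s2 <- event_schedule(c(500, 500, 100), c("NOISE", "IPSP", "EPSP"),
                       c(0.45, 2.5, 3), t_total = 800)
  a <- simulate_model(p, s1)
  b <- simulate_model(p, s2)
  expect_identical(a$V, b$V)
  # assignment first, then addition: gI just after the event is ~2.95
  expect_equal(a$gI[a$t == 500.5],
               2.95 * exp(-0.5 / p$tauI), tolerance = 1e-3)
})

test_that("the ultrafast variant is the small-tau_h limit of the finite variant", {
  pu <- model_parameters()
  tru <- simulate_reference_protocol(pu, NULL, 1600, rtol = 1e-8, atol = 1e-11)
  errs <- sapply(c(0.1, 0.03, 0.01), function(th) {
    pf <- model_parameters(tau_h = th)
    trf <- simulate_reference_protocol(pf, NULL, 1600, rtol = 1e-8, atol = 1e-11)
    # compare away from the near-vertical plateau edges, where a time lag of
    # tau_h shifts a ~300 mV/ms transition and any voltage metric explodes
    slope <- c(0, abs(diff(tru$V))) / 0.5
    interior <- slope < 20
    max(abs(tru$V[interior] - trf$V[interior]))
  })
  expect_lt(errs[3], 1)                 # tau_h = 0.01 ms within 1 mV
  expect_true(all(diff(errs) < 0))      # and converging as tau_h shrinks
  # plateau durations agree to sub-sample precision at tau_h = 0.01
  pf <- model_parameters(tau_h = 0.01)
  trf <- simulate_reference_protocol(pf, NULL, 1600, rtol = 1e-8, atol = 1e-11)
  du <- detect_plateaus(tru)$duration
  df <- detect_plateaus(trf)$duration
  expect_equal(du, df, tolerance = 1e-4)
})

test_that("traces round-trip through CSV", {
  p <- model_parameters()
  tr <- quick_protocol(p, t_total = 600)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  tr2 <- read_trace_csv(path)
  expect_equal(tr2$V, tr$V, tolerance = 1e-12)
  expect_equal(names(tr2), names(as.data.frame(tr)))
})

test_that("solver failures name the failing time", {
  p <- model_parameters()
  expect_error(
    simulate_model(p, event_schedule(t_total = 100), t_total = 100,
                   y0 = state_vector(V = 1e6)),
    "solver failure|non-finite|illegal input")
})
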