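test_that("feeding schedule places EPSP/IPSP pairs at the commanded times", {
  p <- model_parameters()
  s <- feeding_schedule(250, 250, 1100, 100, p)
  expect_equal(s$t[s$kind == "EPSP"], c(100, 600))
  expect_equal(s$t[s$kind == "IPSP"], c(350, 850))
  expect_true(all(s$magnitude[s$kind == "EPSP"] == p$gsynE_max))
  expect_true(all(s$magnitude[s$kind == "IPSP"] == p$gsynI_max))
  expect_true(all(s$t < attr(s, "t_total")))

  s2 <- feeding_schedule(10, 10, 100, 0, p)
  expect_equal(sum(s2$kind == "EPSP"), 5)
  expect_equal(sum(s2$kind == "IPSP"), 5)
})

test_that("a first plateau that does not fit is an error", {
  expect_error(feeding_schedule(250, 250, 200, 100), "fit")
  expect_error(feeding_schedule(-250, 250, 1000, 100), "positive")
})

test_that("events sort by time with the EPSP < IPSP < NOISE tie order", {
  s <- event_schedule(t = c(50, 50, 50, 10), kind = c("NOISE", "EPSP", "IPSP", "NOISE"),
                      magnitude = c(0.3, 3, 2.5, 0.15), t_total = 100)
  expect_equal(s$kind, c("NOISE", "EPSP", "IPSP", "NOISE"))
  expect_equal(s$t, c(10, 50, 50, 50))
})

test_that("apply_event semantics: spikes assign, noise adds", {
  p <- model_parameters()
  s <- state_vector(V = -65, gI = 0.4)
  expect_equal(apply_event(s, "NOISE", 0.30, p)[["gI"]], 0.70)
  s2 <- state_vector(V = -65, gE = 0.2)
  expect_equal(apply_event(s2, "EPSP", params = p)[["gE"]], 3.0)
  s3 <- state_vector(V = -65, gI = 2.5)
  expect_equal(apply_event(s3, "IPSP", params = p)[["gI"]], 2.5)  # idempotent
  # noise never touches the excitatory conductance
  expect_equal(apply_event(s2, "NOISE", 1.0, p)[["gE"]], 0.2)
})

test_that("noise train is deterministic in the seed and empty at lam = 0", {
  p <- model_parameters()
  a <- sample_noise_train(noise_config(0.05, seed = 11), 5000, p)
  b <- sample_noise_train(noise_config(0.05, seed = 11), 5000, p)
  expect_identical(a, b)
  c2 <- sample_noise_train(noise_config(0.05, seed = 12), 5000, p)
  expect_false(identical(a, c2))
  expect_equal(nrow(sample_noise_train(noise_config(0, seed = 1), 5000, p)), 0)
  # sampling restores the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(sample_noise_train(noise_config(0.05, seed = 5), 1000, p))
  expect_identical(.Random.seed, before)
})

test_that("noise train count statistics match the Poisson law", {
  p <- model_parameters()
  # total channel openings over 20 s at lam = 0.05: mean 1000, sd sqrt(1000)
  tr <- sample_noise_train(noise_config(0.05, bin_ms = 1, seed = 4), 20000, p)
  total <- sum(tr$magnitude) / p$noise_quantum
  expect_lt(abs(total - 1000), 3 * sqrt(1000))
  # mean inter-event gap at lam = 0.01 is 1/P(k > 0) ~ 100.5 ms
  tr2 <- sample_noise_train(noise_config(0.01, bin_ms = 1, seed = 4), 2e5, p)
  expect_lt(abs(mean(diff(tr2$t)) - 100), 10)
  # per-bin count histogram vs the Poisson pmf (chi-square GOF)
  lam <- 0.05; nb <- 1e5
  tr3 <- sample_noise_train(noise_config(lam, bin_ms = 1, seed = 42), nb, p)
  k <- round(tr3$magnitude / p$noise_quantum)
  obs <- c(nb - nrow(tr3), sum(k == 1), sum(k >= 2))
  prob <- c(dpois(0, lam), dpois(1, lam), 1 - ppois(1, lam))
  chi2 <- sum((obs - nb * prob)^2 / (nb * prob))
  expect_gt(pchisq(chi2, df = 2, lower.tail = FALSE), 0.01)
})

test_that("schedules round-trip bit-exactly through CSV", {
  p <- model_parameters()
  s <- merge_schedules(feeding_schedule(250, 250, 2000, 100, p),
                       sample_noise_train(noise_config(0.05, seed = 3), 2000, p))
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(s, path)
  s2 <- read_schedule_csv(path)
  expect_identical(s$t, s2$t)
  expect_identical(s$magnitude, s2$magnitude)
  expect_identical(s$kind, s2$kind)
  expect_identical(attr(s, "t_total"), attr(s2, "t_total"))
})

test_that("merging requires a common duration and preserves ordering", {
  a <- event_schedule(10, "EPSP", 3, t_total = 100)
  b <- event_schedule(20, "IPSP", 2.5, t_total = 200)
  expect_error(merge_schedules(a, b), "t_total")
  c2 <- event_schedule(c(10, 5), c("NOISE", "NOISE"), c(0.15, 0.3), t_total = 100)
  m <- merge_schedules(a, c2)
  expect_equal(m$t, c(5, 10, 10))
  expect_equal(m$kind, c("NOISE", "EPSP", "NOISE"))
})
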