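#' Derive a per-condition seed from a base seed
#'
#' Conditions draw their noise seeds from a documented counter scheme,
#' `(base_seed mod 1e6) * 2000 + index`, so adding a condition never
#' reshuffles the seeds of existing ones and all derived seeds stay well
#' below 2^31.
#'
#' @param base_seed integer base seed.
#' @param index condition counter (1, 2, ...).
#' @return integer seed.
#' @export
condition_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) %% 1e6) * 2000 + index)
}

closed_durations <- function(trace, thresholds = regime_thresholds()) {
  segs <- detect_plateaus(trace, thresholds$detect_threshold,
                          thresholds$min_duration)
  segs$duration[!segs$open_ended]
}

#' Conductance-space sweep of the reference protocol
#'
#' Simulates the noiseless reference feeding protocol in every cell of a
#' gK x gCaL grid, recording the mean closed-plateau duration, the number of
#' plateaus and the regime label. This maps the model's behavioral regions:
#' a low-amplitude region at small gCaL, a central physiological band, and
#' an unending-plateau region at large gCaL where the IPSP can no longer
#' terminate the plateau.
#'
#' @param gK_values,gCaL_values grid axes, nS. Defaults cover 0-10 and
#'   0-7.5 nS in 0.25 nS steps (coarser grids via the arguments).
#' @param tau_h `"instantaneous"` or a time constant in ms.
#' @param Vhalf_inact inactivation midpoint, mV (the sweep reference uses
#'   15 mV).
#' @param t_total per-cell protocol duration, ms.
#' @param params base parameter set; each cell overrides `gK`, `gCaL`,
#'   `tau_h` and `Vhalf_inact`.
#' @param thresholds a [regime_thresholds()] list.
#' @param ... passed to [simulate_model()].
#' @return an `exp2_sweep` data frame: one row per cell with columns `gK`,
#'   `gCaL`, `mean_duration`, `n_plateaus`, `regime`.
#' @export
run_conductance_sweep <- function(gK_values = seq(0, 10, by = 0.25),
                                  gCaL_values = seq(0, 7.5, by = 0.25),
                                  tau_h = "instantaneous",
                                  Vhalf_inact = 15,
                                  t_total = 3000,
                                  params = model_parameters(),
                                  thresholds = regime_thresholds(), ...) {
  grid <- expand.grid(gK = gK_values, gCaL = gCaL_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$gK <- grid$gK[i]; p$gCaL <- grid$gCaL[i]
    p$tau_h <- tau_h; p$Vhalf_inact <- Vhalf_inact
    res <- tryCatch({
      sched <- feeding_schedule(t_total = t_total, params = p)
      tr <- simulate_model(p, sched, ...)
      md <- mean_plateau_duration(detect_plateaus(tr, thresholds$detect_threshold,
                                                  thresholds$min_duration))
      data.frame(gK = p$gK, gCaL = p$gCaL,
                 mean_duration = if (md$empty) NA_real_ else md$mean,
                 n_plateaus = md$n,
                 regime = classify_regime(tr, sched, thresholds))
    }, error = function(e)
      data.frame(gK = p$gK, gCaL = p$gCaL, mean_duration = NA_real_,
                 n_plateaus = 0L, regime = "failure"))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exp2_sweep", "data.frame")
  out
}

run_noise_conditions <- function(cond, t_total, n_seeds, base_seed, params,
                                 thresholds, dt_out, ...) {
  # cond: data.frame with columns label, Vhalf, tau_h (list), lam
  rows <- list()
  baselines <- list()
  ci <- 0L
  for (i in seq_len(nrow(cond))) {
    p <- params
    p$Vhalf_inact <- cond$Vhalf[i]
    p$tau_h <- cond$tau_h[[i]]
    key <- paste(cond$Vhalf[i], format(cond$tau_h[[i]]))
    if (is.null(baselines[[key]])) {
      tr0 <- simulate_reference_protocol(p, noise = NULL, t_total = t_total,
                                         dt_out = dt_out, ...)
      baselines[[key]] <- closed_durations(tr0, thresholds)
    }
    base_dur <- baselines[[key]]
    lam <- cond$lam[i]
    if (lam == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant = cond$label[i], Vhalf = cond$Vhalf[i],
        tau_h = format(cond$tau_h[[i]]), lam = 0, seed = NA_integer_,
        n = length(base_dur), mean_duration = mean(base_dur),
        sd_duration = stats::sd(base_dur), z = 0, effect = 0)
      next
    }
    dur_all <- list()
    for (s in seq_len(n_seeds)) {
      ci <- ci + 1L
      seed <- condition_seed(base_seed, 100L * i + s)
      tr <- simulate_reference_protocol(
        p, noise = noise_config(lam, seed = seed), t_total = t_total,
        dt_out = dt_out, ...)
      d <- closed_durations(tr, thresholds)
      dur_all[[s]] <- d
      rep <- if (length(d)) effect_report(d, base_dur) else
        list(z = NA_real_, effect = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = cond$label[i], Vhalf = cond$Vhalf[i],
        tau_h = format(cond$tau_h[[i]]), lam = lam, seed = seed,
        n = length(d), mean_duration = if (length(d)) mean(d) else NA_real_,
        sd_duration = if (length(d) > 1) stats::sd(d) else NA_real_,
        z = rep$z, effect = rep$effect)
    }
    pooled <- unlist(dur_all)
    rep <- if (length(pooled)) effect_report(pooled, base_dur) else
      list(z = NA_real_, effect = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = cond$label[i], Vhalf = cond$Vhalf[i],
      tau_h = format(cond$tau_h[[i]]), lam = lam, seed = NA_integer_,
      n = length(pooled),
      mean_duration = if (length(pooled)) mean(pooled) else NA_real_,
      sd_duration = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
      z = rep$z, effect = rep$effect)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exp2_conditions", "data.frame")
  out
}

#' Noise robustness across inactivation midpoints
#'
#' Runs the ultrafast model under the reference feeding protocol for each
#' half-inactivation voltage and noise intensity, collecting closed plateau
#' durations and comparing each noisy condition against the same-midpoint
#' noiseless run with the Mann-Whitney z and the effect size |z|/sqrt(N).
#' Rows with `seed = NA` at `lam > 0` are pooled over seeds.
#'
#' @param vhalf_list half-inactivation voltages, mV.
#' @param lam_list Poisson intensities per bin (0 = noiseless reference).
#' @param t_total per-condition run length, ms (the full study uses 1000 s;
#'   pass smaller values for quick looks).
#' @param n_seeds independent noise realizations per condition.
#' @param base_seed expanded to per-condition seeds via [condition_seed()].
#' @param params base parameters.
#' @param thresholds a [regime_thresholds()] list.
#' @param dt_out output step, ms.
#' @param ... passed to [simulate_model()].
#' @return an `exp2_conditions` data frame.
#' @export
run_noise_robustness <- function(vhalf_list = c(10, 15, 20),
                                 lam_list = c(0, 0.01, 0.05),
                                 t_total = 1e6, n_seeds = 3, base_seed = 1,
                                 params = model_parameters(),
                                 thresholds = regime_thresholds(),
                                 dt_out = 0.5, ...) {
  cond <- expand.grid(Vhalf = vhalf_list, lam = lam_list,
                      KEEP.OUT.ATTRS = FALSE)
  cond$label <- "ultrafast"
  cond$tau_h <- rep(list("instantaneous"), nrow(cond))
  run_noise_conditions(cond, t_total, n_seeds, base_seed, params,
                       thresholds, dt_out, ...)
}

#' Noise robustness across inactivation time constants
#'
#' As [run_noise_robustness()], but for the finite-tau_h variant at a fixed
#' half-inactivation voltage, keyed by `tau_h`.
#'
#' @param tau_list inactivation time constants, ms.
#' @param Vhalf_inact half-inactivation voltage, mV.
#' @inheritParams run_noise_robustness
#' @return an `exp2_conditions` data frame.
#' @export
run_timescale_robustness <- function(tau_list = c(1, 5, 10, 20),
                                     lam_list = c(0, 0.01, 0.05),
                                     Vhalf_inact = 15,
                                     t_total = 1e6, n_seeds = 3, base_seed = 1,
                                     params = model_parameters(),
                                     thresholds = regime_thresholds(),
                                     dt_out = 0.5, ...) {
  cond <- expand.grid(tau = tau_list, lam = lam_list, KEEP.OUT.ATTRS = FALSE)
  cond$Vhalf <- Vhalf_inact
  cond$label <- "finite_tau_h"
  cond$tau_h <- as.list(cond$tau)
  run_noise_conditions(cond[, c("label", "Vhalf", "tau_h", "lam")],
                       t_total, n_seeds, base_seed, params, thresholds,
                       dt_out, ...)
}

#' Interaction of inactivation and synaptic timescales
#'
#' Sweeps the K-current inactivation time constant against the inhibitory
#' synaptic decay time constant (which sets the duration of noise events)
#' under fixed-intensity noise, recording the mean plateau duration per
#' combination. One curve per synaptic time constant.
#'
#' @param tau_h_list inactivation time constants, ms.
#' @param tau_syn_list inhibitory synaptic time constants, ms.
#' @param lam noise intensity per 1 ms bin (the high-noise value by
#'   default; the figure-level intensity is configurable).
#' @param t_total run length per combination, ms (reference: 100 s).
#' @param n_seeds noise realizations per combination.
#' @param base_seed seed base.
#' @param Vhalf_inact half-inactivation voltage, mV.
#' @param params base parameters.
#' @param thresholds a [regime_thresholds()] list.
#' @param ... passed to [simulate_model()].
#' @return data frame with columns `tau_h`, `tau_syn`, `n`, `mean_duration`.
#' @export
run_timescale_interaction <- function(tau_h_list = c(0.5, 1, 2, 3, 4, 5, 6, 8, 10),
                                      tau_syn_list = 1:5,
                                      lam = 0.05, t_total = 1e5, n_seeds = 1,
                                      base_seed = 1, Vhalf_inact = 15,
                                      params = model_parameters(),
                                      thresholds = regime_thresholds(), ...) {
  grid <- expand.grid(tau_h = tau_h_list, tau_syn = tau_syn_list,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$tau_h <- grid$tau_h[i]
    p$tauI <- grid$tau_syn[i]
    p$Vhalf_inact <- Vhalf_inact
    durs <- unlist(lapply(seq_len(n_seeds), function(s) {
      seed <- condition_seed(base_seed, 100L * i + s)
      tr <- simulate_reference_protocol(
        p, noise = noise_config(lam, seed = seed), t_total = t_total, ...)
      closed_durations(tr, thresholds)
    }))
    data.frame(tau_h = grid$tau_h[i], tau_syn = grid$tau_syn[i],
               n = length(durs),
               mean_duration = if (length(durs)) mean(durs) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-event termination threshold of a plateau
#'
#' Bisects the magnitude of a lone inhibitory conductance increment that
#' just terminates the plateau containing `t_inject` under the noiseless
#' reference protocol. This measures how large a shot-noise excursion must
#' be to trip the K-current deinactivation latch, and is the package's
#' quantitative handle on noise sensitivity as a function of the
#' inactivation midpoint.
#'
#' @param params an [model_parameters()] object.
#' @param t_inject injection time, ms; must fall inside a commanded plateau.
#' @param max_magnitude upper bisection bound, nS.
#' @param iterations bisection steps (resolution
#'   `max_magnitude / 2^iterations`).
#' @param thresholds a [regime_thresholds()] list.
#' @param ... passed to [simulate_model()].
#' @return threshold magnitude, nS.
#' @export
termination_threshold <- function(params, t_inject = 700,
                                  max_magnitude = 6, iterations = 18,
                                  thresholds = regime_thresholds(), ...) {
  t_total <- ceiling((t_inject + 900) / 500) * 500
  base <- feeding_schedule(t_total = t_total, params = params)
  ipsp_after <- min(base$t[base$kind == "IPSP" & base$t > t_inject])
  lo <- 0; hi <- max_magnitude
  for (k in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    ev <- event_schedule(t_inject, "NOISE", mid, t_total = t_total)
    tr <- simulate_model(params, merge_schedules(base, ev),
                         t_total = t_total, ...)
    win <- tr$t > t_inject & tr$t < ipsp_after - 1
    terminated <- any(tr$V[win] < thresholds$detect_threshold)
    if (terminated) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
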