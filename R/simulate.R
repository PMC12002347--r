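#' Simulate the membrane model over an event schedule
#'
#' Integrates the model with the adaptive stiff LSODA solver (via
#' \pkg{deSolve} and the package's compiled right-hand side), applying the
#' schedule's discrete conductance events as exact discontinuities: the
#' solver is restarted at every event time, never stepped across one.
#' Output is sampled on a uniform grid of step `dt_out`. Runs are
#' deterministic given identical inputs and tolerances.
#'
#' Equal-time events are combined in the documented tie order
#' (EPSP < IPSP < NOISE): assignments first, then additive noise quanta.
#'
#' @param params an [model_parameters()] object.
#' @param schedule an `exp2_schedule` (may be empty).
#' @param t_total simulation length, ms; defaults to the schedule's
#'   `t_total`.
#' @param dt_out output sampling step, ms. The default 0.5 ms bounds the
#'   quantization of plateau-duration measurements to well under a
#'   millisecond.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param y0 initial state; defaults to [resting_state()].
#' @param chunk_ms if not `NULL`, integrate in chunks of this length
#'   (identical results; bounds solver memory on very long runs).
#' @return an `exp2_trace`: a data frame with columns `t`, `V`, `w`, `h`,
#'   `mT`, `hT`, `mL`, `hL`, `gE`, `gI`, one row per output time. In the
#'   ultrafast variant the `h` column reports \eqn{h_\infty(V)}. Attributes:
#'   `params`, `dt_out`, `schedule_digest`.
#' @examples
#' p <- model_parameters()
#' tr <- simulate_model(p, feeding_schedule(250, 250, 1100, 100, p))
#' range(tr$V)
#' @export
simulate_model <- function(params, schedule, t_total = attr(schedule, "t_total"),
                           dt_out = 0.5, rtol = 1e-6, atol = 1e-9,
                           y0 = resting_state(params), chunk_ms = NULL) {
  validate_parameters(params)
  stopifnot(inherits(schedule, "exp2_schedule"), t_total > 0, dt_out > 0)
  ev <- canonical_events(schedule, params)

  # events at t = 0 belong to the initial condition
  if (nrow(ev) && any(ev$time <= 0)) {
    for (i in which(ev$time <= 0)) {
      y0[ev$var[i]] <- if (ev$method[i] == "rep") ev$value[i] else
        y0[ev$var[i]] + ev$value[i]
    }
    ev <- ev[ev$time > 0, , drop = FALSE]
  }

  if (is.null(chunk_ms)) {
    bounds <- t_total
  } else {
    # chunk boundaries snapped to the output grid so samples stay uniform
    step <- max(round(chunk_ms / dt_out), 2) * dt_out
    bounds <- unique(c(seq(0, t_total, by = step), t_total))
  }
  bounds <- bounds[bounds > 0]

  y <- y0
  pieces <- vector("list", length(bounds))
  t0 <- 0
  for (ci in seq_along(bounds)) {
    t1 <- bounds[ci]
    times <- seq(t0, t1, by = dt_out)
    if (times[length(times)] < t1) times <- c(times, t1)
    sub <- ev[ev$time > t0 & ev$time < t1, , drop = FALSE]
    out <- run_lsoda(y, times, params, sub, rtol, atol)
    y <- unname(out[nrow(out), -1L])
    names(y) <- .state_names
    # events sitting exactly on a chunk boundary apply before the next chunk
    atb <- ev[ev$time == t1, , drop = FALSE]
    if (nrow(atb)) {
      for (i in seq_len(nrow(atb))) {
        y[atb$var[i]] <- if (atb$method[i] == "rep") atb$value[i] else
          y[atb$var[i]] + atb$value[i]
      }
    }
    pieces[[ci]] <- if (ci == 1L) out else out[-1L, , drop = FALSE]
    t0 <- t1
  }
  out <- do.call(rbind, pieces)

  tr <- as.data.frame(out)
  names(tr) <- c("t", .state_names)
  keep <- abs(tr$t / dt_out - round(tr$t / dt_out)) < 1e-8
  tr <- tr[keep, , drop = FALSE]
  rownames(tr) <- NULL
  if (is_ultrafast(params))
    tr$h <- gating_steady_state("hK", tr$V, params)
  attr(tr, "params") <- params
  attr(tr, "dt_out") <- dt_out
  attr(tr, "schedule_digest") <- schedule_digest(schedule)
  class(tr) <- c("exp2_trace", "data.frame")
  tr
}

# one LSODA call over [times], with discontinuities handled by deSolve's
# known-time event mechanism (the solver reinitializes at each event)
run_lsoda <- function(y, times, params, ev, rtol, atol) {
  events <- if (nrow(ev))
    list(data = data.frame(var = ev$var, time = ev$time,
                           value = ev$value, method = ev$method)) else NULL
  out <- withCallingHandlers(
    deSolve::ode(y = y, times = times, func = "exp2_derivs",
                 parms = as_parms_vector(params),
                 dllname = "exp2plateau", initfunc = "exp2_initmod",
                 method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 100000L, events = events),
    warning = function(w) {
      # deSolve warns about event times vs output times even when they
      # coincide; the output grid is checked for integrity below
      if (grepl("event", conditionMessage(w), ignore.case = TRUE))
        invokeRestart("muffleWarning")
    })
  if (nrow(out) < length(times) || !all(is.finite(out)))
    stop(sprintf("solver failure near t = %.3f ms",
                 out[max(1L, nrow(out)), 1L]))
  out
}

# collapse the schedule into one deSolve event row per (time, variable):
# assignments (EPSP/IPSP) first per the tie order, then noise quanta added
canonical_events <- function(schedule, params) {
  if (!nrow(schedule))
    return(data.frame(var = character(), time = numeric(),
                      value = numeric(), method = character()))
  var <- ifelse(schedule$kind == "EPSP", "gE", "gI")
  rows <- split(seq_len(nrow(schedule)), paste(schedule$t, var))
  res <- lapply(rows, function(ix) {
    sub <- schedule[ix, , drop = FALSE]
    v <- if (sub$kind[1] == "EPSP") "gE" else "gI"
    assign_ix <- which(sub$kind %in% c("EPSP", "IPSP"))
    add <- sum(sub$magnitude[sub$kind == "NOISE"])
    if (length(assign_ix)) {
      data.frame(var = v, time = sub$t[1],
                 value = sub$magnitude[assign_ix[length(assign_ix)]] + add,
                 method = "rep")
    } else {
      data.frame(var = v, time = sub$t[1], value = add, method = "add")
    }
  })
  ev <- do.call(rbind, res)
  ev <- ev[order(ev$time, ev$var), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# cheap content checksum recorded on traces for provenance
schedule_digest <- function(schedule) {
  sprintf("n=%d;st=%.10g;sm=%.10g;tt=%.10g", nrow(schedule),
          sum(schedule$t), sum(schedule$magnitude), attr(schedule, "t_total"))
}

#' Simulate the reference feeding protocol
#'
#' Composes the deterministic MC/M3 feeding schedule (250 ms plateaus,
#' 250 ms inter-stimulus interval by default), optionally merged with a
#' Poisson inhibitory noise train, and integrates the model.
#'
#' @param params an [model_parameters()] object.
#' @param noise a [noise_config()] or `NULL` for noiseless runs. A `lam = 0`
#'   configuration is identical to `NULL`.
#' @param t_total run length, ms.
#' @param plateau_ms,isi_ms,t_first protocol timing, ms.
#' @param ... passed to [simulate_model()] (`dt_out`, tolerances, ...).
#' @return an `exp2_trace`.
#' @export
simulate_reference_protocol <- function(params, noise = NULL, t_total,
                                        plateau_ms = 250, isi_ms = 250,
                                        t_first = 100, ...) {
  sched <- feeding_schedule(plateau_ms, isi_ms, t_total, t_first, params)
  if (!is.null(noise)) {
    tr <- sample_noise_train(noise, t_total, params)
    if (nrow(tr)) sched <- merge_schedules(sched, tr)
  }
  simulate_model(params, sched, t_total = t_total, ...)
}

#' @export
print.exp2_trace <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Simulation trace: %d samples, t = [0, %g] ms, dt_out = %g ms\n",
              nrow(x), x$t[nrow(x)], attr(x, "dt_out")))
  cat(sprintf("  variant: %s; V range [%.2f, %.2f] mV\n",
              if (is_ultrafast(p)) "ultrafast" else
                sprintf("tau_h = %g ms", p$tau_h),
              min(x$V), max(x$V)))
  invisible(x)
}

#' Trace CSV round trip
#'
#' Traces export to CSV with columns `t_ms`, `V_mV`, `w`, `h`, `mT`, `hT`,
#' `mL`, `hL`, `gE_nS`, `gI_nS`.
#'
#' @param trace an `exp2_trace`.
#' @param path file path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a data frame with the trace columns (attributes are not
#'   preserved across the CSV boundary).
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  names(df) <- c("t_ms", "V_mV", "w", "h", "mT", "hT", "mL", "hL",
                 "gE_nS", "gI_nS")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  names(df) <- c("t", .state_names)
  df
}
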