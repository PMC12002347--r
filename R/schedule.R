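#' Event schedules
#'
#' An event schedule is a data frame with columns `t` (ms), `kind`
#' (`"EPSP"`, `"IPSP"` or `"NOISE"`) and `magnitude` (nS), carrying the total
#' duration as attribute `t_total`. Events are kept sorted by time with the
#' deterministic tie order EPSP < IPSP < NOISE. EPSP/IPSP magnitudes are the
#' synaptic conductance values *assigned* at spike times; NOISE magnitudes
#' are *added* to the inhibitory conductance (see [apply_event()]).
#'
#' @param t event times, ms.
#' @param kind event kinds.
#' @param magnitude event magnitudes, nS.
#' @param t_total schedule duration, ms; all events must satisfy `t < t_total`.
#' @return an `exp2_schedule` data frame.
#' @export
event_schedule <- function(t = numeric(), kind = character(),
                           magnitude = numeric(), t_total) {
  stopifnot(length(t) == length(kind), length(t) == length(magnitude),
            t_total > 0)
  if (length(t)) {
    if (any(!is.finite(t)) || any(t < 0)) stop("event times must be finite and >= 0")
    if (any(t >= t_total)) stop("all event times must be < t_total")
    if (any(magnitude < 0)) stop("event magnitudes must be >= 0")
    if (!all(kind %in% c("EPSP", "IPSP", "NOISE"))) stop("unknown event kind")
  }
  sched <- data.frame(t = as.numeric(t), kind = as.character(kind),
                      magnitude = as.numeric(magnitude))
  ord <- order(sched$t, match(sched$kind, c("EPSP", "IPSP", "NOISE")))
  sched <- sched[ord, , drop = FALSE]
  rownames(sched) <- NULL
  attr(sched, "t_total") <- as.numeric(t_total)
  class(sched) <- c("exp2_schedule", "data.frame")
  sched
}

#' Deterministic MC/M3 feeding schedule
#'
#' Builds the reference stimulus: EPSPs (plateau-initiating, from the MC
#' neuron) at `t_first + k * (plateau_ms + isi_ms)`, each followed by an
#' IPSP (plateau-terminating, from M3) `plateau_ms` later. All events before
#' `t_total` are kept; a trailing EPSP whose IPSP does not fit produces an
#' open-ended final plateau, which downstream statistics exclude.
#'
#' @param plateau_ms commanded plateau length, ms (reference value 250).
#' @param isi_ms inter-stimulus interval between plateaus, ms (reference 250).
#' @param t_total schedule duration, ms.
#' @param t_first time of the first EPSP, ms (default 100, a warm-up that
#'   lets initialization transients decay).
#' @param params an [model_parameters()] object supplying the EPSP/IPSP
#'   magnitudes.
#' @return an `exp2_schedule`.
#' @examples
#' s <- feeding_schedule(250, 250, 1100, 100)
#' s$t[s$kind == "EPSP"]  # 100, 600
#' s$t[s$kind == "IPSP"]  # 350, 850
#' @export
feeding_schedule <- function(plateau_ms = 250, isi_ms = 250, t_total,
                             t_first = 100, params = model_parameters()) {
  if (plateau_ms <= 0 || isi_ms <= 0 || t_total <= 0 || t_first < 0)
    stop("durations must be positive")
  if (t_first + plateau_ms > t_total)
    stop("first plateau does not fit in t_total")
  period <- plateau_ms + isi_ms
  epsp <- t_first + (0:floor((t_total - t_first) / period)) * period
  epsp <- epsp[epsp < t_total]
  ipsp <- epsp + plateau_ms
  ipsp <- ipsp[ipsp < t_total]
  event_schedule(
    t = c(epsp, ipsp),
    kind = c(rep("EPSP", length(epsp)), rep("IPSP", length(ipsp))),
    magnitude = c(rep(params$gsynE_max, length(epsp)),
                  rep(params$gsynI_max, length(ipsp))),
    t_total = t_total
  )
}

#' Poisson shot-noise configuration
#'
#' @param lam expected number of noise channel openings per bin
#'   (dimensionless; 0.01 is the reference low-noise and 0.05 the
#'   high-noise intensity).
#' @param bin_ms width of the bin over which `lam` applies, ms.
#' @param seed integer seed; identical configuration gives an identical train.
#' @return a `noise_config` list.
#' @export
noise_config <- function(lam, bin_ms = 1, seed = 1L) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0, bin_ms > 0)
  structure(list(lam = lam, bin_ms = bin_ms, seed = as.integer(seed)),
            class = "noise_config")
}

#' Sample an inhibitory shot-noise train
#'
#' Draws a Poisson count `k ~ Poisson(lam)` for every bin of width `bin_ms`;
#' bins with `k > 0` emit one NOISE event at the bin start with magnitude
#' `k * noise_quantum`, representing `k` simultaneous channel openings.
#' Noise targets the inhibitory synaptic conductance only; it never touches
#' the excitatory one. The sampler uses its own RNG stream and restores the
#' caller's RNG state.
#'
#' @param cfg a [noise_config()].
#' @param t_total train duration, ms.
#' @param params an [model_parameters()] object (for `noise_quantum`).
#' @return an `exp2_schedule` of NOISE events.
#' @examples
#' tr <- sample_noise_train(noise_config(0.05, seed = 7), 1000)
#' nrow(tr)  # about 49 events: 1000 bins, P(k > 0) = 1 - exp(-0.05)
#' @export
sample_noise_train <- function(cfg, t_total, params = model_parameters()) {
  stopifnot(inherits(cfg, "noise_config"), t_total > 0)
  n_bins <- floor(t_total / cfg$bin_ms)
  if (n_bins < 1L || cfg$lam == 0)
    return(event_schedule(t_total = t_total))
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  k <- rpois(n_bins, cfg$lam)
  hit <- which(k > 0L)
  event_schedule(
    t = (hit - 1L) * cfg$bin_ms,
    kind = rep("NOISE", length(hit)),
    magnitude = k[hit] * params$noise_quantum,
    t_total = t_total
  )
}

#' Merge event schedules
#'
#' Concatenates schedules and re-sorts by time with the EPSP < IPSP < NOISE
#' tie order. All schedules must share `t_total`.
#'
#' @param ... `exp2_schedule` objects.
#' @return an `exp2_schedule`.
#' @export
merge_schedules <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L)
  tt <- unique(vapply(xs, attr, 0, "t_total"))
  if (length(tt) != 1L) stop("schedules have differing t_total")
  all <- do.call(rbind, lapply(xs, as.data.frame))
  event_schedule(all$t, all$kind, all$magnitude, t_total = tt)
}

#' Apply one synaptic event to a state
#'
#' EPSPs assign `gE <- gsynE_max` and IPSPs assign `gI <- gsynI_max`
#' (assignment, not addition: a spike resets the synapse to its maximal
#' conductance). NOISE events add their magnitude to `gI`, uncapped, so
#' noise quanta superpose on whatever inhibitory conductance is active.
#' All other state entries are unchanged.
#'
#' @param state a [state_vector()].
#' @param kind event kind (`"EPSP"`, `"IPSP"`, `"NOISE"`).
#' @param magnitude event magnitude, nS (used for NOISE; EPSP/IPSP take
#'   their assigned value from `params` when `magnitude` is missing).
#' @param params an [model_parameters()] object.
#' @return the updated state vector.
#' @export
apply_event <- function(state, kind, magnitude = NULL,
                        params = model_parameters()) {
  kind <- match.arg(kind, c("EPSP", "IPSP", "NOISE"))
  s <- state
  if (kind == "EPSP") {
    s[["gE"]] <- if (is.null(magnitude)) params$gsynE_max else magnitude
  } else if (kind == "IPSP") {
    s[["gI"]] <- if (is.null(magnitude)) params$gsynI_max else magnitude
  } else {
    if (is.null(magnitude)) stop("NOISE events need a magnitude")
    s[["gI"]] <- s[["gI"]] + magnitude
  }
  s
}

#' Schedule CSV round trip
#'
#' Event schedules serialize to CSV with columns `t_ms`, `kind`,
#' `magnitude_nS`. The round trip is bit-exact (times and magnitudes are
#' written with full precision).
#'
#' @param sched an `exp2_schedule`.
#' @param path file path.
#' @return `write_schedule_csv()` returns `path` invisibly;
#'   `read_schedule_csv()` returns the schedule.
#' @export
write_schedule_csv <- function(sched, path) {
  stopifnot(inherits(sched, "exp2_schedule"))
  df <- data.frame(t_ms = sprintf("%.17g", sched$t),
                   kind = sched$kind,
                   magnitude_nS = sprintf("%.17g", sched$magnitude))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_total_ms=%.17g", attr(sched, "t_total")), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# t_total_ms=")) stop("not a schedule CSV: ", path)
  tt <- as.numeric(sub("# t_total_ms=", "", header))
  df <- read.csv(path, skip = 1L, colClasses = c("character", "character", "character"))
  event_schedule(as.numeric(df$t_ms), df$kind, as.numeric(df$magnitude_nS),
                 t_total = tt)
}
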