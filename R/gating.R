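#' Steady-state gating curves
#'
#' Voltage dependence of the model's gating variables at steady state.
#' Activation curves (`w`, `mT`, `mL`) are monotone nondecreasing in V;
#' inactivation curves (`hK`, `hT`, `hL`) are monotone nonincreasing.
#' `hK` is the K-current inactivation whose midpoint is the parameter
#' `Vhalf_inact`; in the ultrafast model variant the K current uses this
#' curve pointwise.
#'
#' @param curve_id one of `"w"`, `"hK"`, `"mT"`, `"hT"`, `"mL"`, `"hL"`.
#' @param V membrane potential, mV (vectorised).
#' @param params an [model_parameters()] object (used for `hK`).
#' @return steady-state value(s) in \[0, 1\].
#' @examples
#' gating_steady_state("w", 12)                      # 0.5 at the midpoint
#' gating_steady_state("hK", 40, model_parameters()) # essentially 0
#' @export
gating_steady_state <- function(curve_id, V, params = model_parameters()) {
  stopifnot(all(is.finite(V)))
  switch(match.arg(curve_id, c("w", "hK", "mT", "hT", "mL", "hL")),
    w  = 0.5 * (1 + tanh((V - 12) / 17.4)),
    hK = 0.5 * (1 - tanh((V - params$Vhalf_inact) / params$k_inact)),
    mT = 0.5 * (1 + tanh((V + 45) / 6)),
    hT = 0.5 * (1 - tanh((V + 40) / 3)),
    mL = 1 / (1 + exp(-(V + 20) / 6.5)),
    hL = 1 / (1 + exp((V - 135) / 55))
  )
}

#' Voltage-dependent gating time constants
#'
#' Time constants of the relaxation of each gating variable towards its
#' steady state, in ms. `tau_w` is symmetric about 12 mV and `tau_mT` about
#' 14.5 mV (reciprocal-cosh forms); `tau_hL` varies between 300 ms at
#' hyperpolarized and 200 ms at depolarized potentials, making L-type
#' inactivation the slowest process in the model. The K-current inactivation
#' time constant is the parameter `tau_h` itself, not a function of V, so it
#' is not listed here.
#'
#' @inheritParams gating_steady_state
#' @return time constant(s), ms, strictly positive.
#' @examples
#' gating_time_constant("w", 12)  # 1 ms at the midpoint
#' @export
gating_time_constant <- function(curve_id, V, params = model_parameters()) {
  stopifnot(all(is.finite(V)))
  switch(match.arg(curve_id, c("w", "mT", "hT", "mL", "hL")),
    w  = 1 / cosh((V - 12) / 34.8),
    mT = 1 / (0.5 * cosh((V - 14.5) / 34.8)),
    hT = 65 / (1 + exp((V + 40) / 7)),
    mL = 1 / (1 + exp((V + 27) / 10)),
    hL = 200 + 100 / (1 + exp((V + 40) / 7))
  )
}
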