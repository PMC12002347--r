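#' Model parameters for the pharyngeal muscle plateau model
#'
#' Builds the full parameter set of the conductance-based pharyngeal corpus
#' muscle model: a leak current, a T-type (CCA-1-like) and an L-type
#' (EGL-19-like) calcium current, a potassium current with voltage-dependent
#' ultrafast (or finite time-constant) inactivation modelled on EXP-2, and
#' decaying excitatory/inhibitory synaptic conductances.
#'
#' Defaults are the model's reference values. The membrane capacitance
#' default (2 pF) is calibrated so that the reference feeding protocol
#' (250 ms plateaus, 250 ms inter-stimulus interval) produces commanded
#' plateaus near +40 mV that are initiated by a single EPSP and terminated
#' by a single IPSP for every inactivation midpoint in 10--20 mV; see the
#' package vignette.
#'
#' @param C membrane capacitance, pF.
#' @param gL,gK,gCaT,gCaL maximal conductances of the leak, K, T-type Ca and
#'   L-type Ca currents, nS.
#' @param gsynE_max,gsynI_max synaptic conductance values assigned at EPSP /
#'   IPSP times, nS.
#' @param VL,VK,VCa,VsynE,VsynI reversal potentials, mV.
#' @param Vhalf_inact half-inactivation voltage of the K current, mV. The
#'   steady-state inactivation is
#'   \eqn{h_\infty(V) = 0.5\,(1 - \tanh((V - V_{1/2})/k))}.
#' @param k_inact inactivation slope factor, mV.
#' @param w_rate dimensionless rate multiplier on the K-current activation
#'   kinetics.
#' @param tauE,tauI synaptic decay time constants, ms.
#' @param tau_h K-current inactivation time constant in ms, or the string
#'   `"instantaneous"` for the ultrafast variant in which inactivation tracks
#'   \eqn{h_\infty(V)} pointwise.
#' @param noise_quantum conductance added to the inhibitory synapse per noise
#'   channel opening, nS.
#'
#' @return An object of class `exp2_parameters`: a named list with the fields
#'   above.
#' @examples
#' p <- model_parameters()
#' p$gK
#' pf <- model_parameters(tau_h = 20)   # finite inactivation time constant
#' @export
model_parameters <- function(C = 2.0,
                             gL = 2.0, gK = 9.0, gCaT = 3.0, gCaL = 3.7,
                             gsynE_max = 3.0, gsynI_max = 2.5,
                             VL = -65.0, VK = -70.0, VCa = 100.0,
                             VsynE = 0.0, VsynI = -65.0,
                             Vhalf_inact = 15.0, k_inact = 3.0,
                             w_rate = 0.04,
                             tauE = 1.0, tauI = 2.0,
                             tau_h = "instantaneous",
                             noise_quantum = 0.15) {
  p <- list(C = C, gL = gL, gK = gK, gCaT = gCaT, gCaL = gCaL,
            gsynE_max = gsynE_max, gsynI_max = gsynI_max,
            VL = VL, VK = VK, VCa = VCa, VsynE = VsynE, VsynI = VsynI,
            Vhalf_inact = Vhalf_inact, k_inact = k_inact, w_rate = w_rate,
            tauE = tauE, tauI = tauI, tau_h = tau_h,
            noise_quantum = noise_quantum)
  class(p) <- "exp2_parameters"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of an [model_parameters()] object:
#' non-negative conductances, strictly positive time constants and
#' capacitance, and a valid `tau_h` (positive number or `"instantaneous"`).
#'
#' @param p an `exp2_parameters` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_parameters <- function(p) {
  expected <- names(formals(model_parameters))
  if (!setequal(names(p), expected)) {
    bad <- setdiff(names(p), expected)
    miss <- setdiff(expected, names(p))
    stop("invalid parameter fields",
         if (length(bad)) paste0("; unknown: ", paste(bad, collapse = ", ")),
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")))
  }
  num <- p[setdiff(expected, "tau_h")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), TRUE)))
    stop("all parameters except tau_h must be finite scalars")
  g <- c("gL", "gK", "gCaT", "gCaL", "gsynE_max", "gsynI_max", "noise_quantum")
  if (any(unlist(p[g]) < 0)) stop("conductances must be >= 0")
  if (p$C <= 0) stop("capacitance C must be > 0")
  if (p$tauE <= 0 || p$tauI <= 0) stop("synaptic time constants must be > 0")
  if (p$k_inact <= 0) stop("k_inact must be > 0")
  if (p$w_rate <= 0) stop("w_rate must be > 0")
  th <- p$tau_h
  ok <- (is.character(th) && length(th) == 1L && th == "instantaneous") ||
    (is.numeric(th) && length(th) == 1L && is.finite(th) && th > 0)
  if (!ok) stop("tau_h must be a positive time constant (ms) or \"instantaneous\"")
  invisible(p)
}

#' @export
print.exp2_parameters <- function(x, ...) {
  variant <- if (is_ultrafast(x)) "ultrafast (instantaneous h)"
             else sprintf("finite inactivation, tau_h = %g ms", x$tau_h)
  cat("Pharyngeal muscle model parameters [", variant, "]\n", sep = "")
  cat(sprintf("  C = %g pF; gL = %g, gK = %g, gCaT = %g, gCaL = %g nS\n",
              x$C, x$gL, x$gK, x$gCaT, x$gCaL))
  cat(sprintf("  V1/2(inact) = %g mV (slope %g mV); w_rate = %g\n",
              x$Vhalf_inact, x$k_inact, x$w_rate))
  cat(sprintf("  synapses: gE_max = %g, gI_max = %g nS; tauE = %g, tauI = %g ms; quantum = %g nS\n",
              x$gsynE_max, x$gsynI_max, x$tauE, x$tauI, x$noise_quantum))
  invisible(x)
}

# TRUE when the K current uses instantaneous inactivation
is_ultrafast <- function(p) identical(p$tau_h, "instantaneous")

# numeric parameter vector for the compiled right-hand side
as_parms_vector <- function(p) {
  v <- unlist(p[setdiff(.parms_order, "tau_h")], use.names = TRUE)
  c(v, tau_h = if (is_ultrafast(p)) -1.0 else as.numeric(p$tau_h))[.parms_order]
}

#' Write / read a parameter configuration file
#'
#' Parameters round-trip losslessly through a plain-text YAML file whose keys
#' are exactly the fields of [model_parameters()]. Unknown keys are an error,
#' so a stale or misspelled configuration cannot pass silently.
#'
#' @param p an `exp2_parameters` object.
#' @param path file path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns an `exp2_parameters` object.
#' @export
write_model_config <- function(p, path) {
  validate_parameters(p)
  yaml::write_yaml(unclass(p), path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(model_parameters))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  do.call(model_parameters, raw)
}
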