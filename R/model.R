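#' Construct a model state vector
#'
#' A state is a named numeric vector with entries `V` (mV), the gating
#' variables `w`, `h`, `mT`, `hT`, `mL`, `hL` (dimensionless, in \[0, 1\])
#' and the synaptic conductances `gE`, `gI` (nS). In the ultrafast variant
#' the `h` entry is carried along but the K current uses
#' \eqn{h_\infty(V)} pointwise.
#'
#' @param V membrane potential, mV.
#' @param w,h,mT,hT,mL,hL gating variables.
#' @param gE,gI synaptic conductances, nS.
#' @return named numeric vector of length 9.
#' @export
state_vector <- function(V, w = 0, h = 1, mT = 0, hT = 1, mL = 0, hL = 1,
                         gE = 0, gI = 0) {
  s <- c(V = V, w = w, h = h, mT = mT, hT = hT, mL = mL, hL = hL,
         gE = gE, gI = gI)
  if (!all(is.finite(s))) stop("non-finite state")
  gates <- s[c("w", "h", "mT", "hT", "mL", "hL")]
  if (any(gates < 0 | gates > 1)) stop("gating variables must lie in [0, 1]")
  if (s["gE"] < 0 || s["gI"] < 0) stop("synaptic conductances must be >= 0")
  s
}

#' Signed membrane current contribution of one channel
#'
#' Returns the term contributed by the named channel to `C dV/dt`, in pA,
#' with the sign convention that positive values are depolarizing. Each term
#' has the form \eqn{-g \cdot (\mathrm{gating}) \cdot (V - V_\mathrm{rev})}:
#' the T-type gating product is \eqn{m_T^2 h_T}, the L-type is
#' \eqn{m_L^2 h_L}, the K current uses \eqn{w \cdot h} (with
#' \eqn{h = h_\infty(V)} in the ultrafast variant), and the synaptic terms
#' use the conductance states `gE`, `gI` directly.
#'
#' @param channel_id one of `"leak"`, `"K"`, `"CaT"`, `"CaL"`, `"synE"`,
#'   `"synI"`.
#' @param state a [state_vector()].
#' @param params an [model_parameters()] object.
#' @return current, pA.
#' @examples
#' p <- model_parameters()
#' channel_current("K", state_vector(V = -70, w = 1, h = 1), p)  # 0 at VK
#' @export
channel_current <- function(channel_id, state, params = model_parameters()) {
  s <- state
  V <- s[["V"]]
  hK <- if (is_ultrafast(params)) gating_steady_state("hK", V, params) else s[["h"]]
  switch(match.arg(channel_id, c("leak", "K", "CaT", "CaL", "synE", "synI")),
    leak = -params$gL * (V - params$VL),
    K    = -params$gK * s[["w"]] * hK * (V - params$VK),
    CaT  = -params$gCaT * s[["mT"]]^2 * s[["hT"]] * (V - params$VCa),
    CaL  = -params$gCaL * s[["mL"]]^2 * s[["hL"]] * (V - params$VCa),
    synE = -s[["gE"]] * (V - params$VsynE),
    synI = -s[["gI"]] * (V - params$VsynI)
  )
}

#' Right-hand side of the membrane model
#'
#' Reference implementation (plain R) of the coupled ODE system; the
#' integrator uses an equivalent compiled version, and the two are tested
#' against each other. `dV/dt` is the sum of all [channel_current()] terms
#' divided by `C`; gating variables relax as \eqn{(x_\infty(V) - x)/\tau_x(V)},
#' with the K activation additionally scaled by `w_rate`; synaptic
#' conductances decay exponentially. In the ultrafast variant there is no
#' `h` dynamics (`dh/dt = 0`) and the K current uses \eqn{h_\infty(V)}.
#'
#' @param t time, ms (unused: the system is autonomous between events).
#' @param state a [state_vector()].
#' @param params an [model_parameters()] object.
#' @return named numeric vector of time derivatives, same layout as the state.
#' @export
membrane_rhs <- function(t, state, params = model_parameters()) {
  if (!all(is.finite(state))) stop("non-finite state")
  s <- state
  V <- s[["V"]]
  I <- sum(vapply(c("leak", "K", "CaT", "CaL", "synE", "synI"),
                  channel_current, 0, state = s, params = params))
  d <- c(
    V  = I / params$C,
    w  = params$w_rate *
      (gating_steady_state("w", V) - s[["w"]]) / gating_time_constant("w", V),
    h  = if (is_ultrafast(params)) 0 else
      (gating_steady_state("hK", V, params) - s[["h"]]) / params$tau_h,
    mT = (gating_steady_state("mT", V) - s[["mT"]]) / gating_time_constant("mT", V),
    hT = (gating_steady_state("hT", V) - s[["hT"]]) / gating_time_constant("hT", V),
    mL = (gating_steady_state("mL", V) - s[["mL"]]) / gating_time_constant("mL", V),
    hL = (gating_steady_state("hL", V) - s[["hL"]]) / gating_time_constant("hL", V),
    gE = -s[["gE"]] / params$tauE,
    gI = -s[["gI"]] / params$tauI
  )
  d
}

#' Total ionic current with all gates at steady state
#'
#' The net intrinsic membrane current (pA, depolarizing positive) at
#' potential `V` with every gating variable set to its steady-state value
#' and no synaptic conductance. Zeros of this function are the membrane
#' equilibria; it is the root-finding target of [resting_state()].
#'
#' @param V membrane potential, mV (vectorised).
#' @param params an [model_parameters()] object.
#' @return current, pA.
#' @export
steady_state_current <- function(V, params = model_parameters()) {
  -params$gL * (V - params$VL) -
    params$gCaT * gating_steady_state("mT", V)^2 *
      gating_steady_state("hT", V) * (V - params$VCa) -
    params$gK * gating_steady_state("w", V) *
      gating_steady_state("hK", V, params) * (V - params$VK) -
    params$gCaL * gating_steady_state("mL", V)^2 *
      gating_steady_state("hL", V) * (V - params$VCa)
}

#' Resting state of the model
#'
#' Locates the hyperpolarized membrane equilibrium by root finding on
#' [steady_state_current()] over \[-80, 0\] mV (taking the most
#' hyperpolarized root, which is the resting attractor) and returns the full
#' state with all gates at steady state and synaptic conductances zero.
#' Simulations start here.
#'
#' @param params an [model_parameters()] object.
#' @return a [state_vector()] at equilibrium.
#' @examples
#' resting_state(model_parameters())[["V"]]  # close to -65 mV
#' @export
resting_state <- function(params = model_parameters()) {
  f <- function(V) steady_state_current(V, params)
  grid <- seq(-80, 0, by = 0.5)
  fg <- f(grid)
  i <- which(sign(fg[-1]) != sign(fg[-length(fg)]))
  if (!length(i)) {
    if (any(fg == 0)) {
      Vs <- grid[which(fg == 0)[1]]
    } else {
      stop("no membrane equilibrium found in [-80, 0] mV; pathological parameters")
    }
  } else {
    Vs <- uniroot(f, c(grid[i[1]], grid[i[1] + 1]), tol = 1e-12)$root
  }
  state_vector(
    V = Vs,
    w = gating_steady_state("w", Vs),
    h = gating_steady_state("hK", Vs, params),
    mT = gating_steady_state("mT", Vs),
    hT = gating_steady_state("hT", Vs),
    mL = gating_steady_state("mL", Vs),
    hL = gating_steady_state("hL", Vs)
  )
}
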