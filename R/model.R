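#' Flux-controlled memristance
#'
#' \eqn{\rho(\phi) = \lambda + 3\beta\phi^2}: the conductance factor through
#' which the magnetic flux feeds back on the membrane potential.
#'
#' @param phi magnetic flux value(s).
#' @param params a [neuron_params()] object.
#' @return \eqn{\rho(\phi)}, always `>= params$lam`.
#' @examples
#' memristance(0) # lambda
#' @export
memristance <- function(phi, params = neuron_params()) {
  if (!all(is.finite(phi))) stop("'phi' must be finite")
  params$lam + 3 * params$beta_mem * phi^2
}

#' Right-hand side of the single-neuron equations
#'
#' Evaluates the three derivatives of the memristive FHN neuron:
#' \deqn{\dot v = v(v-a)(1-v) - w + k_3 v \rho(\phi) - I^{syn}}
#' \deqn{\dot w = \varepsilon (v - d w)}
#' \deqn{\dot \phi = k_1 v - k_2 \phi + \phi_{ext}}
#'
#' @param v,w,phi state of the neuron (vectorized over neurons).
#' @param i_syn synaptic current (0 for an uncoupled neuron).
#' @param params a [neuron_params()] object.
#' @return list with components `dv`, `dw`, `dphi`.
#' @export
neuron_derivative <- function(v, w, phi, i_syn = 0, params = neuron_params()) {
  stopifnot(all(is.finite(c(v, w, phi, i_syn))))
  list(dv = v * (v - params$a) * (1 - v) - w +
         params$k3 * v * memristance(phi, params) - i_syn,
       dw = params$eps * (v - params$d * w),
       dphi = params$k1 * v - params$k2 * phi + params$phi_ext)
}

#' Synaptic gate kinetics
#'
#' Rate of change of the fraction `s` of open synaptic channels of a
#' presynaptic neuron, driven by its delayed membrane potential:
#' \deqn{\dot s = \frac{2(1-s)}{1 + e^{-v(t-\tau_c)/v_{shp}}} - s.}
#' The sigmoid saturates to 0/1 for large `|v|/v_shp` so the exponential
#' cannot overflow. `[0, 1]` is forward-invariant.
#'
#' @param s gate value(s) in `[0, 1]`.
#' @param v_delayed presynaptic membrane potential at `t - tau_c`.
#' @param params a [neuron_params()] object.
#' @return ds/dt.
#' @export
gate_derivative <- function(s, v_delayed, params = neuron_params()) {
  stopifnot(all(s >= 0 & s <= 1))
  x <- v_delayed / params$v_shp
  sig <- ifelse(x > 40, 1, ifelse(x < -40, 0, 1 / (1 + exp(-pmin(pmax(x, -40), 40)))))
  2 * (1 - s) * sig - s
}

#' Synaptic current onto one neuron
#'
#' \deqn{I_i^{syn} = \frac{1}{k_i}\sum_j \ell_{ij} g_{ij} s_j (v_i - v_{syn})}
#' normalized by the in-degree \eqn{k_i}. A neuron with no synaptic inputs
#' (`k_i = 0`) receives zero current. With `v_syn = 2` and trajectories below
#' it, the current is depolarizing (excitatory) whenever a gate is open.
#'
#' @param i postsynaptic neuron index (1-based).
#' @param v_i its membrane potential.
#' @param gates vector of gate values `s_j` for all neurons.
#' @param net a [ws_network()] object.
#' @param weights weight vector aligned with `net$edges`.
#' @param params a [neuron_params()] object.
#' @return scalar synaptic current.
#' @export
synaptic_current <- function(i, v_i, gates, net, weights,
                             params = neuron_params()) {
  inc <- which(net$edges$dst == i)
  if (!length(inc)) return(0)
  sum(weights[inc] * gates[net$edges$src[inc]]) / length(inc) *
    (v_i - params$v_syn)
}
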