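#' STDP modification factor
#'
#' The dimensionless synaptic modification \eqn{M(\Delta t)} of the
#' nearest-spike-pair rule, with \eqn{\Delta t = t_{post} - t_{pre}}:
#' \eqn{P e^{-|\Delta t|/\tau_p}} for \eqn{\Delta t > 0} (potentiation),
#' \eqn{-D e^{-|\Delta t|/\tau_d}} for \eqn{\Delta t < 0} (depression), and 0
#' for coincident spikes. The weight update is multiplicative:
#' \eqn{g \leftarrow g(1 + M)}, hard-clipped to `[g_min, g_max]`.
#'
#' @param delta_t post-minus-pre spike-time difference(s).
#' @param params an [stdp_params()] object.
#' @return M, same length as `delta_t`.
#' @examples
#' stdp_modification(2, stdp_params(P = 1e-3))   #  P * exp(-1)
#' stdp_modification(0, stdp_params(P = 1e-3))   #  0
#' @export
stdp_modification <- function(delta_t, params = stdp_params()) {
  stopifnot(all(is.finite(delta_t)))
  ifelse(delta_t > 0, params$P * exp(-abs(delta_t) / params$tau_p),
         ifelse(delta_t < 0, -params$D * exp(-abs(delta_t) / params$tau_d), 0))
}

#' Apply the STDP rule at one spike event
#'
#' Event-driven sweep of the nearest-spike-pair rule: when neuron `i` spikes
#' at time `t`, each of its incoming synapses `j -> i` is potentiated with
#' \eqn{\Delta t = t - t_j^{last} > 0} and each outgoing synapse `i -> m` is
#' depressed with \eqn{\Delta t = t_m^{last} - t \le 0}, always against the
#' partner's most recent spike. Synapses whose partner has never spiked are
#' untouched; coincident spikes give \eqn{\Delta t = 0}, hence no change.
#' Updated weights are clipped to `[g_min, g_max]`.
#'
#' @param spiking_neuron 1-based index of the neuron that just spiked.
#' @param t its spike time (must be its most recent spike).
#' @param last_spike vector of most recent spike times per neuron (`NA` or
#'   `-Inf` for never-spiked), already including this spike and any
#'   simultaneous ones.
#' @param net a [ws_network()] object.
#' @param weights weight vector aligned with `net$edges`.
#' @param params an [stdp_params()] object.
#' @return updated weight vector.
#' @export
stdp_apply_on_spike <- function(spiking_neuron, t, last_spike, net, weights,
                                params = stdp_params()) {
  ls <- ifelse(is.na(last_spike), -Inf, last_spike)
  inc <- which(net$edges$dst == spiking_neuron)
  for (e in inc) {
    tj <- ls[net$edges$src[e]]
    if (is.finite(tj))
      weights[e] <- weights[e] * (1 + stdp_modification(t - tj, params))
  }
  out <- which(net$edges$src == spiking_neuron)
  for (e in out) {
    tm <- ls[net$edges$dst[e]]
    if (is.finite(tm))
      weights[e] <- weights[e] * (1 + stdp_modification(tm - t, params))
  }
  pmin(pmax(weights, params$g_min), params$g_max)
}

#' Initial synaptic weights
#'
#' One draw per existing edge from Normal(`g0_mean`, `g0_sd`), truncated to
#' `[g_min, g_max]` by resampling (no mass accumulates at the bounds).
#'
#' @param net a [ws_network()] object.
#' @param params an [stdp_params()] object.
#' @param seed optional integer seed.
#' @return numeric weight vector aligned with `net$edges`.
#' @export
init_weights <- function(net, params = stdp_params(), seed = NULL) {
  m <- nrow(net$edges)
  stopifnot(m > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rnorm(m, params$g0_mean, params$g0_sd)
  bad <- which(g < params$g_min | g > params$g_max)
  while (length(bad)) {
    g[bad] <- stats::rnorm(length(bad), params$g0_mean, params$g0_sd)
    bad <- bad[g[bad] < params$g_min | g[bad] > params$g_max]
  }
  g
}
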