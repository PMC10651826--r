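#' Directed Watts-Strogatz network with fixed in-degree
#'
#' Builds the directed small-world / random networks used by the pipeline.
#' Each neuron first receives one synapse from each of its `k_avg/2` nearest
#' ring neighbours on either side; then, independently with probability
#' `beta`, each edge's presynaptic endpoint is replaced by a uniformly random
#' non-self, non-duplicate source. Every in-degree equals `k_avg` by
#' construction (and stays so under HSP rewiring, which keeps the
#' postsynaptic endpoint); `beta = 1` yields the random network.
#'
#' @param n number of neurons (N).
#' @param k_avg even in-degree, `2 <= k_avg < n`.
#' @param beta rewiring probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return An object of class `memfhn_network`: a list with `n`, `k_avg`,
#'   `beta`, `kind` (`"small-world"` or `"random"`) and `edges`, a data frame
#'   of 1-based `src` (presynaptic) and `dst` (postsynaptic) indices.
#' @examples
#' net <- ws_network(100, 10, 0.25, seed = 1)
#' nrow(net$edges)            # n * k_avg edges
#' table(net$edges$dst)[1:5]  # every in-degree = k_avg
#' @export
ws_network <- function(n, k_avg, beta, seed = NULL) {
  stopifnot(n >= 3, k_avg >= 2, k_avg %% 2 == 0, k_avg < n,
            beta >= 0, beta <= 1)
  if (!is.null(seed)) set.seed(seed)
  el <- ws_generate_cpp(as.integer(n), as.integer(k_avg), beta)
  structure(list(n = as.integer(n), k_avg = as.integer(k_avg), beta = beta,
                 kind = if (beta >= 1) "random" else "small-world",
                 edges = data.frame(src = el$src + 1L, dst = el$dst + 1L)),
            class = "memfhn_network")
}

#' Are two neurons distant on the original ring?
#'
#' Neuron `i` is distant from neuron `j` when their circular index distance
#' `min(|i-j|, n - |i-j|)` exceeds `k_avg`, the degree of the ring the
#' Watts-Strogatz construction started from. The HSP small-world rule treats
#' near-pair and distant-pair synapses differently.
#'
#' @param i,j 1-based neuron indices (vectorized).
#' @param k_avg ring degree.
#' @param n network size.
#' @return logical.
#' @export
is_distant <- function(i, j, k_avg, n) {
  stopifnot(all(i != j))
  d <- abs(i - j)
  pmin(d, n - d) > k_avg
}

#' One HSP rewiring step
#'
#' Applies one integration step of the homeostatic structural plasticity rule
#' to a network. Small-world rule: a synapse between distant neurons is
#' rewired to a near neighbour of its postsynaptic neuron with probability
#' `(1-beta)*F*dt`; a synapse between near neighbours is rewired to a distant
#' neuron with probability `beta*F*dt`. Random-network rule: every synapse is
#' rewired to any eligible neuron with probability `(1 - k_avg/(n-1))*F*dt`.
#' Probabilities are clamped to 1. The postsynaptic endpoint is always kept
#' (in-degrees conserved), the new presynaptic endpoint is drawn uniformly
#' from the eligible set (excluding self and existing sources), and the
#' synaptic weight travels with the edge, so the weight multiset is invariant.
#'
#' @param net a [ws_network()] object.
#' @param weights weight vector aligned with `net$edges` (optional; zeros if
#'   missing).
#' @param hsp an [hsp_params()] object.
#' @param dt integration step.
#' @param n_steps number of consecutive steps to apply.
#' @param seed optional integer seed.
#' @return list with updated `net`, `weights`, and counters `n_rewires`,
#'   `n_skips` (rewire attempts dropped because the eligible set was empty).
#' @export
rewire_step <- function(net, weights = NULL, hsp = hsp_params(1),
                        dt = 0.01, n_steps = 1L, seed = NULL) {
  stopifnot(inherits(net, "memfhn_network"))
  if (is.null(weights)) weights <- numeric(nrow(net$edges))
  stopifnot(length(weights) == nrow(net$edges))
  if (!is.null(seed)) set.seed(seed)
  res <- hsp_step_cpp(net$edges$src - 1L, net$edges$dst - 1L, weights,
                      net$n, net$k_avg, net$kind, net$beta,
                      hsp$F, dt, as.integer(n_steps))
  net$edges <- data.frame(src = res$src + 1L, dst = res$dst + 1L)
  list(net = net, weights = res$g,
       n_rewires = res$n_rewires, n_skips = res$n_skips)
}

#' Write / read a plain-text edge-list snapshot
#'
#' Rows of `src dst weight` with 0-based indices, for debugging and golden
#' fixtures.
#'
#' @param net a `memfhn_network`.
#' @param weights weight vector aligned with the edges.
#' @param file path.
#' @return `write_edgelist` returns `file` invisibly; `read_edgelist` a data
#'   frame with columns `src`, `dst`, `weight` (0-based indices, as stored).
#' @export
write_edgelist <- function(net, weights, file) {
  df <- data.frame(src = net$edges$src - 1L, dst = net$edges$dst - 1L,
                   weight = weights)
  utils::write.table(df, file, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(file) {
  df <- utils::read.table(file, col.names = c("src", "dst", "weight"))
  df
}
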