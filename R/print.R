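#' @export
print.memfhn_network <- function(x, ...) {
  cat(sprintf("<memfhn_network> %s, N = %d, <k> = %d, beta = %g, %d edges\n",
              x$kind, x$n, x$k_avg, x$beta, nrow(x$edges)))
  invisible(x)
}

#' @export
print.memfhn_config <- function(x, ...) {
  cat(sprintf(
    "<memfhn_config> N = %d, <k> = %d, beta = %g (%s), tau_c = %g\n",
    x$n_neurons, x$k_avg, x$beta, x$kind, x$tau_c))
  cat(sprintf("  dt = %g, T = %g (transient %g), record stride %d\n",
              x$dt, x$t_total, x$t_transient, x$record_stride))
  cat(sprintf("  STDP: P = %g, D/P = %g, schedule '%s'; HSP: F = %g\n",
              x$stdp$P, x$stdp$depression_ratio, x$stdp$schedule, x$hsp$F))
  invisible(x)
}

#' @export
print.memfhn_sim <- function(x, ...) {
  cfg <- x$config
  nsp <- sum(vapply(x$spikes, length, integer(1)))
  cat(sprintf("<memfhn_sim> N = %d, T = %g, %d spikes, %s rewires\n",
              cfg$n_neurons, cfg$t_total, nsp,
              format(x$n_rewires, big.mark = ",")))
  cat(sprintf("  recorded %d time points in [%g, %g]; final mean weight %.4g\n",
              length(x$t), cfg$t_transient, cfg$t_total, mean(x$weights)))
  invisible(x)
}

#' @export
print.memfhn_sweep <- function(x, ...) {
  cat(sprintf("<memfhn_sweep> %s x %s grid, %d points, %d rows\n",
              x$spec$axis1_name, x$spec$axis2_name,
              nrow(x$aggregate), nrow(x$rows)))
  print(utils::head(x$aggregate, 10))
  invisible(x)
}
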