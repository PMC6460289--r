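#' Spike raster container
#'
#' A spike raster stores, for each neuron, its ordered spike times over an
#' observation window.
#'
#' @param spike_times list of length N; element i is the increasing numeric
#'   vector of spike times (ms) of neuron i.
#' @param window numeric length-2 vector `(t_start, t_end)` in ms.
#' @return an object of class `adex_raster`.
#' @export
adex_raster <- function(spike_times, window) {
  stopifnot(is.list(spike_times), length(window) == 2L, window[2] >= window[1])
  for (s in spike_times) {
    if (length(s)) {
      if (is.unsorted(s, strictly = TRUE)) stop("spike times must be strictly increasing")
      if (s[1] < window[1] || s[length(s)] > window[2])
        stop("spike times outside raster window")
    }
  }
  structure(list(spike_times = spike_times, window = as.numeric(window)),
            class = "adex_raster")
}

raster_from_events <- function(spike_t, spike_i, N, window) {
  lst <- split(spike_t, factor(spike_i, levels = seq_len(N)))
  names(lst) <- NULL
  adex_raster(lapply(lst, as.numeric), window)
}

#' @export
print.adex_raster <- function(x, ...) {
  n <- vapply(x$spike_times, length, 1L)
  cat(sprintf("Spike raster: %d neurons, %d spikes in [%g, %g] ms\n",
              length(n), sum(n), x$window[1], x$window[2]))
  invisible(x)
}

#' Total number of spikes in a raster
#' @param raster an [adex_raster()].
#' @return integer spike count.
#' @export
n_spikes <- function(raster) {
  sum(vapply(raster$spike_times, length, 1L))
}

#' Restrict a raster to a sub-window
#' @param raster an [adex_raster()].
#' @param t_ini,t_fin new window bounds (ms); spikes outside are dropped.
#' @return an [adex_raster()] on the clipped window.
#' @export
clip_raster <- function(raster, t_ini, t_fin) {
  stopifnot(t_fin > t_ini)
  adex_raster(lapply(raster$spike_times, function(s) s[s >= t_ini & s <= t_fin]),
              c(max(t_ini, raster$window[1]), min(t_fin, raster$window[2])))
}

#' Raster plot
#'
#' Draws the standard raster: one point per spike, neuron index against
#' time, excitatory and inhibitory neurons in different colours when the
#' topology is supplied.
#'
#' @param x an [adex_raster()].
#' @param topology optional [adex_topology()] used to colour neuron classes.
#' @param ... passed to [graphics::plot()].
#' @export
plot.adex_raster <- function(x, topology = NULL, ...) {
  n <- vapply(x$spike_times, length, 1L)
  t <- unlist(x$spike_times, use.names = FALSE)
  id <- rep(seq_along(n), n)
  col <- "black"
  if (!is.null(topology)) col <- ifelse(topology$is_excitatory[id], "firebrick", "navy")
  graphics::plot(t, id, pch = ".", col = col, xlab = "time (ms)",
                 ylab = "neuron", ...)
  invisible(x)
}
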