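#' Random directed network topology
#'
#' Builds an Erdos-Renyi directed network of `N` neurons: every ordered
#' off-diagonal pair is connected independently with probability `p`.  The
#' first `floor(frac_exc * N)` neurons are excitatory, the rest inhibitory.
#' The adjacency convention is `M[i, j] = 1` when neuron `j` is presynaptic
#' to neuron `i` (row = postsynaptic target), so the synaptic input of
#' neuron i is `sum_j (Vrev_j - V_i) M[i, j] g_j`.
#'
#' @param N number of neurons.
#' @param p connection probability for each ordered pair.
#' @param frac_exc fraction of excitatory neurons (default 0.8).
#' @param seed optional RNG seed; the same seed reproduces the same network.
#' @return An object of class `adex_topology` with fields `N`, `M` (N x N
#'   0/1 matrix), `is_excitatory` (logical length N), `p`, `seed`.
#' @examples
#' top <- adex_topology(100, p = 0.1, seed = 1)
#' sum(top$M) / (100 * 99)   # close to 0.1
#' @export
adex_topology <- function(N, p = 0.1, frac_exc = 0.8, seed = NULL) {
  stopifnot(N >= 1, p >= 0, p <= 1, frac_exc >= 0, frac_exc <= 1)
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(0L, N, N)
  if (p > 0 && N > 1) {
    M[] <- as.integer(stats::runif(N * N) < p)
    diag(M) <- 0L
  }
  n_exc <- floor(frac_exc * N)
  new_adex_topology(M, seq_len(N) <= n_exc, p = p, seed = seed)
}

new_adex_topology <- function(M, is_excitatory, p = NA_real_, seed = NULL) {
  N <- nrow(M)
  stopifnot(ncol(M) == N, length(is_excitatory) == N, all(diag(M) == 0))
  structure(list(N = N, M = M, is_excitatory = as.logical(is_excitatory),
                 p = p, seed = seed),
            class = "adex_topology")
}

#' @export
print.adex_topology <- function(x, ...) {
  cat(sprintf("AdEx network topology: N=%d (%d excitatory, %d inhibitory), %d edges",
              x$N, sum(x$is_excitatory), sum(!x$is_excitatory), sum(x$M)))
  if (!is.na(x$p)) cat(sprintf(" (p=%g)", x$p))
  cat("\n")
  invisible(x)
}

# CSR over presynaptic index j: targets of j are
# out_idx[(out_ptr[j]+1):out_ptr[j+1]] (0-based indices for the C++ core).
topology_csr <- function(topology) {
  M <- topology$M
  N <- topology$N
  tgt <- lapply(seq_len(N), function(j) which(M[, j] == 1L) - 1L)
  lens <- lengths(tgt)
  list(out_ptr = as.integer(c(0L, cumsum(lens))),
       out_idx = as.integer(unlist(tgt, use.names = FALSE)))
}

#' Remove a fraction of the inhibitory population
#'
#' Emulates inhibitory cell loss: a uniformly random subset of the
#' inhibitory neurons, of the given fraction, is deleted together with all
#' its incident edges.  Excitatory neurons are untouched.  Neuron indices
#' are compacted, so the returned network has fewer neurons.
#'
#' @param topology an [adex_topology()] object.
#' @param fraction fraction of inhibitory neurons to remove, in \[0, 1\].
#'   The count removed is `round(fraction * n_inhibitory)`.
#' @param seed optional RNG seed for the random subset.
#' @return a new `adex_topology`.
#' @export
remove_inhibitory <- function(topology, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  inh <- which(!topology$is_excitatory)
  n_rm <- round(fraction * length(inh))
  if (n_rm == 0L) return(topology)
  if (!is.null(seed)) set.seed(seed)
  drop <- sample(inh, n_rm)
  keep <- setdiff(seq_len(topology$N), drop)
  new_adex_topology(topology$M[keep, keep, drop = FALSE],
                    topology$is_excitatory[keep],
                    p = topology$p, seed = topology$seed)
}
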