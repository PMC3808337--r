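# Directed simple cycles of the internal flow graph, and the
# cycle-decomposition ("comprehensive") cycling index.

# Exhaustive enumeration of simple directed cycles by rooted backtracking
# (Johnson-style: cycles are rooted at their smallest vertex and the
# search never descends below the root).  adj is a logical adjacency
# matrix over compartments; self-loops are ignored.
enumerate_cycles <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- FALSE
  cycles <- list()
  path <- integer(n + 1L)
  for (root in seq_len(n)) {
    visited <- rep(FALSE, n)
    descend <- function(v, depth) {
      path[depth] <<- v
      visited[v] <<- TRUE
      for (w in which(adj[v, ])) {
        if (w == root) {
          cycles[[length(cycles) + 1L]] <<- path[seq_len(depth)]
        } else if (w > root && !visited[w]) {
          descend(w, depth + 1L)
        }
      }
      visited[v] <<- FALSE
    }
    descend(root, 1L)
  }
  cycles
}

#' Count the simple directed cycles of a network
#'
#' Exhaustive enumeration over the internal (compartment-to-compartment)
#' flow graph; boundary nodes are excluded.  Flows at or below
#' `threshold` do not count as edges.
#'
#' @param net a [flow_network()] (or a bare square flow matrix).
#' @param threshold edge threshold, flow units.
#' @return integer cycle count.
#' @export
count_simple_cycles <- function(net, threshold = 1e-9) {
  Tm <- if (inherits(net, "flow_network")) net$T else as.matrix(net)
  length(enumerate_cycles(Tm > threshold))
}

#' Comprehensive cycling index
#'
#' Fraction of total system throughput travelling on cycle arcs, obtained
#' by full cycle decomposition: repeatedly take the simple cycle whose
#' limiting (smallest) arc is the weakest in the network, subtract that
#' arc's flow around the whole cycle, and accumulate the removed cycled
#' throughput, until the graph is acyclic.  Because flow that enters a
#' cycle arc is credited even when it does not complete the loop,
#' `CCI >= FCI`.
#'
#' @param net a [flow_network()].
#' @param threshold arcs at or below this flow are ignored.
#' @return scalar in `[0, 1]`.
#' @export
comprehensive_cycling_index <- function(net, threshold = 1e-9) {
  W <- net$T
  tst <- total_system_throughput(net)
  if (tst <= 0) return(0)
  removed <- 0
  repeat {
    cyc <- enumerate_cycles(W > threshold)
    if (!length(cyc)) break
    # weakest cycle: the one whose minimum arc is smallest (deterministic
    # lexicographic tie-break on the vertex sequence)
    arcmin <- vapply(cyc, function(cc) {
      from <- cc; to <- c(cc[-1L], cc[1L])
      min(W[cbind(from, to)])
    }, 0)
    ord <- order(arcmin, vapply(cyc, paste, "", collapse = ","))
    cc <- cyc[[ord[1L]]]
    m <- arcmin[ord[1L]]
    from <- cc; to <- c(cc[-1L], cc[1L])
    W[cbind(from, to)] <- W[cbind(from, to)] - m
    removed <- removed + m * length(cc)
  }
  removed / tst
}
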