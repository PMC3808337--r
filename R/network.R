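#' Construct a flow network
#'
#' One realized carbon flow network: an internal compartment-to-compartment
#' flow matrix plus boundary vectors.  All values are in the model's flow
#' unit (mgC m-2 per low tide for the bundled models).
#'
#' @param T square internal flow matrix, `T[i, j]` = flow from compartment
#'   `i` to compartment `j`; dimnames are compartment abbreviations.
#' @param z imports per compartment (boundary inputs).
#' @param e exports per compartment (boundary outputs).
#' @param r dissipations (respiration) per compartment.
#' @param compartments a [compartment_table()]; defaults to all-living
#'   compartments named after `T`'s dimnames.
#' @param producers abbreviations of primary producers (compartments whose
#'   imports are gross primary production rather than lateral imports).
#' @return object of class `flow_network`.
#' @export
flow_network <- function(T, z = NULL, e = NULL, r = NULL,
                         compartments = NULL, producers = character(0)) {
  T <- as.matrix(T)
  stopifnot(nrow(T) == ncol(T))
  n <- nrow(T)
  if (is.null(rownames(T))) dimnames(T) <- list(paste0("c", seq_len(n)),
                                                paste0("c", seq_len(n)))
  ab <- rownames(T)
  fill <- function(v) {
    if (is.null(v)) return(setNames(rep(0, n), ab))
    if (is.null(names(v))) return(setNames(rep_len(v, n), ab))
    out <- setNames(rep(0, n), ab); out[names(v)] <- v; out
  }
  z <- fill(z); e <- fill(e); r <- fill(r)
  if (is.null(compartments)) compartments <- compartment_table(ab)
  stopifnot(identical(compartments$abbrev, ab))
  if (any(c(T, z, e, r) < 0)) stop("flow network entries must be >= 0")
  structure(list(T = T, z = z, e = e, r = r,
                 compartments = compartments,
                 producers = intersect(producers, ab)),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat("Flow network:", nrow(x$T), "compartments,",
      sum(x$T > 0), "internal flows\n")
  cat("  imports", sum(x$z), "| exports", sum(x$e),
      "| dissipation", sum(x$r), "\n")
  invisible(x)
}

#' Per-compartment input/output balance
#'
#' @param net a [flow_network()].
#' @return named vector of inputs minus outputs per compartment.
#' @export
network_imbalance <- function(net) {
  inputs <- net$z + colSums(net$T)
  outputs <- net$e + net$r + rowSums(net$T)
  inputs - outputs
}

#' Test whether a network is balanced
#'
#' @param net a [flow_network()].
#' @param tol relative tolerance (scaled by the largest compartment input).
#' @return logical.
#' @export
is_balanced <- function(net, tol = 1e-6) {
  scale <- max(net$z + colSums(net$T), 1)
  all(abs(network_imbalance(net)) <= tol * scale)
}

#' Assemble a flow network from a LIM solution vector
#'
#' Maps each flow code to its place in the network: `gpp`/`imp` sources
#' become imports, `res` sinks become dissipations, `exp`/`ext` sinks
#' become exports, everything else an internal matrix entry.
#'
#' @param p a [lim_problem()].
#' @param x numeric solution vector, one value per flow in `p$flows`.
#' @param check check constraint satisfaction and balance.
#' @param tol relative tolerance for the checks.
#' @return a [flow_network()].
#' @export
network_from_solution <- function(p, x, check = TRUE, tol = 1e-6) {
  stopifnot(inherits(p, "lim_problem"), length(x) == length(p$flows))
  x <- as.numeric(x)
  if (check) {
    scale_b <- pmax(abs(p$b), 1)
    if (any(abs(p$A %*% x - p$b) > tol * scale_b))
      stop("solution violates the equality system beyond tolerance")
    scale_h <- pmax(abs(p$h), 1)
    if (any(p$G %*% x - p$h < -tol * scale_h))
      stop("solution violates the inequality system beyond tolerance")
  }
  ab <- p$compartments$abbrev
  n <- length(ab)
  Tm <- matrix(0, n, n, dimnames = list(ab, ab))
  z <- setNames(rep(0, n), ab); e <- z; r <- z
  ends <- flow_ends(p$flows)
  producers <- character(0)
  for (i in seq_along(p$flows)) {
    s <- ends$source[i]; k <- ends$sink[i]; v <- max(x[i], 0)
    if (s %in% BOUNDARY_SOURCES) {
      z[k] <- z[k] + v
      if (s == "gpp") producers <- union(producers, k)
    } else if (k == "res") {
      r[s] <- r[s] + v
    } else if (k %in% c("exp", "ext")) {
      e[s] <- e[s] + v
    } else {
      Tm[s, k] <- Tm[s, k] + v
    }
  }
  flow_network(Tm, z, e, r, compartments = p$compartments,
               producers = producers)
}

#' Compartment throughput (sum of inputs)
#'
#' The activity of one compartment: its imports plus all internal inflows.
#'
#' @param net a [flow_network()].
#' @param abbrev compartment abbreviation(s); default all.
#' @return named numeric vector.
#' @export
compartment_throughput <- function(net, abbrev = NULL) {
  tp <- net$z + colSums(net$T)
  if (is.null(abbrev)) return(tp)
  missing <- setdiff(abbrev, names(tp))
  if (length(missing)) stop("unknown compartment(s): ",
                            paste(missing, collapse = ", "))
  tp[abbrev]
}
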