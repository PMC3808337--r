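# Canonical trophic aggregation: collapse a balanced flow network onto a
# chain of discrete trophic levels (the Lindeman spine) plus one merged
# detritus pool.
#
# Conventions (matching the seasonal mudflat analysis):
#  - primary producers and the non-living pools sit at level 1; the pools
#    are displayed as a separate "det" box beside level I;
#  - every consumer is apportioned across integer levels by its diet:
#    fraction at level k+1 = sum over food sources of (diet share) x
#    (source's fraction at level k); bacteria feeding on dissolved
#    detritus come out at level II without special-casing;
#  - imports to living non-producer compartments (food ingested outside
#    the modelled window) are rerouted as imports to det and re-emerge as
#    det -> consumer transfers with 100% efficiency;
#  - the first transfer efficiency pools level I and det.

#' Trophic-level apportionment of each compartment
#'
#' @param net a balanced [flow_network()] with `producers` set and pools
#'   flagged in its compartment table.
#' @param max_level recursion cap (levels beyond it are truncated).
#' @param tol convergence tolerance for diet cycles among living
#'   compartments.
#' @return matrix `P` (compartments x levels): `P[i, k]` is the fraction
#'   of compartment i's activity at trophic level k; rows sum to 1
#'   (pools and producers are wholly at level 1).
#' @export
trophic_apportionment <- function(net, max_level = 20L, tol = 1e-12) {
  ab <- net$compartments$abbrev
  n <- length(ab)
  pools <- net$compartments$nonliving_pool
  producers <- ab %in% net$producers
  P <- matrix(0, n, max_level, dimnames = list(ab, NULL))
  P[pools | producers, 1L] <- 1

  consumers <- which(!pools & !producers)
  # diet shares: internal food + rerouted imports (from det, level 1)
  intake <- colSums(net$T) + ifelse(pools | producers, 0, net$z)
  det_share <- ifelse(!pools & !producers & intake > 0,
                      net$z / pmax(intake, .Machine$double.xmin), 0)
  D <- sweep(net$T, 2L, pmax(intake, .Machine$double.xmin), `/`)
  D[, intake <= 0] <- 0

  for (it in seq_len(200L)) {
    P_new <- P
    for (j in consumers) {
      if (intake[j] <= 0) { P_new[j, 2L] <- 1; next }
      row <- numeric(max_level)
      # food from source i at level k arrives at level k+1
      contrib <- crossprod(P[, seq_len(max_level - 1L), drop = FALSE],
                           D[, j])
      row[2:max_level] <- contrib
      row[2L] <- row[2L] + det_share[j]
      P_new[j, ] <- row
    }
    if (max(abs(P_new - P)) < tol) { P <- P_new; break }
    P <- P_new
    if (it == 200L) {
      lost <- 1 - rowSums(P)[consumers]
      if (any(lost > 1e-6))
        stop("trophic apportionment did not converge (diet cycles too ",
             "strong or max_level too small)")
    }
  }
  # renormalize the tiny tail truncated at max_level
  rs <- rowSums(P)
  bad <- abs(rs - 1) > 1e-6 & rs > 0
  P[bad, ] <- P[bad, , drop = FALSE] / rs[bad]
  P
}

#' Aggregate a network into its Lindeman spine
#'
#' @param net a balanced [flow_network()].
#' @param truncate_frac levels whose input falls below
#'   `truncate_frac * TST` are dropped from the spine.
#' @param max_level apportionment cap.
#' @return object of class `lindeman_spine`: `levels` (data.frame with
#'   per-level input, grazing passed to the next level, export,
#'   respiration and return to detritus), `det` (inputs and outputs of
#'   the merged non-living pool), `efficiencies` (transfer efficiency per
#'   level boundary; the first entry is the pooled I+det -> II
#'   efficiency), `L` (number of retained levels), `apportionment`.
#' @export
lindeman_spine <- function(net, truncate_frac = 1e-6, max_level = 20L) {
  if (!is_balanced(net, tol = 1e-4))
    stop("Lindeman aggregation requires a balanced network")
  ab <- net$compartments$abbrev
  pools <- net$compartments$nonliving_pool
  producers <- ab %in% net$producers
  living_cons <- !pools & !producers
  P <- trophic_apportionment(net, max_level = max_level)

  tst <- total_system_throughput(net)
  Tm <- net$T
  to_pools <- rowSums(Tm[, pools, drop = FALSE])
  to_living <- rowSums(Tm[, !pools, drop = FALSE])

  # det box: merged pools plus rerouted imports to living consumers
  imp_reroute <- sum(net$z[living_cons])
  det_returns <- sum(Tm[!pools, pools]) + sum(net$z[pools])
  detritivory <- sum(Tm[pools, !pools])
  det <- list(
    returns = det_returns,
    imports = imp_reroute,
    input = det_returns + imp_reroute,
    detritivory = detritivory,
    passthrough = imp_reroute,       # imports re-emerging as det -> consumers
    output_up = detritivory + imp_reroute,
    export = sum(net$e[pools]),
    respiration = sum(net$r[pools]))

  K <- max_level
  input <- numeric(K); grazing <- numeric(K); expt <- numeric(K)
  resp <- numeric(K); ret <- numeric(K)

  # level 1: producers only (their imports are gross primary production)
  input[1L] <- sum(net$z[producers])
  grazing[1L] <- sum(to_living[producers])
  expt[1L] <- sum(net$e[producers])
  resp[1L] <- sum(net$r[producers])
  ret[1L] <- sum(to_pools[producers])

  # consumers: inputs at level k, outputs apportioned by P[, k]
  for (k in 2:K) {
    # input at level k: food from sources at level k-1 (+ det passthrough)
    inp <- 0
    for (j in which(living_cons)) {
      inp <- inp + sum(Tm[, j] * P[, k - 1L]) +
        if (k == 2L) net$z[j] else 0
    }
    input[k] <- inp
    grazing[k] <- sum(to_living[living_cons] * P[living_cons, k])
    expt[k] <- sum(net$e[living_cons] * P[living_cons, k])
    resp[k] <- sum(net$r[living_cons] * P[living_cons, k])
    ret[k] <- sum(to_pools[living_cons] * P[living_cons, k])
  }

  keep <- input > truncate_frac * tst
  L <- max(which(keep))
  levels <- data.frame(level = seq_len(L), input = input[seq_len(L)],
                       grazing = grazing[seq_len(L)],
                       export = expt[seq_len(L)],
                       respiration = resp[seq_len(L)],
                       return_det = ret[seq_len(L)])

  # transfer efficiencies: boundary k -> k+1 is (carbon passed up) /
  # (total input to level k); the first boundary pools level I and det
  effs <- numeric(max(L - 1L, 0L))
  if (L >= 2L) {
    effs[1L] <- input[2L] / (input[1L] + det$input)
    for (k in 2:(L - 1L)) if (L >= 3L)
      effs[k] <- input[k + 1L] / input[k]
  }
  structure(list(levels = levels, det = det, efficiencies = effs, L = L,
                 apportionment = P[, seq_len(max(L, 2L)), drop = FALSE],
                 TST = tst),
            class = "lindeman_spine")
}

#' @export
print.lindeman_spine <- function(x, ...) {
  cat("Lindeman spine:", x$L, "levels\n")
  print(round(x$levels, 3))
  cat("det: input", round(x$det$input, 3),
      "(returns", round(x$det$returns, 3),
      "+ imports", round(x$det$imports, 3), ")",
      "-> detritivory", round(x$det$output_up, 3), "\n")
  cat("transfer efficiencies (%):",
      paste(round(100 * x$efficiencies, 2), collapse = ", "), "\n")
  invisible(x)
}

#' System trophic efficiency
#'
#' The logarithmic (geometric) mean of the level-boundary transfer
#' efficiencies, in percent.
#'
#' @param spine a [lindeman_spine()].
#' @return percentage.
#' @export
system_trophic_efficiency <- function(spine) {
  e <- spine$efficiencies
  if (!length(e)) stop("no level boundaries")
  if (any(e <= 0)) {
    warning("zero transfer efficiency; log-mean undefined, reporting 0")
    return(0)
  }
  100 * exp(mean(log(e)))
}
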