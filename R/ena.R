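# Ecological network analysis (ENA) indices on a flow network.
#
# Information indices follow the Ulanowicz formulation on the extended
# flow matrix (compartments plus one import source node and separate
# export and dissipation sink nodes).  All logarithms are base 2 (bits),
# with the convention 0 * log(0) = 0.

# extended (n+3) x (n+3) matrix: rows/cols 1..n compartments,
# n+1 import source (row only), n+2 export sink, n+3 dissipation sink
extended_matrix <- function(net) {
  n <- nrow(net$T)
  E <- matrix(0, n + 3L, n + 3L)
  E[seq_len(n), seq_len(n)] <- net$T
  E[n + 1L, seq_len(n)] <- net$z
  E[seq_len(n), n + 2L] <- net$e
  E[seq_len(n), n + 3L] <- net$r
  E
}

xlog2 <- function(x) ifelse(x > 0, log2(x), 0)

#' Total system throughput
#'
#' The sum of all flows: internal exchanges, imports, exports and
#' dissipations.  Measures whole-system activity.
#'
#' @param net a [flow_network()].
#' @return scalar, flow units.
#' @export
total_system_throughput <- function(net) {
  sum(net$T) + sum(net$z) + sum(net$e) + sum(net$r)
}

#' Average mutual information of the flow structure
#'
#' `AMI = sum_ij (T_ij / T..) log2(T_ij T.. / (T_i. T_.j))` over the
#' extended matrix: the degree of specialisation (constraint) of flows,
#' in bits.
#'
#' @param net a [flow_network()].
#' @return scalar, bits.
#' @export
average_mutual_information <- function(net) {
  E <- extended_matrix(net)
  tot <- sum(E)
  if (tot <= 0) stop("AMI undefined for an empty network")
  ro <- rowSums(E); co <- colSums(E)
  ij <- which(E > 0, arr.ind = TRUE)
  sum(E[ij] / tot * xlog2(E[ij] * tot / (ro[ij[, 1]] * co[ij[, 2]])))
}

#' Ascendency, development capacity and the overhead partition
#'
#' Ascendency `A = TST * AMI` is the organised fraction of activity;
#' development capacity `DC = -TST * sum p_ij log2 p_ij` is its upper
#' bound.  The difference `DC - A` decomposes exactly by flow class into
#' overheads on imports, on exports, dissipative overheads, and the
#' internal redundancy `R`.
#'
#' @param net a [flow_network()].
#' @return list with `TST`, `AMI`, `A`, `DC`, `A_rel` (= A/DC),
#'   `O_imports`, `O_exports`, `O_dissipation`, `R` (absolute,
#'   mgC x bits) and the same four as percentages of DC (`*_pct`).
#' @export
ascendency_decomposition <- function(net) {
  E <- extended_matrix(net)
  n <- nrow(net$T)
  tot <- sum(E)
  if (tot <= 0) stop("indices undefined for an empty network")
  ro <- rowSums(E); co <- colSums(E)
  A <- 0; DC <- 0
  Phi <- matrix(0, n + 3L, n + 3L)   # per-entry overhead
  ij <- which(E > 0, arr.ind = TRUE)
  t_ij <- E[ij]
  A <- sum(t_ij * xlog2(t_ij * tot / (ro[ij[, 1]] * co[ij[, 2]])))
  DC <- -sum(t_ij * xlog2(t_ij / tot))
  Phi[ij] <- -t_ij * xlog2(t_ij^2 / (ro[ij[, 1]] * co[ij[, 2]]))
  idx <- seq_len(n)
  O_imp <- sum(Phi[n + 1L, ])
  O_exp <- sum(Phi[, n + 2L])
  O_dis <- sum(Phi[, n + 3L])
  R <- sum(Phi[idx, idx])
  out <- list(TST = tot, AMI = A / tot, A = A, DC = DC,
              A_rel = A / DC,
              O_imports = O_imp, O_exports = O_exp,
              O_dissipation = O_dis, R = R)
  pct <- function(x) 100 * x / DC
  out$A_pct <- pct(A); out$O_imports_pct <- pct(O_imp)
  out$O_exports_pct <- pct(O_exp); out$O_dissipation_pct <- pct(O_dis)
  out$R_pct <- pct(R)
  out
}

#' Internal relative ascendency
#'
#' Ascendency and development capacity computed on the
#' compartment-to-compartment flows only: imports, exports and
#' dissipations are excluded, leaving the organisation of the internal
#' exchanges.
#'
#' @param net a [flow_network()].
#' @return list with `A_i`, `DC_i` and their ratio `A_i_rel`.
#' @export
internal_relative_ascendency <- function(net) {
  Tm <- net$T
  tot <- sum(Tm)
  if (tot <= 0) stop("no internal flows")
  ro <- rowSums(Tm); co <- colSums(Tm)
  ij <- which(Tm > 0, arr.ind = TRUE)
  t_ij <- Tm[ij]
  A_i <- sum(t_ij * xlog2(t_ij * tot / (ro[ij[, 1]] * co[ij[, 2]])))
  DC_i <- -sum(t_ij * xlog2(t_ij / tot))
  list(A_i = A_i, DC_i = DC_i,
       A_i_rel = if (DC_i > 0) A_i / DC_i else 1)
}

#' Finn cycling index
#'
#' Fraction of system activity that is recycled.  With input fractions
#' `g_ij = T_ij / T_j` (share of compartment j's throughflow arriving
#' from i) and `N = (I - g)^-1`, the cycled throughflow is
#' `T_c = sum_j (N_jj - 1) / N_jj * T_j` and `FCI = T_c / TST`.
#'
#' @param net a [flow_network()].
#' @param denominator `"tst"` (total system throughput, the default) or
#'   `"throughflow"` (total compartmental throughflow, used by some
#'   legacy ENA software).
#' @return scalar in `[0, 1]`.
#' @export
finn_cycling_index <- function(net, denominator = c("tst", "throughflow")) {
  denominator <- match.arg(denominator)
  Tf <- net$z + colSums(net$T)          # compartment throughflow (inputs)
  n <- length(Tf)
  g <- net$T
  pos <- Tf > 0
  g[, pos] <- sweep(net$T[, pos, drop = FALSE], 2L, Tf[pos], `/`)
  g[, !pos] <- 0
  N <- tryCatch(solve(diag(n) - g), error = function(e)
    stop("singular structure matrix: network unbalanced or purely circular"))
  dN <- diag(N)
  Tc <- sum(ifelse(dN > 0, (dN - 1) / dN, 0) * Tf)
  den <- if (denominator == "tst") total_system_throughput(net) else sum(Tf)
  if (den <= 0) return(0)
  Tc / den
}

#' Average path length
#'
#' `APL = (TST - sum of imports) / sum of imports`: the mean number of
#' compartments a unit of carbon traverses between entering and leaving
#' the system.
#'
#' @param net a [flow_network()].
#' @return scalar >= 0.
#' @export
average_path_length <- function(net) {
  zs <- sum(net$z)
  if (zs <= 0) stop("APL undefined: no imports")
  (total_system_throughput(net) - zs) / zs
}

#' All scalar ENA indices of one network
#'
#' @param net a [flow_network()].
#' @param cycle_threshold flows at or below this value are treated as
#'   absent when enumerating cycles.
#' @param cycles include the (exhaustive) cycle count and comprehensive
#'   cycling index; disable for speed when mapping over large sample sets.
#' @return one-row data.frame with TST, AMI, A, DC, A_rel, A_i, DC_i,
#'   A_i_rel, overhead percentages, R_pct, FCI, APL and (optionally)
#'   CCI and n_cycles.
#' @export
ena <- function(net, cycle_threshold = 1e-9, cycles = TRUE) {
  asc <- ascendency_decomposition(net)
  int <- internal_relative_ascendency(net)
  out <- data.frame(
    TST = asc$TST, AMI = asc$AMI, A = asc$A, DC = asc$DC,
    A_rel = asc$A_rel, A_i = int$A_i, DC_i = int$DC_i,
    A_i_rel = int$A_i_rel,
    O_imports_pct = asc$O_imports_pct, O_exports_pct = asc$O_exports_pct,
    O_dissipation_pct = asc$O_dissipation_pct, R_pct = asc$R_pct,
    FCI = finn_cycling_index(net),
    APL = average_path_length(net))
  if (cycles) {
    out$n_cycles <- count_simple_cycles(net, threshold = cycle_threshold)
    out$CCI <- comprehensive_cycling_index(net, threshold = cycle_threshold)
  }
  out
}

#' ENA indices for every sampled flow vector
#'
#' Maps the vectorized index set (TST, AMI, APL, A/DC, internal A/DC,
#' FCI) over a whole sample set.  Cycle-based indices are exhaustive
#' enumerations and are computed on the mean network only (reported as
#' attributes `mean_network_ena`).
#'
#' @param s a `flow_samples` object.
#' @param p the LIM problem (defaults to the one stored with the samples).
#' @return data.frame with one row per sample and columns TST, AMI,
#'   A_rel, A_i_rel, FCI, APL; failed rows carry `NA` and are counted in
#'   attribute `n_failed`.
#' @export
ena_over_samples <- function(s, p = s$problem) {
  m <- if (inherits(s, "flow_samples")) s$samples else as.matrix(s)
  n_it <- nrow(m)
  cols <- c("TST", "AMI", "A_rel", "A_i_rel", "FCI", "APL")
  out <- matrix(NA_real_, n_it, length(cols),
                dimnames = list(NULL, cols))
  map <- solution_map(p)
  n_failed <- 0L
  for (i in seq_len(n_it)) {
    res <- tryCatch({
      net <- apply_solution_map(map, m[i, ])
      asc <- ascendency_decomposition(net)
      int <- internal_relative_ascendency(net)
      c(asc$TST, asc$AMI, asc$A_rel, int$A_i_rel,
        finn_cycling_index(net), average_path_length(net))
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else out[i, ] <- res
  }
  out <- as.data.frame(out)
  mean_net <- apply_solution_map(map, colMeans(m))
  attr(out, "mean_network_ena") <- ena(mean_net)
  attr(out, "n_failed") <- n_failed
  out
}

# Precomputed index mapping from a flow vector to network slots, so that
# mapping ENA over tens of thousands of samples avoids re-parsing codes.
solution_map <- function(p) {
  ends <- flow_ends(p$flows)
  ab <- p$compartments$abbrev
  n <- length(ab)
  kind <- integer(length(p$flows))        # 1 internal, 2 import, 3 export, 4 resp
  slot <- integer(length(p$flows))
  for (i in seq_along(p$flows)) {
    s <- ends$source[i]; k <- ends$sink[i]
    if (s %in% BOUNDARY_SOURCES) { kind[i] <- 2L; slot[i] <- match(k, ab) }
    else if (k == "res") { kind[i] <- 4L; slot[i] <- match(s, ab) }
    else if (k %in% c("exp", "ext")) { kind[i] <- 3L; slot[i] <- match(s, ab) }
    else { kind[i] <- 1L
           slot[i] <- match(s, ab) + n * (match(k, ab) - 1L) }
  }
  producers <- unique(ends$sink[ends$source == "gpp"])
  list(kind = kind, slot = slot, n = n, ab = ab,
       compartments = p$compartments, producers = producers)
}

apply_solution_map <- function(map, x) {
  n <- map$n
  Tm <- matrix(0, n, n, dimnames = list(map$ab, map$ab))
  z <- setNames(rep(0, n), map$ab); e <- z; r <- z
  x <- pmax(x, 0)
  int <- map$kind == 1L
  Tm[map$slot[int]] <- Tm[map$slot[int]] + x[int]
  for (k in 2:4) {
    idx <- map$kind == k
    if (any(idx)) {
      v <- tapply(x[idx], map$slot[idx], sum)
      tgt <- as.integer(names(v))
      if (k == 2L) z[tgt] <- z[tgt] + v
      else if (k == 3L) e[tgt] <- e[tgt] + v
      else r[tgt] <- r[tgt] + v
    }
  }
  structure(list(T = Tm, z = z, e = e, r = r,
                 compartments = map$compartments,
                 producers = map$producers),
            class = "flow_network")
}
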