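# Synthetic LIM problems, closed-form toy networks and the
# rejection-sampling oracle: everything the test-bench needs without any
# external data.

#' Generate a random feasible LIM problem with a planted interior point
#'
#' Draws a random directed flow topology (at least one import and one
#' export, weakly connected), plants a strictly positive balanced flow
#' vector on it, and wraps every flow in a box constraint around its
#' planted value.  The planted point is therefore strictly feasible by
#' construction and is returned with the problem.
#'
#' @param n_compartments number of compartments (>= 2).
#' @param density probability of each ordered internal arc (0, 1].
#' @param tightness half-width of the per-flow box as a fraction of the
#'   planted value (default 0.5, i.e. +/- 50%).
#' @param seed RNG seed.
#' @param n_fixed number of flows pinned by measured-equality rows
#'   (values taken from the planted point).
#' @return list with `problem` (a [lim_problem()]) and `x_star` (the
#'   planted feasible flow vector).
#' @export
generate_random_lim <- function(n_compartments = 5L, density = 0.3,
                                tightness = 0.5, seed = 1L,
                                n_fixed = 0L) {
  stopifnot(n_compartments >= 2L, density > 0, density <= 1,
            tightness > 0, tightness < 1)
  set.seed(seed)
  ab <- vapply(seq_len(n_compartments), function(i)
    paste0("q", letters[(i - 1L) %/% 26L + 1L],
           letters[(i - 1L) %% 26L + 1L]), "")
  for (attempt in 1:100) {
    adj <- matrix(runif(n_compartments^2) < density,
                  n_compartments, n_compartments)
    diag(adj) <- FALSE
    # weak connectivity via undirected reachability
    und <- adj | t(adj)
    reach <- und | diag(TRUE, n_compartments)
    for (k in seq_len(n_compartments))
      reach <- reach | (reach %*% reach > 0)
    if (all(reach)) break
    if (attempt == 100) stop("could not draw a connected topology")
  }
  # planted internal flows
  Tm <- matrix(0, n_compartments, n_compartments)
  Tm[adj] <- runif(sum(adj), 0.5, 2)
  # balance with imports/exports
  imbalance <- colSums(Tm) - rowSums(Tm)   # input - output
  z <- pmax(-imbalance, 0) + 0.5           # everyone imports a little
  e <- pmax(imbalance, 0) + 0.5            # ... and exports a little
  flows <- character(0); x_star <- numeric(0)
  for (i in seq_len(n_compartments)) {
    flows <- c(flows, paste0("impTO", ab[i]))
    x_star <- c(x_star, z[i])
  }
  ij <- which(adj, arr.ind = TRUE)
  flows <- c(flows, paste0(ab[ij[, 1]], "TO", ab[ij[, 2]]))
  x_star <- c(x_star, Tm[ij])
  for (i in seq_len(n_compartments)) {
    flows <- c(flows, paste0(ab[i], "TOexp"))
    x_star <- c(x_star, e[i])
  }
  names(x_star) <- flows

  box <- lapply(seq_along(flows), function(i) NULL)
  constraints <- list()
  for (i in seq_along(flows)) {
    constraints <- c(constraints, list(
      list(coef = setNames(1, flows[i]), dir = ">=",
           rhs = (1 - tightness) * x_star[[i]],
           label = paste0("box_lo_", flows[i])),
      list(coef = setNames(1, flows[i]), dir = "<=",
           rhs = (1 + tightness) * x_star[[i]],
           label = paste0("box_up_", flows[i]))))
  }
  measured <- list()
  if (n_fixed > 0L) {
    pick <- sample(seq_along(flows), min(n_fixed, length(flows)))
    measured <- lapply(pick, function(i)
      list(coef = setNames(1, flows[i]), value = x_star[[i]],
           label = paste0("fix_", flows[i])))
  }
  comp <- compartment_table(ab)
  prob <- lim_problem(comp, flows, measured, constraints)
  stopifnot(max(abs(prob$A %*% x_star - prob$b)) < 1e-9,
            all(prob$G %*% x_star - prob$h > -1e-12))
  list(problem = prob, x_star = x_star)
}

#' Closed-form toy networks with known index values
#'
#' A named list of small [flow_network()]s whose headline ENA values have
#' straight-line derivations, stored alongside each network:
#' \describe{
#'   \item{chain}{import 1 -> A -> B -> export: TST 3, APL 2, FCI 0.}
#'   \item{parallel3}{three disjoint unit chains: internal-flow mutual
#'     information log2(3) bits.}
#'   \item{uniform}{4 compartments, all internal flows equal: AMI 0.}
#'   \item{loop}{import 1 -> A; A -> B 1.5; B -> A 0.5; B export 1:
#'     FCI 1/4 from the closed-form 2x2 inversion.}
#'   \item{lossless}{import -> P -> H -> C -> export, no losses: every
#'     transfer efficiency 100%.}
#' }
#'
#' @return named list; each element is a list with `net` and `expect`
#'   (named numeric vector of analytic values).
#' @export
toy_network_suite <- function() {
  out <- list()
  cmp <- function(ab, ...) compartment_table(ab, ...)

  Tm <- matrix(0, 2, 2, dimnames = list(c("aaa","bbb"), c("aaa","bbb")))
  Tm["aaa","bbb"] <- 1
  out$chain <- list(
    net = flow_network(Tm, z = c(aaa = 1), e = c(bbb = 1),
                       producers = "aaa"),
    expect = c(TST = 3, APL = 2, FCI = 0, R = 0))

  ab <- c("aa1","bb1","aa2","bb2","aa3","bb3")
  Tm <- matrix(0, 6, 6, dimnames = list(ab, ab))
  Tm["aa1","bb1"] <- 1; Tm["aa2","bb2"] <- 1; Tm["aa3","bb3"] <- 1
  out$parallel3 <- list(
    net = flow_network(Tm, z = c(aa1 = 1, aa2 = 1, aa3 = 1),
                       e = c(bb1 = 1, bb2 = 1, bb3 = 1),
                       producers = c("aa1","aa2","aa3")),
    expect = c(AMI_internal = log2(3)))

  ab <- c("aaa","bbb","ccc","ddd")
  Tm <- matrix(1, 4, 4, dimnames = list(ab, ab))
  out$uniform <- list(
    net = flow_network(Tm),
    expect = c(AMI = 0))

  Tm <- matrix(0, 2, 2, dimnames = list(c("aaa","bbb"), c("aaa","bbb")))
  Tm["aaa","bbb"] <- 1.5; Tm["bbb","aaa"] <- 0.5
  out$loop <- list(
    net = flow_network(Tm, z = c(aaa = 1), e = c(bbb = 1),
                       producers = "aaa"),
    # T_A = T_B = 1.5; g = [[0,1],[1/3,0]]; N = inv(I-g) has diagonal
    # (1.5, 1.5); Tc = 2 * (0.5/1.5) * 1.5 = 1; TST = 4; FCI = 1/4
    expect = c(FCI = 0.25, n_cycles = 1))

  ab <- c("ppp","hhh","ccc")
  Tm <- matrix(0, 3, 3, dimnames = list(ab, ab))
  Tm["ppp","hhh"] <- 1; Tm["hhh","ccc"] <- 1
  out$lossless <- list(
    net = flow_network(Tm, z = c(ppp = 1), e = c(ccc = 1),
                       producers = "ppp"),
    expect = c(TE = 1, system_TE_pct = 100))
  out
}

#' Uniform rejection sampling over a LIM polytope (validation oracle)
#'
#' Draws uniformly from the axis-aligned bounding box of the reduced
#' (null-space) polytope, found by exact support LPs, and keeps the
#' points that satisfy all constraints.  Exact uniformity by
#' construction; exponential cost in the number of free dimensions, so
#' the polytope must have at most `max_free` of them.
#'
#' @param p a [lim_problem()].
#' @param count samples to return.
#' @param seed RNG seed.
#' @param max_free refuse problems with more free dimensions than this.
#' @param min_rate abort when the empirical acceptance rate falls below
#'   this (polytope too thin for rejection).
#' @return list with `samples` (count x n matrix of flow vectors) and
#'   `acceptance_rate`.
#' @export
rejection_sample_oracle <- function(p, count = 10000L, seed = 1L,
                                    max_free = 5L, min_rate = 1e-6) {
  mn <- solve_minnorm(p$A, p$b)
  if (!mn$consistent) stop("inconsistent equality system")
  Z <- nullspace_basis(p$A)
  d <- ncol(Z)
  if (d > max_free)
    stop("rejection oracle limited to ", max_free, " free dimensions (got ",
         d, ")")
  set.seed(seed)
  if (d == 0L) {
    x <- matrix(rep(mn$x, each = count), count)
    colnames(x) <- p$flows
    return(list(samples = x, acceptance_rate = 1))
  }
  Gq <- p$G %*% Z
  hq <- p$h - as.numeric(p$G %*% mn$x)
  pr <- prune_reduced_rows(Gq, hq)
  if (!pr$constant_rows_ok) stop("infeasible problem")
  bb <- reduced_box_bounds(pr$G, pr$h)
  width <- bb[, "upper"] - bb[, "lower"]
  got <- 0L; tried <- 0L; accepted <- 0L
  keep <- matrix(0, count, d)
  while (got < count) {
    batch <- max(2L * (count - got), 1000L)
    Q <- matrix(runif(batch * d), batch, d)
    Q <- sweep(sweep(Q, 2L, width, `*`), 2L, bb[, "lower"], `+`)
    ok <- which(rowSums(tcrossprod(Q, pr$G) <
                          rep(pr$h, each = batch) - 1e-12) == 0)
    tried <- tried + batch
    accepted <- accepted + length(ok)
    if (length(ok)) {
      take <- ok[seq_len(min(length(ok), count - got))]
      keep[(got + 1L):(got + length(take)), ] <- Q[take, , drop = FALSE]
      got <- got + length(take)
    }
    if (tried > 1e6 && accepted / tried < min_rate)
      stop("acceptance rate below ", min_rate, "; polytope too thin")
  }
  x <- sweep(keep %*% t(Z), 2L, mn$x, `+`)
  colnames(x) <- p$flows
  list(samples = x, acceptance_rate = accepted / tried)
}
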