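# Mirror-reflection MCMC over the LIM flow polytope.
#
# Equalities are honoured exactly by walking in the null space of A;
# inequalities act as mirrors: a Gaussian jump that leaves the polytope is
# reflected specularly off each violated face, in the order the faces are
# hit along the travel direction, until the whole step length has been
# used up inside the polytope.  Because the proposal is symmetric and
# every step ends feasible, the chain's stationary distribution is uniform
# over the polytope.

#' Sampler configuration
#'
#' @param iterations number of emitted samples (after burn-in/thinning).
#' @param jump Gaussian step scale in the orthonormal null-space
#'   coordinates (flow units).
#' @param seed RNG seed (integer).
#' @param burn_in steps discarded before emission (default 0: every
#'   accepted state is kept).
#' @param thin keep every `thin`-th state.
#' @param max_reflections safety cap on mirror bounces per step; a step
#'   exceeding it is rejected and the current state repeated.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(iterations = 50000L, jump = 1, seed = 1L,
                           burn_in = 0L, thin = 1L,
                           max_reflections = 1000L) {
  stopifnot(jump > 0, iterations >= 1, thin >= 1, burn_in >= 0,
            max_reflections >= 1)
  structure(list(iterations = as.integer(iterations), jump = jump,
                 seed = as.integer(seed), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 max_reflections = as.integer(max_reflections)),
            class = "sampler_config")
}

#' Strictly feasible starting point for a LIM problem
#'
#' Returns the minimum-norm solution of the equality system when it
#' already satisfies the inequalities with a safety margin; otherwise the
#' Chebyshev centre (deepest interior point) of the reduced polytope.
#'
#' @param p a [lim_problem()].
#' @param margin required inequality slack (relative to `max(|h|, 1)`)
#'   for accepting the minimum-norm point.
#' @return feasible flow vector.
#' @export
initial_solution <- function(p, margin = 1e-9) {
  mn <- solve_minnorm(p$A, p$b)
  if (!mn$consistent) stop("equality system is inconsistent")
  Z <- nullspace_basis(p$A)
  slack <- as.numeric(p$G %*% mn$x) - p$h
  if (all(slack >= margin * pmax(abs(p$h), 1))) return(mn$x)
  if (ncol(Z) == 0L) stop("problem is infeasible (unique equality solution ",
                          "violates the inequalities)")
  Gq <- p$G %*% Z
  hq <- p$h - as.numeric(p$G %*% mn$x)
  # least-distance projection of the minimum-norm point, pushed inward to
  # half the inscribed-ball radius so the start is strictly feasible
  ch <- chebyshev_reduced(Gq, hq)
  if (!ch$feasible) stop("problem is infeasible (empty polytope)")
  q <- qp_point(Gq, hq, eps = ch$radius / 2)
  if (is.null(q)) q <- ch$q
  as.numeric(mn$x + Z %*% q)
}

#' Sample the flow polytope with the mirror technique
#'
#' @param p a [lim_problem()].
#' @param cfg a [sampler_config()].
#' @param x0 optional feasible start (defaults to [initial_solution()]).
#' @return object of class `flow_samples`: list with `samples`
#'   (iterations x n matrix, columns named by flow code), `labels`,
#'   `config`, `problem`, and `n_rejected` (steps that hit the
#'   reflection cap).
#' @export
mirror_sample <- function(p, cfg = sampler_config(), x0 = NULL) {
  stopifnot(inherits(p, "lim_problem"), inherits(cfg, "sampler_config"))
  if (is.null(x0)) x0 <- initial_solution(p)
  n <- length(p$flows)
  stopifnot(length(x0) == n)
  Z <- nullspace_basis(p$A)
  d <- ncol(Z)
  keep <- cfg$iterations
  out_q <- matrix(0, keep, max(d, 1L))
  set.seed(cfg$seed)
  n_rejected <- 0L

  if (d > 0L) {
    Gq <- p$G %*% Z
    hq <- p$h - as.numeric(p$G %*% x0)
    scale_h <- pmax(abs(p$h), 1)
    q <- numeric(d)
    gq <- as.numeric(Gq %*% q)             # current slack offset: gq - hq >= 0
    if (any(gq - hq < -1e-9 * scale_h))
      stop("start point is infeasible")
    total <- cfg$burn_in + keep * cfg$thin
    emit <- 0L
    for (it in seq_len(total)) {
      s <- cfg$jump * rnorm(d)
      q_try <- q; gq_try <- gq
      rem <- 1; refl <- 0L; ok <- TRUE
      gs <- as.numeric(Gq %*% s)
      repeat {
        slack <- gq_try - hq
        dec <- gs < 0
        t_hit <- rem
        i_hit <- 0L
        if (any(dec)) {
          tt <- -slack[dec] / gs[dec]
          tt[tt < 0] <- 0
          j <- which.min(tt)
          if (tt[j] < t_hit) {
            t_hit <- tt[j]
            i_hit <- which(dec)[j]
          }
        }
        q_try <- q_try + t_hit * s
        gq_try <- gq_try + t_hit * gs
        rem <- rem - t_hit
        if (i_hit == 0L || rem <= 0) break
        g <- Gq[i_hit, ]
        s <- s - 2 * (sum(g * s) / sum(g * g)) * g
        gs <- as.numeric(Gq %*% s)
        refl <- refl + 1L
        if (refl > cfg$max_reflections) { ok <- FALSE; break }
      }
      if (ok) {
        q <- q_try
        gq <- as.numeric(Gq %*% q)          # refresh to kill drift
      } else {
        n_rejected <- n_rejected + 1L
      }
      if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
        emit <- emit + 1L
        out_q[emit, ] <- q
      }
    }
    samples <- sweep(out_q[, seq_len(d), drop = FALSE] %*% t(Z), 2L,
                     x0, `+`)
  } else {
    # zero-dimensional null space: the unique solution, repeated
    samples <- matrix(rep(x0, each = keep), keep, n)
  }
  colnames(samples) <- p$flows
  structure(list(samples = samples, labels = p$flows, config = cfg,
                 problem = p, n_rejected = n_rejected),
            class = "flow_samples")
}

#' @export
print.flow_samples <- function(x, ...) {
  cat("Flow sample set:", nrow(x$samples), "samples x",
      ncol(x$samples), "flows (jump", x$config$jump,
      ", seed", x$config$seed, ")\n")
  invisible(x)
}

#' Per-flow summary of a sample set
#'
#' @param s a `flow_samples` object (or a bare samples matrix with
#'   flow-code column names).
#' @return data.frame with columns `code`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_samples <- function(s) {
  m <- if (inherits(s, "flow_samples")) s$samples else as.matrix(s)
  stopifnot(nrow(m) >= 1L)
  data.frame(code = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2L, sd),
             min = apply(m, 2L, min),
             max = apply(m, 2L, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of samples satisfying all constraints
#'
#' @param s a `flow_samples` object.
#' @param p the problem (defaults to the one stored in `s`).
#' @param tol absolute tolerance.
#' @return fraction in `[0, 1]`.
#' @export
feasible_fraction <- function(s, p = s$problem, tol = 1e-8) {
  m <- s$samples
  scale_b <- pmax(abs(p$b), 1)
  scale_h <- pmax(abs(p$h), 1)
  eq_ok <- abs(m %*% t(p$A) - rep(p$b, each = nrow(m))) <=
    rep(tol * scale_b, each = nrow(m))
  in_ok <- m %*% t(p$G) - rep(p$h, each = nrow(m)) >=
    rep(-tol * scale_h, each = nrow(m))
  mean(rowSums(!eq_ok) + rowSums(!in_ok) == 0)
}
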