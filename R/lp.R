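# Linear-algebra and feasibility support for LIM polytopes.
# The polytope is {x : A x = b, G x >= h}; equalities are eliminated by an
# orthonormal null-space basis so that all feasibility/MCMC work happens
# in the reduced coordinates q with x = x0 + Z q.

#' Orthonormal null-space basis of a matrix
#'
#' @param A numeric matrix.
#' @param tol singular values below `tol * max(sv) * max(dim)` count as zero.
#' @return matrix whose columns span the null space (possibly 0 columns).
#' @export
nullspace_basis <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  r <- sum(sv$d > tol * max(sv$d, 0) * max(dim(A)))
  if (r >= ncol(A))
    return(matrix(0, ncol(A), 0L))
  sv$v[, (r + 1L):ncol(A), drop = FALSE]
}

#' Minimum-norm solution of A x = b
#' @param A,b equality system.
#' @param tol rank tolerance.
#' @return list with `x` and `consistent` (logical).
#' @export
solve_minnorm <- function(A, b, tol = 1e-10) {
  if (nrow(A) == 0L) return(list(x = rep(0, ncol(A)), consistent = TRUE))
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d) * max(dim(A))
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  list(x = as.numeric(x),
       consistent = max(abs(A %*% x - b)) <= 1e-7 * max(abs(b), 1))
}

# Drop constraint rows whose null-space projection vanishes (constraints
# on flows that the equality system fixes).  Such rows are constants in
# the reduced coordinates: satisfiable or not, independent of q.
prune_reduced_rows <- function(Gq, hq, tol = 1e-7) {
  nrm <- sqrt(rowSums(Gq^2))
  scale <- max(nrm, 1)
  live <- nrm > 1e-11 * scale
  sat <- all(hq[!live] <= tol * pmax(abs(hq[!live]), 1))
  list(G = Gq[live, , drop = FALSE], h = hq[live], nrm = nrm[live],
       constant_rows_ok = sat)
}

# Least-distance point of {q : Gq q >= hq + eps * ||g_i||}, i.e. the point
# of the (eps-shrunken) reduced polytope closest to `target`.
# Returns the point or NULL when the shrunken polytope is empty.
# Rows are pre-normalized; degenerate rows must be pruned by the caller
# (qp_point does it itself when `prune = TRUE`).
qp_point <- function(Gq, hq, eps = 0, target = NULL, prune = TRUE) {
  d <- ncol(Gq)
  if (is.null(target)) target <- numeric(d)
  if (prune) {
    pr <- prune_reduced_rows(Gq, hq)
    if (!pr$constant_rows_ok) return(NULL)
    Gq <- pr$G; hq <- pr$h; nrm <- pr$nrm
  } else {
    nrm <- sqrt(rowSums(Gq^2)); nrm[nrm == 0] <- 1
  }
  if (nrow(Gq) == 0L) return(target)
  res <- tryCatch(
    pracma::quadprog(C = diag(d), d = -target,
                     A = -Gq / nrm, b = -(hq / nrm + eps)),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$xmin) || anyNA(res$xmin)) return(NULL)
  res$xmin
}

# Chebyshev radius (largest inscribed ball) of the reduced polytope by
# bisection on the shrink parameter, using the QP feasibility oracle.
# Returns list(q = centre-ish point, radius, feasible).
chebyshev_reduced <- function(Gq, hq, tol = 1e-9) {
  d <- ncol(Gq)
  if (d == 0L)
    return(list(q = numeric(0), radius = if (all(hq <= 1e-9)) 0 else -Inf,
                feasible = all(hq <= 1e-9)))
  pr <- prune_reduced_rows(Gq, hq)
  if (!pr$constant_rows_ok)
    return(list(q = rep(NA_real_, d), radius = -Inf, feasible = FALSE))
  Gq <- pr$G; hq <- pr$h
  q0 <- qp_point(Gq, hq, 0, prune = FALSE)
  if (is.null(q0))
    return(list(q = rep(NA_real_, d), radius = -Inf, feasible = FALSE))
  if (nrow(Gq) == 0L)
    return(list(q = q0, radius = Inf, feasible = TRUE))
  slack0 <- min((as.numeric(Gq %*% q0) - hq) / pr$nrm)
  lo <- max(slack0, 0); q_best <- q0
  hi <- max(1, lo) * 4
  repeat {                         # grow until infeasible
    qh <- qp_point(Gq, hq, hi, prune = FALSE)
    if (is.null(qh)) break
    lo <- hi; q_best <- qh; hi <- hi * 4
    if (hi > 1e12) return(list(q = q_best, radius = Inf, feasible = TRUE))
  }
  for (it in seq_len(80L)) {
    if (hi - lo <= max(tol, 1e-6 * lo)) break
    mid <- (lo + hi) / 2
    qm <- qp_point(Gq, hq, mid, prune = FALSE)
    if (is.null(qm)) hi <- mid else { lo <- mid; q_best <- qm }
  }
  list(q = q_best, radius = lo, feasible = TRUE)
}

# ---------------------------------------------------------------------
# Dense two-phase primal simplex with Bland's rule, for the small exact
# LPs used by the rejection-sampling oracle (per-coordinate support of a
# low-dimensional polytope).  Solves  min cc'x  s.t.  A x <= b, x >= 0.
# Returns list(x, fval, status) with status one of "optimal",
# "infeasible", "unbounded".
# ---------------------------------------------------------------------
simplex_lp <- function(cc, A, b, max_pivots = 20000L) {
  m <- nrow(A); n <- ncol(A)
  M <- cbind(A, diag(m)); rhs <- b
  basis <- n + seq_len(m)
  neg <- rhs < 0
  if (any(neg)) { M[neg, ] <- -M[neg, , drop = FALSE]; rhs[neg] <- -rhs[neg] }
  n_art <- sum(neg)
  if (n_art) {
    Art <- matrix(0, m, n_art)
    Art[cbind(which(neg), seq_len(n_art))] <- 1
    M <- cbind(M, Art)
    basis[neg] <- n + m + seq_len(n_art)
  }
  ncol_tot <- ncol(M)

  run_phase <- function(obj, allowed) {
    for (it in seq_len(max_pivots)) {
      # reduced costs z_j = obj_j - obj_B' B^-1 A_j  (tableau form)
      cb <- obj[basis]
      red <- obj - as.numeric(cb %*% M)
      red[!allowed] <- Inf
      enter <- which(red < -1e-9)
      if (!length(enter)) return("optimal")
      j <- min(enter)                         # Bland
      col <- M[, j]
      pos <- which(col > 1e-11)
      if (!length(pos)) return("unbounded")
      ratio <- rhs[pos] / col[pos]
      r <- pos[ratio == min(ratio)]
      r <- r[which.min(basis[r])]             # Bland tie-break
      # explicit pivot
      pv <- M[r, j]
      M[r, ] <<- M[r, ] / pv; rhs[r] <<- rhs[r] / pv
      for (i in seq_len(m)) if (i != r && M[i, j] != 0) {
        f <- M[i, j]
        M[i, ] <<- M[i, ] - f * M[r, ]
        rhs[i] <<- rhs[i] - f * rhs[r]
      }
      basis[r] <<- j
    }
    stop("simplex pivot limit reached")
  }

  if (n_art) {
    obj1 <- c(rep(0, n + m), rep(1, n_art))
    st <- run_phase(obj1, allowed = rep(TRUE, ncol_tot))
    val1 <- sum(obj1[basis] * rhs)
    if (st != "optimal" || val1 > 1e-7)
      return(list(x = NULL, fval = NA_real_, status = "infeasible"))
    # drive any residual artificials out of the basis if possible
    for (r in which(basis > n + m)) {
      cand <- which(abs(M[r, seq_len(n + m)]) > 1e-9)
      if (length(cand)) {
        j <- cand[1]; pv <- M[r, j]
        M[r, ] <- M[r, ] / pv; rhs[r] <- rhs[r] / pv
        for (i in seq_len(m)) if (i != r && M[i, j] != 0) {
          f <- M[i, j]; M[i, ] <- M[i, ] - f * M[r, ]
          rhs[i] <- rhs[i] - f * rhs[r]
        }
        basis[r] <- j
      }
    }
  }
  obj2 <- c(cc, rep(0, m), rep(0, n_art))
  allowed <- c(rep(TRUE, n + m), rep(FALSE, n_art))
  st <- run_phase(obj2, allowed)
  if (st != "optimal") return(list(x = NULL, fval = NA_real_, status = st))
  x <- numeric(ncol_tot); x[basis] <- rhs
  list(x = x[seq_len(n)], fval = sum(cc * x[seq_len(n)]), status = "optimal")
}

# Per-coordinate bounds of {q : Gq q >= hq}: 2d small exact LPs with the
# free coordinates split into positive parts.
reduced_box_bounds <- function(Gq, hq) {
  d <- ncol(Gq)
  A <- cbind(-Gq, Gq)          # -Gq(u - v) <= -hq
  lo <- numeric(d); hi <- numeric(d)
  for (j in seq_len(d)) {
    for (s in c(1, -1)) {
      cc <- numeric(2 * d); cc[j] <- s; cc[d + j] <- -s
      res <- simplex_lp(cc, A, -hq)
      if (res$status == "unbounded")
        stop("polytope is unbounded in reduced coordinate ", j)
      if (res$status != "optimal")
        stop("support LP failed: ", res$status)
      if (s > 0) lo[j] <- res$fval else hi[j] <- -res$fval
    }
  }
  cbind(lower = lo, upper = hi)
}

#' Diagnose a LIM problem
#'
#' Reports the rank of the equality system, the number of free directions
#' of the flow polytope, and feasibility (non-emptiness) established by a
#' least-distance feasibility phase; `radius` is the largest ball (in the
#' reduced coordinates) that fits inside the polytope, found by bisection.
#' Infeasibility is a reported diagnostic, never an error.
#'
#' @param p a [lim_problem()].
#' @param tol feasibility slack tolerance.
#' @return list with `rank`, `n_free`, `consistent`, `feasible`, `radius`
#'   and `x_center` (a deep feasible flow vector, or `NULL`).
#' @export
validate_problem <- function(p, tol = 1e-7) {
  stopifnot(inherits(p, "lim_problem"))
  n <- length(p$flows)
  rank <- if (nrow(p$A)) qr(p$A)$rank else 0L
  mn <- solve_minnorm(p$A, p$b)
  if (!mn$consistent) {
    return(list(rank = rank, n_free = n - rank, consistent = FALSE,
                feasible = FALSE, radius = -Inf, x_center = NULL))
  }
  Z <- nullspace_basis(p$A)
  Gq <- p$G %*% Z
  hq <- p$h - as.numeric(p$G %*% mn$x)
  if (ncol(Z) == 0L) {
    feas <- all(-hq >= -tol * pmax(abs(p$h), 1))
    return(list(rank = rank, n_free = 0L, consistent = TRUE,
                feasible = feas, radius = 0,
                x_center = if (feas) mn$x else NULL))
  }
  ch <- chebyshev_reduced(Gq, hq)
  list(rank = rank, n_free = ncol(Z), consistent = TRUE,
       feasible = ch$feasible, radius = ch$radius,
       x_center = if (ch$feasible) as.numeric(mn$x + Z %*% ch$q) else NULL)
}
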