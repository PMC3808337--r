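# Shared fixtures, built in code and cached per test run.

# the suite is diagnostic: report every failing expectation rather than
# stopping at the default cap
options(testthat.progress.max_fails = 1000L)

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

brouage_cached <- function(season) {
  cached(paste0("model_", season), brouage_model(season))
}

# mean-flow networks realized from the bundled synthetic stand-in for the
# unpublished supplementary mean-flow table
s1_means <- function() {
  cached("s1", read.csv(tideweb_file("table_s1_means_synthetic.csv")))
}

mean_network <- function(season) {
  cached(paste0("net_", season), {
    p <- brouage_cached(season)
    s1 <- s1_means()
    mu <- s1[[paste0(season, "_mean")]][match(p$flows, s1$code)]
    network_from_solution(p, mu, check = FALSE)
  })
}

# abstract polytopes used across sampler tests
simplex_problem <- function() {
  raw_lim_problem(c("x1", "x2"), A = matrix(1, 1, 2), b = 1)
}

unit_box_problem <- function(d = 3L) {
  nm <- paste0("x", seq_len(d))
  raw_lim_problem(nm, G = -diag(d), h = rep(-1, d))   # x <= 1 (+ nonneg)
}

# independent brute-force cycle counter: plain DFS over all simple paths,
# no root-blocking optimizations shared with the package implementation
brute_count_cycles <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- FALSE
  count <- 0L
  # count each cycle once: only cycles whose first vertex is its minimum
  walk <- function(path) {
    v <- path[length(path)]
    for (w in seq_len(n)) {
      if (!adj[v, w]) next
      if (w == path[1L] && length(path) >= 2L) count <<- count + 1L
      else if (w == path[1L] && length(path) == 1L) next
      else if (!(w %in% path) && w > path[1L]) walk(c(path, w))
    }
    # 2-cycles and self-returns handled above
  }
  for (s in seq_len(n)) walk(s)
  # cycles of length 1 excluded, length >= 2 counted when returning to root;
  # but a->a self loops ignored and a->b->a counted once from root min(a,b)
  count
}

# straight-line AMI evaluation (independent of the package's matrix code)
brute_ami <- function(E) {
  tot <- sum(E)
  ro <- rowSums(E); co <- colSums(E)
  s <- 0
  for (i in seq_len(nrow(E))) for (j in seq_len(ncol(E))) {
    t <- E[i, j]
    if (t > 0) s <- s + t / tot * log2(t * tot / (ro[i] * co[j]))
  }
  s
}
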