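test_that("starting points are feasible and match closed forms", {
  # minimum-norm point of the 2-simplex
  expect_equal(initial_solution(simplex_problem()), c(0.5, 0.5))
  # equality-determined problem returns its unique solution
  det <- raw_lim_problem(c("x1", "x2"),
                         A = rbind(c(1, 1), c(1, -1)), b = c(2, 0))
  expect_equal(initial_solution(det), c(1, 1))
  # full model: strictly feasible, balanced
  p <- brouage_cached("winter")
  x0 <- initial_solution(p)
  expect_true(all(p$G %*% x0 - p$h > 0))
  expect_lt(max(abs(p$A %*% x0 - p$b)), 1e-8)
  expect_error(initial_solution(raw_lim_problem("x1",
    G = matrix(c(1, -1), 2, 1), h = c(2, -1))), "infeasible")
})

test_that("uniform sampling on the segment and the cube matches moments", {
  s <- mirror_sample(simplex_problem(),
                     sampler_config(iterations = 50000L, jump = 1,
                                    seed = 42L))
  # U(0,1) marginal: mean 1/2, variance 1/12; MC error ~ 1/sqrt(n) scaled
  expect_equal(mean(s$samples[, 1]), 0.5, tolerance = 0.02)
  expect_equal(var(s$samples[, 1]), 1 / 12, tolerance = 0.05)
  expect_equal(feasible_fraction(s), 1)

  b <- mirror_sample(unit_box_problem(3L),
                     sampler_config(iterations = 50000L, jump = 1,
                                    seed = 7L))
  for (j in 1:3) {
    expect_equal(mean(b$samples[, j]), 0.5, tolerance = 0.02)
    expect_equal(var(b$samples[, j]), 1 / 12, tolerance = 0.05)
  }
})

test_that("the chain is reproducible and start-point invariant", {
  p <- simplex_problem()
  cfg <- sampler_config(iterations = 5000L, jump = 1, seed = 123L)
  s1 <- mirror_sample(p, cfg)
  s2 <- mirror_sample(p, cfg)
  expect_identical(s1$samples, s2$samples)
  # different start, same stationary mean within MC error
  s3 <- mirror_sample(p, sampler_config(iterations = 30000L, jump = 1,
                                        seed = 11L),
                      x0 = c(0.99, 0.01))
  expect_equal(mean(s3$samples[, 1]), 0.5, tolerance = 0.03)
})

test_that("equality-determined problems return the unique solution", {
  det <- raw_lim_problem(c("x1", "x2"),
                         A = rbind(c(1, 1), c(1, -1)), b = c(2, 0))
  s <- mirror_sample(det, sampler_config(iterations = 10L, seed = 1L))
  expect_equal(nrow(s$samples), 10L)
  expect_equal(unname(s$samples), matrix(1, 10L, 2L), tolerance = 1e-9)
})

test_that("marginals agree with the rejection oracle (KS, alpha = 0.01)", {
  g <- generate_random_lim(n_compartments = 3L, density = 0.4,
                           seed = 5L, n_fixed = 4L)
  v <- validate_problem(g$problem)
  expect_lte(v$n_free, 5L)
  o <- rejection_sample_oracle(g$problem, count = 4000L, seed = 2L)
  s <- mirror_sample(g$problem,
                     sampler_config(iterations = 8000L, jump = 1,
                                    seed = 3L))
  free <- apply(o$samples, 2L, sd) > 1e-10
  pv <- vapply(which(free), function(j)
    suppressWarnings(stats::ks.test(s$samples[, j],
                                    o$samples[, j])$p.value), 0)
  expect_true(all(pv > 0.01))
})

test_that("sample summaries expose fixed flows with zero spread", {
  p <- brouage_cached("winter")
  s <- mirror_sample(p, sampler_config(iterations = 500L, jump = 1,
                                       seed = 9L))
  tab <- summarize_samples(s)
  gpp <- tab[tab$code == "gppTOmpb", ]
  expect_equal(gpp$mean, 413.09, tolerance = 1e-9)
  expect_equal(gpp$sd, 0, tolerance = 1e-9)
  # constant sample set: all SDs zero
  const <- s; const$samples <- s$samples[rep(1L, 50L), ]
  expect_true(all(summarize_samples(const)$sd < 1e-12))
  # simplex mean table
  ssum <- summarize_samples(
    mirror_sample(simplex_problem(),
                  sampler_config(iterations = 20000L, seed = 4L)))
  expect_equal(ssum$mean, c(0.5, 0.5), tolerance = 0.02)
})

test_that("reflection cap rejections keep the chain inside the polytope", {
  p <- unit_box_problem(2L)
  s <- mirror_sample(p, sampler_config(iterations = 2000L, jump = 50,
                                       seed = 21L, max_reflections = 3L))
  expect_true(s$n_rejected > 0)          # huge jumps must bounce a lot
  expect_equal(feasible_fraction(s), 1)  # yet every sample stays feasible
})
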