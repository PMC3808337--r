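test_that("throughput and path length follow their definitions", {
  toys <- toy_network_suite()
  chain <- toys$chain$net
  expect_equal(total_system_throughput(chain), 3)
  expect_equal(average_path_length(chain), 2)
  # import immediately exported: TST 2, APL 1
  Tm <- matrix(0, 1, 1, dimnames = list("aaa", "aaa"))
  pass <- flow_network(Tm, z = c(aaa = 1), e = c(aaa = 1))
  expect_equal(average_path_length(pass), 1)
  # empty network
  empty <- flow_network(Tm)
  expect_equal(total_system_throughput(empty), 0)
  expect_error(average_path_length(empty), "no imports")
})

test_that("mutual information matches brute-force evaluation", {
  toys <- toy_network_suite()
  expect_equal(average_mutual_information(toys$uniform$net), 0)
  # independent parallel chains: internal flows carry log2(3) bits
  p3 <- toys$parallel3$net
  expect_equal(internal_relative_ascendency(p3)$A_i / sum(p3$T), log2(3))
  # random network: AMI equals an independent double-sum evaluation
  set.seed(31)
  for (k in 1:5) {
    Tm <- matrix(rexp(25), 5, 5); diag(Tm) <- 0
    dimnames(Tm) <- list(paste0("c", 1:5, "z"), paste0("c", 1:5, "z"))
    net <- flow_network(Tm, z = runif(5), e = runif(5), r = runif(5))
    n <- 5L
    E <- matrix(0, n + 3L, n + 3L)
    E[1:n, 1:n] <- net$T; E[n + 1L, 1:n] <- net$z
    E[1:n, n + 2L] <- net$e; E[1:n, n + 3L] <- net$r
    expect_equal(average_mutual_information(net), brute_ami(E),
                 tolerance = 1e-12)
  }
})

test_that("ascendency decomposition is exact on random networks", {
  set.seed(77)
  for (k in 1:8) {
    n <- sample(3:7, 1)
    Tm <- matrix(rexp(n * n) * (runif(n * n) < 0.6), n, n); diag(Tm) <- 0
    dimnames(Tm) <- list(paste0("c", seq_len(n), "z"),
                         paste0("c", seq_len(n), "z"))
    net <- flow_network(Tm, z = runif(n), e = runif(n), r = runif(n))
    a <- ascendency_decomposition(net)
    expect_equal(a$A + a$O_imports + a$O_exports + a$O_dissipation + a$R,
                 a$DC, tolerance = 1e-9 * a$DC)
    expect_equal(a$A, a$TST * a$AMI, tolerance = 1e-9)
    expect_gte(a$AMI, 0)
    expect_true(a$A_rel >= 0 && a$A_rel <= 1)
  }
})

test_that("single and uniform internal structures bracket A_i/DC_i", {
  Tm <- matrix(0, 2, 2, dimnames = list(c("aaa","bbb"), c("aaa","bbb")))
  Tm["aaa", "bbb"] <- 2
  one <- flow_network(Tm, z = c(aaa = 2), e = c(bbb = 2))
  expect_equal(internal_relative_ascendency(one)$A_i_rel, 1)
  uni <- toy_network_suite()$uniform$net
  expect_equal(internal_relative_ascendency(uni)$A_i, 0)
})

test_that("Finn index: zero on acyclic networks, closed form on the loop", {
  toys <- toy_network_suite()
  expect_equal(finn_cycling_index(toys$chain$net), 0)
  # closed form for the two-compartment loop, rederived inline:
  # throughflows T = (1.5, 1.5); g = [[0, 1], [1/3, 0]];
  # N = (I - g)^-1 => diag(N) = (1, 1) / (1 - 1/3) = (1.5, 1.5);
  # Tc = 2 * ((1.5 - 1) / 1.5) * 1.5 = 1; TST = 4
  loop <- toys$loop$net
  N <- solve(diag(2) - rbind(c(0, 1), c(1 / 3, 0)))
  Tc <- sum((diag(N) - 1) / diag(N) * c(1.5, 1.5))
  expect_equal(finn_cycling_index(loop), Tc / 4)
  expect_equal(finn_cycling_index(loop), 0.25)
  expect_equal(finn_cycling_index(loop, denominator = "throughflow"),
               Tc / 3)
})

test_that("Finn index grows strictly with the recycle flow", {
  fci_at <- function(r) {
    # import 1 -> A; A -> B (1 + r); B -> A r; B export 1; balanced
    Tm <- matrix(0, 2, 2, dimnames = list(c("aaa","bbb"), c("aaa","bbb")))
    Tm["aaa", "bbb"] <- 1 + r; Tm["bbb", "aaa"] <- r
    finn_cycling_index(flow_network(Tm, z = c(aaa = 1), e = c(bbb = 1)))
  }
  rs <- c(0, 0.25, 0.5, 1, 2, 5)
  vals <- vapply(rs, fci_at, 0)
  expect_equal(vals[1], 0)
  expect_true(all(diff(vals) > 0))
})

test_that("cycle counts agree with a brute-force enumerator", {
  # complete digraph on 3 nodes: three 2-cycles and two 3-cycles
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  dimnames(K3) <- list(paste0("n", 1:3, "z"), paste0("n", 1:3, "z"))
  expect_equal(count_simple_cycles(flow_network(K3)), 5L)
  expect_equal(count_simple_cycles(toy_network_suite()$chain$net), 0L)
  set.seed(99)
  for (k in 1:10) {
    n <- sample(3:7, 1)
    adj <- matrix(runif(n * n) < 0.4, n, n); diag(adj) <- FALSE
    Tm <- adj * 1
    dimnames(Tm) <- list(paste0("c", seq_len(n), "z"),
                         paste0("c", seq_len(n), "z"))
    expect_equal(count_simple_cycles(flow_network(Tm)),
                 brute_count_cycles(adj))
  }
})

test_that("cycle threshold separates real arcs from numerical dust", {
  Tm <- matrix(0, 2, 2, dimnames = list(c("aaa","bbb"), c("aaa","bbb")))
  Tm["aaa", "bbb"] <- 1; Tm["bbb", "aaa"] <- 1e-12
  net <- flow_network(Tm, z = c(aaa = 1), e = c(aaa = 0, bbb = 1))
  expect_equal(count_simple_cycles(net), 0L)            # default threshold
  expect_equal(count_simple_cycles(net, threshold = 0), 1L)
})

test_that("comprehensive cycling dominates Finn cycling", {
  toys <- toy_network_suite()
  expect_equal(comprehensive_cycling_index(toys$chain$net), 0)
  # two-compartment loop by exhaustive stripping: one cycle, weakest arc
  # 0.5, removes 0.5 from both arcs -> cycled throughput 1, TST 4
  expect_equal(comprehensive_cycling_index(toys$loop$net), 0.25)
  set.seed(13)
  for (k in 1:6) {
    n <- sample(3:6, 1)
    Tm <- matrix(rexp(n * n) * (runif(n * n) < 0.5), n, n); diag(Tm) <- 0
    dimnames(Tm) <- list(paste0("c", seq_len(n), "z"),
                         paste0("c", seq_len(n), "z"))
    imb <- colSums(Tm) - rowSums(Tm)
    net <- flow_network(Tm, z = pmax(-imb, 0) + 0.2,
                        e = pmax(imb, 0) + 0.2)
    fci <- finn_cycling_index(net)
    cci <- comprehensive_cycling_index(net)
    expect_gte(cci, fci - 1e-9)
    expect_lte(cci, 1)
    if (count_simple_cycles(net) == 0L) expect_equal(fci, 0)
    if (fci > 1e-12) expect_gt(count_simple_cycles(net), 0L)
  }
})

test_that("ratio indices are scale invariant; extensive ones scale", {
  p <- brouage_cached("winter")
  s1 <- s1_means()
  mu <- s1$winter_mean[match(p$flows, s1$code)]
  net <- network_from_solution(p, mu, check = FALSE)
  for (cmult in c(0.25, 3)) {
    scaled <- flow_network(net$T * cmult, net$z * cmult, net$e * cmult,
                           net$r * cmult, net$compartments, net$producers)
    e1 <- ena(net); e2 <- ena(scaled)
    for (col in c("AMI", "A_rel", "A_i_rel", "FCI", "CCI", "APL",
                  "R_pct", "O_imports_pct"))
      expect_equal(e2[[col]], e1[[col]], tolerance = 1e-9)
    for (col in c("TST", "A", "DC"))
      expect_equal(e2[[col]], cmult * e1[[col]], tolerance = 1e-9)
    expect_equal(e2$n_cycles, e1$n_cycles)
  }
})

test_that("mapping indices over samples equals the per-sample loop", {
  g <- generate_random_lim(n_compartments = 4L, density = 0.5, seed = 17L)
  s <- mirror_sample(g$problem,
                     sampler_config(iterations = 100L, jump = 0.5,
                                    seed = 2L))
  tab <- ena_over_samples(s)
  expect_equal(nrow(tab), 100L)
  expect_equal(attr(tab, "n_failed"), 0L)
  for (i in c(1L, 50L, 100L)) {
    net <- network_from_solution(g$problem, s$samples[i, ], check = FALSE)
    expect_equal(tab$TST[i], total_system_throughput(net))
    expect_equal(tab$AMI[i], average_mutual_information(net))
    expect_equal(tab$FCI[i], finn_cycling_index(net))
    expect_equal(tab$APL[i], average_path_length(net))
  }
  # constant sample set gives constant index columns
  sc <- s; sc$samples <- s$samples[rep(7L, 20L), ]
  tc <- ena_over_samples(sc)
  expect_true(all(vapply(tc, function(col) max(col) - min(col), 0) < 1e-12))
})
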