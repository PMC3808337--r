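test_that("flow codes parse into source and sink, rejecting malformed ones", {
  ends <- flow_ends(c("mpbTOmfb", "gppTOmpb", "bcbTOres"))
  expect_equal(ends$source, c("mpb", "gpp", "bcb"))
  expect_equal(ends$sink, c("mfb", "mpb", "res"))
  expect_error(flow_ends("mpbtomfb"), "malformed")
  expect_error(flow_ends("mpbTOmpb"), "identical source and sink")
  expect_error(flow_ends("mpbTOmf"), "malformed")
})

test_that("mass-balance rows are generated from the topology with b = 0", {
  p <- lim_problem(
    compartment_table(c("aaa", "bbb", "ccc")),
    c("impTOaaa", "aaaTObbb", "bbbTOccc", "cccTOexp", "bbbTOres"))
  bal <- p$A[seq_len(p$n_balances), , drop = FALSE]
  expect_equal(nrow(bal), 3L)
  expect_equal(p$b[1:3], rep(0, 3))
  # +1 on inflows, -1 on outflows
  expect_equal(unname(bal["balance_bbb", ]), c(0, 1, -1, 0, -1))
  # every balance row: coefficient count equals flows touching the
  # compartment, and inflow/outflow signs
  for (cp in c("aaa", "bbb", "ccc")) {
    ends <- flow_ends(p$flows)
    expect_equal(sum(bal[paste0("balance_", cp), ] == 1),
                 sum(ends$sink == cp))
    expect_equal(sum(bal[paste0("balance_", cp), ] == -1),
                 sum(ends$source == cp))
  }
})

test_that("constructor rejects inconsistent declarations", {
  cmp <- compartment_table(c("aaa", "bbb"))
  expect_error(lim_problem(cmp, c("aaaTOxyz")), "undeclared")
  expect_error(lim_problem(cmp, c("aaaTObbb", "aaaTObbb")), "duplicate")
  expect_error(
    lim_problem(cmp, "aaaTObbb",
                constraints = list(list(coef = c(cccTOaaa = 1), dir = ">=",
                                        rhs = 0, label = "bad"))),
    "undeclared flow")
  expect_error(compartment_table(c("aaa", "aaa")))
  expect_error(compartment_table("res"), "reserved")
})

test_that("declaration documents round-trip exactly", {
  for (season in c("winter", "summer")) {
    p <- brouage_cached(season)
    p2 <- parse_lim(format_lim(p))
    expect_identical(p2$flows, p$flows)
    expect_identical(unname(p2$A), unname(p$A))
    expect_identical(unname(p2$b), unname(p$b))
    expect_identical(unname(p2$G), unname(p$G))
    expect_identical(unname(p2$h), unname(p$h))
    expect_identical(p2$compartments, p$compartments)
    expect_identical(p2$season, p$season)
  }
  # and for a random synthetic problem
  g <- generate_random_lim(n_compartments = 4, density = 0.4, seed = 9)
  p2 <- parse_lim(format_lim(g$problem))
  expect_identical(unname(p2$G), unname(g$problem$G))
  expect_identical(unname(p2$b), unname(g$problem$b))
})

test_that("bundled model files parse to the built models", {
  for (season in c("winter", "summer")) {
    bundled <- read_lim(tideweb_file(paste0("brouage_", season, ".lim")))
    built <- brouage_cached(season)
    expect_identical(bundled$flows, built$flows)
    expect_identical(unname(bundled$A), unname(built$A))
    expect_identical(unname(bundled$b), unname(built$b))
    expect_identical(unname(bundled$G), unname(built$G))
    expect_identical(unname(bundled$h), unname(built$h))
  }
})

test_that("solution vectors map onto balanced flow networks", {
  p <- lim_problem(
    compartment_table(c("aaa", "bbb")),
    c("gppTOaaa", "aaaTObbb", "aaaTOres", "bbbTOexp", "bbbTOres"))
  x <- c(10, 6, 4, 5, 1)
  net <- network_from_solution(p, x)
  expect_equal(unname(net$z["aaa"]), 10)   # gpp -> import
  expect_equal(unname(net$r["aaa"]), 4)    # res -> dissipation
  expect_equal(unname(net$e["bbb"]), 5)    # exp -> export
  expect_equal(net$T["aaa", "bbb"], 6)
  expect_equal(net$producers, "aaa")
  expect_true(is_balanced(net))
  # zero solution on a toy with no measured flows -> zero network
  p0 <- lim_problem(compartment_table(c("aaa", "bbb")),
                    c("impTOaaa", "aaaTObbb", "bbbTOexp"))
  net0 <- network_from_solution(p0, c(0, 0, 0))
  expect_equal(total_system_throughput(net0), 0)
  # violating a constraint beyond tolerance errors
  expect_error(network_from_solution(p, c(10, 6, 4, 5, 2)),
               "equality")
})

test_that("SCOR export writes the expected record structure", {
  net <- toy_network_suite()$chain$net
  f <- tempfile(fileext = ".scor")
  write_scor(net, f, title = "chain")
  lines <- readLines(f)
  expect_equal(lines[1], "chain")
  expect_equal(lines[2], "2 2")
  expect_equal(lines[3:4], c("aaa", "bbb"))
  # biomass, imports, exports, respiration, flows: five -1 terminators
  expect_equal(sum(lines == "-1"), 5L)
  expect_true(any(grepl("^1 2 1$", lines)))   # the internal flow record
})

test_that("allometric helpers follow their published forms", {
  expect_equal(cell_carbon(1), 133.754)
  expect_equal(cell_carbon(0), 0)
  # direct evaluation at the mean observed biovolume
  expect_equal(cell_carbon(0.28), 133.754 * 0.28^0.438)
  expect_error(cell_carbon(-1), ">= 0")

  b <- 1234
  expect_equal(bird_consumption_bound(1, b, 1), 3 * b)
  expect_equal(bird_consumption_bound(0, b, 0.8), 0)
  # maximum observed density with the standard assimilation efficiency:
  # n * 3 * BMR / 0.8 = n * 3.75 * BMR
  expect_equal(bird_consumption_bound(2.05e-4, b, 0.8),
               2.05e-4 * 3.75 * b)
  expect_error(bird_consumption_bound(1, b, 0), "assimilation")
})

test_that("problem diagnostics report rank, free directions, feasibility", {
  v <- validate_problem(brouage_cached("winter"))
  expect_true(v$feasible)
  expect_equal(v$n_free, length(brouage_cached("winter")$flows) - v$rank)
  expect_gt(v$radius, 0)
  x <- v$x_center
  expect_true(all(brouage_cached("winter")$G %*% x -
                    brouage_cached("winter")$h > -1e-9))

  # contradictory bounds: infeasible, reported not thrown
  bad <- raw_lim_problem("x1",
    G = matrix(c(1, -1), 2, 1), h = c(2, -1))   # x >= 2 and x <= 1
  vb <- validate_problem(bad)
  expect_false(vb$feasible)

  # equality-determined system: zero free directions
  det <- raw_lim_problem(c("x1", "x2"),
                         A = rbind(c(1, 1), c(1, -1)), b = c(2, 0))
  vd <- validate_problem(det)
  expect_equal(vd$n_free, 0L)
  expect_true(vd$feasible)
  expect_equal(vd$x_center, c(1, 1))
})
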