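# Mechanism- and system-level causal analysis

xor_net <- function() {
  # C = XOR(A, B); A, B inputless (for repertoire arithmetic checks)
  fs <- list(function(b) 0L, function(b) 0L,
             function(b) as.integer(xor(b[1] == 1, b[2] == 1)))
  animatphi:::net_from_functions(fs, labels = c("A", "B", "C"))
}

test_that("cause repertoires invert the dynamics under a uniform prior", {
  net <- xor_net()
  s <- parse_state("101")
  cr <- cause_repertoire(net, s, mechanism = 3, purview = c(1, 2))
  expect_equal(unname(cr), c(0, 0.5, 0.5, 0))  # only 10 and 01 possible
  # empty mechanism: unconstrained (uniform) past
  cr0 <- cause_repertoire(net, s, mechanism = integer(0), purview = c(1, 2))
  expect_equal(unname(cr0), rep(0.25, 4))
})

test_that("unreachable mechanism states give undefined cause repertoires", {
  # element whose update is constant 1, observed in state 0
  fs <- list(function(b) 1L, function(b) b[1])
  net <- animatphi:::net_from_functions(fs)
  expect_null(cause_repertoire(net, parse_state("00"), 1, 2))
  expect_equal(mechanism_phi(net, parse_state("00"), 1, 2, "cause")$phi, 0)
})

test_that("effect repertoires factorize over purview elements", {
  net <- xor_net()
  s <- parse_state("101")
  # empty mechanism, XOR target with uniform inputs: P(on) = 0.5
  er <- effect_repertoire(net, s, integer(0), 3)
  expect_equal(unname(er), c(0.5, 0.5))
  # full deterministic input set: degenerate distribution
  er2 <- effect_repertoire(net, s, c(1, 2), 3)
  expect_equal(unname(er2), c(0, 1))  # XOR(1, 0) = 1
})

test_that("the EMD reproduces the closed-form transport examples", {
  # states written in element order ABC; element A is bit 0
  p <- numeric(8); p[animatphi:::bits_to_int(c(1, 1, 0)) + 1] <- 1
  q <- p
  q[animatphi:::bits_to_int(c(1, 1, 0)) + 1] <- 0.75
  q[animatphi:::bits_to_int(c(0, 0, 1)) + 1] <- 0.25
  expect_equal(emd_hamming(p, q), 0.75)
  q2 <- p
  q2[animatphi:::bits_to_int(c(1, 1, 0)) + 1] <- 0.75
  q2[animatphi:::bits_to_int(c(1, 0, 0)) + 1] <- 0.25
  expect_equal(emd_hamming(p, q2), 0.25)
  expect_equal(emd_hamming(p, p), 0)
})

test_that("the EMD is a metric (fuzz against the LP transport oracle)", {
  set.seed(30)
  for (k in 1:3) {
    D <- oracle_hamming_D(k)
    for (i in 1:25) {
      p <- runif(2^k); p <- p / sum(p)
      q <- runif(2^k); q <- q / sum(q)
      r <- runif(2^k); r <- r / sum(r)
      d_pq <- emd_hamming(p, q)
      expect_equal(d_pq, oracle_emd(p, q, D), tolerance = 1e-9)
      expect_equal(d_pq, emd_hamming(q, p), tolerance = 1e-12)
      expect_gte(d_pq + emd_hamming(q, r) + 1e-12, emd_hamming(p, r))
      expect_gte(d_pq, 0)
    }
  }
})

test_that("the three-node example reproduces all printed phi values", {
  ex <- three_node_example()
  net <- ex$network; s <- ex$state
  expect_equal(mechanism_phi(net, s, c(1, 2), c(1, 2, 3), "effect")$phi,
               0.25, tolerance = 1e-9)
  expect_equal(mechanism_phi(net, s, c(1, 2), 3, "effect")$phi, 0.5,
               tolerance = 1e-9)
  cpt <- compute_concept(net, s, c(1, 2))
  expect_equal(cpt$cause$phi, 1 / 3, tolerance = 1e-9)
  expect_equal(cpt$cause$purview, c(1, 2, 3))
  expect_equal(cpt$effect$purview, 3)
  expect_equal(cpt$phi, 1 / 3, tolerance = 1e-9)
})

test_that("causally independent elements form no higher-order mechanism", {
  # X and Y: two separate self-loop copies, jointly reducible
  fs <- list(function(b) b[1], function(b) b[2])
  net <- animatphi:::net_from_functions(fs, labels = c("X", "Y"))
  expect_null(compute_concept(net, parse_state("10"), c(1, 2)))
})

test_that("the three-node conceptual structure has exactly four concepts", {
  ex <- three_node_example()
  cs <- conceptual_structure(ex$network, ex$state)
  mechs <- lapply(cs$concepts, `[[`, "mechanism")
  expect_equal(cs$n_concepts, 4)
  expect_setequal(vapply(mechs, paste, character(1), collapse = ","),
                  c("1", "2", "3", "1,2"))
  phis <- vapply(cs$concepts, `[[`, numeric(1), "phi")
  names(phis) <- vapply(mechs, paste, character(1), collapse = ",")
  expect_equal(unname(phis[c("1", "2", "3", "1,2")]),
               c(0.25, 1 / 6, 0.25, 1 / 3), tolerance = 1e-9)
})

test_that("system-level integration matches the printed value and MIP logic", {
  ex <- three_node_example()
  sp <- system_phi(ex$network, ex$state)
  expect_equal(sp$big_phi, 11 / 12, tolerance = 1e-9)
  # disconnected pairs analyzed jointly are reducible
  dp <- disconnected_pairs_system()
  expect_equal(system_phi(dp$network, dp$state)$big_phi, 0)
})

test_that("feed-forward brains never form a complex", {
  set.seed(31)
  for (i in 1:60) {
    b <- random_brain("feedforward", n_gates = sample(2:6, 1))
    mc <- find_main_complex(b, sample(0:255, 1))
    expect_equal(mc$big_phi, 0)
    expect_null(mc$elements)
  }
})

test_that("self-loop memory alone does not count as integration", {
  set.seed(32)
  for (i in 1:20) {
    b <- random_brain("selfloop", n_gates = 4)
    mc <- find_main_complex(b, sample(0:255, 1))
    expect_equal(mc$big_phi, 0)
  }
})

test_that("the main complex dominates every candidate subset (exclusion)", {
  ex <- three_node_example()
  mc <- find_main_complex(ex$network, ex$state)
  expect_equal(mc$elements, c(1L, 2L, 3L))
  expect_equal(mc$big_phi, 11 / 12, tolerance = 1e-9)
  expect_equal(mc$n_mc_concepts, 4)
  for (cand in mc$candidates)
    expect_lte(cand$big_phi, mc$big_phi + 1e-9)
  # candidate sets must have at least two elements
  expect_error(system_phi(ex$network, ex$state, nodes = 1), "at least 2")
})

test_that("whole-brain concepts are capped at 15 and empty brains have none", {
  b0 <- build_brain(list())
  expect_equal(whole_brain_concepts(b0, 0L)$n_concepts, 0)
  expect_equal(whole_brain_concepts(b0, 0L)$sum_phi, 0)
  set.seed(33)
  for (i in 1:10) {
    b <- random_brain("recurrent", n_gates = sample(3:8, 1))
    wb <- whole_brain_concepts(b, sample(0:255, 1))
    expect_lte(wb$n_concepts, 15)
    expect_gte(wb$sum_phi, 0)
  }
})

test_that("phi values are non-negative across random analyses", {
  set.seed(34)
  for (i in 1:15) {
    net <- oracle_random_net(3)
    st <- sample(0:7, 1)
    cs <- conceptual_structure(net, st)
    for (cpt in cs$concepts) {
      expect_gte(cpt$phi, 0)
      expect_gte(cpt$cause$phi, 0)
      expect_gte(cpt$effect$phi, 0)
      expect_equal(cpt$phi, min(cpt$cause$phi, cpt$effect$phi),
                   tolerance = 1e-12)
    }
    expect_gte(system_phi(net, st)$big_phi, 0)
  }
})

test_that("state-weighted averages are convex combinations of state values", {
  set.seed(35)
  b <- random_brain("recurrent", 5)
  sw <- state_weighted_summary(b, task_spec(1))
  expect_equal(sum(sw$per_state$weight), 1, tolerance = 1e-12)
  for (m in c("n_concepts", "sum_phi", "n_mc_elements", "n_mc_concepts",
              "big_phi")) {
    expect_gte(sw[[m]], min(sw$per_state[[m]]) - 1e-12)
    expect_lte(sw[[m]], max(sw$per_state[[m]]) + 1e-12)
  }
})
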