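# LOD measure tables, correlations, comparisons, structure counting

tiny_archive <- function(seed = 50, gens = 24) {
  set.seed(seed)
  run_evolution(task_spec(1),
                evolution_config(population_size = 15, generations = gens,
                                 lod_sample_interval = 8,
                                 genome_length = 1000))
}

fake_table <- function(gens, f, measures = NULL) {
  tab <- data.frame(generation = gens, F = f)
  for (m in measure_cols_for_tests()) {
    tab[[m]] <- if (is.null(measures)) stats::runif(length(gens)) else measures
  }
  class(tab) <- c("measures_table", "data.frame")
  tab
}

measure_cols_for_tests <- function() {
  c("n_concepts", "sum_phi", "n_mc_elements", "n_mc_concepts", "big_phi",
    "I_smmi", "I_pred", "H_sen", "H_mot", "H_state")
}

test_that("LOD measure tables carry one full row per sampled generation", {
  arch <- tiny_archive()
  tab <- compute_lod_measures(arch)
  expect_s3_class(tab, "measures_table")
  expect_equal(tab$generation, seq(0, 24, by = 8))
  expect_true(all(diff(tab$generation) > 0))
  # ancestral generation: no gates, no concepts, baseline fitness
  expect_equal(tab$F[1], 0.4375)
  expect_equal(tab$n_concepts[1], 0)
  expect_equal(tab$big_phi[1], 0)
  expect_true(all(is.finite(as.matrix(tab[-1]))))
  expect_true(all(as.matrix(tab[, measure_cols_for_tests()]) >= 0))
})

test_that("rank correlations hit the co-monotone and anti-monotone poles", {
  gens <- seq(0, 2560, by = 512)
  f <- seq(0.4, 0.9, length.out = length(gens))
  tab <- fake_table(gens, f)
  tab$n_concepts <- f * 10           # co-monotone
  tab$sum_phi <- -f                  # anti-monotone
  tab$big_phi <- rep(0.3, length(f)) # constant -> undefined
  r <- lod_correlations(tab)
  expect_equal(unname(r["n_concepts"]), 1)
  expect_equal(unname(r["sum_phi"]), -1)
  expect_true(is.na(r["big_phi"]))
  expect_error(lod_correlations(tab[1:2, ]), "at least 3")
})

test_that("independent measures have correlations centered on zero", {
  set.seed(51)
  rs <- replicate(200, {
    gens <- seq(0, 5120, by = 512)
    tab <- fake_table(gens, stats::runif(length(gens)))
    lod_correlations(tab)["n_concepts"]
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("condition comparisons use windowed means and detect offsets", {
  set.seed(52)
  gens <- seq(0, 5632, by = 512)
  mk <- function(offset) lapply(1:8, function(i) {
    tab <- fake_table(gens, stats::runif(length(gens), 0.5, 0.6))
    tab$n_concepts <- stats::runif(length(gens)) + offset
    tab
  })
  tables <- list(a = mk(0), b = mk(10))
  rep <- compare_conditions(tables, window = 3000)
  # a 3000-generation window at 512 spacing covers exactly 6 samples
  expect_equal(sum(gens > max(gens) - 3000), 6)
  expect_lt(rep$n_concepts$pairwise$p[1], 0.001)
  expect_lt(rep$n_concepts$kruskal$p, 0.01)
  # identical conditions: no significant difference
  same <- list(a = tables$a, b = tables$a)
  rep2 <- compare_conditions(same, window = 3000)
  expect_gt(rep2$n_concepts$pairwise$p[1], 0.9)
})

test_that("a window longer than the table is rejected", {
  tab <- fake_table(c(0, 512), c(0.4, 0.5))
  expect_error(windowed_mean(tab, "F", 1e6), "window")
  expect_equal(windowed_mean(tab, "F", 200), 0.5)
})

test_that("fitness matching picks the fittest prefix closest to the reference", {
  gens <- seq(0, 5632, by = 512)
  mk <- function(fval) fake_table(gens, rep(fval, length(gens)))
  ref <- list(mk(0.8), mk(0.8))
  # three of ten LODs share the reference mean exactly, and they are fittest
  lods <- c(lapply(c(0.8, 0.8, 0.8), mk), lapply(seq(0.3, 0.75, length.out = 7), mk))
  idx <- fitness_matched_subset(lods, ref, window = 5000)
  expect_equal(idx, 1:3)
  # brute-force oracle over fittest-prefix subsets
  f <- vapply(lods, windowed_mean, numeric(1), "F", 5000)
  ord <- order(f, decreasing = TRUE)
  errs <- abs(cumsum(f[ord]) / seq_along(ord) - 0.8)
  best_k <- max(which(errs <= min(errs) + 1e-12))
  expect_equal(sort(ord[seq_len(best_k)]), idx)
  # reference = the collection itself: the full set minimizes the mismatch
  expect_equal(fitness_matched_subset(ref, ref, 5000), 1:2)
})

test_that("structure counting is label-invariant and logic-sensitive", {
  set.seed(53)
  b <- random_brain("recurrent", 4)
  # permuted-label copy (swap hidden 3 and 4)
  perm <- c(1:2, 4, 3, 5:8)
  tpm <- matrix(0, 256, 8)
  for (s in 0:255) {
    bits <- animatphi:::int_to_bits(s, 8)
    olds <- animatphi:::bits_to_int(bits[perm])
    tpm[s + 1, ] <- animatphi:::int_to_bits(b$next_state[olds + 1], 8)[perm]
  }
  b_perm <- logic_network(tpm, b$cm[perm, perm],
                          roles = animatphi:::animat_roles())
  res <- count_distinct_structures(list(b, b_perm, b))
  expect_equal(res$n_tpms, 1)
  expect_equal(res$n_wirings, 1)
  expect_equal(res$n_behaviors, 1)
  # same wiring, one flipped table row: wiring count stays, TPM count grows
  g1 <- list(gate_spec(c(3, 4), 5, c(0L, 1L, 1L, 0L)),
             gate_spec(5, 3, c(0L, 1L)), gate_spec(3, 4, c(0L, 1L)))
  g2 <- list(gate_spec(c(3, 4), 5, c(1L, 1L, 1L, 0L)),
             gate_spec(5, 3, c(0L, 1L)), gate_spec(3, 4, c(0L, 1L)))
  res2 <- count_distinct_structures(list(build_brain(g1), build_brain(g2)))
  expect_equal(res2$n_wirings, 1)
  expect_equal(res2$n_tpms, 2)
  expect_lte(res2$n_wirings, res2$n_tpms)
})

test_that("the pipeline is deterministic end to end", {
  arch <- tiny_archive(seed = 54, gens = 16)
  t1 <- compute_lod_measures(arch)
  t2 <- compute_lod_measures(arch)
  expect_identical(t1, t2)
})
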