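# Genome encoding, decoding and mutation

test_that("decoding finds genes at start codons and skips everything else", {
  g <- ancestral_genome(1000)
  expect_length(decode_genome(g), 0)

  # one crafted gene: codon + counts + addresses + table
  g <- ancestral_genome(1000)
  g[101:102] <- c(42L, 213L)
  g[103] <- 0L                      # 1 input
  g[104] <- 1L                      # 2 outputs
  g[105] <- 2L                      # input address -> element 3 (hidden A)
  g[109:110] <- c(0L, 3L)           # outputs -> elements 3 and 6
  g[113:114] <- c(3L, 1L)           # table rows
  gates <- decode_genome(g)
  expect_length(gates, 1)
  expect_equal(gates[[1]]$inputs, 3L)
  expect_equal(gates[[1]]$outputs, c(3L, 6L))
  expect_equal(gates[[1]]$table, c(3L, 1L))

  # input/output counts come from the two loci after the codon
  g[103] <- 6L   # 6 %% 4 = 2 -> 3 inputs
  expect_length(decode_genome(g)[[1]]$inputs, 3L)
})

test_that("overlapping start codons decode one gene each", {
  g <- ancestral_genome(1200)
  g[501:504] <- c(42L, 213L, 42L, 213L)
  expect_length(decode_genome(g), 2)
  # independent oracle: count codon occurrences by direct scanning
  n_codons <- sum(g[-length(g)] == 42L & g[-1] == 213L)
  expect_length(decode_genome(g), n_codons)
})

test_that("genes wrap around the circular genome end", {
  g <- ancestral_genome(1000)
  g[999:1000] <- c(42L, 213L)       # codon at the very end; body wraps
  g[1] <- 3L                        # n_inputs locus (wrapped)
  gates <- decode_genome(g)
  expect_length(gates, 1)
  expect_length(gates[[1]]$inputs, 4L)  # 3 %% 4 + 1
})

test_that("ancestral genomes decode to nothing and give empty brains", {
  g <- ancestral_genome(5000)
  expect_length(decode_genome(g), 0)
  brain <- build_brain(decode_genome(g))
  expect_equal(sum(brain$cm), 0)
  expect_equal(whole_brain_concepts(brain, 0L)$n_concepts, 0)
  expect_error(ancestral_genome(999), "length")
})

test_that("zero mutation rates are a no-op", {
  set.seed(1)
  g <- random_genome(2000)
  cfg <- mutation_config(point_rate = 0, deletion_prob = 0,
                         duplication_prob = 0)
  expect_identical(mutate_genome(g, cfg), g)
})

test_that("point mutations resample loci uniformly", {
  set.seed(2)
  g <- random_genome(20000)
  cfg <- mutation_config(point_rate = 1, deletion_prob = 0,
                         duplication_prob = 0)
  m <- mutate_genome(g, cfg)
  # every locus redrawn uniformly: expected fraction unchanged = 1/256
  frac <- mean(m == g)
  sigma <- sqrt((1 / 256) * (255 / 256) / length(g))
  expect_lt(abs(frac - 1 / 256), 3 * sigma + 1e-9)
  expect_true(all(m >= 0 & m <= 255))
})

test_that("deletions at the minimum length are suppressed", {
  set.seed(3)
  g <- random_genome(1000)
  cfg <- mutation_config(point_rate = 0, deletion_prob = 1,
                         duplication_prob = 0)
  for (i in 1:20) expect_length(mutate_genome(g, cfg), 1000)
})

test_that("duplications at the maximum length are suppressed", {
  set.seed(4)
  g <- random_genome(20000)
  cfg <- mutation_config(point_rate = 0, deletion_prob = 0,
                         duplication_prob = 1)
  for (i in 1:20) expect_length(mutate_genome(g, cfg), 20000)
})

test_that("mutation respects genome bounds and locus range under fuzzing", {
  set.seed(5)
  cfg <- mutation_config()
  g <- random_genome(1100)
  for (i in 1:500) {
    g <- mutate_genome(g, cfg)
    expect_true(length(g) >= 1000 && length(g) <= 20000)
    expect_true(all(g >= 0 & g <= 255))
  }
})

test_that("decode of mutated genomes always yields structurally valid gates", {
  set.seed(6)
  cfg <- mutation_config(point_rate = 0.02)
  for (i in 1:300) {
    g <- mutate_genome(random_genome(1000), cfg)
    for (gate in decode_genome(g)) {
      expect_true(all(gate$inputs %in% 1:6))
      expect_true(all(gate$outputs %in% 3:8))
      expect_true(length(gate$inputs) %in% 1:4)
      expect_true(length(gate$outputs) %in% 1:4)
      expect_length(gate$table, 2^length(gate$inputs))
      expect_true(all(gate$table >= 0 &
                        gate$table < 2^length(gate$outputs)))
    }
  }
})

test_that("duplication tends to add genes and deletion to remove them", {
  set.seed(7)
  base <- ancestral_genome(1500)
  # plant 10 genes
  for (k in 0:9) base[(k * 100 + 1):(k * 100 + 2)] <- c(42L, 213L)
  n0 <- length(decode_genome(base))
  dup_cfg <- mutation_config(point_rate = 0, deletion_prob = 0,
                             duplication_prob = 1)
  del_cfg <- mutation_config(point_rate = 0, deletion_prob = 1,
                             duplication_prob = 0)
  dup_n <- replicate(200, length(decode_genome(mutate_genome(base, dup_cfg))))
  del_n <- replicate(200, length(decode_genome(mutate_genome(base, del_cfg))))
  expect_gte(mean(dup_n), n0)
  expect_lte(mean(del_n), n0)
})

test_that("prefix padding with non-codon loci leaves the gene count stable", {
  set.seed(8)
  g <- random_genome(1500)
  g[g == 42L] <- 40L  # remove accidental codons entirely for a clean check
  g[300:301] <- c(42L, 213L)
  n1 <- length(decode_genome(g))
  padded <- c(rep(7L, 200), g)  # insert inert loci before the first codon
  expect_length(decode_genome(padded), n1)
})

test_that("genome text round-trip preserves loci", {
  set.seed(9)
  gs <- list(random_genome(1000), ancestral_genome(1200))
  path <- tempfile(fileext = ".txt")
  write_genomes(gs, path)
  expect_identical(read_genomes(path), lapply(gs, as.integer))
  unlink(path)
})
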