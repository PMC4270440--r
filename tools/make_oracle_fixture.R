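#!/usr/bin/env Rscript
# Regenerates tests/testthat/fixtures/oracle_corpus.json: 100 random small
# deterministic networks with concepts, phi^max and Phi^max computed by the
# independent reference implementation (tests/testthat/helper-oracle.R).
# Run from the package root. Slow (the reference is deliberately naive).

library(animatphi)
source("tests/testthat/helper-oracle.R")

set.seed(20140918)
corpus <- list()
sizes <- c(rep(3L, 88), rep(4L, 12))
for (i in seq_along(sizes)) {
  oracle_reset()
  n <- sizes[i]
  net <- oracle_random_net(n)
  st <- sample(0:(2^n - 1), 1)
  O <- oracle_conceptual_structure(net, st, seq_len(n))
  bp <- oracle_big_phi(net, st, seq_len(n))
  corpus[[i]] <- list(
    n = n,
    tpm = as.integer(net$tpm %*% 2^(0:(n - 1))),
    cm = unname(net$cm),
    state = st,
    concepts = lapply(O, function(c)
      list(mechanism = c$mechanism, phi = c$phi,
           phi_cause = c$phi_cause, phi_effect = c$phi_effect)),
    big_phi = bp)
  cat(sprintf("[%d/%d] n=%d state=%d concepts=%d Phi=%.6f\n",
              i, length(sizes), n, st, length(O), bp))
  flush(stdout())
}
dir.create("tests/testthat/fixtures", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(corpus, "tests/testthat/fixtures/oracle_corpus.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote tests/testthat/fixtures/oracle_corpus.json\n")
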