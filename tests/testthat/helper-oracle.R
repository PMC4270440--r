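# Independent reference implementation of the causal analysis, used as the
# oracle in equivalence tests. Deliberately written as plain nested loops over
# full state enumerations, with its own partition enumeration and an
# LP-based exact transport solver (boot::simplex), sharing no code with the
# package's engine beyond the logic_network container.

cut_key <- function(cut) {
  if (is.null(cut)) return("")
  paste(paste(cut$from, collapse = "."), paste(cut$to, collapse = "."),
        sep = ">")
}

oracle_bits <- function(s, n) bitwAnd(bitwShiftR(as.integer(s), 0:(n - 1)), 1L)
oracle_int <- function(bits) sum(bits * 2^(seq_along(bits) - 1))

oracle_hamming_D <- function(k) {
  outer(0:(2^k - 1), 0:(2^k - 1), function(a, b) {
    x <- bitwXor(a, b)
    vapply(x, function(v) sum(bitwAnd(bitwShiftR(v, 0:10), 1L)), numeric(1))
  })
}

# exact transport via linear programming; shared mass cancelled first
.oracle_emd_memo <- new.env(parent = emptyenv())
oracle_emd <- function(p, q, D) {
  if (max(abs(p - q)) < 1e-13) return(0)
  key <- paste(c(signif(p, 12), signif(q, 12), dim(D)), collapse = "|")
  hit <- .oracle_emd_memo[[key]]
  if (!is.null(hit)) return(hit)
  m <- pmin(p, q)
  pe <- p - m; qe <- q - m
  si <- which(pe > 1e-13); ti <- which(qe > 1e-13)
  val <- if (length(si) == 0 || length(ti) == 0) {
    0
  } else if (length(si) == 1) {
    sum(qe[ti] * D[si, ti])
  } else if (length(ti) == 1) {
    sum(pe[si] * D[si, ti])
  } else {
    n1 <- length(si); n2 <- length(ti); nv <- n1 * n2
    cost <- as.vector(t(D[si, ti, drop = FALSE]))
    A3 <- matrix(0, n1 + n2 - 1, nv)
    for (r in seq_len(n1)) A3[r, ((r - 1) * n2 + 1):(r * n2)] <- 1
    if (n2 > 1)
      for (cc in seq_len(n2 - 1)) A3[n1 + cc, seq(cc, nv, by = n2)] <- 1
    res <- boot::simplex(a = cost, A3 = A3,
                         b3 = c(pe[si], qe[ti][seq_len(n2 - 1)]),
                         maxi = FALSE)
    unname(res$value)
  }
  .oracle_emd_memo[[key]] <- val
  val
}

# probability that node j is ON next step given a full current state,
# averaging over severed inputs (cut = list(from, to), noised connections)
oracle_p_on <- function(net, full_bits, j, cut = NULL) {
  sev <- if (!is.null(cut) && j %in% cut$to)
    intersect(cut$from, which(net$cm[, j] > 0)) else integer(0)
  if (length(sev) == 0)
    return(net$tpm[oracle_int(full_bits) + 1, j])
  tot <- 0
  for (mask in 0:(2^length(sev) - 1)) {
    fb <- full_bits
    fb[sev] <- oracle_bits(mask, length(sev))
    tot <- tot + net$tpm[oracle_int(fb) + 1, j]
  }
  tot / 2^length(sev)
}

# cause repertoire (factorized over mechanism elements, Bayesian inversion
# over a uniform perturbation prior); nodes outside `nodes` are marginalized
# uniformly, like every other unconstrained element
oracle_cause_rep <- function(net, state, mech, purview, nodes, cut = NULL) {
  n <- net$n
  purview <- sort(purview); mech <- sort(mech)
  state_bits <- oracle_bits(state, n)
  np <- length(purview)
  if (length(mech) == 0) return(rep(1 / 2^np, 2^np))
  free <- setdiff(seq_len(n), purview)
  out <- rep(1, 2^np)
  for (m in mech) {
    g <- numeric(2^np)
    for (ps in 0:(2^np - 1)) {
      pb <- oracle_bits(ps, np)
      tot <- 0
      for (fs in 0:(2^length(free) - 1)) {
        fb <- state_bits                      # background at current state
        fb[purview] <- pb
        if (length(free) > 0) fb[free] <- oracle_bits(fs, length(free))
        pon <- oracle_p_on(net, fb, m, cut)
        tot <- tot + if (state_bits[m] == 1) pon else 1 - pon
      }
      g[ps + 1] <- tot / 2^length(free)
    }
    out <- out * g
  }
  tot <- sum(out)
  if (tot <= 0) return(NULL)
  out / tot
}

# effect repertoire: product over purview elements of next-state marginals
oracle_effect_rep <- function(net, state, mech, purview, nodes, cut = NULL) {
  n <- net$n
  purview <- sort(purview); mech <- sort(mech)
  state_bits <- oracle_bits(state, n)
  free <- setdiff(seq_len(n), mech)
  marg <- vapply(purview, function(j) {
    tot <- 0
    for (fs in 0:(2^length(free) - 1)) {
      fb <- state_bits
      if (length(free) > 0) fb[free] <- oracle_bits(fs, length(free))
      tot <- tot + oracle_p_on(net, fb, j, cut)
    }
    tot / 2^length(free)
  }, numeric(1))
  out <- 1
  for (m in marg) out <- c(out * (1 - m), out * m)
  out
}

# per-network memo for repertoires and phi values (pure functions of their
# arguments; reset when switching networks)
.oracle_memo <- new.env(parent = emptyenv())
oracle_reset <- function() {
  rm(list = ls(.oracle_memo), envir = .oracle_memo)
}

oracle_rep <- function(net, state, mech, purview, nodes, side, cut = NULL) {
  key <- paste("r", state, side, paste(mech, collapse = "."),
               paste(purview, collapse = "."), paste(nodes, collapse = "."),
               cut_key(cut), sep = "|")
  hit <- .oracle_memo[[key]]
  if (!is.null(hit)) return(if (identical(hit, "null")) NULL else hit)
  v <- if (side == "cause") oracle_cause_rep(net, state, mech, purview, nodes, cut)
       else oracle_effect_rep(net, state, mech, purview, nodes, cut)
  .oracle_memo[[key]] <- if (is.null(v)) "null" else v
  v
}

oracle_subsets <- function(v, include_empty = FALSE) {
  out <- list()
  for (mask in 0:(2^length(v) - 1)) {
    if (!include_empty && mask == 0) next
    out[[length(out) + 1]] <- v[bitwAnd(bitwShiftR(mask, seq_along(v) - 1), 1L) == 1L]
  }
  out
}

# phi over one mechanism/purview pair: minimum over bipartitions of the
# transport distance between whole and partitioned repertoires
oracle_phi <- function(net, state, mech, purview, nodes, side, cut = NULL) {
  key <- paste("phi", state, side, paste(mech, collapse = "."),
               paste(sort(purview), collapse = "."),
               paste(nodes, collapse = "."),
               cut_key(cut), sep = "|")
  hit <- .oracle_memo[[key]]
  if (!is.null(hit)) return(hit)
  v <- oracle_phi_raw(net, state, mech, purview, nodes, side, cut)
  .oracle_memo[[key]] <- v
  v
}

oracle_phi_raw <- function(net, state, mech, purview, nodes, side, cut = NULL) {
  purview <- sort(purview)
  np <- length(purview)
  whole <- oracle_rep(net, state, mech, purview, nodes, side, cut)
  if (is.null(whole)) return(0)
  D <- oracle_hamming_D(np)
  best <- Inf
  # keep the first mechanism element in part 1 so each unordered partition
  # is enumerated once
  for (m0 in oracle_subsets(mech[-1], include_empty = TRUE)) {
    m1 <- setdiff(mech, m0)
    for (p0 in oracle_subsets(purview, include_empty = TRUE)) {
      p1 <- setdiff(purview, p0)
      if (length(m0) == 0 && length(p0) == 0) next
      if (length(m1) == 0 && length(p1) == 0) next
      part <- rep(1, 2^np)
      ok <- TRUE
      for (half in list(list(m0, p0), list(m1, p1))) {
        if (length(half[[2]]) == 0) next
        r <- oracle_rep(net, state, half[[1]], half[[2]], nodes, side, cut)
        if (is.null(r)) { ok <- FALSE; break }
        pos <- match(half[[2]], purview)
        expand <- numeric(2^np)
        for (s in 0:(2^np - 1)) {
          sb <- oracle_bits(s, np)
          expand[s + 1] <- r[oracle_int(sb[pos]) + 1]
        }
        part <- part * expand
      }
      if (!ok) next
      d <- oracle_emd(whole, part, D)
      if (d < best) best <- d
    }
  }
  if (!is.finite(best)) 0 else max(best, 0)
}

oracle_core_phi <- function(net, state, mech, nodes, side, cut = NULL,
                            space = nodes) {
  best <- 0
  for (pv in oracle_subsets(space)) {
    ph <- oracle_phi(net, state, mech, pv, nodes, side, cut)
    if (ph > best) best <- ph
  }
  best
}

# all concepts of a candidate set: mechanism subsets with phi^max > 0
oracle_conceptual_structure <- function(net, state, nodes, cut = NULL,
                                        mech_space = nodes,
                                        cause_space = nodes,
                                        effect_space = nodes) {
  out <- list()
  for (mech in oracle_subsets(mech_space)) {
    pc <- oracle_core_phi(net, state, mech, nodes, "cause", cut, cause_space)
    if (pc <= 1e-10) next
    pe <- oracle_core_phi(net, state, mech, nodes, "effect", cut, effect_space)
    if (pe <= 1e-10) next
    out[[length(out) + 1]] <- list(mechanism = mech, phi = min(pc, pe),
                                   phi_cause = pc, phi_effect = pe)
  }
  out
}

# core repertoires expanded over the candidate set, with the package's
# tie-break (largest purview, then lexicographically first), needed for the
# concept-level ground distances of big phi
oracle_core_full <- function(net, state, mech, nodes, side, cut = NULL) {
  cand <- list(phi = 0, purview = NULL)
  for (pv in oracle_subsets(nodes)) {
    ph <- oracle_phi(net, state, mech, pv, nodes, side, cut)
    better <- ph > cand$phi + 1e-10
    tie <- ph > 1e-10 && abs(ph - cand$phi) <= 1e-10 && !is.null(cand$purview) &&
      (length(pv) > length(cand$purview) ||
         (length(pv) == length(cand$purview) &&
            paste(pv, collapse = ",") < paste(cand$purview, collapse = ",")))
    if (better || tie) cand <- list(phi = ph, purview = pv)
  }
  if (is.null(cand$purview)) return(NULL)
  r <- oracle_rep(net, state, mech, cand$purview, nodes, side, cut)
  # expand over all candidate-set elements
  rest <- setdiff(nodes, cand$purview)
  fill <- if (side == "cause") rep(1 / 2^length(rest), 2^length(rest))
          else oracle_effect_rep(net, state, integer(0), rest, nodes, cut)
  k <- length(nodes)
  full <- numeric(2^k)
  for (s in 0:(2^k - 1)) {
    sb <- oracle_bits(s, k)
    ip <- oracle_int(sb[match(sort(cand$purview), sort(nodes))])
    ir <- oracle_int(sb[match(sort(rest), sort(nodes))])
    full[s + 1] <- r[ip + 1] * fill[ir + 1]
  }
  list(phi = cand$phi, purview = cand$purview, full = full)
}

oracle_big_phi <- function(net, state, nodes) {
  nodes <- sort(nodes)
  k <- length(nodes)
  C <- oracle_conceptual_structure(net, state, nodes)
  if (length(C) == 0) return(0)
  D <- oracle_hamming_D(k)
  concept_data <- function(cut) {
    cs <- oracle_conceptual_structure(net, state, nodes, cut)
    lapply(cs, function(cpt) {
      cc <- oracle_core_full(net, state, cpt$mechanism, nodes, "cause", cut)
      ce <- oracle_core_full(net, state, cpt$mechanism, nodes, "effect", cut)
      list(phi = cpt$phi, cr = cc$full, er = ce$full)
    })
  }
  whole <- concept_data(NULL)
  null_cr <- rep(1 / 2^k, 2^k)
  null_er <- oracle_effect_rep(net, state, integer(0), nodes, nodes)
  gdist <- function(a_cr, a_er, b_cr, b_er)
    oracle_emd(a_cr, b_cr, D) + oracle_emd(a_er, b_er, D)
  best <- Inf
  for (from in oracle_subsets(nodes)) {
    to <- setdiff(nodes, from)
    if (length(to) == 0) next
    cut <- list(from = from, to = to)
    cutC <- concept_data(cut)
    n1 <- length(whole); n2 <- length(cutC)
    phis1 <- vapply(whole, `[[`, numeric(1), "phi")
    phis2 <- if (n2 > 0) vapply(cutC, `[[`, numeric(1), "phi") else numeric(0)
    src <- c(phis1, max(sum(phis2) - sum(phis1), 0))
    dst <- c(phis2, max(sum(phis1) - sum(phis2), 0))
    cost <- matrix(0, n1 + 1, n2 + 1)
    for (i in seq_len(n1)) {
      for (j in seq_len(n2))
        cost[i, j] <- gdist(whole[[i]]$cr, whole[[i]]$er,
                            cutC[[j]]$cr, cutC[[j]]$er)
      cost[i, n2 + 1] <- gdist(whole[[i]]$cr, whole[[i]]$er, null_cr, null_er)
    }
    for (j in seq_len(n2))
      cost[n1 + 1, j] <- gdist(null_cr, null_er, cutC[[j]]$cr, cutC[[j]]$er)
    # transport phi mass between the structures (rectangular, totals padded)
    d <- transport_lp(src, dst, cost)
    if (d < best) best <- d
  }
  max(best, 0)
}

transport_lp <- function(src, dst, cost) {
  si <- which(src > 1e-13); ti <- which(dst > 1e-13)
  if (length(si) == 0 || length(ti) == 0) return(0)
  if (length(si) == 1) return(sum(dst[ti] * cost[si, ti]))
  if (length(ti) == 1) return(sum(src[si] * cost[si, ti]))
  n1 <- length(si); n2 <- length(ti); nv <- n1 * n2
  a <- as.vector(t(cost[si, ti, drop = FALSE]))
  A3 <- matrix(0, n1 + n2 - 1, nv)
  for (r in seq_len(n1)) A3[r, ((r - 1) * n2 + 1):(r * n2)] <- 1
  if (n2 > 1)
    for (cc in seq_len(n2 - 1)) A3[n1 + cc, seq(cc, nv, by = n2)] <- 1
  unname(boot::simplex(a = a, A3 = A3,
                       b3 = c(src[si], dst[ti][seq_len(n2 - 1)]),
                       maxi = FALSE)$value)
}

# random deterministic network with dependency-consistent cm
oracle_random_net <- function(n) {
  repeat {
    tpm <- matrix(sample(0:1, 2^n * n, replace = TRUE), 2^n, n)
    cm <- matrix(0L, n, n)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      for (s in 0:(2^n - 1)) {
        if (tpm[s + 1, j] != tpm[bitwXor(s, bitwShiftL(1L, i - 1L)) + 1, j]) {
          cm[i, j] <- 1L
          break
        }
      }
    }
    if (sum(cm) > 0) break
  }
  animatphi::logic_network(tpm, cm)
}
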