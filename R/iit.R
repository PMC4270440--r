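#' Integrated information (IIT 3.0) analysis of logic-gate networks
#'
#' Implements the full mechanism- and system-level causal analysis for small
#' deterministic binary networks: cause and effect repertoires under uniform
#' perturbation, earth-mover's distances with a Hamming ground metric,
#' mechanism-level integrated information (phi) with minimum information
#' partitions, concepts and conceptual structures, system-level integrated
#' conceptual information (big Phi) under unidirectional partitions, and the
#' search for the main complex.
#'
#' Conventions follow the EMD-based formulation of IIT 3.0: cause
#' repertoires are Bayesian inversions over a uniform perturbation prior,
#' factorized over mechanism elements; effect repertoires factorize over
#' purview elements; partitions replace severed connections by independent
#' uniform noise. When a proper subset of elements is analyzed as a
#' candidate complex, the elements outside the candidate set are rendered
#' causally ineffective by the same independent uniform perturbation (see
#' the methods vignette for why this convention, rather than clamping, is
#' required to reproduce the worked examples).
#'
#' @name iit
NULL

# cached bit matrices: states_bits(k)[s + 1, ] = little-endian bits of s
.iit_cache <- new.env(parent = emptyenv())

states_bits <- function(k) {
  key <- as.character(k)
  if (!is.null(.iit_cache[[key]])) return(.iit_cache[[key]])
  m <- matrix(0L, 2^k, max(k, 1))
  if (k > 0)
    for (i in seq_len(k)) m[, i] <- bitwAnd(bitwShiftR(0:(2^k - 1), i - 1L), 1L)
  m <- m[, seq_len(k), drop = FALSE]
  .iit_cache[[key]] <- m
  m
}

#' Construct a subsystem for causal analysis
#'
#' @param net A `logic_network`.
#' @param state Integer state code of the whole network.
#' @param nodes Candidate set of element indices (1-based); elements outside
#'   the candidate set are rendered causally ineffective by independent
#'   uniform perturbation (their inputs to candidate elements are
#'   marginalized), so that a candidate set is analyzed as a causal entity
#'   in its own right.
#' @param cut Optional unidirectional partition `list(from =, to =)`:
#'   connections from `from` to `to` are replaced by uniform noise.
#' @return A subsystem object (used by the repertoire and phi functions).
#' @export
make_subsystem <- function(net, state, nodes = seq_len(net$n), cut = NULL) {
  stopifnot(inherits(net, "logic_network"))
  nodes <- sort(as.integer(nodes))
  n <- net$n
  k <- length(nodes)
  if (k < 1) stop("candidate set must be non-empty")
  state_bits <- int_to_bits(state, n)
  bg <- setdiff(seq_len(n), nodes)
  Xsub <- states_bits(k)
  w_full <- 2^(nodes - 1)
  pOn <- matrix(0, 2^k, k)
  cm_eff <- net$cm
  if (!is.null(cut)) cm_eff[cut$from, cut$to] <- 0L
  for (jj in seq_len(k)) {
    j <- nodes[jj]
    cut_in <- if (!is.null(cut) && j %in% cut$to) cut$from else integer(0)
    # marginalize background inputs and severed inputs uniformly
    marg <- intersect(union(bg, cut_in), which(net$cm[, j] > 0))
    keep_sub <- !(nodes %in% marg)
    idx_base <- as.vector(Xsub[, keep_sub, drop = FALSE] %*%
                            w_full[keep_sub])
    if (length(marg) == 0) {
      pOn[, jj] <- net$tpm[idx_base + 1, j]
    } else {
      Xs <- states_bits(length(marg))
      acc <- numeric(2^k)
      for (r in seq_len(nrow(Xs))) {
        add <- sum(Xs[r, ] * 2^(marg - 1))
        acc <- acc + net$tpm[idx_base + add + 1, j]
      }
      pOn[, jj] <- acc / nrow(Xs)
    }
  }
  structure(list(net = net, state = state, state_bits = state_bits,
                 nodes = nodes, k = k, bg = bg, cut = cut,
                 pOn = pOn, cm_eff = cm_eff[nodes, nodes, drop = FALSE],
                 cache = new.env(parent = emptyenv())),
            class = "iit_subsystem")
}

# positions (within sub$nodes) of absolute node ids
node_pos <- function(sub, ids) match(sort(as.integer(ids)), sub$nodes)

purview_index <- function(sub, ppos) {
  key <- paste0("pi", paste(ppos, collapse = "."))
  v <- sub$cache[[key]]
  if (is.null(v)) {
    Xsub <- states_bits(sub$k)
    v <- as.integer(Xsub[, ppos, drop = FALSE] %*% 2^(seq_along(ppos) - 1)) + 1L
    sub$cache[[key]] <- v
  }
  v
}

# cause repertoire over purview positions; NULL when the mechanism state is
# unreachable under every perturbation
sub_cause_rep <- function(sub, mpos, ppos) {
  key <- paste0("c", paste(mpos, collapse = "."), "|", paste(ppos, collapse = "."))
  v <- sub$cache[[key]]
  if (!is.null(v)) return(if (identical(v, "null")) NULL else v)
  np <- length(ppos)
  if (length(mpos) == 0) {
    out <- rep(1 / 2^np, 2^np)
  } else {
    gidx <- purview_index(sub, ppos)
    g <- rep(1, 2^np)
    for (m in mpos) {
      s_m <- sub$state_bits[sub$nodes[m]]
      vm <- if (s_m == 1) sub$pOn[, m] else 1 - sub$pOn[, m]
      gm <- as.vector(rowsum(vm, gidx, reorder = TRUE)) / 2^(sub$k - np)
      g <- g * gm
    }
    tot <- sum(g)
    if (tot <= 0) {
      sub$cache[[key]] <- "null"
      return(NULL)
    }
    out <- g / tot
  }
  sub$cache[[key]] <- out
  out
}

# effect repertoire: vector of on-probability marginals, one per purview node
sub_effect_marginals <- function(sub, mpos, ppos) {
  key <- paste0("e", paste(mpos, collapse = "."), "|", paste(ppos, collapse = "."))
  v <- sub$cache[[key]]
  if (!is.null(v)) return(v)
  if (length(mpos) == 0) {
    out <- colMeans(sub$pOn[, ppos, drop = FALSE])
  } else {
    Xsub <- states_bits(sub$k)
    ms <- sub$state_bits[sub$nodes[mpos]]
    match_rows <- rowSums(Xsub[, mpos, drop = FALSE] !=
                            matrix(ms, 2^sub$k, length(mpos), byrow = TRUE)) == 0
    out <- colMeans(sub$pOn[match_rows, ppos, drop = FALSE])
  }
  sub$cache[[key]] <- out
  out
}

marginals_to_joint <- function(marg) {
  out <- 1
  for (m in marg) out <- c(out * (1 - m), out * m)
  out
}

#' Cause and effect repertoires
#'
#' The cause repertoire of a mechanism in its current state is the
#' distribution over past purview states obtained by Bayesian inversion of
#' the element-wise transition probabilities under a uniform perturbation
#' prior (factorized over mechanism elements). The effect repertoire is the
#' distribution of future purview states with the mechanism clamped to its
#' current sub-state and all other inputs perturbed uniformly (factorized
#' over purview elements).
#'
#' @param net A `logic_network`.
#' @param state Integer state code.
#' @param mechanism Element indices of the mechanism (may be empty for the
#'   unconstrained repertoire).
#' @param purview Element indices of the purview.
#' @param nodes Candidate set (defaults to the whole network).
#' @return Named numeric vector of probabilities over the purview's states
#'   (little-endian over the sorted purview), or `NULL` for an undefined
#'   cause repertoire (mechanism state unreachable).
#' @export
cause_repertoire <- function(net, state, mechanism, purview,
                             nodes = seq_len(net$n)) {
  sub <- make_subsystem(net, state, nodes)
  r <- sub_cause_rep(sub, node_pos(sub, mechanism), node_pos(sub, purview))
  label_rep(r, length(purview))
}

#' @rdname cause_repertoire
#' @export
effect_repertoire <- function(net, state, mechanism, purview,
                              nodes = seq_len(net$n)) {
  sub <- make_subsystem(net, state, nodes)
  m <- sub_effect_marginals(sub, node_pos(sub, mechanism), node_pos(sub, purview))
  label_rep(marginals_to_joint(m), length(purview))
}

label_rep <- function(r, np) {
  if (is.null(r)) return(NULL)
  names(r) <- apply(states_bits(np), 1, paste, collapse = "")
  r
}

#' Earth-mover's distance between repertoires
#'
#' Exact optimal-transport cost between two distributions over k-bit states
#' with the Hamming distance between states as ground metric.
#'
#' @param p,q Numeric probability vectors of equal power-of-two length.
#' @return The transport cost.
#' @export
emd_hamming <- function(p, q) {
  if (length(p) != length(q)) stop("mismatched purviews")
  cpp_emd_hamming(as.numeric(p), as.numeric(q))
}

# partition enumeration for a mechanism/purview pair: unordered mechanism
# bipartitions x directed purview bipartitions; each part must be non-empty
# in mechanism or purview; the unpartitioned pair is excluded.
mip_partitions <- function(nm, np) {
  out <- list()
  mech_masks <- if (nm == 0) 0L else 0:(2^(nm - 1) - 1)  # first element fixed in part 1
  for (mm in mech_masks) {
    for (pm in 0:(2^np - 1)) {
      m0 <- mm; m1_size <- nm - sum(int_to_bits(mm, max(nm, 1)))
      p0_size <- sum(int_to_bits(pm, max(np, 1)))
      if (sum(int_to_bits(mm, max(nm, 1))) == 0 && p0_size == 0) next
      if (m1_size == 0 && (np - p0_size) == 0) next
      out[[length(out) + 1]] <- c(mm, pm)
    }
  }
  out
}

# phi for one mechanism/purview pair on one side; returns list(phi, mip)
sub_phi_side <- function(sub, mpos, ppos, side) {
  nm <- length(mpos); np <- length(ppos)
  if (np == 0) return(list(phi = 0, mip = NULL))
  if (side == "cause") {
    whole <- sub_cause_rep(sub, mpos, ppos)
    if (is.null(whole)) return(list(phi = 0, mip = NULL))
  } else {
    whole_m <- sub_effect_marginals(sub, mpos, ppos)
  }
  best <- Inf; best_part <- NULL
  mbits_all <- states_bits(max(nm, 1))
  for (part in mip_partitions(nm, np)) {
    mm <- part[1]; pm <- part[2]
    in0m <- which(bitwAnd(bitwShiftR(mm, 0:(nm - 1)), 1L) == 1L)
    m0 <- mpos[in0m]; m1 <- mpos[setdiff(seq_len(nm), in0m)]
    in0p <- which(bitwAnd(bitwShiftR(pm, 0:(np - 1)), 1L) == 1L)
    p0 <- ppos[in0p]; p1 <- ppos[setdiff(seq_len(np), in0p)]
    if (side == "cause") {
      r <- rep(1, 2^np)
      ok <- TRUE
      for (pt in list(list(m0, p0, in0p), list(m1, p1, setdiff(seq_len(np), in0p)))) {
        if (length(pt[[2]]) == 0) next
        rp <- sub_cause_rep(sub, pt[[1]], pt[[2]])
        if (is.null(rp)) { ok <- FALSE; break }
        # expand over the full purview
        pos_in_p <- pt[[3]]
        idx <- as.integer(states_bits(np)[, pos_in_p, drop = FALSE] %*%
                            2^(seq_along(pos_in_p) - 1)) + 1L
        r <- r * rp[idx]
      }
      if (!ok) next
      d <- cpp_emd_hamming(whole, r)
    } else {
      part_m <- numeric(np)
      for (pt in list(list(m0, p0, in0p), list(m1, p1, setdiff(seq_len(np), in0p)))) {
        if (length(pt[[2]]) == 0) next
        part_m[pt[[3]]] <- sub_effect_marginals(sub, pt[[1]], pt[[2]])
      }
      d <- sum(abs(whole_m - part_m))
    }
    if (d < best - 1e-12) {
      best <- d
      best_part <- list(mech0 = sub$nodes[m0], purview0 = sub$nodes[p0],
                        mech1 = sub$nodes[m1], purview1 = sub$nodes[p1])
    }
    if (best <= 1e-12) break
  }
  if (!is.finite(best)) best <- 0
  list(phi = max(best, 0), mip = best_part)
}

#' Mechanism-level integrated information over one purview
#'
#' phi is the earth-mover's distance between the whole cause (or effect)
#' repertoire of a mechanism over a purview and the repertoire of its
#' minimum information partition -- the bipartition of (mechanism, purview)
#' that destroys the least information.
#'
#' @inheritParams cause_repertoire
#' @param side `"cause"` or `"effect"`.
#' @return List with `phi` and `mip` (the minimizing bipartition).
#' @export
mechanism_phi <- function(net, state, mechanism, purview,
                          side = c("cause", "effect"),
                          nodes = seq_len(net$n)) {
  side <- match.arg(side)
  sub <- make_subsystem(net, state, nodes)
  sub_phi_side(sub, node_pos(sub, mechanism), node_pos(sub, purview), side)
}

# candidate purview elements: those with an (effective) edge to/from the
# mechanism; purviews containing unconnected elements provably have phi = 0.
relevant_purview_space <- function(sub, mpos, side, space_pos) {
  if (side == "cause") {
    keep <- which(rowSums(sub$cm_eff[, mpos, drop = FALSE]) > 0)
  } else {
    keep <- which(colSums(sub$cm_eff[mpos, , drop = FALSE]) > 0)
  }
  intersect(space_pos, keep)
}

# core cause/effect: maximum phi over purviews; ties broken by larger
# purview, then lexicographically smallest element set.
sub_core <- function(sub, mpos, side, space_pos) {
  space <- relevant_purview_space(sub, mpos, side, space_pos)
  best <- list(phi = 0, purview = NULL, mip = NULL, rep = NULL)
  if (length(space) == 0) return(best)
  subsets <- all_subsets(space)
  for (ppos in subsets) {
    r <- sub_phi_side(sub, mpos, ppos, side)
    if (r$phi > best$phi + 1e-10) {
      best <- list(phi = r$phi, purview = ppos, mip = r$mip)
    } else if (r$phi > 1e-10 && abs(r$phi - best$phi) <= 1e-10 &&
               !is.null(best$purview)) {
      if (length(ppos) > length(best$purview) ||
          (length(ppos) == length(best$purview) &&
           vec_less(sub$nodes[ppos], sub$nodes[best$purview])))
        best <- list(phi = r$phi, purview = ppos, mip = r$mip)
    }
  }
  best
}

all_subsets <- function(v) {
  out <- list()
  for (mask in 1:(2^length(v) - 1))
    out[[mask]] <- v[bitwAnd(bitwShiftR(mask, seq_along(v) - 1), 1L) == 1L]
  out
}

# mechanisms worth evaluating: every element needs an input from the cause
# space and an output into the effect space (otherwise phi = 0 provably)
mechanism_is_viable <- function(sub, mpos, cause_space, effect_space) {
  all(colSums(sub$cm_eff[cause_space, mpos, drop = FALSE]) > 0) &&
    all(rowSums(sub$cm_eff[mpos, effect_space, drop = FALSE]) > 0)
}

sub_concept <- function(sub, mpos, cause_space, effect_space) {
  if (!mechanism_is_viable(sub, mpos, cause_space, effect_space)) return(NULL)
  cc <- sub_core(sub, mpos, "cause", cause_space)
  if (cc$phi <= 1e-10) return(NULL)
  ce <- sub_core(sub, mpos, "effect", effect_space)
  if (ce$phi <= 1e-10) return(NULL)
  mech_ids <- sub$nodes[mpos]
  structure(list(
    mechanism = mech_ids,
    mechanism_state = sub$state_bits[mech_ids],
    phi = min(cc$phi, ce$phi),
    cause = list(purview = sub$nodes[cc$purview], phi = cc$phi, mip = cc$mip,
                 repertoire = sub_cause_rep(sub, mpos, cc$purview),
                 purview_pos = cc$purview),
    effect = list(purview = sub$nodes[ce$purview], phi = ce$phi, mip = ce$mip,
                  marginals = sub_effect_marginals(sub, mpos, ce$purview),
                  purview_pos = ce$purview)),
    class = "iit_concept")
}

#' Compute the concept of a mechanism
#'
#' Maximizes cause-side phi over all admissible cause purviews and
#' effect-side phi over effect purviews; the concept's phi^max is the
#' minimum of the two maxima. Returns `NULL` when the mechanism is
#' reducible (phi^max = 0).
#'
#' @inheritParams cause_repertoire
#' @param cause_space,effect_space Element sets from which purviews may be
#'   drawn (default: the candidate set).
#' @return An `iit_concept` or `NULL`.
#' @export
compute_concept <- function(net, state, mechanism, nodes = seq_len(net$n),
                            cause_space = nodes, effect_space = nodes) {
  sub <- make_subsystem(net, state, nodes)
  sub_concept(sub, node_pos(sub, mechanism),
              node_pos(sub, cause_space), node_pos(sub, effect_space))
}

sub_conceptual_structure <- function(sub, mech_space, cause_space, effect_space) {
  concepts <- list()
  viable <- mech_space[vapply(mech_space, function(m)
    sum(sub$cm_eff[cause_space, m]) > 0 && sum(sub$cm_eff[m, effect_space]) > 0,
    logical(1))]
  if (length(viable) > 0) {
    for (mpos in all_subsets(viable)) {
      cpt <- sub_concept(sub, mpos, cause_space, effect_space)
      if (!is.null(cpt)) concepts[[length(concepts) + 1]] <- cpt
    }
  }
  structure(list(concepts = concepts,
                 n_concepts = length(concepts),
                 sum_phi = sum(vapply(concepts, `[[`, numeric(1), "phi"))),
            class = "conceptual_structure")
}

#' Conceptual structure of a set of elements
#'
#' Evaluates every non-empty mechanism over the mechanism space and collects
#' the irreducible ones (phi^max > 0) with their core cause/effect purviews.
#'
#' @inheritParams compute_concept
#' @param mechanism_space Elements from which mechanisms are drawn
#'   (default: the candidate set).
#' @return A `conceptual_structure` with `concepts`, `n_concepts`,
#'   `sum_phi`.
#' @export
conceptual_structure <- function(net, state, nodes = seq_len(net$n),
                                 mechanism_space = nodes,
                                 cause_space = nodes, effect_space = nodes) {
  sub <- make_subsystem(net, state, nodes)
  sub_conceptual_structure(sub, node_pos(sub, mechanism_space),
                           node_pos(sub, cause_space),
                           node_pos(sub, effect_space))
}

#' @export
print.conceptual_structure <- function(x, ...) {
  cat("conceptual_structure:", x$n_concepts, "concepts, sum phi^max =",
      round(x$sum_phi, 4), "\n")
  for (c in x$concepts)
    cat(sprintf("  [%s] phi^max = %.4f (cause %s: %.4f, effect %s: %.4f)\n",
                paste(c$mechanism, collapse = ","), c$phi,
                paste(c$cause$purview, collapse = ","), c$cause$phi,
                paste(c$effect$purview, collapse = ","), c$effect$phi))
  invisible(x)
}

# ---- system level ---------------------------------------------------------

strongly_connected <- function(adj) {
  k <- nrow(adj)
  if (k < 2) return(FALSE)
  diag(adj) <- 0
  reach <- function(a) {
    seen <- rep(FALSE, k); seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier) > 0) {
      nxt <- which(colSums(a[frontier, , drop = FALSE] > 0) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }
  reach(adj) && reach(t(adj))
}

# expanded repertoires over the full candidate set, used for the extended EMD
expand_cause <- function(sub, cpt) {
  ppos <- cpt$cause$purview_pos
  r <- cpt$cause$repertoire
  k <- sub$k
  idx <- as.integer(states_bits(k)[, ppos, drop = FALSE] %*%
                      2^(seq_along(ppos) - 1)) + 1L
  r[idx] / 2^(k - length(ppos))
}

expand_effect <- function(sub, cpt) {
  # marginals over all candidate elements; non-purview ones unconstrained
  m <- sub_effect_marginals(sub, integer(0), seq_len(sub$k))
  m[cpt$effect$purview_pos] <- cpt$effect$marginals
  m
}

ces_distance <- function(sub, C, sub_cut, C_cut) {
  k <- sub$k
  reps1 <- lapply(C$concepts, function(c)
    list(cr = expand_cause(sub, c), em = expand_effect(sub, c)))
  reps2 <- lapply(C_cut$concepts, function(c)
    list(cr = expand_cause(sub_cut, c), em = expand_effect(sub_cut, c)))
  null_rep <- list(cr = rep(1 / 2^k, 2^k),
                   em = sub_effect_marginals(sub, integer(0), seq_len(k)))
  phis1 <- vapply(C$concepts, `[[`, numeric(1), "phi")
  phis2 <- if (C_cut$n_concepts > 0)
    vapply(C_cut$concepts, `[[`, numeric(1), "phi") else numeric(0)
  gdist <- function(a, b)
    cpp_emd_hamming(a$cr, b$cr) + sum(abs(a$em - b$em))
  n1 <- length(reps1); n2 <- length(reps2)
  tot1 <- sum(phis1); tot2 <- sum(phis2)
  src <- c(phis1, max(tot2 - tot1, 0))
  dst <- c(phis2, max(tot1 - tot2, 0))
  cost <- matrix(0, n1 + 1, n2 + 1)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) cost[i, j] <- gdist(reps1[[i]], reps2[[j]])
    cost[i, n2 + 1] <- gdist(reps1[[i]], null_rep)
  }
  if (n2 > 0)
    for (j in seq_len(n2)) cost[n1 + 1, j] <- gdist(null_rep, reps2[[j]])
  cpp_transport(src, dst, cost)
}

#' System-level integrated conceptual information
#'
#' Evaluates big Phi for a candidate set: the extended earth-mover's
#' distance between the conceptual structure of the intact set and that of
#' its minimum unidirectional partition (connections from one part to the
#' other replaced by noise). In the extended EMD the concepts' phi^max
#' values are transported; the ground distance between two concepts is the
#' EMD between their cause repertoires plus the EMD between their effect
#' repertoires, expanded over the candidate set, and surplus phi^max mass is
#' transported to the null concept (the unconstrained repertoires).
#'
#' @inheritParams compute_concept
#' @return List with `big_phi`, `mip` (the minimizing directed partition),
#'   `n_concepts`, `sum_phi` and `concepts` (the intact conceptual
#'   structure).
#' @export
system_phi <- function(net, state, nodes = seq_len(net$n)) {
  nodes <- sort(as.integer(nodes))
  if (length(nodes) < 2) stop("candidate sets must have at least 2 elements")
  sub <- make_subsystem(net, state, nodes)
  C <- sub_conceptual_structure(sub, seq_len(sub$k), seq_len(sub$k),
                                seq_len(sub$k))
  out <- list(big_phi = 0, mip = NULL, n_concepts = C$n_concepts,
              sum_phi = C$sum_phi, concepts = C)
  if (C$n_concepts == 0) return(out)
  if (!strongly_connected(sub$cm_eff)) return(out)
  k <- length(nodes)
  best <- Inf; best_cut <- NULL
  for (mask in 1:(2^k - 2)) {
    from <- nodes[bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L) == 1L]
    to <- setdiff(nodes, from)
    cut <- list(from = from, to = to)
    sub_cut <- make_subsystem(net, state, nodes, cut = cut)
    C_cut <- sub_conceptual_structure(sub_cut, seq_len(k), seq_len(k),
                                      seq_len(k))
    d <- ces_distance(sub, C, sub_cut, C_cut)
    if (d < best - 1e-12) {
      best <- d; best_cut <- cut
    }
    if (best <= 1e-12) break
  }
  out$big_phi <- max(best, 0)
  out$mip <- best_cut
  out
}

#' Find the main complex of a brain in a state
#'
#' Evaluates big Phi for every candidate set and returns the maximally
#' integrated one. For animat brains the candidates are the subsets of
#' hidden elements with at least 2 members: subsets containing a sensor or
#' motor are excluded a priori because elements connected in a feed-forward
#' manner cannot be part of an integrated system (their Phi is 0); for
#' generic networks all subsets of size >= 2 are candidates.
#'
#' @param net A `logic_network`.
#' @param state Integer state code.
#' @return A `complex_result`: `elements` (NULL when no complex exists),
#'   `big_phi`, `n_mc_elements`, `n_mc_concepts`, `mc_concepts`
#'   (conceptual structure of the winner), `mip`, and `candidates` (per-set
#'   Phi values from the search).
#' @export
find_main_complex <- function(net, state) {
  stopifnot(inherits(net, "logic_network"))
  pool <- if (any(net$roles != "hidden")) which(net$roles == "hidden")
          else seq_len(net$n)
  cand_sets <- Filter(function(s) length(s) >= 2, all_subsets(pool))
  best <- NULL; best_phi <- 0
  cand_log <- list()
  for (s in cand_sets) {
    r <- system_phi(net, state, s)
    cand_log[[length(cand_log) + 1]] <- list(elements = s, big_phi = r$big_phi)
    if (r$big_phi > best_phi + 1e-10 ||
        (r$big_phi > 1e-10 && abs(r$big_phi - best_phi) <= 1e-10 &&
         !is.null(best) && length(s) > length(best$elements))) {
      best_phi <- r$big_phi
      best <- list(elements = s, result = r)
    }
  }
  if (is.null(best) || best_phi <= 1e-10) {
    return(structure(list(elements = NULL, big_phi = 0, n_mc_elements = 0L,
                          n_mc_concepts = 0L, mc_concepts = NULL, mip = NULL,
                          candidates = cand_log),
                     class = "complex_result"))
  }
  structure(list(elements = best$elements, big_phi = best_phi,
                 n_mc_elements = length(best$elements),
                 n_mc_concepts = best$result$n_concepts,
                 mc_concepts = best$result$concepts,
                 mip = best$result$mip,
                 candidates = cand_log),
            class = "complex_result")
}

#' @export
print.complex_result <- function(x, ...) {
  if (is.null(x$elements)) {
    cat("complex_result: no complex (Phi = 0 for all candidate sets)\n")
  } else {
    cat(sprintf("complex_result: MC = {%s}, Phi^max = %.4f, %d concepts\n",
                paste(x$elements, collapse = ","), x$big_phi, x$n_mc_concepts))
  }
  invisible(x)
}

#' Whole-brain concept analysis
#'
#' Evaluates all mechanisms over the hidden elements of an animat brain with
#' the entire brain as candidate set (no background): sensors and motors
#' cannot give rise to concepts because, by design, they lack causes or
#' effects within the system, but cause purviews may include sensors and
#' effect purviews may include motors. The maximal possible number of
#' concepts is therefore \code{2^4 - 1 = 15}.
#'
#' @param net An animat `logic_network`.
#' @param state Integer state code.
#' @return List with `n_concepts`, `sum_phi` and `concepts`.
#' @export
whole_brain_concepts <- function(net, state) {
  stopifnot(inherits(net, "logic_network"))
  if (any(net$roles != "hidden")) {
    mech <- which(net$roles == "hidden")
    cspace <- which(net$roles %in% c("sensor", "hidden"))
    espace <- which(net$roles %in% c("hidden", "motor"))
  } else {
    mech <- cspace <- espace <- seq_len(net$n)
  }
  cs <- conceptual_structure(net, state, nodes = seq_len(net$n),
                             mechanism_space = mech,
                             cause_space = cspace, effect_space = espace)
  list(n_concepts = cs$n_concepts, sum_phi = cs$sum_phi, concepts = cs)
}

#' State-weighted causal summary of a brain on a task
#'
#' Runs the full trial battery, then computes the whole-brain concept
#' measures and the main-complex measures for every experienced brain state
#' and averages them weighted by each state's probability of occurrence.
#'
#' @param net An animat `logic_network`.
#' @param task A [task_spec()].
#' @param record Optional precomputed [evaluate_brain()] result.
#' @return List with `n_concepts`, `sum_phi`, `n_mc_elements`,
#'   `n_mc_concepts`, `big_phi` (each state-weighted), `fitness`, and
#'   `per_state` (data frame of per-state values and weights).
#' @export
state_weighted_summary <- function(net, task, record = NULL) {
  if (is.null(record)) record <- evaluate_brain(net, task)
  states <- as.integer(names(record$state_distribution))
  w <- as.numeric(record$state_distribution)
  # the causal measures depend only on the hidden elements' states (sensor
  # and motor values enter neither the mechanisms nor the repertoires), so
  # memoize per hidden-state
  memo <- new.env(parent = emptyenv())
  vals <- vapply(states, function(s) {
    key <- as.character(bitwAnd(bitwShiftR(s, 2L), 15L))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    wb <- whole_brain_concepts(net, s)
    mc <- find_main_complex(net, s)
    v <- c(wb$n_concepts, wb$sum_phi, mc$n_mc_elements, mc$n_mc_concepts,
           mc$big_phi)
    memo[[key]] <- v
    v
  }, numeric(5))
  avg <- as.numeric(vals %*% w)
  list(n_concepts = avg[1], sum_phi = avg[2], n_mc_elements = avg[3],
       n_mc_concepts = avg[4], big_phi = avg[5], fitness = record$F,
       per_state = data.frame(state = states, weight = w,
                              n_concepts = vals[1, ], sum_phi = vals[2, ],
                              n_mc_elements = vals[3, ],
                              n_mc_concepts = vals[4, ],
                              big_phi = vals[5, ]))
}
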