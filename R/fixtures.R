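#' Example networks and random synthetic brains
#'
#' Worked-example systems with known printed causal-analysis values, plus a
#' generator of random animat brains with controlled wiring classes, so that
#' every downstream analysis stage is testable without running evolution.
#'
#' @name fixtures
NULL

#' Three-node example system
#'
#' The didactic three-element network analyzed in state ABC = 101: C is an
#' XOR gate receiving from A and B and outputting to both, and A and B close
#' the loop. In this state the system specifies a conceptual structure with
#' 4 concepts (A, B, C and the second-order mechanism AB with
#' phi^max = 0.33) and is maximally integrated with Phi^max = 0.92.
#'
#' @return An `example_network`: list with `network` (a `logic_network`),
#'   `state`, and `expected` (named list of reference values, rounded to
#'   2 decimals as printed).
#' @export
three_node_example <- function() {
  fs <- example_gate_functions()
  net <- net_from_functions(fs$three_node_funs, labels = c("A", "B", "C"))
  list(network = net,
       state = parse_state("101"),
       expected = list(
         phi_effect_AB_over_ABC = 0.25,
         phi_cause_AB_max = 0.33,
         phi_effect_AB_max = 0.5,
         phi_max_AB = 0.33,
         n_concepts = 4,
         concept_mechanisms = list(1L, 2L, 3L, c(1L, 2L)),
         big_phi = 0.92))
}

#' Two disconnected two-element loops
#'
#' A four-element system made of two independent feedback pairs; analyzed
#' jointly it is reducible (Phi = 0), illustrating that disconnected parts
#' cannot form one integrated system.
#'
#' @return An `example_network` list.
#' @export
disconnected_pairs_system <- function() {
  # W <-> X copy loop, Y <-> Z copy loop
  fs <- list(function(b) b[2], function(b) b[1],
             function(b) b[4], function(b) b[3])
  net <- net_from_functions(fs, labels = c("W", "X", "Y", "Z"))
  list(network = net, state = parse_state("1010"),
       expected = list(big_phi = 0))
}

#' Eight-element example animat
#'
#' A hypothetical animat brain (2 sensors, 4 hidden elements A-D, 2 motors)
#' analyzed in state 00-1010-10. The whole brain specifies 6 concepts
#' ([A], [B], [C], [D], [AB], [AC]) with a summed phi^max of 1.08, and its
#' main complex is ABC with Phi^max = 0.92 and 4 concepts.
#'
#' @return An `example_network` list.
#' @export
animat_example <- function() {
  gates <- example_animat_gates()
  net <- build_brain(gates)
  list(network = net,
       state = parse_state("00-1010-10"),
       expected = list(
         n_concepts = 6,
         sum_phi = 1.078125,
         concept_mechanisms = list(3L, 4L, 5L, 6L, c(3L, 4L), c(3L, 5L)),
         mc_elements = c(3L, 4L, 5L),
         big_phi = 0.92,
         n_mc_concepts = 4))
}

# build a generic deterministic logic_network from per-node update functions
net_from_functions <- function(fs, labels = NULL) {
  n <- length(fs)
  tpm <- matrix(0, 2^n, n)
  for (s in 0:(2^n - 1)) {
    bits <- int_to_bits(s, n)
    for (j in seq_len(n)) tpm[s + 1, j] <- fs[[j]](bits)
  }
  cm <- matrix(0L, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    for (s in 0:(2^n - 1)) {
      if (tpm[s + 1, j] !=
          tpm[bitwXor(s, bitwShiftL(1L, i - 1L)) + 1, j]) {
        cm[i, j] <- 1L
        break
      }
    }
  }
  logic_network(tpm, cm, labels = labels)
}

#' Random animat brain with controlled wiring
#'
#' Generates structurally valid brains for property tests. `"recurrent"`
#' draws unconstrained random gates; `"feedforward"` guarantees an acyclic
#' graph among hidden elements (no self-loops), which provably yields
#' Phi = 0; `"selfloop"` gives every hidden element only a self-connection
#' (memory without integration). Uses R's random stream; seed with
#' [set.seed()].
#'
#' @param wiring Wiring class.
#' @param n_gates Number of gates to draw.
#' @return A `logic_network` with animat roles.
#' @export
random_brain <- function(wiring = c("recurrent", "feedforward", "selfloop"),
                         n_gates = 6L) {
  wiring <- match.arg(wiring)
  gates <- vector("list", n_gates)
  for (i in seq_len(n_gates)) {
    if (wiring == "recurrent") {
      n_in <- sample(1:3, 1); n_out <- sample(1:2, 1)
      inputs <- sample(1:6, n_in, replace = TRUE)
      outputs <- sample(3:8, n_out, replace = TRUE)
    } else if (wiring == "feedforward") {
      # hidden inputs must be strictly lower-ranked than any hidden output
      out_h <- sample(4:6, 1)
      outputs <- c(out_h, if (stats::runif(1) < 0.3) sample(7:8, 1))
      legal_in <- c(1:2, 3:(out_h - 1))
      inputs <- sample(legal_in, sample(1:3, 1), replace = TRUE)
    } else {
      h <- sample(3:6, 1)
      inputs <- h; outputs <- h
    }
    inputs <- sort(unique(inputs)); outputs <- sort(unique(outputs))
    table <- sample(0:(2^length(outputs) - 1), 2^length(inputs),
                    replace = TRUE)
    gates[[i]] <- gate_spec(inputs, outputs, table)
  }
  if (wiring == "selfloop") {
    # self-copy logic so the loops genuinely carry memory
    gates <- lapply(gates, function(g)
      gate_spec(g$inputs, g$outputs, c(0L, 1L)))
  }
  build_brain(gates)
}

# gate functions for the example systems (transcribed so that the printed
# phi/Phi values of the analyses are reproduced; see the methods vignette)
example_gate_functions <- function() {
  list(three_node_funs = three_node_gate_functions())
}

# A = B AND NOT C; B = A AND NOT C; C = XOR(A, B)
three_node_gate_functions <- function() {
  list(function(b) as.integer(b[2] == 1 && b[3] == 0),
       function(b) as.integer(b[1] == 1 && b[3] == 0),
       function(b) as.integer(xor(b[1] == 1, b[2] == 1)))
}

# the same three-element core embedded as hidden elements A, B, C of an
# animat brain (elements 3, 4, 5)
example_core_gates <- function() {
  list(gate_spec(c(4, 5), 3, c(0L, 1L, 0L, 0L)),
       gate_spec(c(3, 5), 4, c(0L, 1L, 0L, 0L)),
       gate_spec(c(3, 4), 5, c(0L, 1L, 1L, 0L)))
}

# Full gate list of the example animat: the three-element core; a weakly
# selective memory element D written by two dense gates over sensors, core
# and its own state (their OR gives D an effective six-input update whose
# concept has phi^max = 1/64); a motor gate over sensors + A + C that gives
# the second-order mechanism AC an irreducible effect of phi = 1/16; and a
# sensor-to-motor reflex on the second motor (sensor-only inputs, so it
# cannot enter any hidden mechanism's analysis).
example_animat_gates <- function() {
  c(example_core_gates(), list(
    gate_spec(c(1, 2, 4), 6,
              as.integer(c(1, 1, 1, 1, 1, 1, 1, 0))),
    gate_spec(c(2, 3, 5, 6), 6,
              as.integer(c(1, 0, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1, 0, 0, 0, 0))),
    gate_spec(c(1, 2, 3, 5), 7,
              as.integer(c(0, 1, 0, 0, 0, 0, 0, 1, 1, 1, 1, 0, 1, 1, 0, 0))),
    gate_spec(c(1, 2), 8, c(0L, 1L, 1L, 1L))))
}
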