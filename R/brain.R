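#' Logic-gate networks
#'
#' A `logic_network` holds a binary network: a state-by-node transition
#' probability matrix `tpm` (rows are the \code{2^n} current states in
#' little-endian order, element 1 is bit 0; entries are the probability that
#' an element is ON next step -- 0/1 for the deterministic networks evolved
#' here), an \code{n x n} connectivity matrix `cm` (\code{cm[i, j] = 1} iff
#' element i is an input of element j), labels, and element roles. Animat
#' brains are `logic_network`s with the fixed architecture 2 sensors
#' (elements 1--2), 4 hidden (3--6), 2 motors (7--8).
#'
#' @param tpm Numeric \code{2^n x n} matrix of on-probabilities, or an
#'   integer vector of \code{2^n} deterministic next-state codes.
#' @param cm Binary \code{n x n} connectivity matrix.
#' @param labels Optional character labels.
#' @param roles Optional character vector of roles ("sensor", "hidden",
#'   "motor"); defaults to all "hidden" (a generic network).
#' @return A `logic_network` object.
#' @export
logic_network <- function(tpm, cm, labels = NULL, roles = NULL) {
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (ncol(cm) != n) stop("cm must be square")
  if (is.null(dim(tpm))) {
    next_state <- as.integer(tpm)
    if (length(next_state) != 2^n) stop("tpm length must be 2^n")
    probs <- t(vapply(next_state, function(s) as.numeric(int_to_bits(s, n)),
                      numeric(n)))
  } else {
    probs <- as.matrix(tpm)
    if (nrow(probs) != 2^n || ncol(probs) != n)
      stop("tpm must be 2^n x n")
    if (all(probs %in% c(0, 1))) {
      next_state <- as.integer(probs %*% 2^(0:(n - 1)))
    } else next_state <- NULL
  }
  if (is.null(labels)) labels <- default_labels(n, roles)
  if (is.null(roles)) roles <- rep("hidden", n)
  structure(list(n = n, tpm = probs, next_state = next_state, cm = cm,
                 labels = labels, roles = roles),
            class = "logic_network")
}

default_labels <- function(n, roles = NULL) {
  if (!is.null(roles) && identical(roles, c("sensor", "sensor", "hidden",
                                            "hidden", "hidden", "hidden",
                                            "motor", "motor")))
    return(c("S1", "S2", "A", "B", "C", "D", "M1", "M2"))
  LETTERS[seq_len(n)]
}

animat_roles <- function() {
  c("sensor", "sensor", "hidden", "hidden", "hidden", "hidden",
    "motor", "motor")
}

#' @export
print.logic_network <- function(x, ...) {
  cat("logic_network:", x$n, "elements (",
      paste(x$labels, collapse = " "), ")\n")
  cat("  roles:", paste(x$roles, collapse = " "), "\n")
  cat("  deterministic:", !is.null(x$next_state), "\n")
  cat("  connections:", sum(x$cm), "\n")
  invisible(x)
}

int_to_bits <- function(s, n) {
  bitwAnd(bitwShiftR(as.integer(s), 0:(n - 1)), 1L)
}

bits_to_int <- function(bits) {
  as.integer(sum(bits * 2^(seq_along(bits) - 1)))
}

#' Parse a state string
#'
#' Converts a state written element-by-element (e.g. \code{"00-1010-10"} for
#' sensors-hidden-motors, separators optional) into the integer state code.
#'
#' @param s Character state string; first character is element 1.
#' @return Integer state code (little-endian).
#' @export
parse_state <- function(s) {
  digs <- as.integer(strsplit(gsub("[^01]", "", s), "")[[1]])
  bits_to_int(digs)
}

#' Build an animat brain from gates
#'
#' Combines hidden Markov gates into the deterministic 256-state TPM and
#' 8x8 connectivity matrix of an animat brain. When several gates write the
#' same element, their outputs are OR-combined; elements written by no gate
#' go to 0. Sensors are never written (their next state is always 0; fresh
#' input arrives from the environment), and motors are never read.
#'
#' @param gates List of [gate_spec()] objects (or the result of
#'   [decode_genome()]).
#' @return A `logic_network` with animat roles.
#' @export
build_brain <- function(gates = list()) {
  gates <- lapply(gates, function(g) {
    if (!inherits(g, "gate_spec")) g <- gate_spec(g$inputs, g$outputs, g$table)
    g
  })
  raw <- lapply(gates, function(g) list(inputs = g$inputs - 1L,
                                        outputs = g$outputs - 1L,
                                        table = g$table))
  built <- cpp_build_brain(raw)
  net <- logic_network(built$next_state, built$cm, roles = animat_roles())
  net$gates <- gates
  net
}

#' Advance a brain one time step
#'
#' Applies the TPM to the current state and then writes the new sensor
#' values into the returned state (the TPM itself zeroes sensors, since no
#' gate may write them).
#'
#' @param brain A deterministic `logic_network` with animat roles.
#' @param state Integer state code (0--255).
#' @param sensors Length-2 vector of sensor bits.
#' @return Integer next state.
#' @export
brain_step <- function(brain, state, sensors = c(0L, 0L)) {
  stopifnot(inherits(brain, "logic_network"), !is.null(brain$next_state))
  s <- brain$next_state[state + 1L]
  s <- bitwOr(bitwAnd(s, bitwNot(3L)), sensors[1] + 2L * sensors[2])
  s
}

#' Canonical normal form of a brain's causal structure
#'
#' Reduces a network to its causally active part and canonicalizes element
#' labels so that networks differing only by a relabeling of elements within
#' a role class compare equal. Hidden elements with only inputs or only
#' outputs (or neither) are excluded iteratively; excluded elements are
#' clamped to 0 as inputs. All permutations of the remaining elements within
#' each role class are enumerated, and the lexicographically first permuted
#' (tpm, cm) pair is the normal form.
#'
#' @param brain A deterministic `logic_network`.
#' @return A `normal_form` object with fields `tpm` (bit matrix), `cm`,
#'   `active` (logical mask over original elements), and `class_sizes`.
#' @export
normal_form <- function(brain) {
  stopifnot(inherits(brain, "logic_network"), !is.null(brain$next_state))
  n <- brain$n
  cm <- brain$cm
  roles <- brain$roles
  active <- rep(TRUE, n)
  repeat {
    changed <- FALSE
    for (i in which(active & roles == "hidden")) {
      ins <- which(active)[cm[active, i] > 0]
      outs <- which(active)[cm[i, active] > 0]
      # self-loops count as both an input and an output
      if (length(ins) == 0 || length(outs) == 0) {
        active[i] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- which(active)
  k <- length(keep)
  if (k == 0) {
    return(structure(list(tpm = matrix(0, 1, 0), cm = matrix(0, 0, 0),
                          cm_canonical = matrix(0, 0, 0),
                          active = active, class_sizes = c(0, 0, 0)),
                     class = "normal_form"))
  }
  # restricted TPM: inactive elements clamped to 0 as inputs
  m <- 2^k
  sub_tpm <- matrix(0, m, k)
  for (s in 0:(m - 1)) {
    bits <- int_to_bits(s, k)
    full <- integer(n)
    full[keep] <- bits
    nxt <- int_to_bits(brain$next_state[bits_to_int(full) + 1L], n)
    sub_tpm[s + 1, ] <- nxt[keep]
  }
  sub_cm <- brain$cm[keep, keep, drop = FALSE]
  sub_roles <- roles[keep]
  classes <- list(which(sub_roles == "sensor"), which(sub_roles == "hidden"),
                  which(sub_roles == "motor"))
  best <- NULL
  best_cm <- NULL
  for (perm in role_permutations(classes, k)) {
    # perm[i] = new position of old element i; inv[j] = old element at new j
    ptpm <- matrix(0L, m, k)
    inv <- order(perm)
    for (s in 0:(m - 1)) {
      bits <- int_to_bits(s, k)
      old_bits <- bits[perm]         # state s in new labels -> old state
      olds <- bits_to_int(old_bits)
      ptpm[s + 1, ] <- sub_tpm[olds + 1, inv]
    }
    pcm <- sub_cm[inv, inv, drop = FALSE]
    key <- c(as.integer(t(ptpm)), as.integer(t(pcm)))
    if (is.null(best) || vec_less(key, best$key))
      best <- list(key = key, tpm = ptpm, cm = pcm)
    # the wiring diagram is canonicalized on its own (the minimizing
    # permutation for the TPM need not minimize the cm)
    cm_key <- as.integer(t(pcm))
    if (is.null(best_cm) || vec_less(cm_key, best_cm$key))
      best_cm <- list(key = cm_key, cm = pcm)
  }
  structure(list(tpm = best$tpm, cm = best$cm,
                 cm_canonical = best_cm$cm, active = active,
                 class_sizes = lengths(classes)),
            class = "normal_form")
}

role_permutations <- function(classes, k) {
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  out <- list()
  for (p1 in perms_of(classes[[1]]))
    for (p2 in perms_of(classes[[2]]))
      for (p3 in perms_of(classes[[3]])) {
        perm <- integer(k)
        perm[c(classes[[1]], classes[[2]], classes[[3]])] <- c(p1, p2, p3)
        out[[length(out) + 1]] <- perm  # perm[i] = new position of old i
      }
  out
}

vec_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Hamming distance between canonical TPMs
#'
#' Counts the TPM entries (0s or 1s) in which two normal forms differ.
#' Label-permuted copies of the same network have distance 0.
#'
#' @param a,b `normal_form` objects over the same element-class sizes.
#' @return Non-negative integer count.
#' @export
tpm_hamming <- function(a, b) {
  stopifnot(inherits(a, "normal_form"), inherits(b, "normal_form"))
  if (!identical(dim(a$tpm), dim(b$tpm)))
    stop("normal forms have incompatible dimensions")
  sum(a$tpm != b$tpm)
}

#' Read and write networks as JSON
#'
#' Schema: \code{\{"n_sensors":2,"n_hidden":4,"n_motors":2,"tpm":[256
#' next-state integers],"cm":[[8x8 bits]]\}}. Generic networks use role
#' counts 0/n/0.
#'
#' @param net A deterministic `logic_network`.
#' @param path File path.
#' @return `read_network_json` returns a `logic_network`.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "logic_network"), !is.null(net$next_state))
  obj <- list(n_sensors = sum(net$roles == "sensor"),
              n_hidden = sum(net$roles == "hidden"),
              n_motors = sum(net$roles == "motor"),
              tpm = net$next_state,
              cm = unname(net$cm))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- obj$n_sensors + obj$n_hidden + obj$n_motors
  roles <- rep(c("sensor", "hidden", "motor"),
               c(obj$n_sensors, obj$n_hidden, obj$n_motors))
  logic_network(as.integer(obj$tpm), matrix(as.integer(as.matrix(obj$cm)), n, n),
                roles = roles)
}
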