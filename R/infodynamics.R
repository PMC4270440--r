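#' Observational Shannon measures along trajectories
#'
#' Plug-in (empirical) mutual information and entropies over consecutive
#' brain states pooled across trials. The sensory-motor mutual information
#' I_SMMI is computed between the sensor state at t and the motor state at
#' t+1; the predictive information I_Pred between the full 8-bit brain
#' states at t and t+1. Transitions never span trial boundaries.
#'
#' @param trajectories Integer matrix (trials x steps) of brain state codes,
#'   e.g. the `trajectories` element of [evaluate_brain()], or a list of
#'   integer vectors.
#' @return List with `I_smmi`, `I_pred`, `H_sen`, `H_mot`, `H_state` (bits).
#'   H_sen is the entropy of the sensor marginal at t, H_mot of the motor
#'   marginal at t+1, H_state of the full state at t+1, so that
#'   \code{I_smmi <= min(H_sen, H_mot)} and \code{I_pred <= H_state}.
#' @export
shannon_summary <- function(trajectories) {
  if (is.list(trajectories))
    trajectories <- do.call(rbind, lapply(trajectories, as.integer))
  if (is.null(dim(trajectories)) || ncol(trajectories) < 2 ||
      nrow(trajectories) == 0)
    stop("trajectories must contain at least one trial with two steps")
  t0 <- as.integer(trajectories[, -ncol(trajectories)])
  t1 <- as.integer(trajectories[, -1])
  sen0 <- bitwAnd(t0, 3L)
  mot1 <- bitwAnd(bitwShiftR(t1, 6L), 3L)
  list(I_smmi = plugin_mi(sen0, mot1),
       I_pred = plugin_mi(t0, t1),
       H_sen = plugin_entropy(sen0),
       H_mot = plugin_entropy(mot1),
       H_state = plugin_entropy(t1))
}

plugin_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

plugin_mi <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}
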