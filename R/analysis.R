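#' Line-of-descent measure tables and condition comparisons
#'
#' These functions orchestrate the full pipeline: trace a line of descent,
#' rebuild the brain at every sampled generation, evaluate it on its task,
#' and attach the causal (IIT) and Shannon measures; then compare measures
#' across task conditions with the nonparametric tests used throughout
#' (Spearman rank correlations along LODs; Kruskal-Wallis omnibus and
#' pairwise Mann-Whitney U tests on windowed end-of-run averages).
#'
#' @name analysis
NULL

#' Compute measures along a line of descent
#'
#' @param archive An `evolution_archive` from [run_evolution()].
#' @param task A [task_spec()]; defaults to the archive's task.
#' @param pick Final-generation animat whose LOD is traced.
#' @return A `measures_table` data frame: one row per sampled generation
#'   with columns `generation`, `F`, `n_concepts`, `sum_phi`,
#'   `n_mc_elements`, `n_mc_concepts`, `big_phi`, `I_smmi`, `I_pred`,
#'   `H_sen`, `H_mot`, `H_state`.
#' @export
compute_lod_measures <- function(archive, task = archive$task, pick = 1L) {
  lod <- trace_lod(archive, pick)
  rows <- lapply(lod, function(rec) {
    brain <- build_brain(decode_genome(rec$genome))
    fr <- evaluate_brain(brain, task)
    sw <- state_weighted_summary(brain, task, record = fr)
    sh <- shannon_summary(fr$trajectories)
    data.frame(generation = rec$generation, F = fr$F,
               n_concepts = sw$n_concepts, sum_phi = sw$sum_phi,
               n_mc_elements = sw$n_mc_elements,
               n_mc_concepts = sw$n_mc_concepts, big_phi = sw$big_phi,
               I_smmi = sh$I_smmi, I_pred = sh$I_pred, H_sen = sh$H_sen,
               H_mot = sh$H_mot, H_state = sh$H_state)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("measures_table", "data.frame")
  out
}

measure_columns <- function() {
  c("n_concepts", "sum_phi", "n_mc_elements", "n_mc_concepts", "big_phi",
    "I_smmi", "I_pred", "H_sen", "H_mot", "H_state")
}

#' Spearman rank correlation of each measure with fitness along a LOD
#'
#' Constant series have an undefined rank correlation; they are reported as
#' `NA` and excluded from any cross-LOD averaging.
#'
#' @param table A `measures_table` from [compute_lod_measures()].
#' @param measures Columns to correlate against `F`.
#' @return Named numeric vector of Spearman R values.
#' @export
lod_correlations <- function(table, measures = measure_columns()) {
  if (nrow(table) < 3) stop("need at least 3 sampled generations")
  vapply(measures, function(m) {
    x <- table[[m]]
    if (stats::sd(x) == 0 || stats::sd(table$F) == 0) return(NA_real_)
    suppressWarnings(stats::cor(x, table$F, method = "spearman"))
  }, numeric(1))
}

#' Windowed end-of-run average of one LOD measure
#'
#' @param table A `measures_table`.
#' @param measure Column name.
#' @param window Averaging window in generations (counted back from the
#'   last sampled generation, inclusive); 3000 generations at 512-generation
#'   sampling gives 6 data points.
#' @return Scalar mean.
#' @export
windowed_mean <- function(table, measure, window = 3000) {
  gmax <- max(table$generation)
  if (window > gmax + 1) stop("window longer than table")
  rows <- table$generation > gmax - window
  mean(table[[measure]][rows])
}

#' Compare task conditions on end-of-run averages
#'
#' Each LOD is reduced to its mean over the final `window` generations;
#' conditions are then compared by a Kruskal-Wallis omnibus test followed by
#' pairwise Mann-Whitney U tests (normal approximation for Z). No
#' multiple-testing correction is applied.
#'
#' @param tables Named list of conditions; each condition is a list of
#'   `measures_table`s (one per LOD).
#' @param window Averaging window in generations.
#' @param measures Measure columns to compare.
#' @return A `comparison_report`: per-measure list with `values` (per-LOD
#'   windowed means by condition), `kruskal` (statistic, df, p) and
#'   `pairwise` (data frame of U, Z, p per condition pair).
#' @export
compare_conditions <- function(tables, window = 3000,
                               measures = c("F", measure_columns())) {
  if (length(tables) < 2) stop("need at least 2 conditions")
  out <- lapply(measures, function(m) {
    vals <- lapply(tables, function(cond)
      vapply(cond, windowed_mean, numeric(1), measure = m, window = window))
    groups <- factor(rep(names(tables), lengths(vals)))
    x <- unlist(vals, use.names = FALSE)
    kw <- stats::kruskal.test(x, groups)
    prs <- utils::combn(names(tables), 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(prs, function(pr) {
      a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
      mw <- mann_whitney(a, b)
      data.frame(a = pr[1], b = pr[2], U = mw$U, Z = mw$Z, p = mw$p)
    }))
    list(values = vals,
         kruskal = list(statistic = unname(kw$statistic),
                        df = unname(kw$parameter), p = kw$p.value),
         pairwise = pw)
  })
  names(out) <- measures
  structure(out, class = "comparison_report")
}

# Mann-Whitney U with normal approximation and tie correction
mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U <- min(U1, n1 * n2 - U1)
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
  z <- if (sigma > 0) (U - mu) / sigma else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(U = U, Z = z, p = p)
}

#' Select a fitness-matched subset of LODs
#'
#' Returns the k fittest LODs (by mean fitness over the final `window`
#' generations) whose average best matches the reference collection's mean,
#' scanning prefixes of the fitness-ranked LODs from the fittest down and
#' choosing the prefix size minimizing the absolute difference in means.
#'
#' @param lods List of `measures_table`s for the condition to subset.
#' @param reference_lods List of `measures_table`s of the reference
#'   condition (e.g. Task 1).
#' @param window Fitness-averaging window in generations.
#' @return Integer indices (into `lods`) of the selected subset.
#' @export
fitness_matched_subset <- function(lods, reference_lods, window = 5000) {
  stopifnot(length(lods) > 0, length(reference_lods) > 0)
  f <- vapply(lods, windowed_mean, numeric(1), measure = "F", window = window)
  ref <- mean(vapply(reference_lods, windowed_mean, numeric(1),
                     measure = "F", window = window))
  ord <- order(f, decreasing = TRUE)
  prefix_means <- cumsum(f[ord]) / seq_along(ord)
  err <- abs(prefix_means - ref)
  # ties favour the larger subset (more LODs at the same match quality)
  k <- max(which(err <= min(err) + 1e-12))
  sort(ord[seq_len(k)])
}

#' Count distinct causal structures and behaviors
#'
#' TPMs and wiring diagrams are compared in normal form (label-invariant,
#' causally inactive hidden elements removed); behavior is fingerprinted as
#' the animat's column at every time step of every noise-free trial.
#'
#' @param brains List of animat `logic_network`s.
#' @param task A [task_spec()] used for the behavioral fingerprint.
#' @return List with `n_tpms`, `n_wirings`, `n_behaviors`.
#' @export
count_distinct_structures <- function(brains, task = task_spec(1)) {
  stopifnot(length(brains) > 0)
  nfs <- lapply(brains, normal_form)
  tpm_keys <- vapply(nfs, function(nf)
    paste(c(dim(nf$tpm), as.integer(t(nf$tpm))), collapse = ","), character(1))
  cm_keys <- vapply(nfs, function(nf)
    paste(c(dim(nf$cm_canonical), as.integer(t(nf$cm_canonical))),
          collapse = ","), character(1))
  beh_keys <- vapply(brains, function(b) {
    fr <- evaluate_brain(b, task)
    paste(as.integer(t(fr$positions)), collapse = ",")
  }, character(1))
  list(n_tpms = length(unique(tpm_keys)),
       n_wirings = length(unique(cm_keys)),
       n_behaviors = length(unique(beh_keys)))
}
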