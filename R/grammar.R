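# Third pass: iterative Bayesian smoothing of the per-epoch posterior
# sequence. Left and right context distributions (exponentially decayed
# neighbor sums blended with a file-level prior) are pushed through the
# bigram class-transition table, and the resulting factor re-weights each
# epoch's posterior with an iteration-annealed grammar exponent.

#' Packaged bigram class-transition grammar
#'
#' The 6x6 table of transition probabilities between consecutive epoch
#' labels, as used in the third pass. Rows are the originating class,
#' columns the destination, in canonical order. The values encode clinical
#' context (e.g. P(PLED -> PLED) = 0.90 because periodic lateralized
#' discharges are long-lived, and P(PLED -> SPSW) = 0 because grouped
#' spikes are read as periodic discharges, not isolated spikes). Two rows
#' (ARTF, BCKG) sum to 1.02 due to rounding; they are stored verbatim by
#' default.
#'
#' @param renormalize if TRUE, rows are rescaled to sum to exactly 1.
#' @return 6x6 numeric matrix with class-label dimnames.
#' @export
bigram_grammar <- function(renormalize = FALSE) {
  g <- matrix(c(
    # SPSW  PLED  GPED  EYEM  ARTF  BCKG
    0.40, 0.00, 0.00, 0.10, 0.20, 0.30,  # SPSW
    0.00, 0.90, 0.00, 0.00, 0.05, 0.05,  # PLED
    0.00, 0.00, 0.60, 0.00, 0.20, 0.20,  # GPED
    0.10, 0.00, 0.00, 0.40, 0.10, 0.40,  # EYEM
    0.23, 0.05, 0.05, 0.23, 0.23, 0.23,  # ARTF
    0.33, 0.05, 0.05, 0.23, 0.13, 0.23   # BCKG
  ), nrow = 6L, byrow = TRUE,
  dimnames = list(class_labels(), class_labels()))
  if (renormalize) g <- g / rowSums(g)
  g
}

#' Read a bigram grammar from CSV
#'
#' Expects a 6x6 table with class-name header row and first column.
#'
#' @param path CSV file path.
#' @param renormalize rescale rows to sum to 1?
#' @return 6x6 numeric matrix.
#' @export
read_grammar <- function(path, renormalize = FALSE) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  g <- as.matrix(df)
  if (!identical(rownames(g), class_labels()) ||
      !identical(colnames(g), class_labels())) {
    stop("grammar file rows/columns must be the six class labels in canonical order")
  }
  if (any(g < 0 | g > 1)) stop("grammar entries must lie in [0, 1]")
  if (renormalize) g <- g / rowSums(g)
  g
}

#' Write a bigram grammar to CSV
#' @param grammar 6x6 matrix with class dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grammar <- function(grammar, path) {
  utils::write.csv(as.data.frame(grammar), path, quote = FALSE)
  invisible(path)
}

#' Estimate a bigram grammar from label sequences (utility)
#'
#' Simple add-one-smoothed transition counts over consecutive epoch labels.
#' Provided as a convenience; the packaged [bigram_grammar()] is the
#' default operating table.
#'
#' @param label_sequences list of character vectors of epoch labels.
#' @param smoothing additive smoothing count (default 1).
#' @return 6x6 row-stochastic matrix.
#' @export
estimate_bigram_grammar <- function(label_sequences, smoothing = 1) {
  counts <- matrix(smoothing, 6L, 6L,
                   dimnames = list(class_labels(), class_labels()))
  for (seq in label_sequences) {
    idx <- label_index(seq)
    if (length(idx) < 2L) next
    for (t in seq_len(length(idx) - 1L)) {
      counts[idx[t], idx[t + 1L]] <- counts[idx[t], idx[t + 1L]] + 1
    }
  }
  counts / rowSums(counts)
}

#' Grammar-pass configuration
#'
#' Defaults are the standard operating point of the third pass.
#'
#' @param epsilon_prior scalar prior mass added per class in the file prior.
#' @param M weight of the prior term in the file prior.
#' @param lambda exponential decay of the context window weights.
#' @param alpha blend weight of the file prior inside the context terms.
#' @param gamma grammar weight (exponent numerator).
#' @param n_max maximum smoothing iterations.
#' @param N context window length in epochs (per side).
#' @param anneal if TRUE (default) the grammar exponent is `gamma / n` at
#'   iteration n (annealed influence); if FALSE, `gamma * n`.
#' @return list of class `grammar_config`.
#' @export
grammar_config <- function(epsilon_prior = 0.1, M = 1, lambda = 0.2,
                           alpha = 0.1, gamma = 1, n_max = 20L, N = 10L,
                           anneal = TRUE) {
  stopifnot(N >= 1L, n_max >= 1L, epsilon_prior >= 0, M >= 0, lambda >= 0,
            alpha >= 0, gamma >= 0)
  structure(list(epsilon_prior = epsilon_prior, M = M, lambda = lambda,
                 alpha = alpha, gamma = gamma, n_max = as.integer(n_max),
                 N = as.integer(N), anneal = anneal),
            class = "grammar_config")
}

#' File-level prior distribution over classes
#'
#' `P_gprior = (sum_i P_i + epsilon_prior * M) / (L + M)` component-wise over
#' the L epoch posteriors, renormalized to sum to 1.
#'
#' @param posteriors matrix `L x 6` of per-epoch posteriors.
#' @param config a [grammar_config()].
#' @return length-6 probability vector.
#' @export
file_prior <- function(posteriors, config = grammar_config()) {
  posteriors <- rbind(posteriors)
  L <- nrow(posteriors)
  p <- (colSums(posteriors) + config$epsilon_prior * config$M) / (L + config$M)
  p / sum(p)
}

#' Left or right context distribution for one epoch
#'
#' An exponentially decayed sum of the N neighboring epoch posteriors on
#' one side (neighbors beyond the record boundary are skipped), blended
#' with the file prior by weight `alpha`, and normalized to a distribution.
#'
#' @param posteriors matrix `L x 6`.
#' @param k epoch index (1-based).
#' @param side `"left"` or `"right"`.
#' @param g_prior file prior from [file_prior()].
#' @param config a [grammar_config()].
#' @return length-6 probability vector.
#' @export
context_probability <- function(posteriors, k, side = c("left", "right"),
                                g_prior, config = grammar_config()) {
  side <- match.arg(side)
  posteriors <- rbind(posteriors)
  L <- nrow(posteriors)
  acc <- numeric(ncol(posteriors))
  for (i in seq_len(config$N)) {
    j <- if (side == "left") k - i else k + i
    if (j < 1L || j > L) next
    acc <- acc + exp(-i * config$lambda) * posteriors[j, ]
  }
  v <- (acc + config$alpha * g_prior) / (1 + config$alpha)
  v / sum(v)
}

#' One grammar update of a single epoch's posterior
#'
#' For each class c the grammar factor is
#' `[sum_i LPP(i) Prob(i,c)] * [sum_j RPP(j) Prob(c,j)]`; the posterior is
#' multiplied by this factor raised to the iteration-annealed grammar
#' exponent (`gamma / n` by default) and renormalized.
#'
#' @param p_k current length-6 posterior of the epoch.
#' @param lpp,rpp left/right context distributions.
#' @param grammar 6x6 transition table.
#' @param config a [grammar_config()].
#' @param iteration iteration number n (1-based).
#' @return updated length-6 posterior.
#' @export
smooth_epoch <- function(p_k, lpp, rpp, grammar, config = grammar_config(),
                         iteration = 1L) {
  factor <- as.vector(lpp %*% grammar) * as.vector(grammar %*% rpp)
  if (all(factor == 0)) {
    warning("degenerate grammar: all-zero context factor; epoch left unchanged")
    return(p_k / sum(p_k))
  }
  expo <- if (config$anneal) config$gamma / iteration else
    config$gamma * iteration
  upd <- p_k * factor^expo
  upd / sum(upd)
}

#' Run the iterative grammar smoothing pass
#'
#' Iterates [smooth_epoch()] over all epochs, recomputing the file prior
#' and contexts each iteration, until the argmax label assignment is stable
#' between successive iterations or `n_max` is reached.
#'
#' @param posteriors matrix `L x 6` of per-epoch posteriors (pass-2 output).
#' @param grammar 6x6 transition table (default the packaged grammar).
#' @param config a [grammar_config()].
#' @return list of class `smoothed_sequence` with `posteriors` (L x 6),
#'   `labels` (character), and `iterations_used`.
#' @export
run_grammar_pass <- function(posteriors, grammar = bigram_grammar(),
                             config = grammar_config()) {
  p <- rbind(posteriors)
  if (nrow(p) < 1L) stop("need at least one epoch")
  p <- p / rowSums(p)
  labels_of <- function(m) class_labels()[apply(m, 1L, which.max)]
  prev_labels <- labels_of(p)
  iterations <- 0L
  for (n in seq_len(config$n_max)) {
    iterations <- n
    gp <- file_prior(p, config)
    new_p <- p
    for (k in seq_len(nrow(p))) {
      lpp <- context_probability(p, k, "left", gp, config)
      rpp <- context_probability(p, k, "right", gp, config)
      new_p[k, ] <- smooth_epoch(p[k, ], lpp, rpp, grammar, config, n)
    }
    p <- new_p
    labs <- labels_of(p)
    if (identical(labs, prev_labels)) break
    prev_labels <- labs
  }
  structure(list(posteriors = p, labels = prev_labels,
                 iterations_used = iterations),
            class = "smoothed_sequence")
}
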