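# Scoring: confusion matrices under 6/4/2-way label collapses, with
# event-based (per channel-epoch) or epoch-based units, the sensitivity /
# false-alarm conventions used for EEG event detection, and DET curves.

#' Collapse a six-way label to the 4-way or 2-way scheme
#'
#' Four-way: the three non-pathological classes {EYEM, ARTF, BCKG} merge
#' into BCKG. Two-way: additionally the three epileptiform classes
#' {SPSW, GPED, PLED} merge into TARG.
#'
#' @param label character vector of six-way labels.
#' @param scheme `"six"`, `"four"` or `"two"`.
#' @return collapsed character vector.
#' @export
collapse_labels <- function(label, scheme = c("six", "four", "two")) {
  scheme <- match.arg(scheme)
  validate_labels(label)
  if (scheme == "six") return(label)
  out <- ifelse(label %in% c("EYEM", "ARTF", "BCKG"), "BCKG", label)
  if (scheme == "two") out <- ifelse(out == "BCKG", "BCKG", "TARG")
  out
}

collapsed_levels <- function(scheme) {
  switch(scheme,
         six = class_labels(),
         four = c("SPSW", "PLED", "GPED", "BCKG"),
         two = c("TARG", "BCKG"))
}

#' Score a hypothesis label grid against a reference
#'
#' Event-based scoring counts every (epoch, channel) cell as one unit
#' (forced-choice, matching per-channel decoding); epoch-based scoring
#' first collapses each grid row to a single epoch label by the
#' clinical-priority vote and counts epochs. Sensitivity is the percentage
#' of TARG reference units hypothesized TARG. Two false-alarm style
#' quantities are reported for the 2-way collapse: `false_alarm_rate`
#' (percentage of BCKG reference units hypothesized TARG — the quantity
#' often reported as "specificity" in this application area) and
#' `specificity_conventional` (100 - false_alarm_rate).
#'
#' @param reference,hypothesis character matrices (`n_epochs x n_channels`)
#'   for event-based mode, or character vectors of epoch labels for
#'   epoch-based mode.
#' @param mode `"event"` or `"epoch"`.
#' @param collapse `"six"`, `"four"` or `"two"`.
#' @return list of class `eeg_score` with `counts`, `percent` (row
#'   percentages), `mode`, `collapse` and, for the 2-way collapse,
#'   `sensitivity`, `false_alarm_rate`, `specificity_conventional`.
#' @export
score_run <- function(reference, hypothesis, mode = c("event", "epoch"),
                      collapse = c("six", "four", "two")) {
  mode <- match.arg(mode)
  collapse <- match.arg(collapse)
  if (!identical(dim(reference), dim(hypothesis)) ||
      length(reference) != length(hypothesis)) {
    stop("reference and hypothesis shapes differ")
  }
  if (mode == "epoch" && is.matrix(reference)) {
    reference <- epoch_priority_labels(reference)
    hypothesis <- epoch_priority_labels(hypothesis)
  }
  ref <- collapse_labels(as.vector(reference), collapse)
  hyp <- collapse_labels(as.vector(hypothesis), collapse)
  lev <- collapsed_levels(collapse)
  counts <- table(factor(ref, levels = lev), factor(hyp, levels = lev))
  counts <- matrix(as.integer(counts), nrow = length(lev),
                   dimnames = list(reference = lev, hypothesis = lev))
  rs <- rowSums(counts)
  percent <- 100 * counts / ifelse(rs == 0, 1, rs)
  out <- list(counts = counts, percent = percent, mode = mode,
              collapse = collapse)
  if (collapse == "two") {
    out$sensitivity <- percent["TARG", "TARG"]
    out$false_alarm_rate <- percent["BCKG", "TARG"]
    out$specificity_conventional <- 100 - out$false_alarm_rate
  }
  structure(out, class = "eeg_score")
}

#' @export
print.eeg_score <- function(x, ...) {
  cat(sprintf("<eeg_score> %s-based, %s-way (row %%)\n", x$mode, x$collapse))
  print(round(x$percent, 2))
  if (!is.null(x$sensitivity)) {
    cat(sprintf("sensitivity: %.2f%%  false-alarm rate: %.2f%%\n",
                x$sensitivity, x$false_alarm_rate))
  }
  invisible(x)
}

#' Detection error tradeoff (DET) curve
#'
#' Sweeps a penalty subtracted from the target-class score: a unit is
#' hypothesized TARG iff `score - penalty > 0.5`. For each penalty the
#' false-alarm rate (percent of reference-background units called TARG)
#' and miss rate (percent of reference-target units called BCKG) are
#' recorded. The zero-penalty point reproduces the forced-choice 2-way
#' operating point.
#'
#' @param scores numeric vector of target-class scores in `[0, 1]`.
#' @param reference logical (or 0/1) vector: TRUE for target reference units.
#' @param penalties numeric vector of penalties to sweep (0 must be covered
#'   to mark the operating point; added if absent).
#' @return list of class `det_curve` with `points` (data.frame: penalty,
#'   false_alarm, miss) and `zero_penalty_point` (row index).
#' @export
det_curve <- function(scores, reference,
                      penalties = seq(-0.5, 0.5, by = 0.02)) {
  reference <- as.logical(reference)
  if (all(reference) || !any(reference)) {
    stop("reference contains a single class; DET curve undefined")
  }
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (!any(abs(penalties) < 1e-12)) penalties <- sort(c(0, penalties))
  pts <- t(vapply(penalties, function(p) {
    hyp <- (scores - p) > 0.5
    fa <- 100 * mean(hyp[!reference])
    miss <- 100 * mean(!hyp[reference])
    c(false_alarm = fa, miss = miss)
  }, c(false_alarm = 0, miss = 0)))
  df <- data.frame(penalty = penalties, false_alarm = pts[, 1],
                   miss = pts[, 2])
  structure(list(points = df,
                 zero_penalty_point = which(abs(penalties) < 1e-12)[1]),
            class = "det_curve")
}
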