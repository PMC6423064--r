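#' Canonical six-class EEG event label set
#'
#' The six event classes used throughout the pipeline, in the fixed canonical
#' order that indexes posterior vectors and the bigram grammar rows/columns:
#' SPSW (spike and/or sharp wave), PLED (periodic lateralized epileptiform
#' discharges), GPED (generalized periodic epileptiform discharges), EYEM
#' (eye movement), ARTF (artifact) and BCKG (background).
#'
#' @return Character vector of the six labels in canonical order.
#' @export
#' @examples
#' class_labels()
class_labels <- function() {
  c("SPSW", "PLED", "GPED", "EYEM", "ARTF", "BCKG")
}

#' Number of event classes
#' @return Integer, always 6.
#' @export
n_classes <- function() length(class_labels())

#' Validate a vector of class labels
#'
#' @param labels character vector to check.
#' @return `labels`, invisibly, if all are valid.
#' @keywords internal
validate_labels <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), class_labels())
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(sprintf("\"%s\"", bad), collapse = ", "),
         "; expected one of ", paste(class_labels(), collapse = ", "))
  }
  invisible(labels)
}

#' Convert labels to canonical integer indices (1-based)
#' @param labels character vector of class labels.
#' @return integer vector of indices into `class_labels()`.
#' @keywords internal
label_index <- function(labels) {
  validate_labels(labels)
  match(as.character(labels), class_labels())
}
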