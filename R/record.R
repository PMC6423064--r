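#' Construct a multichannel EEG signal record
#'
#' A `eeg_record` holds sampled multichannel EEG: a samples matrix
#' (rows = time, columns = channels) in physical units (microvolts), the
#' sampling rate, ordered channel names (electrode names for raw records,
#' "A-B" derivation names for montaged records) and the recording-relative
#' start time in seconds.
#'
#' @param samples numeric matrix, `n_samples x n_channels`, in microvolts.
#' @param rate sampling rate in samples/second; must be > 0.
#' @param channel_names character vector, one name per column of `samples`.
#' @param start_time seconds offset from the start of the recording.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, rate, channel_names = colnames(samples),
                       start_time = 0) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (is.null(channel_names)) {
    channel_names <- paste0("CH", seq_len(ncol(samples)))
  }
  if (length(channel_names) != ncol(samples)) {
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", ncol(samples), ")")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, rate = rate,
         channel_names = as.character(channel_names),
         start_time = start_time),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channel(s), %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$rate,
              nrow(x$samples) / x$rate))
  cat("  channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Record duration in seconds
#' @param record an `eeg_record`.
#' @return duration in seconds.
#' @export
record_duration <- function(record) nrow(record$samples) / record$rate

#' Construct a per-channel annotation table
#'
#' Annotations label half-open time intervals `[start, stop)` (seconds from
#' record start) on individual montage channels. Channel indices are 0-based,
#' matching the on-disk CSV dialect.
#'
#' @param channel_index integer vector, 0-based channel indices.
#' @param start,stop numeric vectors, interval bounds in seconds, `start < stop`.
#' @param label character vector of class labels (see [class_labels()]).
#' @return A `data.frame` with class `eeg_annotations`.
#' @export
annotations <- function(channel_index = integer(), start = numeric(),
                        stop = numeric(), label = character()) {
  df <- data.frame(channel_index = as.integer(channel_index),
                   start = as.numeric(start), stop = as.numeric(stop),
                   label = as.character(label), stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  required <- c("channel_index", "start", "stop", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("annotation table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$channel_index <- as.integer(df$channel_index)
  if (nrow(df) > 0L) {
    if (any(df$channel_index < 0L)) stop("channel_index must be >= 0")
    bad <- df$stop <= df$start
    if (any(bad)) {
      stop(sprintf("annotation with stop <= start (row %d: [%g, %g))",
                   which(bad)[1], df$start[which(bad)[1]], df$stop[which(bad)[1]]))
    }
    validate_labels(df$label)
  }
  class(df) <- c("eeg_annotations", "data.frame")
  df
}

#' Read per-channel annotations from CSV
#'
#' The dialect is a UTF-8 CSV with header `channel_index,start,stop,label`;
#' channel indices are 0-based, times are seconds as decimal floats, labels
#' are the six canonical class symbols.
#'
#' @param path CSV file path.
#' @return An `eeg_annotations` data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(channel_index = "integer",
                                       start = "numeric", stop = "numeric",
                                       label = "character"))
  validate_annotations(df)
}

#' Write per-channel annotations to CSV
#' @param ann an `eeg_annotations` data frame (or compatible data frame).
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(as.data.frame(ann))
  utils::write.csv(ann[, c("channel_index", "start", "stop", "label")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Epoch-level label grids from per-channel annotations
#'
#' Cuts the timeline into fixed-length epochs and assigns each
#' (epoch, channel) cell the label covering the majority of the epoch on
#' that channel (BCKG where nothing else is annotated). Used both to build
#' training targets and as the scoring reference.
#'
#' @param ann `eeg_annotations` table.
#' @param n_epochs number of epochs in the record.
#' @param n_channels number of montage channels.
#' @param epoch_duration epoch length in seconds (pipeline-wide 1 s).
#' @return character matrix `n_epochs x n_channels` of class labels.
#' @export
annotation_label_grid <- function(ann, n_epochs, n_channels,
                                  epoch_duration = 1) {
  grid <- matrix("BCKG", nrow = n_epochs, ncol = n_channels)
  if (nrow(ann) == 0L) return(grid)
  if (any(ann$channel_index >= n_channels)) {
    stop("annotation channel_index out of range for ", n_channels, " channels")
  }
  # coverage bookkeeping: per cell, seconds covered by each label
  for (e in seq_len(n_epochs)) {
    e0 <- (e - 1) * epoch_duration
    e1 <- e * epoch_duration
    hit <- ann$start < e1 & ann$stop > e0
    if (!any(hit)) next
    sub <- ann[hit, , drop = FALSE]
    cover <- pmin(sub$stop, e1) - pmax(sub$start, e0)
    for (ch in unique(sub$channel_index)) {
      rows <- sub$channel_index == ch
      tot <- tapply(cover[rows], sub$label[rows], sum)
      # remaining time is implicit background
      bg <- epoch_duration - sum(cover[rows])
      tot["BCKG"] <- sum(tot["BCKG"], bg, na.rm = TRUE)
      grid[e, ch + 1L] <- names(tot)[which.max(tot)]
    }
  }
  grid
}

#' Epoch-level single label by clinical-priority vote
#'
#' Collapses a per-channel epoch label row to one label per epoch: the
#' highest-priority label present wins, with priority
#' SPSW > PLED > GPED > EYEM > ARTF > BCKG (clinical significance order).
#'
#' @param grid character matrix `n_epochs x n_channels` from
#'   [annotation_label_grid()].
#' @return character vector of length `n_epochs`.
#' @export
epoch_priority_labels <- function(grid) {
  priority <- c("SPSW", "PLED", "GPED", "EYEM", "ARTF", "BCKG")
  apply(grid, 1L, function(row) priority[min(match(row, priority))])
}
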