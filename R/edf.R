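# EDF (European Data Format) codec. EDF stores a fixed 256-byte ASCII header,
# one 256-byte ASCII header extension per signal, then data records of
# little-endian 16-bit integers scaled per channel by the physical/digital
# min/max header fields.

EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

num_field <- function(x, width) {
  # numeric header field: fit into `width` ASCII chars
  s <- formatC(x, format = "g", digits = width - 2L, width = 1L)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  pad_ascii(s, width)
}

read_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n) stop("malformed EDF header: file truncated")
  trimws(rawToChar(raw))
}

#' Read an EDF file into an `eeg_record`
#'
#' Amplitudes are converted to physical units using the per-channel
#' physical/digital min/max scaling declared in the header. All signals must
#' share one sampling rate (true for the EEG exports this pipeline handles).
#'
#' @param path EDF file path.
#' @return An [eeg_record()] at the file's native sampling rate.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  version <- read_ascii(con, 8L)
  if (version != "0") stop("malformed EDF header: field 'version' is \"",
                           version, "\" (expected \"0\")")
  invisible(read_ascii(con, 80L))  # patient id
  invisible(read_ascii(con, 80L))  # recording id
  invisible(read_ascii(con, 8L))   # start date
  invisible(read_ascii(con, 8L))   # start time
  header_bytes <- suppressWarnings(as.integer(read_ascii(con, 8L)))
  invisible(read_ascii(con, 44L))  # reserved
  n_records <- suppressWarnings(as.integer(read_ascii(con, 8L)))
  rec_dur <- suppressWarnings(as.numeric(read_ascii(con, 8L)))
  ns <- suppressWarnings(as.integer(read_ascii(con, 4L)))
  if (is.na(ns)) stop("malformed EDF header: field 'number of signals' not numeric")
  if (ns == 0L) stop("EDF file contains zero signals: ", path)
  if (is.na(n_records) || is.na(rec_dur) || rec_dur <= 0) {
    stop("malformed EDF header: field 'data records / record duration'")
  }
  if (is.na(header_bytes) || header_bytes != 256L + 256L * ns) {
    stop("malformed EDF header: field 'header bytes' inconsistent with signal count")
  }

  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16L), "")
  invisible(readBin(con, "raw", 80L * ns))  # transducer
  invisible(readBin(con, "raw", 8L * ns))   # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8L)), 0)
  invisible(readBin(con, "raw", 80L * ns))  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8L)), 0L)
  invisible(readBin(con, "raw", 32L * ns))  # reserved
  if (any(is.na(pmin) | is.na(pmax) | is.na(dmin) | is.na(dmax))) {
    stop("malformed EDF header: field 'physical/digital min/max' not numeric")
  }
  if (length(unique(spr)) != 1L) {
    stop("EDF signals with differing sampling rates are not supported")
  }
  rate <- spr[1] / rec_dur

  n_per_rec <- sum(spr)
  out <- matrix(0, nrow = spr[1] * n_records, ncol = ns)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = n_per_rec, size = 2L,
                     signed = TRUE, endian = "little")
    if (length(block) < n_per_rec) stop("malformed EDF file: data truncated")
    off <- 0L
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (s in seq_len(ns)) {
      dig <- block[(off + 1L):(off + spr[s])]
      out[rows, s] <- (dig - dmin[s]) * scale[s] + pmin[s]
      off <- off + spr[s]
    }
  }
  eeg_record(out, rate = rate, channel_names = labels)
}

#' Write an `eeg_record` to an EDF file
#'
#' Per-channel physical min/max headers are chosen to cover the data, so the
#' 16-bit quantization error is at most one least-significant bit of the
#' per-channel scale. The data-record duration is 1 s; records whose
#' duration is not a whole number of seconds are zero-padded to the next
#' second.
#'
#' @param record an [eeg_record()]; samples must be finite.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  x <- record$samples
  if (nrow(x) == 0L || ncol(x) == 0L) stop("cannot write an empty record")
  if (!all(is.finite(x))) stop("record contains non-finite samples (NaN/Inf)")
  rate <- record$rate
  if (abs(rate - round(rate)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate, got ", rate)
  }
  rate <- as.integer(round(rate))
  ns <- ncol(x)
  n <- nrow(x)
  n_records <- ceiling(n / rate)
  if (n_records * rate > n) {
    x <- rbind(x, matrix(0, n_records * rate - n, ns))
  }

  pmin <- apply(x, 2L, min)
  pmax <- apply(x, 2L, max)
  degenerate <- pmax - pmin < 1e-9
  pmin[degenerate] <- pmin[degenerate] - 1
  pmax[degenerate] <- pmax[degenerate] + 1
  # round-trip the header's ASCII representation so scaling matches readers
  pmin <- as.numeric(trimws(vapply(pmin, num_field, "", width = 8L)))
  pmax <- as.numeric(trimws(vapply(pmax, num_field, "", width = 8L)))
  pmax <- pmax(pmax, pmin + 1e-6)

  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeBin(charToRaw(s), con)
  put(pad_ascii("0", 8L))
  put(pad_ascii("X X X X", 80L))
  put(pad_ascii("Startdate 01-JAN-2000 X X X", 80L))
  put(pad_ascii("01.01.00", 8L))
  put(pad_ascii("00.00.00", 8L))
  put(pad_ascii(256L + 256L * ns, 8L))
  put(pad_ascii("", 44L))
  put(pad_ascii(n_records, 8L))
  put(pad_ascii("1", 8L))
  put(pad_ascii(ns, 4L))
  for (nm in record$channel_names) put(pad_ascii(nm, 16L))
  for (i in seq_len(ns)) put(pad_ascii("", 80L))
  for (i in seq_len(ns)) put(pad_ascii("uV", 8L))
  for (i in seq_len(ns)) put(num_field(pmin[i], 8L))
  for (i in seq_len(ns)) put(num_field(pmax[i], 8L))
  for (i in seq_len(ns)) put(pad_ascii(EDF_DIG_MIN, 8L))
  for (i in seq_len(ns)) put(pad_ascii(EDF_DIG_MAX, 8L))
  for (i in seq_len(ns)) put(pad_ascii("", 80L))
  for (i in seq_len(ns)) put(pad_ascii(rate, 8L))
  for (i in seq_len(ns)) put(pad_ascii("", 32L))

  drange <- EDF_DIG_MAX - EDF_DIG_MIN
  for (r in seq_len(n_records)) {
    rows <- ((r - 1L) * rate + 1L):(r * rate)
    for (s in seq_len(ns)) {
      dig <- round((x[rows, s] - pmin[s]) / (pmax[s] - pmin[s]) * drange +
                     EDF_DIG_MIN)
      dig <- pmin(pmax(dig, EDF_DIG_MIN), EDF_DIG_MAX)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Resample a record to a target rate
#'
#' Fourier-domain resampling: the spectrum is truncated (ideal zero-phase
#' anti-alias low-pass) or zero-extended and inverse-transformed at the new
#' length. Deterministic, delay-free, and exact for band-limited content;
#' the output length is `round(n * target_rate / rate)`, so duration is
#' preserved to within one sample period. Records sampled below the target
#' are upsampled with a warning.
#'
#' @param record an [eeg_record()].
#' @param target_rate desired rate in samples/second (pipeline canon: 250).
#' @return resampled `eeg_record` at `target_rate`.
#' @export
resample_record <- function(record, target_rate = 250) {
  if (target_rate <= 0) stop("target_rate must be > 0")
  if (abs(record$rate - target_rate) < 1e-9) return(record)
  if (record$rate < target_rate) {
    warning("record rate ", record$rate, " Hz is below target ", target_rate,
            " Hz; upsampling")
  }
  n_out <- round(nrow(record$samples) * target_rate / record$rate)
  out <- apply(record$samples, 2L, fft_resample, n_out = n_out)
  eeg_record(out, rate = target_rate, channel_names = record$channel_names,
             start_time = record$start_time)
}

fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  keep <- min(n, n_out)
  h <- (keep - 1L) %/% 2L                     # bins strictly below Nyquist
  Y <- complex(n_out)
  Y[seq_len(h + 1L)] <- X[seq_len(h + 1L)]
  if (h >= 1L) Y[(n_out - h + 1L):n_out] <- X[(n - h + 1L):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Standard 22-channel TCP montage
#'
#' The temporal-central-parasagittal (TCP) bipolar montage over the 10/20
#' electrode set, as standardized by the ACNS and used for clinical EEG
#' exports: 22 derivations, each the sample-wise difference of two
#' electrodes.
#'
#' @return data.frame with columns `anode` and `cathode` (22 rows).
#' @export
tcp_montage <- function() {
  pairs <- c(
    "FP1-F7", "F7-T3", "T3-T5", "T5-O1",
    "FP2-F8", "F8-T4", "T4-T6", "T6-O2",
    "A1-T3", "T3-C3", "C3-CZ", "CZ-C4", "C4-T4", "T4-A2",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2"
  )
  parts <- strsplit(pairs, "-", fixed = TRUE)
  data.frame(anode = vapply(parts, `[`, "", 1L),
             cathode = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Read a montage specification from YAML
#'
#' The file holds a list of two-element electrode pairs, e.g.
#' `- [FP1, F7]`.
#'
#' @param path YAML file path.
#' @return data.frame with columns `anode`, `cathode`.
#' @export
read_montage <- function(path) {
  spec <- yaml::read_yaml(path)
  if (length(spec) == 0L) stop("montage spec is empty")
  data.frame(anode = vapply(spec, function(p) as.character(p[[1]]), ""),
             cathode = vapply(spec, function(p) as.character(p[[2]]), ""),
             stringsAsFactors = FALSE)
}

#' Apply a bipolar montage to an electrode-referential record
#'
#' Each output channel is `anode - cathode`, sample-wise; output channel
#' names are `"A-B"` strings. With the default [tcp_montage()] this yields
#' the standard 22 channels.
#'
#' @param record an [eeg_record()] whose channel names are electrode names.
#' @param montage_spec data.frame with `anode`/`cathode` columns; defaults to
#'   the standard TCP montage.
#' @return montaged `eeg_record`.
#' @export
apply_tcp_montage <- function(record, montage_spec = tcp_montage()) {
  needed <- unique(c(montage_spec$anode, montage_spec$cathode))
  missing <- setdiff(needed, record$channel_names)
  if (length(missing) > 0L) {
    stop("montage references electrode(s) absent from record: ",
         paste(missing, collapse = ", "))
  }
  a <- match(montage_spec$anode, record$channel_names)
  b <- match(montage_spec$cathode, record$channel_names)
  out <- record$samples[, a, drop = FALSE] - record$samples[, b, drop = FALSE]
  eeg_record(out, rate = record$rate,
             channel_names = paste0(montage_spec$anode, "-", montage_spec$cathode),
             start_time = record$start_time)
}
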