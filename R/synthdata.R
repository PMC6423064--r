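# Synthetic annotated EEG generator. Produces 22-channel, 250 Hz montaged
# records containing 1/f background noise plus stylized class-separable
# events with the temporal and spatial signatures the pipeline assumes:
# focal biphasic transients (SPSW), lateralized periodic discharges (PLED),
# bilaterally symmetric periodic discharges (GPED), frontal low-frequency
# deflections (EYEM) and broadband bursts (ARTF). Waveforms are stylized,
# not biophysical; the goal is statistical structure, not realism.

# channel groups within the standard 22-channel TCP montage
TCP_LEFT <- as.integer(c(1:4, 9, 10, 15:18))
TCP_RIGHT <- as.integer(c(5:8, 13, 14, 19:22))
TCP_FRONTAL <- as.integer(c(1, 5, 15, 19))

#' Corpus generation specification
#'
#' The `"easy"` profile (default) uses moderate class imbalance and a high
#' signal-to-noise ratio suited to fast pipeline tests; the `"hard"`
#' profile uses the heavier background-dominated imbalance typical of
#' clinical event corpora (roughly 1% SPSW, 64% BCKG) and doubled noise.
#'
#' @param n_records number of records in the corpus.
#' @param duration record duration in seconds (whole seconds).
#' @param profile `"easy"` or `"hard"` preset, or NULL if `class_mix` given.
#' @param class_mix named numeric vector of target epoch proportions over
#'   the six classes (must sum to 1); overrides the profile preset.
#' @param noise_level background noise multiplier (1 = 15 uV RMS).
#' @param seed corpus-level RNG seed; record seeds derive from it.
#' @param train_fraction fraction of records assigned to the training split.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_records = 10L, duration = 60,
                        profile = c("easy", "hard"), class_mix = NULL,
                        noise_level = NULL, seed = 1L,
                        train_fraction = 0.8) {
  profile <- match.arg(profile)
  if (is.null(class_mix)) {
    class_mix <- switch(profile,
      easy = c(SPSW = 0.05, PLED = 0.15, GPED = 0.15, EYEM = 0.08,
               ARTF = 0.12, BCKG = 0.45),
      hard = c(SPSW = 0.008, PLED = 0.134, GPED = 0.074, EYEM = 0.014,
               ARTF = 0.132, BCKG = 0.638))
  }
  class_mix <- class_mix[class_labels()]
  if (abs(sum(class_mix) - 1) > 1e-6) stop("class_mix must sum to 1")
  if (is.null(noise_level)) noise_level <- if (profile == "hard") 2 else 1
  if (abs(duration - round(duration)) > 1e-9) {
    stop("duration must be a whole number of seconds")
  }
  structure(list(n_records = as.integer(n_records), duration = duration,
                 profile = profile, class_mix = class_mix,
                 noise_level = noise_level, seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "corpus_spec")
}

pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                      # symmetric bin frequencies
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# one-period biphasic transient, tapered; width in samples
biphasic_wave <- function(width, amp) {
  t <- seq(0, 1, length.out = width)
  amp * sin(2 * pi * t) * sin(pi * t)
}

halfsine_wave <- function(width, amp) {
  amp * sin(pi * seq(0, 1, length.out = width))
}

#' Generate one annotated synthetic record
#'
#' Produces a 22-channel, 250 Hz montaged record with events placed on
#' whole 1 s epochs (annotations exactly cover the occupied epochs;
#' remaining time is annotated BCKG per channel). PLED events are
#' lateralized to one hemisphere's derivations, GPED events cover
#' symmetric left/right pairs, EYEM events sit on the frontal derivations
#' and SPSW on a small random focal channel subset. A record never
#' contains both PLED and GPED events.
#'
#' @param spec a [corpus_spec()].
#' @param seed record-level RNG seed.
#' @param periodic_kind which periodic class this record may contain
#'   (`"PLED"` or `"GPED"`); if NULL, sampled in proportion to the class
#'   mix.
#' @return list with `record` (an [eeg_record()]) and `annotations`.
#' @export
generate_record <- function(spec = corpus_spec(), seed = spec$seed,
                            periodic_kind = NULL) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  rate <- 250L
  n_ep <- as.integer(round(spec$duration))
  n <- n_ep * rate
  n_ch <- 22L
  noise_sd <- 15 * spec$noise_level
  x <- vapply(seq_len(n_ch), function(ch) pink_noise(n) * noise_sd,
              numeric(n))

  mix <- spec$class_mix
  if (is.null(periodic_kind)) {
    pp <- mix[c("PLED", "GPED")]
    periodic_kind <- if (sum(pp) <= 0) "PLED" else
      sample(c("PLED", "GPED"), 1L, prob = pp)
  }
  quota <- round(mix * n_ep)
  quota[periodic_kind] <- round((mix["PLED"] + mix["GPED"]) * n_ep)
  quota[setdiff(c("PLED", "GPED"), periodic_kind)] <- 0L

  free <- rep(TRUE, n_ep)
  place_run <- function(len) {
    if (len > n_ep) return(NULL)
    ok <- which(vapply(seq_len(n_ep - len + 1L),
                       function(s) all(free[s:(s + len - 1L)]), TRUE))
    if (length(ok) == 0L) return(NULL)
    s <- ok[sample.int(length(ok), 1L)]
    free[s:(s + len - 1L)] <<- FALSE
    s
  }
  ann <- list()
  add_ann <- function(channels, e_start, e_len, label) {
    for (ch in channels) {
      ann[[length(ann) + 1L]] <<- data.frame(
        channel_index = ch - 1L, start = e_start - 1,
        stop = e_start - 1 + e_len, label = label,
        stringsAsFactors = FALSE)
    }
  }
  add_burst <- function(channels, t0, wave) {
    idx <- t0:(t0 + length(wave) - 1L)
    keep <- idx <= n
    for (ch in channels) x[idx[keep], ch] <<- x[idx[keep], ch] + wave[keep]
  }

  inject_periodic <- function(kind) {
    placed <- 0L
    while (placed < quota[kind]) {
      len <- sample(6:12, 1L)
      len <- min(len, quota[kind] - placed)
      if (len < 2L) len <- 2L
      s <- place_run(len)
      if (is.null(s)) break
      channels <- if (kind == "GPED") seq_len(n_ch) else
        if (stats::runif(1) < 0.5) TCP_LEFT else TCP_RIGHT
      ipi <- stats::runif(1, 0.5, 3)           # inter-discharge interval, s
      width <- if (kind == "GPED") round(0.20 * rate) else round(0.07 * rate)
      amp <- 90
      times <- seq((s - 1) + 0.1, (s - 1) + len - 0.3, by = ipi)
      for (tt in times) {
        w <- biphasic_wave(width, amp * stats::runif(1, 0.8, 1.2))
        add_burst(channels, round(tt * rate) + 1L, w)
      }
      add_ann(channels, s, len, kind)
      placed <- placed + len
    }
  }
  inject_spsw <- function() {
    placed <- 0L
    while (placed < quota["SPSW"]) {
      s <- place_run(1L)
      if (is.null(s)) break
      channels <- sample.int(n_ch, sample(1:4, 1L))
      width <- round(stats::runif(1, 0.02, 0.07) * rate)
      t0 <- round(((s - 1) + stats::runif(1, 0.2, 0.7)) * rate) + 1L
      add_burst(channels, t0, biphasic_wave(max(width, 5L), 120))
      add_ann(channels, s, 1L, "SPSW")
      placed <- placed + 1L
    }
  }
  inject_eyem <- function() {
    placed <- 0L
    while (placed < quota["EYEM"]) {
      len <- min(sample(1:2, 1L), max(quota["EYEM"] - placed, 1L))
      s <- place_run(len)
      if (is.null(s)) break
      width <- round(stats::runif(1, 0.3, 0.5) * rate)
      for (rep in seq_len(len)) {
        t0 <- round(((s - 1) + (rep - 1) + stats::runif(1, 0.1, 0.4)) * rate) + 1L
        sign <- sample(c(-1, 1), 1L)
        add_burst(TCP_FRONTAL, t0, halfsine_wave(width, sign * 150))
      }
      add_ann(TCP_FRONTAL, s, len, "EYEM")
      placed <- placed + len
    }
  }
  inject_artf <- function() {
    placed <- 0L
    while (placed < quota["ARTF"]) {
      len <- min(sample(1:3, 1L), max(quota["ARTF"] - placed, 1L))
      s <- place_run(len)
      if (is.null(s)) break
      channels <- sample.int(n_ch, sample(3:8, 1L))
      burst <- stats::rnorm(len * rate) * 50
      add_burst(channels, (s - 1L) * rate + 1L, burst)
      add_ann(channels, s, len, "ARTF")
      placed <- placed + len
    }
  }
  inject_periodic(periodic_kind)
  inject_eyem()
  inject_artf()
  inject_spsw()

  ann_df <- if (length(ann) > 0L) do.call(rbind, ann) else
    data.frame(channel_index = integer(), start = numeric(),
               stop = numeric(), label = character())
  # explicit BCKG annotations over each channel's uncovered time
  grid_cov <- matrix(FALSE, n_ep, n_ch)
  if (nrow(ann_df) > 0L) {
    for (r in seq_len(nrow(ann_df))) {
      eps <- (ann_df$start[r] + 1L):(ann_df$stop[r])
      grid_cov[eps, ann_df$channel_index[r] + 1L] <- TRUE
    }
  }
  for (ch in seq_len(n_ch)) {
    runs <- rle(!grid_cov[, ch])
    pos <- cumsum(c(0L, runs$lengths))
    for (i in seq_along(runs$values)) {
      if (!runs$values[i]) next
      ann_df <- rbind(ann_df, data.frame(
        channel_index = ch - 1L, start = pos[i], stop = pos[i + 1L],
        label = "BCKG", stringsAsFactors = FALSE))
    }
  }
  ann_df <- ann_df[order(ann_df$channel_index, ann_df$start), ]
  rownames(ann_df) <- NULL
  rec <- eeg_record(x, rate = rate,
                    channel_names = paste0(tcp_montage()$anode, "-",
                                           tcp_montage()$cathode))
  list(record = rec, annotations = validate_annotations(ann_df))
}

#' Generate a corpus of EDF + annotation CSV pairs with a train/eval split
#'
#' Records are disjoint pseudo-patients; the first
#' `ceiling(train_fraction * n_records)` go to the training split. A
#' `manifest.json` records the file lists and per-class annotation-row
#' counts.
#'
#' @param spec a [corpus_spec()] with `n_records >= 2`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (list with `train`, `eval`,
#'   `class_counts`, `spec` summary).
#' @export
generate_corpus <- function(spec, out_dir) {
  if (spec$n_records < 2L) stop("need at least 2 records for a split")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_train <- ceiling(spec$train_fraction * spec$n_records)
  files <- character(spec$n_records)
  counts <- stats::setNames(numeric(n_classes()), class_labels())
  # deterministic stratified assignment of the periodic class per record, so
  # small corpora still realize both PLED and GPED in proportion to the mix
  pp <- spec$class_mix[c("PLED", "GPED")]
  p_pled <- if (sum(pp) > 0) pp[["PLED"]] / sum(pp) else 0
  kinds <- ifelse(round(seq_len(spec$n_records) * p_pled) >
                    round((seq_len(spec$n_records) - 1L) * p_pled),
                  "PLED", "GPED")
  for (r in seq_len(spec$n_records)) {
    gen <- generate_record(spec, seed = spec$seed * 10000L + r,
                           periodic_kind = kinds[r])
    base <- sprintf("rec%03d", r)
    write_edf(gen$record, file.path(out_dir, paste0(base, ".edf")))
    write_annotations(gen$annotations, file.path(out_dir, paste0(base, ".csv")))
    files[r] <- base
    tab <- table(gen$annotations$label)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  manifest <- list(train = files[seq_len(n_train)],
                   eval = files[(n_train + 1L):spec$n_records],
                   class_counts = as.list(counts),
                   n_records = spec$n_records, duration = spec$duration,
                   profile = spec$profile, seed = spec$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
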