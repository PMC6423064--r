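test_that("EDF write/read round trip preserves samples to 16-bit precision", {
  rec <- sine_record(10, duration = 10, amp = 50)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_equal(back$rate, 250)
  expect_identical(back$channel_names, rec$channel_names)
  # error bounded by one LSB of the per-channel quantization scale
  lsb <- (max(rec$samples) - min(rec$samples)) / 65535
  expect_lt(max(abs(back$samples - rec$samples)), 1.5 * lsb)
  expect_gt(stats::cor(back$samples[, 1], rec$samples[, 1]), 0.999)
  # write(read(f)) re-read matches the first read-back
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(back, f2)
  again <- read_edf(f2)
  expect_lt(max(abs(again$samples - back$samples)), 1.5 * lsb)
})

test_that("EDF files use 16-bit integer storage and honest headers", {
  rec <- eeg_record(matrix(stats::rnorm(250 * 22) * 30, ncol = 22), 250,
                    paste0("E", 1:22))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  # header 256 + 22*256 bytes; one data record of 22 * 250 int16 samples
  expect_identical(file.info(f)$size, 256 + 22 * 256 + 22 * 250 * 2)
  con <- file(f, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 256 + 22 * 256))
  dig <- readBin(con, "integer", n = 22 * 250, size = 2L, signed = TRUE,
                 endian = "little")
  expect_true(all(dig >= -32768 & dig <= 32767))
  # ramp read-back max within 1 LSB of written max
  ramp <- eeg_record(matrix(seq(0, 100, length.out = 500), ncol = 1), 250, "R")
  f3 <- withr::local_tempfile(fileext = ".edf")
  write_edf(ramp, f3)
  expect_lt(abs(max(read_edf(f3)$samples) - 100), 100 / 65535 * 1.5)
})

test_that("an independent EDF reader (mne) agrees with the writer", {
  rec <- sine_record(10, duration = 4, amp = 40)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  out <- suppressWarnings(system2("python", c("-c", shQuote(sprintf(
    "import mne, numpy as np; raw = mne.io.read_raw_edf('%s', verbose='ERROR'); x = raw.get_data()[0] * 1e6; ref = np.sin(2*np.pi*10*np.arange(1000)/250)*40; print(np.corrcoef(x, ref)[0,1])",
    f))), stdout = TRUE, stderr = FALSE))
  corr <- suppressWarnings(as.numeric(out[length(out)]))
  expect_false(is.na(corr))
  expect_gt(corr, 0.999)
})

test_that("degenerate records and malformed files are rejected with clear errors", {
  zero <- eeg_record(matrix(0, 250, 1), 250, "Z")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(zero, f)
  expect_true(all(abs(read_edf(f)$samples) < 1e-3))
  bad <- eeg_record(matrix(c(1, NaN, 3, 4), 2, 2), 2, c("A", "B"))
  expect_error(write_edf(bad, f), "non-finite")
  expect_error(read_edf(tempfile()), "does not exist")
  garbage <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw(paste(rep("9", 600), collapse = "")), garbage)
  expect_error(read_edf(garbage), "version")
})

test_that("resampling preserves tones, duration, and band-limited content", {
  same <- resample_record(sine_record(10, 2), 250)
  expect_identical(same$samples, sine_record(10, 2)$samples)

  r500 <- eeg_record(matrix(sin(2 * pi * 10 * (0:29999) / 500), ncol = 1),
                     500, "X")
  down <- resample_record(r500, 250)
  expect_equal(nrow(down$samples), 15000)
  spec <- Mod(stats::fft(down$samples[, 1]))[1:7500]
  expect_lt(abs((which.max(spec) - 1) * 250 / 15000 - 10), 250 / 15000 + 1e-9)

  r1024 <- eeg_record(matrix(stats::rnorm(1024 * 60), ncol = 1), 1024, "Y")
  out <- resample_record(r1024, 250)
  expect_lte(abs(nrow(out$samples) - 15000), 1)

  # 250 -> 500 -> 250 round trip on a band-limited signal
  t <- (0:4999) / 250
  x <- sin(2 * pi * 7 * t) + 0.5 * sin(2 * pi * 31 * t)
  rec <- eeg_record(matrix(x, ncol = 1), 250, "B")
  rt <- resample_record(suppressWarnings(resample_record(rec, 500)), 250)
  mid <- 500:4500  # ignore filter edge transients
  rel_rms <- sqrt(mean((rt$samples[mid, 1] - x[mid])^2)) / sqrt(mean(x[mid]^2))
  expect_lt(rel_rms, 1e-2)

  expect_warning(resample_record(eeg_record(matrix(0, 200, 1), 200, "L"), 250),
                 "upsampling")
})

test_that("TCP montage produces 22 difference channels and is linear", {
  electrodes <- unique(c(tcp_montage()$anode, tcp_montage()$cathode))
  n <- 500
  x <- matrix(stats::rnorm(n * length(electrodes)), n)
  rec <- eeg_record(x, 250, electrodes)
  m <- apply_tcp_montage(rec)
  expect_identical(ncol(m$samples), 22L)
  expect_identical(m$channel_names[1], "FP1-F7")
  expect_equal(m$samples[, 1],
               x[, match("FP1", electrodes)] - x[, match("F7", electrodes)])
  # self-difference channel is identically zero
  self <- apply_tcp_montage(rec, data.frame(anode = "CZ", cathode = "CZ"))
  expect_true(all(self$samples == 0))
  # linearity in the input record
  rec2 <- eeg_record(3 * x, 250, electrodes)
  expect_equal(apply_tcp_montage(rec2)$samples, 3 * m$samples)
  # missing electrode is named
  rec3 <- eeg_record(x[, -match("F7", electrodes)], 250,
                     setdiff(electrodes, "F7"))
  expect_error(apply_tcp_montage(rec3), "F7")
})

test_that("montage specs round trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- [FP1, F7]", "- [F7, T3]"), f)
  spec <- read_montage(f)
  expect_identical(spec$anode, c("FP1", "F7"))
  expect_identical(spec$cathode, c("F7", "T3"))
})

test_that("annotation CSV I/O validates and round trips", {
  ann <- annotations(channel_index = c(3L, 0L), start = c(10, 0),
                     stop = c(11, 2.5), label = c("SPSW", "BCKG"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  expect_identical(back$label[1], "SPSW")
  # empty table round trips through a header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(annotations(), f2)
  expect_identical(nrow(read_annotations(f2)), 0L)
  # property: random annotation tables survive a round trip
  set.seed(42)
  for (i in 1:5) {
    n <- sample(1:20, 1)
    st <- round(stats::runif(n, 0, 50), 3)
    a <- annotations(sample(0:21, n, TRUE), st, st + stats::runif(n, 0.5, 5),
                     sample(class_labels(), n, TRUE))
    f3 <- withr::local_tempfile(fileext = ".csv")
    write_annotations(a, f3)
    expect_equal(as.data.frame(read_annotations(f3)), as.data.frame(a))
  }
  expect_error(annotations(0L, 1, 1, "SPSW"), "stop <= start")
  expect_error(annotations(0L, 1, 2, "PLEDS"), "PLEDS")
})

test_that("annotation label grids implement majority labels and priority votes", {
  ann <- annotations(channel_index = c(0L, 0L, 1L),
                     start = c(0, 1.6, 0), stop = c(1.6, 3, 3),
                     label = c("PLED", "BCKG", "GPED"))
  grid <- annotation_label_grid(ann, 3, 2)
  expect_identical(grid[, 1], c("PLED", "PLED", "BCKG"))  # 0.6 s majority
  expect_identical(grid[, 2], rep("GPED", 3))
  expect_identical(epoch_priority_labels(grid), c("PLED", "PLED", "GPED"))
})
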