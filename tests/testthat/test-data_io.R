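test_that("delimited recordings load as channels x samples with metadata", {
  m <- matrix(seq_len(2000), nrow = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  rec <- load_recording(path, format = "delimited", sfreq = 500,
                        channel_names = c("a", "b"))
  expect_s3_class(rec, "continuous_recording")
  expect_equal(dim(rec$signal), c(2, 1000))
  expect_equal(unname(rec$signal), m, ignore_attr = TRUE)
  expect_equal(rec$channel_names, c("a", "b"))

  # channels-in-columns orientation transposes
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.table(t(m), path2, sep = ",", row.names = FALSE, col.names = FALSE)
  rec2 <- load_recording(path2, format = "delimited", sfreq = 500,
                         channels_in = "columns")
  expect_equal(rec2$signal, rec$signal, ignore_attr = TRUE)
})

test_that("NaN samples are refused with the offending location named", {
  m <- matrix(rnorm(20), nrow = 2)
  m[2, 7] <- NaN
  path <- withr::local_tempfile(fileext = ".csv")
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(load_recording(path, format = "delimited", sfreq = 10),
               "row 2.*sample 7")
})

test_that("binary input requires a sidecar and round-trips", {
  m <- matrix(rnorm(300), nrow = 3)
  path <- withr::local_tempfile(fileext = ".bin")
  writeBin(as.numeric(m), path, size = 8, endian = "little")
  expect_error(load_recording(path, format = "binary"), "sidecar")
  jsonlite::write_json(list(n_channels = 3, sfreq = 250,
                            channel_names = c("x", "y", "z")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  rec <- load_recording(path, format = "binary")
  expect_equal(rec$signal, m, ignore_attr = TRUE)
  expect_equal(rec$sfreq, 250)
})

test_that("EDF recordings load with header labels in order", {
  sfreq <- 50
  sig <- matrix(sample(-300:300, 3 * sfreq * 4, replace = TRUE), nrow = 3)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(path, sig, sfreq, c("Fp1", "Cz", "O2"))
  rec <- load_recording(path)
  expect_equal(rec$channel_names, c("Fp1", "Cz", "O2"))
  expect_equal(rec$sfreq, sfreq)
  expect_equal(round(rec$signal), sig, ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("epoching splits into non-overlapping 1-s windows and drops the tail", {
  # a 935-s recording at 500 Hz yields 935 one-second epochs
  rec <- continuous_recording(matrix(rnorm(2 * 935 * 500), 2), 500)
  ep <- epoch_signal(rec, 1)
  expect_equal(dim(ep$data), c(935, 2, 500))
  expect_equal(ep$epoch_index, 0:934)

  # trailing partial epoch discarded: 10.5 s -> 10 epochs
  rec2 <- continuous_recording(matrix(rnorm(2 * 5250), 2), 500)
  ep2 <- epoch_signal(rec2, 1)
  expect_equal(dim(ep2$data)[1], 10)

  # 0.3-s epochs at 500 Hz: 150 samples each
  ep3 <- epoch_signal(rec2, 0.3)
  expect_equal(dim(ep3$data)[3], 150)
  expect_equal(dim(ep3$data)[1], 5250 %/% 150)

  # non-integer samples per epoch is an error
  expect_error(epoch_signal(rec2, 1 / 3), "integer")
})

test_that("concatenating epochs reproduces the leading samples exactly", {
  rec <- continuous_recording(matrix(rnorm(3 * 1050), 3), 100)
  ep <- epoch_signal(rec, 1)
  rebuilt <- do.call(cbind, lapply(seq_len(dim(ep$data)[1]), function(e) {
    matrix(ep$data[e, , ], nrow = 3)
  }))
  expect_identical(rebuilt, unname(rec$signal[, 1:1000]))
})

test_that("partition files round-trip boundaries bit-identically", {
  p <- segment_partition(c(120), n_epochs = 935)
  tab <- tidy(p)
  expect_equal(tab$duration_s, c(120, 815))

  path <- withr::local_tempfile(fileext = ".csv")
  write_partition(p, path)
  expect_identical(read_partition(path)$boundaries, p$boundaries)

  # single state covers everything in one row
  p1 <- segment_partition(integer(0), n_epochs = 50)
  write_partition(p1, path)
  tab1 <- read.csv(path)
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$duration_s, 50)
  expect_identical(read_partition(path)$boundaries, p1$boundaries)

  expect_error(read_partition({
    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines("a,b\n1,2", bad); bad
  }), "malformed")
})

test_that("segment partitions validate their invariants", {
  expect_error(segment_partition(c(-5), 10), "boundaries")
  expect_error(segment_partition(c(12), 10), "boundaries")
  p <- segment_partition(c(3, 7), 10)
  expect_equal(n_states(p), 3)
  expect_equal(state_labels(p), rep(1:3, c(3, 4, 3)))
  expect_equal(sum(diff(p$boundaries)), 10)
})
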