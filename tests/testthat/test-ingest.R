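devices <- default_devices()
motion <- devices$device_id[devices$name == "Kitchen Motion"]
cabinet <- devices$device_id[devices$name == "Cabinet (Food)"]
cooker <- devices$device_id[devices$name == "Cooker"]

test_that("a 0->1 / 1->0 pair forms one terminated signal event", {
  rr <- dplyr::bind_rows(
    signal_reading(cabinet, "10:00:00", 0, 1),
    signal_reading(cabinet, "10:00:30", 1, 0))
  ev <- extract_signal_events(rr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, ts("10:00:00"))
  expect_equal(ev$end, ts("10:00:30"))
  expect_true(ev$terminated)
  expect_equal(extract_signal_events(rr[0, ]), ev[0, ])
})

test_that("an unterminated signal is closed at stream end and flagged", {
  rr <- signal_reading(cabinet, "10:00:00", 0, 1)
  ev <- extract_signal_events(rr, ingest_config(), stream_end = ts("10:05:00"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end, ts("10:05:00"))
  expect_false(ev$terminated)
  dropped <- extract_signal_events(
    rr, ingest_config(unterminated_policy = "drop"),
    stream_end = ts("10:05:00"))
  expect_equal(nrow(dropped), 0)
})

test_that("repeated 0->1 transitions are ignored with a warning", {
  rr <- dplyr::bind_rows(
    signal_reading(cabinet, "10:00:00", 0, 1),
    signal_reading(cabinet, "10:00:10", 0, 1),
    signal_reading(cabinet, "10:00:30", 1, 0))
  expect_warning(ev <- extract_signal_events(rr), "repeated")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, ts("10:00:00"))
})

test_that("unordered signal readings are a contract error", {
  rr <- dplyr::bind_rows(
    signal_reading(cabinet, "10:00:30", 0, 1),
    signal_reading(cabinet, "10:00:00", 1, 0))
  expect_error(extract_signal_events(rr), "time-ordered")
})

test_that("wattage above threshold opens an event, first idle reading closes it", {
  rr <- dplyr::bind_rows(
    watt_reading(cooker, "10:00:00", 0.8),
    watt_reading(cooker, "10:01:00", 42),
    watt_reading(cooker, "10:02:00", 55),
    watt_reading(cooker, "10:03:00", 0.9))
  ev <- extract_consumption_events(rr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, ts("10:01:00"))
  expect_equal(ev$end, ts("10:03:00"))
  expect_equal(ev$max_watts, 55)
  expect_equal(ev$mean_watts, mean(c(42, 55)))
  # all-idle series yields nothing
  idle <- dplyr::bind_rows(watt_reading(cooker, "10:00:00", 0),
                           watt_reading(cooker, "10:01:00", 0))
  expect_equal(nrow(extract_consumption_events(idle)), 0)
})

test_that("the 5 W boundary itself counts as in use", {
  for (w in c(4.9, 5.0, 5.1)) {
    ev <- extract_consumption_events(dplyr::bind_rows(
      watt_reading(cooker, "10:00:00", w),
      watt_reading(cooker, "10:01:00", 0.5)))
    expect_equal(nrow(ev), as.integer(w >= 5), label = paste(w, "W"))
  }
})

test_that("an event open at stream end closes at the last reading", {
  rr <- dplyr::bind_rows(
    watt_reading(cooker, "10:00:00", 900),
    watt_reading(cooker, "10:05:00", 1100))
  ev <- extract_consumption_events(rr)
  expect_equal(ev$end, ts("10:05:00"))
  expect_false(ev$terminated)
})

test_that("negative wattage is rejected", {
  expect_error(extract_consumption_events(watt_reading(cooker, "10:00:00", -1)),
               "negative")
})

test_that("normalize_events truncates implausibly long signal events", {
  ev <- dplyr::bind_rows(
    extract_signal_events(dplyr::bind_rows(
      signal_reading(cabinet, "10:00:00", 0, 1),
      signal_reading(cabinet, "14:00:00", 1, 0))),
    extract_signal_events(dplyr::bind_rows(
      signal_reading(cabinet, "09:00:00", 0, 1),
      signal_reading(cabinet, "09:00:30", 1, 0))))
  out <- normalize_events(ev, ingest_config(max_plausible_signal_duration_s = 600))
  long <- out[out$start == ts("10:00:00"), ]
  expect_equal(long$end, ts("10:10:00"))
  expect_false(long$terminated)
  short <- out[out$start == ts("09:00:00"), ]
  expect_equal(short$end, ts("09:00:30"))
  expect_true(short$terminated)
  expect_equal(nrow(normalize_events(ev[0, ])), 0)
})

test_that("readings round-trip through CSV and JSON-lines with validation", {
  rr <- dplyr::bind_rows(
    signal_reading(motion, "10:00:00", 0, 1),
    signal_reading(motion, "10:30:00", 1, 0),
    watt_reading(cooker, "10:05:00", 900))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_readings(rr, csv)
  back <- read_readings(csv, devices)
  expect_equal(back[, names(rr)], dplyr::arrange(rr, device_id, timestamp))
  # JSON-lines dialect
  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(sprintf(
    '{"device_id":"%s","timestamp":"%s","old_value":%d,"new_value":%d}',
    motion, c("2024-03-04T10:00:00Z", "2024-03-04T10:30:00Z"),
    c(0L, 1L), c(1L, 0L)), jl)
  backj <- read_readings(jl, devices)
  expect_equal(nrow(backj), 2)
  expect_equal(backj$timestamp, c(ts("10:00:00"), ts("10:30:00")))
  # empty file with header
  writeLines("device_id,timestamp,old_value,new_value,watts", csv)
  expect_equal(nrow(read_readings(csv, devices)), 0)
})

test_that("unknown devices, bad timestamps and kind mismatches are rejected", {
  expect_error(validate_readings(signal_reading("dev_ghost", "10:00:00", 0, 1),
                                 devices), "dev_ghost")
  bad_ts <- signal_reading(motion, "10:00:00", 0, 1)
  bad_ts$timestamp <- "not-a-time"
  expect_error(validate_readings(bad_ts, devices), "malformed timestamp")
  expect_error(validate_readings(watt_reading(motion, "10:00:00", 10), devices),
               "old_value/new_value")
  expect_error(validate_readings(signal_reading(cooker, "10:00:00", 0, 1),
                                 devices), "watts")
})

test_that("no-op transitions (old == new) are discarded", {
  rr <- dplyr::bind_rows(
    signal_reading(motion, "10:00:00", 0, 1),
    signal_reading(motion, "10:10:00", 1, 1),
    signal_reading(motion, "10:30:00", 1, 0))
  out <- validate_readings(rr, devices)
  expect_equal(nrow(out), 2)
})

test_that("per-device signal events never overlap (randomized streams)", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    vals <- sample(0:1, n, replace = TRUE)
    rr <- tibble::tibble(
      device_id = cabinet,
      timestamp = ts("08:00:00") + sort(sample(1:50000, n)),
      old_value = 1L - vals, new_value = vals, watts = NA_real_)
    ev <- suppressWarnings(extract_signal_events(rr))
    if (nrow(ev) > 1) {
      expect_true(all(as.numeric(ev$start[-1]) >=
                        as.numeric(ev$end[-nrow(ev)])))
    }
    expect_true(all(ev$end >= ev$start))
  }
})

test_that("raising the threshold shrinks and nests consumption events", {
  # the active-reading set shrinks as the threshold rises, so every event
  # found at a higher threshold nests inside an event at a lower one
  set.seed(72)
  for (rep in 1:15) {
    n <- sample(10:60, 1)
    rr <- tibble::tibble(
      device_id = cooker,
      timestamp = ts("08:00:00") + sort(sample(1:50000, n)),
      old_value = NA_integer_, new_value = NA_integer_,
      watts = round(stats::rexp(n, 1 / 20), 2))
    thrs <- c(1, 5, 20, 60)
    evs <- lapply(thrs, function(thr) {
      extract_consumption_events(
        rr, ingest_config(consumption_threshold_watts = thr))
    })
    for (i in seq_len(length(thrs) - 1)) {
      lo <- evs[[i]]; hi <- evs[[i + 1]]
      expect_lte(sum(rr$watts >= thrs[i + 1]), sum(rr$watts >= thrs[i]))
      if (nrow(hi) > 0) {
        nested <- sapply(seq_len(nrow(hi)), function(j) {
          any(as.numeric(lo$start) <= as.numeric(hi$start[j]) &
                as.numeric(lo$end) >= as.numeric(hi$end[j]))
        })
        expect_true(all(nested))
      }
    }
  }
})

test_that("consumption segmentation is idempotent on boundary readings", {
  set.seed(73)
  rr <- tibble::tibble(
    device_id = cooker,
    timestamp = ts("08:00:00") + sort(sample(1:5000, 30)),
    old_value = NA_integer_, new_value = NA_integer_,
    watts = round(runif(30, 0, 100), 2))
  ev <- extract_consumption_events(rr)
  # rebuild a minimal reading stream from the event boundaries: the opening
  # reading (>= 5 W) and the closing reading (< 5 W)
  rebuilt <- dplyr::bind_rows(
    tibble::tibble(device_id = cooker, timestamp = ev$start,
                   old_value = NA_integer_, new_value = NA_integer_,
                   watts = ev$max_watts),
    tibble::tibble(device_id = cooker, timestamp = ev$end,
                   old_value = NA_integer_, new_value = NA_integer_,
                   watts = 0))
  rebuilt <- dplyr::arrange(rebuilt, timestamp)
  ev2 <- extract_consumption_events(rebuilt)
  expect_equal(ev2[, c("start", "end")], ev[, c("start", "end")])
})

test_that("events serialize byte-stably to JSON lines and read back", {
  rr <- dplyr::bind_rows(
    signal_reading(motion, "10:00:00", 0, 1),
    signal_reading(motion, "10:30:00", 1, 0),
    watt_reading(cooker, "10:05:00", 900),
    watt_reading(cooker, "10:20:00", 0.4))
  ev <- extract_events(rr, devices)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_events(ev, f1); write_events(ev, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_events(f1)
  expect_equal(back, ev)
})
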