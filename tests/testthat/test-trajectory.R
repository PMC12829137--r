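test_that("read/write round-trips a rendition table", {
  traj <- pitch_trajectory(day = c(0, 0, 1), h = c(0.3, 0.4, 0.35),
                           pitch = c(990, 1005, 1001), subject = "b01")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$pitch, traj$pitch)
  expect_equal(back$day, traj$day)
  expect_equal(back$h, traj$h)
  expect_identical(attr(back, "meta")$subject, "b01")
  # a second round trip is byte-stable modulo float formatting
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(back, f2)
  expect_equal(read_trajectory(f2)$pitch, traj$pitch)
})

test_that("read_trajectory validates pitch and required columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("day,h,pitch_hz", "0,0.3,1000", "0,0.4,-5", "0,0.5,1000"), f)
  expect_error(read_trajectory(f), "row 2")
  writeLines(c("day,h,frequency", "0,0.3,1000"), f)
  expect_error(read_trajectory(f), "pitch")
})

test_that("ISO timestamps convert to day index and time fraction", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,pitch_hz",
               "2024-03-01T06:00:00,1000",
               "2024-03-01T18:00:00,1010",
               "2024-03-02T06:00:00,1005"), f)
  tr <- read_trajectory(f)
  expect_equal(tr$day, c(0L, 0L, 1L))
  expect_equal(tr$h, c(0.25, 0.75, 0.25))
})

test_that("trajectory invariants are enforced", {
  expect_error(pitch_trajectory(0, 0.5, 1000), "at least 2")
  expect_error(pitch_trajectory(c(0, 0), c(0.5, 0.4), c(1000, 1000)),
               "ordered")
  # hit without threshold
  expect_error(pitch_trajectory(c(0, 0), c(0.4, 0.5), c(1000, 1000),
                                hit = c(TRUE, NA)),
               "jointly")
  # hit flag contradicting the contingency
  expect_error(pitch_trajectory(c(0, 0), c(0.4, 0.5), c(900, 1100),
                                hit = c(FALSE, TRUE),
                                threshold = 1000, contingency = "low"),
               "inconsistent")
})

test_that("split separates a contiguous feedback suffix exactly", {
  thr <- c(rep(NA, 40), rep(995, 60))
  pitch <- c(seq(990, 1009.75, length.out = 100))
  tr <- pitch_trajectory(day = rep(0:4, each = 20),
                         h = rep(seq(0.3, 0.8, length.out = 20), 5),
                         pitch = pitch,
                         hit = ifelse(is.na(thr), NA, pitch < thr),
                         threshold = thr,
                         contingency = ifelse(is.na(thr), NA, "low"))
  sp <- split_baseline_feedback(tr)
  expect_equal(nrow(sp$baseline), 40)
  expect_equal(nrow(sp$feedback), 60)
  expect_true(all(is.na(sp$baseline$threshold)))
  expect_true(all(!is.na(sp$feedback$threshold)))
  expect_equal(rbind(as.data.frame(sp$baseline), as.data.frame(sp$feedback)),
               as.data.frame(tr), ignore_attr = TRUE)

  allb <- pitch_trajectory(c(0, 0), c(0.4, 0.5), c(1000, 1001))
  sp2 <- split_baseline_feedback(allb)
  expect_equal(nrow(sp2$baseline), 2)
  expect_equal(nrow(sp2$feedback), 0)

  bad <- tr
  bad$threshold[50] <- NA
  bad$hit[50] <- NA
  expect_error(split_baseline_feedback(bad), "contiguous")
})

test_that("history counts match a brute-force window count", {
  # 10 renditions 0.1 s apart: window of 2 s holds all predecessors
  h <- (3600 + seq(0, 0.9, by = 0.1)) / 86400
  tr <- pitch_trajectory(day = rep(0, 10), h = h, pitch = rep(1000, 10))
  expect_equal(history_counts(tr, x = 2, N_h = 5),
               c(0, 1, 2, 3, 4, 4, 4, 4, 4, 4))
  # brute force at irregular times
  set.seed(7)
  tt <- sort(3600 + cumsum(runif(40, 0.2, 4)))
  tr2 <- pitch_trajectory(day = rep(0, 40), h = tt / 86400,
                          pitch = rep(1000, 40))
  brute <- vapply(seq_along(tt), function(i)
    min(sum(tt > tt[i] - 2 & tt < tt[i]), 9L), numeric(1))
  expect_equal(history_counts(tr2, x = 2, N_h = 10), brute)
  # gap of 3 s empties the window; day boundaries reset the count
  h3 <- c(3600, 3600.5, 3604, 3604.5) / 86400
  tr3 <- pitch_trajectory(day = c(0, 0, 0, 1), h = h3[c(1, 2, 3, 1)],
                          pitch = rep(1000, 4))
  expect_equal(history_counts(tr3, x = 2, N_h = 5), c(0, 1, 0, 0))
  # counts depend on times only, not pitch
  tr4 <- tr2; tr4$pitch <- tr4$pitch + rnorm(40, 0, 30)
  expect_equal(history_counts(tr4, x = 2, N_h = 10),
               history_counts(tr2, x = 2, N_h = 10))
})
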