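test_that("a concentration peak yields a 4 x 60 window at the right frames", {
  rec <- flat_recording(duration_s = 540)
  rec$hr_bpm <- 70 + seq_len(5400) / 1000    # make frames identifiable
  samples <- extract_positive_samples(rec, concentration_events(150.0))
  expect_equal(nrow(samples), 1)
  m <- samples$signal[[1]]
  expect_equal(dim(m), c(4, 60))
  # 3 s before and after a peak at 150 s: frames 1471..1530 (1-based)
  expect_equal(unname(m["HR", ]), rec$hr_bpm[1471:1530])
  expect_equal(samples$klass, "concentrated")
  expect_equal(samples$origin_time_s, 150)
})

test_that("windows beyond the recording bounds or invalid spans are skipped", {
  rec <- flat_recording(duration_s = 540)
  s <- extract_positive_samples(rec, concentration_events(1.0))
  expect_equal(nrow(s), 0)
  expect_equal(attr(s, "n_skipped"), 1L)

  rec$hr_bpm[2000:2030] <- 400               # long artifact at 200 s
  filtered <- filter_artifacts(rec)
  s2 <- extract_positive_samples(filtered,
                                 concentration_events(c(150, 200, 300)))
  expect_equal(nrow(s2), 2)
  expect_setequal(s2$origin_time_s, c(150, 300))
})

test_that("two in-bounds events give two concentrated samples", {
  rec <- flat_recording(duration_s = 300)
  s <- extract_positive_samples(rec, concentration_events(c(100, 200)))
  expect_equal(nrow(s), 2)
  expect_true(all(s$klass == "concentrated"))
  expect_true(all(vapply(s$signal, ncol, integer(1)) == 60))
})

test_that("negative slots pack greedily around a mid-session peak", {
  # 300 s session, one peak at 150 s: eligible [1, 30] and [270, 300],
  # giving 2 + 3 slots of 6 s with 6 s gaps
  rec <- flat_recording(duration_s = 300)
  s <- extract_negative_samples(rec, concentration_events(150))
  expect_equal(nrow(s), 5)
  expect_equal(s$origin_time_s, c(1, 13, 270, 282, 294))
  expect_true(all(s$klass == "non_concentrated"))
})

test_that("an event-free minute fits five slots and a 5 s session none", {
  rec <- flat_recording(duration_s = 60)
  s <- extract_negative_samples(rec, concentration_events(numeric(0)))
  expect_equal(s$origin_time_s, c(1, 13, 25, 37, 49))

  tiny <- flat_recording(duration_s = 5)
  expect_equal(nrow(extract_negative_samples(tiny,
                                             concentration_events(numeric(0)))), 0)
})

test_that("emitted negative slots always satisfy every separation rule", {
  withr::with_seed(11, {
    for (case in 1:20) {
      dur <- sample(30:120, 1)
      n_peaks <- sample(0:3, 1)
      peaks <- sort(runif(n_peaks, 0, dur))
      gap <- sample(c(10, 20, 40), 1)
      rec <- flat_recording(duration_s = dur)
      s <- extract_negative_samples(rec, concentration_events(peaks),
                                    peak_gap_s = gap)
      if (nrow(s) == 0) next
      a <- s$origin_time_s
      b <- a + 6
      expect_true(all(a >= 1))                     # first-second exclusion
      expect_true(all(b <= dur + 1e-9))            # in bounds
      if (nrow(s) > 1) {
        expect_true(all(a[-1] - b[-length(b)] >= 6 - 1e-9))  # slot gap
      }
      for (p in peaks) {
        expect_true(all(p <= a - gap | p >= b + gap))
      }
    }
  })
})

test_that("greedy slot counts match the exhaustive-search maximum", {
  withr::with_seed(23, {
    for (case in 1:25) {
      dur <- sample(20:120, 1)
      peaks <- sort(runif(sample(0:3, 1), 0, dur))
      gap <- sample(c(5, 15, 30, 120), 1)
      rec <- flat_recording(duration_s = dur)
      got <- nrow(extract_negative_samples(rec, concentration_events(peaks),
                                           peak_gap_s = gap))
      want <- max_slots_exhaustive(dur * 10, 10, peaks, peak_gap_s = gap)
      expect_equal(got, want, info = sprintf("dur=%d gap=%d", dur, gap))
    }
  })
})

test_that("slots avoid invalidated artifact spans", {
  rec <- flat_recording(duration_s = 60)
  rec$hr_bpm[101:140] <- 400                  # 4 s artifact at 10-14 s
  filtered <- filter_artifacts(rec)
  s <- extract_negative_samples(filtered, concentration_events(numeric(0)))
  for (i in seq_len(nrow(s))) {
    expect_false(anyNA(s$signal[[i]]))
  }
  got <- nrow(s)
  valid <- !seq_len(600) %in% 101:140
  want <- max_slots_exhaustive(600, 10, numeric(0), valid = valid)
  expect_equal(got, want)
})

test_that("channel projection keeps requested rows in order", {
  rec <- flat_recording(duration_s = 300)
  rec$hr_bpm <- rec$hr_bpm + 1
  rec$st_c <- rec$st_c + 2
  s <- extract_positive_samples(rec, concentration_events(100))

  one <- project_channels(s, "ST")
  expect_equal(dim(one$signal[[1]]), c(1, 60))
  expect_equal(one$channels[[1]], "ST")

  all4 <- project_channels(s, c("HR", "BR", "SC", "ST"))
  expect_equal(all4$signal[[1]], s$signal[[1]])

  two <- project_channels(s, c("HR", "ST"))
  expect_equal(rownames(two$signal[[1]]), c("HR", "ST"))
  expect_equal(unname(two$signal[[1]][1, 1]), 71)

  # idempotent, and commutes with direct row selection
  expect_equal(project_channels(two, c("HR", "ST")), two)
  expect_equal(two$signal[[1]], s$signal[[1]][c("HR", "ST"), ])

  expect_error(project_channels(s, "XX"), "Unknown channel")
  expect_error(project_channels(s, character(0)), "at least one")
})

test_that("samples serialise to CSV matrices and back", {
  rec <- flat_recording(duration_s = 300)
  rec$br_bcpm <- 15 + sin(seq_len(3000) / 50)
  s <- dplyr::bind_rows(
    extract_positive_samples(rec, concentration_events(c(100, 200))),
    extract_negative_samples(rec, concentration_events(c(100, 200)),
                             peak_gap_s = 30)
  )
  dir <- withr::local_tempdir()
  write_samples(s, dir)
  back <- read_samples(dir)
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$klass, s$klass)
  for (i in seq_len(nrow(s))) {
    expect_equal(back$signal[[i]], s$signal[[i]], tolerance = 1e-12)
  }
})
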