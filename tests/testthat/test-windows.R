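test_that("timestamp windowing yields floor(duration/interval) complete windows", {
  g <- generateSequence(motionProfile(durationS = 185, fps = 5, seed = 2))
  expect_length(segmentWindows(g$seq, 30), 6L)     # floor(185 / 30)
  expect_length(segmentWindows(g$seq, 180), 1L)
  expect_length(segmentWindows(g$seq, 60), 3L)
  short <- g$seq[, timestamps(g$seq) <= 29000]
  expect_warning(w <- segmentWindows(short, 30),
                 class = "neomotion_short_sequence")
  expect_length(w, 0L)
  expect_error(segmentWindows(g$seq, -5),
               class = "neomotion_parameter_error")
})

test_that("windows are half-open, non-overlapping and boundary transitions fall outside", {
  g <- generateSequence(motionProfile(durationS = 65, fps = 5, seed = 4))
  wins <- segmentWindows(g$seq, 30)
  t0 <- timestamps(g$seq)[1]
  for (k in seq_along(wins)) {
    ts <- timestamps(wins[[k]])
    expect_true(all(ts >= t0 + (k - 1) * 30000 & ts < t0 + k * 30000))
  }
  # no frame is shared between windows
  allTs <- unlist(lapply(wins, timestamps))
  expect_equal(anyDuplicated(allTs), 0L)
  # whole-sequence total = window totals + the boundary steps they skip
  seqCover <- g$seq[, timestamps(g$seq) < t0 + 60000]
  whole <- motionValue(motionTotal(projectRegion(seqCover, "whole_body"),
                                   "euclidean"))
  winSum <- sum(vapply(wins[1:2], function(w)
    motionValue(motionTotal(projectRegion(w, "whole_body"),
                            "euclidean")), numeric(1)))
  lastIn1 <- max(which(timestamps(seqCover) < t0 + 30000))
  x <- poseCoords(seqCover, "x"); y <- poseCoords(seqCover, "y")
  z <- poseCoords(seqCover, "z")
  boundary <- sum(sqrt((x[, lastIn1 + 1] - x[, lastIn1])^2 +
                         (y[, lastIn1 + 1] - y[, lastIn1])^2 +
                         (z[, lastIn1 + 1] - z[, lastIn1])^2))
  expect_equal(whole, winSum + boundary, tolerance = 1e-12)
})

test_that("summary statistics follow the stated contracts", {
  s <- makeSummary(c(2, 4, 6))
  rec <- summaryRecord(s)
  expect_equal(rec$min_value, 2)
  expect_equal(rec$max_value, 6)
  expect_equal(rec$avg, 4)
  expect_equal(rec$median, 4)
  expect_equal(rec$std, sqrt(8 / 3), tolerance = 1e-12)  # population SD
  expect_equal(rec$n_windows, 3L)

  one <- makeSummary(5.5)
  expect_equal(windowValues(one), 5.5)
  expect_equal(summaryRecord(one)$std, 0)
  expect_equal(summaryRecord(one)$min_value,
               summaryRecord(one)$max_value)
})

test_that("summarizeMovement applies quantifiers per window and errors when none fit", {
  g <- generateSequence(motionProfile(durationS = 95, fps = 5, seed = 6))
  ms <- summarizeMovement(g$seq, 30, "whole_body", "euclidean")
  expect_s4_class(ms, "MovementSummary")
  expect_length(windowValues(ms), 3L)
  wins <- segmentWindows(projectRegion(g$seq, "whole_body"), 30)
  direct <- vapply(wins, function(w)
    motionValue(motionTotal(w, "euclidean")), numeric(1))
  expect_equal(windowValues(ms), direct, tolerance = 1e-12)

  frozen <- generateSequence(motionProfile(amplitudes = 0, jitterSD = 0,
                                           durationS = 65, fps = 5,
                                           seed = 1))
  mz <- summarizeMovement(frozen$seq, 30, "head", "manhattan")
  expect_equal(windowValues(mz), c(0, 0))

  expect_error(summarizeMovement(g$seq, 300, "head", "euclidean"),
               class = "neomotion_empty_summary")
})

test_that("emitSummaryFiles writes the full combinatorial grid with the exact schema", {
  outdir <- file.path(tempdir(), "emit648")
  unlink(outdir, recursive = TRUE)
  cohort <- lapply(1:2, function(i)
    generateSequence(motionProfile(durationS = 185, fps = 2, seed = i),
                     subjectID = sprintf("s%02d", i))$seq)
  n <- emitSummaryFiles(cohort, outdir = outdir)
  expect_equal(as.integer(n), 2L * 4L * 9L * 9L)    # 648
  files <- list.files(outdir, pattern = "\\.json$")
  expect_length(files, 648L)
  expect_true("s01__30s__lower_body__minkowski.json" %in% files)

  rec <- jsonlite::fromJSON(file.path(outdir,
                                      "s01__60s__trunk__euclidean.json"))
  expect_named(rec, c("subject", "interval_s", "region", "method",
                      "values", "min_value", "max_value", "avg", "std",
                      "median", "n_windows"))
  # persisted statistics reproduce exactly from the persisted values
  v <- as.numeric(rec$values)
  expect_identical(rec$min_value, min(v))
  expect_identical(rec$max_value, max(v))
  expect_equal(rec$avg, mean(v), tolerance = 1e-12)
  expect_equal(rec$std, sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
  expect_equal(rec$median, median(v), tolerance = 1e-12)
  expect_equal(rec$n_windows, length(v))

  # the cached farneback fast path equals the direct computation
  fb <- jsonlite::fromJSON(
    file.path(outdir, "s02__60s__head__farneback.json"))
  direct <- summarizeMovement(cohort[[2]], 60, "head", "farneback")
  expect_equal(as.numeric(fb$values), windowValues(direct),
               tolerance = 1e-12)
})

test_that("a single combination writes one file and the count formula holds", {
  outdir <- file.path(tempdir(), "emit1")
  unlink(outdir, recursive = TRUE)
  g <- generateSequence(motionProfile(durationS = 35, fps = 5, seed = 3),
                        subjectID = "solo")
  n <- emitSummaryFiles(list(solo = g$seq), intervals = 30,
                        regions = "whole_body", methods = "chebyshev",
                        outdir = outdir)
  expect_equal(as.integer(n), 1L)
  expect_true(file.exists(
    file.path(outdir, "solo__30s__whole_body__chebyshev.json")))
})
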