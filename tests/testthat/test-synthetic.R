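test_that("generation is deterministic and honors frozen profiles", {
  p <- motionProfile(durationS = 12, seed = 99)
  a <- generateSequence(p)
  b <- generateSequence(p)
  expect_identical(poseCoords(a$seq, "x"), poseCoords(b$seq, "x"))
  expect_identical(timestamps(a$seq), timestamps(b$seq))
  expect_equal(a$truth$totalPathLength, b$truth$totalPathLength)

  frozen <- generateSequence(motionProfile(amplitudes = 0, jitterSD = 0,
                                           smoothAmp = 0, durationS = 12,
                                           seed = 1))
  expect_equal(frozen$truth$totalPathLength, 0)
  for (m in c("euclidean", "diffacc", "angular"))
    expect_equal(motionValue(motionTotal(frozen$seq, m)), 0, label = m)
})

test_that("ground-truth path length equals the Euclidean total exactly", {
  for (seed in c(5, 23)) {
    g <- generateSequence(motionProfile(durationS = 20, seed = seed))
    mt <- motionTotal(g$seq, "euclidean")
    expect_equal(motionValue(mt), g$truth$totalPathLength,
                 tolerance = 1e-14)
    perRegion <- projectRegion(g$seq, "lower_body")
    idx <- regionIndices("lower_body") + 1L
    expect_equal(motionValue(motionTotal(perRegion, "euclidean")),
                 sum(g$truth$pathLength[idx]), tolerance = 1e-14)
  }
})

test_that("timestamps follow the frame clock and coordinates stay in range", {
  p <- motionProfile(durationS = 10, fps = 4, seed = 3)
  g <- generateSequence(p)
  expect_equal(timestamps(g$seq), round(seq_len(40) * 250))
  expect_true(all(poseCoords(g$seq, "x") >= 0 &
                    poseCoords(g$seq, "x") <= 1))
  expect_true(all(poseCoords(g$seq, "y") >= 0 &
                    poseCoords(g$seq, "y") <= 1))
  expect_equal(frameRate(g$seq), 4)
  # default amplitudes keep clipping negligible
  g2 <- generateSequence(motionProfile(durationS = 185, seed = 17))
  expect_lt(g2$truth$nClipped / (33 * 2 * nFrames(g2$seq)), 0.001)
})

test_that("larger part amplitudes yield larger quantified movement", {
  p <- motionProfile(amplitudes = c(left_arm = 1.0, right_arm = 0.25),
                     durationS = 60, seed = 7)
  g <- generateSequence(p)
  for (m in c("euclidean", "manhattan", "chebyshev", "minkowski")) {
    left <- motionValue(motionTotal(projectRegion(g$seq, "left_arm"), m))
    right <- motionValue(motionTotal(projectRegion(g$seq, "right_arm"), m))
    expect_gt(left, right, label = m)
  }
})

test_that("per-window Euclidean totals grow linearly with window duration", {
  g <- generateSequence(motionProfile(smoothAmp = 0, durationS = 1300,
                                      seed = 29))
  m30 <- mean(windowValues(summarizeMovement(g$seq, 30, "whole_body",
                                             "euclidean")))
  m60 <- mean(windowValues(summarizeMovement(g$seq, 60, "whole_body",
                                             "euclidean")))
  expect_equal(m60 / m30, 2, tolerance = 0.05)
})

test_that("cohort generation pairs sessions with shared subject effects", {
  ep <- motionProfile(amplitudes = 0.4, durationS = 12)
  lp <- motionProfile(amplitudes = 0.8, durationS = 12)
  cohort <- generateCohort(3, ep, lp, seed = 5, subjectEffectSD = 0.2)
  expect_length(cohort, 3L)
  expect_named(cohort, c("subj01", "subj02", "subj03"))
  s1 <- cohort$subj01
  expect_equal(subjectID(s1$early), "subj01_early")
  # the same lognormal effect scales both sessions
  expect_equal(s1$truth$late$amplitudes / s1$truth$early$amplitudes,
               rep(2, 6), ignore_attr = TRUE, tolerance = 1e-12)
  # zero effect SD: every subject effect is exactly 1
  flat <- generateCohort(3, ep, lp, seed = 5, subjectEffectSD = 0)
  expect_equal(vapply(flat, function(s) s$truth$subjectEffect,
                      numeric(1)),
               rep(1, 3), ignore_attr = TRUE)
  # determinism under the master seed
  again <- generateCohort(3, ep, lp, seed = 5, subjectEffectSD = 0.2)
  expect_identical(poseCoords(again$subj02$late, "x"),
                   poseCoords(cohort$subj02$late, "x"))
})

test_that("occlusion invalidates only the target region's quantification", {
  g <- generateSequence(motionProfile(durationS = 20, seed = 13))
  expect_identical(occludeRegion(g$seq, "lower_body", 0), g$seq)

  full <- occludeRegion(g$seq, "lower_body", 1, seed = 2)
  expect_error(motionTotal(projectRegion(full, "lower_body"),
                           "euclidean"),
               class = "neomotion_insufficient_data")
  # upper body is untouched
  expect_equal(
    motionValue(motionTotal(projectRegion(full, "upper_body"),
                            "euclidean")),
    motionValue(motionTotal(projectRegion(g$seq, "upper_body"),
                            "euclidean")), tolerance = 1e-14)

  half1 <- occludeRegion(g$seq, "left_leg", 0.5, seed = 11)
  half2 <- occludeRegion(g$seq, "left_leg", 0.5, seed = 11)
  expect_identical(poseCoords(half1, "x"), poseCoords(half2, "x"))
  expect_equal(sum(!is.finite(poseCoords(half1, "x")["left_knee", ])),
               round(0.5 * nFrames(g$seq)))
  # partially occluded frames are dropped, the rest still quantifies
  mt <- motionTotal(projectRegion(half1, "left_leg"), "euclidean")
  expect_gt(motionValue(mt), 0)
  expect_equal(motionFlags(mt)$nInvalidFrames, round(0.5 * nFrames(g$seq)))
})
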