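test_that("per-step distances match their closed forms and ordering", {
  expect_equal(stepEuclidean(c(0, 0, 0)), 0)
  expect_equal(stepEuclidean(c(1, 2, 2)), 3)
  expect_equal(stepManhattan(c(1, -2, 2)), 5)
  expect_equal(stepChebyshev(c(1, -2, 2)), 2)
  expect_equal(stepChebyshev(c(0, 0, 0)), 0)
  expect_equal(stepMinkowski(c(1, -2, 2), p = 1), 5)
  expect_error(stepMinkowski(c(1, 0, 0), p = 0.5),
               class = "neomotion_parameter_error")
  # large p approaches the Chebyshev limit
  expect_lt(abs(stepMinkowski(c(1, -2, 2), p = 64) - 2), 0.05)

  set.seed(42)
  d <- matrix(rnorm(900), ncol = 3)
  expect_equal(stepMinkowski(d, p = 2), stepEuclidean(d),
               tolerance = 1e-14)
  expect_equal(stepMinkowski(d, p = 1), stepManhattan(d),
               tolerance = 1e-14)
  expect_true(all(stepChebyshev(d) <= stepEuclidean(d) + 1e-15))
  expect_true(all(stepEuclidean(d) <= stepManhattan(d) + 1e-15))
  expect_equal(stepMahalanobis(d, diag(3)), stepEuclidean(d),
               tolerance = 1e-14)
  expect_equal(stepMahalanobis(c(1, 2, 2), 4 * diag(3)), 1.5)
})

test_that("every quantifier is zero on a constant sequence and positive on motion", {
  const <- makePose(matrix(0.4, 2, 12), matrix(0.6, 2, 12),
                    matrix(0.1, 2, 12))
  moving <- randomWalkPose(n = 12, L = 2, seed = 5)
  for (m in methodNames()) {
    prm <- if (m == "farneback") list(render = list(width = 32L,
                                                    height = 32L)) else list()
    expect_equal(motionValue(motionTotal(const, m, prm)), 0, label = m)
    expect_gt(motionValue(motionTotal(moving, m, prm)), 0, label = m)
  }
})

test_that("a single 3-4-5 step gives Euclidean total 0.5", {
  ps <- makePose(c(0.1, 0.4), c(0.1, 0.5))
  mt <- motionTotal(ps, "euclidean")
  expect_equal(motionValue(mt), 0.5)
  expect_equal(nSteps(mt), 1L)
})

test_that("distance totals equal the naive double-loop oracle on random sequences", {
  for (seed in 1:3) {
    ps <- randomWalkPose(n = 20, L = 4, seed = seed)
    expect_equal(motionValue(motionTotal(ps, "manhattan")),
                 naivePairwiseTotal(ps, stepManhattan), tolerance = 1e-12)
    expect_equal(motionValue(motionTotal(ps, "euclidean")),
                 naivePairwiseTotal(ps, stepEuclidean), tolerance = 1e-12)
    expect_equal(motionValue(motionTotal(ps, "chebyshev")),
                 naivePairwiseTotal(ps, stepChebyshev), tolerance = 1e-12)
    expect_equal(motionValue(motionTotal(ps, "minkowski",
                                         list(minkowskiP = 3))),
                 naivePairwiseTotal(ps, function(d)
                   stepMinkowski(d, 3)), tolerance = 1e-12)
    cov <- fitCovariance(ps)
    expect_equal(motionValue(motionTotal(ps, "mahalanobis")),
                 naivePairwiseTotal(ps, function(d)
                   stepMahalanobis(d, cov)), tolerance = 1e-10)
  }
})

test_that("Minkowski totals reduce to Manhattan (p=1) and Euclidean (p=2)", {
  ps <- randomWalkPose(n = 25, L = 3, seed = 9)
  man <- motionValue(motionTotal(ps, "manhattan"))
  euc <- motionValue(motionTotal(ps, "euclidean"))
  expect_equal(motionValue(motionTotal(ps, "minkowski",
                                       list(minkowskiP = 1))), man,
               tolerance = 1e-12)
  expect_equal(motionValue(motionTotal(ps, "minkowski",
                                       list(minkowskiP = 2))), euc,
               tolerance = 1e-12)
  # identity covariance forces the Mahalanobis total onto the Euclidean
  expect_equal(motionValue(motionTotal(ps, "mahalanobis",
                                       list(mahalanobisCov = diag(3)))),
               euc, tolerance = 1e-12)
})

test_that("covariance fitting recovers isotropy, flags degeneracy, ridges rank deficiency", {
  set.seed(7)
  iso <- matrix(rnorm(30000, sd = 0.2), ncol = 3)
  cm <- fitCovariance(iso)
  expect_false(covFlagged(cm))
  S <- covMatrix(cm)
  expect_true(all(abs(diag(S) - 0.04) < 0.004))        # within 10%
  expect_true(all(abs(S[upper.tri(S)]) < 0.004))

  flat <- fitCovariance(matrix(0.3, 50, 3))
  expect_true(covFlagged(flat))
  expect_equal(covMatrix(flat), diag(3))

  line <- matrix(rnorm(500), ncol = 1) %*% t(c(1, 2, 3))
  cl <- fitCovariance(line)
  expect_gt(covRidge(cl), 0)
  d <- stepMahalanobis(c(1, 0, 0), cl)    # invertible after ridge
  expect_true(is.finite(d))

  set.seed(8)
  A <- matrix(rnorm(9), 3); Spd <- crossprod(A) + diag(3) * 0.1
  dd <- matrix(rnorm(30), ncol = 3)
  expect_equal(stepMahalanobis(dd, Spd),
               apply(dd, 1, function(v)
                 sqrt(drop(t(v) %*% solve(Spd) %*% v))),
               tolerance = 1e-12)
})

test_that("differential acceleration matches hand evaluation and vanishes on uniform motion", {
  # one landmark, x steps 0, 0, 0.1 at 10 fps: |(0.1 - 0) * 10| = 1
  ps2 <- makePose(c(0.2, 0.2, 0.3), rep(0.5, 3), ts = c(100, 200, 300))
  expect_equal(motionValue(differentialAcceleration(ps2, fps = 10)), 1)
  # uniform linear motion: second difference is zero
  lin <- makePose(seq(0.1, 0.5, length.out = 9), rep(0.5, 9))
  expect_equal(motionValue(motionTotal(lin, "diffacc")), 0)
  # triple-loop oracle on a random walk
  ps <- randomWalkPose(n = 15, L = 3, seed = 21)
  x <- poseCoords(ps, "x"); y <- poseCoords(ps, "y"); z <- poseCoords(ps, "z")
  fps <- frameRate(ps)
  total <- 0
  for (i in 2:(ncol(x) - 1)) {
    for (l in seq_len(nrow(x))) {
      for (m in list(x, y, z)) {
        v1 <- (m[l, i] - m[l, i - 1]) * fps
        v2 <- (m[l, i + 1] - m[l, i]) * fps
        total <- total + abs(v2 - v1)
      }
    }
  }
  expect_equal(motionValue(motionTotal(ps, "diffacc")), total,
               tolerance = 1e-12)
})

test_that("angular displacement measures turning angles in radians", {
  # collinear motion: no turning
  lin <- makePose(seq(0.1, 0.6, length.out = 6), rep(0.5, 6))
  expect_equal(motionValue(motionTotal(lin, "angular")), 0)
  # one right-angle turn in the xy plane
  turn <- makePose(c(0.2, 0.3, 0.3), c(0.5, 0.5, 0.6))
  expect_equal(motionValue(motionTotal(turn, "angular")), pi / 2,
               tolerance = 1e-12)
  # atan2-based alternative formula oracle
  ps <- randomWalkPose(n = 18, L = 3, seed = 13)
  x <- poseCoords(ps, "x"); y <- poseCoords(ps, "y"); z <- poseCoords(ps, "z")
  total <- 0
  for (i in 2:(ncol(x) - 1)) {
    for (l in seq_len(nrow(x))) {
      a <- c(x[l, i] - x[l, i - 1], y[l, i] - y[l, i - 1],
             z[l, i] - z[l, i - 1])
      b <- c(x[l, i + 1] - x[l, i], y[l, i + 1] - y[l, i],
             z[l, i + 1] - z[l, i])
      cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
      total <- total + abs(atan2(sqrt(sum(cr^2)), sum(a * b)))
    }
  }
  expect_equal(motionValue(motionTotal(ps, "angular")), total,
               tolerance = 1e-9)
})

test_that("Lucas-Kanade solves the stencil system by pseudoinverse", {
  skip_if_not_installed("MASS")
  # constant sequence: zero velocity everywhere
  const <- makePose(matrix(0.4, 2, 8), matrix(0.6, 2, 8))
  expect_equal(motionValue(motionTotal(const, "lucas_kanade")), 0)
  # uniform translation: per-stencil speed strictly positive, constant
  n <- 7
  tr <- makePose(0.2 + (0:(n - 1)) * 0.01, 0.3 + (0:(n - 1)) * 0.004)
  per <- motionValue(motionTotal(tr[, 1:3], "lucas_kanade"))
  expect_gt(per, 0)
  expect_equal(motionValue(motionTotal(tr, "lucas_kanade")),
               (n - 2) * per, tolerance = 1e-12)
  # literal Eq-by-Eq oracle with an explicit pseudoinverse
  ps <- randomWalkPose(n = 16, L = 3, seed = 31)
  x <- poseCoords(ps, "x"); y <- poseCoords(ps, "y"); z <- poseCoords(ps, "z")
  total <- 0
  for (i in 2:(ncol(x) - 1)) {
    for (l in seq_len(nrow(x))) {
      g <- c(x[l, i + 1] - x[l, i - 1], y[l, i + 1] - y[l, i - 1],
             z[l, i + 1] - z[l, i - 1]) / 2
      b <- c(x[l, i + 1] - x[l, i], y[l, i + 1] - y[l, i],
             z[l, i + 1] - z[l, i])
      A <- rbind(g, g, g)
      v <- MASS::ginv(A) %*% b
      total <- total + sqrt(sum(v^2))
    }
  }
  expect_equal(motionValue(motionTotal(ps, "lucas_kanade")), total,
               tolerance = 1e-9)
})

test_that("pairwise totals are additive over windows sharing a boundary frame", {
  ps <- randomWalkPose(n = 30, L = 3, seed = 17)
  for (m in c("euclidean", "manhattan", "chebyshev", "minkowski")) {
    whole <- motionValue(motionTotal(ps, m))
    left <- motionValue(motionTotal(ps[, 1:12], m))
    right <- motionValue(motionTotal(ps[, 12:30], m))
    expect_equal(whole, left + right, tolerance = 1e-12, label = m)
  }
})

test_that("distance totals are invariant to a constant offset of every frame", {
  ps <- randomWalkPose(n = 20, L = 3, seed = 23, stepSD = 0.002)
  shift <- function(seq, dx, dy, dz) {
    PoseSequence(poseCoords(seq, "x") + dx, poseCoords(seq, "y") + dy,
                 poseCoords(seq, "z") + dz, timestamps(seq),
                 subjectID = subjectID(seq), region = regionName(seq))
  }
  shifted <- shift(ps, 0.11, -0.07, 0.4)
  for (m in c("euclidean", "manhattan", "chebyshev", "minkowski",
              "mahalanobis", "diffacc", "angular")) {
    expect_equal(motionValue(motionTotal(shifted, m)),
                 motionValue(motionTotal(ps, m)), tolerance = 1e-9,
                 label = m)
  }
})

test_that("transitions across recording dropouts are excluded from totals", {
  x <- 0.2 + cumsum(rep(0.01, 10))
  ts <- c(100, 200, 300, 400, 500, 2500, 2600, 2700, 2800, 2900)
  ps <- makePose(x, rep(0.5, 10), ts = ts)
  mt <- motionTotal(ps, "euclidean")
  expect_equal(motionFlags(mt)$nExcluded, 1L)
  expect_equal(motionValue(mt), 8 * 0.01, tolerance = 1e-12)
  # with a generous gap factor nothing is excluded
  all10 <- motionTotal(ps, "euclidean", list(gapFactor = 100))
  expect_equal(motionValue(all10), 9 * 0.01, tolerance = 1e-12)
})

test_that("too-few frames and unknown methods raise classed errors", {
  two <- makePose(c(0.1, 0.2), c(0.1, 0.2))
  expect_error(motionTotal(two, "angular"),
               class = "neomotion_insufficient_data")
  expect_error(motionTotal(two[, 1], "euclidean"),
               class = "neomotion_insufficient_data")
  expect_error(motionTotal(two, "warp"))
})
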