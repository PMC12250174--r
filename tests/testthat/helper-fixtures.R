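# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# PoseSequence from landmark x frames coordinate matrices (or vectors
# for a single landmark). Timestamps default to a uniform 10 fps clock.
makePose <- function(x, y, z = NULL, ts = NULL, subject = "fix",
                     region = "test") {
  toMat <- function(m) {
    m <- if (is.matrix(m)) m else matrix(m, nrow = 1)
    dimnames(m) <- NULL
    m
  }
  x <- toMat(x); y <- toMat(y)
  z <- if (is.null(z)) matrix(0, nrow(x), ncol(x)) else toMat(z)
  if (is.null(ts)) ts <- seq_len(ncol(x)) * 100
  PoseSequence(x, y, z, ts, subjectID = subject, region = region)
}

# random-walk sequence with L landmarks and n frames (small steps keep
# coordinates in [0, 1])
randomWalkPose <- function(n = 20, L = 3, seed = 1, stepSD = 0.005,
                           fpsMs = 100) {
  set.seed(seed)
  mk <- function(center) {
    t(vapply(seq_len(L), function(i)
      center + cumsum(rnorm(n, 0, stepSD)), numeric(n)))
  }
  makePose(mk(0.5), mk(0.5), mk(0), ts = seq_len(n) * fpsMs)
}

# full 33-landmark random-walk sequence (named rows, projectable)
randomWalkPose33 <- function(n = 20, seed = 1, stepSD = 0.003,
                             fpsMs = 200) {
  set.seed(seed)
  base <- neutralPose()
  mk <- function(d) {
    m <- matrix(0, 33, n)
    for (l in 1:33) m[l, ] <- base[l, d] + cumsum(rnorm(n, 0, stepSD))
    m
  }
  PoseSequence(mk(1), mk(2), mk(3), seq_len(n) * fpsMs,
               subjectID = "rw33")
}

# landmark CSV text in the tuple dialect; coords is a list of per-row
# length-33 lists of c(x, y, z)
writeTupleCSV <- function(path, timestamps, rows) {
  hdr <- paste(c("timestamp", paste0("landmark_", 0:32)), collapse = ",")
  lines <- vapply(seq_along(timestamps), function(i) {
    cells <- vapply(rows[[i]], function(p)
      sprintf("\"(%g,%g,%g)\"", p[1], p[2], p[3]), character(1))
    paste(c(format(timestamps[i], scientific = FALSE), cells),
          collapse = ",")
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

# one CSV row: 33 identical points, optionally overriding one landmark
uniformRow <- function(x = 0.5, y = 0.5, z = 0, override = NULL) {
  row <- rep(list(c(x, y, z)), 33)
  if (!is.null(override)) row[[override$index + 1L]] <- override$point
  row
}

# MovementSummary with prescribed window values, built via the public
# JSON round trip
makeSummary <- function(values, subject = "s1", interval = 30,
                        region = "whole_body", method = "euclidean") {
  fp <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(subject = subject, interval_s = interval, region = region,
         method = method, values = values, min_value = min(values),
         max_value = max(values), avg = mean(values), std = 0,
         median = median(values), n_windows = length(values)),
    fp, auto_unbox = TRUE, digits = NA)
  readSummaryJSON(fp)
}

# naive per-step oracle for the pairwise distance quantifiers
naivePairwiseTotal <- function(seq, stepFun) {
  x <- poseCoords(seq, "x"); y <- poseCoords(seq, "y")
  z <- poseCoords(seq, "z")
  total <- 0
  for (t in seq_len(ncol(x) - 1)) {
    for (l in seq_len(nrow(x))) {
      d <- c(x[l, t + 1] - x[l, t], y[l, t + 1] - y[l, t],
             z[l, t + 1] - z[l, t])
      total <- total + stepFun(d)
    }
  }
  total
}
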