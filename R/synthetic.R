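#' MotionProfile: parameters of the synthetic motion generator
#'
#' @description
#' Describes a statistically controlled synthetic pose recording:
#' 33 landmarks around a plausible supine-infant neutral pose, each
#' moving as *base + amplitude x (sinusoid + Gaussian random-walk
#' jitter)*. The jitter is a random walk (not i.i.d. noise about the
#' base) so expected path length grows linearly with observation time —
#' the stationary regime in which per-window movement totals are
#' proportional to window duration. Amplitudes are set per body part
#' over the partition head / arms / trunk / legs, so region-resolved
#' quantifiers can be validated against known ground truth.
#'
#' Defaults describe the emulated study conditions: 5 frames per
#' second landmark logging, 185 s sessions, per-frame jitter step SD
#' 0.003 (normalized image units) and amplitude 0.5 for every part —
#' small enough that clipping to \[0, 1\] is negligible.
#'
#' @name MotionProfile-class
#' @aliases MotionProfile
#' @exportClass MotionProfile
setClass("MotionProfile", representation(
  amplitudes = "numeric", smoothFreqHz = "numeric", smoothAmp = "numeric",
  jitterSD = "numeric", fps = "numeric", durationS = "numeric",
  seed = "integer"))

setValidity("MotionProfile", function(object) {
  msgs <- character()
  if (any(object@amplitudes < 0)) msgs <- c(msgs, "amplitudes must be >= 0")
  if (object@fps <= 0) msgs <- c(msgs, "fps must be > 0")
  if (object@durationS <= 0) msgs <- c(msgs, "durationS must be > 0")
  if (object@jitterSD < 0) msgs <- c(msgs, "jitterSD must be >= 0")
  if (length(msgs)) msgs else TRUE
})

# Amplitude partition: every landmark belongs to exactly one part
# (shoulders and hips count as trunk, the rest of each limb as the limb).
.AMPLITUDE_PARTS <- list(
  head      = 0:10,
  left_arm  = c(13L, 15L, 17L, 19L, 21L),
  right_arm = c(14L, 16L, 18L, 20L, 22L),
  trunk     = c(11L, 12L, 23L, 24L),
  left_leg  = c(25L, 27L, 29L, 31L),
  right_leg = c(26L, 28L, 30L, 32L))

#' Construct a synthetic motion profile
#'
#' @param amplitudes named numeric vector of per-part motion
#'   amplitudes; parts are `head`, `left_arm`, `right_arm`, `trunk`,
#'   `left_leg`, `right_leg`. Unnamed scalar = same amplitude for all
#'   parts. Missing parts default to 0.5.
#' @param smoothFreqHz frequency of the smooth sinusoidal component.
#' @param smoothAmp amplitude of the sinusoid (normalized units).
#' @param jitterSD per-frame SD of the Gaussian random-walk step
#'   (normalized units).
#' @param fps frame rate of the emulated recording (frames/second).
#' @param durationS session length in seconds.
#' @param seed integer seed; generation is fully deterministic given
#'   the profile.
#' @return A [MotionProfile-class].
#' @examples
#' motionProfile(jitterSD = 0, amplitudes = 0)   # a frozen pose
#' @export
motionProfile <- function(amplitudes = 0.5, smoothFreqHz = 0.25,
                          smoothAmp = 0.01, jitterSD = 0.003, fps = 5,
                          durationS = 185, seed = 1L) {
  parts <- names(.AMPLITUDE_PARTS)
  amp <- rep(0.5, length(parts)); names(amp) <- parts
  if (is.null(names(amplitudes))) {
    amp[] <- amplitudes
  } else {
    bad <- setdiff(names(amplitudes), parts)
    if (length(bad))
      .nmStop("neomotion_lookup_error", "unknown part(s): %s",
              paste(bad, collapse = ", "))
    amp[names(amplitudes)] <- amplitudes
  }
  new("MotionProfile", amplitudes = amp, smoothFreqHz = smoothFreqHz,
      smoothAmp = smoothAmp, jitterSD = jitterSD, fps = fps,
      durationS = durationS, seed = as.integer(seed))
}

# Neutral supine-infant pose: 33 (x, y, z) rows, normalized coordinates.
# Infant lies head-up in the image center; exact values are arbitrary
# but anatomically ordered.
.neutralPose <- function() {
  m <- matrix(c(
    # x,    y,     z
    0.50, 0.15, -0.05,   # 0 nose
    0.52, 0.13, -0.05,   # 1 left_eye_inner
    0.53, 0.13, -0.05,   # 2 left_eye
    0.54, 0.13, -0.05,   # 3 left_eye_outer
    0.48, 0.13, -0.05,   # 4 right_eye_inner
    0.47, 0.13, -0.05,   # 5 right_eye
    0.46, 0.13, -0.05,   # 6 right_eye_outer
    0.56, 0.14, -0.02,   # 7 left_ear
    0.44, 0.14, -0.02,   # 8 right_ear
    0.52, 0.18, -0.04,   # 9 mouth_left
    0.48, 0.18, -0.04,   # 10 mouth_right
    0.62, 0.30,  0.00,   # 11 left_shoulder
    0.38, 0.30,  0.00,   # 12 right_shoulder
    0.68, 0.42,  0.02,   # 13 left_elbow
    0.32, 0.42,  0.02,   # 14 right_elbow
    0.70, 0.52, -0.02,   # 15 left_wrist
    0.30, 0.52, -0.02,   # 16 right_wrist
    0.72, 0.56, -0.03,   # 17 left_pinky
    0.28, 0.56, -0.03,   # 18 right_pinky
    0.71, 0.57, -0.03,   # 19 left_index
    0.29, 0.57, -0.03,   # 20 right_index
    0.69, 0.55, -0.02,   # 21 left_thumb
    0.31, 0.55, -0.02,   # 22 right_thumb
    0.58, 0.55,  0.00,   # 23 left_hip
    0.42, 0.55,  0.00,   # 24 right_hip
    0.60, 0.70,  0.02,   # 25 left_knee
    0.40, 0.70,  0.02,   # 26 right_knee
    0.58, 0.83,  0.01,   # 27 left_ankle
    0.42, 0.83,  0.01,   # 28 right_ankle
    0.57, 0.86,  0.02,   # 29 left_heel
    0.43, 0.86,  0.02,   # 30 right_heel
    0.59, 0.88, -0.01,   # 31 left_foot_index
    0.41, 0.88, -0.01),  # 32 right_foot_index
    ncol = 3, byrow = TRUE)
  dimnames(m) <- list(.LANDMARK_NAMES, c("x", "y", "z"))
  m
}

#' Neutral pose table used by the generator
#'
#' @return 33-by-3 matrix of (x, y, z) coordinates of the supine
#'   neutral pose.
#' @export
neutralPose <- function() .neutralPose()

# run code under a local RNG state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic landmark sequence with ground truth
#'
#' @param profile a [MotionProfile-class].
#' @param subjectID subject identifier for the generated sequence.
#' @return List with elements:
#' * `seq`: a [PoseSequence-class]; timestamps are
#'   `round(i * 1000 / fps)` for frames `i = 1..n`;
#' * `truth`: list with `pathLength` (per-landmark Euclidean path
#'   length of the generated trajectory, computed after clipping, so it
#'   matches the Euclidean quantifier exactly), `totalPathLength`,
#'   `nClipped` (coordinate values clipped into \[0, 1\]) and
#'   `amplitudes`.
#' @examples
#' g <- generateSequence(motionProfile(durationS = 10, seed = 42))
#' nFrames(g$seq)   # 50
#' @export
generateSequence <- function(profile, subjectID = "synthetic") {
  stopifnot(is(profile, "MotionProfile"))
  n <- round(profile@durationS * profile@fps)
  ts <- round(seq_len(n) * 1000 / profile@fps)
  ampPerLm <- numeric(33)
  for (part in names(.AMPLITUDE_PARTS))
    ampPerLm[.AMPLITUDE_PARTS[[part]] + 1L] <- profile@amplitudes[[part]]
  base <- .neutralPose()
  tSec <- ts / 1000
  coords <- .withSeed(profile@seed, {
    out <- list(x = matrix(0, 33, n), y = matrix(0, 33, n),
                z = matrix(0, 33, n))
    for (l in 1:33) {
      for (d in 1:3) {
        phase <- runif(1, 0, 2 * pi)
        sinus <- profile@smoothAmp *
          sin(2 * pi * profile@smoothFreqHz * tSec + phase)
        walk <- cumsum(rnorm(n, 0, profile@jitterSD))
        path <- base[l, d] + ampPerLm[l] * (sinus + walk)
        out[[d]][l, ] <- path
      }
    }
    out
  })
  nClipped <- sum(coords$x < 0 | coords$x > 1) +
    sum(coords$y < 0 | coords$y > 1)
  coords$x <- pmin(pmax(coords$x, 0), 1)
  coords$y <- pmin(pmax(coords$y, 0), 1)
  seq <- PoseSequence(coords$x, coords$y, coords$z, ts,
                      subjectID = subjectID)
  dx <- coords$x[, -1, drop = FALSE] - coords$x[, -n, drop = FALSE]
  dy <- coords$y[, -1, drop = FALSE] - coords$y[, -n, drop = FALSE]
  dz <- coords$z[, -1, drop = FALSE] - coords$z[, -n, drop = FALSE]
  pathLength <- rowSums(sqrt(dx^2 + dy^2 + dz^2))
  list(seq = seq,
       truth = list(pathLength = pathLength,
                    totalPathLength = sum(pathLength),
                    nClipped = nClipped,
                    amplitudes = profile@amplitudes))
}

#' Generate a paired admission/discharge synthetic cohort
#'
#' Per subject, one "near admission" (early) and one "near discharge"
#' (late) sequence. A per-subject lognormal random effect multiplies
#' both sessions' amplitudes, so between-subject variability does not
#' bias the within-subject percent change; the expected recovered mean
#' percent change for amplitude ratio `r` is `100 * (r - 1)` in the
#' jitter-dominated regime.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param earlyProfile,lateProfile [MotionProfile-class] objects for
#'   the two sessions (their `seed` slots are ignored; per-sequence
#'   seeds are derived from `seed`).
#' @param seed integer master seed.
#' @param subjectEffectSD SD of the lognormal per-subject amplitude
#'   effect (0 = identical subjects).
#' @return Named list (one element per subject) of lists with
#'   `subject`, `early`, `late` ([PoseSequence-class]) and `truth`
#'   (early/late generator truth plus the subject effect).
#' @export
generateCohort <- function(nSubjects, earlyProfile, lateProfile,
                           seed = 1L, subjectEffectSD = 0.15) {
  stopifnot(nSubjects >= 1)
  effects <- .withSeed(seed, exp(rnorm(nSubjects, 0, subjectEffectSD)))
  out <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    sid <- sprintf("subj%02d", i)
    ep <- earlyProfile; lp <- lateProfile
    ep@amplitudes <- ep@amplitudes * effects[i]
    lp@amplitudes <- lp@amplitudes * effects[i]
    ep@seed <- as.integer((seed * 1000L + 2L * i) %% .Machine$integer.max)
    lp@seed <- as.integer((seed * 1000L + 2L * i + 1L) %% .Machine$integer.max)
    ge <- generateSequence(ep, subjectID = paste0(sid, "_early"))
    gl <- generateSequence(lp, subjectID = paste0(sid, "_late"))
    out[[i]] <- list(subject = sid, early = ge$seq, late = gl$seq,
                     truth = list(early = ge$truth, late = gl$truth,
                                  subjectEffect = effects[i]))
  }
  names(out) <- vapply(out, `[[`, character(1), "subject")
  out
}

#' Occlude a body region in part of a recording
#'
#' Emulates partial covering (blankets, interventions) by marking the
#' region's landmarks invalid (`NA`) in a random fraction of frames.
#' Downstream quantifiers drop affected frames in views containing
#' those landmarks, so fully occluding a region makes that region's
#' quantification fail with insufficient data while other regions are
#' unaffected.
#'
#' @param seq a [PoseSequence-class].
#' @param region region to occlude.
#' @param fraction fraction of frames to occlude, in \[0, 1\].
#' @param seed integer seed for the frame mask (deterministic).
#' @param map optional region-map override.
#' @return The degraded [PoseSequence-class].
#' @export
occludeRegion <- function(seq, region, fraction, seed = 1L, map = NULL) {
  if (fraction < 0 || fraction > 1)
    .nmStop("neomotion_parameter_error", "fraction must be in [0, 1]")
  if (fraction == 0) return(seq)
  idx <- regionIndices(region, map)
  rows <- match(landmarkNames()[idx + 1L], rownames(seq))
  rows <- rows[!is.na(rows)]
  n <- nFrames(seq)
  nOcc <- round(fraction * n)
  cols <- .withSeed(seed, sort(sample.int(n, nOcc)))
  for (a in c("x", "y", "z")) {
    m <- SummarizedExperiment::assay(seq, a)
    m[rows, cols] <- NA_real_
    SummarizedExperiment::assay(seq, a) <- m
  }
  seq
}
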