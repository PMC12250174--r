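#' PoseSequence: a landmark time series
#'
#' @description
#' `PoseSequence` holds one contactlessly recorded pose time series for a
#' single subject/session. It extends
#' [SummarizedExperiment::SummarizedExperiment] with three assays —
#' `"x"`, `"y"` and `"z"` — each a landmarks-by-frames numeric matrix.
#' Rows are body landmarks (up to 33, named after the standard 33-point
#' pose convention), columns are video frames. `x` and `y` are
#' normalized image coordinates in \[0, 1\] (0 = left/top edge), `z` is
#' a signed relative depth (negative = closer to the camera); all three
#' are dimensionless. Frame timestamps (Unix epoch milliseconds) live in
#' `colData`, and the derived frame rate, subject identifier and current
#' region restriction in `metadata`.
#'
#' Region restriction ([projectRegion()]) and time windowing
#' ([segmentWindows()]) are row and column subsetting of this container,
#' so all `SummarizedExperiment` machinery applies.
#'
#' @section Frame rate:
#' `frameRate()` is derived at construction as `1000 / median
#' inter-frame gap in ms`; the median makes it robust to occasional
#' dropped frames. Subsetting keeps the parent's frame rate.
#'
#' @name PoseSequence-class
#' @aliases PoseSequence
#' @exportClass PoseSequence
setClass("PoseSequence", contains = "SummarizedExperiment")

# The 33 landmark names of the standard pose convention, index 0..32.
.LANDMARK_NAMES <- c(
  "nose", "left_eye_inner", "left_eye", "left_eye_outer",
  "right_eye_inner", "right_eye", "right_eye_outer", "left_ear",
  "right_ear", "mouth_left", "mouth_right", "left_shoulder",
  "right_shoulder", "left_elbow", "right_elbow", "left_wrist",
  "right_wrist", "left_pinky", "right_pinky", "left_index",
  "right_index", "left_thumb", "right_thumb", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle", "left_heel",
  "right_heel", "left_foot_index", "right_foot_index")

#' Landmark names of the 33-point pose convention
#'
#' @return Character vector of length 33; element `i` names landmark
#'   index `i - 1` (indices are 0-based in the pose convention).
#' @examples
#' landmarkNames()[1]   # "nose"
#' @export
landmarkNames <- function() .LANDMARK_NAMES

setValidity("PoseSequence", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("x", "y", "z") %in% an))
    msgs <- c(msgs, "assays must include 'x', 'y' and 'z'")
  if (nrow(object) < 1L || nrow(object) > 33L)
    msgs <- c(msgs, "between 1 and 33 landmarks expected")
  cd <- SummarizedExperiment::colData(object)
  if (!"timestamp_ms" %in% colnames(cd)) {
    msgs <- c(msgs, "colData must contain 'timestamp_ms'")
  } else if (ncol(object) > 0L) {
    ts <- cd$timestamp_ms
    if (any(!is.finite(ts)) || any(ts <= 0))
      msgs <- c(msgs, "timestamps must be finite and strictly positive")
    else if (ncol(object) > 1L && any(diff(ts) <= 0))
      msgs <- c(msgs, "timestamps must be strictly increasing")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PoseSequence
#'
#' @param x,y,z landmarks-by-frames numeric matrices of equal dimension.
#'   `x`/`y` are normalized image coordinates, `z` relative depth.
#' @param timestampMs numeric vector of frame timestamps in Unix epoch
#'   milliseconds, strictly increasing, one per frame (column).
#' @param subjectID opaque subject/session identifier.
#' @param region name of the body region the rows represent
#'   (`"whole_body"` for a full 33-landmark recording).
#' @param nRejected number of input rows dropped by validation (kept as
#'   provenance in `metadata`).
#' @return A [PoseSequence-class] object. The frame rate is derived as
#'   `1000 / median(diff(timestampMs))`.
#' @examples
#' n <- 5
#' ps <- PoseSequence(
#'   x = matrix(0.5, 33, n), y = matrix(0.5, 33, n),
#'   z = matrix(0, 33, n), timestampMs = seq(200, by = 200, length.out = n),
#'   subjectID = "demo")
#' frameRate(ps)   # 5 fps
#' @export
PoseSequence <- function(x, y, z, timestampMs, subjectID = "",
                         region = "whole_body", nRejected = 0L) {
  x <- as.matrix(x); y <- as.matrix(y); z <- as.matrix(z)
  stopifnot(all(dim(x) == dim(y)), all(dim(x) == dim(z)),
            length(timestampMs) == ncol(x))
  if (is.null(rownames(x)) && nrow(x) == 33L)
    rownames(x) <- rownames(y) <- rownames(z) <- .LANDMARK_NAMES
  fps <- if (length(timestampMs) > 1L)
    1000 / stats::median(diff(as.numeric(timestampMs))) else NA_real_
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = x, y = y, z = z),
    colData = S4Vectors::DataFrame(timestamp_ms = as.numeric(timestampMs)),
    metadata = list(subject_id = subjectID, fps = fps, region = region,
                    n_rejected = as.integer(nRejected)))
  new("PoseSequence", se)
}

#' @rdname neomotion-generics
#' @export
setMethod("timestamps", "PoseSequence", function(x)
  SummarizedExperiment::colData(x)$timestamp_ms)

#' @rdname neomotion-generics
#' @export
setMethod("frameRate", "PoseSequence", function(x)
  S4Vectors::metadata(x)$fps)

#' @rdname neomotion-generics
#' @export
setMethod("subjectID", "PoseSequence", function(x)
  S4Vectors::metadata(x)$subject_id)

#' @rdname neomotion-generics
#' @export
setMethod("nFrames", "PoseSequence", function(x) ncol(x))

#' @rdname neomotion-generics
#' @export
setMethod("nLandmarks", "PoseSequence", function(x) nrow(x))

#' @rdname neomotion-generics
#' @export
setMethod("regionName", "PoseSequence", function(x)
  S4Vectors::metadata(x)$region)

#' Extract coordinate matrices from a PoseSequence
#'
#' @param object a [PoseSequence-class].
#' @param which one of `"x"`, `"y"`, `"z"`.
#' @return A landmarks-by-frames numeric matrix.
#' @examples
#' ps <- PoseSequence(matrix(0.4, 2, 3), matrix(0.6, 2, 3),
#'                    matrix(0, 2, 3), c(100, 200, 300))
#' dim(poseCoords(ps, "x"))
#' @export
poseCoords <- function(object, which = c("x", "y", "z")) {
  which <- match.arg(which)
  SummarizedExperiment::assay(object, which)
}

setMethod("show", "PoseSequence", function(object) {
  cat("PoseSequence:", subjectID(object), "\n")
  cat("  landmarks:", nLandmarks(object),
      sprintf("(region: %s)", regionName(object)), "\n")
  ts <- timestamps(object)
  dur <- if (length(ts) > 1) (ts[length(ts)] - ts[1]) / 1000 else 0
  cat(sprintf("  frames: %d (%.1f s @ %.2f fps)\n", nFrames(object),
              dur, frameRate(object)))
  if (S4Vectors::metadata(object)$n_rejected > 0L)
    cat("  rejected input rows:", S4Vectors::metadata(object)$n_rejected, "\n")
  invisible(NULL)
})
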