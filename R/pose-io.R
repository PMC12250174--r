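#' Read a landmark CSV file
#'
#' @description
#' Reads one pose recording: a header CSV with a `timestamp` column
#' (Unix epoch milliseconds) and 33 landmark columns in landmark-index
#' order (0..32). Two cell dialects are accepted:
#'
#' * tuple dialect — each landmark cell is a `"(x,y,z)"` string
#'   (parentheses/brackets optional, `,` or `;` separated);
#' * flat dialect — 99 numeric columns `x0,y0,z0,...,x32,y32,z32`.
#'
#' `x`/`y` must be normalized image coordinates in \[0, 1\]; `z` is an
#' unbounded signed relative depth. Rows whose cells fail to parse, or
#' whose `x`/`y` fall outside \[0, 1\], are handled per `validation`:
#' `"reject"` (default) drops the row and logs a count — clamping would
#' fabricate motion at the image border — while `"clamp"` clips `x`/`y`
#' into \[0, 1\] (unparseable rows are still dropped).
#'
#' @param path path to the CSV file.
#' @param validation `"reject"` or `"clamp"`.
#' @param subjectID subject identifier; defaults to the file name
#'   without extension.
#' @return A [PoseSequence-class] with strictly increasing timestamps
#'   and the frame rate derived from the median inter-frame gap. The
#'   number of rejected rows is kept in the object's metadata.
#' @section Errors:
#' Missing/malformed columns raise a format error; fewer than 3 valid
#' rows an insufficient-data error; non-monotone timestamps an ordering
#' error naming the first offending row.
#' @seealso [writeLandmarkCSV()]
#' @export
readLandmarkCSV <- function(path, validation = c("reject", "clamp"),
                            subjectID = NULL) {
  validation <- match.arg(validation)
  if (!file.exists(path))
    .nmStop("neomotion_format_error", "file not found: %s", path)
  if (is.null(subjectID))
    subjectID <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df))
    .nmStop("neomotion_format_error",
            "missing 'timestamp' column in %s", path)
  lmCols <- setdiff(names(df), "timestamp")
  nr <- nrow(df)
  ts <- suppressWarnings(as.numeric(df$timestamp))

  if (length(lmCols) == 33L) {
    coords <- .parseTupleCells(df[lmCols])        # list of x,y,z n x 33
  } else if (length(lmCols) == 99L) {
    m <- suppressWarnings(
      matrix(as.numeric(as.matrix(df[lmCols])), nrow = nr))
    coords <- list(x = m[, seq(1, 99, 3), drop = FALSE],
                   y = m[, seq(2, 99, 3), drop = FALSE],
                   z = m[, seq(3, 99, 3), drop = FALSE])
  } else {
    .nmStop("neomotion_format_error",
            "expected 33 landmark columns (or 99 flat), found %d",
            length(lmCols))
  }

  x <- coords$x; y <- coords$y; z <- coords$z
  parseOK <- is.finite(ts) & ts > 0 &
    rowSums(!is.finite(x)) == 0L & rowSums(!is.finite(y)) == 0L &
    rowSums(!is.finite(z)) == 0L
  if (validation == "clamp") {
    x <- pmin(pmax(x, 0), 1)
    y <- pmin(pmax(y, 0), 1)
    valid <- parseOK
  } else {
    inRange <- rowSums(x < 0 | x > 1, na.rm = TRUE) == 0L &
      rowSums(y < 0 | y > 1, na.rm = TRUE) == 0L
    valid <- parseOK & inRange
  }
  nRejected <- sum(!valid)
  if (nRejected > 0L)
    message(sprintf("readLandmarkCSV: rejected %d of %d row(s) in %s",
                    nRejected, nr, basename(path)))
  if (sum(valid) < 3L)
    .nmStop("neomotion_insufficient_data",
            "fewer than 3 valid rows in %s (%d valid)", path, sum(valid))

  keep <- which(valid)
  tsK <- ts[keep]
  bad <- which(diff(tsK) <= 0)
  if (length(bad) > 0L)
    .nmStop("neomotion_ordering_error",
            "non-monotone timestamp at file row %d of %s",
            keep[bad[1] + 1L], path)

  PoseSequence(x = t(x[keep, , drop = FALSE]),
               y = t(y[keep, , drop = FALSE]),
               z = t(z[keep, , drop = FALSE]),
               timestampMs = tsK, subjectID = subjectID,
               nRejected = nRejected)
}

# Parse a data.frame of "(x,y,z)" character cells into n x 33 matrices.
.parseTupleCells <- function(df) {
  nr <- nrow(df); nc <- ncol(df)
  x <- y <- z <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    cells <- gsub("[][()\\s\"]", "", df[[j]], perl = TRUE)
    parts <- strsplit(cells, "[,;]")
    ok <- lengths(parts) == 3L
    if (any(ok)) {
      m <- suppressWarnings(
        matrix(as.numeric(unlist(parts[ok])), ncol = 3, byrow = TRUE))
      x[ok, j] <- m[, 1]; y[ok, j] <- m[, 2]; z[ok, j] <- m[, 3]
    }
  }
  list(x = x, y = y, z = z)
}

#' Write a PoseSequence as a landmark CSV file
#'
#' Writes the tuple dialect read by [readLandmarkCSV()]: a `timestamp`
#' column plus one `"(x,y,z)"` column per landmark, coordinates at 6
#' decimal places (the round-trip precision contract).
#'
#' @param seq a [PoseSequence-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLandmarkCSV <- function(seq, path) {
  x <- poseCoords(seq, "x"); y <- poseCoords(seq, "y")
  z <- poseCoords(seq, "z")
  n <- nFrames(seq); L <- nLandmarks(seq)
  cells <- matrix(sprintf("(%.6f,%.6f,%.6f)", t(x), t(y), t(z)), n, L)
  hdr <- if (L == 33L) paste0("landmark_", 0:32)
         else paste0("landmark_", seq_len(L) - 1L)
  df <- data.frame(format(timestamps(seq), scientific = FALSE,
                          trim = TRUE),
                   cells, stringsAsFactors = FALSE)
  names(df) <- c("timestamp", hdr)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
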