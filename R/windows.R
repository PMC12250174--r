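#' MovementSummary: per-window movement totals and their statistics
#'
#' One summary record per (subject, interval, region, method): the list
#' of per-window movement totals plus min, max, arithmetic mean,
#' population standard deviation and median. Retrieve the per-window
#' values with [windowValues()] and the whole record as a plain list
#' with [summaryRecord()].
#'
#' @name MovementSummary-class
#' @aliases MovementSummary
#' @exportClass MovementSummary
setClass("MovementSummary", representation(
  subject = "character", intervalS = "numeric", region = "character",
  method = "character", values = "numeric", minValue = "numeric",
  maxValue = "numeric", avg = "numeric", std = "numeric",
  median = "numeric"))

setValidity("MovementSummary", function(object) {
  if (length(object@values) == 0L) return("values must be non-empty")
  TRUE
})

#' @rdname neomotion-generics
#' @export
setMethod("windowValues", "MovementSummary", function(x) x@values)

#' @rdname neomotion-generics
#' @export
setMethod("subjectID", "MovementSummary", function(x) x@subject)

#' @rdname neomotion-generics
#' @export
setMethod("regionName", "MovementSummary", function(x) x@region)

#' @rdname neomotion-generics
#' @export
setMethod("methodName", "MovementSummary", function(x) x@method)

setMethod("show", "MovementSummary", function(object) {
  cat(sprintf("MovementSummary: %s / %gs / %s / %s\n", object@subject,
              object@intervalS, object@region, object@method))
  cat(sprintf("  %d window(s): avg %.6g, std %.6g, median %.6g [%.6g, %.6g]\n",
              length(object@values), object@avg, object@std,
              object@median, object@minValue, object@maxValue))
  invisible(NULL)
})

.newMovementSummary <- function(subject, intervalS, region, method,
                                values) {
  new("MovementSummary", subject = subject, intervalS = intervalS,
      region = region, method = method, values = values,
      minValue = min(values), maxValue = max(values),
      avg = mean(values), std = .popSD(values),
      median = stats::median(values))
}

#' Summary record as a plain list (the persisted JSON schema)
#'
#' @param x a [MovementSummary-class].
#' @return Named list with keys `subject`, `interval_s`, `region`,
#'   `method`, `values`, `min_value`, `max_value`, `avg`, `std`,
#'   `median`, `n_windows`.
#' @export
summaryRecord <- function(x) {
  list(subject = x@subject, interval_s = x@intervalS, region = x@region,
       method = x@method, values = x@values, min_value = x@minValue,
       max_value = x@maxValue, avg = x@avg, std = x@std,
       median = x@median, n_windows = length(x@values))
}

#' Segment a sequence into fixed-duration time windows
#'
#' Splits a recording into consecutive, non-overlapping windows of
#' exactly `intervalS` seconds by timestamp (half-open
#' `[t0, t0 + interval)`, so windowing is robust to variable frame
#' rates). The trailing partial window is discarded — padding it would
#' bias totals downward. Windows retaining fewer than 2 frames are
#' dropped with a message. Transitions that straddle a window boundary
#' belong to neither window, keeping windows independent.
#'
#' @param seq a [PoseSequence-class].
#' @param intervalS window length in seconds (the study intervals are
#'   30, 60, 120 and 180 s; any positive value is accepted).
#' @return List of [PoseSequence-class] window views. If the recording
#'   is shorter than one interval, an empty list with a warning.
#' @examples
#' ts <- seq(200, by = 200, length.out = 926)   # 185 s at 5 fps
#' ps <- PoseSequence(matrix(0.5, 1, 926), matrix(0.5, 1, 926),
#'                    matrix(0, 1, 926), ts)
#' length(segmentWindows(ps, 30))   # 6
#' @export
segmentWindows <- function(seq, intervalS) {
  if (!is.numeric(intervalS) || length(intervalS) != 1L || intervalS <= 0)
    .nmStop("neomotion_parameter_error", "intervalS must be positive")
  ts <- timestamps(seq)
  durS <- (ts[length(ts)] - ts[1]) / 1000
  nWin <- floor(durS / intervalS)
  if (nWin < 1L) {
    .nmWarn("neomotion_short_sequence",
            "sequence (%.1f s) shorter than interval (%g s): 0 windows",
            durS, intervalS)
    return(list())
  }
  w <- intervalS * 1000
  out <- vector("list", nWin)
  dropped <- 0L
  for (k in seq_len(nWin)) {
    lo <- ts[1] + (k - 1) * w
    sel <- ts >= lo & ts < lo + w
    if (sum(sel) < 2L) {
      dropped <- dropped + 1L
      out[k] <- list(NULL)
    } else {
      out[[k]] <- seq[, sel]
    }
  }
  if (dropped > 0L)
    message(sprintf("segmentWindows: dropped %d window(s) with < 2 frames",
                    dropped))
  out[!vapply(out, is.null, logical(1))]
}

#' Windowed movement summary for one subject/interval/region/method
#'
#' Segments the recording into `intervalS`-second windows, restricts
#' each to `region`, applies the quantifier and collects the per-window
#' totals and their statistics (population standard deviation).
#'
#' @inheritParams motionTotal
#' @param intervalS window length in seconds.
#' @param region region name (see [regionNames()]).
#' @param map optional region-map override.
#' @param .contribs optional precomputed per-transition contribution
#'   vector for pairwise methods (internal fast path used by
#'   [emitSummaryFiles()]; results are identical to the direct path).
#' @return A [MovementSummary-class].
#' @export
summarizeMovement <- function(seq, intervalS, region, method,
                              params = list(), map = NULL,
                              .contribs = NULL) {
  params <- .defaultParams(params)
  proj <- projectRegion(seq, region, map)
  wins <- withCallingHandlers(
    segmentWindows(proj, intervalS),
    neomotion_short_sequence = function(w) invokeRestart("muffleWarning"))
  if (length(wins) == 0L)
    .nmStop("neomotion_empty_summary",
            "no complete %g s window in sequence '%s'", intervalS,
            subjectID(seq))
  vals <- vapply(wins, function(w) {
    if (!is.null(.contribs)) {
      .windowTotalFromContribs(w, .contribs, params, method)
    } else {
      motionValue(motionTotal(w, method, params))
    }
  }, numeric(1))
  .newMovementSummary(subjectID(seq), intervalS, region, method, vals)
}

# Fast path: sum cached per-transition contributions for the frames of a
# window view. `contribs` must come from .sequenceContribs() on the same
# projected, validity-filtered sequence; equality with the direct path is
# exact because per-transition values do not depend on the windowing.
.windowTotalFromContribs <- function(win, contribs, params, method) {
  sel <- match(timestamps(win), contribs$ts)
  vf <- !is.na(sel)
  pos <- sel[vf]
  if (length(pos) < 2L) return(0)       # should not occur for clean data
  stencil <- method %in% .STENCIL_METHODS
  # transitions/stencils fully inside the window = consecutive positions
  runs <- pos[-1] == pos[-length(pos)] + 1L
  if (!all(runs)) pos <- pos[c(TRUE, runs)]    # defensive; contiguous anyway
  ts <- contribs$ts[pos]
  if (stencil) {
    idx <- pos[seq_len(max(length(pos) - 2L, 0L))]
    vals <- contribs$values[idx]
  } else {
    idx <- pos[-length(pos)]
    vals <- contribs$values[idx]
  }
  if (length(vals) == 0L) return(0)
  .assembleTotal(vals, ts, params$gapFactor, stencil)$value
}

# Precompute per-transition contributions for one projected region view.
.sequenceContribs <- function(proj, method, params) {
  vf <- .validFrames(proj)
  seq <- vf$seq
  sc <- .stepContribs(seq, method, params)
  list(ts = timestamps(seq), values = sc$values)
}

#' Emit the per-combination summary JSON files for a cohort
#'
#' Writes one JSON file per (subject, interval, region, method)
#' combination — the structured output of the quantification study; for
#' 10 subjects, 4 intervals, 9 regions and 9 methods that is 3240
#' files. Filenames follow
#' `<subject>__<interval_s>s__<region>__<method>.json` and the JSON
#' schema of [summaryRecord()].
#'
#' @param cohort named list of [PoseSequence-class] objects (names are
#'   subject identifiers; unnamed lists use each sequence's own
#'   subject id).
#' @param intervals numeric vector of window lengths in seconds.
#' @param regions character vector of region names.
#' @param methods character vector of method tokens.
#' @param outdir output directory (created if needed).
#' @param params method parameters as in [motionTotal()].
#' @param map optional region-map override.
#' @return Number of files written (`subjects x intervals x regions x
#'   methods`), invisibly the paths as an attribute.
#' @export
emitSummaryFiles <- function(cohort, intervals = c(30, 60, 120, 180),
                             regions = regionNames(tableOrder = TRUE),
                             methods = methodNames(), outdir,
                             params = list(), map = NULL) {
  params <- .defaultParams(params)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    .nmStop("neomotion_io_error", "cannot create output dir %s", outdir)
  if (is.null(names(cohort)))
    names(cohort) <- vapply(cohort, subjectID, character(1))
  paths <- character(0)
  for (sid in names(cohort)) {
    seq <- cohort[[sid]]
    for (region in regions) {
      proj <- projectRegion(seq, region, map)
      # farneback transitions are expensive: compute once per region and
      # reuse across intervals (exact, transition values are windowless)
      cache <- list()
      if ("farneback" %in% methods)
        cache$farneback <- .sequenceContribs(proj, "farneback", params)
      for (intervalS in intervals) {
        for (method in methods) {
          ms <- summarizeMovement(seq, intervalS, region, method,
                                  params = params, map = map,
                                  .contribs = cache[[method]])
          ms@subject <- sid
          fn <- sprintf("%s__%gs__%s__%s.json", sid, intervalS, region,
                        method)
          fp <- file.path(outdir, fn)
          jsonlite::write_json(summaryRecord(ms), fp, auto_unbox = TRUE,
                               digits = NA, pretty = TRUE)
          paths <- c(paths, fp)
        }
      }
    }
  }
  structure(length(paths), paths = paths)
}

#' Re-read a summary JSON file
#'
#' @param path path to a file written by [emitSummaryFiles()].
#' @return A [MovementSummary-class].
#' @export
readSummaryJSON <- function(path) {
  rec <- jsonlite::fromJSON(path)
  .newMovementSummary(rec$subject, rec$interval_s, rec$region,
                      rec$method, as.numeric(rec$values))
}
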