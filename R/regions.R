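#' Body-region decomposition of the 33-landmark pose
#'
#' @description
#' Movement is quantified for the whole body and for eight body regions:
#' head, left/right arm, trunk, left/right leg, and the upper/lower body
#' halves. Landmark indices follow the standard 33-point pose
#' convention (0-based):
#'
#' * `whole_body`: 0–32
#' * `head`: 0–10 (face landmarks)
#' * `left_arm`: 11, 13, 15, 17, 19, 21 (shoulder to fingers)
#' * `right_arm`: 12, 14, 16, 18, 20, 22
#' * `trunk`: 11, 12, 23, 24 (shoulders and hips)
#' * `left_leg`: 23, 25, 27, 29, 31 (hip to foot)
#' * `right_leg`: 24, 26, 28, 30, 32
#' * `upper_body`: 0–22 (waist up)
#' * `lower_body`: 23–32 (waist down)
#'
#' `upper_body` and `lower_body` partition the whole body. The table can
#' be overridden from a JSON file (see [loadRegionMap()]), e.g. for
#' 2D-only or reduced landmark schemes.
#'
#' @name regions
NULL

.REGION_MAP <- list(
  whole_body = 0:32,
  head       = 0:10,
  left_arm   = c(11L, 13L, 15L, 17L, 19L, 21L),
  right_arm  = c(12L, 14L, 16L, 18L, 20L, 22L),
  trunk      = c(11L, 12L, 23L, 24L),
  left_leg   = c(23L, 25L, 27L, 29L, 31L),
  right_leg  = c(24L, 26L, 28L, 30L, 32L),
  upper_body = 0:22,
  lower_body = 23:32
)

# Reporting order used in cohort tables (whole body first).
.REGIONS_TABLE_ORDER <- c("whole_body", "head", "left_arm", "right_arm",
                          "left_leg", "right_leg", "trunk", "upper_body",
                          "lower_body")

#' Region names
#'
#' @param tableOrder if `TRUE`, return regions in the column order used
#'   by cohort tables (whole body, head, arms, legs, trunk, body
#'   halves); otherwise in definition order.
#' @return Character vector of the nine region names.
#' @examples
#' regionNames()
#' @export
regionNames <- function(tableOrder = FALSE) {
  if (tableOrder) .REGIONS_TABLE_ORDER else names(.REGION_MAP)
}

#' Landmark indices of a body region
#'
#' @param name region name, one of [regionNames()].
#' @param map optional region map (named list of 0-based integer
#'   vectors) overriding the built-in table, e.g. from
#'   [loadRegionMap()].
#' @return Sorted integer vector of 0-based landmark indices.
#' @examples
#' regionIndices("left_leg")     # 23 25 27 29 31
#' length(regionIndices("whole_body"))   # 33
#' @export
regionIndices <- function(name, map = NULL) {
  map <- if (is.null(map)) .REGION_MAP else map
  if (!name %in% names(map))
    .nmStop("neomotion_lookup_error", "unknown region '%s'", name)
  sort(as.integer(map[[name]]))
}

#' Load a region-map override from JSON
#'
#' The file must hold an object `{region_name: [indices], ...}` with
#' 0-based landmark indices. Missing regions fall back to the built-in
#' table; indices must lie in 0..32.
#'
#' @param path path to a JSON file.
#' @return Named list of integer vectors usable as the `map` argument of
#'   [regionIndices()] and [projectRegion()].
#' @export
loadRegionMap <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)))
    .nmStop("neomotion_format_error", "region map must be a JSON object")
  map <- .REGION_MAP
  for (nm in names(raw)) {
    idx <- as.integer(raw[[nm]])
    if (any(is.na(idx)) || any(idx < 0L) || any(idx > 32L))
      .nmStop("neomotion_format_error",
              "region '%s': indices must lie in 0..32", nm)
    map[[nm]] <- sort(unique(idx))
  }
  map
}

#' Restrict a PoseSequence to a body region
#'
#' Returns a view of `seq` whose rows are the region's landmarks (same
#' timestamps and frame rate). Projection is idempotent, and projecting
#' onto `whole_body` returns a full recording unchanged.
#'
#' @param seq a [PoseSequence-class].
#' @param region region name, one of [regionNames()].
#' @param map optional region-map override (see [loadRegionMap()]).
#' @return A [PoseSequence-class] restricted to the region's landmarks.
#'   Landmarks absent from `seq` (already-projected views) are silently
#'   skipped.
#' @examples
#' ps <- PoseSequence(matrix(0.5, 33, 4), matrix(0.5, 33, 4),
#'                    matrix(0, 33, 4), c(200, 400, 600, 800))
#' nLandmarks(projectRegion(ps, "trunk"))   # 4
#' @export
projectRegion <- function(seq, region, map = NULL) {
  idx <- regionIndices(region, map)
  want <- landmarkNames()[idx + 1L]
  keep <- intersect(want, rownames(seq))
  if (length(keep) == 0L)
    .nmStop("neomotion_lookup_error",
            "no landmarks of region '%s' present in sequence", region)
  out <- seq[keep, ]
  S4Vectors::metadata(out)$region <- region
  out
}
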