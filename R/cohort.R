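#' Admission-to-discharge percent change
#'
#' Percentage change in movement level between a subject's sessions
#' near NICU admission and near discharge:
#' `100 * (late - early) / early`, computed on the mean per-window
#' movement totals of the same subject, region, method and interval.
#' Positive values indicate more movement near discharge.
#'
#' @param early,late [MovementSummary-class] objects for the same
#'   subject/region/method/interval (early = near admission, late =
#'   near discharge; which sessions count as "near" is an explicit
#'   input, not inferred).
#' @return One-row `data.frame` with columns `subject`, `region`,
#'   `method`, `interval_s`, `early_level`, `late_level`, `pct`,
#'   `undefined`. A zero early level yields `pct = NA` with
#'   `undefined = TRUE` (flagged and excluded from cohort means).
#' @examples
#' # early mean 2, late mean 3 -> +50%
#' @export
percentChange <- function(early, late) {
  stopifnot(is(early, "MovementSummary"), is(late, "MovementSummary"))
  if (early@region != late@region || early@method != late@method ||
      early@intervalS != late@intervalS)
    .nmStop("neomotion_parameter_error",
            "early/late summaries must match region, method and interval")
  undef <- early@avg == 0
  if (undef)
    message(sprintf(
      "percentChange: zero early level for %s/%s/%s, flagged undefined",
      early@subject, early@region, early@method))
  data.frame(subject = early@subject, region = early@region,
             method = early@method, interval_s = early@intervalS,
             early_level = early@avg, late_level = late@avg,
             pct = if (undef) NA_real_ else
               100 * (late@avg - early@avg) / early@avg,
             undefined = undef, stringsAsFactors = FALSE)
}

#' Coefficient of variation
#'
#' `CV = 100 * sigma / mu` with `sigma` the population standard
#' deviation — relative variability on a percent scale, comparable
#' across movement scales and hence used to rank quantifiers.
#'
#' @param values numeric vector.
#' @return The CV in percent. Scale-invariant: `cv(k * v) == cv(v)` for
#'   `k > 0`.
#' @examples
#' coefficientOfVariation(c(2, 4))   # 33.33
#' @export
coefficientOfVariation <- function(values) {
  mu <- mean(values)
  if (mu == 0)
    .nmStop("neomotion_numeric_error",
            "coefficient of variation undefined for zero mean")
  100 * .popSD(values) / mu
}

#' Build the cohort percent-change table
#'
#' Aggregates per-subject percent changes into a methods-by-regions
#' table: each cell is the mean percent change over subjects (flagged
#' undefined values excluded), an `average` column holds the row mean
#' over the eight body regions (whole body excluded), and a `coef_var`
#' column the per-method coefficient of variation.
#'
#' @param changes `data.frame` of rows from [percentChange()].
#' @param cvBasis population over which each method's CV is computed:
#'   `"subject_whole_body"` (default) — across the per-subject
#'   whole-body percent changes; `"regions"` — across the eight
#'   region-mean cells of the row; `"none"` — `NA`. A single-subject
#'   cohort under the default yields CV 0.
#' @return `data.frame` with one row per method (canonical order) and
#'   columns `method`, the nine regions in table order, `average`,
#'   `coef_var`.
#' @export
buildCohortTable <- function(changes,
                             cvBasis = c("subject_whole_body", "regions",
                                         "none")) {
  cvBasis <- match.arg(cvBasis)
  stopifnot(is.data.frame(changes))
  changes <- changes[!changes$undefined & !is.na(changes$pct), ,
                     drop = FALSE]
  if (nrow(changes) == 0L)
    .nmStop("neomotion_insufficient_data", "no usable percent changes")
  methods <- intersect(.METHODS, unique(changes$method))
  regions <- .REGIONS_TABLE_ORDER
  partRegions <- setdiff(regions, "whole_body")
  rows <- lapply(methods, function(m) {
    sub <- changes[changes$method == m, , drop = FALSE]
    cells <- vapply(regions, function(r) {
      v <- sub$pct[sub$region == r]
      if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1))
    avg <- mean(cells[partRegions], na.rm = TRUE)
    cv <- switch(cvBasis,
      subject_whole_body = {
        v <- sub$pct[sub$region == "whole_body"]
        if (length(v) < 2L) 0 else coefficientOfVariation(v)
      },
      regions = coefficientOfVariation(cells[partRegions]),
      none = NA_real_)
    c(cells, average = avg, coef_var = cv)
  })
  out <- data.frame(method = methods, do.call(rbind, rows),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("method", regions, "average", "coef_var")
  out
}

#' Cohort table from published per-method region values
#'
#' Builds the same table as [buildCohortTable()] directly from a matrix
#' of already-aggregated percent changes (one value per method and
#' region), recomputing the derived `average` column. Used to
#' cross-check the package's aggregation arithmetic against published
#' cohort tables.
#'
#' @param df `data.frame` with a `method` column and the nine region
#'   columns in table order (as read from
#'   `inst/extdata/reference_cohort_table.csv`).
#' @param cvBasis as in [buildCohortTable()]; the default here is
#'   `"regions"` since per-subject values are not available.
#' @return As [buildCohortTable()].
#' @export
cohortTableFromValues <- function(df, cvBasis = "regions") {
  regions <- intersect(.REGIONS_TABLE_ORDER, names(df))
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(subject = "published", region = regions,
               method = df$method[i], interval_s = 30,
               early_level = 1, late_level = 1,
               pct = as.numeric(unlist(df[i, regions])), undefined = FALSE,
               stringsAsFactors = FALSE)
  }))
  buildCohortTable(long, cvBasis = cvBasis)
}

#' Region-versus-whole-body similarity
#'
#' For every method and body region, the relative difference between
#' the region's cohort-mean value and the whole-body value:
#' `100 * |region - whole| / whole`. A region is an acceptable proxy
#' for the whole body when the difference is strictly below 10 percent.
#'
#' @param table cohort table from [buildCohortTable()] or
#'   [cohortTableFromValues()].
#' @param tolerancePct acceptability threshold (default 10, strict
#'   `<`).
#' @return `data.frame` with columns `method`, `region`,
#'   `rel_diff_pct`, `acceptable`. Whole-body rows (self-similarity 0)
#'   are included. A zero whole-body value yields `NA` (undefined
#'   cell).
#' @export
regionSimilarity <- function(table, tolerancePct = 10) {
  regions <- intersect(.REGIONS_TABLE_ORDER, names(table))
  out <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    whole <- table$whole_body[i]
    rel <- vapply(regions, function(r) {
      if (is.na(whole) || whole == 0) return(NA_real_)
      100 * abs(table[[r]][i] - whole) / whole
    }, numeric(1))
    data.frame(method = table$method[i], region = regions,
               rel_diff_pct = rel,
               acceptable = !is.na(rel) & rel < tolerancePct,
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}

#' Interval proportionality relative to a baseline window length
#'
#' For stationary movement, the total within a window scales with its
#' duration, so per-window means at 60/120/180 s are about 2/4/6 times
#' the 30 s mean. This function normalizes mean per-window totals to a
#' baseline interval, per method and region.
#'
#' @param summaries list of [MovementSummary-class] objects covering
#'   the baseline and target intervals.
#' @param baseline baseline interval in seconds (default 30).
#' @return `data.frame` with columns `method`, `region`, `interval_s`,
#'   `ratio` (mean per-window total divided by the baseline mean; the
#'   baseline row is 1 by construction).
#' @export
intervalProportionality <- function(summaries, baseline = 30) {
  df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(method = s@method, region = s@region,
               interval_s = s@intervalS, avg = s@avg,
               stringsAsFactors = FALSE)))
  agg <- stats::aggregate(avg ~ method + region + interval_s, df, mean)
  base <- agg[agg$interval_s == baseline, c("method", "region", "avg")]
  if (nrow(base) == 0L)
    .nmStop("neomotion_parameter_error",
            "no summaries at the baseline interval (%g s)", baseline)
  names(base)[3] <- "base_avg"
  m <- merge(agg, base, by = c("method", "region"))
  m$ratio <- m$avg / m$base_avg
  m <- m[order(m$method, m$region, m$interval_s),
         c("method", "region", "interval_s", "ratio")]
  row.names(m) <- NULL
  m
}

#' Heatmap of region-versus-whole-body similarity
#'
#' Renders the [regionSimilarity()] table as a base-graphics heatmap:
#' methods by regions, cell colour by relative difference (capped for
#' display), cells annotated with the percentage. Mirrors how such
#' proxy analyses are usually inspected.
#'
#' @param sim `data.frame` from [regionSimilarity()].
#' @param capPct colour-scale cap in percent (differences above are
#'   shown saturated; default 25).
#' @param main plot title.
#' @return Invisibly, the matrix that was drawn.
#' @export
plotRegionSimilarity <- function(sim, capPct = 25,
                                 main = "Region vs whole-body similarity") {
  methods <- unique(sim$method)
  regions <- setdiff(intersect(.REGIONS_TABLE_ORDER, unique(sim$region)),
                     "whole_body")
  m <- matrix(NA_real_, length(methods), length(regions),
              dimnames = list(methods, regions))
  for (i in seq_len(nrow(sim)))
    if (sim$region[i] %in% regions)
      m[sim$method[i], sim$region[i]] <- sim$rel_diff_pct[i]
  shown <- pmin(m, capPct)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  op <- graphics::par(mar = c(7, 8, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_along(regions), seq_along(methods),
                  t(shown[rev(seq_along(methods)), , drop = FALSE]),
                  col = pal, zlim = c(0, capPct), axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_along(regions), regions, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_along(methods), rev(methods), las = 1,
                 cex.axis = 0.8)
  for (i in seq_along(methods))
    for (j in seq_along(regions))
      graphics::text(j, length(methods) - i + 1,
                     sprintf("%.1f", m[i, j]), cex = 0.6)
  graphics::box()
  invisible(m)
}

#' Wall-time profile of the quantifiers
#'
#' Median wall time per method and region over repeated runs, reported
#' for orientation only (never asserted against reference values —
#' timings are machine-dependent).
#'
#' @param seq a [PoseSequence-class].
#' @param methods method tokens to profile.
#' @param regions region names to profile.
#' @param repeats number of repetitions per cell (at least 3).
#' @param params method parameters as in [motionTotal()].
#' @return `data.frame` with columns `method`, `region`, `median_ms`.
#' @export
timingProfile <- function(seq, methods = methodNames(),
                          regions = regionNames(tableOrder = TRUE),
                          repeats = 3, params = list()) {
  if (repeats < 3)
    .nmStop("neomotion_parameter_error", "repeats must be >= 3")
  grid <- expand.grid(method = methods, region = regions,
                      stringsAsFactors = FALSE)
  grid$median_ms <- vapply(seq_len(nrow(grid)), function(i) {
    proj <- projectRegion(seq, grid$region[i])
    times <- vapply(seq_len(repeats), function(k) {
      t0 <- proc.time()[["elapsed"]]
      motionTotal(proj, grid$method[i], params)
      (proc.time()[["elapsed"]] - t0) * 1000
    }, numeric(1))
    stats::median(times)
  }, numeric(1))
  grid
}
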