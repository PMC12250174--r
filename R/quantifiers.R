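#' MotionTotal: a cumulative movement total
#'
#' Result container for one quantifier applied to one landmark-sequence
#' view: the cumulative motion over all frame transitions (dimensionless
#' movement units; summed radians for angular displacement). Access with
#' [motionValue()], [nSteps()], [methodName()] and [regionName()];
#' `flags()` via `motionFlags()`.
#'
#' @name MotionTotal-class
#' @aliases MotionTotal
#' @exportClass MotionTotal
setClass("MotionTotal", representation(
  method = "character", region = "character", value = "numeric",
  nSteps = "integer", nExcluded = "integer", flags = "list"))

setValidity("MotionTotal", function(object) {
  if (length(object@value) != 1L || is.na(object@value) ||
      object@value < 0)
    return("value must be a single non-negative number")
  TRUE
})

#' @rdname neomotion-generics
#' @export
setMethod("motionValue", "MotionTotal", function(x) x@value)

#' @rdname neomotion-generics
#' @export
setMethod("nSteps", "MotionTotal", function(x) x@nSteps)

#' @rdname neomotion-generics
#' @export
setMethod("methodName", "MotionTotal", function(x) x@method)

#' @rdname neomotion-generics
#' @export
setMethod("regionName", "MotionTotal", function(x) x@region)

#' Diagnostic flags of a MotionTotal
#'
#' @param x a [MotionTotal-class].
#' @return Named list: `nExcluded` (transitions dropped by the
#'   frame-gap rule), plus method-specific entries such as
#'   `nIllConditioned` (Lucas-Kanade) or `covFallback` (Mahalanobis).
#' @export
motionFlags <- function(x) c(list(nExcluded = x@nExcluded), x@flags)

setMethod("show", "MotionTotal", function(object) {
  cat(sprintf("MotionTotal: %s on %s = %.6g (%d steps, %d excluded)\n",
              object@method, object@region, object@value, object@nSteps,
              object@nExcluded))
  invisible(NULL)
})

.newMotionTotal <- function(method, region, value, nSteps,
                            nExcluded = 0L, flags = list()) {
  new("MotionTotal", method = method, region = region,
      value = max(value, 0), nSteps = as.integer(nSteps),
      nExcluded = as.integer(nExcluded), flags = flags)
}

# ---- per-step distance measures ------------------------------------------

#' Per-step distance measures
#'
#' @description
#' The distance quantifiers accumulate, over every frame transition and
#' landmark, a norm of the displacement vector
#' `d = (x2 - x1, y2 - y1, z2 - z1)`:
#'
#' * Euclidean: `sqrt(dx^2 + dy^2 + dz^2)` — straight-line displacement;
#' * Manhattan: `|dx| + |dy| + |dz|` — sum of per-axis displacements;
#' * Chebyshev: `max(|dx|, |dy|, |dz|)` — dominant-axis displacement;
#' * Minkowski: `(|dx|^p + |dy|^p + |dz|^p)^(1/p)`, `p >= 1`; reduces to
#'   Manhattan at `p = 1` and Euclidean at `p = 2`, and approaches
#'   Chebyshev as `p` grows;
#' * Mahalanobis: `sqrt(d' S^-1 d)` with `S` the covariance of the
#'   pooled coordinate samples — displacement in units of the data's own
#'   spread, accounting for coordinate correlations.
#'
#' All accept a length-3 vector or an n-by-3 matrix of displacement
#' rows and return one non-negative value per displacement.
#'
#' @param d numeric length-3 vector or n-by-3 matrix of displacements.
#' @param p Minkowski order, a single number `>= 1`.
#' @param cov a [CovarianceModel-class] (or plain 3x3 matrix) for the
#'   Mahalanobis step.
#' @return Numeric vector of per-step distances.
#' @examples
#' stepEuclidean(c(1, 2, 2))     # 3
#' stepManhattan(c(1, -2, 2))    # 5
#' stepChebyshev(c(1, -2, 2))    # 2
#' stepMinkowski(c(1, -2, 2), p = 1)   # 5, Manhattan
#' @name step-distances
NULL

.asRows <- function(d) {
  if (is.matrix(d)) d else matrix(d, ncol = 3)
}

#' @rdname step-distances
#' @export
stepEuclidean <- function(d) {
  m <- .asRows(d)
  sqrt(rowSums(m * m))
}

#' @rdname step-distances
#' @export
stepManhattan <- function(d) {
  rowSums(abs(.asRows(d)))
}

#' @rdname step-distances
#' @export
stepChebyshev <- function(d) {
  m <- abs(.asRows(d))
  pmax(m[, 1], m[, 2], m[, 3])
}

#' @rdname step-distances
#' @export
stepMinkowski <- function(d, p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    .nmStop("neomotion_parameter_error", "Minkowski order p must be >= 1")
  m <- abs(.asRows(d))
  rowSums(m^p)^(1 / p)
}

#' @rdname step-distances
#' @export
stepMahalanobis <- function(d, cov) {
  Sinv <- .covInverse(cov)
  m <- .asRows(d)
  q <- rowSums((m %*% Sinv) * m)
  sqrt(pmax(q, 0))
}

# ---- covariance model ----------------------------------------------------

#' CovarianceModel: regularized coordinate covariance
#'
#' A 3x3 symmetric covariance of the pooled (x, y, z) coordinate samples
#' of an analysis window, with an optional ridge added to the diagonal
#' so the inverse needed by the Mahalanobis distance exists. If the
#' condition number exceeds `condThreshold` the ridge is
#' `ridgeScale * trace(S) / 3`; a fully degenerate window (all points
#' identical) falls back to the identity matrix and is flagged.
#'
#' @name CovarianceModel-class
#' @aliases CovarianceModel
#' @exportClass CovarianceModel
setClass("CovarianceModel", representation(
  S = "matrix", ridge = "numeric", flagged = "logical"))

setValidity("CovarianceModel", function(object) {
  if (!all(dim(object@S) == c(3L, 3L))) return("S must be 3x3")
  if (max(abs(object@S - t(object@S))) > 1e-8 * (1 + max(abs(object@S))))
    return("S must be symmetric")
  if (object@ridge < 0) return("ridge must be non-negative")
  TRUE
})

#' Fit a coordinate covariance model
#'
#' Pools every (x, y, z) coordinate sample over frames and landmarks of
#' the given sequence view (or takes an n-by-3 sample matrix directly)
#' and estimates the 3x3 covariance used by the Mahalanobis quantifier.
#'
#' @param data a [PoseSequence-class] view or an n-by-3 numeric matrix
#'   of coordinate samples.
#' @param condThreshold condition-number threshold above which a ridge
#'   is added (default 1e8).
#' @param ridgeScale ridge magnitude as a fraction of `trace(S)/3`
#'   (default 1e-9).
#' @return A [CovarianceModel-class]. `covMatrix()`, `covRidge()` and
#'   `covFlagged()` access the fit.
#' @examples
#' set.seed(1)
#' fitCovariance(matrix(rnorm(3000), ncol = 3))
#' @export
fitCovariance <- function(data, condThreshold = 1e8, ridgeScale = 1e-9) {
  if (is(data, "PoseSequence")) {
    if (nFrames(data) < 4L)
      .nmStop("neomotion_insufficient_data",
              "need >= 4 frames to fit a covariance model")
    samples <- cbind(as.vector(poseCoords(data, "x")),
                     as.vector(poseCoords(data, "y")),
                     as.vector(poseCoords(data, "z")))
  } else {
    samples <- as.matrix(data)
    if (ncol(samples) != 3L)
      .nmStop("neomotion_parameter_error", "sample matrix must be n x 3")
  }
  samples <- samples[rowSums(!is.finite(samples)) == 0L, , drop = FALSE]
  S <- stats::cov(samples)
  if (!all(is.finite(S)) || max(abs(S)) == 0) {
    return(new("CovarianceModel", S = diag(3), ridge = 0,
               flagged = TRUE))
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  kappa <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  ridge <- if (kappa > condThreshold)
    ridgeScale * sum(diag(S)) / 3 else 0
  new("CovarianceModel", S = S, ridge = ridge, flagged = FALSE)
}

#' @describeIn fitCovariance the fitted (unridged) covariance matrix.
#' @param model a [CovarianceModel-class].
#' @export
covMatrix <- function(model) model@S

#' @describeIn fitCovariance the ridge added before inversion.
#' @export
covRidge <- function(model) model@ridge

#' @describeIn fitCovariance `TRUE` if the degenerate identity fallback
#'   was used.
#' @export
covFlagged <- function(model) model@flagged

.covInverse <- function(cov) {
  if (is(cov, "CovarianceModel")) {
    M <- cov@S + cov@ridge * diag(3)
  } else {
    M <- as.matrix(cov)
  }
  inv <- tryCatch(solve(M), error = function(e)
    .nmStop("neomotion_numeric_error",
            "covariance not invertible after ridge: %s", conditionMessage(e)))
  inv
}

# ---- sequence-level machinery --------------------------------------------

# Drop frames containing any non-finite coordinate (occluded frames).
.validFrames <- function(seq) {
  bad <- colSums(!is.finite(poseCoords(seq, "x"))) > 0L |
    colSums(!is.finite(poseCoords(seq, "y"))) > 0L |
    colSums(!is.finite(poseCoords(seq, "z"))) > 0L
  list(seq = if (any(bad)) seq[, !bad] else seq,
       nDropped = sum(bad))
}

# Transition gaps in ms and the exclusion mask (gap > gapFactor * median).
.gapMask <- function(ts, gapFactor) {
  dt <- diff(ts)
  if (length(dt) == 0L) return(logical(0))
  dt > gapFactor * stats::median(dt)
}

# Per-transition (pairwise methods) or per-stencil (three-frame methods)
# contribution vector for one method on a cleaned sequence view.
.stepContribs <- function(seq, method, params) {
  X <- poseCoords(seq, "x"); Y <- poseCoords(seq, "y")
  Z <- poseCoords(seq, "z")
  n <- ncol(X)
  flags <- list()
  if (method %in% c("euclidean", "manhattan", "chebyshev", "minkowski",
                    "mahalanobis")) {
    dX <- X[, -1, drop = FALSE] - X[, -n, drop = FALSE]
    dY <- Y[, -1, drop = FALSE] - Y[, -n, drop = FALSE]
    dZ <- Z[, -1, drop = FALSE] - Z[, -n, drop = FALSE]
    perLm <- switch(method,
      euclidean = sqrt(dX^2 + dY^2 + dZ^2),
      manhattan = abs(dX) + abs(dY) + abs(dZ),
      chebyshev = pmax(abs(dX), abs(dY), abs(dZ)),
      minkowski = (abs(dX)^params$minkowskiP + abs(dY)^params$minkowskiP +
                     abs(dZ)^params$minkowskiP)^(1 / params$minkowskiP),
      mahalanobis = {
        cov <- params$mahalanobisCov
        if (is.null(cov))
          cov <- fitCovariance(seq, condThreshold = params$condThreshold,
                               ridgeScale = params$ridgeScale)
        if (is(cov, "CovarianceModel") && cov@flagged)
          flags$covFallback <- TRUE
        Sinv <- .covInverse(cov)
        q <- Sinv[1, 1] * dX^2 + Sinv[2, 2] * dY^2 + Sinv[3, 3] * dZ^2 +
          2 * (Sinv[1, 2] * dX * dY + Sinv[1, 3] * dX * dZ +
                 Sinv[2, 3] * dY * dZ)
        sqrt(pmax(q, 0))
      })
    vals <- colSums(perLm)
  } else if (method == "diffacc") {
    fps <- frameRate(seq)
    if (!is.finite(fps) || fps <= 0)
      .nmStop("neomotion_parameter_error", "fps must be positive")
    # second difference of position, scaled by fps (velocity change)
    A_x <- (X[, 3:n, drop = FALSE] - 2 * X[, 2:(n - 1), drop = FALSE] +
              X[, 1:(n - 2), drop = FALSE]) * fps
    A_y <- (Y[, 3:n, drop = FALSE] - 2 * Y[, 2:(n - 1), drop = FALSE] +
              Y[, 1:(n - 2), drop = FALSE]) * fps
    A_z <- (Z[, 3:n, drop = FALSE] - 2 * Z[, 2:(n - 1), drop = FALSE] +
              Z[, 1:(n - 2), drop = FALSE]) * fps
    vals <- colSums(abs(A_x) + abs(A_y) + abs(A_z))
  } else if (method == "angular") {
    ax <- X[, 2:(n - 1), drop = FALSE] - X[, 1:(n - 2), drop = FALSE]
    ay <- Y[, 2:(n - 1), drop = FALSE] - Y[, 1:(n - 2), drop = FALSE]
    az <- Z[, 2:(n - 1), drop = FALSE] - Z[, 1:(n - 2), drop = FALSE]
    bx <- X[, 3:n, drop = FALSE] - X[, 2:(n - 1), drop = FALSE]
    by <- Y[, 3:n, drop = FALSE] - Y[, 2:(n - 1), drop = FALSE]
    bz <- Z[, 3:n, drop = FALSE] - Z[, 2:(n - 1), drop = FALSE]
    dot <- ax * bx + ay * by + az * bz
    na <- sqrt(ax^2 + ay^2 + az^2)
    nb <- sqrt(bx^2 + by^2 + bz^2)
    denom <- na * nb
    cosv <- ifelse(denom > 0, pmin(pmax(dot / pmax(denom, 1e-300), -1), 1), 1)
    theta <- acos(cosv)
    theta[denom == 0] <- 0       # zero-length step: no turning angle
    vals <- colSums(abs(theta))
  } else if (method == "lucas_kanade") {
    # documented assembly: per landmark and interior frame, A has three
    # identical rows g = central-difference spatial gradient, b is the
    # forward temporal difference; v = pinv(A) b = g * sum(b) / (3|g|^2)
    gx <- (X[, 3:n, drop = FALSE] - X[, 1:(n - 2), drop = FALSE]) / 2
    gy <- (Y[, 3:n, drop = FALSE] - Y[, 1:(n - 2), drop = FALSE]) / 2
    gz <- (Z[, 3:n, drop = FALSE] - Z[, 1:(n - 2), drop = FALSE]) / 2
    bx <- X[, 3:n, drop = FALSE] - X[, 2:(n - 1), drop = FALSE]
    by <- Y[, 3:n, drop = FALSE] - Y[, 2:(n - 1), drop = FALSE]
    bz <- Z[, 3:n, drop = FALSE] - Z[, 2:(n - 1), drop = FALSE]
    g2 <- gx^2 + gy^2 + gz^2
    sb <- bx + by + bz
    ok <- g2 > params$lkGradEps
    scale <- ifelse(ok, sb / (3 * pmax(g2, params$lkGradEps)), 0)
    vnorm <- abs(scale) * sqrt(g2)
    flags$nIllConditioned <- sum(!ok & (abs(bx) + abs(by) + abs(bz)) > 0)
    vals <- colSums(vnorm)
  } else if (method == "farneback") {
    rp <- params$render; fp <- params$flow
    if (rp$width < 32L || rp$height < 32L)
      .nmStop("neomotion_parameter_error",
              "render resolution must be at least 32x32")
    vals <- farneback_pair_sums(X, Y, as.integer(rp$width),
                                as.integer(rp$height),
                                as.integer(rp$radius), rp$intensity,
                                fp$pyrScale, as.integer(fp$levels),
                                as.integer(fp$winsize),
                                as.integer(fp$iterations),
                                as.integer(fp$polyN), fp$polySigma)
  } else {
    .nmStop("neomotion_lookup_error", "unknown method '%s'", method)
  }
  list(values = vals, flags = flags)
}

# Sum a contribution vector under the frame-gap exclusion rule.
# Pairwise methods: contribution k spans frames (k, k+1), excluded if
# that gap is an outlier. Stencil methods: contribution k spans frames
# (k, k+1, k+2), excluded if either adjacent gap is.
.assembleTotal <- function(values, ts, gapFactor, stencil) {
  mask <- .gapMask(ts, gapFactor)
  if (stencil) {
    excl <- mask[-length(mask)] | mask[-1]
  } else {
    excl <- mask
  }
  list(value = sum(values[!excl]), nExcluded = sum(excl))
}

#' Cumulative motion total of a landmark sequence
#'
#' @description
#' Applies one of the nine motion quantifiers to a (possibly
#' region-restricted) [PoseSequence-class] and returns the cumulative
#' movement total over all frame transitions. Method tokens:
#' `euclidean`, `manhattan`, `chebyshev`, `minkowski`, `mahalanobis`,
#' `diffacc` (differential acceleration), `angular` (angular
#' displacement), `lucas_kanade`, `farneback`.
#'
#' Frames with any non-finite coordinate (e.g. occluded) are dropped
#' first. Transitions whose inter-frame gap exceeds `gapFactor` times
#' the median gap are excluded from the total (recording dropouts would
#' otherwise register as spurious motion) and counted in the flags.
#'
#' @param seq a [PoseSequence-class] (project with [projectRegion()]
#'   first to quantify one region).
#' @param method one of [methodNames()].
#' @param params named list of method parameters, merged over defaults:
#'   `minkowskiP` (3), `gapFactor` (3), `mahalanobisCov` (optional
#'   covariance override, e.g. `diag(3)`), `condThreshold` (1e8),
#'   `ridgeScale` (1e-9), `lkGradEps` (1e-12), `render` (list: `width`
#'   64, `height` 64, `radius` 3, `intensity` 255) and `flow` (list:
#'   `pyrScale` 0.5, `levels` 2, `winsize` 9, `iterations` 2, `polyN`
#'   5, `polySigma` 1.1) for the Farneback pipeline.
#' @return A [MotionTotal-class].
#' @examples
#' ps <- PoseSequence(matrix(c(0.1, 0.4), 1, 2),
#'                    matrix(c(0.1, 0.5), 1, 2),
#'                    matrix(0, 1, 2), c(100, 200), region = "demo")
#' motionValue(motionTotal(ps, "euclidean"))   # 0.5
#' @export
motionTotal <- function(seq, method, params = list()) {
  method <- match.arg(method, .METHODS)
  params <- .defaultParams(params)
  vf <- .validFrames(seq)
  seq <- vf$seq
  n <- nFrames(seq)
  needed <- if (method %in% .STENCIL_METHODS) 3L else 2L
  if (n < needed)
    .nmStop("neomotion_insufficient_data",
            "method '%s' needs >= %d frames, have %d", method, needed, n)
  sc <- .stepContribs(seq, method, params)
  asm <- .assembleTotal(sc$values, timestamps(seq), params$gapFactor,
                        stencil = method %in% .STENCIL_METHODS)
  flags <- sc$flags
  if (vf$nDropped > 0L) flags$nInvalidFrames <- vf$nDropped
  .newMotionTotal(method, regionName(seq), asm$value,
                  nSteps = n - (if (method %in% .STENCIL_METHODS) 2L else 1L),
                  nExcluded = asm$nExcluded, flags = flags)
}

#' Differential acceleration total
#'
#' Sums, over every interior frame, landmark and coordinate dimension,
#' the absolute change in velocity between the incoming and outgoing
#' frame transition, with velocities scaled by the frame rate:
#' `|((P[i+1] - P[i]) - (P[i] - P[i-1])) * fps|`. Uniform linear motion
#' contributes zero.
#'
#' @inheritParams motionTotal
#' @param fps optional frame-rate override; defaults to the sequence's
#'   derived rate.
#' @return A [MotionTotal-class].
#' @export
differentialAcceleration <- function(seq, fps = NULL, params = list()) {
  if (!is.null(fps)) {
    if (!is.numeric(fps) || fps <= 0)
      .nmStop("neomotion_parameter_error", "fps must be positive")
    S4Vectors::metadata(seq)$fps <- fps
  }
  motionTotal(seq, "diffacc", params)
}

#' Angular displacement total
#'
#' Sums the absolute turning angle of every landmark at every interior
#' frame: with successive displacement vectors `a = P[i] - P[i-1]` and
#' `b = P[i+1] - P[i]`, the angle is `acos(a.b / (|a||b|))` (cosine
#' clamped to \[-1, 1\]; zero-length steps contribute 0). The result is
#' in summed radians and is invariant to translation of the scene.
#'
#' @inheritParams motionTotal
#' @return A [MotionTotal-class].
#' @export
angularDisplacement <- function(seq, params = list())
  motionTotal(seq, "angular", params)

#' Lucas-Kanade landmark motion total
#'
#' Gradient-based motion estimate applied directly to landmark
#' coordinates over a three-frame stencil. Per landmark and interior
#' frame, spatial derivatives are central differences
#' `g = (P[i+1] - P[i-1]) / 2` and the temporal derivative is
#' `b = P[i+1] - P[i]`; the velocity solves the stacked gradient system
#' by pseudoinverse (`v = g * sum(b) / (3 |g|^2)`, the closed form for
#' the three identical gradient rows of the documented assembly) and
#' contributes `|v|`. Near-zero-gradient stencils contribute 0 and are
#' flagged as ill-conditioned; the quantifier never fails for data
#' reasons.
#'
#' @inheritParams motionTotal
#' @return A [MotionTotal-class].
#' @export
lucasKanadeMotion <- function(seq, params = list())
  motionTotal(seq, "lucas_kanade", params)
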