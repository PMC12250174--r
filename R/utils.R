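# Internal helpers: classed conditions, canonical tokens, tiny hash.

.nmStop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "neomotion_error")))
}

.nmWarn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(class, "neomotion_warning")))
}

# Canonical method tokens, in reporting order.
.METHODS <- c("euclidean", "manhattan", "chebyshev", "minkowski",
              "mahalanobis", "diffacc", "angular", "lucas_kanade",
              "farneback")

# Methods needing a three-frame stencil.
.STENCIL_METHODS <- c("diffacc", "angular", "lucas_kanade")

#' Motion quantification method tokens
#'
#' @return Character vector of the nine method tokens, in canonical
#'   reporting order.
#' @examples
#' methodNames()
#' @export
methodNames <- function() .METHODS

# Population standard deviation (divide by n).
.popSD <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# FNV-1a 32-bit hash of a character scalar, hex string. The state is
# kept as a double in [0, 2^32); the xor touches only the low byte and
# the modular multiply is split to stay within exact double precision.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# Default quantifier parameters; user params override.
.defaultParams <- function(params = list()) {
  def <- list(
    minkowskiP = 3,
    gapFactor = 3,
    mahalanobisCov = NULL,
    condThreshold = 1e8,
    ridgeScale = 1e-9,
    lkGradEps = 1e-12,
    render = list(width = 64L, height = 64L, radius = 3L, intensity = 255),
    flow = list(pyrScale = 0.5, levels = 2L, winsize = 9L,
                iterations = 2L, polyN = 5L, polySigma = 1.1)
  )
  for (nm in names(params)) {
    if (nm %in% c("render", "flow") && is.list(params[[nm]])) {
      for (k in names(params[[nm]])) def[[nm]][[k]] <- params[[nm]][[k]]
    } else {
      def[[nm]] <- params[[nm]]
    }
  }
  def
}
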